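# Fixture builders used across the suite. Everything is constructed in
# code; no binary fixtures.

# one atom row
atom_row <- function(serial, name, element, res_name, res_seq, chain,
                     x, y, z, charge = 0, radius = NA_real_) {
  data.frame(serial = serial, name = name, element = element,
             res_name = res_name, res_seq = res_seq, chain = chain,
             x = x, y = y, z = z, charge = charge, radius = radius,
             het = FALSE, stringsAsFactors = FALSE)
}

# toy peptide: residues spaced 4 A apart along x, each with backbone
# N/CA/C/O + CB and the reduced-model charge-site atoms its type needs
SIDE_ATOMS <- list(
  ARG = c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
  LYS = c("CG", "CD", "CE", "NZ"),
  ASP = c("CG", "OD1", "OD2"),
  GLU = c("CG", "CD", "OE1", "OE2")
)

toy_peptide <- function(seq1, chain = "A", res_seq = NULL, id = "toy") {
  letters1 <- strsplit(seq1, "")[[1]]
  res3 <- vapply(letters1, function(l) {
    epogram:::AA3[match(l, epogram:::AA1)]
  }, character(1))
  if (is.null(res_seq)) res_seq <- seq_along(letters1)
  rows <- list()
  serial <- 0L
  for (i in seq_along(letters1)) {
    x0 <- 4 * (i - 1)
    base <- list(N = c(0, 0, 0), CA = c(1.2, 0.6, 0), C = c(2.4, 0, 0),
                 O = c(2.4, -1.2, 0), CB = c(1.2, 1.4, 1.1))
    extra <- SIDE_ATOMS[[res3[i]]]
    if (!is.null(extra)) {
      for (k in seq_along(extra)) {
        base[[extra[k]]] <- c(1.2 + 0.5 * k, 1.4 + 0.8 * k, 1.1)
      }
    }
    if (res3[i] == "GLY") base$CB <- NULL
    for (nm in names(base)) {
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- atom_row(
        serial, nm, substr(nm, 1, 1), res3[i], res_seq[i], chain,
        x0 + base[[nm]][1], base[[nm]][2], base[[nm]][3])
    }
  }
  new_structure(do.call(rbind, rows), id = id)
}

# single pseudo-atom "structure" for solver/skin tests
point_structure <- function(x = 0, y = 0, z = 0, q = 1, r = 2,
                            id = "point") {
  new_structure(atom_row(1L, "X", "C", "UNK", 1L, "A", x, y, z,
                         charge = q, radius = r), id = id)
}

two_point_structure <- function(p1, p2, q = c(1, 1), r = c(2, 2)) {
  new_structure(rbind(
    atom_row(1L, "X1", "C", "UNK", 1L, "A", p1[1], p1[2], p1[3],
             charge = q[1], radius = r[1]),
    atom_row(2L, "X2", "C", "UNK", 2L, "A", p2[1], p2[2], p2[3],
             charge = q[2], radius = r[2])), id = "two-point")
}

# brute-force skin oracle: scan every grid point against every atom
brute_force_skin <- function(s, g, sigma, delta) {
  ax <- epogram:::grid_axes(g)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  xyz <- coords(s)
  rad <- s$atoms$radius
  members <- vapply(seq_len(nrow(pts)), function(i) {
    sd <- min(sqrt(colSums((t(xyz) - pts[i, ])^2)) - rad)
    sd >= sigma && sd <= sigma + delta
  }, logical(1))
  # expand.grid varies x fastest == R array layout
  array(members, g$dims)
}

# uniform potential grid from a function of (x, y, z)
grid_from_function <- function(g, f) {
  ax <- epogram:::grid_axes(g)
  vals <- array(0, g$dims)
  for (k in seq_len(g$dims[3])) {
    for (j in seq_len(g$dims[2])) {
      vals[, j, k] <- f(ax[[1]], ax[[2]][j], ax[[3]][k])
    }
  }
  potential_grid(g, vals)
}

expect_silent_or_warning <- function(expr) {
  tryCatch(expr, warning = function(w) invisible(NULL))
}
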