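## Regular scalar grids: the container for electrostatic potentials
## (kT/e) and for boolean region masks.  OpenDX scalar files (the
## standard APBS grid format) are read and written for interchange.

#' Define a regular grid
#'
#' @param origin 3-vector, Angstrom: position of grid node (1,1,1).
#' @param spacing scalar grid spacing h, Angstrom.
#' @param dims integer 3-vector (nx, ny, nz), each >= 2.
#' @return an object of class `"GridSpec"`.
#' @export
grid_spec <- function(origin, spacing, dims) {
  stopifnot(length(origin) == 3, length(dims) == 3)
  if (spacing <= 0) stop("grid spacing must be positive")
  dims <- as.integer(dims)
  if (any(dims < 2)) stop("grid dims must each be >= 2")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims), class = "GridSpec")
}

#' Grid enclosing a structure with padding
#'
#' @param s a `Structure`.
#' @param spacing grid spacing h, Angstrom (default 1.0).
#' @param padding clearance beyond the atom extent, Angstrom (default 15).
#' @return a [grid_spec()].
#' @export
grid_from_structure <- function(s, spacing = 1.0, padding = 15) {
  xyz <- coords(s)
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(lo, spacing, dims)
}

grid_axes <- function(g) {
  lapply(1:3, function(k) g$origin[k] + g$spacing * (seq_len(g$dims[k]) - 1))
}

same_grid <- function(a, b, tol = 1e-8) {
  all(abs(a$origin - b$origin) < tol) &&
    abs(a$spacing - b$spacing) < tol && all(a$dims == b$dims)
}

#' Construct a potential grid
#'
#' @param spec a [grid_spec()].
#' @param values numeric array of dimension `spec$dims`, in kT/e.
#' @return an object of class `"PotentialGrid"`.
#' @export
potential_grid <- function(spec, values) {
  values <- as.array(values)
  if (!all(dim(values) == spec$dims)) stop("values do not match grid dims")
  if (!all(is.finite(values))) stop("non-finite potential values")
  structure(list(spec = spec, values = values), class = "PotentialGrid")
}

#' @export
print.PotentialGrid <- function(x, ...) {
  cat(sprintf("PotentialGrid %dx%dx%d, h=%.3g A, range [%.3g, %.3g] kT/e\n",
              x$spec$dims[1], x$spec$dims[2], x$spec$dims[3],
              x$spec$spacing, min(x$values), max(x$values)))
  invisible(x)
}

#' Trilinear interpolation of a potential grid
#'
#' @param pg a `PotentialGrid`.
#' @param points numeric matrix (n x 3) of query positions, Angstrom.
#' @return numeric vector of interpolated potentials (kT/e).
#' @export
interpolate_potential <- function(pg, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  g <- pg$spec
  t <- sweep(points, 2, g$origin) / g$spacing
  i0 <- pmin(pmax(floor(t), 0), g$dims - 2)  # 0-based lower node
  if (any(t < -1e-9) || any(t > rep(g$dims - 1, each = nrow(points)) + 1e-9)) {
    stop("query point outside grid")
  }
  f <- t - i0
  v <- pg$values
  idx <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  }
  idx(0,0,0) * (1-f[,1])*(1-f[,2])*(1-f[,3]) +
  idx(1,0,0) * f[,1]*(1-f[,2])*(1-f[,3]) +
  idx(0,1,0) * (1-f[,1])*f[,2]*(1-f[,3]) +
  idx(0,0,1) * (1-f[,1])*(1-f[,2])*f[,3] +
  idx(1,1,0) * f[,1]*f[,2]*(1-f[,3]) +
  idx(1,0,1) * f[,1]*(1-f[,2])*f[,3] +
  idx(0,1,1) * (1-f[,1])*f[,2]*f[,3] +
  idx(1,1,1) * f[,1]*f[,2]*f[,3]
}

#' Write a scalar grid as OpenDX
#'
#' Writes the `object 1 gridpositions` / `gridconnections` / `array`
#' layout used by APBS, three values per line, x fastest in the
#' innermost loop per the DX convention (z varies fastest in the data
#' stream).
#'
#' @param pg a `PotentialGrid` (or a `RegionMask`, written as 0/1).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(pg, path) {
  g <- pg$spec
  vals <- if (inherits(pg, "RegionMask")) as.numeric(pg$members) else pg$values
  n <- prod(g$dims)
  ## DX stores with z fastest: permute from R's x-fastest layout
  v <- aperm(array(vals, g$dims), c(3, 2, 1))
  flat <- as.vector(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by epogram",
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("origin %.6e %.6e %.6e", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", g$spacing),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", g$spacing),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  pad <- (3 - length(flat) %% 3) %% 3
  m <- matrix(c(flat, rep(NA_real_, pad)), nrow = 3)
  lines <- apply(m, 2, function(r) {
    paste(sprintf("%.6e", r[!is.na(r)]), collapse = " ")
  })
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' @param path an OpenDX file written by [write_dx()] or APBS.
#' @return a `PotentialGrid`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) stop("not an OpenDX gridpositions file: ", path)
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", gp)),
                              "[[:space:]]+")[[1]])
  org <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", org)),
                                "[[:space:]]+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(d) {
    as.numeric(strsplit(trimws(sub("^delta", "", d)), "[[:space:]]+")[[1]])
  }, numeric(3)))
  spacing <- dmat[1, 1]
  if (!isTRUE(all.equal(diag(c(spacing, spacing, spacing)), unname(dmat),
                        tolerance = 1e-8))) {
    stop("only axis-aligned cubic-spacing DX grids are supported")
  }
  start <- grep("data follows", lines)[1]
  endmarks <- grep("^(attribute|object \")", lines)
  endmarks <- endmarks[endmarks > start]
  end <- if (length(endmarks) > 0) min(endmarks) - 1 else length(lines)
  flat <- as.numeric(unlist(strsplit(trimws(lines[(start + 1):end]),
                                     "[[:space:]]+")))
  n <- prod(dims)
  if (length(flat) < n) stop("DX data stream shorter than declared items")
  v <- aperm(array(flat[seq_len(n)], rev(dims)), c(3, 2, 1))
  potential_grid(grid_spec(origin, spacing, dims), v)
}
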