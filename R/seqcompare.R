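## Sequence divergence (amino-acid p-distances from an alignment),
## rigid-body structural superposition (Kabsch), per-residue structural
## similarity (Qres), and Ramachandran model QC.

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA (rows of equal length; gaps `-`).
#' @return named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  aln <- as.character(set)
  names(aln) <- sub("\\s.*$", "", names(set))
  validate_alignment(aln)
}

validate_alignment <- function(aln) {
  if (length(aln) < 2) stop("alignment needs at least 2 sequences")
  len <- unique(nchar(aln))
  if (length(len) != 1) stop("aligned rows differ in length")
  bad <- grepl(sprintf("[^%s.X-]", paste(AA1, collapse = "")),
               toupper(aln))
  if (any(bad)) {
    stop("alignment rows contain non amino-acid symbols: ",
         paste(names(aln)[bad], collapse = ", "))
  }
  if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
  toupper(aln)
}

#' Amino-acid p-distance matrix
#'
#' Proportion of differing residues per compared site.  With
#' `deletion = "pairwise"` sites carrying a gap or `X` in either member
#' of a pair are removed for that pair; with `"complete"` any column
#' with a gap or `X` in any row is removed for all pairs.
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (or the result of [read_alignment()]).
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return symmetric matrix of distances in `[0, 1]` with attribute
#'   `n_sites` (per-pair compared-site counts).
#' @export
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  aln <- validate_alignment(aln)
  chars <- do.call(rbind, strsplit(aln, ""))
  ok <- chars != "-" & chars != "X" & chars != "."
  if (deletion == "complete") {
    keep <- apply(ok, 2, all)
    chars <- chars[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  ns <- matrix(ncol(chars), n, n, dimnames = dimnames(d))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) {
        stop(sprintf("no comparable sites for pair %s vs %s",
                     names(aln)[i], names(aln)[j]))
      }
      d[i, j] <- d[j, i] <- mean(chars[i, comp] != chars[j, comp])
      ns[i, j] <- ns[j, i] <- sum(comp)
    }
  }
  attr(d, "n_sites") <- ns
  attr(d, "deletion") <- deletion
  d
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD
#' between paired coordinate sets (SVD solution with reflection
#' correction).
#'
#' @param ref n x 3 matrix of reference coordinates (e.g. CA atoms).
#' @param mov n x 3 matrix of moving coordinates, paired row-by-row.
#' @return list of class `"StructureComparison"`: `rotation` (3 x 3,
#'   det +1), `translation`, `rmsd` (Angstrom), `transformed` (mov
#'   superposed onto ref).
#' @export
kabsch_superpose <- function(ref, mov) {
  ref <- matrix(as.numeric(as.matrix(ref)), ncol = 3)
  mov <- matrix(as.numeric(as.matrix(mov)), ncol = 3)
  if (nrow(ref) != nrow(mov)) stop("coordinate sets differ in length")
  n <- nrow(ref)
  if (n < 3) stop("need at least 3 paired points")
  cr <- colMeans(ref); cm <- colMeans(mov)
  A <- sweep(ref, 2, cr); B <- sweep(mov, 2, cm)
  if (qr(A)$rank < 2 || qr(B)$rank < 2) {
    stop("degenerate (collinear) coordinates")
  }
  H <- t(B) %*% A
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  transformed <- sweep(B %*% t(R), 2, cr, `+`)
  rmsd <- sqrt(mean(rowSums((transformed - ref)^2)))
  structure(list(rotation = R, translation = as.numeric(cr - cm %*% t(R)),
                 rmsd = rmsd, transformed = transformed),
            class = "StructureComparison")
}

#' Per-residue structural similarity (Qres)
#'
#' For paired residues i, `Q_i` is the mean over partners j with
#' `|i - j| >= min_sep` of
#' `exp(-(d_ij^ref - d_ij^mov)^2 / (2 sigma_ij^2))` with
#' `sigma_ij = |i - j|^0.15` Angstrom, where `d_ij` are intramolecular
#' CA-CA distances.  Values lie in (0, 1]; 1 means locally identical
#' internal geometry.  Superposition-free and symmetric in its inputs.
#'
#' @param ref,mov n x 3 CA coordinate matrices.
#' @param pairing optional 2-column index matrix pairing rows of `ref`
#'   with rows of `mov` (default: row-by-row); residue separation is
#'   taken from the `ref` indices.
#' @param min_sep minimum sequence separation (default 3).
#' @return numeric vector of Q values, one per paired residue.
#' @export
qres_profile <- function(ref, mov, pairing = NULL, min_sep = 3) {
  ref <- matrix(as.numeric(as.matrix(ref)), ncol = 3)
  mov <- matrix(as.numeric(as.matrix(mov)), ncol = 3)
  if (is.null(pairing)) {
    if (nrow(ref) != nrow(mov)) stop("coordinate sets differ in length")
    pairing <- cbind(seq_len(nrow(ref)), seq_len(nrow(mov)))
  }
  pairing <- as.matrix(pairing)
  np <- nrow(pairing)
  if (np < 3) stop("need at least 3 paired residues")
  r <- ref[pairing[, 1], , drop = FALSE]
  m <- mov[pairing[, 2], , drop = FALSE]
  dr <- as.matrix(stats::dist(r))
  dm <- as.matrix(stats::dist(m))
  sep <- abs(outer(pairing[, 1], pairing[, 1], `-`))
  q <- numeric(np)
  for (i in seq_len(np)) {
    j <- which(sep[i, ] >= min_sep)
    if (length(j) == 0) {
      q[i] <- NA_real_
      next
    }
    sig <- sep[i, j]^0.15
    q[i] <- mean(exp(-(dr[i, j] - dm[i, j])^2 / (2 * sig^2)))
  }
  q
}

## torsion angle of four points, IUPAC sign convention, degrees in
## (-180, 180]
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Default coarse Ramachandran region map
#'
#' Rectangular (phi, psi) boxes: favored alpha and beta cores, an
#' additional left-handed alpha box that is favored for glycine and
#' allowed otherwise, and allowed margins of 20 degrees around each
#' favored core; anything else is disallowed.  This is a deliberately
#' coarse, documented map for model QC, not a re-derivation of any
#' published density-based map.
#'
#' @return data frame of boxes with columns `region`, `phi_min`,
#'   `phi_max`, `psi_min`, `psi_max`, `class`.
#' @export
default_rama_regions <- function() {
  data.frame(
    region  = c("alpha", "beta", "beta_pp", "alphaL"),
    phi_min = c(-100, -180, -180, 30),
    phi_max = c(-30, -60, -60, 90),
    psi_min = c(-80, 90, -180, -20),
    psi_max = c(0, 180, -150, 80),
    stringsAsFactors = FALSE
  )
}

classify_phi_psi <- function(phi, psi, res_name,
                             regions = default_rama_regions(),
                             margin = 20) {
  in_box <- function(b, m = 0) {
    phi >= b$phi_min - m & phi <= b$phi_max + m &
      psi >= b$psi_min - m & psi <= b$psi_max + m
  }
  hit_fav <- hit_alw <- FALSE
  for (k in seq_len(nrow(regions))) {
    b <- regions[k, ]
    core <- in_box(b)
    marg <- in_box(b, margin)
    if (b$region == "alphaL") {
      ## left-handed helix: favored only for glycine
      if (res_name == "GLY") {
        hit_fav <- hit_fav || core
        hit_alw <- hit_alw || marg
      } else {
        hit_alw <- hit_alw || core
      }
    } else {
      hit_fav <- hit_fav || core
      hit_alw <- hit_alw || marg
    }
  }
  if (hit_fav) "favored" else if (hit_alw) "allowed" else "disallowed"
}

#' Backbone dihedral table of a structure
#'
#' Computes phi/psi (degrees, IUPAC convention) for every residue with
#' complete backbone context within its chain.  Chain-terminal residues
#' lack a full phi/psi pair and are excluded; residues with missing
#' backbone atoms are skipped with a warning.
#'
#' @param s a `Structure`.
#' @return data frame: `chain`, `res_seq`, `res_name`, `phi`, `psi`.
#' @export
phi_psi_table <- function(s) {
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  rows <- list()
  skipped <- 0L
  for (ch in unique(a$chain)) {
    ca <- a[a$chain == ch, , drop = FALSE]
    resseq <- unique(ca$res_seq)
    get <- function(rs, nm) {
      hit <- which(ca$res_seq == rs & ca$name == nm)
      if (length(hit) == 0) return(NULL)
      as.numeric(ca[hit[1], c("x", "y", "z")])
    }
    if (length(resseq) < 3) next
    for (k in 2:(length(resseq) - 1)) {
      rs <- resseq[k]
      prevC <- get(resseq[k - 1], "C")
      N <- get(rs, "N"); CA <- get(rs, "CA"); C <- get(rs, "C")
      nextN <- get(resseq[k + 1], "N")
      if (is.null(prevC) || is.null(N) || is.null(CA) || is.null(C) ||
          is.null(nextN)) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, res_seq = rs,
        res_name = ca$res_name[ca$res_seq == rs][1],
        phi = dihedral_angle(prevC, N, CA, C),
        psi = dihedral_angle(N, CA, C, nextN),
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0) {
    warning(skipped, " residue(s) skipped: incomplete backbone")
  }
  if (length(rows) == 0) {
    return(data.frame(chain = character(0), res_seq = integer(0),
                      res_name = character(0), phi = numeric(0),
                      psi = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Ramachandran summary of a structure
#'
#' Classifies each residue's (phi, psi) with the bundled coarse region
#' map (user-overridable) and reports percentages in favored / allowed
#' / disallowed regions; percentages sum to 100 over classified
#' residues.  Gly and Pro are additionally tabulated separately.
#'
#' @param s a `Structure`.
#' @param regions region map, see [default_rama_regions()].
#' @return list of class `"RamachandranSummary"`: `table` (per-residue
#'   phi/psi/class), `percent` (named vector), `by_residue_type`
#'   (counts for general / GLY / PRO).
#' @export
ramachandran_summary <- function(s, regions = default_rama_regions()) {
  tab <- phi_psi_table(s)
  if (nrow(tab) == 0) {
    return(structure(list(table = tab,
                          percent = c(favored = NA_real_,
                                      allowed = NA_real_,
                                      disallowed = NA_real_),
                          by_residue_type = NULL),
                     class = "RamachandranSummary"))
  }
  tab$class <- vapply(seq_len(nrow(tab)), function(i) {
    classify_phi_psi(tab$phi[i], tab$psi[i], tab$res_name[i], regions)
  }, character(1))
  lev <- c("favored", "allowed", "disallowed")
  counts <- table(factor(tab$class, levels = lev))
  pct <- 100 * as.numeric(counts) / nrow(tab)
  names(pct) <- lev
  grp <- ifelse(tab$res_name == "GLY", "GLY",
                ifelse(tab$res_name == "PRO", "PRO", "general"))
  by_type <- table(grp, factor(tab$class, levels = lev))
  structure(list(table = tab, percent = pct, by_residue_type = by_type),
            class = "RamachandranSummary")
}

#' @export
print.RamachandranSummary <- function(x, ...) {
  if (nrow(x$table) == 0) {
    cat("Ramachandran summary: no classifiable residues\n")
    return(invisible(x))
  }
  cat(sprintf("Ramachandran summary over %d residues:\n", nrow(x$table)))
  cat(sprintf("  favored %.1f%%, allowed %.1f%%, disallowed %.1f%%\n",
              x$percent["favored"], x$percent["allowed"],
              x$percent["disallowed"]))
  invisible(x)
}
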