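## PIPSA-style electrostatic comparison: potentials from superposed
## structures are compared over a "skin" of grid points lying a fixed
## offset outside the protein surface, optionally restricted to a
## sphere around an anchor (e.g. the CA centroid of a target-recognition
## motif), with Hodgkin or Carbo similarity indices and the associated
## electrostatic distance D = sqrt(2 - 2 SI).

#' Region specification for electrostatic comparisons
#'
#' @param mode `"whole-skin"` or `"anchored"` (skin intersected with a
#'   sphere of `radius` around `anchor`).
#' @param sigma skin offset from the atom surface, Angstrom (default 3).
#' @param delta skin thickness, Angstrom (default 4).
#' @param anchor 3-vector, Angstrom (required for anchored mode unless a
#'   motif is given to the caller performing anchoring).
#' @param radius anchor-sphere radius, Angstrom (default 35, the
#'   target-recognition-domain comparison radius).
#' @return an object of class `"RegionSpec"`.
#' @export
region_spec <- function(mode = c("whole-skin", "anchored"), sigma = 3,
                        delta = 4, anchor = NULL, radius = 35) {
  mode <- match.arg(mode)
  if (sigma < 0) stop("sigma must be >= 0")
  if (delta <= 0) stop("delta must be > 0")
  if (radius <= 0) stop("radius must be > 0")
  if (mode == "anchored" && !is.null(anchor)) stopifnot(length(anchor) == 3)
  structure(list(mode = mode, sigma = sigma, delta = delta,
                 anchor = anchor, radius = radius), class = "RegionSpec")
}

new_region_mask <- function(spec, members, provenance = list()) {
  structure(list(spec = spec, members = members, provenance = provenance),
            class = "RegionMask")
}

#' Number of member points of a region mask
#' @param m a `RegionMask`.
#' @return integer count.
#' @export
mask_size <- function(m) sum(m$members)

#' Compute a protein skin mask on a grid
#'
#' A grid point belongs to the skin when its distance to the nearest
#' atom surface, `min_i (|x - x_i| - r_i)`, lies in `[sigma, sigma +
#' delta]`.
#'
#' @param s a `Structure` with radii assigned.
#' @param g a [grid_spec()].
#' @param sigma skin offset, Angstrom.
#' @param delta skin thickness, Angstrom.
#' @return a `RegionMask` over `g`.
#' @export
compute_skin_mask <- function(s, g, sigma = 3, delta = 4) {
  if (n_atoms(s) == 0) stop("structure has no atoms")
  if (anyNA(s$atoms$radius)) stop("radii not assigned")
  if (delta <= 0) stop("empty skin: delta must be > 0")
  sd <- surface_distance_cpp(g$origin, g$spacing, g$dims, coords(s),
                             s$atoms$radius, sigma + delta)
  members <- array(sd >= sigma & sd <= sigma + delta, g$dims)
  if (!any(members)) {
    stop("skin mask is empty; enlarge the grid or check sigma/delta")
  }
  new_region_mask(g, members,
                  list(structure = s$id, sigma = sigma, delta = delta))
}

#' Locate a sequence motif and return its CA centroid
#'
#' Finds the first occurrence of `motif` in the chain sequence and
#' returns the centroid of the CA atoms of the matched residues: the
#' anchor for anchored electrostatic comparisons.  Multiple occurrences
#' trigger a warning; the first is used.
#'
#' @param s a `Structure`.
#' @param motif 1-letter amino-acid string (e.g. `"CFT"`).
#' @param chain chain identifier; default: first chain.
#' @return 3-vector, Angstrom.
#' @export
anchor_from_motif <- function(s, motif, chain = NULL) {
  if (is.null(chain)) chain <- s$atoms$chain[1]
  seq1 <- structure_sequence(s, chain)[[1]]
  hits <- gregexpr(motif, seq1, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    stop(sprintf("motif '%s' not found in chain '%s'", motif, trimws(chain)))
  }
  if (length(hits) > 1) {
    warning(sprintf("motif '%s' occurs %d times in chain '%s'; using the first",
                    motif, length(hits), trimws(chain)))
  }
  ca <- s$atoms[s$atoms$chain == chain & s$atoms$name == "CA", , drop = FALSE]
  idx <- hits[1]:(hits[1] + nchar(motif) - 1)
  colMeans(as.matrix(ca[idx, c("x", "y", "z")]))
}

intersect_sphere <- function(mask, anchor, radius) {
  g <- mask$spec
  ax <- grid_axes(g)
  dx2 <- (ax[[1]] - anchor[1])^2
  dy2 <- (ax[[2]] - anchor[2])^2
  dz2 <- (ax[[3]] - anchor[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
  new_region_mask(g, mask$members & inside,
                  c(mask$provenance, list(anchor = anchor, radius = radius)))
}

#' Intersection of two region masks
#' @param a,b `RegionMask` objects on the same grid.
#' @return a `RegionMask`.
#' @export
intersect_masks <- function(a, b) {
  if (!same_grid(a$spec, b$spec)) stop("masks live on different grids")
  new_region_mask(a$spec, a$members & b$members,
                  list(a = a$provenance, b = b$provenance))
}

region_mask_for <- function(s, g, region) {
  m <- compute_skin_mask(s, g, region$sigma, region$delta)
  if (region$mode == "anchored") {
    if (is.null(region$anchor)) stop("anchored region requires an anchor")
    m <- intersect_sphere(m, region$anchor, region$radius)
  }
  m
}

mask_sums <- function(a, b, m) {
  if (!same_grid(a$spec, b$spec) || !same_grid(a$spec, m$spec)) {
    stop("potential grids and mask must share one GridSpec")
  }
  sel <- m$members
  if (!any(sel)) stop("region mask is empty")
  pa <- a$values[sel]; pb <- b$values[sel]
  list(pa = pa, pb = pb, aa = sum(pa * pa), bb = sum(pb * pb),
       ab = sum(pa * pb), n = length(pa))
}

#' Electrostatic similarity index over a region
#'
#' Hodgkin: `SI = 2 sum(ab) / (sum(a^2) + sum(b^2))`;
#' Carbo: `SI = sum(ab) / sqrt(sum(a^2) sum(b^2))`; sums run over the
#' mask points.  The electrostatic distance is `D = sqrt(2 - 2 SI)`.
#'
#' @param a,b `PotentialGrid`s on the same grid.
#' @param m a `RegionMask` on the same grid.
#' @param kind `"hodgkin"` (default, the PIPSA convention) or `"carbo"`.
#' @return list of class `"SimilarityResult"`: `SI`, `D`, `n_points`,
#'   `kind`.
#' @export
similarity_index <- function(a, b, m, kind = c("hodgkin", "carbo")) {
  kind <- match.arg(kind)
  s <- mask_sums(a, b, m)
  if (s$aa == 0 && s$bb == 0) {
    stop("similarity undefined: both fields are zero on the mask")
  }
  si <- if (kind == "hodgkin") {
    2 * s$ab / (s$aa + s$bb)
  } else {
    if (s$aa == 0 || s$bb == 0) {
      stop("Carbo index undefined: a field is zero on the mask")
    }
    s$ab / sqrt(s$aa * s$bb)
  }
  structure(list(SI = si, D = sqrt(max(0, 2 - 2 * si)), n_points = s$n,
                 kind = kind), class = "SimilarityResult")
}

#' Mean potential difference over a region
#'
#' Mean over the mask of `phi_a - phi_b`, converted from kT/e to
#' kcal/mol/e (x 0.5922 at 298.15 K).  Signed and antisymmetric in its
#' arguments; this is the quantity the kinetic stage regresses against
#' differences in ln(kcat/Km).
#'
#' @param a,b `PotentialGrid`s on the same grid.
#' @param m a `RegionMask`.
#' @return scalar, kcal/mol/e.
#' @export
mean_potential_difference <- function(a, b, m) {
  s <- mask_sums(a, b, m)
  mean(s$pa - s$pb) * KT_TO_KCAL
}

#' Pairwise electrostatic distance matrix
#'
#' For every pair the comparison mask is the intersection of the two
#' members' skins (and of the anchor sphere in anchored mode), so both
#' fields are defined on every compared point.  Structures must be
#' pre-superposed and all grids share one `GridSpec`; this function
#' refuses mismatched grids rather than resampling.
#'
#' @param entries list of `list(label=, structure=, grid=)` entries.
#' @param region a [region_spec()].
#' @param kind similarity kind, see [similarity_index()].
#' @return symmetric matrix of D values, zero diagonal, labelled;
#'   attribute `n_points` holds the per-pair mask sizes.
#' @export
ep_distance_matrix <- function(entries, region = region_spec(),
                               kind = "hodgkin") {
  labels <- vapply(entries, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate labels in entries")
  n <- length(entries)
  g <- entries[[1]]$grid$spec
  for (e in entries) {
    if (!same_grid(e$grid$spec, g)) {
      stop("all potential grids must share one GridSpec (entry ",
           e$label, " differs)")
    }
  }
  masks <- lapply(entries, function(e) {
    region_mask_for(e$structure, g, region)
  })
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  np <- matrix(0L, n, n, dimnames = list(labels, labels))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m <- intersect_masks(masks[[i]], masks[[j]])
      if (!any(m$members)) {
        stop(sprintf("empty pairwise mask for %s vs %s",
                     labels[i], labels[j]))
      }
      sr <- similarity_index(entries[[i]]$grid, entries[[j]]$grid, m, kind)
      D[i, j] <- D[j, i] <- sr$D
      np[i, j] <- np[j, i] <- sr$n_points
    }
  }
  attr(D, "n_points") <- np
  attr(D, "region") <- region
  attr(D, "kind") <- kind
  D
}

#' Write a labelled distance matrix
#'
#' @param d symmetric labelled matrix.
#' @param path output path.
#' @param format `"csv"` (labelled, default) or `"phylip"` (square).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(d), path, row.names = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      writeLines(paste(sprintf("%-10s", substr(rownames(d)[i], 1, 10)),
                       paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a labelled distance matrix written by [write_distance_matrix()]
#'
#' @param path CSV path.
#' @return symmetric labelled matrix.
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}
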