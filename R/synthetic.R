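## Self-contained synthetic fixtures: ideal alpha-helical scaffolds with
## surface-exposed charge sites, charge-variant families built through
## the mutator, and an end-to-end kinetics benchmark in which
## ln(kcat/Km) values are generated from the same anchored
## mean-potential-difference operationalization the kinetic stage fits,
## so parameter recovery exercises the true pipeline path.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## natural-extension-reference-frame placement: position D such that
## |CD| = bond, angle(B,C,D) = theta and torsion(A,B,C,D) = chi (degrees)
nerf_place <- function(A, B, C, bond, theta, chi) {
  th <- theta * pi / 180; ch <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- bond * c(-cos(th), sin(th) * cos(ch), -sin(th) * sin(ch))
  C + d[1] * bc + d[2] * m + d[3] * n
}

HELIX_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.53,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.5,
  t_cb = 122.6   # torsion C-N-CA-CB, L-configuration
)

#' Build an ideal alpha-helix from a sequence
#'
#' Backbone N/CA/C/O plus CB (except glycine) at ideal helical
#' dihedrals (phi = -57, psi = -47, omega = 180 degrees) and standard
#' bond geometry.  Consecutive CA-CA distances come out near 3.8 A and
#' the rise per residue near 1.5 A, which makes the geometry
#' analytically checkable and keeps charge sites surface-exposed.
#'
#' @param sequence 1-letter amino-acid string.
#' @param id structure label.
#' @param chain chain identifier.
#' @param phi,psi,omega backbone dihedrals, degrees.
#' @return a `Structure` (charges unassigned, radii unassigned).
#' @export
make_ideal_helix <- function(sequence, id = "helix", chain = "A",
                             phi = -57, psi = -47, omega = 180) {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) == 0) stop("empty sequence")
  res3 <- aa1_to_3(letters1)   # errors on invalid letters
  g <- HELIX_GEOM
  n_res <- length(letters1)
  rows <- list()
  add <- function(name, element, res_i, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      serial = length(rows) + 1L, name = name, element = element,
      res_name = res3[res_i], res_seq = res_i, chain = chain,
      x = xyz[1], y = xyz[2], z = xyz[3], charge = 0,
      radius = NA_real_, het = FALSE, stringsAsFactors = FALSE)
  }
  ## seed residue 1 in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C <- CA + g$b_ca_c * c(-cos(th), sin(th), 0)
  prev <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N <- nerf_place(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n, psi)
      CA <- nerf_place(prev$CA, prev$C, N, g$b_n_ca, g$a_c_n_ca, omega)
      C <- nerf_place(prev$C, N, CA, g$b_ca_c, g$a_n_ca_c, phi)
    }
    O <- nerf_place(N, CA, C, g$b_c_o, g$a_ca_c_o, psi + 180)
    add("N", "N", i, N); add("CA", "C", i, CA); add("C", "C", i, C)
    add("O", "O", i, O)
    if (res3[i] != "GLY") {
      CB <- nerf_place(C, N, CA, g$b_ca_cb, g$a_n_ca_cb, g$t_cb)
      add("CB", "C", i, CB)
    }
    prev <- list(N = N, CA = CA, C = C)
  }
  new_structure(do.call(rbind, rows), id = id)
}

#' Build a superposed family of charge variants
#'
#' Starts from an ideal helix of `base_sequence`, assigns the reduced
#' charge model with the CB fallback (the helix is a side-chain stub
#' model), and derives one variant per element of `variant_specs`
#' through the mutator, so the family shares the base backbone exactly
#' and differs only at mutated residues.
#'
#' @param base_sequence 1-letter string for the base helix.
#' @param variant_specs list; each element is a list of
#'   [mutation_spec()]s (empty list = identical to base).
#' @param labels optional labels, defaults to `variant-1 ...`.
#' @return list of charge-assigned `Structure`s, base first.
#' @export
make_charge_variant_family <- function(base_sequence, variant_specs,
                                       labels = NULL) {
  base <- make_ideal_helix(base_sequence, id = "base")
  base <- assign_charges(base, fallback = "cb")
  if (is.null(labels)) {
    labels <- paste0("variant-", seq_along(variant_specs))
  }
  variants <- lapply(seq_along(variant_specs), function(i) {
    specs <- variant_specs[[i]]
    if (length(specs) == 0) {
      out <- base
      out$id <- labels[i]
      return(out)
    }
    apply_mutant_set(base, mutant_set(labels[i], specs))
  })
  c(list(base), variants)
}

default_benchmark_sequence <- function() "AKEACFTKEKAKEKAKEA"

#' Generate an end-to-end kinetics recovery benchmark
#'
#' Builds `n_enzymes` charge-variant helices (a fixed base carrying the
#' CFT anchor motif plus variants with random charged-to-alanine
#' mutations), solves the LPBE for each on one shared grid, computes
#' anchored mean potential differences to the base through the skin
#' machinery, and assigns
#' `ln_i = ln_ref + dEP(i, base) / true_slope + eps_i` with
#' `eps_i ~ N(0, noise_sd)`.  Refitting the through-origin kinetic
#' model on the recorded pairs recovers `true_slope` up to noise.  All
#' randomness flows from `seed`; regenerating with the same seed
#' reproduces the bundle exactly.
#'
#' @param n_enzymes number of enzymes including the base (>= 3).
#' @param true_slope generating slope, kcal/mol/e per ln unit (nonzero;
#'   default -0.1046, the magnitude reported for methyltransferase
#'   surface potentials).
#' @param noise_sd Gaussian noise on generated ln values (ln units).
#' @param seed integer RNG seed.
#' @param base_sequence base helix sequence (must contain `CFT`).
#' @param ln_ref anchor ln(kcat/Km) for the base enzyme.
#' @param spacing,padding grid parameters, Angstrom.
#' @param params a [solver_params()].
#' @param region a [region_spec()]; default anchored on the CFT motif
#'   with the standard 35 A radius.
#' @return list of class `"BenchmarkBundle"`: `structures`, `grids`,
#'   `records` (label, kcat_km, ln_kcat_km), `pairs` (dln, dep),
#'   `true_slope`, `noise_sd`, `seed`, `region`, `log`.
#' @export
make_qpipsa_benchmark <- function(n_enzymes = 20, true_slope = -0.1046,
                                  noise_sd = 0.05, seed = 1,
                                  base_sequence = default_benchmark_sequence(),
                                  ln_ref = ln_kcat_km(1.20e7),
                                  spacing = 1.0, padding = 15,
                                  params = solver_params(),
                                  region = NULL) {
  if (n_enzymes < 3) stop("need at least 3 enzymes")
  if (true_slope == 0) stop("true_slope must be nonzero")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  letters1 <- strsplit(base_sequence, "")[[1]]
  chargeable <- which(letters1 %in% c("K", "R", "D", "E"))
  if (length(chargeable) < 2) stop("base sequence needs charged residues")
  if (!grepl("CFT", base_sequence, fixed = TRUE)) {
    stop("base sequence must contain the CFT anchor motif")
  }
  specs <- lapply(seq_len(n_enzymes - 1), function(i) {
    k <- sample(seq_len(min(6, length(chargeable))), 1)
    pos <- sort(sample(chargeable, k))
    lapply(pos, function(p) mutation_spec("A", p, letters1[p], "A"))
  })
  labels <- c("base", sprintf("enzyme-%02d", seq_len(n_enzymes - 1)))
  structures <- make_charge_variant_family(base_sequence, specs,
                                           labels = labels[-1])
  structures[[1]]$id <- "base"
  g <- grid_from_structure(structures[[1]], spacing, padding)
  grids <- lapply(structures, function(s) solve_lpbe(s, g, params))
  anchor <- anchor_from_motif(structures[[1]], "CFT")
  if (is.null(region)) {
    region <- region_spec("anchored", anchor = anchor)
  } else if (region$mode == "anchored" && is.null(region$anchor)) {
    region$anchor <- anchor
  }
  masks <- lapply(structures, function(s) region_mask_for(s, g, region))
  dep <- vapply(seq_len(n_enzymes), function(i) {
    m <- intersect_masks(masks[[i]], masks[[1]])
    mean_potential_difference(grids[[i]], grids[[1]], m)
  }, numeric(1))
  noise <- c(0, stats::rnorm(n_enzymes - 1, 0, noise_sd))
  ln <- ln_ref + dep / true_slope + noise
  records <- data.frame(label = labels, kcat_km = exp(ln),
                        ln_kcat_km = ln, stringsAsFactors = FALSE)
  pairs <- data.frame(dln = ln[-1] - ln[1], dep = dep[-1])
  structure(list(structures = structures, grids = grids, masks = masks,
                 records = records, pairs = pairs,
                 true_slope = true_slope, noise_sd = noise_sd,
                 seed = seed, region = region,
                 log = sprintf(
                   "qpipsa benchmark: n=%d slope=%g noise_sd=%g seed=%d h=%g pad=%g",
                   n_enzymes, true_slope, noise_sd, seed, spacing, padding)),
            class = "BenchmarkBundle")
}

#' Refit the kinetic model on a benchmark bundle
#'
#' @param bundle a [make_qpipsa_benchmark()] result.
#' @param through_origin see [fit_kinetic_model()].
#' @return a `KineticModel`.
#' @export
fit_benchmark <- function(bundle, through_origin = TRUE) {
  fit_kinetic_model(bundle$pairs, through_origin = through_origin)
}

#' Write a benchmark bundle to disk
#'
#' Emits one PQR per structure, a TSV of kinetic records and a JSON
#' manifest (seed, parameters) into a directory.
#'
#' @param bundle a `BenchmarkBundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in bundle$structures) {
    write_structure(s, file.path(dir, paste0(s$id, ".pqr")), "pqr")
  }
  utils::write.table(bundle$records, file.path(dir, "kinetics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- sprintf(
    '{"seed": %d, "true_slope": %g, "noise_sd": %g, "n_enzymes": %d}',
    bundle$seed, bundle$true_slope, bundle$noise_sd,
    nrow(bundle$records))
  writeLines(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}
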