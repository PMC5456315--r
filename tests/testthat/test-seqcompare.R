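# p-distances, Kabsch superposition, Qres, Ramachandran QC

test_that("p-distances follow site bookkeeping", {
  aln <- c(a = "AAAA", b = "AATT", c = "AAAA")
  d <- p_distance_matrix(aln)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # pairwise deletion: gap sites removed per pair
  d2 <- p_distance_matrix(c(x = "A-CD", y = "AVCD"))
  expect_equal(d2["x", "y"], 0)
  expect_equal(attr(d2, "n_sites")["x", "y"], 3)
  # complete deletion uses <= the pairwise site count
  aln3 <- c(p = "AKC-EF", q = "AK-DEF", r = "AKCDEF")
  dp <- p_distance_matrix(aln3, "pairwise")
  dc <- p_distance_matrix(aln3, "complete")
  expect_true(all(attr(dc, "n_sites") <= attr(dp, "n_sites")))
  expect_error(p_distance_matrix(c(u = "A---", v = "-VVV")),
               "no comparable sites")
})

test_that("aligned FASTA reads into a validated alignment", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "AK-DE", ">s2", "AKCDE"), path)
  aln <- read_alignment(path)
  expect_equal(names(aln), c("s1", "s2"))
  expect_equal(unname(nchar(aln)), c(5L, 5L))
  d <- p_distance_matrix(aln)
  expect_equal(d["s1", "s2"], 0)
})

test_that("Kabsch superposition is exact under rigid motions", {
  set.seed(9)
  ref <- matrix(rnorm(30, sd = 4), ncol = 3)
  idcmp <- kabsch_superpose(ref, ref)
  expect_equal(idcmp$rmsd, 0, tolerance = 1e-10)
  expect_equal(idcmp$rotation, diag(3), tolerance = 1e-10)
  th <- pi / 2
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  mov <- ref %*% t(Rz) + matrix(c(5, -3, 11), nrow(ref), 3, byrow = TRUE)
  cmp <- kabsch_superpose(ref, mov)
  expect_equal(cmp$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(cmp$rotation), 1, tolerance = 1e-10)
  expect_equal(crossprod(cmp$rotation), diag(3), tolerance = 1e-10)
  # rigid-motion invariance of the minimized RMSD
  set.seed(10)
  noisy <- ref + matrix(rnorm(30, sd = 0.5), ncol = 3)
  r0 <- kabsch_superpose(ref, noisy)$rmsd
  r1 <- kabsch_superpose(ref, noisy %*% t(Rz) + 7)$rmsd
  expect_equal(r0, r1, tolerance = 1e-8)
  expect_error(kabsch_superpose(ref[1:2, ], mov[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate|collinear")
})

test_that("Kabsch RMSD matches a brute-force rotation-grid oracle", {
  ref <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 1))
  mov <- ref
  mov[3, ] <- mov[3, ] + c(0, 0, 1)   # displace one point by 1 A
  opt <- kabsch_superpose(ref, mov)$rmsd
  # dense scan over Euler angles with centroid-matched translation
  A <- sweep(ref, 2, colMeans(ref))
  B <- sweep(mov, 2, colMeans(mov))
  grid <- seq(-pi, pi, by = pi / 24)
  half <- seq(-pi / 2, pi / 2, by = pi / 24)
  best <- Inf
  for (a in grid) for (b in half) for (cc in grid) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(cc); sg <- sin(cc)
    R <- rbind(c(cb * cg, sa * sb * cg - ca * sg, ca * sb * cg + sa * sg),
               c(cb * sg, sa * sb * sg + ca * cg, ca * sb * sg - sa * cg),
               c(-sb, sa * cb, ca * cb))
    r <- sqrt(mean(rowSums((B %*% t(R) - A)^2)))
    if (r < best) best <- r
  }
  expect_lte(opt, best + 1e-12)   # Kabsch is the true minimum
  expect_lt(best - opt, 0.05)     # and the scan approaches it
})

test_that("Qres is 1 for identical structures and localizes deviations", {
  set.seed(12)
  ref <- cbind(cumsum(rnorm(10, 3.8, 0.1)), rnorm(10), rnorm(10))
  expect_equal(qres_profile(ref, ref), rep(1, 10))
  # uniform doubling destroys internal-distance agreement
  ext <- cbind(3.8 * (1:20), 0, 0)
  q <- qres_profile(ext, 2 * ext)
  expect_true(all(q < 0.5))
  # single displaced residue is the minimum of the profile
  mov <- ref
  mov[5, ] <- mov[5, ] + c(0, 4, 0)
  q2 <- qres_profile(ref, mov)
  expect_equal(which.min(q2), 5L)
  # symmetric under swapping inputs
  expect_equal(qres_profile(ref, mov), qres_profile(mov, ref))
  expect_error(qres_profile(ref[1:2, ], ref[1:2, ]), "at least 3")
})

test_that("Qres decreases monotonically with displacement", {
  ref <- cbind(3.8 * (1:8), 0, 0)
  qs <- vapply(c(0.5, 1, 2, 4), function(dz) {
    mov <- ref; mov[4, 3] <- mov[4, 3] + dz
    qres_profile(ref, mov)[4]
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
})

test_that("Ramachandran classification follows the bundled map", {
  helix <- make_ideal_helix(strrep("A", 12))
  rs <- ramachandran_summary(helix)
  expect_equal(unname(rs$percent["favored"]), 100)
  expect_equal(sum(rs$percent), 100)
  # 2-residue chain: no classifiable residue
  short <- make_ideal_helix("AA")
  expect_equal(nrow(ramachandran_summary(short)$table), 0L)
  # (60, -60) is disallowed for non-glycine
  twisted <- make_ideal_helix("AAAAA", phi = 60, psi = -60)
  rt <- ramachandran_summary(twisted)
  expect_equal(unname(rt$percent["disallowed"]), 100)
  # but alphaL (60, 45) is favored for glycine, allowed otherwise
  expect_equal(epogram:::classify_phi_psi(60, 45, "GLY"), "favored")
  expect_equal(epogram:::classify_phi_psi(60, 45, "ALA"), "allowed")
  # percentages partition classified residues
  mixed <- make_ideal_helix(strrep("A", 8), phi = -120, psi = 130)
  rm <- ramachandran_summary(mixed)
  expect_equal(sum(rm$percent), 100)
})

test_that("phi/psi extraction matches the generating dihedrals", {
  h <- make_ideal_helix("AAAAAA", phi = -75, psi = 145)
  pp <- phi_psi_table(h)
  expect_equal(pp$phi, rep(-75, nrow(pp)), tolerance = 1e-6)
  expect_equal(pp$psi, rep(145, nrow(pp)), tolerance = 1e-6)
  # missing backbone atoms skip the residue with a warning
  broken <- h
  broken$atoms <- broken$atoms[!(broken$atoms$res_seq == 3 &
                                   broken$atoms$name == "N"), ]
  expect_warning(pp2 <- phi_psi_table(broken), "skipped")
  expect_lt(nrow(pp2), nrow(pp))
})
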