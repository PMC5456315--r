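# Skin masks, motif anchors, similarity indices, distance matrices

test_that("single-atom skin equals the brute-force scan", {
  s <- point_structure(r = 2, q = 0)
  g <- grid_spec(c(-12, -12, -12), 0.5, c(49, 49, 49))
  m <- compute_skin_mask(s, g, sigma = 3, delta = 4)
  oracle <- brute_force_skin(s, g, 3, 4)
  expect_identical(m$members, oracle)
  # shell is 5 <= |x| <= 9 from the centre
  ax <- epogram:::grid_axes(g)
  r <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
  expect_identical(m$members, r >= 5 & r <= 9)
})

test_that("disjoint shells add and degenerate shells error", {
  s1 <- point_structure(r = 2, q = 0)
  g1 <- grid_spec(c(-12, -12, -12), 1, c(25, 25, 25))
  n1 <- mask_size(compute_skin_mask(s1, g1, 3, 4))
  s2 <- two_point_structure(c(-20, 0, 0), c(20, 0, 0), q = c(0, 0))
  g2 <- grid_spec(c(-32, -12, -12), 1, c(65, 25, 25))
  m2 <- compute_skin_mask(s2, g2, 3, 4)
  expect_equal(mask_size(m2), 2 * n1)
  expect_identical(m2$members, brute_force_skin(s2, g2, 3, 4))
  expect_error(compute_skin_mask(s1, g1, 3, 0), "delta")
  tiny <- grid_spec(c(-1, -1, -1), 1, c(3, 3, 3))
  expect_error(compute_skin_mask(s1, tiny, 3, 4), "empty")
})

test_that("motif anchors sit at the CA centroid of the first match", {
  h <- make_ideal_helix("AAACFTAAA")
  ca <- h$atoms[h$atoms$name == "CA", c("x", "y", "z")]
  anchor <- anchor_from_motif(h, "CFT")
  expect_equal(anchor, colMeans(as.matrix(ca[4:6, ])),
               ignore_attr = TRUE)
  expect_error(anchor_from_motif(h, "WWW"), "not found")
  h2 <- make_ideal_helix("ACFTACFTA")
  expect_warning(a2 <- anchor_from_motif(h2, "CFT"), "first")
  ca2 <- h2$atoms[h2$atoms$name == "CA", c("x", "y", "z")]
  expect_equal(a2, colMeans(as.matrix(ca2[2:4, ])), ignore_attr = TRUE)
})

test_that("similarity indices obey their algebra", {
  g <- grid_spec(c(0, 0, 0), 1, c(4, 4, 4))
  set.seed(7)
  a <- potential_grid(g, array(rnorm(64), c(4, 4, 4)))
  b <- potential_grid(g, array(rnorm(64), c(4, 4, 4)))
  m <- epogram:::new_region_mask(g, array(TRUE, c(4, 4, 4)))
  self <- similarity_index(a, a, m)
  expect_equal(self$SI, 1)
  expect_equal(self$D, 0)
  neg <- a; neg$values <- -neg$values
  anti <- similarity_index(a, neg, m)
  expect_equal(anti$SI, -1)
  expect_equal(anti$D, 2)
  # symmetry, D relation, bounds
  for (kind in c("hodgkin", "carbo")) {
    ab <- similarity_index(a, b, m, kind)
    ba <- similarity_index(b, a, m, kind)
    expect_equal(ab$SI, ba$SI)
    expect_gte(ab$SI, -1); expect_lte(ab$SI, 1)
    expect_equal(ab$D, sqrt(2 - 2 * ab$SI))
  }
  # Hodgkin invariant under joint scaling; Carbo under independent ones
  sa <- a; sa$values <- 3 * sa$values
  sb <- b; sb$values <- 3 * sb$values
  expect_equal(similarity_index(sa, sb, m, "hodgkin")$SI,
               similarity_index(a, b, m, "hodgkin")$SI)
  sb5 <- b; sb5$values <- 5 * sb5$values
  expect_equal(similarity_index(sa, sb5, m, "carbo")$SI,
               similarity_index(a, b, m, "carbo")$SI)
  # hand-computed two-point case: Hodgkin 2/3
  g2 <- grid_spec(c(0, 0, 0), 1, c(2, 2, 2))
  pa <- array(0, c(2, 2, 2)); pa[1, 1, 1] <- 1; pa[2, 1, 1] <- 1
  pb <- array(0, c(2, 2, 2)); pb[1, 1, 1] <- 1
  m2 <- epogram:::new_region_mask(g2, array(c(TRUE, TRUE, rep(FALSE, 6)),
                                            c(2, 2, 2)))
  two <- similarity_index(potential_grid(g2, pa), potential_grid(g2, pb),
                          m2)
  expect_equal(two$SI, 2 / 3)
  expect_equal(two$D, sqrt(2 / 3))
  expect_equal(two$n_points, 2L)
  # degenerate and mismatched inputs
  zero <- potential_grid(g, array(0, c(4, 4, 4)))
  expect_error(similarity_index(zero, zero, m), "zero")
  gg <- grid_spec(c(1, 0, 0), 1, c(4, 4, 4))
  expect_error(similarity_index(a, potential_grid(gg, b$values), m),
               "share")
})

test_that("mean potential difference is a signed kcal/mol/e mean", {
  g <- grid_spec(c(0, 0, 0), 1, c(2, 2, 2))
  pa <- array(0, c(2, 2, 2)); pa[1, 1, 1] <- 2
  pb <- array(0, c(2, 2, 2))
  m <- epogram:::new_region_mask(g, array(c(TRUE, TRUE, rep(FALSE, 6)),
                                          c(2, 2, 2)))
  a <- potential_grid(g, pa); b <- potential_grid(g, pb)
  expect_equal(mean_potential_difference(a, b, m), 1.0 * 0.5922)
  expect_equal(mean_potential_difference(a, a, m), 0)
  expect_equal(mean_potential_difference(b, a, m),
               -mean_potential_difference(a, b, m))
  # constant offset maps to c * 0.5922
  pc <- pa + 3
  expect_equal(mean_potential_difference(potential_grid(g, pc), a, m),
               3 * 0.5922)
})

test_that("distance matrices from the full pipeline behave", {
  base_seq <- "AKEACFTKEKAK"
  fam <- make_charge_variant_family(base_seq, list(
    list(),                                        # duplicate of base
    list(mutation_spec("A", 2, "K", "A")),         # one charge removed
    list(mutation_spec("A", 2, "K", "A"),
         mutation_spec("A", 8, "K", "A"))          # two charges removed
  ), labels = c("dup", "one", "two"))
  g <- grid_from_structure(fam[[1]], 1.0, 12)
  entries <- lapply(seq_along(fam), function(i) {
    list(label = c("base", "dup", "one", "two")[i],
         structure = fam[[i]],
         grid = suppressWarnings(solve_lpbe(fam[[i]], g)))
  })
  D <- ep_distance_matrix(entries, region_spec("whole-skin"))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 2))
  expect_equal(D["base", "dup"], 0)
  expect_gt(D["base", "two"], D["base", "one"])
  expect_gt(D["base", "one"], 0)
  # one-entry matrix is 1x1 zero
  D1 <- ep_distance_matrix(entries[1])
  expect_equal(unname(D1), matrix(0, 1, 1), ignore_attr = TRUE)
  # monotone perturbation: growing the perturbing charge grows D
  s3 <- fam[[1]]
  qs <- c(0.5, 1.5, 3)
  dd <- vapply(qs, function(qq) {
    sp <- s3
    sp$atoms$charge[which(sp$atoms$name == "CB")[2]] <-
      sp$atoms$charge[which(sp$atoms$name == "CB")[2]] + qq
    e2 <- list(list(label = "a", structure = fam[[1]], grid = entries[[1]]$grid),
               list(label = "b", structure = sp,
                    grid = suppressWarnings(solve_lpbe(sp, g))))
    ep_distance_matrix(e2)["a", "b"]
  }, numeric(1))
  expect_true(all(diff(dd) > 0))
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  write_distance_matrix(D, path)
  expect_equal(read_distance_matrix(path), D, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("pairwise masks must overlap", {
  s1 <- point_structure(q = 1, r = 2, id = "a")
  s2 <- point_structure(x = 40, q = 1, r = 2, id = "b")
  g <- grid_spec(c(-14, -14, -14), 1, c(69, 29, 29))
  e <- list(
    list(label = "a", structure = s1,
         grid = suppressWarnings(solve_lpbe(s1, g))),
    list(label = "b", structure = s2,
         grid = suppressWarnings(solve_lpbe(s2, g))))
  expect_error(ep_distance_matrix(e), "empty pairwise mask.*a vs b")
})
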