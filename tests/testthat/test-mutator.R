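# Side-chain stub mutagenesis and the bundled mutant-panel fixtures

test_that("R -> A truncates beyond CB and drops one positive charge", {
  wt <- assign_charges(toy_peptide("ARA"))
  mut <- mutate_residue(wt, mutation_spec("A", 2, "R", "A"))
  gone <- c("CG", "CD", "NE", "CZ", "NH1", "NH2")
  expect_false(any(gone %in% mut$atoms$name[mut$atoms$res_seq == 2]))
  expect_equal(mut$atoms$res_name[mut$atoms$res_seq == 2][1], "ALA")
  expect_equal(net_charge(mut) - net_charge(wt), -1)
  # backbone coordinates bit-identical, atom count not increased
  bb <- function(s) coords(s)[s$atoms$name %in% c("N", "CA", "C", "O"), ]
  expect_identical(bb(mut), bb(wt))
  expect_lte(n_atoms(mut), n_atoms(wt))
})

test_that("identity mutation and error contracts", {
  wt <- assign_charges(toy_peptide("AAA"))
  same <- mutate_residue(wt, mutation_spec("A", 2, "A", "A"))
  expect_equal(same$atoms, wt$atoms)
  expect_error(mutate_residue(wt, mutation_spec("A", 2, "K", "A")),
               "expected K, found A")
  expect_error(mutate_residue(wt, mutation_spec("A", 9, "A", "V")),
               "not present")
  expect_error(mutation_spec("A", 2, "A", "G"), "glycine")
  gly <- toy_peptide("AGA")
  expect_error(mutate_residue(assign_charges(gly),
                              mutation_spec("A", 2, "G", "A")),
               "glycine source")
})

test_that("charged targets place their net charge on CB", {
  wt <- assign_charges(toy_peptide("AAA"))
  mut <- mutate_residue(wt, mutation_spec("A", 2, "A", "K"))
  cb <- mut$atoms[mut$atoms$res_seq == 2 & mut$atoms$name == "CB", ]
  expect_equal(cb$charge, 1)
  expect_equal(net_charge(mut) - net_charge(wt), 1)
})

test_that("mutant sets apply atomically, order-independently", {
  wt <- assign_charges(toy_peptide("KKDE"))
  specs <- list(mutation_spec("A", 1, "K", "A"),
                mutation_spec("A", 3, "D", "A"))
  m1 <- apply_mutant_set(wt, mutant_set("fwd", specs))
  m2 <- apply_mutant_set(wt, mutant_set("rev", rev(specs)))
  expect_equal(m1$atoms[, names(m1$atoms) != "serial"],
               m2$atoms[, names(m2$atoms) != "serial"])
  # K(+1) -> A and D(-1) -> A cancel
  expect_equal(net_charge(m1) - net_charge(wt), 0)
  # empty set: identity
  empty <- apply_mutant_set(wt, mutant_set("none", list()))
  expect_equal(empty$atoms, wt$atoms)
  # one bad spec -> no partial result, all failures listed
  bad <- mutant_set("bad", list(mutation_spec("A", 1, "K", "A"),
                                mutation_spec("A", 2, "D", "A"),
                                mutation_spec("A", 9, "K", "A")))
  err <- tryCatch(apply_mutant_set(wt, bad), error = conditionMessage)
  expect_match(err, "expected D, found K")
  expect_match(err, "not present")
  # re-applying a set errors on the wild-type check (no silent re-mutation)
  t1 <- apply_mutant_set(wt, mutant_set("once",
                                        list(mutation_spec("A", 1, "K", "A"))))
  expect_error(apply_mutant_set(t1, mutant_set("once",
                                 list(mutation_spec("A", 1, "K", "A")))),
               "expected K, found A")
})

test_that("bundled HaeIII panel reproduces table-implied charge deltas", {
  sets <- read_mutant_sets(system.file("extdata", "haeiii_mutants.tsv",
                                       package = "epogram"))
  expect_setequal(names(sets),
                  c("R225A", "T29", "T7", "T28", "T26", "T45", "T1", "T40"))
  # toy scaffold with author numbering 225..262 carrying R/N/L/N
  seq1 <- paste0("R", strrep("A", 34), "NLN")
  wt <- make_ideal_helix(seq1, id = "haeiii-toy")
  wt$atoms$res_seq <- wt$atoms$res_seq + 224L
  wt <- assign_charges(wt, fallback = "cb")
  for (lbl in names(sets)) {
    m <- apply_mutant_set(wt, sets[[lbl]])
    expected <- sum(vapply(sets[[lbl]]$specs, function(sp) {
      epogram:::residue_net_charge(epogram:::aa1_to_3(sp$target_aa)) -
        epogram:::residue_net_charge(epogram:::aa1_to_3(sp$wt_aa))
    }, numeric(1)))
    expect_equal(net_charge(m) - net_charge(wt), expected, info = lbl)
  }
  # the four-residue T29 swap loses exactly the R225 positive charge
  expect_equal(net_charge(apply_mutant_set(wt, sets$T29)) - net_charge(wt),
               -1)
  expect_equal(length(sets$T29$specs), 4L)
})

test_that("bundled human DNMT2 panel drops one basic charge per mutant", {
  sets <- read_mutant_sets(system.file("extdata", "human_dnmt2_mutants.tsv",
                                       package = "epogram"))
  expect_length(sets, 6L)
  pos <- c(122, 275, 289, 295, 367, 371)
  aa <- c("K", "R", "R", "K", "K", "R")
  wt <- make_ideal_helix(paste0("A", paste(aa, collapse = ""), "A"),
                         id = "dnmt2-toy")
  wt$atoms$res_seq <- c(1L, pos, 400L)[wt$atoms$res_seq]
  wt <- assign_charges(wt, fallback = "cb")
  for (lbl in names(sets)) {
    m <- apply_mutant_set(wt, sets[[lbl]])
    expect_equal(net_charge(m) - net_charge(wt), -1, info = lbl)
  }
  expect_equal(vapply(sets[["Mutant-VI"]]$specs, `[[`, integer(1),
                      "res_seq"), 275L)
})
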