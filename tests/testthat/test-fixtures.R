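# Synthetic libraries and label models.

test_that("library generation is seeded, distinct and parseable", {
  lib1 <- generate_library(10, seed = 42)
  lib2 <- generate_library(10, seed = 42)
  expect_identical(lib1, lib2)
  expect_equal(nrow(lib1), 10L)
  expect_false(anyDuplicated(lib1$smiles) > 0L)
  for (s in lib1$smiles) expect_s3_class(parse_smiles(s), "sme_mol")
  expect_error(generate_library(0), ">= 1")
})

test_that("common functional groups occur often enough in a 500-library", {
  lib <- fixture_library()
  catal <- load_fg_catalog()
  counts <- table(unlist(lapply(lib$smiles, function(s)
    vapply(functional_group_matches(parse_smiles(s), catal), `[[`, "",
           "name"))))
  for (g in c("hydroxyl", "primary_amine", "methyl"))
    expect_gte(counts[[g]], 10L)
})

test_that("noise-free additive labels equal the designed linear form exactly", {
  spec <- label_spec("additive_regression", noise_sd = 0)
  catal <- load_fg_catalog()
  # independent counting loop over catalog matches
  lib <- fixture_library()
  for (s in lib$smiles[seq(1, 100, by = 7)]) {
    m <- parse_smiles(s)
    got <- label_molecule(m, spec, catal)
    want <- 0
    for (g in names(spec$group_weights)) {
      k <- sum(vapply(functional_group_matches(m, catal), `[[`, "",
                      "name") == g)
      want <- want + spec$group_weights[[g]] * k
    }
    expect_equal(got, want, tolerance = 1e-12)
  }
  # worked example: ethanol = 1 hydroxyl + 1 methyl
  w <- spec$group_weights
  expect_equal(label_molecule("CCO", spec, catal),
               w[["hydroxyl"]] + w[["methyl"]])
})

test_that("binary labels implement toxicophore presence with flips", {
  spec <- label_spec("toxicophore_binary", flip_prob = 0)
  expect_equal(label_molecule("O=[N+]([O-])c1ccccc1", spec), 1)
  expect_equal(label_molecule("Nc1ccccc1", spec), 1)
  expect_equal(label_molecule("CCO", spec), 0)
  expect_equal(label_molecule("CCN", spec), 0)   # aliphatic amine not toxic
  expect_error(label_spec("toxicophore_binary", flip_prob = 0.6), "flip_prob")
})

test_that("descriptor labels compute local physicochemical values", {
  expect_equal(label_molecule("c1ccccc1", label_spec("descriptor",
                                                     descriptor = "HBD")), 0)
  expect_equal(mol_descriptor("Oc1ccccc1", "HBD"), 1)
  expect_equal(mol_descriptor("NCCO", "HBD"), 2)
  expect_gt(mol_descriptor("Oc1ccccc1", "TPSA"), 0)
  expect_equal(mol_descriptor("c1ccccc1", "TPSA"), 0)
  expect_error(mol_descriptor("CC", "XLOGP3"), "arg")
})

test_that("datasets split 8:1:1 with disjoint, reproducible parts", {
  spec <- label_spec("additive_regression", noise_sd = 0.1)
  ds <- make_dataset(spec, 100, seed = 9)
  expect_equal(nrow(ds$train), 80L)
  expect_equal(nrow(ds$val), 10L)
  expect_equal(nrow(ds$test), 10L)
  ids <- c(ds$train$id, ds$val$id, ds$test$id)
  expect_false(anyDuplicated(ids) > 0L)
  ds2 <- make_dataset(spec, 100, seed = 9)
  expect_identical(ds, ds2)
  ds3 <- make_dataset(spec, 10, seed = 9)
  expect_equal(vapply(ds3, nrow, 1L), c(train = 8L, val = 1L, test = 1L))
})

test_that("binary fixture is class-balanced with a double-toxicophore subset", {
  spec <- label_spec("toxicophore_binary")
  ds <- make_dataset(spec, 400, seed = 31)
  all <- rbind(ds$train, ds$val, ds$test)
  expect_gte(mean(all$label), 0.3)
  expect_lte(mean(all$label), 0.7)
  ndist <- vapply(all$smiles[all$label == 1], function(s) {
    m <- parse_smiles(s)
    sum(vapply(spec$toxic_smarts, function(ts) has_smarts(m, ts), TRUE))
  }, 1)
  expect_gte(mean(ndist >= 2), 0.2)
})
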