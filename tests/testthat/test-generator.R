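# Fragment pools, selection and recombination.

test_that("pool construction aggregates per canonical fragment", {
  fm <- fixture_small_model()
  data <- fm$data$test[1:25, ]
  pool <- build_pool(fm$model, data)
  expect_s3_class(pool, "sme_fragment_pool")
  expect_true(all(pool$count >= 1L))
  expect_false(anyDuplicated(pool$fragment) > 0L)

  # oracle: loop molecules x fragments and re-aggregate
  vals <- list()
  for (i in seq_len(nrow(data))) {
    rec <- molecule_record(data$id[i], data$smiles[i])
    frs <- brics_fragments(rec)
    if (length(frs) < 2L) next
    for (sub in frs) {
      links <- attr(sub, "links")
      key <- mol_to_smiles(
        smexplain:::mol_subgraph(rec$mol, sub$atom_indices + 1L,
                                 links = links)$mol)
      row <- attribute(fm$model, rec, sub)
      vals[[key]] <- c(vals[[key]], row$attribution)
    }
  }
  expect_setequal(pool$fragment, names(vals))
  for (k in pool$fragment) {
    expect_equal(pool$mean_attribution[pool$fragment == k], mean(vals[[k]]),
                 tolerance = 1e-10)
  }
})

test_that("zero-weight consensus gives an all-zero pool", {
  model <- zero_weights(fixture_untrained_model(n_models = 1L))
  lib <- fixture_library()
  pool <- build_pool(model, data.frame(id = 1:15, smiles = lib$smiles[1:15]))
  expect_true(all(pool$mean_attribution == 0))
})

test_that("selection keeps the ceiling of the extreme fraction", {
  mk <- function(means) {
    p <- data.frame(fragment = sprintf("F%02d", seq_along(means)),
                    mean_attribution = means,
                    count = 1L, links = "16")
    attr(p, "mols") <- as.list(seq_along(means))
    class(p) <- c("sme_fragment_pool", "data.frame")
    p
  }
  p10 <- mk(-(1:10) / 10)
  s <- select_fragments(p10, "negative", 0.2)
  expect_equal(nrow(s), 2L)
  expect_equal(s$mean_attribution, c(-1, -0.9))

  p7 <- mk((1:7) / 10)
  s7 <- select_fragments(p7, "positive", 0.2)
  expect_equal(nrow(s7), 2L)                 # ceiling(1.4)

  expect_equal(nrow(select_fragments(p7, "positive", 1)), 7L)
  expect_error(select_fragments(p7, "negative"), "no pool entries")
})

test_that("recombination yields valid, distinct, capped, reproducible molecules", {
  fm <- fixture_small_model()
  pool <- build_pool(fm$model, fm$data$train[1:60, ])
  sel <- select_fragments(pool, "negative", 0.5)
  out1 <- recombine(sel, n_molecules = 40L, seed = 11L, max_heavy_atoms = 50L)
  out2 <- recombine(sel, n_molecules = 40L, seed = 11L, max_heavy_atoms = 50L)
  expect_identical(out1, out2)               # seeded determinism
  expect_false(anyDuplicated(out1) > 0L)
  for (s in out1) {
    m <- parse_smiles(s)
    expect_lte(m$n, 50L)
  }
})

test_that("pools without a complementary link pair are rejected", {
  p <- data.frame(fragment = c("[12*]S(C)(=O)=O", "[12*]S(CC)(=O)=O"),
                  mean_attribution = c(-1, -2), count = 1L, links = "12")
  attr(p, "mols") <- lapply(p$fragment, parse_smiles)
  class(p) <- c("sme_fragment_pool", "data.frame")
  # L12 pairs only with L5: no partner inside this pool
  expect_error(recombine(p, n_molecules = 5L, seed = 1L), "link types")
})

test_that("fragments negative under two properties generate doubly-negative molecules", {
  add <- fixture_additive_study()
  bin <- fixture_binary_study()
  pool_a <- fixture_pool_additive()
  pool_b <- build_pool(bin$model, bin$data$train[1:300, ])
  neg_a <- pool_a$fragment[pool_a$mean_attribution < 0]
  neg_b <- pool_b$fragment[pool_b$mean_attribution < 0]
  shared <- intersect(neg_a, neg_b)
  expect_gte(length(shared), 2L)
  keep <- pool_a$fragment %in% shared
  sub <- pool_a[keep, , drop = FALSE]
  attr(sub, "mols") <- attr(pool_a, "mols")[keep]
  class(sub) <- c("sme_fragment_pool", "data.frame")
  mols <- suppressWarnings(recombine(sub, n_molecules = 100L, seed = 41L,
                                     max_heavy_atoms = 60L))
  expect_gte(length(mols), 30L)
  p_add <- predict(add$model, mols)
  p_bin <- predict(bin$model, mols)
  expect_gte(mean(p_add < 0 & p_bin < 0.5), 0.8)
})

test_that("property distributions summarize separation and overlap", {
  fm <- fixture_small_model()
  lib <- fixture_library()
  a <- lib$smiles[1:15]; b <- lib$smiles[16:30]
  pd <- property_distribution(fm$model, a, a)
  expect_equal(pd$summary[[1]][["overlap"]], 0.5, tolerance = 0.15)
  pd2 <- property_distribution(list(m1 = fm$model, m2 = fm$model), a, b)
  expect_length(pd2$predictions, 2L)
  expect_equal(pd2$predictions$m1$positive, predict(fm$model, a),
               tolerance = 1e-12)
})
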