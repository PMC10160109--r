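# The attribution engine: masks, attribution identities, normalization,
# combinations and extreme components.

test_that("mask vectors encode substructures as documented", {
  g <- featurize("CCCC")
  expect_equal(mask_vector(g, NULL), rep(1, 4))
  expect_equal(mask_vector(g, substructure("BRICS", 0:3, "all")), rep(0, 4))
  expect_equal(mask_vector(g, substructure("BRICS", c(0L, 2L), "x")),
               c(0, 1, 0, 1))
  expect_error(mask_vector(g, substructure("BRICS", 7L, "bad")),
               "out of range")
})

test_that("empty-substructure attribution is exactly zero", {
  model <- fixture_untrained_model(n_models = 2L)
  lib <- fixture_library()
  for (s in lib$smiles[1:20]) {
    g <- featurize(s)
    y1 <- predict(model, g)
    y2 <- predict(model, g, mask = rep(1, g$n))
    expect_identical(y1, y2)          # bitwise-equal forward passes
  }
})

test_that("message passing ignores the mask (readout locality)", {
  model <- fixture_untrained_model(n_models = 1L)
  g <- featurize("OCc1ccccc1")
  b <- smexplain:::batch_graphs(list(g))
  p <- model$sub_models[[1]]
  fw_full <- smexplain:::rgcn_forward_batch(p, b, model$config,
                                            mask = rep(1, g$n), keep = TRUE)
  fw_mask <- smexplain:::rgcn_forward_batch(p, b, model$config,
                                            mask = c(0, rep(1, g$n - 1L)),
                                            keep = TRUE)
  expect_identical(fw_full$H, fw_mask$H)
})

test_that("masking all nodes gives the zero-embedding prediction for every molecule", {
  model <- fixture_untrained_model(n_models = 2L)
  lib <- fixture_library()
  ref <- NULL
  for (s in lib$smiles[1:15]) {
    g <- featurize(s)
    ysub <- predict(model, g, mask = rep(0, g$n))
    if (is.null(ref)) ref <- ysub
    expect_equal(ysub, ref, tolerance = 1e-12)   # same for all molecules
  }
})

test_that("attribution equals an independently coded masked forward pass", {
  fm <- fixture_small_model()
  model <- fm$model
  set.seed(31)
  for (s in fm$data$test$smiles[1:10]) {
    rec <- molecule_record("m", s)
    frs <- brics_fragments(rec)
    sub <- frs[[sample.int(length(frs), 1L)]]
    row <- attribute(model, rec, sub)
    g <- featurize(rec, model$feature_cfg)
    mask <- mask_vector(g, sub)
    # oracle: full dense forward + per-node readout, per sub-model
    ys <- vapply(model$sub_models, function(p) {
      H <- dense_forward_oracle(p, g, model$config)
      masked_head_oracle(p, H, mask, model$config)
    }, 1)
    y0 <- vapply(model$sub_models, function(p) {
      H <- dense_forward_oracle(p, g, model$config)
      masked_head_oracle(p, H, rep(1, g$n), model$config)
    }, 1)
    expect_equal(row$Y_sub, mean(ys), tolerance = 1e-6)
    expect_equal(row$Y, mean(y0), tolerance = 1e-6)
    expect_equal(row$attribution, row$Y - row$Y_sub, tolerance = 1e-12)
  }
})

test_that("normalization methods behave on the stated examples", {
  df <- data.frame(attribution = c(2, -1))
  out <- normalize_attributions(df, "maxabs")
  expect_equal(out$attribution_n, c(1, -0.5))

  df0 <- data.frame(attribution = c(0, 0, 0))
  expect_equal(normalize_attributions(df0, "maxabs")$attribution_n, c(0, 0, 0))
  expect_equal(normalize_attributions(df0, "minmax01")$attribution_n, c(0, 0, 0))

  df2 <- data.frame(attribution = c(1, 3))
  expect_equal(normalize_attributions(df2, "minmax01")$attribution_n, c(0, 1))
  expect_error(normalize_attributions(data.frame(attribution = numeric(0))),
               "empty")
})

test_that("combination enumeration covers the subset lattice", {
  subs <- lapply(1:3, function(i)
    substructure("MURCKO", i - 1L, paste0("s", i)))
  combos <- enumerate_combinations(subs, max_n = 100L)
  expect_length(combos, 7L)                          # 2^3 - 1
  sizes <- table(vapply(combos, function(c) length(c$atom_indices), 1L))
  expect_equal(as.integer(sizes[c("1", "2", "3")]), c(3L, 3L, 1L))

  single <- enumerate_combinations(subs[1], max_n = 10L)
  expect_length(single, 1L)

  expect_error(enumerate_combinations(subs, max_n = 2L), "singletons")
})

test_that("combination sampling caps at max_n with all singletons, reproducibly", {
  subs <- lapply(1:10, function(i)
    substructure("BRICS", i - 1L, paste0("f", i)))
  c1 <- enumerate_combinations(subs, max_n = 100L, seed = 7L)
  c2 <- enumerate_combinations(subs, max_n = 100L, seed = 7L)
  expect_length(c1, 100L)
  keys <- vapply(c1, function(s) paste(s$atom_indices, collapse = ","), "")
  expect_false(anyDuplicated(keys) > 0L)             # distinct subsets
  expect_true(all(as.character(0:9) %in% keys))      # singletons included
  expect_identical(vapply(c2, `[[`, "", "name"),
                   vapply(c1, `[[`, "", "name"))     # seeded reproducibility
})

test_that("extreme components return the max/min attribution with tie-breaks", {
  # zero-weight consensus: all attributions are exactly 0; tie-breaking
  # must return the smallest fragment (then lexicographic name)
  model <- zero_weights(fixture_untrained_model(n_models = 1L))
  ec <- extreme_components(model, "CCOc1ccc(CN)cc1", seed = 3L)
  expect_equal(ec$most_positive$attribution, 0)
  expect_equal(ec$most_negative$attribution, 0)
  np <- length(strsplit(ec$most_positive$atom_indices, ";")[[1]])
  all_sizes <- vapply(strsplit(ec$records$atom_indices, ";"), length, 1L)
  expect_equal(np, min(all_sizes))

  # trained model: extremes must bound every sampled combination
  fm <- fixture_small_model()
  ec <- extreme_components(fm$model, fm$data$test$smiles[3], seed = 5L)
  expect_gte(ec$most_positive$attribution, max(ec$records$attribution) - 1e-12)
  expect_lte(ec$most_negative$attribution, min(ec$records$attribution) + 1e-12)
  expect_error(extreme_components(fm$model, "CC", schemes = "MURCKO"),
               "no fragments")
})

test_that("explain produces one row per substructure with shared Y per molecule", {
  fm <- fixture_small_model()
  rows <- explain(fm$model, fm$data$test[1:5, ],
                  schemes = c("BRICS", "FUNCTIONAL_GROUP"))
  expect_true(all(c("molecule_id", "scheme", "substructure_name", "Y",
                    "Y_sub", "attribution", "attribution_n") %in% names(rows)))
  for (id in unique(rows$molecule_id)) {
    expect_length(unique(rows$Y[rows$molecule_id == id]), 1L)
  }
  expect_equal(rows$attribution, rows$Y - rows$Y_sub, tolerance = 1e-12)
  expect_true(all(abs(rows$attribution_n) <= 1 + 1e-12))
})
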