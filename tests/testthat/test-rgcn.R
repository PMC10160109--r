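# RGCN forward pass, attention pooling, consensus prediction, training and
# evaluation. The forward-pass and readout oracles live in
# helper-oracles.R.

random_small_graph <- function(seed) {
  set.seed(seed)
  lib <- c("CC", "CCO", "C=O", "C#N", "CCN", "C=C", "CO", "CCC", "OCO",
           "NCC", "C=CC", "CC=O", "COC")
  featurize(lib[sample.int(length(lib), 1L)])
}

test_that("forward pass equals the explicit double-sum oracle", {
  model <- fixture_untrained_model(n_models = 1L, hidden = 7L)
  cfg <- model$config
  for (trial in 1:100) {
    g <- random_small_graph(trial)
    b <- smexplain:::batch_graphs(list(g))
    fw <- smexplain:::rgcn_forward_batch(model$sub_models[[1]], b, cfg,
                                         keep = TRUE)
    Ho <- dense_forward_oracle(model$sub_models[[1]], g, cfg)
    expect_equal(fw$H, Ho, tolerance = 1e-10)
  }
})

test_that("isolated-node and zero-weight limits hold", {
  model <- fixture_untrained_model(n_models = 1L, hidden = 5L)
  p <- model$sub_models[[1]]
  g <- featurize("C")                       # single node, no edges
  b <- smexplain:::batch_graphs(list(g))
  fw <- smexplain:::rgcn_forward_batch(p, b, model$config, keep = TRUE)
  H <- g$X
  for (l in seq_along(p$conv)) H <- pmax(H %*% p$conv[[l]]$W0, 0)
  expect_equal(fw$H, H, tolerance = 1e-12)

  zm <- zero_weights(model)
  fwz <- smexplain:::rgcn_forward_batch(zm$sub_models[[1]], b, model$config,
                                        keep = TRUE)
  expect_true(all(fwz$H == 0))
})

test_that("masked attention readout equals per-node summation oracle", {
  model <- fixture_untrained_model(n_models = 1L, hidden = 6L)
  cfg <- model$config
  set.seed(99)
  g <- featurize("NCC(=O)c1ccc(O)cc1")     # 8+ nodes
  b <- smexplain:::batch_graphs(list(g))
  p <- model$sub_models[[1]]
  fw <- smexplain:::rgcn_forward_batch(p, b, cfg, keep = TRUE)
  for (trial in 1:20) {
    mask <- sample(c(0, 1), g$n, replace = TRUE)
    got <- smexplain:::rgcn_head_masked(p, b, cfg, fw$H, fw$om, list(mask))
    want <- masked_head_oracle(p, fw$H, mask, cfg)
    expect_equal(drop(got), want, tolerance = 1e-10)
  }
  # all-ones mask reproduces the unmasked readout
  got1 <- smexplain:::rgcn_head_masked(p, b, cfg, fw$H, fw$om,
                                       list(rep(1, g$n)))
  expect_equal(drop(got1), fw$pred, tolerance = 1e-12)
  # all-zero mask gives the head output at the zero embedding
  got0 <- smexplain:::rgcn_head_masked(p, b, cfg, fw$H, fw$om,
                                       list(rep(0, g$n)))
  expect_equal(drop(got0), masked_head_oracle(p, fw$H, rep(0, g$n), cfg),
               tolerance = 1e-12)
})

test_that("consensus prediction is the sub-model mean and order-invariant", {
  model <- fixture_untrained_model(n_models = 3L, hidden = 6L)
  g <- featurize("CCOc1ccccc1")
  preds <- vapply(model$sub_models, function(p)
    smexplain:::rgcn_forward_batch(p, smexplain:::batch_graphs(list(g)),
                                   model$config)$pred, 1)
  expect_equal(predict(model, g), mean(preds), tolerance = 1e-12)
  shuffled <- model
  shuffled$sub_models <- model$sub_models[c(3, 1, 2)]
  expect_equal(predict(shuffled, g), predict(model, g), tolerance = 1e-12)

  # identical sub-models collapse to a single model's output
  same <- model
  same$sub_models <- model$sub_models[c(1, 1, 1)]
  expect_equal(predict(same, g), preds[1], tolerance = 1e-12)
})

test_that("zero-weight regression consensus predicts the head bias", {
  model <- zero_weights(fixture_untrained_model(n_models = 2L))
  model$sub_models <- lapply(model$sub_models, function(p) {
    p$fc$b3 <- 0.7
    p
  })
  expect_equal(predict(model, "CCO"), 0.7, tolerance = 1e-12)
})

test_that("binary consensus outputs stay within [0, 1]", {
  model <- fixture_untrained_model(n_models = 2L, task = "binary")
  lib <- fixture_library()
  p <- predict(model, lib$smiles[1:30])
  expect_true(all(p >= 0 & p <= 1))
})

test_that("evaluation metrics match closed-form computation", {
  # regression: predictions equal to labels give R2 = 1
  expect_equal(smexplain:::r2_score(c(1, 2, 3), c(1, 2, 3)), 1)
  # 6-point toy table, hand-computed: SSres = 6*0.01, SStot = 4.375
  y <- c(1, 2, 3, 4, 5, 6) / 2
  yh <- y + c(0.1, -0.1, 0.1, -0.1, 0.1, -0.1)
  expect_equal(smexplain:::r2_score(y, yh), 1 - 0.06 / 4.375, tolerance = 1e-12)
  # AUC: perfect separation = 1; hand-computed 6-point case
  expect_equal(smexplain:::auc_score(c(0, 0, 0, 1, 1, 1),
                                     c(.1, .2, .3, .7, .8, .9)), 1)
  # one inversion among 3x3 pairs -> 8/9
  expect_equal(smexplain:::auc_score(c(0, 0, 0, 1, 1, 1),
                                     c(.1, .2, .75, .7, .8, .9)), 8 / 9)
  expect_error(smexplain:::auc_score(c(1, 1), c(.2, .3)), "single class")
  # independent cross-check of the rank-based AUC on a random case
  set.seed(12)
  y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  p <- runif(40) + 0.3 * y
  expect_equal(smexplain:::auc_score(y, p),
               as.numeric(suppressMessages(pROC::auc(y, p, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("training contract: smoke run, reproducibility, error cases", {
  ds <- fixture_small_model()$data
  cfg <- rgcn_config(n_layers = 1L, hidden = 8L, fc_dims = c(6L, 4L),
                     n_models = 1L, seeds = 0L, epochs = 1L, batch_size = 64L)
  m <- rgcn_consensus(ds$train[1:10, ], ds$val[1:5, ], config = cfg)
  expect_s3_class(m, "rgcn_consensus")
  expect_true(is.finite(predict(m, ds$test$smiles[1])))

  # same seed twice -> byte-identical sub-models
  cfg2 <- rgcn_config(n_layers = 1L, hidden = 8L, fc_dims = c(6L, 4L),
                      n_models = 2L, seeds = c(0L, 0L), epochs = 2L,
                      batch_size = 32L)
  m2 <- rgcn_consensus(ds$train[1:30, ], ds$val[1:10, ], config = cfg2)
  expect_identical(m2$sub_models[[1]][c("conv", "att", "fc")],
                   m2$sub_models[[2]][c("conv", "att", "fc")])

  expect_error(rgcn_consensus(list(), config = cfg), "empty")
  bad <- ds$train[1:10, ]; bad$label <- 1
  bval <- ds$val[1:5, ]; bval$label <- rep(c(0, 1), length.out = 5)
  cfgb <- cfg; cfgb$task <- "binary"
  expect_error(rgcn_consensus(bad, bval, config = cfgb), "single class")
})

test_that("trained small consensus reaches solid validation accuracy", {
  fm <- fixture_small_model()
  metric <- evaluate_consensus(fm$model, fm$data$test)
  expect_gt(metric[["r2"]], 0.8)
})

test_that("model methods expose the fit", {
  fm <- fixture_small_model()
  expect_output(print(fm$model), "Consensus RGCN")
  s <- summary(fm$model)
  expect_output(print(s), "parameters per sub-model")
  expect_length(coef(fm$model), fm$model$m)
  expect_equal(length(residuals(fm$model)), length(fitted(fm$model)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fm$model))
  expect_silent(plot(fm$model, "history"))
})
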