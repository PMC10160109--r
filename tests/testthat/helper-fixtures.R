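# Shared test fixtures, built once per test run and memoised in an
# environment: random molecule libraries for property-style checks and
# small/large trained consensus models for the attribution tests.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# 500-molecule library for structural property checks (partition, edge
# symmetry, determinism)
fixture_library <- function() {
  memo("library500", function() generate_library(500, seed = 101))
}

# small additive-regression dataset + a 2-sub-model consensus over it;
# enough signal for the qualitative attribution checks
fixture_small_model <- function() {
  memo("small_model", function() {
    ds <- make_dataset(label_spec("additive_regression", noise_sd = 0.1),
                       300, seed = 202)
    cfg <- rgcn_config(n_layers = 2L, hidden = 32L, fc_dims = c(64L, 32L),
                       task = "regression", n_models = 2L, seeds = c(0L, 1L),
                       epochs = 30L, patience = 15L, batch_size = 64L)
    model <- rgcn_consensus(ds$train, ds$val, config = cfg)
    list(model = model, data = ds)
  })
}

# study-size additive fixture (n = 2000, sd 0.1) and the reduced consensus
# trained on it (m = 3, hidden 64); shared by the parameter-recovery and
# generation tests
fixture_additive_study <- function() {
  memo("additive_study", function() {
    ds <- make_dataset(label_spec("additive_regression", noise_sd = 0.1),
                       2000, seed = 5)
    cfg <- rgcn_config(n_layers = 2L, hidden = 64L, fc_dims = c(128L, 64L),
                       task = "regression", n_models = 3L, seeds = 0:2,
                       epochs = 60L, patience = 12L, batch_size = 256L)
    model <- rgcn_consensus(ds$train, ds$val, config = cfg)
    list(model = model, data = ds)
  })
}

# memoised attributed fragment pool of the additive study model
fixture_pool_additive <- function() {
  memo("pool_additive", function() {
    st <- fixture_additive_study()
    build_pool(st$model, st$data$train[1:500, ])
  })
}

# binary toxicophore fixture and its consensus (m = 3)
fixture_binary_study <- function() {
  memo("binary_study", function() {
    spec <- label_spec("toxicophore_binary")
    ds <- make_dataset(spec, 1200, seed = 6)
    cfg <- rgcn_config(n_layers = 2L, hidden = 64L, fc_dims = c(128L, 64L),
                       task = "binary", n_models = 3L, seeds = 0:2,
                       epochs = 40L, patience = 10L, batch_size = 256L)
    model <- rgcn_consensus(ds$train, ds$val, config = cfg)
    list(model = model, data = ds, spec = spec)
  })
}

# an untrained, explicitly initialized tiny consensus for structural checks
fixture_untrained_model <- function(n_models = 2L, hidden = 8L, seed0 = 0L,
                                    task = "regression") {
  cfg <- rgcn_config(n_layers = 2L, hidden = hidden, fc_dims = c(6L, 5L),
                     task = task, n_models = n_models,
                     seeds = seed0 + seq_len(n_models) - 1L)
  fcfg <- feature_config()
  subs <- lapply(cfg$seeds, function(s)
    smexplain:::init_submodel(cfg, fcfg$d_node, fcfg$n_relations, s))
  structure(list(sub_models = subs, m = n_models, config = cfg,
                 feature_cfg = fcfg, task = task, metrics = NULL,
                 histories = NULL, call = NULL),
            class = "rgcn_consensus")
}

# zero out every weight of a consensus (predictions become the head bias)
zero_weights <- function(model) {
  zap <- function(x) if (is.list(x)) lapply(x, zap) else x * 0
  model$sub_models <- lapply(model$sub_models, function(p) {
    p[c("conv", "att", "fc")] <- zap(p[c("conv", "att", "fc")])
    p
  })
  model
}
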