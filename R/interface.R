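# Command-level interface: dataset I/O, model checkpoints and the run_*
# functions behind the command-line tool (inst/cli/sme.R). Every artifact
# carries a provenance header (package version + seed) and every command is
# reproducible from its arguments and seed.

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("smexplain")),
           error = function(e) "dev")
}

#' Read a molecule dataset CSV
#'
#' UTF-8 comma-separated file with a header; a `smiles` column is
#' mandatory, `id` and the label column optional. Unparsable SMILES rows
#' are dropped with a warning (their count is reported).
#'
#' @param path CSV path.
#' @param label_col name of the label column.
#' @return data.frame with columns `id`, `smiles` and (when present)
#'   `label`.
#' @export
read_dataset_csv <- function(path, label_col = "label") {
  if (!file.exists(path)) stop("data file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"smiles" %in% names(df))
    stop("dataset needs a 'smiles' column: ", path, call. = FALSE)
  out <- data.frame(
    id = if ("id" %in% names(df)) as.character(df$id) else
      as.character(seq_len(nrow(df))),
    smiles = df$smiles
  )
  if (label_col %in% names(df)) out$label <- as.numeric(df[[label_col]])
  ok <- vapply(out$smiles, function(s)
    tryCatch({ parse_smiles(s); TRUE }, error = function(e) FALSE), TRUE)
  if (any(!ok))
    warning(sum(!ok), " unparsable SMILES row(s) skipped", call. = FALSE)
  out[ok, , drop = FALSE]
}

write_with_provenance <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# smexplain %s%s", pkg_version(),
                     if (is.null(seed)) "" else paste0(" | seed ", seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
}

# --- checkpoints ------------------------------------------------------------

flatten_params <- function(x) {
  if (is.list(x)) return(lapply(x, flatten_params))
  list(dim = if (is.matrix(x)) dim(x) else length(x), data = as.numeric(x))
}

unflatten_params <- function(x) {
  if (!is.null(x$dim) && !is.null(x$data)) {
    d <- unlist(x$dim)
    v <- unlist(x$data)
    if (length(d) == 2L) return(matrix(v, d[1], d[2]))
    if (length(v) == 1L) return(v)
    return(v)
  }
  lapply(x, unflatten_params)
}

#' Save a consensus model checkpoint
#'
#' Writes a directory with a JSON manifest (configuration, seeds, feature
#' configuration, catalog version, metrics) plus one JSON weights file per
#' sub-model.
#'
#' @param model an `rgcn_consensus` model.
#' @param dir checkpoint directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package_version = pkg_version(),
    task = model$task,
    m = model$m,
    config = unclass(model$config),
    feature_cfg = unclass(model$feature_cfg),
    metrics = as.list(model$metrics),
    catalog_version = "v1"
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_len(model$m)) {
    p <- model$sub_models[[i]]
    jsonlite::write_json(
      list(seed = p$seed,
           weights = flatten_params(p[c("conv", "att", "fc")])),
      file.path(dir, sprintf("submodel_%02d.json", i)),
      auto_unbox = FALSE, digits = NA)
  }
  invisible(dir)
}

#' Load a consensus model checkpoint
#'
#' @param dir checkpoint directory written by [save_checkpoint()].
#' @return an `rgcn_consensus` model.
#' @export
load_checkpoint <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cfg <- mf$config
  config <- rgcn_config(
    n_layers = cfg$n_layers, hidden = cfg$hidden, n_bases = cfg$n_bases,
    fc_dims = unlist(cfg$fc_dims), task = cfg$task, lr = cfg$lr,
    epochs = cfg$epochs, patience = cfg$patience, batch_size = cfg$batch_size,
    n_models = cfg$n_models, seeds = unlist(cfg$seeds),
    normalize_degree = isTRUE(cfg$normalize_degree))
  fcg <- mf$feature_cfg
  feature_cfg <- feature_config(
    elements = unlist(fcg$elements), max_degree = fcg$max_degree,
    max_h = fcg$max_h, use_hybridization = isTRUE(fcg$use_hybridization))
  files <- sort(list.files(dir, pattern = "^submodel_\\d+\\.json$",
                           full.names = TRUE))
  if (length(files) != mf$m)
    stop("checkpoint has ", length(files), " weight files, manifest says ",
         mf$m, call. = FALSE)
  subs <- lapply(files, function(f) {
    j <- jsonlite::read_json(f)
    p <- unflatten_params(j$weights)
    p$att$w <- as.numeric(p$att$w)
    p$seed <- unlist(j$seed)
    p
  })
  structure(list(
    sub_models = subs, m = mf$m, config = config, feature_cfg = feature_cfg,
    task = mf$task, metrics = unlist(mf$metrics), histories = NULL,
    call = NULL), class = "rgcn_consensus")
}

# --- run commands -----------------------------------------------------------

#' Train a consensus model from a dataset CSV
#'
#' @param data_path labeled dataset CSV.
#' @param checkpoint_dir output checkpoint directory.
#' @param task `"regression"` or `"binary"`.
#' @param seed global seed; sub-model seeds default to `seed + 0:(m-1)`.
#' @param n_models,hidden,n_layers,epochs,patience,batch_size,lr model
#'   hyperparameters (see [rgcn_config()]).
#' @param val_path optional validation CSV; otherwise split off internally.
#' @param label_col label column name.
#' @return the fitted model, invisibly; the checkpoint (with metrics in the
#'   manifest) is written to `checkpoint_dir`.
#' @export
run_train <- function(data_path, checkpoint_dir, task = "regression",
                      seed = 0L, n_models = 10L, hidden = 64L, n_layers = 2L,
                      epochs = 200L, patience = 30L, batch_size = 128L,
                      lr = 1e-3, val_path = NULL, label_col = "label") {
  data <- read_dataset_csv(data_path, label_col)
  if (!"label" %in% names(data))
    stop("training data has no '", label_col, "' column", call. = FALSE)
  if (task == "binary" && !all(data$label %in% c(0, 1)))
    stop("task 'binary' requires 0/1 labels", call. = FALSE)
  if (task == "regression" && all(data$label %in% c(0, 1)))
    warning("labels look binary but task is 'regression'", call. = FALSE)
  val <- if (!is.null(val_path)) read_dataset_csv(val_path, label_col)
  config <- rgcn_config(n_layers = n_layers, hidden = hidden,
                        fc_dims = c(128L, 64L), task = task, lr = lr,
                        epochs = epochs, patience = patience,
                        batch_size = batch_size, n_models = n_models,
                        seeds = seed + seq_len(n_models) - 1L)
  model <- rgcn_consensus(data, val = val, config = config)
  save_checkpoint(model, checkpoint_dir)
  invisible(model)
}

#' Explain a dataset from a checkpoint
#'
#' @param checkpoint_dir checkpoint directory.
#' @param data_path dataset CSV.
#' @param out_path output attribution CSV.
#' @param schemes fragmentation schemes.
#' @param combinations include random fragment combinations.
#' @param normalize normalization method.
#' @param max_n combination cap.
#' @param seed RNG seed.
#' @return the attribution data.frame, invisibly.
#' @export
run_explain <- function(checkpoint_dir, data_path, out_path,
                        schemes = c("BRICS", "MURCKO", "FUNCTIONAL_GROUP"),
                        combinations = FALSE, normalize = "maxabs",
                        max_n = 100L, seed = 1L) {
  model <- load_checkpoint(checkpoint_dir)
  data <- read_dataset_csv(data_path)
  rows <- explain(model, data, schemes = schemes, combinations = combinations,
                  normalize = normalize, max_n = max_n, seed = seed)
  write_with_provenance(rows, out_path, seed)
  invisible(rows)
}

#' Functional-group attribution table from a checkpoint
#'
#' @inheritParams run_explain
#' @param min_count occurrence threshold.
#' @return the table, invisibly.
#' @export
run_fgtable <- function(checkpoint_dir, data_path, out_path, min_count = 10L) {
  model <- load_checkpoint(checkpoint_dir)
  data <- read_dataset_csv(data_path)
  tab <- fg_attribution_table(model, data, min_count = min_count)
  write_with_provenance(as.data.frame(tab), out_path)
  invisible(tab)
}

#' Correlate two functional-group attribution tables
#'
#' @param table_a,table_b CSV paths written by [run_fgtable()].
#' @param out_path output JSON report.
#' @return the correlation report, invisibly.
#' @export
run_correlate <- function(table_a, table_b, out_path) {
  ta <- utils::read.csv(table_a, comment.char = "#")
  tb <- utils::read.csv(table_b, comment.char = "#")
  res <- cross_property_correlation(ta, tb)
  res$provenance <- sprintf("smexplain %s", pkg_version())
  jsonlite::write_json(res, out_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(res)
}

#' Optimization suggestions for one molecule
#'
#' @param table_path functional-group table CSV ([run_fgtable()]).
#' @param smiles molecule SMILES.
#' @param out_path output CSV.
#' @param direction `"decrease"` or `"increase"`.
#' @return the suggestion table, invisibly.
#' @export
run_optimize <- function(table_path, smiles, out_path,
                         direction = "decrease") {
  tab <- utils::read.csv(table_path, comment.char = "#")
  sug <- optimization_suggestions(smiles, tab, direction = direction)
  write_with_provenance(sug, out_path)
  invisible(sug)
}

#' Attribution-based molecule generation from a checkpoint
#'
#' @inheritParams run_explain
#' @param sign fragment pool sign (`"positive"` or `"negative"`).
#' @param top_fraction extreme fraction of the pool to keep.
#' @param n_molecules number of molecules to generate.
#' @param smi_path output SMILES file (one molecule per line).
#' @return data.frame of generated SMILES and predictions, invisibly.
#' @export
run_generate <- function(checkpoint_dir, data_path, out_path, smi_path = NULL,
                         sign = "negative", top_fraction = 0.2,
                         n_molecules = 3000L, seed = 1L) {
  model <- load_checkpoint(checkpoint_dir)
  data <- read_dataset_csv(data_path)
  pool <- build_pool(model, data)
  sel <- select_fragments(pool, sign = sign, top_fraction = top_fraction)
  smis <- recombine(sel, n_molecules = n_molecules, seed = seed)
  out <- data.frame(smiles = smis, prediction = predict(model, smis),
                    pool_of_origin = sign)
  write_with_provenance(out, out_path, seed)
  if (!is.null(smi_path)) writeLines(smis, smi_path)
  invisible(out)
}

#' Write a synthetic fixture dataset
#'
#' @param task label-model task (see [label_spec()]).
#' @param n library size.
#' @param seed RNG seed.
#' @param out_prefix output prefix; writes `<prefix>_train.csv`,
#'   `<prefix>_val.csv`, `<prefix>_test.csv`.
#' @param noise_sd additive-task noise standard deviation.
#' @return the dataset list, invisibly.
#' @export
run_fixtures <- function(task = "additive_regression", n = 1000L, seed = 1L,
                         out_prefix = "fixture", noise_sd = 0.1) {
  spec <- label_spec(task, noise_sd = noise_sd)
  ds <- make_dataset(spec, n, seed = seed)
  for (part in names(ds))
    write_with_provenance(ds[[part]], paste0(out_prefix, "_", part, ".csv"),
                          seed)
  invisible(ds)
}
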