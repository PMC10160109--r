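# Consensus RGCN fitting.
#
# rgcn_consensus() is the package's central model-fitting function: it
# trains m RGCN sub-models from different random seeds (Adam, early stopping
# on validation loss) and aggregates them into a consensus whose prediction
# is the mean of the sub-model outputs (post-sigmoid probabilities for
# binary tasks). Gradients are computed by hand over the sparse
# block-diagonal batch representation.

prepare_records <- function(data) {
  if (inherits(data, "sme_molecule")) data <- list(data)
  if (is.data.frame(data)) {
    if (!"smiles" %in% names(data)) stop("data needs a 'smiles' column", call. = FALSE)
    ids <- if ("id" %in% names(data)) as.character(data$id) else
      as.character(seq_len(nrow(data)))
    labels <- if ("label" %in% names(data)) data$label else rep(NA_real_, nrow(data))
    records <- lapply(seq_len(nrow(data)), function(i)
      molecule_record(ids[i], data$smiles[i],
                      if (is.na(labels[i])) NULL else labels[i]))
    return(records)
  }
  if (is.character(data))
    return(lapply(seq_along(data), function(i) molecule_record(i, data[i])))
  if (is.list(data) && all(vapply(data, inherits, TRUE, "sme_molecule")))
    return(data)
  stop("unsupported dataset type", call. = FALSE)
}

record_labels <- function(records) {
  vapply(records, function(r) if (is.null(r$label)) NA_real_ else r$label, 1)
}

# --- gradients --------------------------------------------------------------

grad_submodel <- function(params, batch, y, cfg) {
  fw <- rgcn_forward_batch(params, batch, cfg, keep = TRUE)
  nm <- batch$n_mols
  if (cfg$task == "binary") {
    p <- fw$pred
    eps <- 1e-12
    loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
    dyraw <- (p - y) / nm
  } else {
    loss <- mean((fw$yraw - y)^2)
    dyraw <- 2 * (fw$yraw - y) / nm
  }
  fc <- params$fc
  g <- list()
  g$fc <- list()
  g$fc$W3 <- t(fw$A2) %*% dyraw
  g$fc$b3 <- sum(dyraw)
  dA2 <- outer(dyraw, drop(fc$W3))
  dZ2 <- dA2 * (fw$Z2 > 0)
  g$fc$W2 <- t(fw$A1) %*% dZ2
  g$fc$b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(fc$W2)
  dZ1 <- dA1 * (fw$Z1 > 0)
  g$fc$W1 <- t(fw$E) %*% dZ1
  g$fc$b1 <- colSums(dZ1)
  dE <- dZ1 %*% t(fc$W1)

  H <- fw$H
  dHg <- as.matrix(Matrix::t(batch$P) %*% dE)
  dH <- dHg * fw$g
  dom <- rowSums(dHg * H) * fw$mask
  ds <- dom * fw$om * (1 - fw$om)
  g$att <- list(w = drop(t(H) %*% ds), b = sum(ds))
  dH <- dH + outer(ds, params$att$w)

  nL <- length(params$conv)
  g$conv <- vector("list", nL)
  for (l in rev(seq_len(nL))) {
    layer <- params$conv[[l]]
    Hin <- fw$Hs[[l]]
    dZ <- dH * (fw$Zs[[l]] > 0)
    gW0 <- t(Hin) %*% dZ
    dHin <- dZ %*% t(layer$W0)
    Wr <- fw$Ws[[l]]
    R <- length(Wr)
    dWr <- vector("list", R)
    for (r in seq_len(R)) {
      AH <- as.matrix(batch$A[[r]] %*% Hin)
      dWr[[r]] <- t(AH) %*% dZ
      dHin <- dHin + as.matrix(Matrix::t(batch$A[[r]]) %*% dZ) %*% t(Wr[[r]])
    }
    nb <- length(layer$V)
    gV <- vector("list", nb)
    gcomb <- matrix(0, R, nb)
    for (b in seq_len(nb)) {
      acc <- layer$comb[1, b] * dWr[[1]]
      if (R > 1L) for (r in 2:R) acc <- acc + layer$comb[r, b] * dWr[[r]]
      gV[[b]] <- acc
      for (r in seq_len(R)) gcomb[r, b] <- sum(dWr[[r]] * layer$V[[b]])
    }
    g$conv[[l]] <- list(V = gV, comb = gcomb, W0 = gW0)
    dH <- dHin
  }
  list(loss = loss, grads = g)
}

# --- Adam over nested parameter lists --------------------------------------

adam_init <- function(params) {
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    list(m = x * 0, v = x * 0)
  }
  lapply(params[c("conv", "att", "fc")], walk)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) names(p)
              else seq_along(p)
      for (k in keys) {
        r <- upd(p[[k]], g[[k]], s[[k]])
        out_p[[k]] <- r$p; out_s[[k]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    g <- as.matrix(g)
    if (!is.matrix(p)) g <- drop(g)
    m <- beta1 * s$m + (1 - beta1) * g
    v <- beta2 * s$v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
  }
  slots <- c("conv", "att", "fc")
  for (k in slots) {
    r <- upd(params[[k]], grads[[k]], state[[k]])
    params[[k]] <- r$p; state[[k]] <- r$s
  }
  list(params = params, state = state)
}

# --- metrics ----------------------------------------------------------------

r2_score <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

auc_score <- function(y, p) {
  if (length(unique(y)) < 2L)
    stop("ROC-AUC undefined: evaluation set has a single class", call. = FALSE)
  r <- rank(p, ties.method = "average")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# --- the fitting function ---------------------------------------------------

#' Fit a consensus RGCN property model
#'
#' Trains `config$n_models` relational graph convolutional sub-models with
#' attention-pooled readout and a three-layer fully connected head, one per
#' random seed, and aggregates them into a consensus whose prediction is
#' the mean of the sub-model outputs. Training minimizes mean squared error
#' (regression) or cross-entropy (binary classification) with Adam and
#' early stopping on validation loss.
#'
#' @param data training set: a data.frame with columns `smiles`, `label`
#'   (and optionally `id`), or a list of [molecule_record()]s.
#' @param val validation set in the same format; if `NULL`, a random 1/9 of
#'   `data` is held out (seeded by the first sub-model seed).
#' @param config an [rgcn_config()] object; its `task` must match the labels.
#' @param feature_cfg a [feature_config()] object.
#' @param verbose print per-epoch validation losses.
#' @return an object of class `rgcn_consensus` with `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals` and `plot` methods.
#' @seealso [predict.rgcn_consensus()], [explain()], [evaluate_consensus()]
#' @export
rgcn_consensus <- function(data, val = NULL, config = rgcn_config(),
                           feature_cfg = feature_config(), verbose = FALSE) {
  cl <- match.call()
  train_rec <- prepare_records(data)
  if (!length(train_rec)) stop("empty training set", call. = FALSE)
  y_tr <- record_labels(train_rec)
  if (anyNA(y_tr)) stop("training set has missing labels", call. = FALSE)
  if (is.null(val)) {
    set.seed(config$seeds[1])
    nv <- max(1L, floor(length(train_rec) / 9))
    vi <- sample(seq_along(train_rec), nv)
    val_rec <- train_rec[vi]; train_rec <- train_rec[-vi]
    y_tr <- record_labels(train_rec)
  } else {
    val_rec <- prepare_records(val)
  }
  y_va <- record_labels(val_rec)
  if (anyNA(y_va)) stop("validation set has missing labels", call. = FALSE)
  if (config$task == "binary") {
    if (!all(y_tr %in% c(0, 1)) || !all(y_va %in% c(0, 1)))
      stop("binary task requires 0/1 labels", call. = FALSE)
    if (length(unique(y_tr)) < 2L)
      stop("binary training set has a single class", call. = FALSE)
  }

  g_tr <- lapply(train_rec, featurize, cfg = feature_cfg)
  g_va <- lapply(val_rec, featurize, cfg = feature_cfg)
  vbatch <- batch_graphs(g_va, config$normalize_degree)
  d_node <- ncol(g_tr[[1]]$X)
  R <- feature_cfg$n_relations
  ntr <- length(g_tr)

  sub_models <- vector("list", config$n_models)
  histories <- vector("list", config$n_models)
  for (mi in seq_len(config$n_models)) {
    seed <- config$seeds[mi]
    params <- init_submodel(config, d_node, R, seed)
    state <- adam_init(params)
    best <- list(loss = Inf, params = params)
    stall <- 0L; t <- 0L
    hist <- numeric(0)
    for (ep in seq_len(config$epochs)) {
      idx <- sample(ntr)
      nb <- ceiling(ntr / config$batch_size)
      for (bi in seq_len(nb)) {
        sel <- idx[seq.int((bi - 1L) * config$batch_size + 1L,
                           min(bi * config$batch_size, ntr))]
        batch <- batch_graphs(g_tr[sel], config$normalize_degree)
        gr <- grad_submodel(params, batch, y_tr[sel], config)
        t <- t + 1L
        up <- adam_step(params, gr$grads, state, config$lr, t)
        params <- up$params; state <- up$state
      }
      vf <- rgcn_forward_batch(params, vbatch, config)
      vloss <- if (config$task == "binary") {
        eps <- 1e-12
        -mean(y_va * log(vf$pred + eps) + (1 - y_va) * log(1 - vf$pred + eps))
      } else mean((vf$pred - y_va)^2)
      hist <- c(hist, vloss)
      if (verbose) message(sprintf("model %d epoch %d val loss %.5f", mi, ep, vloss))
      if (vloss < best$loss - 1e-7) {
        best <- list(loss = vloss, params = params); stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
    best$params$seed <- seed
    sub_models[[mi]] <- best$params
    histories[[mi]] <- hist
  }

  model <- structure(list(
    sub_models = sub_models,
    m = config$n_models,
    config = config,
    feature_cfg = feature_cfg,
    task = config$task,
    histories = histories,
    train_records = NULL,
    call = cl
  ), class = "rgcn_consensus")
  vp <- predict(model, val_rec)
  model$metrics <- if (config$task == "binary")
    c(roc_auc = auc_score(y_va, vp)) else c(r2 = r2_score(y_va, vp))
  model$val_pred <- vp
  model$val_obs <- y_va
  model
}

#' Predict from a consensus RGCN
#'
#' @param object an `rgcn_consensus` model.
#' @param newdata molecules: data.frame with a `smiles` column, character
#'   vector of SMILES, list of molecule records, or a single `sme_graph`.
#' @param mask optional 0/1 node mask (1 = kept). Only allowed when
#'   `newdata` is a single molecule/graph; the mask enters at the readout
#'   (message passing always sees the full graph).
#' @param ... unused.
#' @return numeric vector of consensus predictions (mean over sub-models;
#'   probabilities in \[0, 1\] for binary tasks).
#' @export
predict.rgcn_consensus <- function(object, newdata, mask = NULL, ...) {
  if (inherits(newdata, "sme_graph")) {
    graphs <- list(newdata)
  } else {
    records <- prepare_records(newdata)
    graphs <- lapply(records, featurize, cfg = object$feature_cfg)
  }
  if (!is.null(mask) && length(graphs) != 1L)
    stop("a mask can only be supplied for a single molecule", call. = FALSE)
  batch <- batch_graphs(graphs, object$config$normalize_degree)
  if (!is.null(mask)) {
    if (length(mask) != batch$n) stop("mask length must equal node count", call. = FALSE)
    if (!all(mask %in% c(0, 1))) stop("mask entries must be 0 or 1", call. = FALSE)
  }
  preds <- vapply(object$sub_models, function(p)
    rgcn_forward_batch(p, batch, object$config, mask = mask)$pred,
    numeric(batch$n_mols))
  if (batch$n_mols == 1L) mean(preds) else rowMeans(preds)
}

#' Evaluate a consensus model
#'
#' Computes the task metric on a labeled dataset: R-squared for regression,
#' ROC-AUC for binary classification.
#'
#' @param model an `rgcn_consensus` model.
#' @param data labeled dataset (see [rgcn_consensus()] formats).
#' @return named numeric scalar (`r2` or `roc_auc`).
#' @export
evaluate_consensus <- function(model, data) {
  records <- prepare_records(data)
  if (!length(records)) stop("empty evaluation set", call. = FALSE)
  y <- record_labels(records)
  if (anyNA(y)) stop("evaluation set has missing labels", call. = FALSE)
  p <- predict(model, records)
  if (model$task == "binary") c(roc_auc = auc_score(y, p)) else c(r2 = r2_score(y, p))
}

#' @export
print.rgcn_consensus <- function(x, ...) {
  cat("Consensus RGCN model\n")
  cat(sprintf("  task: %s | sub-models: %d | layers: %d | hidden: %d | relations: %d\n",
              x$task, x$m, x$config$n_layers, x$config$hidden,
              x$feature_cfg$n_relations))
  if (!is.null(x$metrics))
    cat(sprintf("  validation %s: %.4f\n", names(x$metrics)[1], x$metrics[1]))
  invisible(x)
}

#' @export
summary.rgcn_consensus <- function(object, ...) {
  np <- sum(rapply(object$sub_models[[1]][c("conv", "att", "fc")],
                   length, how = "unlist"))
  epochs <- vapply(object$histories, length, 1L)
  out <- list(task = object$task, m = object$m,
              n_parameters = np, seeds = object$config$seeds,
              epochs_trained = epochs, metrics = object$metrics)
  class(out) <- "summary.rgcn_consensus"
  out
}

#' @export
print.summary.rgcn_consensus <- function(x, ...) {
  cat("Consensus RGCN summary\n")
  cat(sprintf("  task: %s\n  sub-models: %d (seeds %s)\n", x$task, x$m,
              paste(x$seeds, collapse = ", ")))
  cat(sprintf("  parameters per sub-model: %d\n", x$n_parameters))
  cat(sprintf("  epochs trained: %s\n", paste(x$epochs_trained, collapse = ", ")))
  if (!is.null(x$metrics))
    cat(sprintf("  validation %s: %.4f\n", names(x$metrics)[1], x$metrics[1]))
  invisible(x)
}

#' @export
coef.rgcn_consensus <- function(object, submodel = NULL, ...) {
  if (is.null(submodel)) return(lapply(object$sub_models, function(p)
    p[c("conv", "att", "fc")]))
  object$sub_models[[submodel]][c("conv", "att", "fc")]
}

#' @export
fitted.rgcn_consensus <- function(object, ...) object$val_pred

#' @export
residuals.rgcn_consensus <- function(object, ...) object$val_obs - object$val_pred

#' @export
plot.rgcn_consensus <- function(x, which = c("fit", "history"), ...) {
  which <- match.arg(which)
  if (which == "history") {
    hs <- x$histories
    graphics::plot(NULL, xlim = c(1, max(vapply(hs, length, 1L))),
                   ylim = range(unlist(hs)), xlab = "epoch",
                   ylab = "validation loss", main = "training history")
    for (h in hs) graphics::lines(seq_along(h), h, col = "grey40")
  } else {
    graphics::plot(x$val_obs, x$val_pred, xlab = "observed",
                   ylab = "consensus prediction",
                   main = "validation fit", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
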