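# RGCN sub-model: parameterization and forward pass.
#
# Propagation per layer: h_v <- ReLU( sum_r sum_{u in N_v^r} W_r h_u + W0 h_v ),
# with no degree normalization; W_r is a linear combination of n_bases basis
# matrices. Readout is attention pooling with per-node sigmoid gates; the
# substructure mask enters only at the readout, never during message
# passing. The head is three fully connected layers ending in one output,
# passed through a sigmoid for binary tasks.

#' RGCN consensus configuration
#'
#' @param n_layers number of graph-convolution layers.
#' @param hidden hidden dimension of the convolution layers.
#' @param n_bases number of basis matrices for the relation-weight
#'   decomposition (defaults to the number of relations, i.e. independent
#'   relation weights).
#' @param fc_dims widths of the first two fully connected head layers; the
#'   third layer always has one output.
#' @param task `"regression"` or `"binary"`.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param batch_size minibatch size.
#' @param n_models number of sub-models in the consensus.
#' @param seeds integer seed per sub-model; defaults to `0:(n_models-1)`.
#' @param normalize_degree divide aggregated neighbour messages by the
#'   per-relation in-degree (off by default, matching the propagation rule
#'   as stated above).
#' @return an object of class `sme_rgcn_config`.
#' @export
rgcn_config <- function(n_layers = 2L, hidden = 64L, n_bases = 4L,
                        fc_dims = c(128L, 64L), task = c("regression", "binary"),
                        lr = 1e-3, epochs = 200L, patience = 30L,
                        batch_size = 128L, n_models = 10L, seeds = NULL,
                        normalize_degree = FALSE) {
  task <- match.arg(task)
  if (n_layers < 1L) stop("n_layers must be >= 1", call. = FALSE)
  if (n_bases < 1L) stop("n_bases must be >= 1", call. = FALSE)
  if (length(fc_dims) != 2L) stop("fc_dims must give the two hidden FC widths",
                                  call. = FALSE)
  if (is.null(seeds)) seeds <- seq.int(0L, n_models - 1L)
  if (length(seeds) != n_models) stop("need one seed per sub-model", call. = FALSE)
  out <- list(n_layers = as.integer(n_layers), hidden = as.integer(hidden),
              n_bases = as.integer(n_bases), fc_dims = as.integer(fc_dims),
              task = task, lr = lr, epochs = as.integer(epochs),
              patience = as.integer(patience), batch_size = as.integer(batch_size),
              n_models = as.integer(n_models), seeds = as.integer(seeds),
              normalize_degree = isTRUE(normalize_degree))
  class(out) <- "sme_rgcn_config"
  out
}

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

init_submodel <- function(cfg, d_node, n_relations, seed) {
  set.seed(seed)
  dims <- c(d_node, rep(cfg$hidden, cfg$n_layers))
  conv <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    din <- dims[l]; dout <- dims[l + 1L]
    conv[[l]] <- list(
      V = lapply(seq_len(cfg$n_bases), function(b) glorot(din, dout)),
      comb = matrix(stats::runif(n_relations * cfg$n_bases, -1, 1) /
                      cfg$n_bases, n_relations, cfg$n_bases),
      W0 = glorot(din, dout)
    )
  }
  h <- cfg$hidden
  params <- list(
    conv = conv,
    att = list(w = drop(glorot(h, 1L)), b = 0),
    fc = list(W1 = glorot(h, cfg$fc_dims[1]), b1 = numeric(cfg$fc_dims[1]),
              W2 = glorot(cfg$fc_dims[1], cfg$fc_dims[2]), b2 = numeric(cfg$fc_dims[2]),
              W3 = glorot(cfg$fc_dims[2], 1L), b3 = 0),
    seed = seed
  )
  params
}

relation_weights <- function(layer) {
  nb <- length(layer$V)
  R <- nrow(layer$comb)
  lapply(seq_len(R), function(r) {
    W <- layer$comb[r, 1] * layer$V[[1]]
    if (nb > 1L) for (b in 2:nb) W <- W + layer$comb[r, b] * layer$V[[b]]
    W
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass of one sub-model over a batch. `mask` is a 0/1 vector over
# all batch nodes (1 = kept); it enters only at the readout. With
# `keep = TRUE` all intermediates needed for backprop are returned.
rgcn_forward_batch <- function(params, batch, cfg, mask = NULL, keep = FALSE) {
  if (is.null(mask)) mask <- rep(1, batch$n)
  if (length(mask) != batch$n) stop("mask length must equal node count", call. = FALSE)
  H <- batch$X
  Hs <- list(H)
  Zs <- list()
  Ws <- list()
  for (l in seq_along(params$conv)) {
    layer <- params$conv[[l]]
    Wr <- relation_weights(layer)
    Z <- H %*% layer$W0
    for (r in seq_along(Wr)) {
      Z <- Z + as.matrix(batch$A[[r]] %*% (H %*% Wr[[r]]))
    }
    H <- pmax(Z, 0)
    if (keep) { Zs[[l]] <- Z; Hs[[l + 1L]] <- H; Ws[[l]] <- Wr }
  }
  s <- drop(H %*% params$att$w) + params$att$b
  om <- sigmoid(s)
  g <- om * mask
  E <- as.matrix(batch$P %*% (H * g))
  fc <- params$fc
  Z1 <- sweep(E %*% fc$W1, 2L, fc$b1, "+"); A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% fc$W2, 2L, fc$b2, "+"); A2 <- pmax(Z2, 0)
  yraw <- drop(A2 %*% fc$W3) + fc$b3
  pred <- if (cfg$task == "binary") sigmoid(yraw) else yraw
  if (!keep) return(list(pred = pred, yraw = yraw))
  list(pred = pred, yraw = yraw, H = H, Hs = Hs, Zs = Zs, Ws = Ws,
       s = s, om = om, g = g, mask = mask, E = E,
       Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2)
}

# Given node hidden states of the final conv layer (which do not depend on
# the mask), recompute readout + head for an arbitrary set of masks without
# re-running message passing. `masks` is a list of 0/1 vectors.
rgcn_head_masked <- function(params, batch, cfg, H, om, masks) {
  fc <- params$fc
  vapply(masks, function(mask) {
    g <- om * mask
    E <- as.matrix(batch$P %*% (H * g))
    A1 <- pmax(sweep(E %*% fc$W1, 2L, fc$b1, "+"), 0)
    A2 <- pmax(sweep(A1 %*% fc$W2, 2L, fc$b2, "+"), 0)
    yraw <- drop(A2 %*% fc$W3) + fc$b3
    if (cfg$task == "binary") sigmoid(yraw) else yraw
  }, numeric(batch$n_mols))
}
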