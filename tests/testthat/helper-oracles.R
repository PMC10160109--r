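# Independent oracles for the network forward pass and the masked readout,
# written as explicit per-node/per-relation summations (no sparse algebra,
# no shared code with the implementation paths they check).

# explicit double sum over relations and neighbours, layer by layer
dense_forward_oracle <- function(params, graph, cfg) {
  H <- graph$X
  for (l in seq_along(params$conv)) {
    layer <- params$conv[[l]]
    Wr <- smexplain:::relation_weights(layer)
    Z <- matrix(0, graph$n, ncol(layer$W0))
    for (v in seq_len(graph$n)) {
      acc <- drop(H[v, ] %*% layer$W0)
      for (r in seq_len(graph$n_relations)) {
        nb <- graph$edges$src[graph$edges$dst == v & graph$edges$rel == r]
        for (u in nb) acc <- acc + drop(H[u, ] %*% Wr[[r]])
      }
      Z[v, ] <- acc
    }
    H <- pmax(Z, 0)
  }
  H
}

# explicit per-node summation of the masked attention readout + FC head
masked_head_oracle <- function(params, H, mask, cfg) {
  emb <- numeric(ncol(H))
  for (v in seq_len(nrow(H))) {
    om <- 1 / (1 + exp(-(sum(params$att$w * H[v, ]) + params$att$b)))
    emb <- emb + om * H[v, ] * mask[v]
  }
  fc <- params$fc
  a1 <- pmax(drop(emb %*% fc$W1) + fc$b1, 0)
  a2 <- pmax(drop(a1 %*% fc$W2) + fc$b2, 0)
  y <- sum(a2 * fc$W3) + fc$b3
  if (cfg$task == "binary") 1 / (1 + exp(-y)) else y
}
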