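# Featurized relational molecular graphs.
#
# One node per heavy atom (in SMILES parse order, matching the fragmenter's
# atom indexing), one relation-typed directed edge per bond per direction.
# Node features and the relation scheme are configurable; the defaults are
# the package's own choice of the standard molecular-GNN feature set.

#' Node-feature and relation configuration
#'
#' @param elements element vocabulary for the one-hot element block; atoms
#'   outside it map to a shared "other" slot (with a warning at featurize
#'   time).
#' @param max_degree degrees `0..max_degree` are one-hot encoded.
#' @param max_h implicit-H counts `0..max_h` are one-hot encoded.
#' @param use_hybridization include a one-hot {sp, sp2, sp3, other} block.
#' @param relations the bond-type relation scheme; currently the single
#'   supported scheme is `"bond_order"`: {single, double, triple, aromatic}.
#' @return an object of class `sme_feature_config`.
#' @export
feature_config <- function(elements = c("B", "C", "N", "O", "F", "Si", "P",
                                        "S", "Cl", "Br", "I"),
                           max_degree = 5L, max_h = 4L,
                           use_hybridization = TRUE,
                           relations = "bond_order") {
  relations <- match.arg(relations)
  cfg <- list(elements = elements, max_degree = as.integer(max_degree),
              max_h = as.integer(max_h),
              use_hybridization = isTRUE(use_hybridization),
              relations = relations)
  cfg$n_relations <- 4L
  cfg$d_node <- length(elements) + 1L + (cfg$max_degree + 1L) + 1L +
    (cfg$max_h + 1L) + if (cfg$use_hybridization) 4L else 0L
  cfg$d_node <- cfg$d_node + 2L   # aromatic flag + ring flag
  class(cfg) <- "sme_feature_config"
  cfg
}

atom_hybridization <- function(mol, v) {
  if (mol$aromatic[v]) return("sp2")
  b <- mol$bonds
  sel <- b$a1 == v | b$a2 == v
  if (any(b$order[sel] == 3L)) return("sp")
  if (any(b$order[sel] == 2L)) return("sp2")
  if (mol$symbol[v] %in% c("C", "N", "O", "S", "P", "B", "Si")) return("sp3")
  "other"
}

#' Featurize a molecule into a relational graph
#'
#' @param mol molecule record, `sme_mol` or SMILES string.
#' @param cfg an [feature_config()] object.
#' @return an object of class `sme_graph`: node feature matrix `X`
#'   (n_nodes x d_node), directed edge table `edges` (src, dst, rel) with
#'   both directions present for every bond, and `n_relations`.
#' @export
featurize <- function(mol, cfg = feature_config()) {
  m <- as_sme_mol(mol)
  n <- m$n
  d <- cfg$d_node
  X <- matrix(0, n, d)
  ne <- length(cfg$elements)
  unknown <- character(0)
  for (v in seq_len(n)) {
    j <- 0L
    sym <- m$symbol[v]
    slot <- match(sym, cfg$elements)
    if (is.na(slot)) { slot <- ne + 1L; unknown <- c(unknown, sym) }
    X[v, j + slot] <- 1; j <- j + ne + 1L
    dg <- min(m$degree[v], cfg$max_degree)
    X[v, j + dg + 1L] <- 1; j <- j + cfg$max_degree + 1L
    X[v, j + 1L] <- m$charge[v]; j <- j + 1L
    hh <- min(m$nH[v], cfg$max_h)
    X[v, j + hh + 1L] <- 1; j <- j + cfg$max_h + 1L
    if (cfg$use_hybridization) {
      hy <- match(atom_hybridization(m, v), c("sp", "sp2", "sp3", "other"))
      X[v, j + hy] <- 1; j <- j + 4L
    }
    X[v, j + 1L] <- as.numeric(m$aromatic[v])
    X[v, j + 2L] <- as.numeric(m$in_ring[v])
  }
  if (length(unknown))
    warning("element(s) outside vocabulary mapped to 'other': ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  b <- m$bonds
  rel <- ifelse(b$aromatic, 4L, b$order)   # single=1, double=2, triple=3, aromatic=4
  edges <- data.frame(src = c(b$a1, b$a2), dst = c(b$a2, b$a1),
                      rel = c(rel, rel))
  g <- list(n = n, X = X, edges = edges, n_relations = cfg$n_relations,
            smiles = if (inherits(mol, "sme_molecule")) mol$smiles else mol_to_smiles(m))
  class(g) <- "sme_graph"
  g
}

#' @export
print.sme_graph <- function(x, ...) {
  cat(sprintf("<molecular graph: %d nodes, %d directed edges, %d relations, d=%d>\n",
              x$n, nrow(x$edges), x$n_relations, ncol(x$X)))
  invisible(x)
}

# Stack a list of graphs into one block-diagonal batch: dense node features,
# per-relation sparse adjacency (A_r[v,u] = 1 for edge u->v), and a sparse
# molecule-pooling indicator P (n_mols x n_nodes).
batch_graphs <- function(graphs, normalize_degree = FALSE) {
  ns <- vapply(graphs, `[[`, 1L, "n")
  offs <- cumsum(c(0L, ns[-length(ns)]))
  N <- sum(ns)
  X <- do.call(rbind, lapply(graphs, `[[`, "X"))
  R <- graphs[[1]]$n_relations
  src <- integer(0); dst <- integer(0); rel <- integer(0)
  for (i in seq_along(graphs)) {
    e <- graphs[[i]]$edges
    if (nrow(e)) {
      src <- c(src, e$src + offs[i]); dst <- c(dst, e$dst + offs[i])
      rel <- c(rel, e$rel)
    }
  }
  A <- lapply(seq_len(R), function(r) {
    sel <- rel == r
    M <- Matrix::sparseMatrix(i = dst[sel], j = src[sel], x = 1, dims = c(N, N))
    if (normalize_degree) {
      deg <- Matrix::rowSums(M)
      M <- Matrix::Diagonal(x = 1 / pmax(deg, 1)) %*% M
    }
    M
  })
  P <- Matrix::sparseMatrix(i = rep(seq_along(graphs), ns),
                            j = sequence(ns) + rep(offs, ns),
                            x = 1, dims = c(length(graphs), N))
  list(X = X, A = A, P = P, n = N, n_mols = length(graphs), ns = ns, offs = offs)
}
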