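# Attribution-based molecule generation: score BRICS fragments by mean
# attribution, select the extreme fraction of either sign, and reassemble
# fragments at complementary BRICS link types into new molecules.

brics_compat_pairs <- function() {
  attr(brics_rules(), "compatible")
}

.compat_cache <- new.env(parent = emptyenv())

links_compatible <- function(l1, l2) {
  M <- .compat_cache$M
  if (is.null(M)) {
    M <- matrix(FALSE, 16L, 16L)
    for (p in brics_compat_pairs()) {
      M[p[1], p[2]] <- TRUE
      M[p[2], p[1]] <- TRUE
    }
    .compat_cache$M <- M
  }
  M[cbind(l1, l2)]   # vectorized over label pairs
}

# dummy atoms (attachment points) of a fragment molecule: index + link label
frag_open_links <- function(mol) {
  idx <- which(mol$symbol == "*")
  list(atom = idx, label = mol$isotope[idx], n = length(idx))
}

# join two fragments at the given dummy atoms: the dummies are removed and
# their anchor atoms bonded (double bond for the L7/L7 alkene rule)
join_at_dummies <- function(molA, dummyA, molB, dummyB) {
  lab <- c(molA$isotope[dummyA], molB$isotope[dummyB])
  ord <- if (all(lab == 7L)) 2L else 1L
  anchorA <- {
    b <- molA$bonds
    sel <- which(b$a1 == dummyA | b$a2 == dummyA)[1]
    bond_other(b, sel, dummyA)
  }
  anchorB <- {
    b <- molB$bonds
    sel <- which(b$a1 == dummyB | b$a2 == dummyB)[1]
    bond_other(b, sel, dummyB)
  }
  subA <- mol_subgraph(molA, setdiff(seq_len(molA$n), dummyA), perceive = FALSE)
  subB <- mol_subgraph(molB, setdiff(seq_len(molB$n), dummyB), perceive = FALSE)
  j <- mol_join(subA$mol, subA$map[anchorA], subB$mol, subB$map[anchorB], ord,
                perceive = FALSE)
  j$mol
}

strip_dummies <- function(mol) {
  keep <- which(mol$symbol != "*")
  if (length(keep) == mol$n) return(perceive_mol(mol))
  mol_subgraph(mol, keep, perceive = TRUE)$mol
}

# Random fragment growth: start from a seed fragment, repeatedly join a
# random open link to a random compatible partner from `frags` (a list of
# parsed fragment molecules), until no open link remains or the heavy-atom
# cap is reached. Leftover links are hydrogen-capped (dummies stripped).
assemble_molecule <- function(frags, weights = NULL, max_heavy_atoms = 60L,
                              start = NULL) {
  if (is.null(weights)) weights <- rep(1, length(frags))
  labels_of <- lapply(frags, function(f) frag_open_links(f)$label)
  heavy_of <- vapply(frags, function(f) sum(f$symbol != "*"), 1L)
  cur <- if (is.null(start)) frags[[sample.int(length(frags), 1L, prob = weights)]]
         else start
  repeat {
    links <- frag_open_links(cur)
    n_heavy <- cur$n - links$n
    if (!links$n || n_heavy >= max_heavy_atoms) break
    li <- sample.int(links$n, 1L)
    lab <- links$label[li]
    ok <- which(vapply(labels_of, function(ls)
      any(links_compatible(ls, rep(lab, length(ls)))), TRUE))
    ok <- ok[n_heavy + heavy_of[ok] <= max_heavy_atoms]  # respect the cap
    if (!length(ok)) {
      cur <- mol_subgraph(cur, setdiff(seq_len(cur$n), links$atom[li]),
                          perceive = FALSE)$mol
      next
    }
    pi <- ok[sample.int(length(ok), 1L, prob = weights[ok])]
    partner <- frags[[pi]]
    plinks <- frag_open_links(partner)
    sel <- which(links_compatible(plinks$label, rep(lab, plinks$n)))
    pj <- sel[sample.int(length(sel), 1L)]
    cur <- join_at_dummies(cur, links$atom[li], partner, plinks$atom[pj])
  }
  strip_dummies(cur)
}

# Join a fixed sequence of fragments (first compatible link pair each time);
# used to seed assembly with a designed motif before random growth.
assemble_template <- function(frag_list) {
  cur <- frag_list[[1]]
  for (t in frag_list[-1]) {
    la <- frag_open_links(cur)
    lb <- frag_open_links(t)
    done <- FALSE
    for (i in seq_len(la$n)) {
      for (j in seq_len(lb$n)) {
        if (links_compatible(la$label[i], lb$label[j])) {
          cur <- join_at_dummies(cur, la$atom[i], t, lb$atom[j])
          done <- TRUE
          break
        }
      }
      if (done) break
    }
    if (!done) stop("template fragments have no compatible link pair",
                    call. = FALSE)
  }
  cur
}

#' Build an attributed BRICS fragment pool
#'
#' Decomposes every molecule of a dataset into BRICS fragments, attributes
#' each fragment occurrence with a single-fragment mask, and aggregates by
#' canonical fragment SMILES with labelled attachment points.
#'
#' @param model an `rgcn_consensus` model.
#' @param data dataset (see [rgcn_consensus()] formats).
#' @param min_count minimum occurrence count for a pool entry.
#' @return an object of class `sme_fragment_pool`: data.frame with columns
#'   `fragment` (canonical SMILES with `[n*]` attachment labels),
#'   `mean_attribution`, `count`, `links` (sorted link labels, "+"-joined).
#'   Parsed fragment molecules are attached as attribute `"mols"`.
#' @export
build_pool <- function(model, data, min_count = 1L) {
  records <- prepare_records(data)
  vals <- new.env(parent = emptyenv())
  mols <- new.env(parent = emptyenv())
  any_decomposed <- FALSE
  for (rec in records) {
    frs <- brics_fragments(rec)
    if (length(frs) < 2L) next   # single fragment: no cleavable bond
    any_decomposed <- TRUE
    graph <- featurize(rec, model$feature_cfg)
    masks <- c(list(mask_vector(graph, NULL)),
               lapply(frs, function(s) mask_vector(graph, s)))
    ys <- consensus_masked(model, graph, masks)
    atts <- ys[1] - ys[-1]
    for (i in seq_along(frs)) {
      links <- attr(frs[[i]], "links")
      fm <- mol_subgraph(rec$mol, frs[[i]]$atom_indices + 1L, links = links)$mol
      key <- mol_to_smiles(fm)
      vals[[key]] <- c(vals[[key]], atts[i])
      if (is.null(mols[[key]])) mols[[key]] <- fm
    }
  }
  keys <- ls(vals)
  if (!any_decomposed || !length(keys))
    stop("dataset contains no BRICS-decomposable molecule", call. = FALSE)
  pool <- data.frame(
    fragment = keys,
    mean_attribution = vapply(keys, function(k) mean(vals[[k]]), 1),
    count = vapply(keys, function(k) length(vals[[k]]), 1L),
    links = vapply(keys, function(k) {
      paste(sort(frag_open_links(mols[[k]])$label), collapse = "+")
    }, ""),
    row.names = NULL
  )
  pool <- pool[pool$count >= min_count, , drop = FALSE]
  attr(pool, "mols") <- lapply(pool$fragment, function(k) mols[[k]])
  class(pool) <- c("sme_fragment_pool", "data.frame")
  pool
}

#' Select the extreme fraction of a fragment pool
#'
#' Restricts a pool to fragments whose mean attribution is strictly of the
#' requested sign, then keeps the `ceiling(top_fraction * count)` most
#' extreme entries (ties broken by canonical fragment SMILES).
#'
#' @param pool an `sme_fragment_pool`.
#' @param sign `"positive"` or `"negative"`.
#' @param top_fraction fraction of same-sign fragments to keep.
#' @return the selected `sme_fragment_pool` subset.
#' @export
select_fragments <- function(pool, sign = c("positive", "negative"),
                             top_fraction = 0.2) {
  sign <- match.arg(sign)
  keep <- if (sign == "positive") pool$mean_attribution > 0 else
    pool$mean_attribution < 0
  if (!any(keep))
    stop("no pool entries with ", sign, " mean attribution", call. = FALSE)
  sub <- pool[keep, , drop = FALSE]
  mols <- attr(pool, "mols")[keep]
  k <- ceiling(top_fraction * nrow(sub))
  extremeness <- if (sign == "positive") -sub$mean_attribution else
    sub$mean_attribution
  ord <- order(extremeness, sub$fragment)
  sel <- ord[seq_len(k)]
  out <- sub[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mols") <- mols[sel]
  class(out) <- c("sme_fragment_pool", "data.frame")
  out
}

#' Recombine pool fragments into new molecules
#'
#' Assembles molecules by seeded random growth: starting from a random pool
#' fragment, open attachment points are repeatedly joined to random
#' compatible partners until the molecule is closed or the heavy-atom cap
#' is reached; leftover attachment points are hydrogen-capped. Outputs are
#' canonical, deduplicated and guaranteed to parse.
#'
#' @param pool an `sme_fragment_pool` (at least two fragments with one
#'   BRICS-compatible link-type pair).
#' @param n_molecules number of distinct molecules requested.
#' @param seed RNG seed.
#' @param max_heavy_atoms heavy-atom cap per molecule.
#' @param max_attempts_factor attempt budget multiplier; fewer molecules
#'   are returned (with a warning) when the budget is exhausted.
#' @param max_stall assembly attempts allowed without discovering a new
#'   distinct molecule before generation stops early (small pools can have
#'   an assembly space below `n_molecules`; the stall cutoff detects
#'   exhaustion without burning the whole attempt budget).
#' @return character vector of canonical SMILES.
#' @export
recombine <- function(pool, n_molecules = 3000L, seed = 1L,
                      max_heavy_atoms = 60L, max_attempts_factor = 100L,
                      max_stall = 1000L) {
  frags <- attr(pool, "mols")
  if (length(frags) < 2L)
    stop("pool needs at least two fragments", call. = FALSE)
  all_labels <- unique(unlist(lapply(frags, function(f) frag_open_links(f)$label)))
  pair_ok <- FALSE
  for (l1 in all_labels) for (l2 in all_labels)
    if (links_compatible(l1, l2)) pair_ok <- TRUE
  if (!pair_ok)
    stop("no BRICS-compatible link-type pair in pool (available link types: ",
         paste(sort(all_labels), collapse = ", "), ")", call. = FALSE)
  set.seed(seed)
  seen <- character(0)
  attempts <- 0L
  stall <- 0L
  budget <- n_molecules * max_attempts_factor
  while (length(seen) < n_molecules && attempts < budget &&
         stall < max_stall) {
    attempts <- attempts + 1L
    smi <- tryCatch({
      m <- assemble_molecule(frags, max_heavy_atoms = max_heavy_atoms)
      if (m$n < 2L) NA_character_ else mol_to_smiles(m)
    }, error = function(e) NA_character_)
    if (is.na(smi) || smi %in% seen) { stall <- stall + 1L; next }
    ok <- tryCatch({ parse_smiles(smi); TRUE }, error = function(e) FALSE)
    if (!ok) { stall <- stall + 1L; next }
    seen <- c(seen, smi)
    stall <- 0L
  }
  if (length(seen) < n_molecules)
    warning("attempt budget exhausted: generated ", length(seen), " of ",
            n_molecules, " requested molecules", call. = FALSE)
  seen
}

#' Predicted-property distributions of generated molecule groups
#'
#' Predicts two groups of molecules (e.g. positive-pool and negative-pool
#' recombinants) under one or more consensus models and summarizes their
#' separation. The overlap measure is the mean of (i) the fraction of
#' negative-group molecules predicted above the positive-group median and
#' (ii) the fraction of positive-group molecules predicted below the
#' negative-group median; identical groups give overlap 0.5 (maximal),
#' perfectly separated groups give 0.
#'
#' @param models an `rgcn_consensus` or named list of them.
#' @param positive,negative character vectors of SMILES.
#' @return list with `predictions` (per model: list of `positive`,
#'   `negative` prediction vectors) and `summary` (per model: group means
#'   and overlap).
#' @export
property_distribution <- function(models, positive, negative) {
  if (inherits(models, "rgcn_consensus")) models <- list(model = models)
  preds <- lapply(models, function(m)
    list(positive = predict(m, positive), negative = predict(m, negative)))
  summ <- lapply(preds, function(p) {
    ov <- mean(c(mean(p$negative > stats::median(p$positive)),
                 mean(p$positive < stats::median(p$negative))))
    c(mean_positive = mean(p$positive), mean_negative = mean(p$negative),
      overlap = ov)
  })
  list(predictions = preds, summary = summ)
}
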