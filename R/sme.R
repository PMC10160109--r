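# Substructure-mask explanation.
#
# The attribution of a substructure is the difference between the consensus
# prediction on the intact molecule (Y) and the prediction with the
# substructure's nodes zeroed at the attention-pooled readout (Y_sub):
# attribution = Y - Y_sub. Message passing always runs on the full graph;
# the mask enters only in the readout sum, so node hidden states are
# computed once per sub-model and reused across masks.

#' Build a readout mask from a substructure
#'
#' @param graph an `sme_graph`.
#' @param sub an `sme_substructure` (0-based atom indices), or `NULL` for
#'   the identity (all-ones) mask.
#' @return numeric 0/1 vector over nodes; 0 marks masked atoms.
#' @export
mask_vector <- function(graph, sub = NULL) {
  mask <- rep(1, graph$n)
  if (is.null(sub)) return(mask)
  idx <- sub$atom_indices + 1L
  if (length(idx) && (min(idx) < 1L || max(idx) > graph$n))
    stop("substructure atom index out of range for graph", call. = FALSE)
  mask[idx] <- 0
  mask
}

# Consensus predictions for a set of masks on one molecule, computing the
# message-passing hidden states once per sub-model.
consensus_masked <- function(model, graph, masks) {
  batch <- batch_graphs(list(graph), model$config$normalize_degree)
  acc <- numeric(length(masks))
  for (p in model$sub_models) {
    fw <- rgcn_forward_batch(p, batch, model$config, keep = TRUE)
    acc <- acc + rgcn_head_masked(p, batch, model$config, fw$H, fw$om, masks)
  }
  acc / model$m
}

#' Attribution of one substructure
#'
#' Computes the attribution record for a single substructure of a molecule:
#' the consensus prediction before (`Y`) and after (`Y_sub`) masking the
#' substructure's nodes at the readout, and their difference. A positive
#' attribution means the substructure pushes the prediction up.
#'
#' @param model an `rgcn_consensus` model.
#' @param mol molecule record, `sme_mol` or SMILES string.
#' @param sub an `sme_substructure` of the same molecule.
#' @return one-row data.frame with columns `molecule_id`, `smiles`,
#'   `scheme`, `substructure_name`, `atom_indices` (0-based,
#'   semicolon-joined), `Y`, `Y_sub`, `attribution`.
#' @export
attribute <- function(model, mol, sub) {
  rec <- if (inherits(mol, "sme_molecule")) mol else
    molecule_record(id = "mol", smiles = if (is.character(mol)) mol else mol_to_smiles(mol))
  graph <- featurize(rec, model$feature_cfg)
  masks <- list(mask_vector(graph, NULL), mask_vector(graph, sub))
  ys <- consensus_masked(model, graph, masks)
  data.frame(
    molecule_id = rec$id, smiles = rec$smiles, scheme = sub$scheme,
    substructure_name = sub$name,
    atom_indices = paste(sub$atom_indices, collapse = ";"),
    Y = ys[1], Y_sub = ys[2], attribution = ys[1] - ys[2]
  )
}

#' Normalize attribution scores
#'
#' Adds an `attribution_n` column over the whole record set. The default
#' `"maxabs"` divides by the largest absolute attribution (sign-preserving,
#' range \[-1, 1\]); `"minmax01"` maps linearly to \[0, 1\]. All-zero
#' attributions map to zeros.
#'
#' @param records data.frame with an `attribution` column.
#' @param method `"maxabs"` or `"minmax01"`.
#' @return the data.frame with `attribution_n` added.
#' @export
normalize_attributions <- function(records, method = c("maxabs", "minmax01")) {
  method <- match.arg(method)
  if (!nrow(records)) stop("empty attribution record set", call. = FALSE)
  a <- records$attribution
  if (method == "maxabs") {
    m <- max(abs(a))
    records$attribution_n <- if (m == 0) a * 0 else a / m
  } else {
    rng <- range(a)
    records$attribution_n <- if (diff(rng) == 0) a * 0 else (a - rng[1]) / diff(rng)
  }
  records
}

#' Enumerate substructure combinations
#'
#' Builds COMBINATION substructures (atom-set unions) from the fragments of
#' one molecule and one scheme. When the number of nonempty subsets
#' `2^k - 1` does not exceed `max_n`, all are returned; otherwise all `k`
#' singletons are guaranteed and the remaining budget is filled with
#' uniformly sampled distinct larger subsets.
#'
#' @param subs list of substructures from one molecule and one scheme.
#' @param max_n per-molecule combination cap.
#' @param seed RNG seed for the sampling branch.
#' @return list of `sme_substructure` objects (scheme `"COMBINATION"`);
#'   singleton combinations keep the member's atom set and name.
#' @export
enumerate_combinations <- function(subs, max_n = 100L, seed = 1L) {
  k <- length(subs)
  if (!k) stop("no substructures to combine", call. = FALSE)
  if (max_n < k)
    stop("max_n (", max_n, ") below fragment count (", k,
         "): singletons must fit", call. = FALSE)
  make_comb <- function(members) {
    atoms <- sort(unique(unlist(lapply(subs[members], `[[`, "atom_indices"))))
    nm <- paste(vapply(subs[members], `[[`, "", "name"), collapse = "+")
    substructure("COMBINATION", atoms, nm, members = subs[members])
  }
  if (k <= 25L && (2^k - 1) <= max_n) {
    combos <- lapply(seq_len(2^k - 1L), function(code) {
      members <- which(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
      make_comb(members)
    })
    return(combos)
  }
  set.seed(seed)
  chosen <- lapply(seq_len(k), function(i) i)          # singletons first
  keys <- vapply(chosen, paste, "", collapse = ",")
  attempts <- 0L
  while (length(chosen) < max_n && attempts < 200L * max_n) {
    attempts <- attempts + 1L
    members <- which(stats::runif(k) < 0.5)
    if (length(members) < 2L) next
    key <- paste(members, collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    chosen[[length(chosen) + 1L]] <- members
  }
  lapply(chosen, make_comb)
}

#' Most positive and most negative substructure combinations
#'
#' Attributes every sampled fragment combination from the requested schemes
#' and returns the records with the largest and smallest attribution. Ties
#' are broken by smaller atom count, then lexicographic name.
#'
#' @param model an `rgcn_consensus` model.
#' @param mol molecule record or SMILES string.
#' @param schemes fragmentation schemes to combine.
#' @param max_n per-scheme combination cap.
#' @param seed RNG seed for combination sampling.
#' @return list with elements `most_positive` and `most_negative` (one-row
#'   attribution data.frames, each with the winning substructure attached as
#'   attribute `"sub"`), plus `records`, the full attribution table.
#' @export
extreme_components <- function(model, mol, schemes = c("BRICS", "MURCKO"),
                               max_n = 100L, seed = 1L) {
  rec <- if (inherits(mol, "sme_molecule")) mol else
    molecule_record("mol", if (is.character(mol)) mol else mol_to_smiles(mol))
  graph <- featurize(rec, model$feature_cfg)
  all_subs <- list()
  for (sc in schemes) {
    frs <- switch(sc,
      BRICS = brics_fragments(rec),
      MURCKO = suppressWarnings(murcko_fragments(rec)),
      stop("unsupported scheme for combinations: ", sc, call. = FALSE))
    if (!length(frs)) next
    all_subs <- c(all_subs, enumerate_combinations(frs, max_n = max_n, seed = seed))
  }
  if (!length(all_subs))
    stop("molecule has no fragments under schemes ",
         paste(schemes, collapse = ", "), call. = FALSE)
  masks <- c(list(mask_vector(graph, NULL)),
             lapply(all_subs, function(s) mask_vector(graph, s)))
  ys <- consensus_masked(model, graph, masks)
  Y <- ys[1]
  att <- Y - ys[-1]
  natoms <- vapply(all_subs, function(s) length(s$atom_indices), 1L)
  nms <- vapply(all_subs, `[[`, "", "name")
  pick <- function(best_val) {
    cand <- which(att == best_val)
    cand <- cand[order(natoms[cand], nms[cand])]
    cand[1]
  }
  ip <- pick(max(att)); im <- pick(min(att))
  row_of <- function(i) {
    out <- data.frame(
      molecule_id = rec$id, smiles = rec$smiles, scheme = "COMBINATION",
      substructure_name = nms[i],
      atom_indices = paste(all_subs[[i]]$atom_indices, collapse = ";"),
      Y = Y, Y_sub = ys[i + 1L], attribution = att[i])
    attr(out, "sub") <- all_subs[[i]]
    out
  }
  records <- data.frame(
    molecule_id = rec$id, smiles = rec$smiles, scheme = "COMBINATION",
    substructure_name = nms, atom_indices = vapply(all_subs, function(s)
      paste(s$atom_indices, collapse = ";"), ""),
    Y = Y, Y_sub = ys[-1], attribution = att)
  list(most_positive = row_of(ip), most_negative = row_of(im), records = records)
}

#' Explain a dataset
#'
#' Runs substructure-mask attribution for every molecule of a dataset under
#' the requested fragmentation schemes, optionally adding random fragment
#' combinations, and normalizes the attribution scores over the whole run.
#'
#' @param model an `rgcn_consensus` model.
#' @param data dataset (see [rgcn_consensus()] formats).
#' @param schemes subset of `c("BRICS", "MURCKO", "FUNCTIONAL_GROUP")`.
#' @param catalog functional-group catalog used when
#'   `"FUNCTIONAL_GROUP"` is requested.
#' @param combinations also attribute random combinations of BRICS/Murcko
#'   fragments (capped at `max_n` per molecule and scheme).
#' @param max_n per-molecule, per-scheme combination cap.
#' @param normalize normalization method, see [normalize_attributions()].
#' @param seed RNG seed for combination sampling.
#' @return data.frame of attribution records with `attribution_n`.
#' @export
explain <- function(model, data,
                    schemes = c("BRICS", "MURCKO", "FUNCTIONAL_GROUP"),
                    catalog = load_fg_catalog(), combinations = FALSE,
                    max_n = 100L, normalize = "maxabs", seed = 1L) {
  schemes <- match.arg(schemes, c("BRICS", "MURCKO", "FUNCTIONAL_GROUP"),
                       several.ok = TRUE)
  records <- prepare_records(data)
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    graph <- featurize(rec, model$feature_cfg)
    subs <- list()
    for (sc in schemes) {
      frs <- switch(sc,
        BRICS = brics_fragments(rec),
        MURCKO = suppressWarnings(murcko_fragments(rec)),
        FUNCTIONAL_GROUP = functional_group_matches(rec, catalog))
      if (combinations && sc %in% c("BRICS", "MURCKO") && length(frs))
        frs <- c(frs, enumerate_combinations(frs, max_n = max_n,
                                             seed = seed + i))
      subs <- c(subs, frs)
    }
    if (!length(subs)) next
    masks <- c(list(mask_vector(graph, NULL)),
               lapply(subs, function(s) mask_vector(graph, s)))
    ys <- consensus_masked(model, graph, masks)
    out[[i]] <- data.frame(
      molecule_id = rec$id, smiles = rec$smiles,
      scheme = vapply(subs, `[[`, "", "scheme"),
      substructure_name = vapply(subs, `[[`, "", "name"),
      atom_indices = vapply(subs, function(s)
        paste(s$atom_indices, collapse = ";"), ""),
      Y = ys[1], Y_sub = ys[-1], attribution = ys[1] - ys[-1])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out) || !nrow(out)) stop("no substructures found in dataset", call. = FALSE)
  normalize_attributions(out, normalize)
}
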