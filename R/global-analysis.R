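# Dataset-level SAR mining on top of the attribution engine: functional-
# group attribution tables, cross-property correlation, substituent scans
# and attribution-guided optimization suggestions.

#' Functional-group attribution table
#'
#' Attributes every functional-group occurrence in every molecule of a
#' dataset and aggregates per catalog entry. Groups occurring fewer than
#' `min_count` times are excluded; the table is sorted by mean attribution.
#'
#' @param model an `rgcn_consensus` model.
#' @param data dataset (see [rgcn_consensus()] formats).
#' @param catalog functional-group catalog.
#' @param min_count minimum occurrence count for a group to be reported
#'   (inclusive).
#' @return data.frame of class `sme_fg_table` with columns `fg_name`,
#'   `count`, `mean_attribution`, `sd`, `q25`, `q50`, `q75`; the full
#'   per-occurrence record set is attached as attribute `"records"`.
#' @export
fg_attribution_table <- function(model, data, catalog = load_fg_catalog(),
                                 min_count = 10L) {
  records <- prepare_records(data)
  if (!length(records)) stop("empty dataset", call. = FALSE)
  rows <- explain(model, records, schemes = "FUNCTIONAL_GROUP",
                  catalog = catalog, normalize = "maxabs")
  agg <- split(rows$attribution, rows$substructure_name)
  tab <- data.frame(
    fg_name = names(agg),
    count = vapply(agg, length, 1L),
    mean_attribution = vapply(agg, mean, 1),
    sd = vapply(agg, function(a) if (length(a) > 1L) stats::sd(a) else 0, 1),
    q25 = vapply(agg, function(a) stats::quantile(a, 0.25, names = FALSE), 1),
    q50 = vapply(agg, function(a) stats::quantile(a, 0.50, names = FALSE), 1),
    q75 = vapply(agg, function(a) stats::quantile(a, 0.75, names = FALSE), 1),
    row.names = NULL
  )
  tab <- tab[tab$count >= min_count, , drop = FALSE]
  tab <- tab[order(tab$mean_attribution), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "records") <- rows
  class(tab) <- c("sme_fg_table", "data.frame")
  tab
}

#' Cross-property attribution correlation
#'
#' Spearman rank correlation of mean functional-group attributions between
#' two attribution tables, over the intersection of group names.
#'
#' @param statsA,statsB functional-group tables from
#'   [fg_attribution_table()] (or data.frames with `fg_name` and
#'   `mean_attribution`).
#' @return list with `rho`, `p_value` (two-sided), `n_shared` and `pairs`,
#'   the shared-group table.
#' @export
cross_property_correlation <- function(statsA, statsB) {
  shared <- intersect(statsA$fg_name, statsB$fg_name)
  if (length(shared) < 3L)
    stop("need at least 3 shared functional groups (found ",
         length(shared), ")", call. = FALSE)
  a <- statsA$mean_attribution[match(shared, statsA$fg_name)]
  b <- statsB$mean_attribution[match(shared, statsB$fg_name)]
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_shared = length(shared),
       pairs = data.frame(fg_name = shared, mean_A = a, mean_B = b))
}

#' Substituent scan at a terminal site
#'
#' Replaces a single-attachment terminal group of a molecule by each
#' graftable catalog entry in turn, predicts the edited molecules with the
#' consensus model, and reports the candidate's dataset-level mean
#' attribution alongside, so the attribution-vs-prediction correlation can
#' be examined.
#'
#' @param model an `rgcn_consensus` model.
#' @param mol molecule record or SMILES string.
#' @param site_sub an `sme_substructure` marking the substituent to replace;
#'   must attach to the rest of the molecule through exactly one single bond.
#' @param fg_stats functional-group table supplying candidate groups and
#'   their mean attributions (only graftable catalog entries are scanned).
#' @param catalog the catalog defining graft SMILES for the candidates.
#' @return data.frame with columns `candidate`, `smiles`, `prediction`,
#'   `mean_attribution`.
#' @export
substituent_scan <- function(model, mol, site_sub, fg_stats,
                             catalog = load_fg_catalog()) {
  m <- as_sme_mol(if (inherits(mol, "sme_molecule")) mol$mol else mol)
  site_atoms <- site_sub$atom_indices + 1L
  cand <- catalog[nzchar(catalog$graft) & catalog$name %in% fg_stats$fg_name, ,
                  drop = FALSE]
  if (!nrow(cand)) stop("no graftable candidate groups in the table", call. = FALSE)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    edited <- tryCatch({
      graft <- parse_smiles(cand$graft[i])
      em <- mol_replace_terminal(m, site_atoms, graft)
      mol_to_smiles(em)
    }, error = function(e) {
      warning("candidate '", cand$name[i], "' skipped: ",
              conditionMessage(e), call. = FALSE)
      NA_character_
    })
    if (is.na(edited)) next
    out[[length(out) + 1L]] <- data.frame(
      candidate = cand$name[i], smiles = edited,
      mean_attribution = fg_stats$mean_attribution[match(cand$name[i],
                                                         fg_stats$fg_name)])
  }
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no valid substituent grafts at this site", call. = FALSE)
  out$prediction <- predict(model, out$smiles)
  out[, c("candidate", "smiles", "prediction", "mean_attribution")]
}

#' Attribution-guided optimization suggestions
#'
#' Derives ranked structural-edit suggestions from a functional-group
#' attribution table. To decrease the predicted property: add groups with
#' negative mean attribution, remove present groups with positive mean
#' attribution, or replace present groups by absent groups with strictly
#' more negative mean attribution; `direction = "increase"` mirrors the
#' signs. Suggestions are ranked by the absolute expected attribution
#' difference.
#'
#' @param mol molecule record or SMILES string.
#' @param fg_stats functional-group table ([fg_attribution_table()]).
#' @param direction `"decrease"` or `"increase"` the predicted property.
#' @param catalog catalog used to detect which groups are present.
#' @return data.frame with columns `strategy`, `site_fg`, `candidate_fg`,
#'   `expected_change`, `score`, ranked by `score` (may have zero rows).
#' @export
optimization_suggestions <- function(mol, fg_stats,
                                     direction = c("decrease", "increase"),
                                     catalog = load_fg_catalog()) {
  direction <- match.arg(direction)
  m <- as_sme_mol(if (inherits(mol, "sme_molecule")) mol$mol else mol)
  present <- unique(vapply(functional_group_matches(m, catalog), `[[`, "",
                           "name"))
  sgn <- if (direction == "decrease") 1 else -1
  mean_a <- sgn * fg_stats$mean_attribution   # work in "decrease" frame
  names(mean_a) <- fg_stats$fg_name
  rows <- list()
  addable <- fg_stats$fg_name[mean_a < 0]
  for (g in addable)
    rows[[length(rows) + 1L]] <- data.frame(
      strategy = "add_negative", site_fg = NA_character_, candidate_fg = g,
      score = abs(mean_a[[g]]))
  removable <- intersect(present, fg_stats$fg_name[mean_a > 0])
  for (g in removable)
    rows[[length(rows) + 1L]] <- data.frame(
      strategy = "remove_positive", site_fg = g, candidate_fg = NA_character_,
      score = abs(mean_a[[g]]))
  for (g in intersect(present, fg_stats$fg_name)) {
    repl <- setdiff(fg_stats$fg_name[mean_a < mean_a[[g]]], present)
    for (r in repl)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = "replace_more_negative", site_fg = g, candidate_fg = r,
        score = abs(mean_a[[g]] - mean_a[[r]]))
  }
  if (!length(rows))
    return(data.frame(strategy = character(0), site_fg = character(0),
                      candidate_fg = character(0), expected_change = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, rows)
  out$expected_change <- direction
  out <- out[order(-out$score), c("strategy", "site_fg", "candidate_fg",
                                  "expected_change", "score")]
  rownames(out) <- NULL
  out
}
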