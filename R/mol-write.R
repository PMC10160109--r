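# Canonical SMILES output.
#
# Canonical atom ranks come from iterative neighborhood refinement (Morgan
# style) over an initial invariant of (element, degree, charge, H count,
# aromaticity, ring membership); remaining ties are broken by deterministic
# orbit bumping. The writer emits aromatic atoms in lower case, so aromatic
# systems are never kekulized on output.

canonical_ranks <- function(mol) {
  n <- mol$n
  inv <- paste(mol$symbol, mol$degree, mol$charge, mol$nH,
               mol$aromatic, mol$in_ring, mol$isotope, sep = "|")
  rank <- as.integer(factor(inv, levels = sort(unique(inv))))
  if (n == 1L) return(rank)
  b <- mol$bonds
  # directed edge arrays; bond code distinguishes order/aromaticity
  uu <- c(b$a1, b$a2); vv <- c(b$a2, b$a1)
  bcode <- rep(b$order + 4L * b$aromatic, 2L)
  maxdeg <- max(mol$degree)
  ov <- order(vv)
  vv_s <- vv[ov]; uu_s <- uu[ov]; bc_s <- bcode[ov]
  slot <- sequence(tabulate(vv_s, nbins = n))
  rank_rows <- function(K) {
    # integer rank of rows of K under lexicographic order
    cols <- lapply(seq_len(ncol(K)), function(j) K[, j])
    o <- do.call(order, cols)
    Ks <- K[o, , drop = FALSE]
    newcls <- c(1L, 1L + cumsum(rowSums(Ks[-1L, , drop = FALSE] !=
                                          Ks[-nrow(Ks), , drop = FALSE]) > 0L))
    out <- integer(n)
    out[o] <- newcls
    out
  }
  refine <- function(rank) {
    repeat {
      # per-atom signature: own rank + sorted neighbour (rank, bond) codes
      code <- rank[uu_s] * 8L + bc_s
      M <- matrix(0L, n, maxdeg)
      o2 <- order(vv_s, code)
      M[cbind(vv_s[o2], slot)] <- code[o2]
      # sort each row descending so the key is order-free over neighbours
      M <- matrix(M[order(row(M), -M)], n, maxdeg, byrow = TRUE)
      newrank <- rank_rows(cbind(rank, M))
      if (identical(newrank, rank)) return(rank)
      rank <- newrank
    }
  }
  rank <- refine(rank)
  # tie-breaking: bump one atom of the lowest tied orbit and re-refine
  while (length(unique(rank)) < n) {
    tab <- tabulate(rank)
    tied <- which(tab > 1L)[1]
    cand <- which(rank == tied)
    key <- rank * 2L
    key[cand[1]] <- key[cand[1]] - 1L
    rank <- as.integer(factor(key, levels = sort(unique(key))))
    rank <- refine(rank)
  }
  rank
}

smiles_atom_token <- function(mol, v) {
  sym <- mol$symbol[v]
  arom <- mol$aromatic[v]
  disp <- if (arom) tolower(sym) else sym
  needs_bracket <- FALSE
  if (sym == "*") needs_bracket <- mol$isotope[v] > 0L
  if (mol$charge[v] != 0L || mol$isotope[v] > 0L) needs_bracket <- TRUE
  if (!(sym %in% ORGANIC_SUBSET) && sym != "*") needs_bracket <- TRUE
  if (!needs_bracket && sym != "*") {
    # would the implicit-H rules reproduce nH? otherwise bracket with H count
    b <- mol$bonds
    sel <- b$a1 == v | b$a2 == v
    ordsum <- sum(ifelse(b$aromatic[sel], 1.5, b$order[sel]))
    tgt <- atom_valence_target(sym, mol$charge[v])
    used <- as.integer(ceiling(ordsum - 1e-6))
    if (sym %in% c("S", "P") && used > tgt) tgt <- if (used <= 4L) 4L else 6L
    if (max(0L, tgt - used) != mol$nH[v]) needs_bracket <- TRUE
  }
  if (!needs_bracket) return(disp)
  iso <- if (mol$isotope[v] > 0L) as.character(mol$isotope[v]) else ""
  hpart <- if (mol$nH[v] == 0L) "" else if (mol$nH[v] == 1L) "H" else paste0("H", mol$nH[v])
  chg <- mol$charge[v]
  cpart <- if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-" else
    sprintf("%+d", chg)
  paste0("[", iso, disp, hpart, cpart, "]")
}

bond_token <- function(mol, e, from, to) {
  b <- mol$bonds
  if (b$aromatic[e]) return("")                       # implicit between lc atoms
  if (b$order[e] == 2L) return("=")
  if (b$order[e] == 3L) return("#")
  if (mol$aromatic[from] && mol$aromatic[to]) return("-")  # biaryl single
  ""
}

#' Write a molecule as canonical SMILES
#'
#' @param mol an `sme_mol` object.
#' @return a SMILES string; identical input graphs yield identical strings.
#' @export
mol_to_smiles <- function(mol) {
  stopifnot(inherits(mol, "sme_mol"))
  if (mol$n == 0L) return("")
  rank <- canonical_ranks(mol)
  adj <- vector("list", mol$n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], i)
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], i)
  }
  visited <- logical(mol$n)
  bond_used <- logical(nrow(b))
  ring_digit <- 0L
  closures <- vector("list", mol$n)   # per atom: vector of digit strings
  digit_of_bond <- rep(NA_character_, nrow(b))

  # pre-pass: identify ring-closure bonds via DFS spanning tree
  order_nb <- function(v) {
    es <- adj[[v]]
    if (is.null(es)) return(integer(0))
    us <- vapply(es, function(e) bond_other(b, e, v), 1L)
    es[order(rank[us], us)]
  }
  start <- which.min(rank)
  # iterative DFS emitting SMILES
  emit <- character(0)
  dfs <- function(v) {
    visited[v] <<- TRUE
    out <- character(0)
    write_atom <- function(v) {
      tok <- smiles_atom_token(mol, v)
      cl <- closures[[v]]
      if (!is.null(cl)) tok <- paste0(tok, paste(cl, collapse = ""))
      tok
    }
    # first find ring closure bonds (tree walk)
    tstack <- list(list(v = v, ei = 0L))
    while (length(tstack)) {
      fr <- tstack[[length(tstack)]]
      vv <- fr$v
      es <- order_nb(vv)
      ei <- fr$ei + 1L
      adv <- FALSE
      while (ei <= length(es)) {
        e <- es[ei]
        if (!bond_used[e]) {
          u <- bond_other(b, e, vv)
          if (visited[u]) {
            # ring closure
            bond_used[e] <<- TRUE
            ring_digit <<- ring_digit + 1L
            dg <- if (ring_digit < 10L) as.character(ring_digit) else paste0("%", ring_digit)
            bt <- bond_token(mol, e, vv, u)
            closures[[u]] <<- c(closures[[u]], paste0(bt, dg))
            closures[[vv]] <<- c(closures[[vv]], paste0(bt, dg))
            digit_of_bond[e] <<- dg
          } else {
            bond_used[e] <<- TRUE
            visited[u] <<- TRUE
            tstack[[length(tstack)]]$ei <- ei
            tstack[[length(tstack) + 1L]] <- list(v = u, ei = 0L)
            adv <- TRUE
            break
          }
        }
        ei <- ei + 1L
      }
      if (adv) next
      tstack[[length(tstack)]] <- NULL
    }
    # second pass: emit following the same order over tree bonds
    visited2 <- logical(mol$n)
    bond_done <- logical(nrow(b))
    bond_done[!is.na(digit_of_bond)] <- TRUE
    rec_emit <- function(vv) {
      out <<- c(out, write_atom(vv))
      visited2[vv] <<- TRUE
      es <- order_nb(vv)
      kids <- list()
      for (e in es) {
        if (bond_done[e]) next
        u <- bond_other(b, e, vv)
        if (visited2[u]) next
        bond_done[e] <<- TRUE
        kids[[length(kids) + 1L]] <- list(e = e, u = u)
      }
      nk <- length(kids)
      for (ki in seq_along(kids)) {
        k <- kids[[ki]]
        bt <- bond_token(mol, k$e, vv, k$u)
        if (ki < nk) {
          out <<- c(out, "(", bt); rec_emit(k$u); out <<- c(out, ")")
        } else {
          out <<- c(out, bt); rec_emit(k$u)
        }
      }
    }
    rec_emit(v)
    out
  }
  emit <- dfs(start)
  if (!all(visited))
    stop("disconnected molecule cannot be written as single-component SMILES",
         call. = FALSE)
  paste(emit, collapse = "")
}

#' Canonicalize a SMILES string
#'
#' Parses and re-writes a SMILES string in the package's canonical form,
#' suitable for deduplication and identity comparison.
#'
#' @param smiles SMILES string(s).
#' @return character vector of canonical SMILES.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) mol_to_smiles(parse_smiles(s)), "", USE.NAMES = FALSE)
}
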