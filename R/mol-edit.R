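# Graph-level molecule editing: induced subgraphs, fragment joining and
# terminal-group grafting. All editing works on the internal representation
# and re-runs perception, so derived molecules carry consistent ring,
# aromaticity and implicit-hydrogen state.

# Induced subgraph over `atoms` (1-based). Optionally appends one dummy atom
# (symbol "*", isotope = link label) per entry of `links`, bonded to the
# retained attachment atom; used to serialize BRICS fragments with labelled
# attachment points.
mol_subgraph <- function(mol, atoms, links = NULL, perceive = TRUE) {
  atoms <- sort(unique(as.integer(atoms)))
  map <- integer(mol$n)
  map[atoms] <- seq_along(atoms)
  sym <- mol$symbol[atoms]
  aro <- mol$aromatic[atoms]
  chg <- mol$charge[atoms]
  iso <- mol$isotope[atoms]
  nhx <- mol$nH_explicit[atoms]
  b <- mol$bonds
  keep <- b$a1 %in% atoms & b$a2 %in% atoms
  nb <- data.frame(a1 = map[b$a1[keep]], a2 = map[b$a2[keep]],
                   order = b$order[keep], aromatic = b$aromatic[keep])
  # aromatic N that loses its substituent must keep its hydrogen, or the
  # ring would be left without its pyrrole-type H donor
  lost <- vapply(atoms, function(v) {
    sel <- (b$a1 == v & !(b$a2 %in% atoms)) | (b$a2 == v & !(b$a1 %in% atoms))
    sum(sel)
  }, 1L)
  fix <- mol$aromatic[atoms] & sym == "N" & lost > 0L &
    !is.na(mol$nH[atoms]) & mol$nH[atoms] == 0L & is.na(nhx)
  nhx[fix] <- 1L
  if (!is.null(links) && nrow(links)) {
    for (i in seq_len(nrow(links))) {
      sym <- c(sym, "*"); aro <- c(aro, FALSE); chg <- c(chg, 0L)
      iso <- c(iso, as.integer(links$label[i])); nhx <- c(nhx, NA_integer_)
      nb <- rbind(nb, data.frame(a1 = map[links$atom[i]], a2 = length(sym),
                                 order = 1L, aromatic = FALSE))
    }
  }
  out <- new_mol(sym, aro, chg, nhx, iso, nb)
  if (perceive) out <- perceive_mol(out)
  list(mol = out, map = map)
}

# Join two fragment molecules by a single (or double) bond between the given
# atoms; returns the merged molecule plus index maps for both parts.
mol_join <- function(molA, atomA, molB, atomB, order = 1L, perceive = TRUE) {
  nA <- molA$n
  sym <- c(molA$symbol, molB$symbol)
  aro <- c(molA$aromatic, molB$aromatic)
  chg <- c(molA$charge, molB$charge)
  iso <- c(molA$isotope, molB$isotope)
  nhx <- c(molA$nH_explicit, molB$nH_explicit)
  bB <- molB$bonds
  nb <- rbind(
    molA$bonds[, c("a1", "a2", "order", "aromatic")],
    data.frame(a1 = bB$a1 + nA, a2 = bB$a2 + nA, order = bB$order,
               aromatic = bB$aromatic),
    data.frame(a1 = atomA, a2 = atomB + nA, order = as.integer(order),
               aromatic = FALSE)
  )
  out <- new_mol(sym, aro, chg, nhx, iso, nb)
  if (perceive) out <- perceive_mol(out)
  list(mol = out, mapA = seq_len(nA), mapB = seq_len(molB$n) + nA)
}

# Remove the atoms of a terminal substituent and graft a replacement group
# at the anchor atom. `site_atoms` must form a connected terminal group
# attached to the rest of the molecule through exactly one single bond.
# `graft` is a molecule whose first atom is the attachment atom (may be NULL
# to just excise the group, i.e. replace by hydrogen).
mol_replace_terminal <- function(mol, site_atoms, graft = NULL) {
  site_atoms <- sort(unique(as.integer(site_atoms)))
  b <- mol$bonds
  cross <- which((b$a1 %in% site_atoms) != (b$a2 %in% site_atoms))
  if (length(cross) != 1L)
    stop("site is not a single-attachment terminal group (",
         length(cross), " attachment bonds)", call. = FALSE)
  e <- cross
  if (b$order[e] != 1L || b$aromatic[e])
    stop("site attachment bond is not a single bond", call. = FALSE)
  anchor <- if (b$a1[e] %in% site_atoms) b$a2[e] else b$a1[e]
  rest <- setdiff(seq_len(mol$n), site_atoms)
  core <- mol_subgraph(mol, rest)
  new_anchor <- core$map[anchor]
  if (is.null(graft)) return(core$mol)
  joined <- mol_join(core$mol, new_anchor, graft, 1L)
  joined$mol
}

mol_components <- function(mol) {
  comp <- integer(mol$n)
  b <- mol$bonds
  adj <- vector("list", mol$n)
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], b$a2[i])
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], b$a1[i])
  }
  k <- 0L
  for (v in seq_len(mol$n)) {
    if (comp[v] > 0L) next
    k <- k + 1L
    q <- v; comp[v] <- k
    while (length(q)) {
      x <- q[1]; q <- q[-1]
      for (u in adj[[x]]) if (comp[u] == 0L) { comp[u] <- k; q <- c(q, u) }
    }
  }
  split(seq_len(mol$n), comp)
}
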