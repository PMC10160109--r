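# Internal molecule representation and SMILES parsing.
#
# A molecule is stored as a plain list of parallel atom vectors plus a bond
# table over heavy atoms only; hydrogens are implicit throughout. Atom
# indices are 1-based internally; every exported interface that serializes
# atom indices converts to the 0-based convention used in output files.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("B", "C", "N", "O", "P", "S")

# default valences used for implicit hydrogen assignment
DEFAULT_VALENCE <- c(
  B = 3L, C = 4L, N = 3L, O = 2L, P = 3L, S = 2L,
  F = 1L, Cl = 1L, Br = 1L, I = 1L, Si = 4L, `*` = 0L
)

ATOMIC_NUMBER <- c(
  `*` = 0L, H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L,
  P = 15L, S = 16L, Cl = 17L, Br = 35L, I = 53L
)

new_mol <- function(symbol, aromatic, charge, nH_explicit, isotope, bonds) {
  n <- length(symbol)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                        aromatic = logical(0))
  }
  mol <- list(
    n = n,
    symbol = symbol,
    aromatic = aromatic,
    charge = as.integer(charge),
    isotope = as.integer(isotope),
    nH = rep(NA_integer_, n),
    nH_explicit = nH_explicit,   # NA unless set by a bracket atom
    bonds = bonds,
    in_ring = rep(FALSE, n),
    rings = list()
  )
  class(mol) <- "sme_mol"
  mol
}

#' @export
print.sme_mol <- function(x, ...) {
  cat(sprintf("<molecule: %d heavy atoms, %d bonds> %s\n",
              x$n, nrow(x$bonds), mol_to_smiles(x)))
  invisible(x)
}

mol_degree <- function(mol) {
  deg <- integer(mol$n)
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds$a1, nbins = mol$n)
    t2 <- tabulate(mol$bonds$a2, nbins = mol$n)
    deg <- t1 + t2
  }
  deg
}

mol_adjacency <- function(mol) {
  adj <- vector("list", mol$n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b$a1[i]]] <- c(adj[[b$a1[i]]], i)
    adj[[b$a2[i]]] <- c(adj[[b$a2[i]]], i)
  }
  adj
}

bond_other <- function(bonds, i, atom) {
  ifelse(bonds$a1[i] == atom, bonds$a2[i], bonds$a1[i])
}

# --- SMILES tokenizer / parser ---------------------------------------------

#' Parse a SMILES string
#'
#' Parses a (single-component) SMILES string into the package's internal
#' molecule representation: heavy atoms with implicit hydrogens, typed bonds,
#' ring perception and aromaticity flags. The supported dialect covers the
#' organic subset, bracket atoms with charges/explicit H/isotope labels,
#' branches, ring closures (including `%nn`), aromatic lower-case atoms and
#' the bond symbols `-`, `=`, `#`, `:`. Dummy atoms (`*`, `[3*]`) are
#' accepted and carry their isotope label, which the BRICS machinery uses as
#' an attachment-point link type.
#'
#' @param smiles a single SMILES string.
#' @param id optional record identifier used in error messages.
#' @return an object of class `sme_mol`.
#' @export
parse_smiles <- function(smiles, id = NULL) {
  who <- if (is.null(id)) sprintf("'%s'", smiles) else sprintf("record '%s' ('%s')", id, smiles)
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop("invalid SMILES input for ", who, call. = FALSE)
  s <- trimws(smiles)
  if (grepl(".", s, fixed = TRUE))
    stop("multi-component SMILES are not supported (", who, ")", call. = FALSE)

  chars <- strsplit(s, "")[[1]]
  i <- 1L; nc <- length(chars)

  symbol <- character(0); aromatic <- logical(0); charge <- integer(0)
  nHx <- integer(0); isotope <- integer(0)
  b_a1 <- integer(0); b_a2 <- integer(0); b_order <- integer(0); b_arom <- logical(0)

  stack <- integer(0)       # open-branch atom stack
  prev <- 0L                # previous atom index
  pend_bond <- NA_character_
  ringmap <- list()         # closure digit -> list(atom, bond)

  add_atom <- function(sym, arom, chg, nh, iso) {
    symbol <<- c(symbol, sym); aromatic <<- c(aromatic, arom)
    charge <<- c(charge, chg); nHx <<- c(nHx, nh); isotope <<- c(isotope, iso)
    length(symbol)
  }
  add_bond <- function(a1, a2, sym, both_arom) {
    if (is.na(sym)) {
      if (both_arom) { ord <- 1L; ar <- TRUE } else { ord <- 1L; ar <- FALSE }
    } else if (sym == "-") { ord <- 1L; ar <- FALSE
    } else if (sym == "=") { ord <- 2L; ar <- FALSE
    } else if (sym == "#") { ord <- 3L; ar <- FALSE
    } else if (sym == ":") { ord <- 1L; ar <- TRUE
    } else stop("unsupported bond symbol '", sym, "' in ", who, call. = FALSE)
    b_a1 <<- c(b_a1, a1); b_a2 <<- c(b_a2, a2)
    b_order <<- c(b_order, ord); b_arom <<- c(b_arom, ar)
  }
  close_ring <- function(key, atom) {
    if (!is.null(ringmap[[key]])) {
      open <- ringmap[[key]]
      sym <- if (!is.na(pend_bond)) pend_bond else open$bond
      add_bond(open$atom, atom, sym, aromatic[open$atom] && aromatic[atom])
      ringmap[[key]] <<- NULL
    } else {
      ringmap[[key]] <<- list(atom = atom, bond = pend_bond)
    }
    pend_bond <<- NA_character_
  }

  while (i <= nc) {
    ch <- chars[i]
    newatom <- NA_integer_
    if (ch == "(") {
      if (prev == 0L) stop("branch before any atom in ", who, call. = FALSE)
      stack <- c(stack, prev); i <- i + 1L; next
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in ", who, call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      # cis/trans markers are accepted and treated as single bonds
      pend_bond <- if (ch %in% c("/", "\\")) "-" else ch
      i <- i + 1L; next
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, prev); i <- i + 1L; next
    } else if (ch == "%") {
      if (i + 2L > nc) stop("bad ring closure in ", who, call. = FALSE)
      key <- paste0(chars[i + 1L], chars[i + 2L])
      close_ring(key, prev); i <- i + 3L; next
    } else if (ch == "[") {
      j <- i
      while (j <= nc && chars[j] != "]") j <- j + 1L
      if (j > nc) stop("unterminated bracket atom in ", who, call. = FALSE)
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, who)
      newatom <- add_atom(at$symbol, at$aromatic, at$charge, at$nH, at$isotope)
      i <- j + 1L
    } else {
      # organic-subset shorthand atom (possibly two letters)
      two <- if (i < nc) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        newatom <- add_atom(two, FALSE, 0L, NA_integer_, 0L); i <- i + 2L
      } else if (ch %in% c(ORGANIC_SUBSET, "*")) {
        newatom <- add_atom(ch, FALSE, 0L, NA_integer_, 0L); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        newatom <- add_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L); i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' in ", who, call. = FALSE)
      }
    }
    if (!is.na(newatom)) {
      if (prev > 0L) {
        add_bond(prev, newatom, pend_bond, aromatic[prev] && aromatic[newatom])
        pend_bond <- NA_character_
      }
      prev <- newatom
    }
  }
  if (length(stack)) stop("unbalanced '(' in ", who, call. = FALSE)
  open_rings <- names(ringmap)[!vapply(ringmap, is.null, TRUE)]
  if (length(open_rings)) stop("unclosed ring bond in ", who, call. = FALSE)
  if (!length(symbol)) stop("empty SMILES in ", who, call. = FALSE)

  bonds <- data.frame(a1 = b_a1, a2 = b_a2, order = b_order, aromatic = b_arom)
  mol <- new_mol(symbol, aromatic, charge, nHx, isotope, bonds)
  mol <- perceive_mol(mol, who)
  mol
}

parse_bracket_atom <- function(body, who) {
  m <- regmatches(body, regexec(
    "^([0-9]*)(\\*|[A-Z][a-z]?|[bcnops])(@{0,2})(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]|-[0-9])?(:[0-9]+)?$",
    body))[[1]]
  if (!length(m)) stop("unsupported bracket atom '[", body, "]' in ", who, call. = FALSE)
  iso <- if (nzchar(m[2])) as.integer(m[2]) else 0L
  sym_raw <- m[3]
  arom <- sym_raw %in% c("b", "c", "n", "o", "p", "s")
  sym <- if (arom) toupper(sym_raw) else sym_raw
  if (sym != "*" && !(sym %in% names(ATOMIC_NUMBER)))
    stop("element '", sym, "' not supported in ", who, call. = FALSE)
  if (sym == "H") stop("explicit hydrogen atoms are not supported in ", who, call. = FALSE)
  nh <- 0L
  if (nzchar(m[5])) {
    nh <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2L))
  }
  chg <- 0L
  if (nzchar(m[6])) {
    cs <- m[6]
    if (grepl("^[+-][0-9]$", cs)) {
      chg <- as.integer(cs)
    } else {
      chg <- nchar(cs) * if (substring(cs, 1L, 1L) == "+") 1L else -1L
    }
  }
  list(symbol = sym, aromatic = arom, charge = chg, nH = nh, isotope = iso)
}

# --- perception: rings, aromaticity, implicit hydrogens --------------------

perceive_mol <- function(mol, who = "molecule") {
  mol <- perceive_rings(mol)
  mol <- perceive_aromaticity(mol, who)
  mol <- assign_implicit_h(mol, who)
  mol
}

# ring bonds via bridge detection; ring list via shortest cycle through each
# ring bond (small molecules: BFS is cheap)
perceive_rings <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(mol)
  adj <- mol_adjacency(mol)
  # iterative DFS bridge finding (Tarjan low-link)
  disc <- integer(mol$n); low <- integer(mol$n)
  bridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(mol$n)) {
    if (disc[root] > 0L) next
    stack <- list(list(v = root, parent_edge = 0L, ei = 0L))
    while (length(stack)) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$ei == 0L) { timer <- timer + 1L; disc[v] <- low[v] <- timer }
      edges <- adj[[v]]
      advanced <- FALSE
      ei <- fr$ei + 1L
      while (ei <= length(edges)) {
        e <- edges[ei]
        if (e != fr$parent_edge) {
          u <- bond_other(mol$bonds, e, v)
          if (disc[u] == 0L) {
            stack[[length(stack)]]$ei <- ei
            stack[[length(stack) + 1L]] <- list(v = u, parent_edge = e, ei = 0L)
            advanced <- TRUE
            break
          } else {
            low[v] <- min(low[v], disc[u])
          }
        }
        ei <- ei + 1L
      }
      if (advanced) next
      # done with v
      stack[[length(stack)]] <- NULL
      if (length(stack)) {
        p <- stack[[length(stack)]]$v
        low[p] <- min(low[p], low[v])
        pe <- fr$parent_edge
        if (low[v] > disc[p]) bridge[pe] <- TRUE
      }
    }
  }
  ring_bond <- !bridge
  mol$bonds$in_ring <- ring_bond
  inr <- logical(mol$n)
  inr[c(mol$bonds$a1[ring_bond], mol$bonds$a2[ring_bond])] <- TRUE
  mol$in_ring <- inr

  # enumerate one smallest ring per ring bond (BFS in ring-bond subgraph)
  rings <- list()
  seen <- character(0)
  rb <- which(ring_bond)
  radj <- vector("list", mol$n)
  for (e in rb) {
    radj[[mol$bonds$a1[e]]] <- c(radj[[mol$bonds$a1[e]]], e)
    radj[[mol$bonds$a2[e]]] <- c(radj[[mol$bonds$a2[e]]], e)
  }
  for (e in rb) {
    a <- mol$bonds$a1[e]; b <- mol$bonds$a2[e]
    # shortest a->b path avoiding bond e
    prevatom <- integer(mol$n); prevatom[a] <- -1L
    q <- a; found <- FALSE
    while (length(q) && !found) {
      v <- q[1]; q <- q[-1]
      for (e2 in radj[[v]]) {
        if (e2 == e) next
        u <- bond_other(mol$bonds, e2, v)
        if (prevatom[u] == 0L) {
          prevatom[u] <- v
          if (u == b) { found <- TRUE; break }
          q <- c(q, u)
        }
      }
    }
    if (!found) next
    path <- b
    v <- b
    while (prevatom[v] != -1L) { v <- prevatom[v]; path <- c(path, v) }
    ring <- sort(path)
    key <- paste(ring, collapse = ",")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1L]] <- path }
  }
  mol$rings <- rings
  mol
}

# conservative Hueckel-style perception: upgrade Kekule-written 5/6-membered
# rings of C/N/O/S to aromatic when the pi-electron count is 6
perceive_aromaticity <- function(mol, who) {
  if (!length(mol$rings)) return(mol)
  b <- mol$bonds
  has_double <- function(v) any((b$a1 == v | b$a2 == v) & b$order == 2L)
  for (ring in mol$rings) {
    k <- length(ring)
    if (!(k %in% c(5L, 6L))) next
    if (any(mol$aromatic[ring])) next
    if (!all(mol$symbol[ring] %in% c("C", "N", "O", "S"))) next
    pi_e <- 0L; ok <- TRUE
    for (v in ring) {
      if (has_double(v)) {
        pi_e <- pi_e + 1L
      } else if (mol$symbol[v] %in% c("N", "O", "S")) {
        pi_e <- pi_e + 2L            # lone pair enters the ring
      } else {
        ok <- FALSE; break           # sp3 carbon blocks aromaticity
      }
    }
    if (!ok || pi_e != 6L) next
    # exocyclic doubles (e.g. quinones) disqualify the simple perception
    ring_bonds <- which(b$in_ring & (b$a1 %in% ring) & (b$a2 %in% ring))
    exo <- FALSE
    for (v in ring) {
      dbl <- which((b$a1 == v | b$a2 == v) & b$order == 2L)
      if (length(setdiff(dbl, ring_bonds))) { exo <- TRUE; break }
    }
    if (exo) next
    mol$aromatic[ring] <- TRUE
    mol$bonds$aromatic[ring_bonds] <- TRUE
    mol$bonds$order[ring_bonds] <- 1L
  }
  mol
}

atom_valence_target <- function(sym, charge) {
  v <- DEFAULT_VALENCE[sym]
  if (is.na(v)) return(0L)
  if (sym %in% c("N", "O", "P", "S")) v <- v + charge
  if (sym %in% c("C", "B")) v <- v - abs(charge)
  max(0L, as.integer(v))
}

assign_implicit_h <- function(mol, who) {
  b <- mol$bonds
  ordsum <- numeric(mol$n)
  if (nrow(b)) {
    w <- ifelse(b$aromatic, 1.5, b$order)
    for (i in seq_len(nrow(b))) {
      ordsum[b$a1[i]] <- ordsum[b$a1[i]] + w[i]
      ordsum[b$a2[i]] <- ordsum[b$a2[i]] + w[i]
    }
  }
  nH <- integer(mol$n)
  for (v in seq_len(mol$n)) {
    if (!is.na(mol$nH_explicit[v])) {
      nH[v] <- mol$nH_explicit[v]
    } else if (mol$symbol[v] == "*") {
      nH[v] <- 0L
    } else {
      tgt <- atom_valence_target(mol$symbol[v], mol$charge[v])
      used <- as.integer(ceiling(ordsum[v] - 1e-6))
      # hypervalent S/P written without brackets (e.g. sulfonyl): allow
      if (mol$symbol[v] %in% c("S", "P") && used > tgt) {
        tgt <- if (used <= 4L) 4L else 6L
      }
      nH[v] <- max(0L, tgt - used)
    }
  }
  mol$nH <- nH
  mol$degree <- mol_degree(mol)
  mol$adj <- mol_adjacency(mol)   # bond-index adjacency, reused by matching
  mol
}

mol_formula_mass <- function(mol) {
  masses <- c(`*` = 0, H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
              F = 18.998, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45,
              Br = 79.904, I = 126.904)
  sum(masses[mol$symbol]) + sum(mol$nH) * masses[["H"]]
}
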