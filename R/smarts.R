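# SMARTS pattern parsing and subgraph matching.
#
# Implements the SMARTS subset needed by the functional-group catalog and
# the BRICS bond-environment rules: element (#n), aromatic/aliphatic symbol
# primitives, a/A/*, degree D, total-H count H, connectivity X, ring
# membership R/!R, formal charge, recursive environments $(...), the
# logical operators ! & , ; at standard precedence, and the bond primitives
# - = # : ~ @ with the same logic. Matching is depth-first backtracking
# over an injective atom mapping (hydrogens are implicit, so `D` counts
# heavy neighbours, as in molecules without explicit hydrogens).

smarts_cache <- new.env(parent = emptyenv())

#' Parse a SMARTS pattern
#'
#' @param smarts SMARTS string (subset; see package vignette).
#' @return an opaque compiled pattern object of class `sme_smarts`.
#' @export
parse_smarts <- function(smarts) {
  key <- smarts
  hit <- smarts_cache[[key]]
  if (!is.null(hit)) return(hit)
  pat <- parse_smarts_impl(smarts)
  assign(key, pat, envir = smarts_cache)
  pat
}

parse_smarts_impl <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  pos <- 1L

  peek <- function() if (pos <= n) chars[pos] else ""
  adv <- function(k = 1L) pos <<- pos + k
  fail <- function(msg) stop("SMARTS parse error in '", s, "': ", msg, call. = FALSE)

  read_int <- function() {
    out <- ""
    while (pos <= n && grepl("[0-9]", chars[pos])) { out <- paste0(out, chars[pos]); adv() }
    if (nzchar(out)) as.integer(out) else NA_integer_
  }

  # ---- atom expression parsing (inside brackets) ----
  prim <- function() {
    ch <- peek()
    if (ch == "!") { adv(); return(list(op = "not", x = prim())) }
    if (ch == "$") {
      adv()
      if (peek() != "(") fail("expected ( after $")
      depth <- 0L; j <- pos
      repeat {
        if (j > n) fail("unbalanced $(...)")
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") { depth <- depth - 1L; if (depth == 0L) break }
        j <- j + 1L
      }
      sub <- paste(chars[(pos + 1L):(j - 1L)], collapse = "")
      pos <<- j + 1L
      return(list(op = "prim", type = "rec", pat = parse_smarts_impl(sub)))
    }
    if (ch == "#") { adv(); v <- read_int(); if (is.na(v)) fail("bad #n")
      return(list(op = "prim", type = "elem", num = v)) }
    if (ch == "*") { adv(); return(list(op = "prim", type = "any")) }
    if (ch == "a") { adv(); return(list(op = "prim", type = "arom", val = TRUE)) }
    if (ch == "A") { adv(); return(list(op = "prim", type = "arom", val = FALSE)) }
    if (ch == "D") { adv(); v <- read_int(); if (is.na(v)) v <- 1L
      return(list(op = "prim", type = "D", n = v)) }
    if (ch == "H") { adv(); v <- read_int(); if (is.na(v)) v <- 1L
      return(list(op = "prim", type = "H", n = v)) }
    if (ch == "X") { adv(); v <- read_int(); if (is.na(v)) v <- 1L
      return(list(op = "prim", type = "X", n = v)) }
    if (ch == "R") { adv(); v <- read_int()
      if (!is.na(v) && v == 0L) return(list(op = "prim", type = "ring", val = FALSE))
      return(list(op = "prim", type = "ring", val = TRUE)) }
    if (ch == "+") { adv(); v <- read_int()
      if (is.na(v)) { v <- 1L; while (peek() == "+") { v <- v + 1L; adv() } }
      return(list(op = "prim", type = "charge", n = v)) }
    if (ch == "-") { adv(); v <- read_int()
      if (is.na(v)) { v <- 1L; while (peek() == "-") { v <- v + 1L; adv() } }
      return(list(op = "prim", type = "charge", n = -v)) }
    # element symbols (two-letter first), aromatic lower-case
    two <- if (pos < n) paste0(chars[pos], chars[pos + 1L]) else ""
    if (two %in% c("Cl", "Br", "Si")) { adv(2L)
      return(list(op = "prim", type = "sym", sym = two, arom = FALSE)) }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) { adv()
      return(list(op = "prim", type = "sym", sym = ch, arom = FALSE)) }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) { adv()
      return(list(op = "prim", type = "sym", sym = toupper(ch), arom = TRUE)) }
    fail(paste0("unsupported atom primitive at '", ch, "'"))
  }
  and_hi <- function() {
    x <- prim()
    repeat {
      ch <- peek()
      if (ch == "&") { adv(); x <- list(op = "and", x = x, y = prim()); next }
      if (ch %in% c("", ",", ";", "]")) return(x)
      # implicit AND (juxtaposition)
      x <- list(op = "and", x = x, y = prim())
    }
  }
  or_expr <- function() {
    x <- and_hi()
    while (peek() == ",") { adv(); x <- list(op = "or", x = x, y = and_hi()) }
    x
  }
  atom_expr <- function() {
    x <- or_expr()
    while (peek() == ";") { adv(); x <- list(op = "and", x = x, y = or_expr()) }
    x
  }

  # ---- bond expression parsing ----
  bond_prim <- function() {
    ch <- peek()
    if (ch == "!") { adv(); return(list(op = "not", x = bond_prim())) }
    if (ch == "-") { adv(); return(list(op = "prim", type = "single")) }
    if (ch == "=") { adv(); return(list(op = "prim", type = "double")) }
    if (ch == "#") { adv(); return(list(op = "prim", type = "triple")) }
    if (ch == ":") { adv(); return(list(op = "prim", type = "aromatic")) }
    if (ch == "~") { adv(); return(list(op = "prim", type = "anybond")) }
    if (ch == "@") { adv(); return(list(op = "prim", type = "ringbond")) }
    NULL
  }
  bond_expr <- function() {
    x <- bond_prim()
    if (is.null(x)) return(NULL)
    repeat {
      ch <- peek()
      if (ch == "&") { adv(); x <- list(op = "and", x = x, y = bond_prim()); next }
      if (ch == ";") { adv(); x <- list(op = "and", x = x, y = bond_prim()); next }
      if (ch == ",") { adv(); x <- list(op = "or", x = x, y = bond_prim()); next }
      nxt <- bond_prim()
      if (is.null(nxt)) return(x)
      x <- list(op = "and", x = x, y = nxt)
    }
  }

  # ---- structure parsing ----
  atoms <- list()
  b_a1 <- integer(0); b_a2 <- integer(0); b_expr <- list()
  stack <- integer(0); prev <- 0L
  pending <- NULL
  ringmap <- list()

  add_pattern_atom <- function(expr) {
    atoms[[length(atoms) + 1L]] <<- expr
    length(atoms)
  }
  add_pattern_bond <- function(a1, a2, expr) {
    b_a1 <<- c(b_a1, a1); b_a2 <<- c(b_a2, a2)
    b_expr[length(b_expr) + 1L] <<- list(expr)   # keeps NULL (default bond)
  }

  while (pos <= n) {
    ch <- peek()
    newatom <- NA_integer_
    if (ch == "(") { stack <- c(stack, prev); adv(); next }
    if (ch == ")") {
      if (!length(stack)) fail("unbalanced )")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      adv(); next
    }
    if (grepl("[0-9]", ch)) {
      key <- ch; adv()
      if (!is.null(ringmap[[key]])) {
        open <- ringmap[[key]]
        ex <- if (!is.null(pending)) pending else open$expr
        add_pattern_bond(open$atom, prev, ex)
        ringmap[[key]] <- NULL
      } else ringmap[[key]] <- list(atom = prev, expr = pending)
      pending <- NULL
      next
    }
    be <- bond_expr()
    if (!is.null(be)) { pending <- be; next }
    if (ch == "[") {
      adv()
      ex <- atom_expr()
      if (peek() == ":") { adv(); read_int() }   # atom map label, ignored
      if (peek() != "]") fail("expected ]")
      adv()
      newatom <- add_pattern_atom(ex)
    } else {
      two <- if (pos < n) paste0(chars[pos], chars[pos + 1L]) else ""
      if (two %in% c("Cl", "Br")) { adv(2L)
        newatom <- add_pattern_atom(list(op = "prim", type = "sym", sym = two, arom = FALSE))
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) { adv()
        newatom <- add_pattern_atom(list(op = "prim", type = "sym", sym = ch, arom = FALSE))
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) { adv()
        newatom <- add_pattern_atom(list(op = "prim", type = "sym", sym = toupper(ch), arom = TRUE))
      } else if (ch == "*") { adv()
        newatom <- add_pattern_atom(list(op = "prim", type = "any"))
      } else if (ch == "a") { adv()
        newatom <- add_pattern_atom(list(op = "prim", type = "arom", val = TRUE))
      } else if (ch == "A") { adv()
        newatom <- add_pattern_atom(list(op = "prim", type = "arom", val = FALSE))
      } else fail(paste0("unexpected '", ch, "'"))
    }
    if (!is.na(newatom)) {
      if (prev > 0L) { add_pattern_bond(prev, newatom, pending); pending <- NULL }
      prev <- newatom
    }
  }
  if (length(stack)) fail("unbalanced (")
  if (any(!vapply(ringmap, is.null, TRUE))) fail("unclosed ring bond")
  if (!length(atoms)) fail("empty pattern")

  pat <- list(atoms = atoms, a1 = b_a1, a2 = b_a2, bexpr = b_expr, smarts = s)
  class(pat) <- "sme_smarts"
  pat
}

# --- evaluation -------------------------------------------------------------

eval_atom_expr <- function(expr, mol, v) {
  switch(expr$op,
    "and" = eval_atom_expr(expr$x, mol, v) && eval_atom_expr(expr$y, mol, v),
    "or"  = eval_atom_expr(expr$x, mol, v) || eval_atom_expr(expr$y, mol, v),
    "not" = !eval_atom_expr(expr$x, mol, v),
    "prim" = switch(expr$type,
      "any"    = TRUE,
      "elem"   = {
        num <- ATOMIC_NUMBER[mol$symbol[v]]
        !is.na(num) && num == expr$num
      },
      "sym"    = mol$symbol[v] == expr$sym && mol$aromatic[v] == expr$arom,
      "arom"   = mol$aromatic[v] == expr$val,
      "D"      = mol$degree[v] == expr$n,
      "H"      = mol$nH[v] == expr$n,
      "X"      = (mol$degree[v] + mol$nH[v]) == expr$n,
      "ring"   = mol$in_ring[v] == expr$val,
      "charge" = mol$charge[v] == expr$n,
      "rec"    = length(match_smarts_from(mol, expr$pat, v, first_only = TRUE)) > 0L,
      stop("unknown primitive ", expr$type)
    ),
    stop("unknown op ", expr$op)
  )
}

eval_bond_expr <- function(expr, mol, e) {
  if (is.null(expr)) {  # default: single or aromatic
    return(mol$bonds$aromatic[e] || mol$bonds$order[e] == 1L)
  }
  switch(expr$op,
    "and" = eval_bond_expr(expr$x, mol, e) && eval_bond_expr(expr$y, mol, e),
    "or"  = eval_bond_expr(expr$x, mol, e) || eval_bond_expr(expr$y, mol, e),
    "not" = !eval_bond_expr(expr$x, mol, e),
    "prim" = switch(expr$type,
      "single"   = !mol$bonds$aromatic[e] && mol$bonds$order[e] == 1L,
      "double"   = !mol$bonds$aromatic[e] && mol$bonds$order[e] == 2L,
      "triple"   = !mol$bonds$aromatic[e] && mol$bonds$order[e] == 3L,
      "aromatic" = mol$bonds$aromatic[e],
      "anybond"  = TRUE,
      "ringbond" = isTRUE(mol$bonds$in_ring[e]),
      stop("unknown bond primitive ", expr$type)
    )
  )
}

# backtracking matcher; pattern atoms are matched in an order where every
# atom after the first is bonded to an already-matched one
smarts_match_order <- function(pat) {
  np <- length(pat$atoms)
  if (np == 1L) return(list(order = 1L, via = 0L))
  placed <- 1L
  order <- 1L; via <- 0L
  nb <- vector("list", np)
  for (i in seq_along(pat$a1)) {
    nb[[pat$a1[i]]] <- c(nb[[pat$a1[i]]], i)
    nb[[pat$a2[i]]] <- c(nb[[pat$a2[i]]], i)
  }
  while (length(order) < np) {
    added <- FALSE
    for (p in order) {
      for (e in nb[[p]]) {
        q <- if (pat$a1[e] == p) pat$a2[e] else pat$a1[e]
        if (!(q %in% order)) {
          order <- c(order, q); via <- c(via, e); added <- TRUE
          break
        }
      }
      if (added) break
    }
    if (!added) stop("disconnected SMARTS pattern: ", pat$smarts, call. = FALSE)
  }
  list(order = order, via = via)
}

match_smarts_from <- function(mol, pat, root, first_only = FALSE) {
  ord <- smarts_match_order(pat)
  np <- length(pat$atoms)
  madj <- mol$adj
  if (is.null(madj)) madj <- mol_adjacency(mol)
  results <- list()
  assign_map <- integer(np)   # pattern atom -> mol atom

  find_bond <- function(u, v) {
    for (e in madj[[u]]) {
      if (mol$bonds$a1[e] == v || mol$bonds$a2[e] == v) return(e)
    }
    0L
  }
  # all pattern bonds between pattern atoms placed so far must hold
  bonds_ok <- function(k) {
    p <- ord$order[k]
    for (i in seq_along(pat$a1)) {
      pa <- pat$a1[i]; pb <- pat$a2[i]
      if ((pa == p && assign_map[pb] > 0L) || (pb == p && assign_map[pa] > 0L)) {
        e <- find_bond(assign_map[pa], assign_map[pb])
        if (e == 0L) return(FALSE)
        if (!eval_bond_expr(pat$bexpr[[i]], mol, e)) return(FALSE)
      }
    }
    TRUE
  }

  rec <- function(k) {
    if (k > np) {
      results[[length(results) + 1L]] <<- assign_map
      return(first_only)
    }
    p <- ord$order[k]
    if (k == 1L) {
      cands <- root
    } else {
      e <- ord$via[k]
      anchor <- if (pat$a1[e] == p) pat$a2[e] else pat$a1[e]
      av <- assign_map[anchor]
      cands <- vapply(madj[[av]], function(me) bond_other(mol$bonds, me, av), 1L)
    }
    for (v in cands) {
      if (v %in% assign_map[assign_map > 0L]) next
      if (!eval_atom_expr(pat$atoms[[p]], mol, v)) next
      assign_map[p] <<- v
      if (bonds_ok(k)) {
        if (rec(k + 1L)) { if (first_only) return(TRUE) }
      }
      assign_map[p] <<- 0L
    }
    FALSE
  }
  rec(1L)
  results
}

#' Match a SMARTS pattern against a molecule
#'
#' @param mol an `sme_mol` object.
#' @param pattern a SMARTS string or compiled `sme_smarts` pattern.
#' @param unique_sets if `TRUE` (default), matches mapping to the same set
#'   of atoms are reported once.
#' @return list of integer vectors of matched atom indices (1-based,
#'   ordered by pattern atom).
#' @export
match_smarts <- function(mol, pattern, unique_sets = TRUE) {
  pat <- if (inherits(pattern, "sme_smarts")) pattern else parse_smarts(pattern)
  res <- match_smarts_from(mol, pat, seq_len(mol$n))
  if (unique_sets && length(res) > 1L) {
    keys <- vapply(res, function(m) paste(sort(m), collapse = ","), "")
    res <- res[!duplicated(keys)]
  }
  res
}

#' Test whether a molecule contains a SMARTS pattern
#' @inheritParams match_smarts
#' @return logical scalar.
#' @export
has_smarts <- function(mol, pattern) {
  pat <- if (inherits(pattern, "sme_smarts")) pattern else parse_smarts(pattern)
  length(match_smarts_from(mol, pat, seq_len(mol$n), first_only = TRUE)) > 0L
}
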