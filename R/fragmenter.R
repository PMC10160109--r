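# Substructure generation: BRICS decomposition, Bemis-Murcko scaffold and
# side chains, and functional-group SMARTS matching.
#
# All three schemes report substructures as sets of 0-based heavy-atom
# indices on the parent molecule, in the parse order of the stored
# canonical SMILES. BRICS and Murcko substructures partition the heavy
# atoms; functional-group matches may overlap.

#' Construct a substructure descriptor
#'
#' @param scheme one of `"BRICS"`, `"MURCKO"`, `"FUNCTIONAL_GROUP"`,
#'   `"COMBINATION"`.
#' @param atom_indices integer vector of 0-based heavy-atom indices.
#' @param name human-readable tag (fragment SMILES, catalog entry name, or
#'   member list for combinations).
#' @param members for combinations, list of source substructures.
#' @return an object of class `sme_substructure`.
#' @export
substructure <- function(scheme, atom_indices, name, members = NULL) {
  scheme <- match.arg(scheme, c("BRICS", "MURCKO", "FUNCTIONAL_GROUP", "COMBINATION"))
  atom_indices <- sort(unique(as.integer(atom_indices)))
  if (!length(atom_indices)) stop("substructure needs a nonempty atom set", call. = FALSE)
  if (any(atom_indices < 0L)) stop("atom indices must be >= 0", call. = FALSE)
  out <- list(scheme = scheme, atom_indices = atom_indices,
              name = as.character(name), members = members)
  class(out) <- "sme_substructure"
  out
}

#' @export
print.sme_substructure <- function(x, ...) {
  cat(sprintf("<%s substructure '%s': atoms {%s}>\n", x$scheme, x$name,
              paste(x$atom_indices, collapse = ",")))
  invisible(x)
}

#' A molecule record
#'
#' @param id identifier string.
#' @param smiles SMILES string; stored in canonical form.
#' @param label optional scalar label (regression value or 0/1 class).
#' @return an object of class `sme_molecule` carrying the parsed molecule.
#' @export
molecule_record <- function(id, smiles, label = NULL) {
  mol <- tryCatch(parse_smiles(smiles, id = id), error = function(e)
    stop("cannot parse molecule ", if (!is.null(id)) paste0("'", id, "'"),
         ": ", conditionMessage(e), call. = FALSE))
  out <- list(id = as.character(id), smiles = mol_to_smiles(mol),
              label = if (is.null(label)) NULL else as.numeric(label),
              n_heavy_atoms = mol$n, mol = mol)
  class(out) <- "sme_molecule"
  out
}

as_sme_mol <- function(x) {
  if (inherits(x, "sme_mol")) return(x)
  if (inherits(x, "sme_molecule")) return(x$mol)
  if (is.character(x) && length(x) == 1L) return(parse_smiles(x))
  stop("expected a molecule record, sme_mol or SMILES string", call. = FALSE)
}

# --- BRICS ------------------------------------------------------------------

#' The BRICS bond-environment rule table
#'
#' Returns the 16 BRICS link environments (L1-L16) used to locate cleavable
#' bonds, following the retrosynthetic fragmentation scheme of Degen et al.
#' Each entry pairs a link label with the SMARTS definition of its chemical
#' environment. L2 is the historical acyclic secondary-amine environment of
#' the original scheme; in this implementation (as in common toolkit
#' practice) its bonds are already covered by the unified amine environment
#' L5, which takes precedence during labelling. The `compatible` attribute
#' holds the ordered list of complementary link-type pairs that define the
#' cleavable bonds and the recombination rules.
#'
#' @return a 16-row data.frame with columns `label`, `smarts`, `description`,
#'   carrying the pair list as attribute `"compatible"`.
#' @export
brics_rules <- function() {
  rules <- data.frame(
    label = 1:16,
    smarts = c(
      "[C;D3]([#0,#6,#7,#8])(=O)",
      "[N;!R;!D1;!$(N=*)]-;!@[#0,#6]",
      "[O;D2]-;!@[#0,#6,#1]",
      "[C;!D1;!$(C=*)]-;!@[#6]",
      "[N;!D1;!$(N=*);!$(N-[!#6;!#16;!#0;!#1]);!$([N;R]@[C;R]=O)]",
      "[C;D3;!R](=O)-;!@[#0,#6,#7,#8]",
      "[C;D2,D3]-[#6]",
      "[C;!R;!D1;!$(C!-*)]",
      "[n;+0;$(n(:[c,n,o,s]):[c,n,o,s])]",
      "[N;R;$(N(@C(=O))@[C,N,O,S])]",
      "[S;D2](-;!@[#0,#6])",
      "[S;D4]([#6,#0])(=O)(=O)",
      "[C;$(C(-;@[C,N,O,S])-;@[N,O,S])]",
      "[c;$(c(:[c,n,o,s]):[n,o,s])]",
      "[C;$(C(-;@C)-;@C)]",
      "[c;$(c(:c):c)]"
    ),
    description = c(
      "acyl carbon", "acyclic secondary amine (historical; see L5)",
      "ether/ester oxygen", "aliphatic carbon attached to carbon",
      "amine nitrogen (unified)", "acyclic carbonyl carbon",
      "vinylic/allylic carbon (double-bond cleavage)",
      "saturated acyclic carbon", "aromatic nitrogen",
      "cyclic amide nitrogen", "thioether sulfur", "sulfonyl sulfur",
      "ring carbon next to ring heteroatom", "aromatic carbon next to ring heteroatom",
      "carbocyclic ring carbon", "aromatic carbon flanked by aromatic carbons"
    )
  )
  compatible <- list(
    c(1L, 3L), c(1L, 5L), c(1L, 10L), c(1L, 2L),
    c(3L, 4L), c(3L, 13L), c(3L, 14L), c(3L, 15L), c(3L, 16L),
    c(4L, 5L), c(4L, 11L),
    c(5L, 12L), c(5L, 13L), c(5L, 14L), c(5L, 15L), c(5L, 16L),
    c(6L, 13L), c(6L, 14L), c(6L, 15L), c(6L, 16L),
    c(7L, 7L),
    c(8L, 9L), c(8L, 10L), c(8L, 13L), c(8L, 14L), c(8L, 15L), c(8L, 16L),
    c(9L, 13L), c(9L, 14L), c(9L, 15L), c(9L, 16L),
    c(10L, 13L), c(10L, 14L), c(10L, 15L), c(10L, 16L),
    c(11L, 13L), c(11L, 14L), c(11L, 15L), c(11L, 16L),
    c(13L, 14L), c(13L, 15L), c(13L, 16L),
    c(14L, 14L), c(14L, 15L), c(14L, 16L),
    c(15L, 16L),
    c(16L, 16L)
  )
  attr(rules, "compatible") <- compatible
  rules
}

# Locate BRICS-cleavable bonds. Returns a data.frame with one row per
# cleavable bond: bond index, the two atoms and their link labels. A bond
# matched by several rules keeps the labels of the first matching pair.
# For speed, per-atom environment membership is computed once for all 16
# environments; candidate bonds are then screened against the ordered pair
# list (acyclic single bonds, or the acyclic double bond of the L7 rule).
brics_find_bonds <- function(mol) {
  rules <- brics_rules()
  pairs <- attr(rules, "compatible")
  empty <- data.frame(bond = integer(0), a1 = integer(0), a2 = integer(0),
                      l1 = integer(0), l2 = integer(0))
  b <- mol$bonds
  if (!nrow(b)) return(empty)
  in_env <- matrix(FALSE, mol$n, nrow(rules))
  for (l in seq_len(nrow(rules))) {
    pat <- parse_smarts(rules$smarts[l])
    in_env[, l] <- vapply(seq_len(mol$n), function(v)
      length(match_smarts_from(mol, pat, v, first_only = TRUE)) > 0L, TRUE)
  }
  rows <- list()
  cand <- which(!b$in_ring & !b$aromatic & b$order <= 2L)
  for (e in cand) {
    u <- b$a1[e]; v <- b$a2[e]
    for (p in pairs) {
      is7 <- p[1] == 7L && p[2] == 7L
      if ((b$order[e] == 2L) != is7) next
      if (in_env[u, p[1]] && in_env[v, p[2]]) {
        rows[[length(rows) + 1L]] <- data.frame(bond = e, a1 = u, a2 = v,
                                                l1 = p[1], l2 = p[2])
        break
      }
      if (in_env[v, p[1]] && in_env[u, p[2]]) {
        rows[[length(rows) + 1L]] <- data.frame(bond = e, a1 = v, a2 = u,
                                                l1 = p[1], l2 = p[2])
        break
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' BRICS fragmentation
#'
#' Decomposes a molecule into BRICS fragments by cleaving every bond that
#' matches one of the 16-environment retrosynthetic bond rules (see
#' [brics_rules()]). Fragments are reported on the parent molecule's atom
#' indices; cleaved-bond attachment points (atom plus link label) are kept
#' in the `links` attribute of each substructure for the fragment
#' recombination machinery. A molecule with no cleavable bond yields a
#' single fragment covering all heavy atoms.
#'
#' @param mol molecule record, `sme_mol` or SMILES string.
#' @return list of `sme_substructure` objects (scheme `"BRICS"`), whose atom
#'   sets partition the heavy atoms of the molecule.
#' @export
brics_fragments <- function(mol) {
  m <- as_sme_mol(mol)
  cb <- brics_find_bonds(m)
  tmp <- m
  if (nrow(cb)) tmp$bonds <- m$bonds[-cb$bond, , drop = FALSE]
  comps <- unname(mol_components(tmp))
  lapply(comps, function(atoms) {
    links <- data.frame(atom = integer(0), label = integer(0))
    if (nrow(cb)) {
      for (i in seq_len(nrow(cb))) {
        if (cb$a1[i] %in% atoms)
          links <- rbind(links, data.frame(atom = cb$a1[i], label = cb$l1[i]))
        if (cb$a2[i] %in% atoms)
          links <- rbind(links, data.frame(atom = cb$a2[i], label = cb$l2[i]))
      }
    }
    frag_smiles <- mol_to_smiles(mol_subgraph(m, atoms)$mol)
    sub <- substructure("BRICS", atoms - 1L, frag_smiles)
    attr(sub, "links") <- links
    sub
  })
}

# --- Murcko -----------------------------------------------------------------

#' Bemis-Murcko scaffold and side chains
#'
#' Splits a molecule into its Murcko scaffold (ring systems plus connecting
#' linkers, including atoms attached to the scaffold by double or triple
#' bonds) and the connected side chains. The scaffold is always the first
#' element. Acyclic molecules have no scaffold: an empty list is returned
#' with a warning.
#'
#' @inheritParams brics_fragments
#' @return list of `sme_substructure` objects (scheme `"MURCKO"`), whose
#'   atom sets partition the heavy atoms when a ring exists.
#' @export
murcko_fragments <- function(mol) {
  m <- as_sme_mol(mol)
  if (!any(m$in_ring)) {
    warning("acyclic molecule has no Murcko scaffold", call. = FALSE)
    return(list())
  }
  keep <- rep(TRUE, m$n)
  b <- m$bonds
  repeat {
    deg <- integer(m$n)
    sel <- keep[b$a1] & keep[b$a2]
    t1 <- tabulate(b$a1[sel], nbins = m$n); t2 <- tabulate(b$a2[sel], nbins = m$n)
    deg <- t1 + t2
    prune <- which(keep & !m$in_ring & deg <= 1L)
    if (!length(prune)) break
    keep[prune] <- FALSE
  }
  # re-attach atoms multiple-bonded to the scaffold (exocyclic =O and kin)
  repeat {
    add <- which(!keep & vapply(seq_len(m$n), function(v) {
      any((b$a1 == v & keep[b$a2] | b$a2 == v & keep[b$a1]) & b$order >= 2L)
    }, TRUE))
    if (!length(add)) break
    keep[add] <- TRUE
  }
  scaffold_atoms <- which(keep)
  scaff_smiles <- mol_to_smiles(mol_subgraph(m, scaffold_atoms)$mol)
  out <- list(substructure("MURCKO", scaffold_atoms - 1L, scaff_smiles))
  rest <- which(!keep)
  if (length(rest)) {
    tmp <- m
    selb <- b$a1 %in% rest & b$a2 %in% rest
    tmp$bonds <- b[selb, , drop = FALSE]
    comp <- integer(m$n)
    comps <- mol_components(tmp)
    for (atoms in comps) {
      atoms <- intersect(atoms, rest)
      if (!length(atoms)) next
      side_smiles <- mol_to_smiles(mol_subgraph(m, atoms)$mol)
      out[[length(out) + 1L]] <- substructure("MURCKO", atoms - 1L, side_smiles)
    }
  }
  out
}

# --- functional groups ------------------------------------------------------

#' Load a functional-group catalog
#'
#' Reads a catalog of named SMARTS patterns, one `name<TAB>SMARTS` (with an
#' optional third graft-SMILES column) per line, `#` comments allowed.
#' `"default"` loads the catalog shipped with the package: 33 common
#' functional groups.
#'
#' @param path file path, or `"default"`.
#' @return an object of class `sme_fg_catalog`: a data.frame with columns
#'   `name`, `smarts`, `graft` plus a `version` attribute.
#' @export
load_fg_catalog <- function(path = "default") {
  if (identical(path, "default")) {
    file <- system.file("extdata", "functional_groups_v1.tsv", package = "smexplain")
    if (!nzchar(file)) file <- "inst/extdata/functional_groups_v1.tsv"
    version <- "v1"
  } else {
    if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
    file <- path
    version <- basename(path)
  }
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("malformed catalog line: ", lines[bad][1], call. = FALSE)
  cat_df <- data.frame(
    name = vapply(parts, `[[`, "", 1L),
    smarts = vapply(parts, `[[`, "", 2L),
    graft = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", "")
  )
  if (anyDuplicated(cat_df$name))
    stop("duplicate functional-group names in catalog: ",
         paste(unique(cat_df$name[duplicated(cat_df$name)]), collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(cat_df))) {
    ok <- tryCatch({ parse_smarts(cat_df$smarts[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("invalid SMARTS for catalog entry '", cat_df$name[i], "': ",
                  cat_df$smarts[i], call. = FALSE)
  }
  attr(cat_df, "version") <- version
  class(cat_df) <- c("sme_fg_catalog", "data.frame")
  cat_df
}

#' Functional-group substructure matches
#'
#' Matches every catalog entry against a molecule. Each distinct occurrence
#' (unique atom-index set per entry) becomes one substructure; overlapping
#' matches from different entries are all kept.
#'
#' @inheritParams brics_fragments
#' @param catalog an `sme_fg_catalog` (default: the shipped catalog).
#' @return list of `sme_substructure` objects (scheme `"FUNCTIONAL_GROUP"`),
#'   named by catalog entry.
#' @export
functional_group_matches <- function(mol, catalog = load_fg_catalog()) {
  m <- as_sme_mol(mol)
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    ms <- match_smarts(m, catalog$smarts[i], unique_sets = TRUE)
    for (mm in ms) {
      out[[length(out) + 1L]] <-
        substructure("FUNCTIONAL_GROUP", sort(mm) - 1L, catalog$name[i])
    }
  }
  out
}
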