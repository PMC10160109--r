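# Synthetic data with known ground truth.
#
# Molecules are assembled by seeded random BRICS joins over a built-in
# vocabulary of ~40 attachment-labelled fragments. The vocabulary
# deliberately carries hydroxyl, amine, nitro, carboxyl, methyl, halogen
# and aromatic-ring fragments so that the default functional-group catalog
# finds each common group at least ten times in libraries of 500 molecules
# or more. Labels come from three generative models: an additive
# group-contribution regression (designed weights + Gaussian noise), a
# toxicophore-presence binary rule (with optional label flips), or a
# locally computed physicochemical descriptor.

#' Built-in fragment vocabulary for synthetic libraries
#'
#' Fragments carry `[n*]` BRICS attachment labels. The `weights` attribute
#' holds the default sampling weights, chosen so that binary toxicophore
#' libraries are roughly class-balanced and a substantial share of positive
#' molecules carries two distinct toxicophores.
#'
#' @return character vector of fragment SMILES with a `weights` attribute.
#' @export
fixture_vocabulary <- function() {
  v <- c(
    # aromatic carriers (L16 / L14 attachment)
    "[16*]c1ccccc1",
    "[16*]c1ccc(O)cc1",
    "[16*]c1cccc(O)c1",
    "[16*]c1ccc(N)cc1",
    "[16*]c1cccc(N)c1",
    "[16*]c1ccc([N+](=O)[O-])cc1",
    "[16*]c1cccc([N+](=O)[O-])c1",
    "[16*]c1ccc([N+](=O)[O-])c(C)c1",
    "[16*]c1ccc(N)c(C)c1",
    "[16*]c1ccc(C)cc1",
    "[16*]c1ccc(Cl)cc1",
    "[16*]c1ccc(F)cc1",
    "[16*]c1ccc(Br)cc1",
    "[16*]c1ccc(I)cc1",
    "[16*]c1ccc(C(F)(F)F)cc1",
    "[16*]c1ccc(S(N)(=O)=O)cc1",
    "[16*]c1ccc(C#N)cc1",
    "[16*]c1ccc(C(=O)O)cc1",
    "[16*]c1ccc(CO)cc1",
    "[16*]c1ccc(N(C)C)cc1",
    "[16*]c1ccc(NC)cc1",
    "[16*]c1ccc(S)cc1",
    "[16*]c1ccc(OC)cc1",
    "[16*]c1ccc(C)c(C)c1",
    # neutral carriers (no designed group): the weakly-attributed bulk that
    # dilutes full-sign fragment pools, as plain scaffolds do in real data
    "[16*]c1ccc2ccccc2c1",
    "[16*]c1cccc2ccccc12",
    "[16*]c1cccnc1",
    "[14*]c1ccco1",
    "[14*]c1cccs1",
    "[15*]C1CCCCC1",
    "[15*]C1CCCC1",
    "[16*]c1cccc([16*])c1",
    "[16*]c1ccc2cc([16*])ccc2c1",
    "[15*]C1CCC([15*])CC1",
    # high-magnitude carriers on the aromatic link class, so the extreme
    # tails of either sign span complementary BRICS link types
    "[16*]c1ccc(O)c(O)c1",
    "[16*]c1cc(O)cc(C(=O)O)c1",
    "[16*]c1cc(Cl)cc(Cl)c1",
    "[16*]c1cc(C(F)(F)F)cc(Br)c1",
    "[14*]c1ccccn1",
    "[16*]c1ccc([16*])cc1",          # para-phenylene (two links)
    # decorated bridges: two-link carriers of strong positive/negative
    # groups, so extreme-tail pools keep a combinatorially rich assembly
    # space (trees, not just chains of one bridge type)
    "[16*]c1cc([16*])cc(O)c1",
    "[16*]c1cc([16*])cc(Cl)c1",
    "[16*]c1cc([16*])cc(C(F)(F)F)c1",
    "[16*]c1cc([16*])cc(C(=O)O)c1",
    "[16*]c1cc([16*])cc([N+](=O)[O-])c1",
    "[16*]c1cc([16*])cc(N)c1",
    # double-group bridges: by design the largest-magnitude carriers of
    # each sign, so extreme-tail pools always contain branching fragments
    "[16*]c1cc(O)c([16*])cc1O",
    "[16*]c1cc(Cl)c([16*])cc1C(F)(F)F",
    "[8*]CC(O)C[8*]",
    # aliphatic carriers (L8 attachment; attachment carbon keeps degree >= 2)
    "[8*]CC",
    "[8*]CCC",
    "[8*]C(C)C",
    "[8*]CCO",
    "[8*]CCCO",
    "[8*]CCN",
    "[8*]CCCl",
    "[8*]CC(=O)O",
    "[8*]CCOC",
    "[8*]CC#N",
    "[8*]CCS",
    "[8*]C(C)O",
    "[8*]CC(F)(F)F",
    "[8*]CC[8*]",                    # ethylene bridge (two links)
    # acyl / heteroatom links
    "[1*]C(C)=O",
    "[1*]C(=O)CC",
    "[5*]NC",
    "[5*]NCC",
    "[3*]OC",
    "[3*]OCC",
    "[11*]SC",
    "[12*]S(C)(=O)=O"
  )
  w <- rep(1, length(v))
  names(w) <- v
  # toxicophore carriers drawn more often: keeps the binary fixture near
  # class balance and gives a solid double-toxicophore subset
  w[grepl("\\[N\\+\\]", v)] <- 2.2
  w[v %in% c("[16*]c1ccc(N)cc1", "[16*]c1cccc(N)c1",
             "[16*]c1ccc(N)c(C)c1")] <- 2.2
  w[v == "[16*]c1ccc([16*])cc1"] <- 2.0
  w[v == "[8*]CC[8*]"] <- 1.2
  # toxic bridges: moderate weight (they both enrich toxic positives and
  # add branching)
  w[v %in% c("[16*]c1cc([16*])cc([N+](=O)[O-])c1",
             "[16*]c1cc([16*])cc(N)c1")] <- 1.5
  attr(v, "weights") <- w
  v
}

#' Label specification for synthetic datasets
#'
#' @param task `"additive_regression"`, `"toxicophore_binary"` or
#'   `"descriptor"`.
#' @param group_weights named numeric vector of designed per-group weights
#'   (functional-group catalog names) for the additive task.
#' @param toxic_smarts named character vector of toxicophore SMARTS for the
#'   binary task.
#' @param flip_prob label-flip probability for the binary task (in
#'   \[0, 0.5)).
#' @param descriptor descriptor name for the descriptor task.
#' @param noise_sd Gaussian noise standard deviation for the additive task.
#' @return an object of class `sme_label_spec`.
#' @export
label_spec <- function(task = c("additive_regression", "toxicophore_binary",
                                "descriptor"),
                       group_weights = NULL, toxic_smarts = NULL,
                       flip_prob = 0, descriptor = "MW", noise_sd = 0.1) {
  task <- match.arg(task)
  if (is.null(group_weights))
    group_weights <- c(
      hydroxyl = 1.0, primary_amine = 0.8, carboxylic_acid = 1.0,
      nitro = -0.6, methyl = -0.5, chloro = -0.8, fluoro = -0.4,
      bromo = -0.9, iodo = -1.0, trifluoromethyl = -1.2, nitrile = 0.3,
      sulfonamide = 0.6, methoxy = 0.2, thioether = -0.7
    )
  if (is.null(toxic_smarts))
    toxic_smarts <- c(nitroaromatic = "[c][N+](=O)[O-]",
                      aromatic_primary_amine = "[c][N;H2;D1]")
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must be in [0, 0.5)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(all(is.finite(group_weights)))
  out <- list(task = task, group_weights = group_weights,
              toxic_smarts = toxic_smarts, flip_prob = flip_prob,
              descriptor = descriptor, noise_sd = noise_sd)
  class(out) <- "sme_label_spec"
  out
}

#' Generate a synthetic SMILES library
#'
#' Assembles `n` distinct molecules by seeded random BRICS joins over the
#' fragment vocabulary.
#'
#' @param n number of molecules (>= 1).
#' @param seed RNG seed.
#' @param vocabulary fragment SMILES with `[n*]` attachment labels.
#' @param weights per-fragment sampling weights.
#' @param max_heavy_atoms heavy-atom cap per molecule.
#' @param templates optional list of fragment-SMILES vectors; each template
#'   is joined in sequence and then grown randomly, seeding a designed
#'   motif into part of the library.
#' @param template_fraction fraction of molecules started from a random
#'   template.
#' @return data.frame with columns `id`, `smiles` (canonical, distinct).
#' @export
generate_library <- function(n, seed = 1L, vocabulary = fixture_vocabulary(),
                             weights = NULL,
                             max_heavy_atoms = 40L,
                             templates = NULL, template_fraction = 0) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (is.null(weights)) {
    weights <- attr(vocabulary, "weights")
    if (is.null(weights)) weights <- rep(1, length(vocabulary))
  }
  frags <- lapply(vocabulary, parse_smiles)
  tmpl <- lapply(templates, function(tv) lapply(tv, parse_smiles))
  set.seed(seed)
  seen <- character(0)
  attempts <- 0L
  budget <- 200L * n
  while (length(seen) < n && attempts < budget) {
    attempts <- attempts + 1L
    start <- NULL
    if (length(tmpl) && stats::runif(1) < template_fraction)
      start <- assemble_template(tmpl[[sample.int(length(tmpl), 1L)]])
    smi <- tryCatch(mol_to_smiles(assemble_molecule(frags, weights,
                                                    max_heavy_atoms,
                                                    start = start)),
                    error = function(e) NA_character_)
    if (is.na(smi) || smi %in% seen) next
    seen <- c(seen, smi)
  }
  if (length(seen) < n)
    stop("could not generate ", n, " distinct molecules from the vocabulary",
         call. = FALSE)
  data.frame(id = sprintf("M%05d", seq_len(n)), smiles = seen)
}

#' Label a molecule under a synthetic label model
#'
#' Additive task: sum of designed group weights times catalog match counts,
#' plus Gaussian noise (drawn from the current RNG stream). Binary task: 1
#' iff any toxicophore SMARTS matches, flipped with probability
#' `flip_prob`. Descriptor task: the named descriptor.
#'
#' @param mol molecule record, `sme_mol` or SMILES string.
#' @param spec an [label_spec()] object.
#' @param catalog functional-group catalog for the additive task.
#' @return numeric label.
#' @export
label_molecule <- function(mol, spec, catalog = load_fg_catalog()) {
  m <- as_sme_mol(if (inherits(mol, "sme_molecule")) mol$mol else mol)
  switch(spec$task,
    additive_regression = {
      matches <- functional_group_matches(m, catalog)
      cnt <- table(vapply(matches, `[[`, "", "name"))
      base <- 0
      for (g in names(spec$group_weights)) {
        k <- if (g %in% names(cnt)) as.integer(cnt[[g]]) else 0L
        base <- base + spec$group_weights[[g]] * k
      }
      base + if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0
    },
    toxicophore_binary = {
      y <- as.numeric(any(vapply(spec$toxic_smarts, function(s)
        has_smarts(m, s), TRUE)))
      if (spec$flip_prob > 0 && stats::runif(1) < spec$flip_prob) y <- 1 - y
      y
    },
    descriptor = mol_descriptor(m, spec$descriptor)
  )
}

#' Generate and split a labeled synthetic dataset
#'
#' Generates a library, labels it under the given specification, shuffles
#' and splits 8:1:1 into train/validation/test.
#'
#' @param spec an [label_spec()] object.
#' @param n library size (>= 10).
#' @param seed RNG seed controlling library assembly, label noise and the
#'   split.
#' @param catalog functional-group catalog for additive labels.
#' @return list with data.frames `train`, `val`, `test` (columns `id`,
#'   `smiles`, `label`), sized `floor(0.8 n)` / `floor(0.1 n)` / rest.
#' @export
make_dataset <- function(spec, n, seed = 1L, catalog = load_fg_catalog()) {
  if (n < 10L) stop("n must be >= 10", call. = FALSE)
  if (spec$task == "toxicophore_binary") {
    # a quarter of the binary library is seeded with a bridged pair of the
    # two designed toxicophores, guaranteeing a double-toxicophore subset
    # held in *different* BRICS fragments
    # the three-link hub leaves one attachment open after both toxicophores
    # are placed, so templated molecules stay diverse under random growth
    tmpl <- list(
      c("[16*]c1cc([16*])cc([16*])c1", "[16*]c1ccc([N+](=O)[O-])cc1",
        "[16*]c1ccc(N)cc1"),
      c("[16*]c1cc([16*])cc([16*])c1", "[16*]c1cccc([N+](=O)[O-])c1",
        "[16*]c1cccc(N)c1")
    )
    lib <- generate_library(n, seed = seed, templates = tmpl,
                            template_fraction = 0.25)
  } else {
    lib <- generate_library(n, seed = seed)
  }
  set.seed(seed + 1L)
  lib$label <- vapply(lib$smiles, function(s) label_molecule(s, spec, catalog), 1,
                      USE.NAMES = FALSE)
  idx <- sample(n)
  ntr <- floor(0.8 * n); nva <- floor(0.1 * n)
  list(train = lib[idx[seq_len(ntr)], , drop = FALSE],
       val = lib[idx[seq.int(ntr + 1L, ntr + nva)], , drop = FALSE],
       test = lib[idx[seq.int(ntr + nva + 1L, n)], , drop = FALSE])
}
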