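---
title: "Substructure-mask explanation of molecular RGCN models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substructure-mask explanation of molecular RGCN models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Graph neural networks predict molecular properties well but offer little
insight into *why* a molecule is predicted soluble, mutagenic or
channel-blocking. Atom- or edge-level saliency rarely aligns with how
chemists reason: a nitro group is one functional unit, not three unrelated
atoms. This package explains a trained graph model at the level of
*chemically meaningful substructures* — BRICS fragments, the Bemis–Murcko
scaffold and its side chains, and catalogued functional groups — by masking
a substructure at the model's readout and measuring how much the consensus
prediction moves.

## The model under explanation

`rgcn_consensus()` fits the model the attribution engine explains: an
ensemble of relational graph convolutional networks (RGCN). Each sub-model
propagates node states with relation-specific weights, one relation per
bond type (single, double, triple, aromatic):

$$h_v^{(l+1)} = \mathrm{ReLU}\Big(\sum_{r \in R}\sum_{u \in N_v^r}
W_r^{(l)} h_u^{(l)} + W_0^{(l)} h_v^{(l)}\Big)$$

There is deliberately **no degree normalization**: the propagation rule is
implemented exactly as written (a `normalize_degree` switch exists but
defaults off). $W_r$ is a linear combination of `n_bases` basis matrices;
the default `n_bases` equals the number of relations, i.e. independent
relation weights. Readout is attention pooling — a per-node sigmoid gate
$\omega_v = \sigma(w\cdot h_v + b)$ followed by a gated sum — and a
three-layer fully connected head produces one output, passed through a
sigmoid for binary tasks. The consensus prediction is the **mean** of the
sub-model outputs (ten sub-models with different seeds by default), which
keeps binary outputs inside $[0,1]$.

Node features default to one-hot element (B, C, N, O, F, Si, P, S, Cl, Br,
I, other), one-hot degree 0–5, formal charge, one-hot implicit-H count 0–4,
one-hot hybridization (sp/sp2/sp3/other), an aromaticity flag and a ring
flag. These defaults are this package's choice of the standard molecular-GNN
feature set and are configurable through `feature_config()`.

Training uses Adam (learning rate `1e-3`), minibatches over a sparse
block-diagonal batch representation, mean-squared error or cross-entropy,
and early stopping on validation loss (patience 30 by default). Gradients
are computed analytically; the implementation was verified against
finite-difference derivatives during development and the forward pass is
continuously tested against an explicit double-sum oracle.

## The attribution

For a substructure $s$ with atom set $A(s)$, build the mask
$m_v = 0$ for $v \in A(s)$, $1$ otherwise, and compute

$$\mathrm{embedding}_{\mathrm{mask}} = \sum_v \omega_v\, h_v\, m_v ,
\qquad \mathrm{attribution}(s) = Y - Y_s ,$$

where $Y$ is the consensus prediction with the all-ones mask and $Y_s$ the
prediction with $s$ masked. Two properties are load-bearing and tested:

* **Readout locality.** Message passing always runs on the *full* graph;
  the mask enters only at the pooled readout. Node hidden states are
  therefore computed once per sub-model and reused for every mask of a
  molecule, which makes dataset-level attribution cheap.
* **Identities.** The empty mask gives attribution exactly 0 (bitwise-equal
  forward passes), and masking every node yields the head's output at the
  zero embedding — a constant per sub-model, independent of the molecule.

A positive attribution means the substructure pushes the prediction up
(toward the property value, or toward the positive class).

### Normalization

Attributions are rescaled over the whole record set of one explain run (not
per molecule) so that values are comparable across a dataset. The default
`"maxabs"` divides by the largest absolute attribution, preserving sign
(range $[-1, 1]$); `"minmax01"` maps linearly onto $[0, 1]$. Both exist
because the two conventions appear in the literature describing this method
and are mutually inconsistent when negative scores are reported; signed
scores are what attribution figures display, so the signed scale is the
default. All-zero records normalize to zeros rather than dividing by zero.

### Fragment combinations

A substructure can hide its importance behind redundancy: in a molecule
with two toxicophores, masking either one alone barely moves a saturated
classifier ($Y_{sub} \approx Y \approx 1$), so both receive attribution
near zero. `enumerate_combinations()` therefore masks random *subsets* of
the BRICS or Murcko fragments: all $2^k - 1$ nonempty subsets when they fit
the per-molecule cap (100 per scheme by default; a molecule with 3
fragments has exactly 7 combinations), otherwise all $k$ singletons plus
uniformly sampled distinct larger subsets up to the cap, with a fixed seed.
`extreme_components()` attributes every sampled combination and returns the
most positive and most negative records; ties break deterministically
(smaller atom set, then lexicographic name). Shapley values are out of
scope by design — the method trades fairness for a number of model calls
linear in the combination cap.

## Fragmentation schemes

* **BRICS** (`brics_fragments()`): bonds are cleaved where the 16
  retrosynthetic link environments L1–L16 of the BRICS scheme match on both
  sides (`brics_rules()` returns the table). L2 is the historical acyclic
  secondary-amine environment of the original scheme; its bonds are fully
  covered by the unified amine environment L5, which takes precedence in
  labelling, so both conventions coexist without changing the cleavage set.
  Fragments are reported as parent-molecule atom sets — a partition of the
  heavy atoms — with attachment points (atom + link label) kept for
  recombination. Dummy atoms never count as molecule atoms.
* **Murcko** (`murcko_fragments()`): iterative pruning of terminal atoms
  leaves the scaffold (rings plus linkers); atoms attached to the scaffold
  by double or triple bonds are retained (a benzophenone keeps its carbonyl
  oxygen). Side chains are the connected components of the remainder.
  Acyclic molecules have no scaffold and return an empty list with a
  warning rather than pretending the whole molecule is one.
* **Functional groups** (`functional_group_matches()`): a catalog of 33
  named SMARTS patterns (`load_fg_catalog()`), one substructure per match
  occurrence; overlapping matches from different entries are all kept, and
  a molecule with two nitro groups contributes two independent records.
  The shipped catalog is an explicit, versioned stand-in for the common
  functional-group collections distributed with cheminformatics toolkits;
  the exact membership of such collections is not standardized, so the
  catalog file format (name, SMARTS, optional graft SMILES) is documented
  and user-replaceable.

### The cheminformatics substrate

No R package available to this project exposes SMILES parsing with
atom-level access, SMARTS matching with match atom indices, or BRICS
fragmentation, so the package carries its own substrate: a SMILES
parser/writer and a SMARTS matcher covering the subset those rules need
(element, aromatic/aliphatic symbols, `#n`, `a`/`A`/`*`, `D`, `H`, `X`,
`R`/`!R`, charges, recursive `$(...)`, the `! & , ;` logic, and the bond
primitives `- = # : ~ @`). Canonicalization uses iterative neighbourhood
refinement with deterministic orbit tie-breaking; identical graphs yield
identical strings, which is what deduplication and identity checks need
(the strings are not required to match any other toolkit's canonical
order). Aromaticity of Kekulé-written rings is perceived conservatively
(5/6-membered C/N/O/S rings with a six-electron count and no exocyclic
double bonds); lower-case aromatic input is taken as declared. Explicit-H
atoms, multi-component SMILES and stereochemistry are out of scope —
stereo markers are accepted and ignored. During development the parser,
writer, and BRICS cleavage were validated against an independent reference
toolkit on reference sets; the test suite keeps the spirit of those checks
with frozen expectations and brute-force oracles.

## Dataset-level analyses

`fg_attribution_table()` attributes every functional-group occurrence in a
dataset and aggregates per group; groups seen fewer than `min_count = 10`
times are excluded (the threshold is inclusive: exactly ten occurrences are
reported). `cross_property_correlation()` takes two such tables and
computes Spearman's rank correlation over the shared groups (at least
three required), the route by which one property's chemistry is related to
another's. `substituent_scan()` excises a single-attachment terminal group
and grafts each graftable catalog entry in its place — the only edit
class the analysis needs — re-predicting each edited molecule so that the
attribution-vs-prediction trend can be examined. Grafts producing invalid
molecules are skipped with a warning. `optimization_suggestions()` turns a
group table into ranked edits: to lower a prediction, add groups with
negative mean attribution, remove present groups with positive mean
attribution, or replace a present group with an absent, strictly more
negative one; candidates are ranked by the absolute attribution difference,
and "increase" mirrors the signs.

## Attribution-guided generation

`build_pool()` attributes every BRICS fragment occurrence (single-fragment
masks) and aggregates by canonical fragment-with-attachment-labels SMILES.
`select_fragments()` keeps the strict-sign entries and then the
`ceiling(top_fraction * n)` most extreme (ties by fragment SMILES).
`recombine()` grows molecules by seeded random joins at complementary BRICS
link types — pick a start fragment, repeatedly join a random open
attachment to a random compatible partner, stop when closed or at the
heavy-atom cap (60), hydrogen-capping leftover links — and returns
canonical, deduplicated, guaranteed-parseable SMILES. A pool whose link
types admit no complementary pair is an error that names the available
types. `property_distribution()` summarizes two generated groups under one
or more models: group means plus an overlap measure — the average of the
fraction of negative-group molecules above the positive-group median and
the fraction of positive-group molecules below the negative-group median
(identical groups give 0.5; perfect separation gives 0).

## Synthetic data and what it can show

`generate_library()` assembles molecules by seeded random BRICS joins over
a built-in vocabulary of ~60 attachment-labelled fragments; label models
(`label_spec()`) provide ground truth with known structure:

* **Additive regression** — label = designed per-group weights times
  catalog match counts plus Gaussian noise (default sd 0.1). The designed
  weights mimic a solubility-like property (hydroxyl +1.0, carboxylic acid
  +1.0, amine +0.8, trifluoromethyl −1.2, halogens −0.4…−1.0, methyl −0.5,
  …).
* **Toxicophore binary** — positive iff a nitroaromatic or aromatic primary
  amine is present, with optional label flips. A quarter of the library is
  template-seeded with a bridged pair of the two toxicophores (held in
  *different* BRICS fragments), guaranteeing the double-toxicophore subset
  that the redundancy analysis needs; the vocabulary weights keep the
  classes near balance.
* **Descriptor** — molecular weight, H-bond donor count, and deliberately
  simplified local TPSA/logP contribution schemes, used only as label
  ground truth for descriptor models.

The vocabulary deliberately contains three tiers: strongly weighted group
carriers (including two-link "bridge" variants so that the extreme tails of
attribution-ranked pools always contain branching, link-compatible
fragments), neutral ring systems carrying no designed group (the
weakly-attributed bulk that dilutes full-sign pools, as plain scaffolds do
in real data), and bridges/hubs that make assembly spaces combinatorially
rich.

**Problem sizes.** The study-scale checks train a reduced consensus (3
sub-models, hidden 64, 2 conv layers, at most 60 epochs with early
stopping, minibatches of 256) on a 2000-molecule additive library and a
1200-molecule binary library; group attributions are aggregated over the
held-out validation+test splits (400 molecules), where all fourteen
designed groups clear the ten-occurrence filter. These sizes are the
package's chosen study conditions; results reported by
`scripts/acceptance.R` use a 1200/800-molecule variant of the same design.

**What passing shows — and does not.** On the additive fixture the trained
consensus reaches validation $R^2 \approx 0.99$ and the per-group mean
attributions recover the designed weights (sign agreement 1.0, Spearman
$\approx 0.98$). This demonstrates that the masking attribution faithfully
reads out what the model learned *when the ground truth really is
additive over substructures*. Real properties are not additive; the
synthetic result bounds implementation correctness, not chemical validity.
On the binary fixture the saturation pathology reproduces exactly as
described above: per-toxicophore attributions concentrate at zero while
the combination masking both approaches $Y$, and the extreme-component
search recovers both toxicophores.

**A known degeneracy.** One documented generation analysis compares the
class overlap of molecules recombined from full-sign pools versus top-20%
pools, expecting the restriction to *strictly* shrink the overlap. On the
additive fixture this comparison degenerates: the consensus recovers
fragment contributions so faithfully that positive- and negative-pool
predictions separate completely and both overlaps are exactly zero — there
is nothing left to shrink. The mechanism that creates overlap on real data
is context dependence of fragment attributions, which an additive
generative model excludes by construction; the binary fixture exhibits the
mechanism but has too few strongly-toxic fragment types to assemble
hundreds of distinct extreme-pool molecules. The corresponding test states
the strict expectation and is expected to fail on this fixture; the
group-mean ordering (negative pools predicted below positive pools) holds
throughout.

## Numerical choices and degenerate inputs

* Attribution equality `attribution = Y - Y_sub` is exact by construction;
  the masked-readout path is tested against an independently coded
  per-node summation at `1e-6` relative tolerance.
* Normalization of an all-zero record set returns zeros (no 0/0).
* `enumerate_combinations()` errors when the cap cannot hold the singletons
  (`max_n < k`); subset sampling draws inclusion masks uniformly and
  rejects duplicates, so sampled subsets are distinct and reproducible
  under the seed.
* Tie-breaks everywhere are deterministic (atom count, then name), so
  explain runs are byte-reproducible given model, data and seed.
* Unparsable SMILES name the offending record; datasets read from CSV drop
  unparsable rows with a warning and a count.
* Training reproducibility: identical seeds, configuration and BLAS give
  identical sub-models; cross-platform bit-equality is not promised.

## Limitations

* The SMILES/SMARTS dialect is the documented subset; no stereochemistry,
  no explicit hydrogens, no multi-component inputs.
* Morgan-style refinement with orbit tie-breaking can in principle assign
  equal strings to distinct highly regular graphs; drug-like molecules are
  unaffected in practice.
* The functional-group catalog is a stand-in, not a normative list; analyses
  depending on exact group identity should ship their own catalog file.
* Fragment attributions transfer imperfectly to newly assembled molecules —
  the very observation the generation analysis studies; generated molecules
  are property candidates, not guarantees.
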