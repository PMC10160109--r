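# Locally computed physicochemical descriptors for synthetic labels:
# molecular weight, hydrogen-bond donor count, a reduced topological polar
# surface area (N/O contributions) and a simplified atom-contribution logP.
# TPSA and logP are deliberately lightweight schemes of this package, not
# reimplementations of any published parameterization; they only serve as
# ground-truth labels for synthetic descriptor models.

tpsa_atom <- function(mol, v) {
  sym <- mol$symbol[v]
  if (!(sym %in% c("N", "O"))) return(0)
  b <- mol$bonds
  sel <- b$a1 == v | b$a2 == v
  ndb <- sum(b$order[sel] == 2L & !b$aromatic[sel])
  ntp <- sum(b$order[sel] == 3L)
  arom <- mol$aromatic[v]
  nh <- mol$nH[v]
  chg <- mol$charge[v]
  if (sym == "N") {
    if (arom) return(if (nh >= 1L) 15.79 else 12.89)
    if (chg == 1L) return(if (ndb >= 1L) 11.68 else 4.44)
    if (ntp >= 1L) return(23.79)
    if (ndb >= 1L) return(if (nh >= 1L) 23.85 else 12.36)
    if (nh >= 2L) return(26.02)
    if (nh == 1L) return(12.03)
    return(3.24)
  }
  # oxygen
  if (arom) return(13.14)
  if (chg == -1L) return(23.06)
  if (ndb >= 1L) return(17.07)
  if (nh >= 1L) return(20.23)
  9.23
}

logp_atom <- function(mol, v) {
  sym <- mol$symbol[v]
  nh <- mol$nH[v]
  base <- switch(sym,
    C = if (mol$aromatic[v]) 0.29 else 0.14,
    N = -0.60, O = -0.45, S = 0.25, P = -0.20,
    F = 0.22, Cl = 0.65, Br = 0.86, I = 1.10,
    B = 0.10, Si = 0.20, 0)
  hterm <- if (sym == "C") 0.12 * nh else if (sym %in% c("N", "O")) -0.25 * nh else 0
  base + hterm - 0.3 * abs(mol$charge[v])
}

#' Compute a molecular descriptor
#'
#' Supported descriptors: `"MW"` (molecular weight including implicit
#' hydrogens), `"HBD"` (number of N/O atoms bearing at least one hydrogen),
#' `"TPSA"` (reduced N/O polar-surface-area contribution scheme) and
#' `"LogP"` (simplified atom-contribution lipophilicity score).
#'
#' @param mol molecule record, `sme_mol` or SMILES string.
#' @param name descriptor name.
#' @return numeric scalar.
#' @export
mol_descriptor <- function(mol, name = c("MW", "TPSA", "LogP", "HBD")) {
  name <- match.arg(name)
  m <- as_sme_mol(if (inherits(mol, "sme_molecule")) mol$mol else mol)
  switch(name,
    MW = mol_formula_mass(m),
    HBD = sum(m$symbol %in% c("N", "O") & m$nH >= 1L),
    TPSA = sum(vapply(seq_len(m$n), function(v) tpsa_atom(m, v), 1)),
    LogP = sum(vapply(seq_len(m$n), function(v) logp_atom(m, v), 1))
  )
}
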