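# The ten-descriptor panel plus auxiliary complexity descriptors, computed
# under the physiological charge-state counting conventions: HBD counts
# every hydrogen on non-anionic N/O (so a protonated amine donates all of
# its N-H hydrogens), and HBA counts N/O/F minus cationic N, N in higher
# oxidation states (nitro/N-oxide) and pyrrole-type aromatic N.

#' Count hydrogen-bond donors
#'
#' Sums the hydrogen atoms (explicit and implicit) bonded to any nitrogen or
#' oxygen that does not carry a negative formal charge. Computed on the
#' requested charge state, so a secondary aliphatic amine contributes one
#' donor in the neutral form but two when protonated at pH 7.0.
#'
#' @param record A `MoleculeRecord`.
#' @param charge_state `"ph7"` (default) or `"neutral"`.
#' @return Integer donor count.
#' @examples
#' count_hbd(parse_structure("CCO", "ethanol"), "neutral")
#' @export
count_hbd <- function(record, charge_state = c("ph7", "neutral")) {
  mol <- .resolve_mol(record, charge_state)
  .count_hbd_mol(mol)
}

.count_hbd_mol <- function(mol) {
  sel <- mol$elements %in% c("N", "O") & mol$charge >= 0
  as.integer(sum(mol$nH[sel]))
}

#' Count hydrogen-bond acceptors
#'
#' Counts all nitrogen, oxygen and fluorine atoms, excluding nitrogens with
#' a positive formal charge, nitrogens in higher oxidation states (bonded to
#' two or more oxygens, covering nitro and N-oxide groups) and pyrrole-type
#' aromatic nitrogens (those donating their lone pair into the aromatic
#' system). This deviates deliberately from the plain N+O count of the
#' Rule of 5.
#'
#' @inheritParams count_hbd
#' @return Integer acceptor count.
#' @examples
#' count_hba(parse_structure("c1cc[nH]c1", "pyrrole"))  # 0
#' count_hba(parse_structure("c1ccncc1", "pyridine"))   # 1
#' @export
count_hba <- function(record, charge_state = c("ph7", "neutral")) {
  mol <- .resolve_mol(record, charge_state)
  .count_hba_mol(mol)
}

.count_hba_mol <- function(mol) {
  n <- length(mol$elements)
  acc <- logical(n)
  for (i in seq_len(n)) {
    el <- mol$elements[i]
    if (!el %in% c("N", "O", "F")) next
    if (el == "N") {
      if (mol$charge[i] > 0) next
      if (mol$pyrrole_n[i]) next
      nb <- .heavy_neighbors(mol, i)
      n_ox <- sum(mol$elements[nb] == "O")
      has_no_double <- any(vapply(nb, function(j) {
        mol$elements[j] == "O" && .bond_order(mol, i, j) == 2
      }, logical(1)))
      if (n_ox >= 2 || has_no_double) next
    }
    acc[i] <- TRUE
  }
  as.integer(sum(acc))
}

# --- Kier flexibility -------------------------------------------------------

# Covalent radii (Angstrom) by element and hybridisation for the Kier alpha
# correction; alpha_i = r_i / r(Csp3) - 1.
.KIER_RADII <- list(
  C = c(sp3 = 0.77, sp2 = 0.67, sp = 0.60),
  N = c(sp3 = 0.74, sp2 = 0.62, sp = 0.55),
  O = c(sp3 = 0.74, sp2 = 0.62, sp = 0.62),
  F = c(sp3 = 0.72, sp2 = 0.72, sp = 0.72),
  Cl = c(sp3 = 0.99, sp2 = 0.99, sp = 0.99),
  Br = c(sp3 = 1.14, sp2 = 1.14, sp = 1.14),
  I = c(sp3 = 1.33, sp2 = 1.33, sp = 1.33),
  S = c(sp3 = 1.04, sp2 = 0.94, sp = 0.94),
  P = c(sp3 = 1.10, sp2 = 1.10, sp = 1.10),
  Si = c(sp3 = 1.17, sp2 = 1.17, sp = 1.17),
  B = c(sp3 = 0.88, sp2 = 0.88, sp = 0.88)
)

.kier_alpha <- function(mol) {
  r_ref <- 0.77
  idx <- which(mol$heavy)
  sum(vapply(idx, function(i) {
    tab <- .KIER_RADII[[mol$elements[i]]]
    r <- if (is.null(tab)) r_ref else {
      h <- mol$hyb[i]
      if (h %in% names(tab)) tab[[h]] else tab[["sp3"]]
    }
    r / r_ref - 1
  }, numeric(1)))
}

#' Kier flexibility index
#'
#' Computes the Kier flexibility index Phi = (1-kappa-alpha * 2-kappa-alpha)
#' / A, where the kappa-alpha shape indices are evaluated on the heavy-atom
#' graph with the covalent-radius alpha correction and A is the number of
#' heavy atoms. Larger values indicate more flexible molecules; a linear
#' alkane scores higher than its cycloalkane isomer.
#'
#' @inheritParams count_hbd
#' @return Numeric flexibility index (`NA` for molecules with fewer than
#'   three heavy atoms, where the second-order index is undefined).
#' @export
kier_phi <- function(record, charge_state = c("ph7", "neutral")) {
  mol <- .resolve_mol(record, charge_state)
  .kier_phi_mol(mol)
}

.kier_phi_mol <- function(mol) {
  A <- mol$n_heavy
  if (A < 3) return(NA_real_)
  alpha <- .kier_alpha(mol)
  hb <- mol$bonds[mol$heavy[mol$bonds$a1] & mol$heavy[mol$bonds$a2], , drop = FALSE]
  P1 <- nrow(hb)
  P2 <- sum(choose(mol$deg_heavy[mol$heavy], 2))
  if (P1 == 0 || P2 == 0) return(NA_real_)
  k1 <- (A + alpha) * (A + alpha - 1)^2 / (P1 + alpha)^2
  k2 <- (A + alpha - 1) * (A + alpha - 2)^2 / (P2 + alpha)^2
  k1 * k2 / A
}

# --- Rotatable bonds and aromatic rings ------------------------------------

.nrotb_mol <- function(mol, exclude_amide = TRUE) {
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  carbonyls <- if (exclude_amide) .carbonyl_c(mol) else integer(0)
  n <- 0L
  for (e in seq_len(nrow(b))) {
    if (b$order[e] != 1 || b$ring[e]) next
    a1 <- b$a1[e]; a2 <- b$a2[e]
    if (!mol$heavy[a1] || !mol$heavy[a2]) next
    if (mol$deg_heavy[a1] < 2 || mol$deg_heavy[a2] < 2) next
    if (exclude_amide) {
      amide <- (mol$elements[a1] == "N" && a2 %in% carbonyls) ||
               (mol$elements[a2] == "N" && a1 %in% carbonyls)
      if (amide) next
    }
    n <- n + 1L
  }
  n
}

.nar_mol <- function(mol) as.integer(sum(mol$arom_ring))

# --- Stereocentres ---------------------------------------------------------

# Tetrahedral stereocentre candidates (defined + undefined): sp3 carbons
# with four substituents falling into distinct Morgan equivalence classes.
.n_stereocenters_mol <- function(mol) {
  cls <- .morgan_classes(mol)
  n <- 0L
  for (i in which(mol$heavy)) {
    if (mol$elements[i] != "C" || mol$hyb[i] != "sp3") next
    if (mol$nH[i] > 1) next
    nb <- .heavy_neighbors(mol, i)
    if (length(nb) + mol$nH[i] != 4) next
    need <- if (mol$nH[i] == 1) 3L else 4L
    if (length(unique(cls[nb])) == need) n <- n + 1L
  }
  n
}

# --- OpenBabel-backed contributions ----------------------------------------

# Ertl TPSA (charged fragments included) and atom-contribution logP from
# OpenBabel for a single SDF.
.propob_one <- function(sdf, id) {
  ss <- methods::new("SDFset", SDF = list(sdf), ID = id)
  p <- ChemmineR::propOB(ss)
  list(TPSA = as.numeric(p$TPSA), logP = as.numeric(p$logP))
}

# ESOL-style solubility estimate (log mol/L) from cLogP, MW, rotatable
# bonds and aromatic proportion.
.clogs_esol <- function(clogp, mw, nrotb, arom_prop) {
  0.16 - 0.63 * clogp - 0.0062 * mw + 0.066 * nrotb - 0.74 * arom_prop
}

#' Compute the descriptor panel for one molecule
#'
#' Fills the full descriptor vector used throughout the chemical-space
#' analysis: molecular weight (MW, Da), carbon count (nC), calculated
#' lipophilicity (cLogP, neutral species, atom-contribution scheme),
#' solubility estimate (cLogS, log mol/L), distribution coefficient
#' approximation (cLogD, used only for the AB-MPS score), Ertl topological
#' polar surface area (TPSA, A^2, charge-state aware), hydrogen-bond donors
#' and acceptors under the physiological counting conventions, rotatable
#' bonds (NRotB, amide C-N excluded by default), aromatic ring count (NAR),
#' Kier flexibility (phi), largest ring size and tetrahedral stereocentre
#' count.
#'
#' @inheritParams count_hbd
#' @param exclude_amide Exclude amide C-N bonds from the rotatable-bond
#'   count (the strict dialect); default `TRUE`.
#' @return A one-row `data.frame`.
#' @examples
#' \donttest{
#' compute_panel(parse_structure("c1ccccc1", "benzene"), "neutral")
#' }
#' @export
compute_panel <- function(record, charge_state = c("ph7", "neutral"),
                          exclude_amide = TRUE) {
  charge_state <- match.arg(charge_state)
  stopifnot(inherits(record, "MoleculeRecord"))
  if (record$contains_metal) {
    stop("descriptor failure: metal-containing structure '", record$id,
         "' cannot be profiled", call. = FALSE)
  }
  if (charge_state == "ph7" && is.null(record$mol_ph7)) {
    record <- protonate_ph7(record)
  }
  mol <- .resolve_mol(record, charge_state)
  prop_neutral <- .propob_one(record$sdf_neutral, record$id)
  prop <- if (charge_state == "neutral") prop_neutral else {
    .propob_one(record$sdf_ph7, record$id)
  }
  mw <- .mol_weight(mol)
  nrotb <- .nrotb_mol(mol, exclude_amide)
  nar <- .nar_mol(mol)
  arom_prop <- sum(mol$arom_atom) / mol$n_heavy
  clogp <- prop_neutral$logP
  # cLogD: neutral-species cLogP with a fixed -3 log-unit correction per
  # ionised centre of the rule-protonated species (approximation; AB-MPS only)
  ph7_mol <- .resolve_mol(record, "ph7")
  n_charged <- sum(abs(ph7_mol$charge))
  clogd <- clogp - 3 * n_charged
  data.frame(
    id = record$id,
    MW = mw,
    nC = as.integer(sum(mol$elements == "C")),
    cLogP = clogp,
    cLogS = .clogs_esol(clogp, mw, nrotb, arom_prop),
    cLogD = clogd,
    TPSA = prop$TPSA,
    HBD = .count_hbd_mol(mol),
    HBA = .count_hba_mol(mol),
    NRotB = nrotb,
    NAR = nar,
    phi = .kier_phi_mol(mol),
    ring_size = record$largest_ring_size,
    n_stereocenters = .n_stereocenters_mol(mol),
    charge_state = charge_state,
    stringsAsFactors = FALSE
  )
}

#' Compute the descriptor table for a set of molecules
#'
#' Applies [compute_panel()] to a list of records, carrying the `route` and
#' `origin` labels along. Metal-containing records are skipped with a
#' warning (their descriptors cannot be computed reliably), never silently
#' zeroed.
#'
#' @param records A list of `MoleculeRecord`s.
#' @inheritParams compute_panel
#' @return A `data.frame` with one row per profiled molecule.
#' @export
descriptor_table <- function(records, charge_state = c("ph7", "neutral"),
                             exclude_amide = TRUE) {
  charge_state <- match.arg(charge_state)
  rows <- list()
  skipped <- character(0)
  for (rec in records) {
    if (rec$contains_metal) {
      skipped <- c(skipped, rec$id)
      next
    }
    row <- compute_panel(rec, charge_state, exclude_amide)
    row$route <- rec$route
    row$origin <- rec$origin
    rows[[length(rows) + 1L]] <- row
  }
  if (length(skipped)) {
    warning("descriptor failure: metal. Skipped record(s): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  do.call(rbind, rows)
}

#' AB-MPS multiparameter score
#'
#' AB-MPS = |cLogD - 3| + NAR + NRotB. Lower is better; scores of 14-15 or
#' below suggest acceptable oral bioavailability for compounds beyond the
#' Rule of 5. The score is minimised, for fixed NAR and NRotB, exactly at
#' cLogD = 3.
#'
#' @param vec A one-row `data.frame` or named list/vector with `cLogD`,
#'   `NAR` and `NRotB` entries, as produced by [compute_panel()].
#' @return Numeric score.
#' @examples
#' ab_mps(list(cLogD = 5, NAR = 3, NRotB = 10))  # 15
#' @export
ab_mps <- function(vec) {
  need <- c("cLogD", "NAR", "NRotB")
  miss <- need[!need %in% names(vec)]
  if (length(miss)) {
    stop("AB-MPS needs ", paste(miss, collapse = ", "),
         "; enable cLogD estimation via compute_panel()", call. = FALSE)
  }
  v <- lapply(need, function(k) as.numeric(vec[[k]]))
  if (anyNA(v[[1]])) {
    stop("AB-MPS needs a cLogD value; enable cLogD estimation via ",
         "compute_panel()", call. = FALSE)
  }
  abs(v[[1]] - 3) + v[[2]] + v[[3]]
}

#' Classify a score against the AB-MPS oral-bioavailability cutoff
#'
#' @param score Numeric AB-MPS score(s).
#' @param cutoff Cutoff value, 15 (differentiates oral from parenteral
#'   drugs) or 14 (acceptable vs low-moderate bioavailability).
#' @return Character vector: `"oral"` where `score <= cutoff`, else
#'   `"parenteral"`.
#' @export
ab_mps_class <- function(score, cutoff = 15) {
  stopifnot(cutoff %in% c(14, 15))
  ifelse(score <= cutoff, "oral", "parenteral")
}
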