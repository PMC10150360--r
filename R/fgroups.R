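# Functional-group detectors on the internal molecular graph. These back the
# rule-based pH-7 protonation model and the HBD chemotype profiler. All
# detectors are neighbourhood queries on the Kekule graph and only ever fire
# on formally neutral centres, which makes the protonation rules idempotent.

.carbonyl_c <- function(mol) {
  which(vapply(seq_along(mol$elements), function(i) {
    mol$elements[i] == "C" &&
      any(vapply(.heavy_neighbors(mol, i), function(j) {
        mol$elements[j] == "O" && .bond_order(mol, i, j) == 2
      }, logical(1)))
  }, logical(1)))
}

.sulfonyl_s <- function(mol) {
  which(vapply(seq_along(mol$elements), function(i) {
    if (mol$elements[i] != "S") return(FALSE)
    nb <- .heavy_neighbors(mol, i)
    sum(vapply(nb, function(j) {
      mol$elements[j] == "O" && .bond_order(mol, i, j) == 2
    }, logical(1))) >= 2
  }, logical(1)))
}

.is_amide_n <- function(mol, i, carbonyls = .carbonyl_c(mol)) {
  mol$elements[i] == "N" &&
    any(vapply(.heavy_neighbors(mol, i), function(j) {
      j %in% carbonyls && .bond_order(mol, i, j) == 1
    }, logical(1)))
}

.is_sulfonamide_n <- function(mol, i, sulfonyls = .sulfonyl_s(mol)) {
  mol$elements[i] == "N" &&
    any(vapply(.heavy_neighbors(mol, i), function(j) {
      j %in% sulfonyls && .bond_order(mol, i, j) == 1
    }, logical(1)))
}

# Aliphatic amines: sp3 neutral N bonded only to carbon, with no aromatic,
# carbonyl, sulfonyl or imine carbon neighbour. These are treated as
# protonated at pH 7 (pKa ~ 10).
.basic_amine_atoms <- function(mol) {
  carbonyls <- .carbonyl_c(mol)
  sulfonyls <- .sulfonyl_s(mol)
  which(vapply(seq_along(mol$elements), function(i) {
    if (mol$elements[i] != "N" || mol$charge[i] != 0) return(FALSE)
    if (mol$arom_atom[i] || mol$hyb[i] != "sp3") return(FALSE)
    nb <- .heavy_neighbors(mol, i)
    if (!length(nb) || !all(mol$elements[nb] == "C")) return(FALSE)
    if (any(mol$arom_atom[nb])) return(FALSE)           # aniline-type
    if (any(nb %in% carbonyls)) return(FALSE)           # amide
    if (any(nb %in% sulfonyls)) return(FALSE)           # sulfonamide
    # exclude N of amidine/guanidine (the group is protonated at its imine N)
    imine_c <- any(vapply(nb, function(j) {
      any(vapply(.heavy_neighbors(mol, j), function(k) {
        mol$elements[k] == "N" && .bond_order(mol, j, k) == 2
      }, logical(1)))
    }, logical(1)))
    !imine_c
  }, logical(1)))
}

# Amidine/guanidine imine nitrogens: C=N where the carbon carries at least
# one further single-bonded nitrogen and no chalcogen double bond.
# Protonated (+1 on the imine N) at pH 7 (pKa ~ 12).
.amidinium_sites <- function(mol) {
  sites <- integer(0)
  for (i in seq_along(mol$elements)) {
    if (mol$elements[i] != "C") next
    nb <- .heavy_neighbors(mol, i)
    imine_n <- nb[vapply(nb, function(j) {
      mol$elements[j] == "N" && .bond_order(mol, i, j) == 2 &&
        mol$charge[j] == 0 && !mol$arom_atom[j]
    }, logical(1))]
    if (!length(imine_n)) next
    chalc_double <- any(vapply(nb, function(j) {
      mol$elements[j] %in% c("O", "S") && .bond_order(mol, i, j) == 2
    }, logical(1)))
    if (chalc_double) next
    other_n <- any(vapply(nb, function(j) {
      mol$elements[j] == "N" && .bond_order(mol, i, j) == 1
    }, logical(1)))
    if (other_n) sites <- c(sites, imine_n[1])
  }
  unique(sites)
}

# Acidic O-H groups deprotonated at pH 7: carboxylic (pKa ~ 4), sulfonic
# (pKa < 0) and one O-H per phosphonic/phosphoric group (pKa1 ~ 2).
.acidic_oh_atoms <- function(mol) {
  carbonyls <- .carbonyl_c(mol)
  sulfonyls_1 <- which(vapply(seq_along(mol$elements), function(i) {
    if (mol$elements[i] != "S") return(FALSE)
    nb <- .heavy_neighbors(mol, i)
    sum(vapply(nb, function(j) {
      mol$elements[j] == "O" && .bond_order(mol, i, j) == 2
    }, logical(1))) >= 1 && sum(mol$elements[nb] == "O") >= 2
  }, logical(1)))
  oh <- which(vapply(seq_along(mol$elements), function(i) {
    mol$elements[i] == "O" && mol$charge[i] == 0 && mol$nH[i] >= 1
  }, logical(1)))
  acid <- integer(0)
  p_done <- integer(0)
  for (o in oh) {
    nb <- .heavy_neighbors(mol, o)
    if (!length(nb)) next
    j <- nb[1]
    if (j %in% carbonyls) {
      acid <- c(acid, o)
    } else if (j %in% sulfonyls_1) {
      acid <- c(acid, o)
    } else if (mol$elements[j] == "P") {
      p_double_o <- any(vapply(.heavy_neighbors(mol, j), function(k) {
        mol$elements[k] == "O" && .bond_order(mol, j, k) == 2
      }, logical(1)))
      if (p_double_o && !(j %in% p_done)) {
        acid <- c(acid, o)
        p_done <- c(p_done, j)
      }
    }
  }
  acid
}

# Tetrazole N-H (pKa ~ 5): protic N in an aromatic 5-ring with four N.
.tetrazole_nh_atoms <- function(mol) {
  out <- integer(0)
  for (r in seq_along(mol$rings)) {
    ring <- mol$rings[[r]]
    if (length(ring) != 5 || !mol$arom_ring[r]) next
    if (sum(mol$elements[ring] == "N") != 4) next
    nh <- ring[mol$elements[ring] == "N" & mol$nH[ring] >= 1 &
                 mol$charge[ring] == 0]
    out <- c(out, nh)
  }
  unique(out)
}

# Acylsulfonamide N-H (pKa ~ 5): N flanked by both a carbonyl C and a
# sulfonyl S; deprotonated at pH 7.
.acylsulfonamide_nh_atoms <- function(mol) {
  carbonyls <- .carbonyl_c(mol)
  sulfonyls <- .sulfonyl_s(mol)
  which(vapply(seq_along(mol$elements), function(i) {
    mol$elements[i] == "N" && mol$charge[i] == 0 && mol$nH[i] >= 1 &&
      .is_amide_n(mol, i, carbonyls) && .is_sulfonamide_n(mol, i, sulfonyls)
  }, logical(1)))
}

.phenol_o_atoms <- function(mol) {
  which(vapply(seq_along(mol$elements), function(i) {
    mol$elements[i] == "O" && mol$charge[i] == 0 && mol$nH[i] >= 1 &&
      any(mol$arom_atom[.heavy_neighbors(mol, i)])
  }, logical(1)))
}
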