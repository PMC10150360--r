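# Internal molecular graph model built on ChemmineR SDF objects.
#
# OpenBabel (via ChemmineR/ChemmineOB) supplies parsing, canonical SMILES,
# Kekule bond orders and formal charges; everything graph-theoretic on top
# (implicit hydrogens, SSSR, aromaticity, hybridisation) is computed here so
# that the counting conventions used by the descriptor panel are explicit
# and reproducible.

.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Se", "Br", "I")

.ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Mn = 54.938, Fe = 55.845,
  Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38, Se = 78.971,
  Br = 79.904, Mo = 95.95, Ru = 101.07, Ag = 107.868, I = 126.904,
  Pt = 195.084, Au = 196.967, Hg = 200.592, Lu = 174.967, Gd = 157.25
)

# molfile charge codes: 0 none, 1 +3, 2 +2, 3 +1, 4 radical, 5 -1, 6 -2, 7 -3
.charge_from_code <- function(code) {
  ifelse(code %in% c(1, 2, 3, 5, 6, 7), 4 - code, 0L)
}

.code_from_charge <- function(charge) {
  ifelse(charge == 0, 0L, 4L - as.integer(charge))
}

.atom_elements <- function(sdf) {
  sub("_\\d+$", "", rownames(ChemmineR::atomblock(sdf)))
}

.bond_table <- function(sdf) {
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || length(bb) == 0) {
    return(data.frame(a1 = integer(0), a2 = integer(0), order = integer(0)))
  }
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1, dimnames = list(NULL, names(bb)))
  data.frame(a1 = as.integer(bb[, "C1"]), a2 = as.integer(bb[, "C2"]),
             order = as.integer(bb[, "C3"]))
}

# Target valence for the implicit-hydrogen model. Hypervalent S/P/I pick the
# smallest allowed valence not below the explicit bond-order sum.
.target_valence <- function(element, charge, bosum) {
  base <- switch(element,
    C = 4 - abs(charge),
    N = 3 + charge,
    P = {
      allowed <- c(3, 5) + charge
      ok <- allowed[allowed >= bosum]
      if (length(ok)) min(ok) else bosum
    },
    O = 2 + charge,
    S = ,
    Se = {
      allowed <- c(2, 4, 6) + charge
      ok <- allowed[allowed >= bosum]
      if (length(ok)) min(ok) else bosum
    },
    F = ,
    Cl = ,
    Br = if (charge == 0) 1 else 0,
    I = {
      allowed <- if (charge == 0) c(1, 3, 5, 7) else 0
      ok <- allowed[allowed >= bosum]
      if (length(ok)) min(ok) else bosum
    },
    B = 3 - charge,
    Si = 4,
    0)
  max(base, 0)
}

# Smallest set of smallest rings by shortest-cycle-per-edge candidates with
# GF(2) independence selection. Returns ring atom cycles (ordered), a
# per-bond ring flag, and bridge information.
.find_sssr <- function(n_atoms, bonds) {
  E <- nrow(bonds)
  ring_bond <- rep(FALSE, E)
  if (E == 0 || n_atoms == 0) {
    return(list(rings = list(), ring_bond = ring_bond))
  }
  adj <- vector("list", n_atoms)
  for (e in seq_len(E)) {
    a <- bonds$a1[e]; b <- bonds$a2[e]
    adj[[a]] <- rbind(adj[[a]], c(b, e))
    adj[[b]] <- rbind(adj[[b]], c(a, e))
  }
  # connected components (over all n_atoms vertices)
  comp <- integer(n_atoms)
  ncomp <- 0L
  for (s in seq_len(n_atoms)) {
    if (comp[s] > 0) next
    ncomp <- ncomp + 1L
    queue <- s; comp[s] <- ncomp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (k in seq_len(nrow(nb))) {
        w <- nb[k, 1]
        if (comp[w] == 0) { comp[w] <- ncomp; queue <- c(queue, w) }
      }
    }
  }
  n_rings <- E - n_atoms + ncomp
  if (n_rings <= 0) return(list(rings = list(), ring_bond = ring_bond))

  # shortest path a -> b avoiding edge `skip`; returns atom sequence or NULL
  bfs_path <- function(a, b, skip) {
    parent <- integer(n_atoms); parent[a] <- -1L
    queue <- a
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (k in seq_len(nrow(nb))) {
        if (nb[k, 2] == skip) next
        w <- nb[k, 1]
        if (parent[w] != 0L) next
        parent[w] <- v
        if (w == b) {
          path <- w
          while (path[1] != a) path <- c(parent[path[1]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
    NULL
  }

  edge_id <- function(a, b) {
    which((bonds$a1 == a & bonds$a2 == b) | (bonds$a1 == b & bonds$a2 == a))[1]
  }
  cycle_edges <- function(atoms) {
    m <- length(atoms)
    ids <- vapply(seq_len(m), function(i) {
      edge_id(atoms[i], atoms[if (i == m) 1 else i + 1])
    }, integer(1))
    v <- rep(FALSE, E); v[ids] <- TRUE
    v
  }

  candidates <- list()
  for (e in seq_len(E)) {
    path <- bfs_path(bonds$a1[e], bonds$a2[e], e)
    if (!is.null(path)) {
      ring_bond[e] <- TRUE
      candidates[[length(candidates) + 1L]] <- path
    }
  }
  if (!length(candidates)) return(list(rings = list(), ring_bond = ring_bond))
  ord <- order(lengths(candidates))
  candidates <- candidates[ord]

  rings <- list()
  basis <- list()   # reduced GF(2) vectors over edges
  pivots <- integer(0)
  for (cand in candidates) {
    vec <- cycle_edges(cand)
    red <- vec
    if (length(basis)) {
      for (j in seq_along(basis)) {
        if (red[pivots[j]]) red <- xor(red, basis[[j]])
      }
    }
    if (any(red)) {
      basis[[length(basis) + 1L]] <- red
      pivots <- c(pivots, which(red)[1])
      rings[[length(rings) + 1L]] <- cand
      if (length(rings) == n_rings) break
    }
  }
  # flag ring bonds from the selected rings too (covers chords already TRUE)
  list(rings = rings, ring_bond = ring_bond)
}

# Hueckel-style aromaticity on Kekule structures: within each 5/6-membered
# SSSR ring a ring double bond contributes one pi electron per atom, a
# saturated N/O/S lone pair two, an exocyclic double bond zero; the ring is
# aromatic when every member is sp2-compatible and the sum is six.
.perceive_aromatic <- function(elements, charge, bonds, rings, deg_total) {
  n <- length(elements)
  arom_atom <- rep(FALSE, n)
  pyrrole_n <- rep(FALSE, n)
  arom_ring <- rep(FALSE, length(rings))
  if (!length(rings)) {
    return(list(atom = arom_atom, ring = arom_ring, pyrrole_n = pyrrole_n))
  }
  bond_order_between <- function(a, b) {
    hit <- (bonds$a1 == a & bonds$a2 == b) | (bonds$a1 == b & bonds$a2 == a)
    if (any(hit)) bonds$order[hit][1] else 0L
  }
  max_order <- function(a) {
    hit <- bonds$a1 == a | bonds$a2 == a
    if (any(hit)) max(bonds$order[hit]) else 0L
  }
  for (r in seq_along(rings)) {
    ring <- rings[[r]]
    m <- length(ring)
    if (m < 5 || m > 6) next
    if (!all(elements[ring] %in% c("C", "N", "O", "S"))) next
    if (any(deg_total[ring] > 3)) next
    pi <- numeric(m)
    ok <- TRUE
    for (i in seq_len(m)) {
      a <- ring[i]
      nxt <- ring[if (i == m) 1 else i + 1]
      prv <- ring[if (i == 1) m else i - 1]
      if (max_order(a) >= 3) { ok <- FALSE; break }
      in_ring_double <- bond_order_between(a, nxt) == 2 ||
        bond_order_between(a, prv) == 2
      if (in_ring_double) {
        pi[i] <- 1
      } else if (max_order(a) == 2) {
        pi[i] <- 0  # exocyclic double bond (e.g. ring C=O)
      } else if (elements[a] %in% c("N", "O", "S")) {
        pi[i] <- 2
      } else if (elements[a] == "C" && charge[a] == -1) {
        pi[i] <- 2
      } else if (elements[a] == "C" && charge[a] == 1) {
        pi[i] <- 0
      } else {
        ok <- FALSE; break
      }
    }
    if (ok && sum(pi) == 6) {
      arom_ring[r] <- TRUE
      arom_atom[ring] <- TRUE
      lp <- ring[pi == 2 & elements[ring] == "N"]
      pyrrole_n[lp] <- TRUE
    }
  }
  list(atom = arom_atom, ring = arom_ring, pyrrole_n = pyrrole_n)
}

# Assemble the full molecular graph from a ChemmineR SDF object.
.build_mol <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  elements <- .atom_elements(sdf)
  n <- length(elements)
  if (n == 0) stop("empty molecule", call. = FALSE)
  charge <- if ("C6" %in% colnames(ab)) {
    .charge_from_code(ab[, "C6"])
  } else rep(0L, n)
  coords <- cbind(x = ab[, "C1"], y = ab[, "C2"],
                  z = if ("C3" %in% colnames(ab)) ab[, "C3"] else rep(0, n))
  bonds <- .bond_table(sdf)

  heavy <- elements != "H"
  bosum <- rep(0, n)
  expl_h <- rep(0L, n)
  deg_heavy <- rep(0L, n)
  if (nrow(bonds)) {
    for (e in seq_len(nrow(bonds))) {
      a <- bonds$a1[e]; b <- bonds$a2[e]; o <- bonds$order[e]
      bosum[a] <- bosum[a] + o
      bosum[b] <- bosum[b] + o
      if (elements[b] == "H") expl_h[a] <- expl_h[a] + 1L
      if (elements[a] == "H") expl_h[b] <- expl_h[b] + 1L
      if (heavy[a] && heavy[b]) {
        deg_heavy[a] <- deg_heavy[a] + 1L
        deg_heavy[b] <- deg_heavy[b] + 1L
      }
    }
  }
  impl_h <- vapply(seq_len(n), function(i) {
    if (!heavy[i]) return(0)
    max(0, .target_valence(elements[i], charge[i], bosum[i]) - bosum[i])
  }, numeric(1))
  nH <- as.integer(round(impl_h)) + expl_h

  # ring perception on the heavy-atom graph (H atoms are never in rings)
  sssr <- .find_sssr(n, bonds[heavy[bonds$a1] & heavy[bonds$a2], , drop = FALSE])
  bonds$ring <- FALSE
  hb <- which(heavy[bonds$a1] & heavy[bonds$a2])
  if (length(hb)) bonds$ring[hb] <- sssr$ring_bond
  in_ring <- rep(FALSE, n)
  for (ring in sssr$rings) in_ring[ring] <- TRUE

  deg_total <- deg_heavy + nH
  arom <- .perceive_aromatic(elements, charge, bonds, sssr$rings, deg_total)

  hyb <- vapply(seq_len(n), function(i) {
    if (!heavy[i]) return("s")
    orders <- bonds$order[bonds$a1 == i | bonds$a2 == i]
    if (any(orders >= 3) || sum(orders == 2) >= 2) "sp"
    else if (any(orders == 2) || arom$atom[i]) "sp2"
    else "sp3"
  }, character(1))

  list(elements = elements, charge = as.integer(charge), coords = coords,
       bonds = bonds, heavy = heavy, n_heavy = sum(heavy), nH = nH,
       deg_heavy = deg_heavy, in_ring = in_ring, rings = sssr$rings,
       arom_atom = arom$atom, arom_ring = arom$ring,
       pyrrole_n = arom$pyrrole_n, hyb = hyb)
}

.neighbors <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

.bond_order <- function(mol, a, b) {
  hit <- (mol$bonds$a1 == a & mol$bonds$a2 == b) |
         (mol$bonds$a1 == b & mol$bonds$a2 == a)
  if (any(hit)) mol$bonds$order[hit][1] else 0L
}

.heavy_neighbors <- function(mol, i) {
  nb <- .neighbors(mol, i)
  nb[mol$heavy[nb]]
}

# Molecular weight (average masses) including implicit and explicit H.
.mol_weight <- function(mol) {
  w <- .ATOMIC_WEIGHTS[mol$elements]
  if (anyNA(w)) {
    stop("no atomic weight for element(s): ",
         paste(unique(mol$elements[is.na(w)]), collapse = ", "), call. = FALSE)
  }
  sum(w) + sum(mol$nH[mol$heavy]) * .ATOMIC_WEIGHTS[["H"]]
}

# Morgan-style iterative refinement into atom equivalence classes; used for
# tetrahedral stereocentre candidate detection.
.morgan_classes <- function(mol) {
  n <- length(mol$elements)
  inv <- paste(mol$elements, mol$charge, mol$deg_heavy, mol$nH,
               mol$arom_atom, mol$in_ring)
  cls <- as.integer(factor(inv))
  adj <- lapply(seq_len(n), function(i) .neighbors(mol, i))
  repeat {
    sig <- vapply(seq_len(n), function(i) {
      paste(cls[i], paste(sort(cls[adj[[i]]]), collapse = ","), sep = "|")
    }, character(1))
    new_cls <- as.integer(factor(sig))
    if (length(unique(new_cls)) == length(unique(cls))) break
    cls <- new_cls
  }
  cls
}
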