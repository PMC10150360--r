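# Chemotype classification of hydrogen-bond donors. Every donor hydrogen is
# assigned to exactly one category, so the categories always partition the
# HBD count of the same charge state.

.HBD_CATEGORIES <- c("amide_NH", "phenol_OH", "aliphatic_OH",
                     "heterocyclic_NH", "protonated_base_H",
                     "acylsulfonamide_NH", "other_HBD")

#' Classify hydrogen-bond donors into chemotype categories
#'
#' Assigns each donor hydrogen (on non-anionic N/O) to one of: amide N-H,
#' phenol O-H, aliphatic O-H, heterocyclic N-H, protonated-base hydrogens
#' (ammonium, amidinium, guanidinium), acylsulfonamide N-H (neutral form
#' only) or other. Hydrogens matching several patterns are resolved by the
#' fixed priority order acylsulfonamide > amide > phenol > aliphatic OH >
#' heterocyclic NH > protonated base > other, so the categories are
#' disjoint and sum to the total donor count.
#'
#' @inheritParams count_hbd
#' @return A one-row `data.frame` with one column per category plus `id`
#'   and `charge_state`.
#' @examples
#' \donttest{
#' classify_hbds(parse_structure("CNC(C)=O", "N-methylacetamide"), "neutral")
#' }
#' @export
classify_hbds <- function(record, charge_state = c("ph7", "neutral")) {
  charge_state <- match.arg(charge_state)
  mol <- .resolve_mol(record, charge_state)
  counts <- stats::setNames(integer(length(.HBD_CATEGORIES)), .HBD_CATEGORIES)
  carbonyls <- .carbonyl_c(mol)
  sulfonyls <- .sulfonyl_s(mol)
  for (i in seq_along(mol$elements)) {
    el <- mol$elements[i]
    if (!el %in% c("N", "O") || mol$charge[i] < 0 || mol$nH[i] == 0) next
    nh <- mol$nH[i]
    cat <- if (el == "N") {
      if (mol$charge[i] == 0 &&
          .is_amide_n(mol, i, carbonyls) &&
          .is_sulfonamide_n(mol, i, sulfonyls)) {
        "acylsulfonamide_NH"
      } else if (.is_amide_n(mol, i, carbonyls)) {
        "amide_NH"
      } else if (mol$in_ring[i]) {
        "heterocyclic_NH"
      } else if (mol$charge[i] > 0 || .is_base_partner_n(mol, i)) {
        "protonated_base_H"
      } else {
        "other_HBD"
      }
    } else {
      nb <- .heavy_neighbors(mol, i)
      if (length(nb) && any(mol$arom_atom[nb])) {
        "phenol_OH"
      } else if (length(nb) && mol$elements[nb[1]] == "C" &&
                 !nb[1] %in% carbonyls) {
        "aliphatic_OH"
      } else {
        "other_HBD"  # e.g. carboxylic/sulfonic O-H in the neutral form, water
      }
    }
    counts[cat] <- counts[cat] + nh
  }
  total <- .count_hbd_mol(mol)
  if (sum(counts) != total) {
    stop("internal consistency error: HBD categories sum to ", sum(counts),
         " but count_hbd gives ", total, " for '", record$id, "'",
         call. = FALSE)
  }
  out <- data.frame(id = record$id, t(counts), charge_state = charge_state,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# N-H of an amidinium/guanidinium group: the nitrogen is single-bonded to a
# carbon that carries a double bond to a (protonated) nitrogen.
.is_base_partner_n <- function(mol, i) {
  any(vapply(.heavy_neighbors(mol, i), function(j) {
    mol$elements[j] == "C" &&
      any(vapply(.heavy_neighbors(mol, j), function(k) {
        k != i && mol$elements[k] == "N" && .bond_order(mol, j, k) == 2 &&
          mol$charge[k] > 0
      }, logical(1)))
  }, logical(1)))
}

#' HBD chemotype table for a set of molecules
#'
#' @param records A list of `MoleculeRecord`s.
#' @inheritParams count_hbd
#' @return A `data.frame` with one row per molecule, category counts and
#'   the `origin`/`route` labels.
#' @export
hbd_profile_table <- function(records, charge_state = c("ph7", "neutral")) {
  charge_state <- match.arg(charge_state)
  rows <- lapply(records, function(rec) {
    row <- classify_hbds(rec, charge_state)
    row$origin <- rec$origin
    row$route <- rec$route
    row
  })
  do.call(rbind, rows)
}

#' Compare HBD chemotype distributions between compound classes
#'
#' Summarises each class (e.g. de novo designed vs natural-product derived)
#' by the median and quartiles of every donor category and compares the two
#' classes with a rank-based two-sample (Wilcoxon) test per category, exact
#' where sample size and ties permit. With more than two classes a
#' Kruskal-Wallis test is used instead.
#'
#' @param profiles A `data.frame` from [hbd_profile_table()].
#' @param group_col Name of the grouping column (default `"origin"`).
#' @return A list with `summary` (per class and category: median, q25, q75)
#'   and `p_values` (one per category).
#' @export
compare_origin_classes <- function(profiles, group_col = "origin") {
  stopifnot(group_col %in% names(profiles))
  g <- profiles[[group_col]]
  keep <- !is.na(g)
  if (any(!keep)) {
    warning("omitting ", sum(!keep), " profile(s) without a '", group_col,
            "' label", call. = FALSE)
  }
  profiles <- profiles[keep, , drop = FALSE]
  g <- factor(profiles[[group_col]])
  if (nlevels(g) < 2) stop("need at least two classes to compare", call. = FALSE)
  cats <- intersect(.HBD_CATEGORIES, names(profiles))
  summ <- do.call(rbind, lapply(levels(g), function(cl) {
    sub <- profiles[g == cl, cats, drop = FALSE]
    do.call(rbind, lapply(cats, function(cc) {
      q <- stats::quantile(sub[[cc]], c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(class = cl, category = cc, q25 = q[1], median = q[2],
                 q75 = q[3], n = nrow(sub), stringsAsFactors = FALSE)
    }))
  }))
  p <- vapply(cats, function(cc) {
    if (nlevels(g) == 2) {
      x <- profiles[[cc]][g == levels(g)[1]]
      y <- profiles[[cc]][g == levels(g)[2]]
      if (all(c(x, y) == c(x, y)[1])) return(1)
      suppressWarnings(stats::wilcox.test(x, y, correct = FALSE)$p.value)
    } else {
      stats::kruskal.test(profiles[[cc]], g)$p.value
    }
  }, numeric(1))
  list(summary = summ, p_values = p)
}
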