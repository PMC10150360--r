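# Ligand shape by normalised principal moments of inertia (NPR). A 3D
# conformer maps to a point (NPR1, NPR2) in the triangle spanned by the
# ideal rod (0, 1), disc (0.5, 0.5) and sphere (1, 1).

.SHAPE_VERTICES <- rbind(rod = c(0, 1), disc = c(0.5, 0.5), sphere = c(1, 1))

#' Normalised principal moments of inertia of a conformer
#'
#' Computes the mass-weighted inertia tensor about the centre of mass,
#' its eigenvalues sorted ascending (I1 <= I2 <= I3) and the normalised
#' ratios NPR1 = I1/I3 and NPR2 = I2/I3. By convention hydrogens are
#' included and atoms are weighted by their atomic masses; both choices are
#' switchable and recorded in the result.
#'
#' @param coords A `data.frame` (or matrix) with columns `x`, `y`, `z` and
#'   `element`.
#' @param use_hydrogens Include hydrogen atoms (default `TRUE`).
#' @param mass_weighted Weight atoms by atomic mass (default `TRUE`);
#'   otherwise unit masses are used.
#' @return A `ShapeResult`: list with `I1`, `I2`, `I3`, `NPR1`, `NPR2`,
#'   `shape_class` and the flags used.
#' @examples
#' rod <- data.frame(x = c(-1, 1), y = 0, z = 0, element = "C")
#' compute_npr(rod)$NPR1  # 0
#' @export
compute_npr <- function(coords, use_hydrogens = TRUE, mass_weighted = TRUE) {
  coords <- as.data.frame(coords)
  stopifnot(all(c("x", "y", "z", "element") %in% names(coords)))
  if (!use_hydrogens) coords <- coords[coords$element != "H", , drop = FALSE]
  if (nrow(coords) < 2) {
    stop("need at least two atoms to define an inertia tensor", call. = FALSE)
  }
  m <- if (mass_weighted) {
    w <- .ATOMIC_WEIGHTS[as.character(coords$element)]
    if (anyNA(w)) stop("unknown element(s): ",
                       paste(unique(coords$element[is.na(w)]), collapse = ", "),
                       call. = FALSE)
    as.numeric(w)
  } else rep(1, nrow(coords))
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  if (all(abs(r) < 1e-12)) {
    stop("degenerate conformer: all atoms coincide", call. = FALSE)
  }
  r2 <- rowSums(r^2)
  tensor <- diag(sum(m * r2) - colSums(r^2 * m))
  tensor[1, 2] <- tensor[2, 1] <- -sum(m * r[, 1] * r[, 2])
  tensor[1, 3] <- tensor[3, 1] <- -sum(m * r[, 1] * r[, 3])
  tensor[2, 3] <- tensor[3, 2] <- -sum(m * r[, 2] * r[, 3])
  ev <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
  ev[ev < 0 & ev > -1e-9] <- 0
  npr1 <- ev[1] / ev[3]
  npr2 <- ev[2] / ev[3]
  structure(list(I1 = ev[1], I2 = ev[2], I3 = ev[3],
                 NPR1 = npr1, NPR2 = npr2,
                 shape_class = classify_shape(npr1, npr2),
                 use_hydrogens = use_hydrogens,
                 mass_weighted = mass_weighted),
            class = "ShapeResult")
}

#' @export
print.ShapeResult <- function(x, ...) {
  cat(sprintf("<ShapeResult> NPR1 = %.3f, NPR2 = %.3f -> %s\n",
              x$NPR1, x$NPR2, x$shape_class))
  invisible(x)
}

#' Classify a shape on the rod-disc-sphere triangle
#'
#' Assigns the nearest triangle vertex in Euclidean NPR distance: rod
#' (0, 1), disc (0.5, 0.5) or sphere (1, 1).
#'
#' @param npr1,npr2 NPR coordinates, or a `ShapeResult` as `npr1`.
#' @param tol Tolerance for the triangle constraints `0 <= NPR1 <= NPR2 <= 1`
#'   and `NPR1 + NPR2 >= 1`; values outside by more than `tol` are rejected
#'   as inconsistent input.
#' @return `"rod"`, `"disc"` or `"sphere"`.
#' @examples
#' classify_shape(0.05, 0.95)  # rod
#' @export
classify_shape <- function(npr1, npr2 = NULL, tol = 1e-6) {
  if (inherits(npr1, "ShapeResult")) {
    npr2 <- npr1$NPR2
    npr1 <- npr1$NPR1
  }
  if (npr1 < -tol || npr2 > 1 + tol || npr1 > npr2 + tol ||
      npr1 + npr2 < 1 - tol) {
    stop(sprintf("NPR pair (%.4f, %.4f) lies outside the shape triangle",
                 npr1, npr2), call. = FALSE)
  }
  d2 <- (.SHAPE_VERTICES[, 1] - npr1)^2 + (.SHAPE_VERTICES[, 2] - npr2)^2
  # exact ties go to the later (more three-dimensional) vertex
  sel <- which(d2 <= min(d2) + 1e-12)
  rownames(.SHAPE_VERTICES)[max(sel)]
}

#' Compare the shape distributions of two conformer sets
#'
#' @param set_a,set_b Lists of `ShapeResult`s.
#' @return A `data.frame` with per-set rod/disc/sphere fractions and the
#'   mean NPR centroid.
#' @export
compare_to_reference <- function(set_a, set_b) {
  stopifnot(length(set_a) > 0, length(set_b) > 0)
  one <- function(set, label) {
    cls <- vapply(set, `[[`, character(1), "shape_class")
    npr <- t(vapply(set, function(s) c(s$NPR1, s$NPR2), numeric(2)))
    data.frame(set = label, n = length(set),
               rod = mean(cls == "rod"), disc = mean(cls == "disc"),
               sphere = mean(cls == "sphere"),
               NPR1_mean = mean(npr[, 1]), NPR2_mean = mean(npr[, 2]),
               stringsAsFactors = FALSE)
  }
  rbind(one(set_a, "A"), one(set_b, "B"))
}

#' Shape results from a multi-conformer SDF file
#'
#' Reads 3D coordinates from an SDF (V2000) file and computes one
#' `ShapeResult` per molecule block.
#'
#' @param file Path to an SDF file with 3D coordinates.
#' @inheritParams compute_npr
#' @return A named list of `ShapeResult`s.
#' @export
shape_from_sdf <- function(file, use_hydrogens = TRUE, mass_weighted = TRUE) {
  sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(file))
  out <- lapply(seq_along(sdfset@SDF), function(i) {
    sdf <- sdfset@SDF[[i]]
    ab <- ChemmineR::atomblock(sdf)
    coords <- data.frame(x = ab[, "C1"], y = ab[, "C2"], z = ab[, "C3"],
                         element = .atom_elements(sdf),
                         stringsAsFactors = FALSE)
    compute_npr(coords, use_hydrogens, mass_weighted)
  })
  names(out) <- ChemmineR::sdfid(sdfset)
  out
}

#' Shape results for HETATM ligands in a PDB file
#'
#' Extracts ligand (HETATM) records, excluding waters, groups them by
#' residue and computes a `ShapeResult` per ligand instance. Requires the
#' `bio3d` package.
#'
#' @param file Path to a PDB file.
#' @param resname Optional residue name(s) to select.
#' @inheritParams compute_npr
#' @return A named list of `ShapeResult`s (name: `resname_chain_resno`).
#' @export
shape_from_pdb <- function(file, resname = NULL, use_hydrogens = TRUE,
                           mass_weighted = TRUE) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("shape_from_pdb() requires the bio3d package", call. = FALSE)
  }
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  het <- at[at$type == "HETATM" & !at$resid %in% c("HOH", "WAT"), , drop = FALSE]
  if (!is.null(resname)) het <- het[het$resid %in% resname, , drop = FALSE]
  if (!nrow(het)) stop("no ligand HETATM records found", call. = FALSE)
  key <- paste(het$resid, het$chain, het$resno, sep = "_")
  out <- lapply(split(seq_len(nrow(het)), key), function(ix) {
    sub <- het[ix, , drop = FALSE]
    elem <- sub$elesy
    if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
      elem <- sub("\\d.*$", "", trimws(sub$elety))
    }
    elem <- paste0(toupper(substr(elem, 1, 1)),
                   tolower(substr(elem, 2, 2)))
    coords <- data.frame(x = sub$x, y = sub$y, z = sub$z, element = trimws(elem),
                         stringsAsFactors = FALSE)
    compute_npr(coords, use_hydrogens, mass_weighted)
  })
  out
}
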