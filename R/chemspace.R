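# PCA mapping of descriptor space with class centroids and 95% confidence
# ellipses. Columns are autoscaled before eigendecomposition so that counts
# and Dalton-scale descriptors contribute comparably.

#' Principal component map of descriptor space
#'
#' Autoscales the selected descriptor columns (zero mean, unit variance),
#' performs PCA and returns scores, loadings, explained variance and, when
#' class labels are given, per-class centroids and 95% covariance ellipses.
#' The loading sign is fixed deterministically: within each component the
#' largest-magnitude loading is made positive. An optional molecular-weight
#' cap excludes very large compounds (e.g. > 1500 Da) before the analysis.
#'
#' @param table Descriptor `data.frame`.
#' @param descriptors Columns to use; defaults to the Rule-of-5/Veber set
#'   plus cLogS: MW, cLogP, cLogS, TPSA, HBD, HBA, NRotB.
#' @param labels Optional class label per row (e.g. `table$route`).
#' @param mw_cap Optional MW exclusion threshold in Da (requires an `MW`
#'   column); excluded rows are reported via a message.
#' @return A `ChemSpaceMap`: list with `scores`, `loadings`,
#'   `explained_variance`, `class_centroids`, `class_ellipses`, `labels`
#'   and `n_excluded`.
#' @export
pca_map <- function(table,
                    descriptors = c("MW", "cLogP", "cLogS", "TPSA",
                                    "HBD", "HBA", "NRotB"),
                    labels = NULL, mw_cap = NULL) {
  stopifnot(all(descriptors %in% names(table)))
  n_excluded <- 0L
  if (!is.null(mw_cap)) {
    stopifnot("MW" %in% names(table))
    keep <- table$MW <= mw_cap
    n_excluded <- sum(!keep)
    if (n_excluded) {
      message("excluding ", n_excluded, " compound(s) with MW > ", mw_cap, " Da")
    }
    table <- table[keep, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[keep]
  }
  x <- as.matrix(table[, descriptors, drop = FALSE])
  storage.mode(x) <- "double"
  const <- apply(x, 2, function(col) stats::sd(col) == 0 || all(is.na(col)))
  if (any(const)) {
    warning("dropping constant descriptor column(s): ",
            paste(descriptors[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  if (ncol(x) < 2) stop("need at least two varying descriptors", call. = FALSE)
  if (nrow(x) < 3) stop("need at least three compounds", call. = FALSE)
  if (nrow(x) < ncol(x)) {
    stop("fewer compounds than descriptors; reduce the descriptor set",
         call. = FALSE)
  }
  pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # deterministic sign convention: dominant loading positive per component
  for (j in seq_len(ncol(pca$rotation))) {
    k <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[k, j] < 0) {
      pca$rotation[, j] <- -pca$rotation[, j]
      pca$x[, j] <- -pca$x[, j]
    }
  }
  ev <- pca$sdev^2 / sum(pca$sdev^2)
  scores <- pca$x
  centroids <- NULL
  ellipses <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(scores))
    lev <- unique(labels[!is.na(labels)])
    centroids <- do.call(rbind, lapply(lev, function(cl) {
      s <- scores[labels == cl, 1:2, drop = FALSE]
      data.frame(class = cl, PC1 = mean(s[, 1]), PC2 = mean(s[, 2]),
                 n = nrow(s), stringsAsFactors = FALSE)
    }))
    ellipses <- lapply(lev, function(cl) {
      confidence_ellipse(scores[labels == cl, 1:2, drop = FALSE])
    })
    names(ellipses) <- lev
  }
  structure(list(scores = scores, loadings = pca$rotation,
                 explained_variance = ev, class_centroids = centroids,
                 class_ellipses = ellipses, labels = labels,
                 center = pca$center, scale = pca$scale,
                 n_excluded = n_excluded),
            class = "ChemSpaceMap")
}

#' @export
print.ChemSpaceMap <- function(x, ...) {
  cat("<ChemSpaceMap>", nrow(x$scores), "compounds,",
      ncol(x$loadings), "descriptors\n")
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  if (!is.null(x$class_centroids)) print(x$class_centroids)
  invisible(x)
}

#' Covariance confidence ellipse of 2D scores
#'
#' Fits the 2x2 covariance of the points and scales it by the chi-square
#' quantile at the requested coverage with two degrees of freedom, the
#' standard normal-theory confidence region for a bivariate cloud.
#'
#' @param scores A two-column matrix or `data.frame` of (PC1, PC2) points
#'   (at least 3).
#' @param level Coverage level (default 0.95).
#' @return A list with `center`, `axes` (semi-axis lengths), `angle`
#'   (radians, first axis vs x), `level` and a `degenerate` flag for
#'   singular covariance (collinear points).
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  s <- as.matrix(scores)
  stopifnot(ncol(s) == 2)
  if (nrow(s) < 3) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(s)
  cv <- stats::cov(s)
  ee <- eigen(cv, symmetric = TRUE)
  degenerate <- min(ee$values) <= max(ee$values) * 1e-12
  q <- stats::qchisq(level, df = 2)
  axes <- sqrt(pmax(ee$values, 0) * q)
  angle <- atan2(ee$vectors[2, 1], ee$vectors[1, 1])
  list(center = ctr, axes = axes, angle = angle, level = level,
       degenerate = degenerate)
}

#' Points on a confidence ellipse outline
#'
#' @param ellipse A list from [confidence_ellipse()].
#' @param n Number of points.
#' @return An `n` x 2 matrix of (x, y) coordinates.
#' @export
ellipse_coords <- function(ellipse, n = 100) {
  t <- seq(0, 2 * pi, length.out = n)
  unit <- cbind(ellipse$axes[1] * cos(t), ellipse$axes[2] * sin(t))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  sweep(unit %*% t(rot), 2, ellipse$center, `+`)
}

#' Per-class descriptor medians for radar summaries
#'
#' Computes the median of each descriptor per class plus a 0-1
#' normalisation by the pooled range, the form used for radar-plot
#' comparison of oral and parenteral property profiles.
#'
#' @param table Descriptor `data.frame`.
#' @param descriptors Descriptor column names.
#' @param labels Class label per row.
#' @return A list with `medians` and `normalized` (classes x descriptors).
#' @export
median_radar <- function(table, descriptors, labels) {
  stopifnot(all(descriptors %in% names(table)),
            length(labels) == nrow(table))
  lev <- unique(labels[!is.na(labels)])
  if (length(lev) < 1) stop("no labelled rows", call. = FALSE)
  med <- matrix(NA_real_, nrow = length(lev), ncol = length(descriptors),
                dimnames = list(lev, descriptors))
  for (cl in lev) {
    med[cl, ] <- vapply(descriptors, function(d) {
      stats::median(table[[d]][labels == cl], na.rm = TRUE)
    }, numeric(1))
  }
  rng <- vapply(descriptors, function(d) {
    range(table[[d]], na.rm = TRUE)
  }, numeric(2))
  norm <- med
  for (j in seq_along(descriptors)) {
    span <- rng[2, j] - rng[1, j]
    norm[, j] <- if (span == 0) 0.5 else (med[, j] - rng[1, j]) / span
  }
  list(medians = med, normalized = norm)
}

#' Plot a chemical-space map
#'
#' Score plot with class colours, centroids and confidence ellipses, plus
#' loading arrows, in base graphics.
#'
#' @param x A `ChemSpaceMap`.
#' @param arrow_scale Scaling factor for the loading arrows.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.ChemSpaceMap <- function(x, arrow_scale = NULL, ...) {
  s <- x$scores[, 1:2, drop = FALSE]
  cols <- if (is.null(x$labels)) "grey30" else {
    pal <- c("#1f78b4", "#e6a400", "#33a02c", "#e31a1c")
    pal[as.integer(factor(x$labels))]
  }
  graphics::plot(s, col = cols, pch = 16,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]),
                 ...)
  if (!is.null(x$class_ellipses)) {
    for (e in x$class_ellipses) {
      if (!e$degenerate) graphics::lines(ellipse_coords(e), lty = 2)
    }
  }
  if (!is.null(x$class_centroids)) {
    graphics::points(x$class_centroids$PC1, x$class_centroids$PC2,
                     pch = 21, bg = "white", cex = 2)
  }
  if (is.null(arrow_scale)) {
    arrow_scale <- 0.8 * min(diff(range(s[, 1])), diff(range(s[, 2]))) / 2
  }
  ld <- x$loadings[, 1:2, drop = FALSE]
  graphics::arrows(0, 0, ld[, 1] * arrow_scale, ld[, 2] * arrow_scale,
                   length = 0.08, col = "grey40")
  graphics::text(ld[, 1] * arrow_scale * 1.1, ld[, 2] * arrow_scale * 1.1,
                 rownames(ld), cex = 0.8, col = "grey20")
  invisible(x)
}
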