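# Oral-vs-parenteral classification from descriptor cutoffs. Cutoffs are
# derived as the major intersection of the two class kernel densities;
# classifiers are conjunctions of one to three (descriptor, cutoff,
# direction) conditions; quality is reported as sensitivity, specificity,
# GMean, accuracy and Cohen's kappa with orals as the positive class.

.DISCRETE_DESCRIPTORS <- c("HBD", "HBA", "NRotB", "NAR", "nC", "ring_size",
                           "n_stereocenters")

#' Derive a descriptor cutoff from class density intersection
#'
#' Fits a Gaussian kernel density (Silverman bandwidth, 512-point grid
#' spanning the pooled range extended by three bandwidths) to each class and
#' locates the major intersection: the crossing between the two class
#' medians at which the oral density passes the parenteral density. If
#' several crossings lie between the medians the one with the highest pooled
#' density is taken. When no crossing exists between the medians the
#' midpoint of the medians is used with a warning. For discrete descriptors
#' the raw intersection is rounded to the nearest integer.
#'
#' @param values_oral,values_parenteral Numeric descriptor values per class
#'   (at least 5 each).
#' @param discrete Round the cutoff to the nearest integer (counts such as
#'   HBD, HBA, NRotB).
#' @param descriptor Optional descriptor name carried into the result.
#' @return A `CutoffEstimate`: list with `descriptor`, `raw_intersection`,
#'   `cutoff` and `direction` (`"<="`/`"<"` when the oral class lies below
#'   the cutoff, `">="`/`">"` otherwise; inclusive for discrete
#'   descriptors, strict for continuous ones).
#' @examples
#' set.seed(1)
#' derive_cutoff(rnorm(500, 0), rnorm(500, 4))$cutoff  # ~ 2
#' @export
derive_cutoff <- function(values_oral, values_parenteral, discrete = FALSE,
                          descriptor = NA_character_) {
  values_oral <- as.numeric(values_oral[is.finite(values_oral)])
  values_parenteral <- as.numeric(values_parenteral[is.finite(values_parenteral)])
  if (length(values_oral) < 5 || length(values_parenteral) < 5) {
    stop("need at least 5 finite values per class", call. = FALSE)
  }
  if (length(values_oral) == length(values_parenteral) &&
      all(sort(values_oral) == sort(values_parenteral))) {
    stop("classes are identical; no cutoff can be derived", call. = FALSE)
  }
  med_o <- stats::median(values_oral)
  med_p <- stats::median(values_parenteral)
  bw_o <- stats::bw.nrd0(values_oral)
  bw_p <- stats::bw.nrd0(values_parenteral)
  pooled <- c(values_oral, values_parenteral)
  pad <- 3 * max(bw_o, bw_p)
  lo <- min(pooled) - pad
  hi <- max(pooled) + pad
  d_o <- stats::density(values_oral, bw = bw_o, from = lo, to = hi, n = 512)
  d_p <- stats::density(values_parenteral, bw = bw_p, from = lo, to = hi, n = 512)
  grid <- d_o$x
  diff_d <- d_o$y - d_p$y
  sgn <- sign(diff_d)
  cross_idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  crossings <- vapply(cross_idx, function(i) {
    # linear interpolation of the zero of the density difference
    x1 <- grid[i]; x2 <- grid[i + 1]
    y1 <- diff_d[i]; y2 <- diff_d[i + 1]
    x1 - y1 * (x2 - x1) / (y2 - y1)
  }, numeric(1))
  lo_med <- min(med_o, med_p)
  hi_med <- max(med_o, med_p)
  between <- crossings[crossings >= lo_med & crossings <= hi_med]
  if (length(between) == 0) {
    warning("no density crossing between the class medians; ",
            "falling back to their midpoint", call. = FALSE)
    raw <- (med_o + med_p) / 2
  } else if (length(between) == 1) {
    raw <- between
  } else {
    pooled_dens <- stats::approx(grid, d_o$y + d_p$y, xout = between)$y
    raw <- between[which.max(pooled_dens)]
  }
  cutoff <- if (discrete) round(raw) else raw
  direction <- if (med_o <= med_p) {
    if (discrete) "<=" else "<"
  } else {
    if (discrete) ">=" else ">"
  }
  structure(list(descriptor = descriptor, raw_intersection = raw,
                 cutoff = cutoff, direction = direction),
            class = "CutoffEstimate")
}

#' @export
print.CutoffEstimate <- function(x, ...) {
  cat(sprintf("<CutoffEstimate> %s %s %s (raw intersection %.4g)\n",
              if (is.na(x$descriptor)) "value" else x$descriptor,
              x$direction, format(x$cutoff), x$raw_intersection))
  invisible(x)
}

#' Build a conjunctive rule model
#'
#' A rule model is a conjunction of one to three conditions of the form
#' `descriptor direction cutoff`; a compound is predicted oral only when
#' every condition holds.
#'
#' @param ... `CutoffEstimate`s, or lists with `descriptor`, `cutoff` and
#'   `direction` entries.
#' @return A `RuleModel`.
#' @examples
#' m <- rule_model(list(descriptor = "HBD", cutoff = 7, direction = "<="),
#'                 list(descriptor = "MW", cutoff = 982, direction = "<"))
#' @export
rule_model <- function(...) {
  conds <- list(...)
  if (length(conds) == 1 && !is.null(conds[[1]]$descriptor) == FALSE) {
    conds <- conds[[1]]
  }
  if (length(conds) < 1 || length(conds) > 3) {
    stop("a rule model has 1-3 conditions", call. = FALSE)
  }
  df <- do.call(rbind, lapply(conds, function(cc) {
    stopifnot(!is.null(cc$descriptor), !is.null(cc$cutoff),
              cc$direction %in% c("<=", "<", ">", ">="))
    data.frame(descriptor = cc$descriptor, cutoff = as.numeric(cc$cutoff),
               direction = cc$direction, stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(df$descriptor)) {
    stop("each descriptor may appear at most once in a rule model",
         call. = FALSE)
  }
  structure(list(conditions = df, combination = "and"), class = "RuleModel")
}

#' @export
print.RuleModel <- function(x, ...) {
  cond <- x$conditions
  cat("<RuleModel> oral iff",
      paste(cond$descriptor, cond$direction, format(cond$cutoff),
            collapse = "  AND  "), "\n")
  invisible(x)
}

#' Apply a rule model to descriptor vectors
#'
#' @param vec A `data.frame` of descriptor values (one row per compound).
#' @param model A `RuleModel`.
#' @return Character vector of predicted classes (`"oral"`/`"parenteral"`).
#' @examples
#' m <- rule_model(list(descriptor = "HBD", cutoff = 7, direction = "<="))
#' apply_rule(data.frame(HBD = c(5, 8)), m)
#' @export
apply_rule <- function(vec, model) {
  stopifnot(inherits(model, "RuleModel"))
  vec <- as.data.frame(vec)
  cond <- model$conditions
  miss <- setdiff(cond$descriptor, names(vec))
  if (length(miss)) {
    stop("descriptor(s) missing from input: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok <- rep(TRUE, nrow(vec))
  for (i in seq_len(nrow(cond))) {
    x <- vec[[cond$descriptor[i]]]
    ok <- ok & switch(cond$direction[i],
                      "<=" = x <= cond$cutoff[i],
                      "<"  = x <  cond$cutoff[i],
                      ">"  = x >  cond$cutoff[i],
                      ">=" = x >= cond$cutoff[i])
  }
  ifelse(ok, "oral", "parenteral")
}

#' Confusion matrix with orals as positives
#'
#' @param predictions,labels Character vectors in `{"oral", "parenteral"}`.
#' @return A `ConfusionMatrix`: list with `TP`, `TN`, `FP`, `FN`.
#' @examples
#' confusion(c("oral", "oral"), c("oral", "parenteral"))
#' @export
confusion <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  bad <- unique(c(predictions, labels))
  bad <- bad[!bad %in% c("oral", "parenteral")]
  if (length(bad)) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    TP = sum(predictions == "oral" & labels == "oral"),
    TN = sum(predictions == "parenteral" & labels == "parenteral"),
    FP = sum(predictions == "oral" & labels == "parenteral"),
    FN = sum(predictions == "parenteral" & labels == "oral")
  ), class = "ConfusionMatrix")
}

#' Construct a confusion matrix from counts
#'
#' Convenience constructor for evaluating the metric formulas on published
#' confusion matrices.
#'
#' @param TP,TN,FP,FN Non-negative counts; orals are positives.
#' @return A `ConfusionMatrix`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "ConfusionMatrix")
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  cat(sprintf("<ConfusionMatrix> TP %d  TN %d  FP %d  FN %d\n",
              x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), their geometric
#' mean GMean, overall accuracy (TP+TN)/n, and Cohen's kappa
#' (p_o - p_e)/(1 - p_e) where p_o is the accuracy and p_e the chance
#' agreement from the marginal products.
#'
#' @param cm A `ConfusionMatrix`.
#' @return Named numeric vector: `sensitivity`, `specificity`, `gmean`,
#'   `accuracy`, `kappa`. When the chance agreement p_e equals 1 (all
#'   margins concentrated in one class) kappa is undefined and returned as
#'   `NA` with a warning.
#' @examples
#' classifier_metrics(confusion_counts(20, 30, 8, 4))
#' @export
classifier_metrics <- function(cm) {
  stopifnot(inherits(cm, "ConfusionMatrix"))
  tp <- cm$TP; tn <- cm$TN; fp <- cm$FP; fn <- cm$FN
  if (tp + fn == 0) stop("no positive (oral) examples", call. = FALSE)
  if (tn + fp == 0) stop("no negative (parenteral) examples", call. = FALSE)
  n <- tp + tn + fp + fn
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("chance agreement p_e = 1; kappa is undefined", call. = FALSE)
    NA_real_
  } else {
    (acc - pe) / (1 - pe)
  }
  c(sensitivity = sens, specificity = spec, gmean = sqrt(sens * spec),
    accuracy = acc, kappa = kappa)
}

#' Enumerate and rank conjunctive descriptor models
#'
#' Derives one cutoff per descriptor from the labelled table, builds every
#' `order`-descriptor conjunctive model and evaluates it on the same table.
#' Models are ranked by Cohen's kappa, with accuracy and then GMean breaking
#' ties.
#'
#' @param table Labelled descriptor `data.frame` with a `route` column.
#' @param descriptors Descriptor column names to combine.
#' @param order Model size: 1, 2 or 3 descriptors.
#' @return A list with `ranking` (a `data.frame` of models and metrics,
#'   best first), `models` (the corresponding `RuleModel`s) and `cutoffs`
#'   (the per-descriptor `CutoffEstimate`s).
#' @export
enumerate_models <- function(table, descriptors, order = 2) {
  stopifnot("route" %in% names(table),
            all(descriptors %in% names(table)))
  if (order > length(descriptors)) {
    stop("model order exceeds the number of descriptors", call. = FALSE)
  }
  oral <- table$route == "oral"
  cutoffs <- lapply(descriptors, function(d) {
    derive_cutoff(table[[d]][oral], table[[d]][!oral],
                  discrete = d %in% .DISCRETE_DESCRIPTORS, descriptor = d)
  })
  names(cutoffs) <- descriptors
  combos <- utils::combn(descriptors, order, simplify = FALSE)
  rows <- list()
  models <- list()
  for (combo in combos) {
    model <- do.call(rule_model, unname(cutoffs[combo]))
    pred <- apply_rule(table, model)
    met <- classifier_metrics(confusion(pred, table$route))
    rows[[length(rows) + 1L]] <- data.frame(
      model = paste(combo, collapse = "+"), t(met),
      stringsAsFactors = FALSE)
    models[[length(models) + 1L]] <- model
  }
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$kappa, -ranking$accuracy, -ranking$gmean)
  list(ranking = ranking[ord, , drop = FALSE], models = models[ord],
       cutoffs = cutoffs)
}

#' Benchmark the AB-MPS score as an oral-bioavailability classifier
#'
#' Predicts oral whenever AB-MPS = |cLogD - 3| + NAR + NRotB is at or below
#' the cutoff, and evaluates the prediction with the same confusion-matrix
#' metrics as the rule models.
#'
#' @param table Labelled descriptor `data.frame` with `cLogD`, `NAR`,
#'   `NRotB` and `route` columns.
#' @param cutoff 14 or 15 (default 15).
#' @return A list with `scores`, the `ConfusionMatrix` and the metrics.
#' @export
benchmark_abmps <- function(table, cutoff = 15) {
  stopifnot("route" %in% names(table))
  scores <- vapply(seq_len(nrow(table)), function(i) ab_mps(table[i, ]),
                   numeric(1))
  pred <- ab_mps_class(scores, cutoff)
  cm <- confusion(pred, table$route)
  list(scores = scores, confusion = cm, metrics = classifier_metrics(cm))
}
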