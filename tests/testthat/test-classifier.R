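# Independent recount oracle used by the property tests: metrics recomputed
# from first principles on the raw prediction/label vectors.
oracle_metrics <- function(pred, lab) {
  tp <- sum(pred == "oral" & lab == "oral")
  tn <- sum(pred == "parenteral" & lab == "parenteral")
  fp <- sum(pred == "oral" & lab == "parenteral")
  fn <- sum(pred == "parenteral" & lab == "oral")
  n <- length(pred)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  acc <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  c(TP = tp, TN = tn, FP = fp, FN = fn,
    sensitivity = sens, specificity = spec, gmean = sqrt(sens * spec),
    accuracy = acc, kappa = (acc - pe) / (1 - pe))
}

test_that("metrics reproduce the published bi-descriptor model statistics", {
  # training set: HBD with MW / cLogP / TPSA; test set: HBD with MW / cLogP
  cases <- list(
    list(cm = c(20, 30, 8, 4), want = c(0.83, 0.79, 0.81, 0.60)),
    list(cm = c(21, 30, 8, 3), want = c(0.88, 0.79, 0.82, 0.64)),
    list(cm = c(22, 28, 10, 2), want = c(0.92, 0.74, 0.81, 0.62)),
    list(cm = c(15, 30, 12, 3), want = c(0.83, 0.71, 0.75, 0.48)),
    list(cm = c(17, 28, 14, 1), want = c(0.94, 0.67, 0.75, 0.51))
  )
  for (cs in cases) {
    m <- classifier_metrics(do.call(confusion_counts, as.list(cs$cm)))
    got <- round(m[c("sensitivity", "specificity", "accuracy", "kappa")], 2)
    expect_equal(unname(got), cs$want, label = paste(cs$cm, collapse = ","))
  }
  # perfect matrix
  perfect <- classifier_metrics(confusion_counts(10, 10, 0, 0))
  expect_true(all(perfect == 1))
})

test_that("metrics agree with a brute-force recount oracle on random vectors", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(10:200, 1)
    lab <- sample(c("oral", "parenteral"), n, TRUE)
    if (length(unique(lab)) < 2) next
    pred <- sample(c("oral", "parenteral"), n, TRUE)
    cm <- confusion(pred, lab)
    want <- oracle_metrics(pred, lab)
    expect_equal(cm$TP, unname(want["TP"]))
    expect_equal(cm$FN, unname(want["FN"]))
    got <- classifier_metrics(cm)
    expect_equal(unname(got), unname(want[names(got)]), tolerance = 1e-12)
  }
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(55)
  for (i in 1:50) {
    cm <- confusion_counts(sample(1:50, 1), sample(1:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    m <- classifier_metrics(cm)
    p <- cm$TP + cm$FN; nneg <- cm$TN + cm$FP
    expect_equal(unname(m["gmean"]^2),
                 unname(m["sensitivity"] * m["specificity"]), tolerance = 1e-12)
    expect_equal(unname(m["accuracy"]),
                 unname((m["sensitivity"] * p + m["specificity"] * nneg) /
                          (p + nneg)), tolerance = 1e-12)
    expect_lte(m["kappa"], m["accuracy"] + 1e-12)
  }
})

test_that("swapping class labels swaps sensitivity and specificity", {
  set.seed(77)
  lab <- sample(c("oral", "parenteral"), 80, TRUE)
  pred <- sample(c("oral", "parenteral"), 80, TRUE)
  swap <- function(x) ifelse(x == "oral", "parenteral", "oral")
  m1 <- classifier_metrics(confusion(pred, lab))
  m2 <- classifier_metrics(confusion(swap(pred), swap(lab)))
  expect_equal(unname(m1["sensitivity"]), unname(m2["specificity"]))
  expect_equal(unname(m1["specificity"]), unname(m2["sensitivity"]))
  cm1 <- confusion(pred, lab); cm2 <- confusion(swap(pred), swap(lab))
  expect_equal(cm1$TP, cm2$TN); expect_equal(cm1$FP, cm2$FN)
})

test_that("degenerate confusion matrices are handled explicitly", {
  expect_error(classifier_metrics(confusion_counts(0, 5, 5, 0)), "positive")
  expect_error(classifier_metrics(confusion_counts(5, 0, 0, 5)), "negative")
  # uninformative predictor: kappa collapses to 0, not an error
  m <- classifier_metrics(confusion_counts(24, 0, 38, 0))
  expect_equal(unname(m["kappa"]), 0)
})

test_that("derive_cutoff recovers the midpoint of two equal Gaussians", {
  set.seed(202)
  o <- rnorm(10000, 0, 1)
  p <- rnorm(10000, 4, 1)
  est <- derive_cutoff(o, p)
  expect_equal(est$raw_intersection, 2, tolerance = 0.1)
  expect_equal(est$direction, "<")
})

test_that("derive_cutoff matches the analytic root for unequal variances", {
  # oracle: solve f(x) = dnorm(x, 0, 1) - dnorm(x, 6, 2) = 0 between means
  root <- uniroot(function(x) dnorm(x, 0, 1) - dnorm(x, 6, 2),
                  lower = 0, upper = 6)$root
  set.seed(203)
  est <- derive_cutoff(rnorm(10000, 0, 1), rnorm(10000, 6, 2))
  expect_equal(est$raw_intersection, root, tolerance = 0.1)
})

test_that("derive_cutoff validates input and rounds discrete descriptors", {
  expect_error(derive_cutoff(1:3, 1:10), "at least 5")
  expect_error(derive_cutoff(1:10, 10:1), "identical")
  set.seed(9)
  est <- derive_cutoff(rpois(500, 4), rpois(500, 9), discrete = TRUE)
  expect_equal(est$cutoff, round(est$raw_intersection))
  expect_equal(est$direction, "<=")
  # orals on the high side flip the direction
  est2 <- derive_cutoff(rnorm(200, 5), rnorm(200, 0))
  expect_equal(est2$direction, ">")
})

test_that("rule models apply conjunctively with exact boundary semantics", {
  m <- rule_model(list(descriptor = "HBD", cutoff = 7, direction = "<="),
                  list(descriptor = "MW", cutoff = 982, direction = "<"))
  expect_equal(apply_rule(data.frame(HBD = 5, MW = 900), m), "oral")
  expect_equal(apply_rule(data.frame(HBD = 8, MW = 900), m), "parenteral")
  expect_equal(apply_rule(data.frame(HBD = 7, MW = 982), m), "parenteral")
  m2 <- rule_model(list(descriptor = "HBD", cutoff = 7, direction = "<="),
                   list(descriptor = "cLogP", cutoff = 2.22, direction = ">"))
  expect_equal(apply_rule(data.frame(HBD = 7, cLogP = 2.22), m2), "parenteral")
  expect_equal(apply_rule(data.frame(HBD = 7, cLogP = 2.23), m2), "oral")
  expect_error(apply_rule(data.frame(HBD = 5), m), "MW")
  expect_error(rule_model(list(descriptor = "HBD", cutoff = 7, direction = "<="),
                          list(descriptor = "HBD", cutoff = 9, direction = "<=")),
               "at most once")
})

test_that("model enumeration evaluates every combination and ranks by kappa", {
  set.seed(301)
  n <- 120
  tab <- data.frame(
    route = rep(c("oral", "parenteral"), each = n),
    HBD = c(rpois(n, 4), rpois(n, 10)),
    MW = c(rlnorm(n, log(700), 0.2), rlnorm(n, log(1200), 0.2)),
    cLogP = rnorm(2 * n, 2, 1),      # uninformative
    TPSA = rnorm(2 * n, 250, 30)     # uninformative
  )
  res <- enumerate_models(tab, c("HBD", "MW", "cLogP", "TPSA"), order = 2)
  expect_equal(nrow(res$ranking), choose(4, 2))
  expect_equal(res$ranking$model[1], "HBD+MW")
  expect_true(all(diff(res$ranking$kappa) <= 1e-12))
  expect_error(enumerate_models(tab, c("HBD", "MW"), order = 3), "order")
})

test_that("a perfectly separating descriptor reaches kappa 1", {
  tab <- data.frame(route = rep(c("oral", "parenteral"), each = 30),
                    MW = c(rnorm(30, 300, 10), rnorm(30, 1500, 10)),
                    HBD = rep(5, 60))
  res <- enumerate_models(tab, c("MW"), order = 1)
  expect_equal(res$ranking$kappa[1], 1)
})

test_that("AB-MPS benchmarking separates constructed classes in the right direction", {
  set.seed(404)
  n <- 80
  tab <- data.frame(
    route = rep(c("oral", "parenteral"), each = n),
    cLogD = c(rnorm(n, 3, 1), rnorm(n, -1, 1)),
    NAR = c(rpois(n, 1), rpois(n, 2)),
    NRotB = c(rpois(n, 5), rpois(n, 15))
  )
  bench <- benchmark_abmps(tab, cutoff = 15)
  expect_gt(unname(bench$metrics["kappa"]), 0)
  # boundary behaviour
  one <- data.frame(route = c("oral", "parenteral"),
                    cLogD = c(3, 3), NAR = c(5, 5), NRotB = c(10, 10))
  expect_equal(ab_mps(one[1, ]), 15)
  expect_equal(ab_mps_class(ab_mps(one[1, ]), 15), "oral")
  expect_equal(ab_mps_class(ab_mps(one[1, ]), 14), "parenteral")
})
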