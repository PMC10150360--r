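test_that("PCA reconstructs the autoscaled data and normalises variance", {
  set.seed(21)
  tab <- data.frame(MW = rlnorm(50, log(800), 0.3),
                    cLogP = rnorm(50, 2, 2),
                    TPSA = rlnorm(50, log(250), 0.3),
                    HBD = rpois(50, 5))
  map <- pca_map(tab, c("MW", "cLogP", "TPSA", "HBD"))
  expect_equal(sum(map$explained_variance), 1, tolerance = 1e-12)
  x_scaled <- scale(as.matrix(tab))
  recon <- map$scores %*% t(map$loadings)
  expect_equal(unname(recon), unname(x_scaled[, rownames(map$loadings)]),
               tolerance = 1e-8, ignore_attr = TRUE)
  # loadings are orthonormal
  expect_equal(t(map$loadings) %*% map$loadings, diag(ncol(map$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PCA is deterministic and invariant to descriptor order", {
  set.seed(22)
  tab <- data.frame(MW = rlnorm(40, log(900), 0.2), cLogP = rnorm(40),
                    TPSA = rlnorm(40, log(300), 0.2))
  m1 <- pca_map(tab, c("MW", "cLogP", "TPSA"))
  m2 <- pca_map(tab, c("MW", "cLogP", "TPSA"))
  expect_identical(m1$scores, m2$scores)
  m3 <- pca_map(tab, c("TPSA", "MW", "cLogP"))
  expect_equal(abs(m1$explained_variance), abs(m3$explained_variance),
               tolerance = 1e-12)
})

test_that("perfectly correlated descriptors put all variance on PC1", {
  x <- rnorm(30)
  tab <- data.frame(a = x, b = 2 * x + 5)
  map <- pca_map(tab, c("a", "b"))
  expect_gt(map$explained_variance[1], 1 - 1e-9)
})

test_that("isotropic data splits variance evenly", {
  set.seed(23)
  tab <- data.frame(a = rnorm(10000), b = rnorm(10000))
  map <- pca_map(tab, c("a", "b"))
  expect_lt(max(abs(map$explained_variance - 0.5)), 0.02)
})

test_that("class centroids recover the generator's separation direction", {
  set.seed(24)
  n <- 300
  # two classes shifted along a known direction in descriptor space
  oral <- data.frame(MW = rnorm(n, 700, 100), TPSA = rnorm(n, 180, 30))
  par <- data.frame(MW = rnorm(n, 1100, 100), TPSA = rnorm(n, 320, 30))
  tab <- rbind(oral, par)
  labels <- rep(c("oral", "parenteral"), each = n)
  map <- pca_map(tab, c("MW", "TPSA"), labels = labels)
  cen <- map$class_centroids
  # both descriptors load positively on PC1 (sign convention), so the class
  # with larger MW/TPSA must sit at larger PC1
  d <- cen$PC1[cen$class == "parenteral"] - cen$PC1[cen$class == "oral"]
  expect_gt(abs(d), 1)
  expect_equal(sign(d), sign(sum(map$loadings[, 1])))
  expect_equal(cen$PC1[cen$class == "oral"],
               mean(map$scores[labels == "oral", 1]), tolerance = 1e-12)
})

test_that("the MW cap excludes heavy compounds and constant columns are dropped", {
  tab <- data.frame(MW = c(400, 600, 800, 2000, 2500),
                    cLogP = c(1, 2, 3, 4, 5), K = rep(7, 5))
  expect_message(map <- pca_map(tab, c("MW", "cLogP"), mw_cap = 1500),
                 "excluding 2")
  expect_equal(nrow(map$scores), 3)
  expect_equal(map$n_excluded, 2L)
  expect_warning(pca_map(tab, c("MW", "cLogP", "K")), "constant")
  expect_error(suppressWarnings(pca_map(tab[1:2, ], c("MW", "cLogP", "K"))))
})

test_that("confidence ellipses follow the chi-square closed form", {
  set.seed(25)
  s <- matrix(rnorm(40000), ncol = 2)
  e <- confidence_ellipse(s, 0.95)
  expect_equal(unname(e$axes), rep(sqrt(qchisq(0.95, 2)), 2), tolerance = 0.05)
  expect_false(e$degenerate)
  # collinear points flag a degenerate ellipse
  line <- cbind(1:10, 2 * (1:10))
  expect_true(confidence_ellipse(line)$degenerate)
  expect_error(confidence_ellipse(s[1:2, ]), "at least 3")
})

test_that("ellipse coverage is close to the nominal level", {
  set.seed(26)
  s <- matrix(rnorm(4000), ncol = 2)
  e <- confidence_ellipse(s, 0.95)
  # oracle: Mahalanobis distance against the chi-square quantile
  inside <- mahalanobis(s, colMeans(s), cov(s)) <= qchisq(0.95, 2)
  expect_equal(mean(inside), 0.95, tolerance = 0.02)
  pts <- ellipse_coords(e, 400)
  d <- mahalanobis(pts, colMeans(s), cov(s))
  expect_equal(unname(d), rep(qchisq(0.95, 2), 400), tolerance = 1e-6)
})

test_that("ellipse area shrinks with the coverage level", {
  set.seed(27)
  s <- matrix(rnorm(600), ncol = 2) %*% matrix(c(2, 0.5, 0.5, 1), 2)
  areas <- vapply(c(0.99, 0.95, 0.90, 0.80), function(lv) {
    e <- confidence_ellipse(s, lv)
    pi * prod(e$axes)
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("median radar summarises per-class medians with range normalisation", {
  tab <- data.frame(MW = c(1, 3, 5, 11, 13, 15), HBD = rep(4, 6))
  labels <- rep(c("oral", "parenteral"), each = 3)
  mr <- median_radar(tab, c("MW", "HBD"), labels)
  expect_equal(mr$medians["oral", "MW"], 3)
  expect_equal(mr$medians["parenteral", "MW"], 13)
  expect_equal(mr$normalized["oral", "MW"], (3 - 1) / 14)
  expect_equal(unname(mr$normalized[, "HBD"]), c(0.5, 0.5))
  same <- median_radar(tab, "MW", rep("x", 6))
  expect_equal(unname(same$medians[, "MW"]), 8)
})
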