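test_that("published logistic score: worked example, boundary, monotonicity", {
  fig1 <- list(cbv_p10 = 0.40, k2_p90 = 0.32, adc_p10 = 384)
  p <- logistic_score(fig1)
  expect_equal(p$score, 1.75 - 9.526 * 0.40 + 2.7924 * 0.32)
  expect_equal(p$score, -1.16683, tolerance = 1e-5)
  expect_identical(p$label, 1L)
  # boundary: a score exactly at the threshold counts as PH (the solved
  # crossing point reproduces -1.45 to double precision; the inclusive rule
  # is asserted with the threshold set to the bit-exact score)
  b <- logistic_score(list(cbv_p10 = 3.2 / 9.526, k2_p90 = 0))
  expect_equal(b$score, -1.45, tolerance = 1e-12)
  at_thr <- published_logistic()
  at_thr$threshold <- b$score
  expect_identical(logistic_score(list(cbv_p10 = 3.2 / 9.526, k2_p90 = 0),
                                  at_thr)$label, 1L)
  n <- logistic_score(list(cbv_p10 = 1.0, k2_p90 = 0))
  expect_equal(n$score, -7.776)
  expect_identical(n$label, 0L)
  expect_error(logistic_score(list(cbv_p10 = 0.4)), "k2_p90")
  expect_error(logistic_score(list(cbv_p10 = NA, k2_p90 = 0.2)), "cbv_p10")
  # lower CBV / higher K2 never lowers the score
  set.seed(30)
  for (i in 1:25) {
    cbv <- runif(1, 0, 1.2); k2 <- runif(1, -0.2, 0.8)
    s0 <- logistic_score(list(cbv_p10 = cbv, k2_p90 = k2))$score
    expect_gte(logistic_score(list(cbv_p10 = cbv - runif(1, 0, 0.3),
                                   k2_p90 = k2))$score, s0)
    expect_gte(logistic_score(list(cbv_p10 = cbv,
                                   k2_p90 = k2 + runif(1, 0, 0.3)))$score, s0)
  }
})

test_that("published tree covers all quadrants under each policy", {
  expect_identical(tree_predict(list(cbv_p10 = 0.40, k2_p90 = 0.32)), 1L)
  expect_identical(tree_predict(list(cbv_p10 = 0.50, k2_p90 = 0.20)), 0L)
  # boundary values land on the PH side of each split
  expect_identical(tree_predict(list(cbv_p10 = 0.47, k2_p90 = 0.28)), 0L)
  expect_identical(tree_predict(list(cbv_p10 = 0.469, k2_p90 = 0.28)), 1L)
  # mixed quadrant (0.50, 0.30): logistic fallback scores -2.17528 -> no PH
  expect_identical(tree_predict(list(cbv_p10 = 0.50, k2_p90 = 0.30)), 0L)
  expect_identical(tree_predict(list(cbv_p10 = 0.50, k2_p90 = 0.30),
                                published_tree("root_cbv")), 0L)
  expect_identical(tree_predict(list(cbv_p10 = 0.40, k2_p90 = 0.20),
                                published_tree("root_cbv")), 1L)
  expect_identical(tree_predict(list(cbv_p10 = 0.40, k2_p90 = 0.20),
                                published_tree("majority")), 0L)
  bad <- published_tree()
  bad$policy <- "nonsense"
  expect_error(tree_predict(list(cbv_p10 = 0.5, k2_p90 = 0.3), bad),
               "unknown mixed-quadrant policy")
})

test_that("evaluate reproduces the balanced-accuracy identity exactly", {
  ev <- evaluate(counts = c(tp = 19, fn = 1, tn = 46, fp = 17))
  expect_equal(ev$report$sensitivity, 95)
  expect_equal(ev$report$specificity, 100 * 46 / 63)
  expect_equal(ev$report$overall_accuracy,
               (ev$report$sensitivity + ev$report$specificity) / 2)
  set.seed(31)
  for (i in 1:20) {
    cts <- as.list(sample(0:40, 4, replace = TRUE))
    names(cts) <- c("tp", "fn", "tn", "fp")
    if (cts$tp + cts$fn == 0 || cts$tn + cts$fp == 0) next
    ev <- evaluate(counts = cts)
    expect_identical(ev$report$overall_accuracy,
                     (ev$report$sensitivity + ev$report$specificity) / 2)
  }
  # single-class labels: the undefined rate is reported as NA
  ev <- evaluate(c(1, 0, 1), c(1, 1, 1))
  expect_true(is.na(ev$report$specificity))
})

test_that("AUC equals the exhaustive pairwise oracle, ties included", {
  expect_equal(auc_scores(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  set.seed(32)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc_scores(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("optimal_threshold matches the brute-force scan", {
  x <- c(0, 0, 0, 1, 1)
  ot <- optimal_threshold(x, x, "high")
  expect_equal(ot$eval$report$overall_accuracy, 100)
  set.seed(33)
  for (dir in c("low", "high")) for (i in 1:4) {
    n <- sample(30:200, 1)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    x <- round(rnorm(n, ifelse(labels == 1, -0.4, 0.4) *
                       ifelse(dir == "low", 1, -1)), 2)
    ot <- optimal_threshold(x, labels, dir)
    or <- oracle_best_cut(x, labels, dir)
    expect_equal(ot$threshold, or$thr)
    expect_equal(ot$eval$report$overall_accuracy, or$acc)
  }
  expect_identical(optimal_threshold(rep(1, 10), rbinom(10, 1, 0.5))$flag,
                   "constant_feature")
})

test_that("Spearman correlations match oracle; degenerate columns are NA", {
  d <- data.frame(cbv_p10 = 1:10, adc_p10 = (1:10)^3,
                  k2_p90 = c(2, 2, 5, 1, 7, 7, 3, 9, 0, 4))
  rs <- feature_correlations(d)
  expect_equal(rs$rho[rs$feature_a == "cbv_p10" &
                        rs$feature_b == "adc_p10"], 1)
  for (r in seq_len(nrow(rs)))
    expect_equal(rs$rho[r], oracle_spearman(d[[rs$feature_a[r]]],
                                            d[[rs$feature_b[r]]]))
  set.seed(34)
  big <- data.frame(cbv_p10 = rnorm(4000), adc_p10 = rnorm(4000),
                    k2_p90 = rnorm(4000))
  expect_lt(max(abs(feature_correlations(big)$rho)), 0.05)
  d$k2_p90 <- 1
  expect_true(is.na(feature_correlations(d)$rho[3]))
})

test_that("IRLS logistic agrees with the glm oracle", {
  set.seed(35)
  n <- 300
  d <- data.frame(cbv_p10 = rnorm(n, 0.5, 0.2), k2_p90 = rnorm(n, 0.3, 0.1))
  d$ph_label <- rbinom(n, 1, plogis(1.75 - 9.526 * d$cbv_p10 +
                                      2.7924 * d$k2_p90))
  fit <- fit_logistic_backward(d, c("cbv_p10", "k2_p90"), alpha = 1)
  g <- stats::glm(ph_label ~ cbv_p10 + k2_p90, data = d, family = binomial)
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(stats::coef(g)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(g)$coefficients[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("backward elimination removes null candidates and keeps signal", {
  set.seed(36)
  n <- 500
  d <- data.frame(x = rnorm(n))
  d$ph_label <- rbinom(n, 1, 0.3)            # label independent of x
  fit <- fit_logistic_backward(d, "x")
  expect_length(fit$coefficients, 0)
  # degenerate constant candidate is dropped with a warning
  d$flat <- 1
  expect_warning(fit_logistic_backward(d, c("x", "flat")), "degenerate")
})

test_that("backward elimination recovers the generating two-variable model", {
  set.seed(37)
  n <- 2000
  d <- data.frame(cbv_p10 = rnorm(n, 0.5, 0.2), k2_p90 = rnorm(n, 0.3, 0.12))
  d$ph_label <- rbinom(n, 1, plogis(1.75 - 9.526 * d$cbv_p10 +
                                      2.7924 * d$k2_p90))
  fit <- fit_logistic_backward(d, c("cbv_p10", "k2_p90"))
  expect_setequal(names(fit$coefficients), c("cbv_p10", "k2_p90"))
  expect_lt(abs(fit$coefficients[["cbv_p10"]] - (-9.526)),
            3 * fit$se[["cbv_p10"]])
  expect_lt(abs(fit$coefficients[["k2_p90"]] - 2.7924),
            3 * fit$se[["k2_p90"]])
})

test_that("perfect separation is flagged, not fatal", {
  d <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)),
                  ph_label = rep(c(0, 1), each = 20))
  fit <- fit_logistic_backward(d, "x")
  expect_true(fit$separation)
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
})

test_that("fit_tree: separable split, single leaf, oracle agreement", {
  # perfectly separable: depth-1 split at the separating midpoint
  d <- data.frame(f = c(1, 2, 3, 4, 10, 11, 12, 13, 14, 15),
                  ph_label = c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1))
  tm <- fit_tree(d, "f", max_depth = 1, min_leaf = 2)
  expect_equal(tree_thresholds(tm)$f, 7)
  expect_identical(tree_predict(list(f = 8), tm), 1L)
  expect_identical(tree_predict(list(f = 6), tm), 0L)
  # depth-1 single feature reduces to optimal_threshold on separable data
  ot <- optimal_threshold(d$f, d$ph_label, "high")
  expect_equal(tree_thresholds(tm)$f, ot$threshold)
  # all labels identical: a single leaf
  d0 <- data.frame(f = rnorm(20), ph_label = rep(0, 20))
  t0 <- fit_tree(d0, "f")
  expect_true(t0$root$leaf)
  expect_identical(t0$root$label, 0L)
  # root split equals a brute-force Gini scan
  set.seed(38)
  d2 <- data.frame(a = rnorm(120), b = rnorm(120))
  d2$ph_label <- rbinom(120, 1, plogis(1.5 * d2$a - d2$b))
  tm2 <- fit_tree(d2, c("a", "b"), max_depth = 1, min_leaf = 5)
  gini <- function(p, n) { pp <- p / n; 2 * pp * (1 - pp) }
  best <- NULL
  n <- nrow(d2)
  parent <- gini(sum(d2$ph_label), n)
  for (f in c("a", "b")) {
    ux <- sort(unique(d2[[f]]))
    for (thr in (ux[-1] + ux[-length(ux)]) / 2) {
      l <- d2[[f]] < thr
      if (sum(l) < 5 || sum(!l) < 5) next
      dec <- parent - (sum(l) * gini(sum(d2$ph_label[l]), sum(l)) +
                         sum(!l) * gini(sum(d2$ph_label[!l]), sum(!l))) / n
      if (is.null(best) || dec > best$dec + 1e-12)
        best <- list(dec = dec, f = f, thr = thr)
    }
  }
  expect_identical(tm2$root$feature, best$f)
  expect_equal(tm2$root$threshold, best$thr)
})

test_that("fit_tree recovers generating thresholds on margined cohorts", {
  set.seed(39)
  n <- 1000
  margin <- function(v, lo, hi) v[v < lo | v > hi][seq_len(n)]
  cbv <- margin(runif(3 * n, 0.1, 0.9), 0.46, 0.48)
  k2 <- margin(runif(3 * n, 0, 0.6), 0.27, 0.29)
  d <- data.frame(cbv_p10 = cbv, k2_p90 = k2)
  d$ph_label <- as.integer(cbv < 0.47 & k2 >= 0.28)
  tm <- fit_tree(d, c("cbv_p10", "k2_p90"))
  th <- tree_thresholds(tm)
  expect_true(any(abs(th$cbv_p10 - 0.47) <= 0.011))
  expect_true(any(abs(th$k2_p90 - 0.28) <= 0.011))
})
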