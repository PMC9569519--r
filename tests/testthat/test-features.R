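test_that("min-max constants store the data range and reject degenerate input", {
  c1 <- fit_minmax(c(0, 5, 10))
  expect_equal(c(c1$x_min, c1$x_max), c(0, 10))
  c2 <- fit_minmax(c(-1, 1))
  expect_equal(c(c2$x_min, c2$x_max), c(-1, 1))
  expect_error(fit_minmax(500), "degenerate")
  expect_error(fit_minmax(rep(3, 10)), "degenerate")
})

test_that("min-max maps the range onto [0,1], clamps, and is monotone", {
  cn <- fit_minmax(c(0, 10))
  expect_equal(apply_minmax(0, cn), 0)
  expect_equal(apply_minmax(10, cn), 1)
  expect_equal(apply_minmax(2.5, cn), 0.25)
  expect_equal(apply_minmax(-5, cn), 0)   # clamped below
  expect_equal(apply_minmax(20, cn), 1)   # clamped above
  set.seed(8)
  x <- sort(rnorm(200, 5, 6))
  y <- apply_minmax(x, cn)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 0 & y <= 1))
})

test_that("class weights follow w = (1/S)(T/2) and conserve weighted mass", {
  w <- class_weights(50, 50)
  expect_equal(c(w$w_pos, w$w_neg), c(1, 1))
  w <- class_weights(25, 75)
  expect_equal(w$w_pos, 2)
  expect_equal(w$w_neg, 2 / 3)
  expect_equal(w$w_pos * 25 + w$w_neg * 75, 100)
  expect_error(class_weights(0, 10), "empty class")
})

test_that("binary metrics match hand counts and brute-force tallies", {
  # TP=3 FP=1 FN=2 TN=4
  pred <- c(rep(TRUE, 4), rep(FALSE, 6))
  act <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, rep(FALSE, 4))
  m <- binary_metrics(pred, act)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  # perfect predictor
  m2 <- binary_metrics(act, act)
  expect_equal(unlist(m2), c(accuracy = 1, precision = 1, recall = 1))
  # all-negative predictions: recall 0, precision undefined
  m3 <- binary_metrics(rep(FALSE, 10), act)
  expect_equal(m3$recall, 0)
  expect_true(is.na(m3$precision))
  expect_error(binary_metrics(TRUE, c(TRUE, FALSE)), "length")
  # brute force on random instances
  set.seed(31)
  for (i in 1:10) {
    p <- runif(50) > 0.5; a <- runif(50) > 0.4
    m <- binary_metrics(p, a)
    cm <- table(factor(p, c(FALSE, TRUE)), factor(a, c(FALSE, TRUE)))
    expect_equal(m$accuracy, (cm[1, 1] + cm[2, 2]) / 50)
    if (sum(p) > 0) expect_equal(m$precision, cm[2, 2] / sum(p))
    if (sum(a) > 0) expect_equal(m$recall, cm[2, 2] / sum(a))
  }
})

test_that("AUROC agrees with brute-force pair counting", {
  set.seed(12)
  for (i in 1:5) {
    s <- round(runif(40), 2)  # ties included
    y <- runif(40) > 0.5
    if (!any(y) || all(y)) next
    pos <- s[y]; neg <- s[!y]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auroc(s, y), brute)
  }
})

test_that("binding calls use IC50 < 500 and percentile < 1, both strict", {
  expect_true(threshold_binding(499, 0.5))
  expect_false(threshold_binding(500, 0.5))
  expect_false(threshold_binding(100, 2.0))
  expect_false(threshold_binding(100, 1.0))
  expect_identical(threshold_binding(c(1, 600), c(0.1, 0.1)),
                   c(TRUE, FALSE))
})

test_that("distribution comparison annotates significance like the figure convention", {
  set.seed(2)
  g <- rnorm(50)
  same <- compare_distributions(g, g)
  expect_identical(same$annotation, "ns")
  expect_gt(same$p_value, 0.05)
  sep <- compare_distributions(rnorm(50, 0, 0.1), rnorm(50, 5, 0.1))
  expect_lt(sep$p_value, 1e-4)
  expect_identical(sep$annotation, "****")
  expect_error(compare_distributions(1, c(1, 2)), "at least 2")
})

test_that("rank-sum p agrees with a permutation oracle on small samples", {
  set.seed(77)
  a <- rnorm(20, 0.6); b <- rnorm(20)
  obs <- compare_distributions(a, b)
  pool <- c(a, b)
  ref <- sum(rank(pool)[1:20])
  obs_dev <- abs(ref - 20 * 41 / 2)
  perm <- replicate(10000, {
    r <- rank(pool)[sample(40)][1:20]
    abs(sum(r) - 20 * 41 / 2)
  })
  p_perm <- mean(perm >= obs_dev)
  expect_lt(abs(obs$p_value - p_perm), 0.03)  # within Monte-Carlo error
})

test_that("Pearson correlation matches the closed form and flags degeneracy", {
  x <- c(1, 2, 4, 8, 9.5)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  y <- c(2, 1, 5, 7, 11)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y)$r, manual)
  set.seed(4)
  ind <- pearson_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(ind$r), 0.1)
  expect_error(pearson_correlation(x, rep(1, 5)), "zero variance")
  expect_error(pearson_correlation(x, c(1, 2)), "length")
})
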