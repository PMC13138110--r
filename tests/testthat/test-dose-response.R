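test_that("grouping assigns consecutive sorted patients to groups of 11 plus remainder", {
  set.seed(2)
  g73 <- group_patients(runif(73, 0, 300), runif(73) < 0.4)
  expect_equal(g73$n, c(rep(11, 6), 7))
  expect_equal(nrow(g73), 7)
  expect_false(is.unsorted(g73$median_value))
  g11 <- group_patients(runif(11), rep(c(TRUE, FALSE), c(5, 6)))
  expect_equal(nrow(g11), 1)
  g25 <- group_patients(runif(25), runif(25) < 0.5)
  expect_equal(g25$n, c(11, 11, 3))
  expect_error(group_patients(runif(10), runif(10) < 0.5),
               class = "lutadose_input_error")
  # groups partition the cohort
  expect_equal(sort(unname(unlist(attr(g73, "members")))), 1:73)
})

test_that("sigmoid fit recovers exact generating parameters", {
  d <- seq(20, 280, length.out = 7)
  y <- sigmoid_response(d, pmax = 100, dhalf = 135, k = 58)
  fit <- fit_sigmoid(data.frame(median_value = d, prop_pr_pct = y))
  expect_equal(fit$pmax, 100, tolerance = 1e-4)
  expect_equal(fit$dhalf, 135, tolerance = 1e-4)
  expect_equal(fit$k, 58, tolerance = 1e-4)
  expect_equal(fit$quality$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$quality$rmse, 0, tolerance = 1e-6)
})

test_that("sigmoid fit SSE matches the grid-search oracle on noisy groups", {
  set.seed(14)
  for (rep in 1:4) {
    d <- sort(runif(8, 10, 300))
    y <- pmin(100, pmax(0, sigmoid_response(d, 90, 140, 50) + rnorm(8, 0, 8)))
    fit <- fit_sigmoid(data.frame(median_value = d, prop_pr_pct = y))
    oracle <- grid_sigmoid_sse(d, y)
    expect_lte(fit$sse, oracle * (1 + 1e-4) + 1e-10)
  }
  expect_error(fit_sigmoid(data.frame(median_value = 1:2,
                                      prop_pr_pct = c(0, 1))),
               class = "lutadose_input_error")
})

test_that("goodness-of-fit closed forms match hand arithmetic", {
  q <- fit_quality(c(0, 50, 100), c(10, 50, 90))
  expect_equal(q$r_squared, 0.96)
  expect_equal(q$rmse, sqrt(200 / 3), tolerance = 1e-9)
  expect_equal(round(q$rmse, 4), 8.1650)
  perfect <- fit_quality(c(10, 40, 80), c(10, 40, 80))
  expect_equal(perfect$r_squared, 1)
  expect_equal(perfect$rmse, 0)
  at_mean <- fit_quality(c(0, 50, 100), rep(50, 3))
  expect_equal(at_mean$r_squared, 0)
  flat <- fit_quality(rep(40, 3), c(30, 40, 50))
  expect_true(flat$zero_variance)
  expect_true(is.na(flat$r_squared))
})

test_that("2D logistic regression recovers generating coefficients and is duplication-invariant", {
  set.seed(21)
  n <- 1e4
  cad <- runif(n, 0, 300); delta <- runif(n, -70, 20)
  b <- c(-2, 0.015, -0.03)
  p <- 1 / (1 + exp(-(b[1] + b[2] * cad + b[3] * delta)))
  y <- runif(n) < p
  fit <- fit_logistic_2d(cad, delta, y)
  expect_equal(fit$beta0, b[1], tolerance = 0.10)
  expect_equal(fit$beta1, b[2], tolerance = 0.10)
  expect_equal(fit$beta2, b[3], tolerance = 0.10)
  # likelihood is invariant under record duplication
  fit2 <- fit_logistic_2d(rep(cad, 2), rep(delta, 2), rep(y, 2))
  expect_equal(fit2$beta1, fit$beta1, tolerance = 1e-6)
  # uninformative features: slopes near zero, intercept near the log-odds
  y0 <- rep(c(TRUE, FALSE), n / 2)
  fit0 <- fit_logistic_2d(cad, delta, y0)
  expect_equal(fit0$beta1, 0, tolerance = 3 * 2 / (sd(cad) * sqrt(n)))
  expect_equal(fit0$beta0, 0, tolerance = 0.15)
})

test_that("complete separation is flagged", {
  cad <- c(1:10, 101:110); y <- rep(c(FALSE, TRUE), each = 10)
  expect_warning(fit <- fit_logistic_2d(cad, rnorm(20), y), "separation")
  expect_true(fit$separation)
})

test_that("RBF-SVM separates nonlinear structure a linear boundary cannot", {
  # linearly separable toy set: perfect training accuracy
  set.seed(82)
  x <- rbind(matrix(rnorm(40, -3, 0.5), 20), matrix(rnorm(40, 3, 0.5), 20))
  y <- rep(c(FALSE, TRUE), each = 20)
  fit <- fit_svm_rbf(x, y, c_param = 100)
  expect_equal(mean((fit$scores > 0) == y), 1)
  # XOR pattern: RBF achieves perfect training accuracy, linear cannot
  # exceed 75%
  xor_x <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))
  xor_x <- xor_x[rep(1:4, each = 10), ] + matrix(rnorm(80, 0, 0.05), 40)
  xor_y <- (xor_x[, 1] * xor_x[, 2]) > 0
  rbf <- fit_svm_rbf(xor_x, xor_y, c_param = 10)
  expect_equal(mean((rbf$scores > 0) == xor_y), 1)
  lin <- e1071::svm(x = xor_x, y = factor(xor_y), kernel = "linear", cost = 10)
  expect_lte(mean(predict(lin, xor_x) == factor(xor_y)), 0.75)
  # flipping labels negates the oriented decision scores
  flip <- fit_svm_rbf(x, !y, c_param = 100)
  expect_equal(flip$scores, -fit$scores, tolerance = 1e-6)
})

test_that("AUC equals the brute-force pairwise ordering oracle and handles ties", {
  set.seed(33)
  labels <- runif(50) < 0.4
  scores <- rnorm(50) + labels
  expect_equal(auc_rank(scores, labels), pairwise_auc(scores, labels))
  # tied scores
  tied <- round(scores)
  expect_equal(auc_rank(tied, labels), pairwise_auc(tied, labels))
  # perfect scores
  expect_equal(auc_rank(as.numeric(labels), labels), 1)
  # random scores at large n approach 1/2
  big <- runif(1e4) < 0.3
  expect_equal(auc_rank(rnorm(1e4), big), 0.5, tolerance = 0.02)
  # invariance under strictly monotone transform
  expect_equal(auc_rank(exp(3 * scores), labels), auc_rank(scores, labels))
})

test_that("sigmoid-model patient scores give exactly the AUC of cAD alone", {
  set.seed(40)
  cad <- runif(200, 0, 300)
  y <- runif(200) < sigmoid_response(cad, 100, 135, 58) / 100
  p_scores <- sigmoid_response(cad, 100, 135, 58)
  expect_equal(auc_rank(p_scores, y), auc_rank(cad, y))
})

test_that("stratified folds are class-balanced and seeded", {
  y <- rep(c(TRUE, FALSE), c(28, 45))
  f1 <- stratified_folds(y, 5, seed = 11)
  f2 <- stratified_folds(y, 5, seed = 11)
  expect_identical(f1, f2)
  for (cls in c(TRUE, FALSE)) {
    tab <- table(f1[y == cls])
    expect_lte(diff(range(tab)), 1)
    expect_equal(length(tab), 5)
  }
  expect_error(stratified_folds(rep(c(TRUE, FALSE), c(3, 50)), 5),
               class = "lutadose_input_error")
})

test_that("cross-validated AUC behaves sanely on informative and null data", {
  set.seed(55)
  n <- 200
  cad <- runif(n, 0, 300); delta <- runif(n, -70, 20)
  p <- 1 / (1 + exp(-(-2 + 0.015 * cad - 0.03 * delta)))
  y <- runif(n) < p
  ev <- crossval_auc("logistic", cad, delta, y, seed = 3)
  expect_gt(ev$auc, 0.6)
  expect_equal(length(ev$fold_auc), 5)
  expect_equal(length(ev$scores), n)
  # labels as scores: perfect ranking
  expect_equal(auc_rank(as.numeric(y), y), 1)
  # null features: pooled AUC near 1/2
  ev0 <- crossval_auc("logistic", rnorm(n), rnorm(n), rep(c(TRUE, FALSE), n / 2),
                      seed = 3)
  expect_lt(abs(ev0$auc - 0.5), 0.12)
})

test_that("two-feature models beat single-feature models when both features matter", {
  set.seed(60)
  wins <- replicate(20, {
    n <- 300
    cad <- runif(n, 0, 300); delta <- runif(n, -70, 20)
    p <- 1 / (1 + exp(-(-1.5 + 0.012 * cad - 0.04 * delta)))
    y <- runif(n) < p
    if (sum(y) < 5 || sum(!y) < 5) return(NA)
    both <- crossval_auc("logistic", cad, delta, y, seed = 1)$auc
    single <- max(crossval_auc("cad_only", cad, delta, y, seed = 1)$auc,
                  crossval_auc("delta_only", cad, delta, y, seed = 1)$auc)
    both > single
  })
  expect_gt(mean(wins, na.rm = TRUE), 0.7)
})

test_that("rank tests match their oracles and flag degenerate input", {
  # identical paired samples: test undefined, flagged, p reported as 1
  r <- rank_test(1:8, 1:8, paired = TRUE)
  expect_true(r$flagged)
  expect_equal(r$p_value, 1)
  # signed-rank p within 2% of the full sign-flip permutation oracle
  set.seed(71)
  for (rep in 1:3) {
    x <- rnorm(10); y <- x + rnorm(10, 0.4)
    got <- rank_test(x, y, paired = TRUE)$p_value
    expect_equal(got, permutation_signed_rank_p(x, y), tolerance = 0.02)
  }
  # rank-sum on shifted samples is significant, on identical populations not
  set.seed(72)
  a <- rnorm(30); b <- rnorm(30) + 2
  expect_lt(rank_test(a, b)$p_value, 1e-6)
  # perfectly monotone pair: Spearman rho = 1
  expect_equal(spearman_test(1:20, (1:20)^3)$rho, 1)
  expect_equal(spearman_test(1:20, -(1:20)^3)$rho, -1)
  sp <- spearman_test(rnorm(50), rnorm(50))
  expect_gt(sp$p_value, 0.001)
})
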