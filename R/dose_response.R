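#' Group patients by a dose metric for grouped response analysis
#'
#' Patients are sorted in ascending order of the metric (stable sort: ties
#' keep original order) and assigned consecutively to groups of `group_size`,
#' with the final group containing the remaining cases. For each group the
#' median metric and the proportion achieving partial response are recorded.
#'
#' @param values numeric dose metric, one per patient (e.g. cAD in Gy).
#' @param is_pr logical, TRUE for patients with partial response.
#' @param group_size patients per group (default 11).
#' @return data.frame with one row per group: `group`, `n`, `median_value`,
#'   `prop_pr_pct` (percent). Member indices (into the input order) are
#'   attached as attribute `members`.
#' @examples
#' set.seed(1)
#' group_patients(runif(73, 0, 300), runif(73) < 0.4)
#' @export
group_patients <- function(values, is_pr, group_size = 11) {
  n <- length(values)
  if (length(is_pr) != n)
    lutadose_input_error("values and is_pr must have equal length")
  if (n < group_size)
    lutadose_input_error(sprintf("need at least %d patients, got %d",
                                 group_size, n))
  ord <- order(values)                       # stable: ties by original order
  n_full <- n %/% group_size
  sizes <- rep(group_size, n_full)
  if (n %% group_size != 0) sizes <- c(sizes, n %% group_size)
  idx_group <- rep(seq_along(sizes), sizes)
  members <- split(ord, idx_group)
  out <- data.frame(
    group = seq_along(members),
    n = lengths(members),
    median_value = vapply(members, function(i) median(values[i]), numeric(1)),
    prop_pr_pct = vapply(members, function(i) mean(is_pr[i]) * 100, numeric(1)))
  rownames(out) <- NULL
  attr(out, "members") <- members
  out
}

#' Sigmoid dose-response curve
#'
#' \deqn{P_{PR}(d) = P_{max} / (1 + e^{-(d - D_{half})/k})}
#' with `pmax` in percent.
#'
#' @param d dose metric values (Gy).
#' @param pmax plateau response probability, percent.
#' @param dhalf dose at half-plateau, Gy.
#' @param k steepness scale, Gy.
#' @return predicted response probability in percent.
#' @export
sigmoid_response <- function(d, pmax, dhalf, k) {
  pmax / (1 + exp(-(d - dhalf) / k))
}

#' Fit the sigmoid dose-response model to grouped data
#'
#' Unweighted least-squares fit of [sigmoid_response()] to per-group
#' (median dose, percent PR) pairs, with the plateau constrained to
#' \[0, 100\] percent and the steepness scale positive. The plateau enters
#' the model linearly and is profiled out; the remaining two parameters are
#' optimised by Levenberg-Marquardt from a grid of starting values.
#'
#' @param groups data.frame from [group_patients()] (columns `median_value`,
#'   `prop_pr_pct`), or any data.frame with those columns; >= 3 groups.
#' @return list of class `sigmoid_fit` with elements `pmax` (%), `dhalf`
#'   (Gy), `k` (Gy), `fitted` (%), `quality` (a [fit_quality()] result over
#'   the groups) and `sse`.
#' @export
fit_sigmoid <- function(groups) {
  d <- groups$median_value
  y <- groups$prop_pr_pct
  if (length(d) < 3)
    lutadose_input_error("at least 3 groups are required for the sigmoid fit")

  profile_pmax <- function(dhalf, k) {
    s <- 1 / (1 + exp(-(d - dhalf) / k))
    denom <- sum(s * s)
    if (denom <= 0) return(list(pmax = NA_real_, sse = Inf, s = s))
    pmax <- min(100, max(0, sum(y * s) / denom))
    list(pmax = pmax, sse = sum((pmax * s - y)^2), s = s)
  }
  resid_fn <- function(theta) {
    pr <- profile_pmax(theta[1], exp(theta[2]))
    if (!is.finite(pr$sse)) return(rep(1e150, length(y)))
    pr$pmax * pr$s - y
  }
  span <- diff(range(d))
  # coarse profiled-SSE grid seeds the local optimiser alongside fixed
  # quantile starts; the surface can be multimodal when the plateau clip is
  # active
  grid <- expand.grid(dhalf = seq(min(d), max(d), length.out = 15),
                      logk = log(pmax(span * c(0.02, 0.05, 0.1, 0.2, 0.5, 1),
                                      1e-6)))
  grid_sse <- vapply(seq_len(nrow(grid)), function(i)
    profile_pmax(grid$dhalf[i], exp(grid$logk[i]))$sse, numeric(1))
  starts <- rbind(
    grid[order(grid_sse)[1:3], ],
    expand.grid(dhalf = quantile(d, c(0.25, 0.5, 0.75), names = FALSE),
                logk = log(pmax(span * c(0.05, 0.2, 0.5), 1e-6))))
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    try(minpack.lm::nls.lm(
      par = c(starts$dhalf[i], starts$logk[i]), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0)),
      silent = TRUE)
  })
  fits <- Filter(function(f) !inherits(f, "try-error"), fits)
  if (length(fits) == 0)
    lutadose_fit_error("sigmoid dose-response fit failed to converge",
                       diagnostics = list(d = d, y = y))
  sses <- vapply(fits, function(f) sum(resid_fn(f$par)^2), numeric(1))
  best <- fits[[which.min(sses)]]
  dhalf <- best$par[1]; k <- exp(best$par[2])
  pr <- profile_pmax(dhalf, k)
  fitted <- pr$pmax * pr$s
  structure(list(pmax = pr$pmax, dhalf = dhalf, k = k, fitted = fitted,
                 quality = fit_quality(y, fitted), sse = pr$sse),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("Sigmoid dose-response fit: Pmax = %.1f%%, Dhalf = %.1f Gy, k = %.1f Gy\n",
              x$pmax, x$dhalf, x$k))
  cat(sprintf("  R^2 = %.3f, RMSE = %.2f%% over %d groups\n",
              x$quality$r_squared, x$quality$rmse, x$quality$n_groups))
  invisible(x)
}

#' Goodness-of-fit of grouped response proportions
#'
#' \eqn{R^2 = 1 - \sum(o_i - p_i)^2 / \sum(o_i - \bar o)^2} and
#' \eqn{RMSE = \sqrt{\sum(o_i - p_i)^2 / n}}, both on the percent scale of
#' the proportions.
#'
#' @param observed_pct observed percent-PR per group.
#' @param predicted_pct model-predicted percent-PR per group.
#' @return list with `r_squared` (NA and `zero_variance = TRUE` when the
#'   observed values have no variance), `rmse` (%), `n_groups`.
#' @export
fit_quality <- function(observed_pct, predicted_pct) {
  if (length(observed_pct) != length(predicted_pct) || length(observed_pct) < 2)
    lutadose_input_error("observed and predicted must have equal length >= 2")
  sse <- sum((observed_pct - predicted_pct)^2)
  sst <- sum((observed_pct - mean(observed_pct))^2)
  list(r_squared = if (sst > 0) 1 - sse / sst else NA_real_,
       rmse = sqrt(sse / length(observed_pct)),
       n_groups = length(observed_pct),
       zero_variance = sst == 0)
}

#' Two-feature logistic response model
#'
#' Unpenalised maximum-likelihood logistic regression of responder status on
#' cumulative absorbed dose and the cyclic AD/AA change:
#' \eqn{P_{PR} = 1/(1 + e^{-(\beta_0 + \beta_1 cAD + \beta_2 \Delta AD/AA)})}.
#'
#' @param cad cumulative absorbed dose, Gy.
#' @param delta_adaa percent change in AD/AA, cycle 1 to final.
#' @param responder logical (or 0/1) response labels; both classes must be
#'   present.
#' @return list of class `logistic2d_fit`: `beta0`, `beta1` (per Gy), `beta2`
#'   (per %), `fitted` probabilities, `separation` flag (TRUE when the
#'   classes are completely separable and the MLE diverges), and the `glm`
#'   object.
#' @export
fit_logistic_2d <- function(cad, delta_adaa, responder) {
  responder <- as.logical(responder)
  if (length(unique(responder)) < 2)
    lutadose_input_error("both responder classes must be present")
  if (!all(is.finite(cad)) || !all(is.finite(delta_adaa)))
    lutadose_input_error("features must be finite")
  df <- data.frame(y = responder, cad = cad, delta = delta_adaa)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ cad + delta, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  # glm does not always warn on clean separation: a residual deviance of
  # ~0 or an extreme linear predictor are equivalent symptoms of a
  # diverging MLE
  if (!sep && (fit$deviance < 1e-6 ||
               max(abs(predict(fit, type = "link"))) > 25))
    sep <- TRUE
  if (sep)
    warning("complete or quasi-complete separation: logistic coefficients diverge",
            call. = FALSE)
  structure(list(beta0 = unname(cf[1]), beta1 = unname(cf[2]),
                 beta2 = unname(cf[3]),
                 fitted = unname(fit$fitted.values),
                 separation = sep, glm = fit),
            class = "logistic2d_fit")
}

#' @export
predict.logistic2d_fit <- function(object, newdata, ...) {
  unname(predict(object$glm,
                 newdata = data.frame(cad = newdata$cad,
                                      delta = newdata$delta_adaa),
                 type = "response"))
}

#' RBF-kernel support-vector response classifier
#'
#' Gaussian-kernel SVM separating responders from nonresponders in the
#' (cAD, delta AD/AA) plane; features are standardized internally. Returned
#' decision scores are oriented so that larger values are more
#' responder-like.
#'
#' @param features numeric matrix or data.frame of features (rows =
#'   patients).
#' @param responder logical labels, both classes present and each with >= 2
#'   members.
#' @param c_param soft-margin cost (default 1).
#' @param gamma kernel width; default `1/ncol(features)` on the standardized
#'   scale.
#' @return list of class `svm_rbf_fit` with the fitted `e1071::svm` model,
#'   the score `orientation` sign, and `scores` on the training data.
#' @export
fit_svm_rbf <- function(features, responder, c_param = 1, gamma = NULL) {
  x <- as.matrix(features)
  responder <- as.logical(responder)
  if (length(unique(responder)) < 2 || min(table(responder)) < 2)
    lutadose_input_error("each class needs at least 2 members")
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  y <- factor(ifelse(responder, "responder", "nonresponder"),
              levels = c("nonresponder", "responder"))
  model <- e1071::svm(x = x, y = y, kernel = "radial", cost = c_param,
                      gamma = gamma, scale = TRUE)
  dv <- attr(predict(model, x, decision.values = TRUE), "decision.values")[, 1]
  # e1071's decision-value sign convention depends on class ordering in the
  # training data; fix the orientation empirically on the training labels.
  orientation <- if (mean(dv[responder]) >= mean(dv[!responder])) 1 else -1
  structure(list(model = model, orientation = orientation,
                 scores = orientation * dv),
            class = "svm_rbf_fit")
}

#' @export
predict.svm_rbf_fit <- function(object, newdata, ...) {
  dv <- attr(predict(object$model, as.matrix(newdata),
                     decision.values = TRUE), "decision.values")[, 1]
  object$orientation * dv
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' \eqn{AUC = (\sum_i r_i - n_1(n_1+1)/2) / (n_1 n_0)} where the \eqn{r_i}
#' are mid-ranks of the positive-class scores; ties contribute 1/2, so the
#' value equals the probability that a random positive outranks a random
#' negative (ties counted half).
#'
#' @param scores numeric classifier scores, higher = more positive-like.
#' @param labels logical (or 0/1) class labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    lutadose_input_error("both classes must be present to compute AUC")
  r <- rank(scores)                          # mid-ranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams auc_rank
#' @return data.frame of `fpr`, `tpr` swept over all score thresholds.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[ord]); fp <- cumsum(!labels[ord])
  keep <- c(diff(scores[ord]) != 0, TRUE)    # one point per distinct threshold
  data.frame(fpr = c(0, fp[keep] / sum(!labels)),
             tpr = c(0, tp[keep] / sum(labels)))
}

#' Seeded class-stratified fold assignment
#'
#' @param labels logical class labels.
#' @param n_folds number of folds.
#' @param seed RNG seed for the shuffle.
#' @return integer fold id per observation; within each class the fold sizes
#'   differ by at most 1.
#' @export
stratified_folds <- function(labels, n_folds = 5, seed = 1L) {
  labels <- as.logical(labels)
  if (min(table(labels)) < n_folds)
    lutadose_input_error(sprintf(
      "each class needs >= %d members for %d stratified folds",
      n_folds, n_folds))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated ROC evaluation of a response classifier
#'
#' Stratified (class-balanced) k-fold cross-validation: the model is fitted
#' on each training fold and scores the held-out fold; out-of-fold scores
#' are pooled and the pooled AUC computed by [auc_rank()]. Per-fold AUCs are
#' also reported.
#'
#' @param model `"logistic"` (two-feature logistic regression), `"svm"`
#'   (RBF-kernel SVM), or `"cad_only"` / `"delta_only"` (the raw single
#'   feature as score, sign-oriented so higher = more responder-like).
#' @param cad,delta_adaa patient dose metrics.
#' @param responder logical labels.
#' @param n_folds folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param ... passed to the underlying fit function.
#' @return list of class `classifier_eval`: `auc` (pooled), `fold_auc`,
#'   `scores` (pooled out-of-fold), `folds`, `roc` points, `model`, `seed`.
#' @export
crossval_auc <- function(model = c("logistic", "svm", "cad_only", "delta_only"),
                         cad, delta_adaa, responder, n_folds = 5, seed = 1L,
                         ...) {
  model <- match.arg(model)
  responder <- as.logical(responder)
  folds <- stratified_folds(responder, n_folds, seed)
  scores <- numeric(length(responder))
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    if (length(unique(responder[tr])) < 2)
      lutadose_input_error("a class is absent from a training fold")
    scores[te] <- switch(model,
      logistic = {
        fit <- fit_logistic_2d(cad[tr], delta_adaa[tr], responder[tr])
        predict(fit, data.frame(cad = cad[te], delta_adaa = delta_adaa[te]))
      },
      svm = {
        fit <- fit_svm_rbf(cbind(cad = cad[tr], delta = delta_adaa[tr]),
                           responder[tr], ...)
        predict(fit, cbind(cad = cad[te], delta = delta_adaa[te]))
      },
      cad_only = cad[te],
      # decline is protective: more negative delta is more responder-like
      delta_only = -delta_adaa[te])
  }
  fold_auc <- vapply(seq_len(n_folds), function(f)
    auc_rank(scores[folds == f], responder[folds == f]), numeric(1))
  structure(list(auc = auc_rank(scores, responder), fold_auc = fold_auc,
                 scores = scores, folds = folds,
                 roc = roc_points(scores, responder),
                 model = model, seed = seed),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("%s classifier, %d-fold stratified CV (seed %d): pooled AUC = %.3f\n",
              x$model, length(x$fold_auc), x$seed, x$auc))
  cat(sprintf("  per-fold AUC: %s\n",
              paste(sprintf("%.3f", x$fold_auc), collapse = " ")))
  invisible(x)
}

#' Rank-based two-sample / paired test
#'
#' Wilcoxon signed-rank test for paired samples, Wilcoxon rank-sum
#' (Mann-Whitney) for independent samples; two-sided, exact for small
#' tie-free samples and normal-approximated otherwise (the standard
#' definitions as implemented in [stats::wilcox.test()]).
#'
#' @param x,y numeric samples.
#' @param paired TRUE for the signed-rank test on `x - y`.
#' @return list with `statistic`, `p_value`, `method`, `flagged` (TRUE when
#'   all paired differences are zero, in which case the test is undefined
#'   and `p_value` is reported as 1).
#' @export
rank_test <- function(x, y, paired = FALSE) {
  if (paired && length(x) != length(y))
    lutadose_input_error("paired samples must have equal length")
  if (paired && all(x == y)) {
    return(list(statistic = NA_real_, p_value = 1,
                method = "Wilcoxon signed rank test (degenerate: all differences zero)",
                flagged = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(x, y, paired = paired,
                                     alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = wt$method, flagged = FALSE)
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors.
#' @return list with `rho` and two-sided `p_value`.
#' @export
spearman_test <- function(x, y) {
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
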