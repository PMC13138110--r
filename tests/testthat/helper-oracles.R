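# Independent oracles used across test files.

# Quadrature oracle for the time-integrated dose: adaptive quadrature on a
# finite window plus the analytic exponential tail.
quadrature_dose <- function(A, lambda1, lambda2) {
  t_max <- 10 * log(2) / lambda1
  head <- stats::integrate(function(u) A * (exp(-lambda1 * u) - exp(-lambda2 * u)),
                           0, t_max, rel.tol = 1e-12, abs.tol = 0)$value
  tail <- A * (exp(-lambda1 * t_max) / lambda1 - exp(-lambda2 * t_max) / lambda2)
  head + tail
}

# Grid-search + local-refinement oracle for the biexponential SSE. Profiles
# the amplitude (linear parameter) on a dense (lambda1, lambda2) grid, then
# polishes the best grid cell with Nelder-Mead. Independent of the package's
# Levenberg-Marquardt path.
grid_biexp_sse <- function(time_h, doserate, lambda_floor = 0) {
  sse_at <- function(l1, l2) {
    f <- exp(-l1 * time_h) - exp(-l2 * time_h)
    A <- sum(doserate * f) / sum(f * f)
    if (!is.finite(A) || A <= 0) return(Inf)
    sum((A * f - doserate)^2)
  }
  l1_grid <- exp(seq(log(1e-4), log(0.2), length.out = 120))
  if (lambda_floor > 0) l1_grid <- pmax(l1_grid, lambda_floor)
  best <- list(sse = Inf)
  for (l1 in l1_grid) for (mult in exp(seq(log(1.05), log(400), length.out = 120))) {
    s <- sse_at(l1, l1 * mult)
    if (s < best$sse) best <- list(sse = s, l1 = l1, mult = mult)
  }
  ref <- stats::optim(c(log(best$l1 - lambda_floor + 1e-12), log(best$mult - 1)),
                      function(p) {
                        l1 <- lambda_floor + exp(p[1])
                        sse_at(l1, l1 * (1 + exp(p[2])))
                      },
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best$sse, ref$value)
}

# Grid + refinement oracle for the sigmoid dose-response SSE (pmax profiled).
grid_sigmoid_sse <- function(d, y) {
  sse_at <- function(dhalf, k) {
    s <- 1 / (1 + exp(-(d - dhalf) / k))
    pmax_hat <- min(100, max(0, sum(y * s) / sum(s * s)))
    sum((pmax_hat * s - y)^2)
  }
  best <- Inf
  for (dhalf in seq(min(d), max(d), length.out = 150))
    for (k in exp(seq(log(diff(range(d)) / 100), log(diff(range(d))), length.out = 100))) {
      s <- sse_at(dhalf, k)
      if (s < best) { best <- s; at <- c(dhalf, log(k)) }
    }
  ref <- stats::optim(at, function(p) sse_at(p[1], exp(p[2])),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  min(best, ref$value)
}

# Brute-force pairwise-ordering AUC oracle (ties count 1/2).
pairwise_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Full sign-flip permutation oracle for the two-sided Wilcoxon signed-rank
# p-value (no ties, no zeros).
permutation_signed_rank_p <- function(x, y) {
  d <- x - y
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

default_4cycle_quadruple <- function(adaa = c(3.2, 3.1, 2.4, 2.1), aa = 7.4) {
  data.frame(lesion_id = "L1", cycle = 1:4, ad_gy = adaa * aa, aa_gbq = aa)
}
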