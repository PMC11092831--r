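# Brute-force oracles, kept deliberately independent of the package's
# computational paths: explicit normal equations, loops, no shared helpers.

ols_oracle <- function(y, x, covars = NULL) {
  X <- cbind(1, x)
  if (!is.null(covars)) X <- cbind(X, as.matrix(covars))
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  se <- unname(sqrt(drop(sum(res^2) / df) * diag(XtXi)))
  tstat <- unname(beta[2] / se[2])
  list(beta = unname(beta[2]), se = se[2], statistic = tstat,
       p_value = 2 * pt(-abs(tstat), df))
}

drm_oracle <- function(y, g) {
  z <- numeric(length(y))
  for (gv in unique(g)) {
    z[g == gv] <- abs(y[g == gv] - median(y[g == gv]))
  }
  ols_oracle(z, g)
}

ivw_meta_oracle <- function(betas, ses) {
  w <- 1 / ses^2
  b <- sum(w * betas) / sum(w)
  s <- sqrt(1 / sum(w))
  list(beta = b, se = s, z = b / s, p = 2 * pnorm(-abs(b / s)))
}

ivw_mr_oracle <- function(b_exp, b_out, se_out) {
  num <- 0; den <- 0
  for (j in seq_along(b_exp)) {
    num <- num + b_exp[j] * b_out[j] / se_out[j]^2
    den <- den + b_exp[j]^2 / se_out[j]^2
  }
  beta <- num / den
  Q <- sum((b_out - beta * b_exp)^2 / se_out^2)
  list(beta = beta, se_fixed = sqrt(1 / den), Q = Q)
}

# Expected OLS slope of the half-normal class means on allele count under
# Binomial(2, p) class weights.
halfnormal_slope_oracle <- function(p, var_by_g) {
  g <- 0:2
  fg <- dbinom(g, 2, p)
  mu <- sqrt(2 / pi) * sqrt(var_by_g)
  gbar <- sum(fg * g)
  sum(fg * (g - gbar) * mu) / sum(fg * (g - gbar)^2)
}

# Simulated twin cohort with no covariates -> raw-APD test, bypassing the
# phenotype builder (used where the score pipeline itself is under test).
raw_apd_test <- function(tw) {
  mz_difference_test(tibble::tibble(score = abs(tw$y_a - tw$y_b), G = tw$G))
}

exact_binomial_band <- function(n, prob, conf = 0.95) {
  a <- (1 - conf) / 2
  qbinom(c(a, 1 - a), n, prob) / n
}
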