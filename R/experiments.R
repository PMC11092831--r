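#' Analytic power of the variance tests
#'
#' Closed-form large-sample power approximation for detecting a vQTL of
#' effect `beta2` with either the population DRM or the MZ-difference test.
#' The absolute-deviation response within genotype class `g` is modelled as
#' half-normal: mean \eqn{\sqrt{2/\pi}\,\sqrt{V_g}}, variance
#' \eqn{(1 - 2/\pi) V_g}, where \eqn{V_g} is `Var(y | G = g)` for the DRM
#' and \eqn{Var(y_A - y_B \mid G = g) = 2(\beta_2 g + \sigma_e^2)} for the
#' MZ design. The implied OLS slope of the deviation on allele count, its
#' standard error and a normal approximation at level `alpha` give the
#' power.
#'
#' @param beta2 Per-allele variance effect.
#' @param design `"drm"` (population, `n` individuals) or `"mz"`
#'   (`n` pairs).
#' @param n Sample size (individuals or pairs).
#' @param p Allele frequency.
#' @param beta1 Additive effect (absorbed by class medians / pair
#'   differences; enters only through the polygenic remainder).
#' @param sigma_g2 Narrow-sense heritability. The DRM's power is invariant
#'   to it (it moves variance between the shared and residual components
#'   without changing `Var(y | G)`); for the MZ design it shrinks the
#'   within-pair residual \eqn{\sigma_e^2} and so raises power.
#' @param alpha Two-sided significance level.
#' @return Power, a single number in (0, 1).
#' @examples
#' variance_test_power(0.02, "drm", n = 5e5, p = 0.3)
#' @export
variance_test_power <- function(beta2, design = c("drm", "mz"), n, p,
                                beta1 = 0, sigma_g2 = 0.5, alpha = 5e-8) {
  design <- match.arg(design)
  prm <- sim_params(n = n, p = p, beta1 = beta1, beta2 = beta2,
                    sigma_g2 = sigma_g2)
  g <- 0:2
  fg <- dbinom(g, 2, p)
  Vg <- switch(design,
    drm = prm$sigma_z2 + beta2 * g + prm$sigma_e2,
    mz = 2 * (beta2 * g + prm$sigma_e2)
  )
  mu <- sqrt(2 / pi) * sqrt(Vg)
  vres <- (1 - 2 / pi) * Vg
  gbar <- sum(fg * g)
  vG <- sum(fg * (g - gbar)^2)
  b <- sum(fg * (g - gbar) * mu) / vG
  mubar <- sum(fg * mu)
  var_resp <- sum(fg * vres) + sum(fg * (mu - mubar)^2)
  sig2_res <- var_resp - b^2 * vG
  lambda <- abs(b) * sqrt(n * vG / sig2_res)
  zc <- qnorm(1 - alpha / 2)
  pnorm(-zc - lambda) + pnorm(-zc + lambda)
}

#' Calibrate the variance effect size for a target power
#'
#' Finds, by bisection of the analytic approximation
#' [variance_test_power()], the smallest `beta2` whose power meets
#' `target_power` at level `alpha`. The default settings reproduce the
#' reference calibration: 80% power for the DRM in 500,000 unrelated
#' individuals at allele frequency 0.3 with no additive effect, at
#' genome-wide significance.
#'
#' @param target_power Desired power in (0, 1).
#' @param design `"drm"` or `"mz"`.
#' @param n Sample size (individuals or pairs).
#' @param p Allele frequency.
#' @param beta1 Additive effect.
#' @param sigma_g2 Narrow-sense heritability (immaterial for the DRM).
#' @param alpha Two-sided significance level.
#' @param tol Bisection tolerance on `beta2`.
#' @return The calibrated `beta2`.
#' @examples
#' calibrate_beta2(target_power = 0.8, design = "drm", n = 5e5, p = 0.3)
#' @export
calibrate_beta2 <- function(target_power = 0.80, design = c("drm", "mz"),
                            n = 5e5, p = 0.3, beta1 = 0, sigma_g2 = 0.5,
                            alpha = 5e-8, tol = 1e-8) {
  design <- match.arg(design)
  if (target_power <= 0 || target_power >= 1) {
    abort("`target_power` must lie in (0, 1).",
          class = "mzvar_invalid_parameter")
  }
  pw <- function(b2) variance_test_power(b2, design, n, p, beta1, sigma_g2,
                                         alpha)
  lo <- 0
  hi <- (1 - sigma_g2) / (2 * p) * (1 - 1e-9) # residual-variance feasibility
  if (pw(hi) < target_power) {
    abort(paste0("Target power ", target_power, " is unreachable within the ",
                 "feasibility bound sigma_g2 + sigma_v2 <= 1 (max power ",
                 signif(pw(hi), 4), ")."),
          class = "mzvar_invalid_parameter")
  }
  if (pw(0) >= target_power) return(0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pw(mid) >= target_power) hi <- mid else lo <- mid
  }
  hi
}

# One simulated MZ replicate at `locus` ("G" or "G_tag") using the raw or
# INT-transformed absolute difference: c(p-value, slope).
mz_replicate <- function(params, linked = NULL, response = "raw",
                         locus = "G") {
  tw <- simulate_twins(params, linked)
  apd <- abs(tw$y_a - tw$y_b)
  resp <- if (response == "int") inverse_normal_transform(apd) else apd
  fit <- ols_slope_core(resp, tw[[locus]])
  if (is.null(fit)) c(NA_real_, NA_real_) else c(fit$p_value, fit$beta)
}

# One simulated population replicate: DRM at `locus`.
drm_replicate <- function(params, linked = NULL, locus = "G") {
  pop <- simulate_population(params, linked)
  g <- pop[[locus]]
  if (var(g) == 0) return(c(NA_real_, NA_real_))
  fit <- ols_slope_core(drm_deviation(pop$y, g), g)
  if (is.null(fit)) c(NA_real_, NA_real_) else c(fit$p_value, fit$beta)
}

power_cell <- function(pvals, alpha, reps) {
  pow <- mean(pvals < alpha, na.rm = TRUE)
  c(power = pow, mc_se = sqrt(pow * (1 - pow) / reps))
}

#' Power of the MZ-difference and DRM tests across heritability
#'
#' Monte-Carlo power study: for each narrow-sense heritability value on
#' `h2_grid`, twin cohorts of `n_pairs` pairs (MZ arm) and population
#' cohorts of `n_pop` unrelated individuals (DRM arm) are simulated with
#' vQTL effect `beta2`, and the fraction of replicates significant at
#' `alpha` is reported. The MZ arm's power grows with heritability (shared
#' genetic variance cancels within pairs, shrinking the residual); the DRM
#' arm is invariant to it.
#'
#' @param h2_grid Heritability values.
#' @param beta2 vQTL effect, e.g. from [calibrate_beta2()].
#' @param n_pairs MZ pairs per replicate.
#' @param n_pop Unrelated individuals per replicate.
#' @param p Allele frequency.
#' @param beta1 Additive effect.
#' @param alpha Significance threshold (genome-wide 5e-8 by default).
#' @param reps Replicates per cell (200 for routine runs; 1000 for full
#'   reproduction).
#' @param response MZ response scale: `"raw"` absolute difference or
#'   `"int"` its inverse-normal transform.
#' @param methods Which arms to run.
#' @param seed Optional integer seed; results replay exactly.
#' @return A tibble of class `mz_power_study`: one row per (h2, method)
#'   cell with `n_units`, `power`, `mc_se`, `reps`, `alpha`, `beta2`,
#'   `response`. Infeasible cells are skipped with a message.
#' @examples
#' power_study(h2_grid = c(0.2, 0.8), beta2 = 0.1, n_pairs = 500,
#'             n_pop = 1000, reps = 20, alpha = 1e-3, seed = 1)
#' @export
power_study <- function(h2_grid = seq(0.1, 0.9, by = 0.1), beta2,
                        n_pairs = 1e4, n_pop = 2e4, p = 0.3, beta1 = 0,
                        alpha = 5e-8, reps = 200,
                        response = c("raw", "int"),
                        methods = c("mz", "drm"), seed = NULL) {
  response <- match.arg(response)
  if (!is.null(seed)) set.seed(seed)
  cells <- tidyr::expand_grid(h2 = h2_grid, method = methods)
  out <- purrr::pmap_dfr(cells, function(h2, method) {
    n <- if (method == "mz") n_pairs else n_pop
    prm <- tryCatch(
      sim_params(n = n, p = p, beta1 = beta1, beta2 = beta2, sigma_g2 = h2),
      mzvar_invalid_parameter = function(e) {
        message("Skipping infeasible cell h2 = ", h2, " (", method, "): ",
                conditionMessage(e))
        NULL
      })
    if (is.null(prm)) return(NULL)
    pv <- purrr::map_dbl(seq_len(reps), function(i) {
      if (method == "mz") mz_replicate(prm, response = response)[1]
      else drm_replicate(prm)[1]
    })
    cell <- power_cell(pv, alpha, reps)
    tibble(h2 = h2, method = method, n_units = n, power = cell["power"],
           mc_se = cell["mc_se"], reps = reps, alpha = alpha,
           beta2 = beta2, response = response)
  })
  class(out) <- c("mz_power_study", class(out))
  attr(out, "seed") <- seed
  out
}

#' False discoveries at an LD tag locus under a purely additive variant
#'
#' Simulates cohorts with an additive effect (`beta1`) at a causal locus
#' and no vQTL effect (`beta2 = 0`), then runs both variance tests at a tag
#' locus in LD with it, across a grid of squared LD correlations. All
#' rejections are false discoveries. The MZ-difference test is structurally
#' immune (additive and polygenic effects cancel within pairs, so the pair
#' difference is independent of genotype), whereas the population DRM test
#' inflates at incompletely linked tag loci, where each tag genotype class
#' is a mixture over causal genotypes with different means.
#'
#' @param r2_grid Squared-LD grid spanning \[0, 1\].
#' @param beta1 Additive effect at the causal locus (0.1 by default).
#' @param h2 Narrow-sense heritability (0.5).
#' @param p Allele frequency of both loci (0.1).
#' @param n_pairs MZ pairs per replicate.
#' @param n_pop Unrelated individuals per replicate; defaults to 500,000
#'   (modern-GWAS scale, where the phantom-vQTL effect of `beta1 = 0.1` is
#'   resolvable).
#' @param alpha Significance threshold (0.05).
#' @param reps Replicates per cell (500).
#' @param response MZ response scale (raw APD by default).
#' @param methods Which arms to run.
#' @param seed Optional integer seed.
#' @return A tibble of class `mz_fdr_study`: one row per (r2, method) cell
#'   with `rejection_rate` and its binomial `mc_se`, plus the mean fitted
#'   variance-test slope across replicates (`mean_slope`, `slope_se`) — the
#'   spurious-slope diagnostic that quantifies the artifact even where the
#'   per-replicate rejection rate is only mildly elevated. Infeasible cells
#'   are skipped with a message.
#' @examples
#' fdr_study(r2_grid = c(0, 0.5), n_pairs = 500, n_pop = 1000, reps = 20,
#'           seed = 1)
#' @export
fdr_study <- function(r2_grid = c(0, 0.25, 0.5, 0.75, 1), beta1 = 0.1,
                      h2 = 0.5, p = 0.1, n_pairs = 1e4, n_pop = 5e5,
                      alpha = 0.05, reps = 500,
                      response = c("raw", "int"),
                      methods = c("mz", "drm"), seed = NULL) {
  response <- match.arg(response)
  if (!is.null(seed)) set.seed(seed)
  cells <- tidyr::expand_grid(r2 = r2_grid, method = methods)
  out <- purrr::pmap_dfr(cells, function(r2, method) {
    cfg <- tryCatch(ld_config(p_causal = p, p_tag = p, r2_target = r2),
                    mzvar_invalid_parameter = function(e) {
                      message("Skipping infeasible cell r2 = ", r2, ": ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(cfg)) return(NULL)
    n <- if (method == "mz") n_pairs else n_pop
    prm <- sim_params(n = n, p = p, beta1 = beta1, beta2 = 0, sigma_g2 = h2)
    res <- purrr::map(seq_len(reps), function(i) {
      if (method == "mz") {
        mz_replicate(prm, linked = cfg, response = response,
                     locus = "G_tag")
      } else {
        drm_replicate(prm, linked = cfg, locus = "G_tag")
      }
    })
    pv <- purrr::map_dbl(res, 1)
    slopes <- purrr::map_dbl(res, 2)
    cell <- power_cell(pv, alpha, reps)
    tibble(r2 = r2, method = method, n_units = n,
           rejection_rate = cell["power"], mc_se = cell["mc_se"],
           mean_slope = mean(slopes, na.rm = TRUE),
           slope_se = sd(slopes, na.rm = TRUE) / sqrt(sum(!is.na(slopes))),
           reps = reps, alpha = alpha, response = response)
  })
  class(out) <- c("mz_fdr_study", class(out))
  attr(out, "seed") <- seed
  out
}

#' @export
autoplot.mz_power_study <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$h2, y = .data$power,
                                       colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$power - 2 * .data$mc_se),
      ymax = pmin(1, .data$power + 2 * .data$mc_se))) +
    ggplot2::labs(x = expression(h^2), y = "Power",
                  colour = "Method",
                  title = "vQTL detection power by narrow-sense heritability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mz_fdr_study <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$r2, y = .data$rejection_rate,
                                       colour = .data$method)) +
    ggplot2::geom_hline(yintercept = object$alpha[1], linetype = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data$rejection_rate - 2 * .data$mc_se),
      ymax = .data$rejection_rate + 2 * .data$mc_se)) +
    ggplot2::labs(x = expression(LD ~ r^2), y = "Rejection rate",
                  colour = "Method",
                  title = "False discoveries at a tag locus (no vQTL effect)") +
    ggplot2::theme_minimal()
}
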