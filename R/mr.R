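#' Harmonize exposure and outcome summary statistics for MR
#'
#' Matches instruments by chromosome and position and re-expresses the
#' outcome effect for the exposure's effect allele: swapped alleles flip the
#' sign of `beta_out`, complementary-base (strand) flips are resolved for
#' non-palindromic variants, palindromic variants follow the same policy as
#' [harmonize_to_reference()], and incompatible or unmatched variants are
#' dropped with a tally.
#'
#' @param exposure Tibble with columns `snp`, `chr`, `bp`, `ea`, `oa`,
#'   `beta_exp`, `se_exp`.
#' @param outcome Tibble with columns `chr`, `bp`, `ea`, `oa`, `beta_out`,
#'   `se_out` (and optionally `eaf`).
#' @param mode,eaf_tol Palindromic-variant policy, as in
#'   [harmonize_to_reference()].
#' @return A tibble of harmonized instruments with columns `snp`, `chr`,
#'   `bp`, `ea`, `oa`, `beta_exp`, `se_exp`, `beta_out`, `se_out`, with a
#'   drop tally attached as attribute `"report"`. Errors if no instrument
#'   survives.
#' @export
harmonize_instruments <- function(exposure, outcome,
                                  mode = c("strict", "permissive"),
                                  eaf_tol = 0.08) {
  mode <- match.arg(mode)
  exp_tb <- as_tibble(exposure)
  out_tb <- as_tibble(outcome)
  idx <- match(paste(exp_tb$chr, exp_tb$bp, sep = ":"),
               paste(out_tb$chr, out_tb$bp, sep = ":"))

  ea_e <- toupper(exp_tb$ea); oa_e <- toupper(exp_tb$oa)
  ea_o <- toupper(out_tb$ea[idx]); oa_o <- toupper(out_tb$oa[idx])
  b_out <- out_tb$beta_out[idx]
  se_out <- out_tb$se_out[idx]
  eaf_o <- if ("eaf" %in% names(out_tb)) out_tb$eaf[idx] else rep(NA_real_, nrow(exp_tb))

  status <- rep("removed_unmatched", nrow(exp_tb))
  found <- !is.na(idx)
  pal <- found & is_palindromic(ea_e, oa_e)

  direct <- found & !pal & ea_o == ea_e & oa_o == oa_e
  swap <- found & !pal & ea_o == oa_e & oa_o == ea_e
  cea <- unname(STRAND_COMPLEMENT[ea_o]); coa <- unname(STRAND_COMPLEMENT[oa_o])
  strand <- found & !pal & !direct & !swap & !is.na(cea) & !is.na(coa) &
    cea == ea_e & coa == oa_e
  strand_swap <- found & !pal & !direct & !swap & !strand &
    !is.na(cea) & !is.na(coa) & cea == oa_e & coa == ea_e

  status[direct | strand] <- "aligned"
  status[swap | strand_swap] <- "flipped"
  status[found & !pal & !direct & !swap & !strand & !strand_swap] <-
    "removed_allele_mismatch"
  if (mode == "strict") {
    status[pal] <- "removed_palindromic"
  } else {
    pal_match <- pal & ((ea_o == ea_e & oa_o == oa_e) |
                          (ea_o == oa_e & oa_o == ea_e))
    informative <- !is.na(eaf_o) & abs(eaf_o - 0.5) > eaf_tol
    status[pal & (!pal_match | !informative)] <- "removed_palindromic"
    status[pal & pal_match & informative & ea_o == ea_e] <- "aligned"
    status[pal & pal_match & informative & ea_o == oa_e] <- "flipped"
  }

  b_out[status == "flipped"] <- -b_out[status == "flipped"]
  keep <- status %in% c("aligned", "flipped")
  if (!any(keep)) {
    abort("No instruments could be harmonized between exposure and outcome.",
          class = "mzvar_invalid_parameter")
  }
  out <- tibble(
    snp = exp_tb$snp[keep], chr = exp_tb$chr[keep], bp = exp_tb$bp[keep],
    ea = ea_e[keep], oa = oa_e[keep],
    beta_exp = exp_tb$beta_exp[keep], se_exp = exp_tb$se_exp[keep],
    beta_out = b_out[keep], se_out = se_out[keep]
  )
  attr(out, "report") <- dplyr::count(tibble(status = status), .data$status,
                                      name = "count")
  out
}

#' Inverse-variance-weighted Mendelian randomization
#'
#' Two-sample IVW estimate of the causal effect of the exposure on the
#' outcome (here, of a trait's genetic mean liability on its variance):
#' \deqn{\hat\beta = \frac{\sum_j b_{exp,j} b_{out,j} / se_{out,j}^2}
#'                        {\sum_j b_{exp,j}^2 / se_{out,j}^2}}
#' with fixed-effect SE \eqn{(\sum_j b_{exp,j}^2/se_{out,j}^2)^{-1/2}};
#' under the default multiplicative random-effects mode the SE is scaled by
#' \eqn{\max(1, \sqrt{Q/df})}, where \eqn{Q = \sum_j (b_{out,j} - \hat\beta\,
#' b_{exp,j})^2 / se_{out,j}^2} is Cochran's heterogeneity statistic on
#' \eqn{df = k - 1} degrees of freedom. With a single instrument the
#' estimate reduces to the Wald ratio \eqn{b_{out}/b_{exp}} with SE
#' \eqn{se_{out}/|b_{exp}|}.
#'
#' @param instruments Harmonized instrument tibble from
#'   [harmonize_instruments()] (columns `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`; `snp` optional).
#' @param mode `"multiplicative-random"` (default) or `"fixed"`.
#' @return An object of class `mr_ivw` with fields `beta`, `se`, `p`,
#'   `n_instruments`, `Q`, `Q_df`, `Q_p`, `mode` and a per-instrument Wald
#'   ratio tibble in `$instruments`.
#' @examples
#' ins <- tibble::tibble(beta_exp = c(0.1, 0.2), se_exp = c(0.01, 0.01),
#'                       beta_out = c(0.05, 0.10), se_out = c(0.02, 0.02))
#' ivw_mr(ins)
#' @export
ivw_mr <- function(instruments, mode = c("multiplicative-random", "fixed")) {
  mode <- match.arg(mode)
  ins <- as_tibble(instruments)
  drop <- ins$beta_exp == 0
  if (any(drop)) {
    warn(paste0(sum(drop),
                " instrument(s) with a zero exposure effect excluded",
                " (Wald ratio undefined)."))
    ins <- ins[!drop, , drop = FALSE]
  }
  k <- nrow(ins)
  if (k < 1) {
    abort("At least one instrument with a nonzero exposure effect is required.",
          class = "mzvar_invalid_parameter")
  }
  w <- ins$beta_exp^2 / ins$se_out^2
  beta <- sum(ins$beta_exp * ins$beta_out / ins$se_out^2) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  Q <- sum((ins$beta_out - beta * ins$beta_exp)^2 / ins$se_out^2)
  Q_df <- k - 1L
  Q_p <- if (Q_df >= 1) pchisq(Q, Q_df, lower.tail = FALSE) else NA_real_
  se <- if (mode == "multiplicative-random" && Q_df >= 1) {
    se_fixed * max(1, sqrt(Q / Q_df))
  } else {
    se_fixed
  }
  ratios <- tibble(
    snp = if ("snp" %in% names(ins)) ins$snp else paste0("instrument", seq_len(k)),
    ratio = ins$beta_out / ins$beta_exp,
    ratio_se = ins$se_out / abs(ins$beta_exp)
  )
  structure(
    list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)),
         n_instruments = k, Q = Q, Q_df = Q_df, Q_p = Q_p, mode = mode,
         se_fixed = se_fixed, instruments = ratios),
    class = "mr_ivw"
  )
}

#' @export
print.mr_ivw <- function(x, ...) {
  cat(sprintf("<mr_ivw: %s> %d instruments\n", x$mode, x$n_instruments))
  cat(sprintf("  beta = %.4g  se = %.4g  p = %.3g\n", x$beta, x$se, x$p))
  if (x$Q_df >= 1) {
    cat(sprintf("  heterogeneity: Q = %.4g on %d df (p = %.3g)\n",
                x$Q, x$Q_df, x$Q_p))
  }
  invisible(x)
}

#' @export
tidy.mr_ivw <- function(x, ...) {
  tibble(term = "exposure", estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se, p.value = x$p)
}

#' @export
glance.mr_ivw <- function(x, ...) {
  tibble(n_instruments = x$n_instruments, Q = x$Q, Q_df = x$Q_df,
         Q_p = x$Q_p, mode = x$mode)
}

#' Difference between two independent MR estimates
#'
#' Tests whether causal estimates from two independent strata (e.g. child
#' and adult meta-analyses) differ: \eqn{\Delta = \beta_1 - \beta_2},
#' \eqn{se_\Delta = \sqrt{se_1^2 + se_2^2}}, two-sided normal p-value on
#' \eqn{z = \Delta / se_\Delta}.
#'
#' @param est1,est2 Either `mr_ivw` objects or lists/vectors with elements
#'   `beta` and `se`.
#' @return A one-row tibble: `delta`, `se`, `z`, `p`.
#' @examples
#' stratum_difference_test(list(beta = 1.58, se = 0.29),
#'                         list(beta = 0.35, se = 0.35))
#' @export
stratum_difference_test <- function(est1, est2) {
  get_bs <- function(e) {
    if (inherits(e, "mr_ivw")) return(c(e$beta, e$se))
    e <- as.list(e)
    c(as.numeric(e$beta), as.numeric(e$se))
  }
  a <- get_bs(est1); b <- get_bs(est2)
  delta <- a[1] - b[1]
  se <- sqrt(a[2]^2 + b[2]^2)
  z <- delta / se
  tibble(delta = delta, se = se, z = z, p = 2 * pnorm(-abs(z)))
}

bias_transforms <- list(
  identity = function(y) y,
  exponential = function(y) exp(y),
  quadratic = function(y) (y + 3)^2
)

#' Sensitivity of the MZ-difference test to pure mean effects
#'
#' A variance test can be driven by a mean effect when the observed
#' phenotype is a nonlinear monotone transform of the latent scale
#' (mean-variance coupling). This simulation quantifies that bias for the
#' MZ-difference test: cohorts are generated with an additive effect only
#' (`beta2 = 0`), the observed phenotype is a chosen monotone transform of
#' the latent one, and the test is run on the raw absolute pair difference
#' or on its rank-based inverse normal transform.
#'
#' On the latent (identity) scale additive effects cancel exactly within MZ
#' pairs, so rejection stays at the nominal level for any `beta1`; convex
#' transforms couple the pair mean to the pair difference and inflate the
#' raw-APD test, which the INT normalization attenuates.
#'
#' @param beta1 Grid of additive effect sizes.
#' @param transform Subset of `"identity"`, `"exponential"`, `"quadratic"`
#'   (the quadratic is the shifted square `(y + 3)^2`, monotone over
#'   essentially the whole phenotype range).
#' @param normalization Subset of `"raw"`, `"int"`.
#' @param n_pairs MZ pairs per replicate.
#' @param reps Replicates per grid cell.
#' @param p,sigma_g2 Generative allele frequency and heritability.
#' @param alpha Test level for the rejection rate.
#' @param seed Optional integer seed.
#' @return A tibble with one row per (beta1, transform, normalization)
#'   cell: `rejection_rate`, `mc_se` (binomial Monte-Carlo SE) and
#'   `mean_slope`.
#' @examples
#' mean_effect_bias_simulation(beta1 = 0.5, transform = "exponential",
#'                             n_pairs = 500, reps = 20, seed = 1)
#' @export
mean_effect_bias_simulation <- function(beta1 = c(0, 0.25, 0.5),
                                        transform = c("identity", "exponential",
                                                      "quadratic"),
                                        normalization = c("raw", "int"),
                                        n_pairs = 5000, reps = 200,
                                        p = 0.3, sigma_g2 = 0.5,
                                        alpha = 0.05, seed = NULL) {
  bad <- setdiff(transform, names(bias_transforms))
  if (length(bad)) {
    abort(paste0("Unknown transform(s): ", paste(bad, collapse = ", ")),
          class = "mzvar_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(beta1 = beta1, transform = transform,
                             normalization = normalization)
  purrr::pmap_dfr(grid, function(beta1, transform, normalization) {
    f <- bias_transforms[[transform]]
    prm <- sim_params(n = n_pairs, p = p, beta1 = beta1, beta2 = 0,
                      sigma_g2 = sigma_g2)
    res <- purrr::map(seq_len(reps), function(i) {
      tw <- simulate_twins(prm)
      apd <- abs(f(tw$y_a) - f(tw$y_b))
      resp <- if (normalization == "int") inverse_normal_transform(apd) else apd
      fit <- ols_slope_core(resp, tw$G)
      c(p = fit$p_value, slope = fit$beta)
    })
    pv <- purrr::map_dbl(res, "p")
    tibble(beta1 = beta1, transform = transform,
           normalization = normalization, reps = reps,
           rejection_rate = mean(pv < alpha),
           mc_se = sqrt(mean(pv < alpha) * (1 - mean(pv < alpha)) / reps),
           mean_slope = mean(purrr::map_dbl(res, "slope")))
  })
}
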