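#' Absolute phenotypic difference of MZ pairs
#'
#' Computes the absolute phenotypic difference (APD) \eqn{|y_A - y_B|} per
#' pair. Pairs with a missing phenotype in either twin are dropped with a
#' message, never imputed.
#'
#' @param data A data frame with one row per MZ pair.
#' @param y_a,y_b Columns holding the two twins' phenotype values
#'   (tidy-eval; defaults `y_a` and `y_b`).
#' @return The input tibble restricted to complete pairs, with an `apd`
#'   column appended.
#' @examples
#' absolute_pair_difference(tibble::tibble(y_a = c(3, -1), y_b = c(5, 2)))
#' @export
absolute_pair_difference <- function(data, y_a = y_a, y_b = y_b) {
  ya <- dplyr::pull(data, {{ y_a }})
  yb <- dplyr::pull(data, {{ y_b }})
  keep <- !is.na(ya) & !is.na(yb)
  if (any(!keep)) {
    message(sum(!keep), " pair(s) with an incomplete phenotype excluded (not imputed).")
  }
  out <- as_tibble(data)[keep, , drop = FALSE]
  out$apd <- abs(ya[keep] - yb[keep])
  out
}

#' Residualize a variable on covariates by OLS
#'
#' Ordinary-least-squares residuals of `values` on an intercept plus the
#' given covariate columns. Two-level character/factor covariates (e.g. sex)
#' are converted to 0/1 indicators.
#'
#' @param values Numeric response vector.
#' @param covariates A data frame of covariates aligned with `values`; `NULL`
#'   or zero columns mean centering only.
#' @return Numeric residual vector.
#' @examples
#' residualize(c(1, 2, 3, 5), data.frame(x = c(0, 1, 2, 3)))
#' @export
residualize <- function(values, covariates = NULL) {
  n <- length(values)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    return(values - mean(values))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  num <- lapply(covariates, function(col) {
    if (is.numeric(col)) return(as.numeric(col))
    lev <- unique(col)
    if (length(lev) > 2) {
      abort("Non-numeric covariates must have exactly two levels.",
            class = "mzvar_invalid_parameter")
    }
    as.numeric(col == lev[length(lev)])
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, num))
  colnames(X) <- c("(Intercept)", names(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    abort(paste0("Covariate design is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "mzvar_rank_deficient")
  }
  as.numeric(qr.resid(qx, values))
}

#' Rank-based inverse normal transformation
#'
#' Replaces values by normal quantiles of their offset-adjusted ranks:
#' \eqn{\Phi^{-1}((r_i - c) / (n - 2c + 1))} with the Blom constant
#' \eqn{c = 0.375} by default and ties given averaged ranks. The output is
#' invariant to any strictly monotone transformation of the input.
#'
#' @param values Numeric vector, `length >= 2`, not all identical.
#' @param offset Rank offset constant (Blom 0.375).
#' @return Numeric vector of normal scores.
#' @examples
#' inverse_normal_transform(c(10, 20, 30))
#' @export
inverse_normal_transform <- function(values, offset = 0.375) {
  n <- length(values)
  if (n < 2) {
    abort("Need at least two values.", class = "mzvar_invalid_parameter")
  }
  if (length(unique(values)) == 1) {
    abort("All values identical: the rank transform is undefined.",
          class = "mzvar_invalid_parameter")
  }
  r <- rank(values, ties.method = "average")
  qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Build the MZ-difference GWAS phenotype
#'
#' Pipeline from raw twin phenotypes to the analysis score: absolute pair
#' difference, OLS residualization on covariates, standardization, and
#' rank-based inverse normal transformation (INT).
#'
#' Three analysis models are supported:
#' * **Model 1** (primary): residualize the APD on all covariates (age, sex,
#'   genetic PCs, study-specific), standardize, INT.
#' * **Model 2**: identical score to Model 1; the within-pair phenotype mean
#'   is additionally carried in `pair_mean` for use as a regression covariate
#'   in [mz_difference_test()].
#' * **Model 3**: as Model 1 but genetic PC columns are excluded from the
#'   covariates (for small studies where 10 PCs over-correct).
#'
#' @param data One row per MZ pair, holding both phenotypes and covariates.
#' @param model Analysis model, 1, 2 or 3.
#' @param y_a,y_b Phenotype columns (tidy-eval).
#' @param covariates Character vector of covariate column names; default all
#'   columns except `pair_id` and the phenotype columns.
#' @param pc_regex Regular expression identifying genetic PC columns
#'   (dropped under Model 3).
#' @param offset INT rank offset, passed to [inverse_normal_transform()].
#' @return A tibble with columns `pair_id` (if present), `apd`, `residual`,
#'   `score`, `pair_mean` and `model_tag`. `score` has mean 0 and variance
#'   close to 1.
#' @examples
#' tw <- simulate_twins(sim_params(n = 200, p = 0.3, seed = 1))
#' tw$age <- rnorm(200, 40, 10)
#' ph <- build_difference_phenotype(tw, model = 1, covariates = "age")
#' head(ph)
#' @export
build_difference_phenotype <- function(data, model = 1, y_a = y_a, y_b = y_b,
                                       covariates = NULL,
                                       pc_regex = "^PC[0-9]+$",
                                       offset = 0.375) {
  if (!model %in% 1:3) {
    abort("`model` must be 1, 2 or 3.", class = "mzvar_invalid_parameter")
  }
  ya_name <- rlang::as_name(rlang::enquo(y_a))
  yb_name <- rlang::as_name(rlang::enquo(y_b))
  data <- absolute_pair_difference(data, {{ y_a }}, {{ y_b }})
  if (is.null(covariates)) {
    covariates <- setdiff(names(data),
                          c("pair_id", ya_name, yb_name, "apd", "z", "G", "G_tag"))
  }
  if (model == 3) {
    covariates <- covariates[!grepl(pc_regex, covariates)]
  }
  cov_tbl <- data[, covariates, drop = FALSE]
  if (any(!complete.cases(cov_tbl))) {
    bad <- !complete.cases(cov_tbl)
    message(sum(bad), " pair(s) with incomplete covariate data excluded.")
    data <- data[!bad, , drop = FALSE]
    cov_tbl <- cov_tbl[!bad, , drop = FALSE]
  }
  residual <- residualize(data$apd, cov_tbl)
  standardized <- residual / sd(residual)
  score <- inverse_normal_transform(standardized, offset = offset)
  out <- tibble(
    apd = data$apd,
    residual = residual,
    score = score,
    pair_mean = (dplyr::pull(data, {{ y_a }}) + dplyr::pull(data, {{ y_b }})) / 2,
    model_tag = as.integer(model)
  )
  if ("pair_id" %in% names(data)) out <- dplyr::bind_cols(data["pair_id"], out)
  for (extra in intersect(c("G", "G_tag"), names(data))) out[[extra]] <- data[[extra]]
  out
}
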