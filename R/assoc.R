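# Closed-form OLS of resp on (intercept, g, covars); t-based two-sided p for
# the g coefficient. Returns NULL when the design is degenerate.
ols_slope_core <- function(resp, g, covars = NULL) {
  n <- length(resp)
  if (is.null(covars)) {
    gc <- g - mean(g)
    sgg <- sum(gc^2)
    if (sgg <= 0) return(NULL)
    beta <- sum(gc * resp) / sgg
    res <- resp - mean(resp) - beta * gc
    df <- n - 2L
    se <- sqrt(sum(res^2) / df / sgg)
  } else {
    X <- cbind(1, g, as.matrix(covars))
    R <- tryCatch(chol(crossprod(X)), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    coef <- backsolve(R, forwardsolve(t(R), crossprod(X, resp)))
    beta <- coef[2]
    res <- resp - X %*% coef
    df <- n - ncol(X)
    se <- sqrt(sum(res^2) / df * chol2inv(R)[2, 2])
  }
  if (!is.finite(se) || se < 0) return(NULL)
  if (se == 0) {
    # perfect fit (e.g. constant response): slope is exact, test undefined
    return(list(beta = beta, se = 0, statistic = NA_real_,
                p_value = NA_real_, df = df, n = n))
  }
  stat <- beta / se
  list(beta = beta, se = se, statistic = stat,
       p_value = 2 * pt(-abs(stat), df), df = df, n = n)
}

new_vqtl_test <- function(fit, method, n) {
  if (is.null(fit)) {
    out <- list(beta = NA_real_, se = NA_real_, statistic = NA_real_,
                p_value = NA_real_, df = NA_integer_, n = n,
                method = method, estimable = FALSE)
  } else {
    out <- c(fit, list(method = method, estimable = TRUE))
  }
  structure(out, class = "vqtl_test")
}

#' @export
print.vqtl_test <- function(x, ...) {
  cat(sprintf("<vqtl_test: %s> n = %d\n", x$method, x$n))
  if (!x$estimable) {
    cat("  not estimable (degenerate genotype or design)\n")
  } else {
    cat(sprintf("  beta = %.6g  se = %.6g  t = %.4g  p = %.4g\n",
                x$beta, x$se, x$statistic, x$p_value))
  }
  invisible(x)
}

#' @export
tidy.vqtl_test <- function(x, ...) {
  tibble(term = "G", estimate = x$beta, std.error = x$se,
         statistic = x$statistic, p.value = x$p_value)
}

#' @export
glance.vqtl_test <- function(x, ...) {
  tibble(nobs = x$n, df.residual = x$df, method = x$method,
         estimable = x$estimable)
}

#' MZ-difference variance association test
#'
#' Regresses the MZ-difference score (typically the residualized,
#' INT-transformed absolute pair difference from
#' [build_difference_phenotype()]) on the pair's allele count by OLS, one
#' genotype per pair (genotypes are taken from one twin; MZ pairs share
#' them). Two-sided p-values use the t distribution with `n - k` degrees of
#' freedom. Under Model 2, pass the within-pair mean via `covariates`.
#'
#' @param data A data frame with one row per pair.
#' @param score Column holding the difference score (tidy-eval; default
#'   `score`).
#' @param genotype Column holding allele counts (default `G`).
#' @param covariates Optional character vector of extra covariate columns
#'   (e.g. `"pair_mean"` for Model 2).
#' @return A `vqtl_test` object with fields `beta`, `se`, `statistic`,
#'   `p_value`, `df`, `n`, `estimable`. A monomorphic genotype yields an
#'   `estimable = FALSE` result rather than an error, so genome-wide scans
#'   continue.
#' @seealso [drm_test()], [gwas_scan()], [tidy()]
#' @examples
#' tw <- simulate_twins(sim_params(n = 500, p = 0.3, beta2 = 0.2, seed = 1))
#' ph <- build_difference_phenotype(tw, covariates = character())
#' mz_difference_test(ph)
#' @export
mz_difference_test <- function(data, score = score, genotype = G,
                               covariates = NULL) {
  resp <- dplyr::pull(data, {{ score }})
  g <- dplyr::pull(data, {{ genotype }})
  stopifnot(length(resp) == length(g))
  covars <- if (length(covariates)) as.data.frame(data)[, covariates, drop = FALSE]
  k <- 2L + length(covariates)
  if (length(resp) < k + 1L) {
    abort("Too few pairs for the requested model.",
          class = "mzvar_invalid_parameter")
  }
  fit <- if (var(g) == 0) NULL else ols_slope_core(resp, g, covars)
  new_vqtl_test(fit, "mz_difference", length(resp))
}

# Deviation phenotype: |y - median(y within own genotype class)|.
drm_deviation <- function(y, g) {
  med <- tapply(y, g, median)
  abs(y - med[match(g, as.numeric(names(med)))])
}

#' Deviation regression model (DRM) vQTL test
#'
#' Population-based comparator: each individual's absolute deviation from the
#' median phenotype of their own genotype class is regressed on allele count
#' (coded additively 0/1/2) by OLS, with a t-based two-sided p-value.
#' Median (not mean) centering makes the test robust to a mean effect at the
#' tested locus itself.
#'
#' @param data A data frame of unrelated individuals.
#' @param y Phenotype column (tidy-eval; default `y`).
#' @param genotype Allele-count column (default `G`).
#' @return A `vqtl_test` object; monomorphic genotypes give
#'   `estimable = FALSE`.
#' @examples
#' pop <- simulate_population(sim_params(n = 1000, p = 0.3, beta2 = 0.2, seed = 1))
#' drm_test(pop)
#' @export
drm_test <- function(data, y = y, genotype = G) {
  yy <- dplyr::pull(data, {{ y }})
  g <- dplyr::pull(data, {{ genotype }})
  stopifnot(length(yy) == length(g))
  if (var(g) == 0) return(new_vqtl_test(NULL, "drm", length(yy)))
  z <- drm_deviation(yy, g)
  new_vqtl_test(ols_slope_core(z, g), "drm", length(yy))
}

#' Genome-wide scan of the MZ-difference test
#'
#' Applies [mz_difference_test()] to each column of a genotype matrix and
#' emits a METAL-exportable summary-statistic table.
#'
#' @param phenotype A difference-phenotype tibble from
#'   [build_difference_phenotype()] (needs `score`; `pair_mean` when
#'   `model = 2`).
#' @param genotypes Numeric matrix, pairs x variants, of allele counts or
#'   dosages of the effect allele.
#' @param variants Optional variant metadata tibble with columns among
#'   `chr`, `bp`, `rsid`, `effect_allele`, `other_allele`, `info`; defaults
#'   are synthesized (chr 1, consecutive positions, alleles A/G, INFO 1.0 as
#'   appropriate for simulated genotypes).
#' @param model Analysis model (1, 2 or 3); defaults to the phenotype's
#'   `model_tag`. Model 2 adds `pair_mean` as a covariate.
#' @return A tibble with one row per variant: `cptid`, `rsid`, `chr`, `bp`,
#'   `effect_allele`, `other_allele`, `eaf` (computed from the analyzed
#'   pairs), `beta`, `se`, `p`, `info`, `n`, `estimable`.
#' @examples
#' tw <- simulate_twins(sim_params(n = 300, p = 0.3, seed = 1))
#' ph <- build_difference_phenotype(tw, covariates = character())
#' Gm <- sapply(1:5, function(i) draw_genotypes(300, 0.3))
#' gwas_scan(ph, Gm)
#' @export
gwas_scan <- function(phenotype, genotypes, variants = NULL, model = NULL) {
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  if (nrow(genotypes) != nrow(phenotype)) {
    abort("Genotype matrix rows must match phenotype pairs.",
          class = "mzvar_dimension_mismatch")
  }
  if (is.null(variants)) {
    variants <- tibble(chr = 1L, bp = seq_len(m),
                       rsid = paste0("snp", seq_len(m)),
                       effect_allele = "A", other_allele = "G", info = 1)
  }
  variants <- as_tibble(variants)
  if (nrow(variants) != m) {
    abort("Variant metadata rows must match genotype columns.",
          class = "mzvar_dimension_mismatch")
  }
  defaults <- list(chr = 1L, bp = seq_len(m), rsid = paste0("snp", seq_len(m)),
                   effect_allele = "A", other_allele = "G", info = 1)
  for (nm in names(defaults)) {
    if (!nm %in% names(variants)) variants[[nm]] <- defaults[[nm]]
  }
  model <- model %||% phenotype$model_tag[1] %||% 1L
  covariates <- if (model == 2) "pair_mean" else NULL
  resp <- phenotype$score
  covars <- if (!is.null(covariates)) as.data.frame(phenotype)[, covariates, drop = FALSE]
  fits <- purrr::map(seq_len(m), function(j) {
    g <- genotypes[, j]
    if (var(g) == 0) NULL else ols_slope_core(resp, g, covars)
  })
  tibble(
    cptid = paste(variants$chr, variants$bp, variants$effect_allele,
                  variants$other_allele, sep = ":"),
    rsid = variants$rsid,
    chr = variants$chr,
    bp = variants$bp,
    effect_allele = variants$effect_allele,
    other_allele = variants$other_allele,
    eaf = colMeans(genotypes) / 2,
    beta = purrr::map_dbl(fits, ~ .x$beta %||% NA_real_),
    se = purrr::map_dbl(fits, ~ .x$se %||% NA_real_),
    p = purrr::map_dbl(fits, ~ .x$p_value %||% NA_real_),
    info = variants$info,
    n = nrow(phenotype),
    estimable = !purrr::map_lgl(fits, is.null)
  )
}
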