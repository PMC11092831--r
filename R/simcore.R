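#' Parameters of the generative twin/population model
#'
#' Bundles and validates the parameters of the data-generating model
#' \deqn{y_{i,t} = \alpha + \beta_1 G_i + z_i + v_{i,t} + e_{i,t}}
#' where \eqn{G \sim Binom(2, p)} is the allele count at the causal locus,
#' \eqn{z \sim N(0, \sigma_g^2 - 2p(1-p)\beta_1^2)} is the residual polygenic
#' value (shared by both members of an MZ pair), \eqn{v \mid G \sim N(0,
#' \beta_2 G)} is the genotype-dependent variance inflation, and
#' \eqn{e \sim N(0, 1 - \sigma_g^2 - \sigma_v^2)} is the residual. With
#' \eqn{\sigma_v^2 = 2 p \beta_2} (the mean of \eqn{Var(v \mid G)}), the
#' marginal phenotypic variance is 1 in expectation, so `beta1`, `beta2`
#' and `sigma_g2` are all on the standardized-phenotype scale.
#'
#' @param n Number of units: MZ pairs for [simulate_twins()], individuals for
#'   [simulate_population()].
#' @param p Causal allele frequency, in (0, 1).
#' @param beta1 Additive per-allele effect on the phenotype mean.
#' @param beta2 Per-allele increment of the phenotype variance
#'   (\eqn{\ge 0}).
#' @param sigma_g2 Narrow-sense heritability \eqn{h^2 = \sigma_g^2}, in
#'   \eqn{[0, 1)}.
#' @param alpha Phenotype intercept.
#' @param seed Optional integer seed; when supplied, cohort draws are
#'   reproducible and the seed is recorded on the result.
#'
#' @return An object of class `sim_params`: a list with the supplied fields
#'   plus the derived variance components `sigma_z2` (polygenic remainder),
#'   `sigma_v2` (variance-inflation share, `2 * p * beta2`) and `sigma_e2`
#'   (residual, `1 - sigma_g2 - sigma_v2`).
#'
#' @examples
#' prm <- sim_params(n = 1000, p = 0.3, beta2 = 0.05, sigma_g2 = 0.5, seed = 1)
#' prm$sigma_e2
#' @export
sim_params <- function(n, p, beta1 = 0, beta2 = 0, sigma_g2 = 0.5,
                       alpha = 0, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p >= 1) {
    abort("`p` must be a single allele frequency in (0, 1).",
          class = "mzvar_invalid_parameter")
  }
  if (beta2 < 0) {
    abort("`beta2` must be >= 0: v ~ N(0, beta2 * G) needs a nonnegative variance.",
          class = "mzvar_invalid_parameter")
  }
  if (sigma_g2 < 0 || sigma_g2 >= 1) {
    abort("`sigma_g2` must lie in [0, 1).", class = "mzvar_invalid_parameter")
  }
  sigma_z2 <- sigma_g2 - 2 * p * (1 - p) * beta1^2
  if (sigma_z2 < 0) {
    abort(
      paste0("Infeasible parameters: 2*p*(1-p)*beta1^2 = ",
             signif(2 * p * (1 - p) * beta1^2, 4), " exceeds sigma_g2 = ",
             signif(sigma_g2, 4), " (polygenic remainder variance would be negative)."),
      class = "mzvar_invalid_parameter"
    )
  }
  sigma_v2 <- expected_variance_share(beta2, p)
  sigma_e2 <- 1 - sigma_g2 - sigma_v2
  if (sigma_e2 < 0) {
    abort(
      paste0("Infeasible parameters: sigma_g2 + sigma_v2 = ",
             signif(sigma_g2 + sigma_v2, 4),
             " exceeds 1 (residual variance would be negative)."),
      class = "mzvar_invalid_parameter"
    )
  }
  structure(
    list(n = as.integer(n), p = p, beta1 = beta1, beta2 = beta2,
         sigma_g2 = sigma_g2, alpha = alpha, seed = seed,
         sigma_z2 = sigma_z2, sigma_v2 = sigma_v2, sigma_e2 = sigma_e2),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  n = %d, p = %g, beta1 = %g, beta2 = %g\n",
              x$n, x$p, x$beta1, x$beta2))
  cat(sprintf("  variance components: sigma_g2 = %g, sigma_v2 = %g, sigma_e2 = %g\n",
              x$sigma_g2, x$sigma_v2, x$sigma_e2))
  if (!is.null(x$seed)) cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Expected phenotypic variance share of a vQTL
#'
#' The variance-inflation term contributes \eqn{E[Var(v \mid G)] = \beta_2
#' E[G] = 2 p \beta_2} to the marginal phenotypic variance; this is the
#' \eqn{\sigma_v^2} entering the residual variance
#' \eqn{1 - \sigma_g^2 - \sigma_v^2}.
#'
#' @param beta2 Per-allele variance increment (\eqn{\ge 0}).
#' @param p Allele frequency.
#' @return The variance share `2 * p * beta2`.
#' @examples
#' expected_variance_share(0.1, 0.3) # 0.06
#' @export
expected_variance_share <- function(beta2, p) {
  stopifnot(all(beta2 >= 0))
  2 * p * beta2
}

#' Draw allele counts at a biallelic locus
#'
#' @param n Number of draws.
#' @param p Allele frequency in (0, 1).
#' @param seed Optional integer seed.
#' @return Integer vector of length `n` with values in \{0, 1, 2\}, i.i.d.
#'   Binomial(2, `p`).
#' @examples
#' draw_genotypes(5, 0.3, seed = 1)
#' @export
draw_genotypes <- function(n, p, seed = NULL) {
  stopifnot(n >= 1)
  if (p <= 0 || p >= 1) {
    abort("`p` must lie in (0, 1).", class = "mzvar_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  rbinom(n, 2L, p)
}

#' Configure a pair of loci in linkage disequilibrium
#'
#' Describes a causal locus and a tag locus whose allele counts have squared
#' correlation `r2_target`. Internally the pair is generated from two-locus
#' haplotypes with frequency \eqn{p_{11} = p_c p_t + D}, \eqn{D = r
#' \sqrt{p_c(1-p_c)p_t(1-p_t)}}, \eqn{r = +\sqrt{r^2}}; the configuration is
#' rejected when any implied haplotype frequency falls outside \eqn{[0, 1]}
#' (Lewontin bounds).
#'
#' @param p_causal Allele frequency at the causal locus.
#' @param p_tag Allele frequency at the tag locus; defaults to `p_causal`,
#'   which permits any `r2_target` up to 1.
#' @param r2_target Target squared LD correlation, in \eqn{[0, 1]}.
#' @return An object of class `ld_config` carrying the haplotype frequencies.
#' @examples
#' ld_config(p_causal = 0.1, r2_target = 0.5)
#' @export
ld_config <- function(p_causal, p_tag = p_causal, r2_target) {
  for (p in c(p_causal, p_tag)) {
    if (p <= 0 || p >= 1) {
      abort("Allele frequencies must lie in (0, 1).",
            class = "mzvar_invalid_parameter")
    }
  }
  if (r2_target < 0 || r2_target > 1) {
    abort("`r2_target` must lie in [0, 1].", class = "mzvar_invalid_parameter")
  }
  r <- sqrt(r2_target)
  D <- r * sqrt(p_causal * (1 - p_causal) * p_tag * (1 - p_tag))
  hap <- c(
    h11 = p_causal * p_tag + D,
    h10 = p_causal * (1 - p_tag) - D,
    h01 = (1 - p_causal) * p_tag - D,
    h00 = (1 - p_causal) * (1 - p_tag) + D
  )
  bad <- names(hap)[hap < -1e-12 | hap > 1 + 1e-12]
  if (length(bad) > 0) {
    abort(
      paste0("Infeasible (p, r2) combination: haplotype frequency ",
             paste(bad, collapse = ", "), " = ",
             paste(signif(hap[bad], 4), collapse = ", "),
             " falls outside [0, 1]."),
      class = "mzvar_invalid_parameter"
    )
  }
  hap <- pmax(hap, 0)
  structure(
    list(p_causal = p_causal, p_tag = p_tag, r2_target = r2_target,
         r = r, D = D, hap = hap / sum(hap)),
    class = "ld_config"
  )
}

#' @export
print.ld_config <- function(x, ...) {
  cat(sprintf("<ld_config> p_causal = %g, p_tag = %g, r2 = %g\n",
              x$p_causal, x$p_tag, x$r2_target))
  cat("  haplotype frequencies:",
      paste(sprintf("%s=%.4g", names(x$hap), x$hap), collapse = ", "), "\n")
  invisible(x)
}

# Draw (G, G_tag) allele-count pairs from per-individual haplotype pairs.
# RNG state must already be set by the caller.
draw_linked_core <- function(n, config) {
  idx <- sample.int(4L, 2L * n, replace = TRUE, prob = config$hap)
  a <- idx <= 2L               # haplotypes h11, h10 carry the causal allele
  b <- idx == 1L | idx == 3L   # haplotypes h11, h01 carry the tag allele
  odd <- seq(1L, 2L * n, by = 2L)
  list(G = as.integer(a[odd]) + as.integer(a[odd + 1L]),
       G_tag = as.integer(b[odd]) + as.integer(b[odd + 1L]))
}

#' Draw genotypes at a causal locus and an LD tag locus
#'
#' @param n Number of individuals (or MZ pairs).
#' @param config An [ld_config()].
#' @param seed Optional integer seed.
#' @return A tibble with integer columns `G` (causal allele count) and
#'   `G_tag` (tag allele count); their squared sample correlation converges
#'   to `config$r2_target`.
#' @examples
#' gg <- draw_linked_genotypes(1e4, ld_config(0.1, r2_target = 0.5), seed = 1)
#' cor(gg$G, gg$G_tag)^2
#' @export
draw_linked_genotypes <- function(n, config, seed = NULL) {
  stopifnot(inherits(config, "ld_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  as_tibble(draw_linked_core(n, config))
}

# Shared draws for one "unit" row set: polygenic z plus per-realization v + e.
# Var(v | G) = beta2 * G; Var(e) = sigma_e2.
draw_noise <- function(params, G) {
  rnorm(length(G), 0, sqrt(params$beta2 * G)) +
    rnorm(length(G), 0, sqrt(params$sigma_e2))
}

#' Simulate a population cohort of unrelated individuals
#'
#' Draws `n` unrelated individuals under the generative model described in
#' [sim_params()]. When an [ld_config()] is supplied, genotypes at a tag
#' locus in LD with the causal locus are drawn jointly and returned as
#' `G_tag`; the phenotype depends on the causal locus only.
#'
#' @param params A [sim_params()] object.
#' @param linked Optional [ld_config()] for a tag locus.
#' @return A tibble with columns `id`, `G`, (`G_tag`,) `y`. The marginal
#'   variance of `y` is 1 in expectation. The seed used (if any) is attached
#'   as attribute `"seed"`.
#' @examples
#' pop <- simulate_population(sim_params(n = 500, p = 0.3, beta2 = 0.1, seed = 1))
#' var(pop$y)
#' @export
simulate_population <- function(params, linked = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n
  if (is.null(linked)) {
    G <- rbinom(n, 2L, params$p)
    G_tag <- NULL
  } else {
    stopifnot(inherits(linked, "ld_config"))
    gg <- draw_linked_core(n, linked)
    G <- gg$G
    G_tag <- gg$G_tag
  }
  z <- rnorm(n, 0, sqrt(params$sigma_z2))
  y <- params$alpha + params$beta1 * G + z + draw_noise(params, G)
  out <- tibble(id = seq_len(n), G = G)
  if (!is.null(G_tag)) out$G_tag <- G_tag
  out$y <- y
  attr(out, "seed") <- params$seed
  out
}

#' Simulate a cohort of monozygotic twin pairs
#'
#' Both members of a pair share the genotype `G`, the additive effect
#' `beta1 * G` and the polygenic value `z`; the variance-inflation and
#' residual terms `v + e` are drawn independently per twin. Hence
#' \eqn{Var(y_A - y_B \mid G = g) = 2(\beta_2 g + \sigma_e^2)}: the shared
#' components cancel exactly within pairs.
#'
#' @inheritParams simulate_population
#' @return A tibble with columns `pair_id`, `G`, (`G_tag`,) `z`, `y_a`,
#'   `y_b`; `z` is retained for validation against the generating model.
#' @examples
#' tw <- simulate_twins(sim_params(n = 500, p = 0.3, beta2 = 0.1, seed = 1))
#' cor(tw$y_a, tw$y_b)
#' @export
simulate_twins <- function(params, linked = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n
  if (is.null(linked)) {
    G <- rbinom(n, 2L, params$p)
    G_tag <- NULL
  } else {
    stopifnot(inherits(linked, "ld_config"))
    gg <- draw_linked_core(n, linked)
    G <- gg$G
    G_tag <- gg$G_tag
  }
  z <- rnorm(n, 0, sqrt(params$sigma_z2))
  shared <- params$alpha + params$beta1 * G + z
  out <- tibble(pair_id = seq_len(n), G = G)
  if (!is.null(G_tag)) out$G_tag <- G_tag
  out$z <- z
  out$y_a <- shared + draw_noise(params, G)
  out$y_b <- shared + draw_noise(params, G)
  attr(out, "seed") <- params$seed
  out
}
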