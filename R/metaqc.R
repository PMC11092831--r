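STRAND_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_snp_allele <- function(a) a %in% names(STRAND_COMPLEMENT)

is_palindromic <- function(ea, oa) {
  is_snp_allele(ea) & is_snp_allele(oa) &
    unname(STRAND_COMPLEMENT[ea]) == oa
}

#' Quality-control filter for GWAS summary statistics
#'
#' EasyQC-style per-study filtering, applied in a fixed order: (1) records
#' with missing beta, SE, p or INFO; (2) minor allele frequency below
#' `maf_min`; (3) INFO below `info_min`; (4) indels and monomorphic
#' variants; (5) duplicate positions (same chr:bp with different alleles,
#' i.e. potentially tri-allelic), retaining only the record with the largest
#' per-variant sample size. Each record is tallied once, at the first rule
#' it fails.
#'
#' @param sumstats Summary-statistic tibble with columns `chr`, `bp`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `info`, `n`.
#' @param maf_min Minimum minor allele frequency (default 0.01); 0 disables.
#' @param info_min Minimum imputation INFO score (default 0.5; use 0.3 for
#'   HapMap-imputed studies).
#' @param drop_indels Drop non-single-nucleotide alleles (default TRUE).
#' @return An object of class `qc_result`: a list with `sumstats` (the
#'   retained records) and `report` (a tibble of per-reason removal counts
#'   plus the retained count). `removed + retained` equals the input row
#'   count. Applying the filter twice equals applying it once.
#' @examples
#' ss <- demo_sumstats()
#' qc <- qc_filter(ss)
#' qc$report
#' @export
qc_filter <- function(sumstats, maf_min = 0.01, info_min = 0.5,
                      drop_indels = TRUE) {
  ss <- as_tibble(sumstats)
  ss$effect_allele <- toupper(ss$effect_allele)
  ss$other_allele <- toupper(ss$other_allele)
  n_in <- nrow(ss)
  reason <- rep(NA_character_, n_in)

  flag <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- label
  }
  flag(is.na(ss$beta) | is.na(ss$se) | is.na(ss$p) | is.na(ss$info),
       "missing_stats")
  maf <- pmin(ss$eaf, 1 - ss$eaf)
  flag(maf < maf_min, "low_maf")
  flag(ss$info < info_min, "low_info")
  if (drop_indels) {
    flag(nchar(ss$effect_allele) != 1 | nchar(ss$other_allele) != 1 |
           !is_snp_allele(ss$effect_allele) | !is_snp_allele(ss$other_allele),
         "indel")
  }
  flag(ss$effect_allele == ss$other_allele | ss$eaf <= 0 | ss$eaf >= 1,
       "monomorphic")

  # duplicate / potentially tri-allelic positions: keep the largest n
  alive <- which(is.na(reason))
  if (length(alive) > 1) {
    key <- paste(ss$chr[alive], ss$bp[alive], sep = ":")
    ord <- alive[order(key, -ss$n[alive])]
    dup <- duplicated(paste(ss$chr[ord], ss$bp[ord], sep = ":"))
    reason[ord[dup]] <- "duplicate_position"
  }

  keep <- is.na(reason)
  reasons <- c("missing_stats", "low_maf", "low_info", "indel",
               "monomorphic", "duplicate_position")
  counts <- vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  report <- tibble(reason = c(reasons, "retained"),
                   count = unname(c(counts, sum(keep))))
  structure(list(sumstats = ss[keep, , drop = FALSE], report = report),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-20s %d\n", x$report$reason[i], x$report$count[i]))
  }
  invisible(x)
}

#' Harmonize summary statistics to a reference allele map
#'
#' Aligns each record's effect allele to the reference panel's first allele
#' at the same chr:bp. Records whose allele pair matches after swapping get
#' their beta sign flipped and EAF complemented; complementary-base (strand)
#' flips are resolved for non-palindromic variants; palindromic (A/T, C/G)
#' variants are removed under `mode = "strict"` (the default) or retained
#' under `mode = "permissive"` when their EAF is informative
#' (`|EAF - 0.5| > eaf_tol`); all other records are removed and tallied.
#'
#' @param sumstats Summary-statistic tibble (see [qc_filter()]).
#' @param reference Tibble with columns `chr`, `bp`, `ref_allele`,
#'   `alt_allele` (see [read_reference_map()]).
#' @param mode `"strict"` or `"permissive"` palindromic-variant policy.
#' @param eaf_tol EAF distance from 0.5 required to keep a palindromic
#'   variant in permissive mode.
#' @return The harmonized tibble, with a removal/flip tally attached as
#'   attribute `"report"`.
#' @examples
#' ss <- demo_sumstats()[6:10, ]
#' ref <- tibble::tibble(chr = ss$chr, bp = ss$bp,
#'                       ref_allele = ss$effect_allele,
#'                       alt_allele = ss$other_allele)
#' harmonize_to_reference(ss, ref)
#' @export
harmonize_to_reference <- function(sumstats, reference,
                                   mode = c("strict", "permissive"),
                                   eaf_tol = 0.08) {
  mode <- match.arg(mode)
  ss <- as_tibble(sumstats)
  ref <- as_tibble(reference)
  key <- paste(ss$chr, ss$bp, sep = ":")
  idx <- match(key, paste(ref$chr, ref$bp, sep = ":"))

  ea <- toupper(ss$effect_allele)
  oa <- toupper(ss$other_allele)
  a1 <- toupper(ref$ref_allele[idx])
  a2 <- toupper(ref$alt_allele[idx])

  status <- rep("removed_unmatched_position", nrow(ss))
  found <- !is.na(idx)
  pal <- found & is_palindromic(ea, oa)

  direct <- found & !pal & ea == a1 & oa == a2
  swap <- found & !pal & ea == a2 & oa == a1
  cea <- unname(STRAND_COMPLEMENT[ea])
  coa <- unname(STRAND_COMPLEMENT[oa])
  strand <- found & !pal & !direct & !swap & !is.na(cea) & !is.na(coa) &
    cea == a1 & coa == a2
  strand_swap <- found & !pal & !direct & !swap & !strand &
    !is.na(cea) & !is.na(coa) & cea == a2 & coa == a1

  status[direct] <- "aligned"
  status[swap] <- "flipped"
  status[strand] <- "strand_corrected"
  status[strand_swap] <- "strand_corrected_flipped"
  status[found & !pal & !direct & !swap & !strand & !strand_swap] <-
    "removed_allele_mismatch"
  if (mode == "strict") {
    status[pal] <- "removed_palindromic"
  } else {
    pal_match <- pal & ((ea == a1 & oa == a2) | (ea == a2 & oa == a1))
    informative <- abs(ss$eaf - 0.5) > eaf_tol
    status[pal & (!pal_match | !informative)] <- "removed_palindromic"
    status[pal & pal_match & informative & ea == a1] <- "aligned"
    status[pal & pal_match & informative & ea == a2] <- "flipped"
  }

  flip <- status %in% c("flipped", "strand_corrected_flipped")
  ss$beta[flip] <- -ss$beta[flip]
  ss$eaf[flip] <- 1 - ss$eaf[flip]
  relabel <- status %in% c("aligned", "flipped", "strand_corrected",
                           "strand_corrected_flipped")
  ss$effect_allele[relabel] <- a1[relabel]
  ss$other_allele[relabel] <- a2[relabel]
  if ("cptid" %in% names(ss)) {
    ss$cptid[relabel] <- paste(ss$chr[relabel], ss$bp[relabel],
                               ss$effect_allele[relabel],
                               ss$other_allele[relabel], sep = ":")
  }

  keep <- !startsWith(status, "removed")
  out <- ss[keep, , drop = FALSE]
  attr(out, "report") <- dplyr::count(tibble(status = status), .data$status,
                                      name = "count")
  out
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' METAL-style pooling of per-study summary statistics: per variant,
#' \eqn{w_i = 1/se_i^2}, pooled beta \eqn{\sum w_i b_i / \sum w_i}, pooled
#' SE \eqn{\sqrt{1/\sum w_i}}, z = beta/se and a two-sided normal p-value.
#' The per-study direction-of-effect string uses `+`, `-` and `?` (variant
#' absent from that study). All tables must already be harmonized to a
#' shared reference (see [harmonize_to_reference()]).
#'
#' @param tables A (preferably named) list of per-study summary-statistic
#'   tibbles keyed by `cptid`.
#' @return A tibble with one row per variant: `cptid`, alleles, n-weighted
#'   pooled `eaf`, `beta`, `se`, `z`, `p`, total `n`, `n_studies`,
#'   `n_studies_total` and `direction`.
#' @examples
#' s1 <- tibble::tibble(cptid = "1:1:A:G", effect_allele = "A",
#'                      other_allele = "G", eaf = 0.3, beta = 0.3,
#'                      se = 0.1, p = 0.0027, info = 1, n = 100)
#' s2 <- dplyr::mutate(s1, beta = 0.1, se = 0.2)
#' ivw_meta(list(study1 = s1, study2 = s2))
#' @export
ivw_meta <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  k <- length(tables)
  names(tables) <- names(tables) %||% paste0("study", seq_len(k))
  long <- dplyr::bind_rows(purrr::imap(tables, function(tb, nm) {
    tb <- as_tibble(tb)
    if (anyDuplicated(tb$cptid)) {
      abort(paste0("Duplicate cptid within study ", nm,
                   "; run qc_filter() first."),
            class = "mzvar_invalid_parameter")
    }
    tb$.study <- nm
    tb
  }))
  study_levels <- names(tables)
  long |>
    group_by(.data$cptid) |>
    summarise(
      effect_allele = .data$effect_allele[1],
      other_allele = .data$other_allele[1],
      # per-study direction string, in input study order, before pooling
      direction = paste(
        ifelse(study_levels %in% .data$.study,
               c("-", "0", "+")[
                 sign(.data$beta[match(study_levels, .data$.study)]) + 2],
               "?"),
        collapse = ""),
      eaf = sum(.data$eaf * .data$n) / sum(.data$n),
      beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      se = sqrt(1 / sum(1 / .data$se^2)),
      n = sum(.data$n),
      n_studies = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(z = .data$beta / .data$se,
           p = 2 * pnorm(-abs(.data$z)),
           n_studies_total = k) |>
    select("cptid", "effect_allele", "other_allele", "eaf", "beta", "se",
           "z", "p", "n", "n_studies", "n_studies_total", "direction")
}

#' Filter meta-analysis records by study coverage
#'
#' Retains variants observed in at least `min_fraction` of the contributing
#' studies (default 50%).
#'
#' @param meta A meta-analysis tibble from [ivw_meta()].
#' @param min_fraction Minimum fraction of studies a variant must appear in.
#' @return The filtered tibble.
#' @export
coverage_filter <- function(meta, min_fraction = 0.5) {
  filter(meta, .data$n_studies / .data$n_studies_total >= min_fraction)
}

#' Genomic inflation factor from the median p-value
#'
#' \eqn{\lambda = median(\Phi^{-1}(p/2)^2) / 0.4549364}, the median
#' association chi-square over the null median of \eqn{\chi^2_1}. Values
#' well above 1 indicate systematic test-statistic inflation.
#'
#' @param p Vector of two-sided p-values in (0, 1].
#' @return The inflation factor (a single number).
#' @examples
#' lambda_median(runif(1e4))
#' @export
lambda_median <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) {
    abort("No p-values supplied.", class = "mzvar_invalid_parameter")
  }
  if (any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1].", class = "mzvar_invalid_parameter")
  }
  median(qnorm(p / 2)^2) / qchisq(0.5, df = 1)
}

#' Sign-concordance comparison of two GWAS result tables
#'
#' Compares two summary-statistic tables (e.g. analysis Models 1 vs 2) over
#' their shared variants: proportion of effects with the same direction with
#' an exact two-sided binomial sign test against 0.5, and Spearman rank
#' correlations of betas and of p-values.
#'
#' @param table_a,table_b Summary-statistic tibbles keyed by `cptid` with
#'   `beta` and `p` columns.
#' @return A one-row tibble: `n_shared`, `prop_same_sign`, `sign_test_p`,
#'   `beta_correlation`, `p_correlation`.
#' @examples
#' tw <- simulate_twins(sim_params(n = 200, p = 0.3, seed = 1))
#' ph <- build_difference_phenotype(tw, covariates = character())
#' Gm <- sapply(1:10, function(i) draw_genotypes(200, 0.3))
#' a <- gwas_scan(ph, Gm)
#' sign_concordance_test(a, a)
#' @export
sign_concordance_test <- function(table_a, table_b) {
  shared <- inner_join(
    select(as_tibble(table_a), "cptid", beta_a = "beta", p_a = "p"),
    select(as_tibble(table_b), "cptid", beta_b = "beta", p_b = "p"),
    by = "cptid"
  )
  shared <- filter(shared, !is.na(.data$beta_a) & !is.na(.data$beta_b))
  if (nrow(shared) == 0) {
    abort("No shared variants between the two tables.",
          class = "mzvar_invalid_parameter")
  }
  same <- sum(sign(shared$beta_a) == sign(shared$beta_b))
  tibble(
    n_shared = nrow(shared),
    prop_same_sign = same / nrow(shared),
    sign_test_p = stats::binom.test(same, nrow(shared), 0.5)$p.value,
    beta_correlation = cor(shared$beta_a, shared$beta_b, method = "spearman"),
    p_correlation = cor(shared$p_a, shared$p_b, method = "spearman")
  )
}
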