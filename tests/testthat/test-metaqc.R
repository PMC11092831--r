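test_that("the QC filter tallies each removal at its first failing rule", {
  qc <- qc_filter(demo_sumstats())
  counts <- setNames(qc$report$count, qc$report$reason)
  expect_equal(counts[["retained"]], 6L)
  expect_equal(counts[["missing_stats"]], 1L)
  expect_equal(counts[["low_maf"]], 1L)
  expect_equal(counts[["low_info"]], 1L)
  expect_equal(counts[["duplicate_position"]], 1L)
  expect_equal(sum(qc$report$count[qc$report$reason != "retained"]) +
                 counts[["retained"]], nrow(demo_sumstats()))
  # the larger-sample record survives the duplicated position
  expect_true("1:400:T:G" %in% qc$sumstats$cptid)
  expect_false("1:400:T:C" %in% qc$sumstats$cptid)
})

test_that("the QC filter is idempotent and thresholds can be disabled", {
  qc1 <- qc_filter(demo_sumstats())
  qc2 <- qc_filter(qc1$sumstats)
  expect_equal(qc2$sumstats, qc1$sumstats)
  expect_equal(sum(qc2$report$count[qc2$report$reason != "retained"]), 0L)

  clean <- qc1$sumstats
  qc3 <- qc_filter(clean, maf_min = 0)
  expect_equal(nrow(qc3$sumstats), nrow(clean))
  expect_equal(qc3$report$count[qc3$report$reason == "low_maf"], 0L)
})

test_that("indels are removed when requested", {
  ss <- demo_sumstats()
  ss$effect_allele[1] <- "AT"
  qc <- qc_filter(ss)
  expect_equal(qc$report$count[qc$report$reason == "indel"], 1L)
  expect_equal(qc$report$count[qc$report$reason == "retained"], 5L)
})

test_that("harmonization aligns, flips and strand-corrects against the reference", {
  ss <- tibble::tibble(
    cptid = c("1:1:A:G", "1:2:A:C", "1:3:C:G", "1:4:A:G", "1:5:T:C"),
    rsid = paste0("rs", 1:5), chr = "1", bp = 1:5,
    effect_allele = c("A", "A", "C", "A", "T"),
    other_allele = c("G", "C", "G", "G", "C"),
    eaf = c(0.1, 0.2, 0.3, 0.25, 0.4),
    beta = c(0.2, 0.1, 0.3, -0.15, 0.12),
    se = 0.05, p = 0.5, info = 1, n = 100
  )
  ref <- tibble::tibble(chr = "1", bp = 1:5,
                        ref_allele = c("G", "A", "C", "A", "A"),
                        alt_allele = c("A", "T", "G", "G", "G"))
  out <- harmonize_to_reference(ss, ref)
  rep <- attr(out, "report")

  # bp 1: allele swap -> beta flipped, EAF complemented, EA becomes G
  r1 <- out[out$bp == 1, ]
  expect_equal(r1$effect_allele, "G")
  expect_equal(r1$beta, -0.2)
  expect_equal(r1$eaf, 0.9)
  # bp 2: A/C vs reference A/T -> removed as mismatch
  expect_false(2 %in% out$bp)
  # bp 3: palindromic C/G removed under strict mode
  expect_false(3 %in% out$bp)
  # bp 4: already aligned, untouched
  expect_equal(out$beta[out$bp == 4], -0.15)
  # bp 5: record T/C complements to A/G -> retained via strand flip
  expect_equal(out$effect_allele[out$bp == 5], "A")
  expect_equal(out$beta[out$bp == 5], 0.12)
  expect_equal(rep$count[rep$status == "removed_palindromic"], 1L)

  # permissive mode keeps informative palindromic variants
  out_p <- harmonize_to_reference(ss, ref, mode = "permissive")
  expect_true(3 %in% out_p$bp)
})

test_that("unmatched positions are removed and tallied", {
  ss <- demo_sumstats()[c(1, 6), ]
  ref <- tibble::tibble(chr = "1", bp = 100, ref_allele = "A", alt_allele = "G")
  out <- harmonize_to_reference(ss, ref)
  expect_equal(nrow(out), 1)
  rep <- attr(out, "report")
  expect_equal(rep$count[rep$status == "removed_unmatched_position"], 1L)
})

test_that("IVW meta-analysis matches closed-form pooling", {
  mk <- function(beta, se, n = 100) {
    tibble::tibble(cptid = "1:1:A:G", effect_allele = "A", other_allele = "G",
                   eaf = 0.3, beta = beta, se = se, p = 0.5, info = 1, n = n)
  }
  meta <- ivw_meta(list(s1 = mk(0.3, 0.1), s2 = mk(0.1, 0.2)))
  orc <- ivw_meta_oracle(c(0.3, 0.1), c(0.1, 0.2))
  expect_equal(meta$beta, 0.26, tolerance = 1e-12)
  expect_equal(meta$se, orc$se, tolerance = 1e-12)
  expect_equal(meta$se, 0.0894427, tolerance = 1e-6)
  expect_equal(meta$p, orc$p, tolerance = 1e-12)
  expect_equal(meta$direction, "++")
  expect_equal(meta$n, 200)

  # meta of a table with itself halves the variance exactly
  self <- ivw_meta(list(a = mk(0.12, 0.07), b = mk(0.12, 0.07)))
  expect_equal(self$beta, 0.12)
  expect_equal(self$se^2, 0.07^2 / 2, tolerance = 1e-14)

  # single-study passthrough
  one <- ivw_meta(list(only = mk(-0.2, 0.04)))
  expect_equal(one$beta, -0.2)
  expect_equal(one$se, 0.04)
  expect_equal(one$direction, "-")
  expect_equal(one$n_studies, 1L)
})

test_that("direction strings mark absent studies with a question mark", {
  s1 <- demo_sumstats()[c(1, 6), ]
  s2 <- demo_sumstats()[1, ]
  s2$beta <- -s2$beta
  meta <- ivw_meta(list(a = s1, b = s2))
  meta <- meta[order(meta$cptid), ]
  expect_equal(meta$direction[meta$cptid == "1:100:A:G"], "+-")
  expect_equal(meta$direction[meta$cptid == "2:100:A:C"], "-?")
})

test_that("meta estimates are pooled within the per-study range", {
  set.seed(41)
  for (i in 1:5) {
    k <- sample(2:5, 1)
    betas <- rnorm(k)
    ses <- runif(k, 0.02, 0.3)
    tables <- lapply(seq_len(k), function(j) {
      tibble::tibble(cptid = "1:9:A:G", effect_allele = "A",
                     other_allele = "G", eaf = 0.2, beta = betas[j],
                     se = ses[j], p = 0.5, info = 1, n = 50)
    })
    meta <- ivw_meta(tables)
    expect_gte(meta$beta, min(betas))
    expect_lte(meta$beta, max(betas))
    expect_lte(meta$se, min(ses))
  }
})

test_that("duplicate variants within a study are rejected", {
  s <- demo_sumstats()[c(1, 1), ]
  expect_error(ivw_meta(list(a = s)), class = "mzvar_invalid_parameter")
})

test_that("coverage filtering keeps variants in at least half the studies", {
  meta <- tibble::tibble(cptid = c("a", "b", "c"),
                         n_studies = c(2L, 3L, 5L), n_studies_total = 5L)
  kept <- coverage_filter(meta)
  expect_equal(kept$cptid, c("b", "c"))
  expect_equal(coverage_filter(meta, min_fraction = 0), meta)
})

test_that("lambda-median calibrates on null p-values and scales with inflation", {
  expect_equal(lambda_median(rep(0.5, 7)),
               qnorm(0.25)^2 / 0.4549364, tolerance = 1e-6)
  expect_equal(lambda_median(rep(0.5, 7)), 1, tolerance = 1e-4)

  set.seed(42)
  p_null <- runif(1e5)
  expect_equal(lambda_median(p_null), 1, tolerance = 0.02)

  # doubling the chi-square statistics doubles lambda
  q <- qchisq(p_null, df = 1, lower.tail = FALSE)
  p_infl <- pchisq(2 * q, df = 1, lower.tail = FALSE)
  expect_equal(lambda_median(p_infl) / lambda_median(p_null), 2,
               tolerance = 0.05)

  expect_error(lambda_median(numeric(0)), class = "mzvar_invalid_parameter")
  expect_error(lambda_median(c(0.5, 0)), class = "mzvar_invalid_parameter")
})

test_that("the QC-harmonize-meta pipeline is byte-deterministic", {
  run_once <- function() {
    ss <- qc_filter(demo_sumstats())$sumstats
    ref <- tibble::tibble(chr = ss$chr, bp = ss$bp,
                          ref_allele = ss$effect_allele,
                          alt_allele = ss$other_allele)
    harm <- harmonize_to_reference(ss, ref)
    meta <- ivw_meta(list(a = harm, b = harm))
    path <- tempfile(fileext = ".tsv")
    write_sumstats(meta, path)
    on.exit(unlink(path))
    readLines(path)
  }
  expect_identical(run_once(), run_once())
})

test_that("sign concordance compares result tables as specified", {
  base <- tibble::tibble(cptid = paste0("v", 1:10),
                         beta = c(0.2, -0.1, 0.3, 0.15, -0.25,
                                  0.05, 0.4, -0.3, 0.1, 0.2),
                         p = runif(10))
  same <- sign_concordance_test(base, base)
  expect_equal(same$prop_same_sign, 1)
  expect_equal(same$beta_correlation, 1)
  expect_equal(same$p_correlation, 1)

  flipped <- dplyr::mutate(base, beta = -beta)
  opp <- sign_concordance_test(base, flipped)
  expect_equal(opp$prop_same_sign, 0)

  # 8 of 10 concordant: exact binomial two-sided p = 0.109
  partial <- base
  partial$beta[1:2] <- -partial$beta[1:2]
  res <- sign_concordance_test(base, partial)
  expect_equal(res$prop_same_sign, 0.8)
  expect_equal(res$sign_test_p, binom.test(8, 10, 0.5)$p.value,
               tolerance = 1e-12)
  expect_equal(res$sign_test_p, 0.1094, tolerance = 1e-3)

  expect_error(sign_concordance_test(base,
                                     dplyr::mutate(base, cptid = paste0("w", 1:10))),
               class = "mzvar_invalid_parameter")
})
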