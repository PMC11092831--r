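mk_exposure <- function() {
  tibble::tibble(snp = paste0("rs", 1:4), chr = "1", bp = 1:4,
                 ea = c("A", "C", "A", "G"), oa = c("G", "T", "T", "A"),
                 beta_exp = c(0.10, 0.08, 0.12, 0.05),
                 se_exp = c(0.01, 0.01, 0.02, 0.01))
}

test_that("instrument harmonization aligns outcome effects to the exposure allele", {
  exposure <- mk_exposure()
  outcome <- tibble::tibble(chr = "1", bp = c(1, 2, 3, 4),
                            ea = c("A", "T", "A", "G"),
                            oa = c("G", "C", "T", "A"),
                            beta_out = c(0.05, 0.04, 0.03, 0.02),
                            se_out = 0.02)
  out <- harmonize_instruments(exposure, outcome)
  # rs3 (A/T palindromic) removed under strict mode; rs1 aligned; rs2 swapped
  expect_equal(out$snp, c("rs1", "rs2", "rs4"))
  expect_equal(out$beta_out, c(0.05, -0.04, 0.02))
  rep <- attr(out, "report")
  expect_equal(rep$count[rep$status == "removed_palindromic"], 1L)

  # variant absent from the outcome: dropped and tallied
  out2 <- harmonize_instruments(exposure, outcome[1, ])
  expect_equal(out2$snp, "rs1")
  rep2 <- attr(out2, "report")
  expect_equal(rep2$count[rep2$status == "removed_unmatched"], 3L)

  expect_error(
    harmonize_instruments(exposure,
                          dplyr::mutate(outcome, chr = "7")),
    class = "mzvar_invalid_parameter")
})

test_that("IVW MR matches its closed form and reduces to the Wald ratio", {
  ins <- tibble::tibble(beta_exp = c(0.1, 0.2), se_exp = 0.01,
                        beta_out = c(0.05, 0.10), se_out = c(0.02, 0.02))
  est <- ivw_mr(ins)
  orc <- ivw_mr_oracle(ins$beta_exp, ins$beta_out, ins$se_out)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(est$beta, orc$beta, tolerance = 1e-12)
  expect_equal(est$se_fixed, orc$se_fixed, tolerance = 1e-12)
  expect_equal(est$Q, orc$Q, tolerance = 1e-12)
  expect_equal(est$Q_df, 1L)

  # single instrument: Wald ratio with se = se_out / |b_exp|
  one <- ivw_mr(ins[1, ])
  expect_equal(one$beta, 0.05 / 0.1)
  expect_equal(one$se, 0.02 / 0.1)
  expect_equal(one$Q, 0)

  # perfectly consistent instruments: beta equals the shared ratio, Q ~ 0
  cons <- tibble::tibble(beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
                         beta_out = 0.7 * c(0.1, 0.2, 0.3), se_out = 1e-6)
  est_c <- ivw_mr(cons)
  expect_equal(est_c$beta, 0.7, tolerance = 1e-9)
  expect_lt(est_c$Q, 1e-12)
})

test_that("IVW MR is invariant to joint sign flips and drops null instruments", {
  set.seed(51)
  ins <- tibble::tibble(beta_exp = rnorm(8, 0.1, 0.03), se_exp = 0.01,
                        beta_out = rnorm(8, 0.08, 0.03), se_out = runif(8, 0.01, 0.05))
  est <- ivw_mr(ins)
  flip <- ins
  flip$beta_exp[3] <- -flip$beta_exp[3]
  flip$beta_out[3] <- -flip$beta_out[3]
  est_f <- ivw_mr(flip)
  expect_equal(est_f$beta, est$beta, tolerance = 1e-12)
  expect_equal(est_f$se, est$se, tolerance = 1e-12)

  with_zero <- ins
  with_zero$beta_exp[1] <- 0
  expect_warning(est_z <- ivw_mr(with_zero), "zero exposure effect")
  expect_equal(est_z$n_instruments, 7L)
})

test_that("IVW MR recovers a known causal slope with nominal coverage", {
  set.seed(52)
  slope <- 0.8
  n_sets <- 200
  covered <- logical(n_sets)
  est1 <- NULL
  for (i in seq_len(n_sets)) {
    b_exp <- rnorm(102, 0.08, 0.02)
    se_out <- runif(102, 0.03, 0.06)
    b_out <- slope * b_exp + rnorm(102, 0, se_out)
    est <- ivw_mr(tibble::tibble(beta_exp = b_exp, se_exp = 0.01,
                                 beta_out = b_out, se_out = se_out),
                  mode = "fixed")
    covered[i] <- abs(est$beta - slope) <= qnorm(0.975) * est$se
    if (i == 1) est1 <- est
  }
  expect_lt(abs(est1$beta - slope), 2 * est1$se)
  band <- exact_binomial_band(n_sets, 0.95)
  expect_gte(mean(covered), band[1])
  expect_lte(mean(covered), band[2])
})

test_that("stratum-difference test matches closed-form contrasts of independent strata", {
  same <- stratum_difference_test(list(beta = 1, se = 0.2),
                                  list(beta = 1, se = 0.2))
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  # adult vs child variance-MR estimates reported to two decimals
  res <- stratum_difference_test(list(beta = 1.58, se = 0.29),
                                 list(beta = 0.35, se = 0.35))
  expect_gte(res$p, 0.006)
  expect_lte(res$p, 0.009)

  simple <- stratum_difference_test(list(beta = 1, se = 1),
                                    list(beta = 0, se = 1))
  expect_equal(simple$z, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(simple$p, 2 * pnorm(-1 / sqrt(2)), tolerance = 1e-12)
  expect_equal(simple$p, 0.4795, tolerance = 1e-4)
})

test_that("mr_ivw objects tidy and glance cleanly", {
  est <- ivw_mr(tibble::tibble(beta_exp = c(0.1, 0.2), se_exp = 0.01,
                               beta_out = c(0.05, 0.12), se_out = 0.02))
  td <- tidy(est)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  gl <- glance(est)
  expect_equal(gl$n_instruments, 2L)
  expect_equal(gl$Q_df, 1L)
})

test_that("pure mean effects do not inflate the MZ test on the latent scale", {
  res <- mean_effect_bias_simulation(beta1 = 0.5, transform = "identity",
                                     normalization = c("raw", "int"),
                                     n_pairs = 1000, reps = 200, seed = 53)
  band <- exact_binomial_band(200, 0.05)
  expect_gte(min(res$rejection_rate), band[1])
  expect_lte(max(res$rejection_rate), band[2])
})

test_that("convex transforms induce mean-variance bias that INT attenuates", {
  res <- mean_effect_bias_simulation(beta1 = 0.5,
                                     transform = c("exponential", "quadratic"),
                                     normalization = c("raw", "int"),
                                     n_pairs = 2000, reps = 100, seed = 54)
  raw_exp <- res$rejection_rate[res$transform == "exponential" &
                                  res$normalization == "raw"]
  int_exp <- res$rejection_rate[res$transform == "exponential" &
                                  res$normalization == "int"]
  expect_gt(raw_exp, 0.05)
  expect_lte(abs(int_exp - 0.05), abs(raw_exp - 0.05))

  raw_quad <- res$rejection_rate[res$transform == "quadratic" &
                                   res$normalization == "raw"]
  expect_gt(raw_quad, 0.05)

  expect_error(mean_effect_bias_simulation(transform = "cubic"),
               class = "mzvar_invalid_parameter")
})
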