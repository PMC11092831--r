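---
title: "Detecting variance QTLs from monozygotic twin differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting variance QTLs from monozygotic twin differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(mzvar)
```

## The problem

Most GWAS target the *mean* of a phenotype. A variance quantitative trait
locus (vQTL) instead shifts its *variability* — a signature of
gene–environment interaction or environmental sensitivity: carriers respond
more (or less) heterogeneously to whatever else varies between people.
Population-based vQTL tests compare phenotypic spread across genotype
groups in unrelated individuals. They carry two burdens: phenotypic spread
is dominated by polygenic background (noise), and apparent variance effects
can be artifacts of a purely additive variant in linkage disequilibrium
(LD) with the tested SNP.

Monozygotic (MZ) twins offer a cleaner contrast. Both members of a pair
share their genome and their polygenic value, so the *within-pair*
difference removes additive genetic effects — at the tested locus and
genome-wide — leaving environmental and stochastic variation. If a
genotype inflates phenotypic variance, pairs carrying more copies of that
allele are more discordant. Regressing the absolute pair difference on
allele count therefore tests for a variance effect directly, with the
shared background subtracted exactly rather than statistically.

## Generative model

`simulate_twins()` and `simulate_population()` draw from
\[
y_{i,t} = \alpha + \beta_1 G_i + z_i + v_{i,t} + e_{i,t},
\]
with allele count \(G \sim \mathrm{Binom}(2, p)\), polygenic remainder
\(z \sim N(0,\, \sigma_g^2 - 2p(1-p)\beta_1^2)\) (so the additive locus plus
\(z\) contribute exactly the narrow-sense heritability \(\sigma_g^2\)),
variance inflation \(v \mid G \sim N(0, \beta_2 G)\), and residual
\(e \sim N(0,\, 1 - \sigma_g^2 - \sigma_v^2)\). For an MZ pair the twins
share \(G\), \(\beta_1 G\) and \(z\); \(v + e\) is drawn independently per
twin.

The residual variance formula needs a value for \(\sigma_v^2\), the
phenotypic variance share of the vQTL. We define it as the mean conditional
variance contribution,
\(\sigma_v^2 \equiv E[\mathrm{Var}(v \mid G)] = 2 p \beta_2\)
(`expected_variance_share()`): this is the unique choice that makes the
marginal phenotype variance exactly 1 in expectation, so that all effect
sizes are on the standardized scale. Two closed-form consequences anchor
the test suite:

* population: \(\mathrm{Var}(y \mid G = g) = \sigma_z^2 + \beta_2 g + \sigma_e^2\);
* twins: \(\mathrm{Var}(y_A - y_B \mid G = g) = 2(\beta_2 g + \sigma_e^2)\),
  and \(E\lvert y_A - y_B\rvert = \sqrt{2/\pi}\sqrt{2(\beta_2 g + \sigma_e^2)}\)
  (half-normal identity).

LD-tagged locus pairs (`ld_config()`, `draw_linked_genotypes()`) are built
from two-locus haplotypes with
\(p_{11} = p_c p_t + D\), \(D = r\sqrt{p_c(1-p_c)p_t(1-p_t)}\),
\(r = +\sqrt{r^2}\). We take the positive root and default the tag
frequency to the causal frequency: the false-discovery protocol sweeps the
*squared* correlation, for which the sign is immaterial, and equal
frequencies are the only choice for which every \(r^2\) up to 1 is
attainable. Configurations whose implied haplotype frequencies leave
\([0,1]\) are rejected with the violated bound named.

We draw one polygenic value per *pair*, not per twin: a twin-specific
\(z\) would contradict MZ biology (the polygenic value is a function of
the shared genome) and would leave additive effects incompletely cancelled
in differences.

## The MZ-difference phenotype and test

`build_difference_phenotype()` implements the analysis pipeline: absolute
pair difference (APD), ordinary-least-squares residualization on
covariates (age, sex, genetic PCs, study-specific columns),
standardization, then a rank-based inverse normal transformation (INT)
using the Blom offset,
\(\Phi^{-1}\!\big((r_i - 0.375)/(n + 0.25)\big)\), with ties given averaged
ranks. Whether "rank-transformed" should mean plain rank replacement or a
full INT is a genuine design choice; INT is adopted because it is the
prevailing GWAS convention for non-normal difference scores and because
plain ranks would leave the response bounded and heteroscedastic — the
same reasoning that makes INT the default normalization in the MR bias
analysis below. Standardization before INT
is a no-op for the final score (INT is rank-invariant); the standardized
residual is retained in the output for diagnostics.

Pairs missing either phenotype or any covariate are dropped, never
imputed: an imputed co-twin value would fabricate exactly the discordance
the method measures.

Three models are exposed: Model 1 (the primary analysis, all covariates),
Model 2 (identical score, with the within-pair mean carried as a
regression covariate — a sensitivity check for mean-driven differences
which risks over-correction, because genuine vQTLs touch both moments and
the pair mean correlates positively with the APD), and Model 3 (PCs
dropped, for small studies where ten PCs over-fit).

`mz_difference_test()` is OLS of the score on the allele count of one twin
per pair (MZ pairs share genotypes, so the analyzed sample is unrelated),
with t-distributed two-sided p-values — exact at small n, indistinguishable
from normal at GWAS scale. Monomorphic variants yield flagged,
non-estimable rows rather than errors so that `gwas_scan()` continues.

The population comparator, `drm_test()`, is the deviation regression
model: each individual's absolute deviation from the *median* phenotype of
their own genotype class, regressed on allele count. Median centering
makes it robust to a mean shift at the tested locus itself.

## Power calibration

`variance_test_power()` models the deviation response in class \(g\) as
half-normal — mean \(\sqrt{2/\pi}\sqrt{V_g}\), variance \((1-2/\pi)V_g\) —
and converts the implied OLS slope and standard error into normal
approximation power. `calibrate_beta2()` inverts this by bisection. The
reference calibration (DRM, \(n = 500{,}000\), \(p = 0.3\), \(\beta_1 = 0\),
\(\alpha = 5\times10^{-8}\), 80% target) returns \(\beta_2 \approx 0.021\);
re-simulating at that effect size reproduces the target within Monte-Carlo
error (the acceptance script does exactly this). The analytic and
Monte-Carlo routes are cross-validated over a \((p, \text{target})\) grid
at \(n = 50{,}000\) in the test suite.

With \(\beta_1 = 0\), \(\mathrm{Var}(y \mid g) = 1 + \beta_2(g - 2p)\):
heritability cancels from the population split, so DRM power is
h²-invariant by construction (verified by simulation). The MZ design's
conditioning variance is \(2(\beta_2 g + \sigma_e^2)\) with
\(\sigma_e^2 = 1 - h^2 - 2p\beta_2\): higher heritability shrinks the
within-pair residual and raises power — the design is at its best exactly
for highly heritable traits.

```{r power, fig.width = 6, fig.height = 4}
b2 <- calibrate_beta2(target_power = 0.5, design = "mz", n = 2000,
                      p = 0.3, sigma_g2 = 0.5, alpha = 1e-4)
ps <- power_study(h2_grid = c(0.1, 0.5, 0.9), beta2 = b2, n_pairs = 2000,
                  n_pop = 4000, alpha = 1e-4, reps = 100, seed = 7)
autoplot(ps)
```

## False discoveries under LD

`fdr_study()` reproduces the phantom-vQTL protocol: cohorts carry a purely
additive effect (\(\beta_1 = 0.1\), \(\beta_2 = 0\), \(h^2 = 0.5\),
\(p = 0.1\)) at a causal locus, and both variance tests are run at a tag
locus across an LD grid; every rejection is a false discovery.

The mechanism is worth spelling out because it dictates the study design.
Within a tag-genotype class, the phenotype is a *mixture* over causal
genotypes with different means, so the class variance
\(\sigma^2 + \beta_1^2\,\mathrm{Var}(G \mid G^*)\) and shape vary across
tag classes — a spurious variance signal. At \(r^2 = 1\) with equal
frequencies the tag *is* the causal locus, the mixture collapses, and the
median-centred DRM absorbs the mean shift exactly: the artifact lives at
*incomplete* LD and is non-monotone in \(r^2\) (a closed-form
normal-mixture computation places its peak near \(r^2 \approx 0.2\)–\(0.3\)
for these parameters). The MZ-difference test is structurally immune at
every \(r^2\): the pair difference is independent of genotype whenever
\(\beta_2 = 0\).

The noncentrality of the artifact scales with \(\beta_1^2\sqrt{n}\) and is
invisible at 20k individuals for \(\beta_1 = 0.1\); the population arm
therefore defaults to \(n = 500{,}000\) — the modern-GWAS scale that the
power comparison also contemplates — with 10,000 pairs in the MZ arm
(whose calibration is structural and independent of its size). Defaults:
500 repeats per cell, \(\alpha = 0.05\), grid \(\{0, 0.25, 0.5, 0.75, 1\}\).
Because the per-replicate rejection excess is modest at these settings
(about 0.06–0.08 against a nominal 0.05), `fdr_study()` also reports the
mean fitted slope per cell with its Monte-Carlo SE: the pooled
spurious-slope statistic detects the artifact with near-certain power at
500 repeats, while the rejection-rate excess is read alongside it. The MZ
arm shows neither — its slope is centred on zero and its rejection rate
sits inside the binomial band at every \(r^2\).
For the power study the genome-wide threshold \(5\times10^{-8}\) is the
default instead — discovery power and calibration diagnostics are asked at
different levels — and `alpha` is an explicit config field labeled in
every output row.

## Simulation sizes and response scale

Routine runs (tests, examples) use 200 replicates per cell and the raw
absolute difference as the MZ response; full reproductions use 1,000
replicates, and the INT-transformed response is available via
`response = "int"` everywhere. Whether the original power/FDR experiments
transformed inside the loop is not documented; both modes are exposed and
the INT mode is exercised as a sensitivity check in the test suite. The
acceptance re-simulation of the DRM calibration uses 200 cohorts of
500,000, giving a binomial Monte-Carlo SE of about 2.8 percentage points
around 80%.

## QC, meta-analysis, and model comparison

`qc_filter()` applies the per-study filters in a fixed order — missing
statistics, MAF < 0.01, INFO < 0.5, indels/monomorphic variants, duplicate
positions (keeping the largest per-variant n) — tallying each record at
the first rule it fails, so report counts are unambiguous and the filter
is idempotent. The order is a reporting convention, not a statistical
choice; fixing it makes tallies reproducible across runs.

`harmonize_to_reference()` aligns records to a 4-column reference allele
map, flipping effects and complementing frequencies for swapped alleles
and resolving strand flips for non-palindromic variants. Palindromic (A/T,
C/G) variants are removed by default; a permissive mode retains them when
the EAF is informative (\(\lvert \mathrm{EAF} - 0.5\rvert > 0.08\)). The
harmonized orientation follows the reference file's first allele column.

`ivw_meta()` is the METAL fixed-effect pool: weights \(1/se^2\), normal
p-values (the meta convention, versus t in single-study tests), per-study
direction strings (`+`, `-`, `?` for absent), and n-weighted pooled EAF.
`coverage_filter()` implements the ≥50%-of-studies rule used before
gene-based analyses. `lambda_median()` is the median-χ² inflation
diagnostic. `sign_concordance_test()` compares two model's results over
shared variants with an exact binomial sign test plus rank correlations of
betas and p-values.

## Mendelian randomization of mean liability on variance

`ivw_mr()` estimates the effect of genetic liability to a trait's mean on
its variance from pre-clumped instruments (instrument selection is out of
scope): the standard two-sample IVW slope with Cochran's Q and, by
default, multiplicative random-effects scaling
\(se \leftarrow se \cdot \max(1, \sqrt{Q/df})\) — the default of the
standard MR toolchain; a fixed-effect mode is available.
`stratum_difference_test()` contrasts independent strata: for example,
an adult-stratum estimate of 1.58 (SE 0.29) against a child-stratum
estimate of 0.35 (SE 0.35) gives a two-sided interaction p ≈ 0.0068,
which rounds to 0.007–0.008 territory for inputs reported to two
decimals.

Because a variance outcome can be driven by mean effects on a transformed
observed scale, `mean_effect_bias_simulation()` quantifies that bias for
this design: cohorts with only a mean effect, a monotone transform of the
observed scale (identity, exponential, or the shifted square
\((y+3)^2\) — a concrete convex menu chosen here, each cell checked
against its own analytic expectation rather than any external reference),
and the MZ test under raw or INT normalization. On the latent scale the
additive effect cancels exactly; convex transforms inflate the raw-APD
test, and INT pulls the rejection rate back toward nominal — the rationale
for INT as the default GWAS response.

```{r bias}
mean_effect_bias_simulation(beta1 = 0.5,
                            transform = c("identity", "exponential"),
                            n_pairs = 1000, reps = 50, seed = 11)
```

## Numerical and degenerate-input choices

* OLS fits use closed-form normal equations (Cholesky for covariate
  models); results match `lm()` to machine precision and brute-force
  oracles to 1e-10 in the tests.
* A perfectly fit (constant) response returns the exact slope with an
  undefined test (NA p) rather than an error; monomorphic genotypes return
  flagged non-estimable rows.
* Rank-deficient covariate designs error with the collinear columns named.
* Ties in the INT receive averaged ranks; an all-constant input is an
  error, as the transform is undefined.
* DRM genotype classes absent from a sample simply contribute no rows;
  medians are computed only over present classes.
* All stochastic entry points accept a `seed` and replay exactly;
  experiment outputs carry their seed as an attribute and the CLI writes a
  manifest (config echo, seed, package version, timestamp).

## What the simulator does not capture

The generator is single-locus plus a scalar polygenic value: no epistasis,
no multi-locus LD structure beyond one tag pair, no genotyping error or
imputation uncertainty, no covariate confounding, and residuals are
Gaussian on the latent scale. Passing tests therefore certify the
*statistical machinery* — calibration, power ordering, LD robustness,
pipeline arithmetic — not the behaviour of any real phenotype, where scale
choices, informative missingness of co-twins, and longitudinal instability
of differences remain the user's responsibility.
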