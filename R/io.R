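sumstats_cols <- readr::cols(
  cptid = readr::col_character(), rsid = readr::col_character(),
  chr = readr::col_character(), bp = readr::col_double(),
  effect_allele = readr::col_character(),
  other_allele = readr::col_character(),
  eaf = readr::col_double(), beta = readr::col_double(),
  se = readr::col_double(), p = readr::col_double(),
  info = readr::col_double(), n = readr::col_double(),
  .default = readr::col_guess()
)

#' Read and write twin cohort files
#'
#' Tab-delimited with a header; columns `pair_id`, `G`, `y_a`, `y_b` plus
#' any covariate columns.
#'
#' @param path File path.
#' @param data Twin cohort tibble.
#' @return `read_twin_cohort()` returns a tibble; the writers return `data`
#'   invisibly.
#' @export
read_twin_cohort <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_twin_cohort
#' @export
write_twin_cohort <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(data)
}

#' Read and write population cohort files
#'
#' Tab-delimited with a header; columns `id`, `G`, `y`.
#'
#' @inheritParams read_twin_cohort
#' @return A tibble (reader) or `data` invisibly (writer).
#' @export
read_population_cohort <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_population_cohort
#' @export
write_population_cohort <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(data)
}

#' Read and write GWAS summary statistics
#'
#' Tab-delimited with the header `cptid rsid chr bp effect_allele
#' other_allele eaf beta se p info n` (METAL-exportable, round-trips
#' through [qc_filter()] and [ivw_meta()]).
#'
#' @inheritParams read_twin_cohort
#' @return A tibble (reader) or `data` invisibly (writer).
#' @export
read_sumstats <- function(path) {
  readr::read_tsv(path, col_types = sumstats_cols)
}

#' @rdname read_sumstats
#' @export
write_sumstats <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(data)
}

#' Read a reference allele map
#'
#' Four tab-delimited columns: `chr`, `bp`, `ref_allele`, `alt_allele`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_reference_map <- function(path) {
  readr::read_tsv(path, col_names = c("chr", "bp", "ref_allele", "alt_allele"),
                  col_types = "cdcc", skip = 1)
}

#' Read and write MR instrument tables
#'
#' Tab-delimited with the header `snp chr bp ea oa beta_exp se_exp beta_out
#' se_out`.
#'
#' @inheritParams read_twin_cohort
#' @return A tibble (reader) or `data` invisibly (writer).
#' @export
read_instruments <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(chr = readr::col_character(),
                                          .default = readr::col_guess()))
}

#' @rdname read_instruments
#' @export
write_instruments <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(data)
}

#' A small demonstration summary-statistic table
#'
#' Ten variants exercising each quality-control rule: one record with a
#' missing SE, one with MAF below 0.01, one with INFO below 0.5, a
#' duplicated position (potentially tri-allelic; the larger-sample record
#' survives) and five clean records. [qc_filter()] retains six.
#'
#' @return A summary-statistic tibble (see [read_sumstats()] for the
#'   column dialect).
#' @examples
#' qc_filter(demo_sumstats())$report
#' @export
demo_sumstats <- function() {
  tibble(
    cptid = c("1:100:A:G", "1:200:C:T", "1:300:G:A", "1:400:T:C",
              "1:400:T:G", "2:100:A:C", "2:200:G:T", "2:300:C:A",
              "3:100:T:A", "3:200:G:C"),
    rsid = paste0("rs", 1:10),
    chr = c("1", "1", "1", "1", "1", "2", "2", "2", "3", "3"),
    bp = c(100, 200, 300, 400, 400, 100, 200, 300, 100, 200),
    effect_allele = c("A", "C", "G", "T", "T", "A", "G", "C", "T", "G"),
    other_allele = c("G", "T", "A", "C", "G", "C", "T", "A", "A", "C"),
    eaf = c(0.30, 0.005, 0.40, 0.25, 0.25, 0.10, 0.45, 0.20, 0.35, 0.15),
    beta = c(0.10, 0.05, -0.02, 0.03, 0.04, -0.07, 0.01, 0.02, -0.05, 0.06),
    se = c(0.02, 0.02, 0.02, 0.03, 0.03, 0.02, 0.02, 0.02, NA, 0.02),
    p = c(5e-7, 0.012, 0.32, 0.31, 0.18, 4e-4, 0.62, 0.33, 0.012, 0.0027),
    info = c(0.99, 0.95, 0.40, 0.92, 0.97, 0.88, 0.91, 0.93, 0.90, 0.96),
    n = c(1000, 1000, 1000, 100, 200, 1000, 1000, 1000, 1000, 1000)
  )
}
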