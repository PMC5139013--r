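#' Filter configuration for SNP eligibility
#'
#' Thresholds of the SNP/read filter cascade: a per-record minimum of 15
#' REF+ALT+OTHER reads crossing the heterozygous SNP, Hardy-Weinberg
#' equilibrium at p > 1e-5, a genotyping call rate above 95%, a mappability
#' score of 1, and exclusion of SNPs whose OTHER-allele excess rejects the
#' overall-genotyping-error null at p < 0.05.
#'
#' @param min_reads Minimum reads per (SNP, individual) record (inclusive).
#' @param hwe_alpha SNPs are kept when the exact HWE p-value exceeds this.
#' @param min_genotyping_rate SNPs are kept when the fraction of non-missing
#'   genotype calls exceeds this.
#' @param min_mappability Minimum mappability annotation (kept when `>=`).
#' @param error_test_alpha SNPs are excluded when the genotyping-error test
#'   rejects below this level.
#' @param min_reads_scope `"record"` applies `min_reads` per
#'   (SNP, individual) record; `"pooled"` applies it to the SNP's pooled
#'   total instead.
#' @param hwe_method `"exact"` (default) or `"chisq"` for the 1-df
#'   chi-square approximation.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_reads = 15, hwe_alpha = 1e-5,
                          min_genotyping_rate = 0.95, min_mappability = 1,
                          error_test_alpha = 0.05,
                          min_reads_scope = c("record", "pooled"),
                          hwe_method = c("exact", "chisq")) {
  stopifnot(min_reads >= 0, hwe_alpha >= 0, hwe_alpha <= 1,
            min_genotyping_rate >= 0, min_genotyping_rate <= 1,
            min_mappability >= 0, min_mappability <= 1,
            error_test_alpha >= 0, error_test_alpha <= 1)
  structure(list(min_reads = min_reads, hwe_alpha = hwe_alpha,
                 min_genotyping_rate = min_genotyping_rate,
                 min_mappability = min_mappability,
                 error_test_alpha = error_test_alpha,
                 min_reads_scope = match.arg(min_reads_scope),
                 hwe_method = match.arg(hwe_method)),
            class = "filter_config")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on one SNP's genotype counts: conditioning on the
#' observed allele counts, every compatible heterozygote count has
#' probability proportional to its multinomial weight times `2^het`; the
#' two-sided p-value sums the probabilities of all configurations no more
#' probable than the observed one. Computed in log space, so cohorts of
#' thousands are fine.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts (non-negative, total
#'   at least 1).
#' @return The exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(25, 50, 25)   # textbook HWE, p = 1 region
#' hwe_exact_test(50, 0, 50)    # gross heterozygote deficit
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) abort("at least one genotyped individual is required")
  # minor-allele count fixes the set of reachable heterozygote counts
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  hom_minor <- (n_minor - hets) / 2
  hom_major <- n - hets - hom_minor
  logw <- lfactorial(n) - lfactorial(hom_minor) - lfactorial(hets) -
    lfactorial(hom_major) + hets * log(2)
  logw <- logw - max(logw)
  prob <- exp(logw) / sum(exp(logw))
  p_obs <- prob[hets == n_het]
  p <- sum(prob[prob <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

hwe_chisq_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  p <- (2 * n_hom_ref + n_het) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1)
  expd <- n * c(p^2, 2 * p * q, q^2)
  stat <- sum((c(n_hom_ref, n_het, n_hom_alt) - expd)^2 / expd)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Overall genotyping-error rate from allele counts
#'
#' The ratio of OTHER-allele read counts (bases matching neither REF nor
#' ALT) to all allele counts, pooled over every record.
#'
#' @param counts Allele-count tibble with `ref_count`, `alt_count`,
#'   `other_count`.
#' @return The error rate `e` in [0, 1].
#' @export
estimate_error_rate <- function(counts) {
  check_columns(counts, c("ref_count", "alt_count", "other_count"), "counts")
  if (nrow(counts) == 0) abort("counts table is empty")
  total <- sum(counts$ref_count) + sum(counts$alt_count) +
    sum(counts$other_count)
  if (total == 0) abort("counts table has zero total reads")
  sum(counts$other_count) / total
}

#' Exact test of OTHER-allele counts against the overall error rate
#'
#' Tests, for one SNP, the null hypothesis that its OTHER-allele count arose
#' from the overall genotyping-error rate `e`: a two-sided exact binomial
#' test (minimum-likelihood method) of `other` successes in `total` trials
#' at success probability `e`. SNPs rejecting the null harbour potential
#' genotyping error or random monoallelic expression and are excluded by the
#' cascade.
#'
#' @param other OTHER-allele read count at the SNP (pooled over
#'   heterozygotes).
#' @param total Total allele count at the SNP.
#' @param e Overall genotyping-error rate from [estimate_error_rate()].
#' @return Two-sided exact p-value. When `e = 0`, p is 1 if `other = 0` and
#'   0 otherwise (the SNP is always excluded).
#' @export
genotyping_error_test <- function(other, total, e) {
  stopifnot(other >= 0, other <= total, total >= 1, e >= 0, e <= 1)
  if (e == 0) return(as.numeric(other == 0))
  if (e == 1) return(as.numeric(other == total))
  binom.test(other, total, p = e)$p.value
}

new_filter_stage <- function(stage, snps_in, snps_out, reads_in, reads_out) {
  tibble(stage = stage, snps_in = unname(snps_in), snps_out = unname(snps_out),
         reads_in = unname(reads_in), reads_out = unname(reads_out))
}

#' Apply the SNP filter cascade
#'
#' Runs the eligibility filters in their canonical order and reports SNP and
#' read counts at every stage:
#' \enumerate{
#'   \item at least one heterozygous individual (genotype matrix);
#'   \item per-record read minimum — records with fewer than
#'     `min_reads` REF+ALT+OTHER reads are dropped, then SNPs with no
#'     surviving record;
#'   \item exact Hardy-Weinberg test on the cohort's array genotypes,
#'     keep `p > hwe_alpha`;
#'   \item genotyping rate `> min_genotyping_rate` across all genotyped
#'     individuals;
#'   \item mappability `>= min_mappability`;
#'   \item genotyping-error test: test each SNP's pooled OTHER count against
#'     the overall error rate (estimated once, over every record entering the
#'     cascade) and drop SNPs with `p < error_test_alpha`.
#' }
#'
#' @param counts Allele-count tibble (`snp_id`, `individual_id`,
#'   `ref_count`, `alt_count`, `other_count`).
#' @param genotypes Integer genotype matrix (individuals x SNPs).
#' @param panel SNP panel tibble with `snp_id` and `mappability`.
#' @param config A [filter_config()].
#' @return A list of class `ase_filter_result`: `counts` (the eligible
#'   records), `report` (per-stage tibble), and `overall_error_rate`.
#' @export
apply_ase_filters <- function(counts, genotypes, panel,
                              config = filter_config()) {
  check_columns(counts, c("snp_id", "individual_id", "ref_count",
                          "alt_count", "other_count"), "counts")
  unknown <- setdiff(unique(counts$snp_id), colnames(genotypes))
  if (length(unknown) > 0) {
    abort(sprintf("counts contain snp_id absent from genotypes: %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  counts <- mutate(counts,
                   total = .data$ref_count + .data$alt_count + .data$other_count)
  # the "overall" genotyping error is a property of the whole dataset:
  # estimate it on everything entering the cascade, not the survivors
  e <- if (nrow(counts) > 0 && sum(counts$total) > 0) {
    estimate_error_rate(counts)
  } else 0
  report <- list()
  tally <- function(df) c(snps = dplyr::n_distinct(df$snp_id),
                          reads = sum(df$total))

  # stage 1: >= 1 heterozygous individual
  before <- tally(counts)
  n_het_by_snp <- colSums(genotypes == 1L, na.rm = TRUE)
  keep_snps <- names(n_het_by_snp)[n_het_by_snp >= 1L]
  counts <- filter(counts, .data$snp_id %in% keep_snps)
  after <- tally(counts)
  report$het <- new_filter_stage("ge1_heterozygote", before["snps"],
                                 after["snps"], before["reads"], after["reads"])

  # stage 2: read minimum
  before <- after
  if (config$min_reads_scope == "record") {
    counts <- filter(counts, .data$total >= config$min_reads)
  } else {
    pooled <- counts %>% group_by(.data$snp_id) %>%
      summarise(pool = sum(.data$total), .groups = "drop")
    ok <- pooled$snp_id[pooled$pool >= config$min_reads]
    counts <- filter(counts, .data$snp_id %in% ok)
  }
  after <- tally(counts)
  report$reads <- new_filter_stage("min_reads", before["snps"], after["snps"],
                                   before["reads"], after["reads"])

  # stage 3: HWE on array genotypes of the full cohort
  before <- after
  hwe_fun <- if (config$hwe_method == "exact") hwe_exact_test else hwe_chisq_test
  snps_now <- unique(counts$snp_id)
  hwe_p <- vapply(snps_now, function(s) {
    g <- genotypes[, s]
    hwe_fun(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
            sum(g == 2L, na.rm = TRUE))
  }, numeric(1))
  counts <- filter(counts, .data$snp_id %in% snps_now[hwe_p > config$hwe_alpha])
  after <- tally(counts)
  report$hwe <- new_filter_stage("hwe", before["snps"], after["snps"],
                                 before["reads"], after["reads"])

  # stage 4: genotyping rate
  before <- after
  rate <- colMeans(!is.na(genotypes))
  ok <- names(rate)[rate > config$min_genotyping_rate]
  counts <- filter(counts, .data$snp_id %in% ok)
  after <- tally(counts)
  report$rate <- new_filter_stage("genotyping_rate", before["snps"],
                                  after["snps"], before["reads"], after["reads"])

  # stage 5: mappability
  before <- after
  ok <- panel$snp_id[panel$mappability >= config$min_mappability]
  counts <- filter(counts, .data$snp_id %in% ok)
  after <- tally(counts)
  report$map <- new_filter_stage("mappability", before["snps"], after["snps"],
                                 before["reads"], after["reads"])

  # stage 6: genotyping-error test on pooled per-SNP OTHER counts
  before <- after
  if (nrow(counts) > 0) {
    per_snp <- counts %>% group_by(.data$snp_id) %>%
      summarise(other = sum(.data$other_count), tot = sum(.data$total),
                .groups = "drop")
    err_p <- purrr::map2_dbl(per_snp$other, per_snp$tot,
                             genotyping_error_test, e = e)
    counts <- filter(counts,
                     .data$snp_id %in% per_snp$snp_id[err_p >= config$error_test_alpha])
  }
  after <- tally(counts)
  report$err <- new_filter_stage("genotyping_error_test", before["snps"],
                                 after["snps"], before["reads"], after["reads"])

  structure(list(counts = select(counts, -"total"),
                 report = bind_rows(report),
                 overall_error_rate = e,
                 config = config),
            class = "ase_filter_result")
}

#' @export
print.ase_filter_result <- function(x, ...) {
  cat("ASE filter cascade (overall genotyping-error rate ",
      signif(x$overall_error_rate, 3), "):\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Write a filter report to TSV and JSON
#'
#' @param x An `ase_filter_result` from [apply_ase_filters()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_filter_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "filter_report.tsv")
  js <- file.path(dir, "filter_report.json")
  readr::write_tsv(x$report, tsv)
  jsonlite::write_json(
    list(overall_error_rate = x$overall_error_rate, stages = x$report),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = js))
}
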