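# fixture: genotypes/panel/counts where each of 6 SNPs violates exactly one
# filter stage
make_stage_fixture <- function() {
  snps <- paste0("f", 1:6)
  inds <- paste0("P", 1:40)
  geno <- matrix(1L, nrow = 40, ncol = 6, dimnames = list(inds, snps))
  # f1: no heterozygote anywhere
  geno[, "f1"] <- 0L
  # f3: gross heterozygote deficit at allele frequency 1/2
  geno[, "f3"] <- c(rep(0L, 19), 1L, 1L, rep(2L, 19))
  # f4: observed genotypes in perfect HWE but 20% of calls missing
  geno[, "f4"] <- c(rep(0L, 8), rep(1L, 16), rep(2L, 8),
                    rep(NA_integer_, 8))
  # the remaining columns are ordinary HWE draws
  hwe_col <- rep(c(0L, 1L, 1L, 2L), 10)
  for (s in c("f2", "f5", "f6")) geno[, s] <- hwe_col
  panel <- tibble::tibble(
    snp_id = snps, chrom = "chr1", pos = 1:6 * 100L,
    ref_allele = "A", alt_allele = "G",
    mappability = c(1, 1, 1, 1, 0.5, 1))  # f5 fails mappability
  counts <- dplyr::bind_rows(lapply(snps[-1], function(s) {
    hets <- inds[which(geno[, s] == 1L)]
    if (length(hets) == 0) return(NULL)
    tibble::tibble(snp_id = s, individual_id = hets,
                   ref_count = 10L, alt_count = 10L, other_count = 0L)
  }))
  # f2: all records below the 15-read minimum
  counts$ref_count[counts$snp_id == "f2"] <- 5L
  counts$alt_count[counts$snp_id == "f2"] <- 5L
  # f6: OTHER counts far above the overall error rate
  counts$other_count[counts$snp_id == "f6"] <- 15L
  list(geno = geno, panel = panel, counts = counts)
}

test_that("HWE exact test matches its examples and the enumeration oracle", {
  expect_equal(hwe_exact_test(0, 0, 5), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(2:30, 1)
      counts <- as.vector(stats::rmultinom(1, n, prob = runif(3, 0.05, 1)))
      expect_equal(hwe_exact_test(counts[1], counts[2], counts[3]),
                   oracle_hwe(counts[1], counts[2], counts[3]),
                   tolerance = 1e-12)
    }
  })
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("overall genotyping-error rate is the pooled OTHER fraction", {
  tab <- tibble::tibble(ref_count = c(4000, 3000), alt_count = c(2000, 950),
                        other_count = c(30, 20))
  expect_equal(estimate_error_rate(tab), 50 / 10000)
  tab0 <- dplyr::mutate(tab, other_count = 0)
  expect_equal(estimate_error_rate(tab0), 0)
  expect_error(estimate_error_rate(tab[0, ]), "empty")
  expect_error(
    estimate_error_rate(tibble::tibble(ref_count = 0, alt_count = 0,
                                       other_count = 0)),
    "zero total")
})

test_that("estimated error rate recovers the simulated per-base rate", {
  cfg <- sim_config(n_individuals = 300, n_snps = 30, error_rate = 0.01,
                    depth_mean = 50, genotyping_rate = 1,
                    maf_range = c(0.4, 0.5), seed = 5)
  g <- simulate_genotypes(cfg)
  cnt <- simulate_allele_counts(g$genotypes, cfg, simulate_truth_ratios(cfg))
  n_reads <- sum(cnt$ref_count + cnt$alt_count + cnt$other_count)
  expect_gt(n_reads, 1e5)
  e_hat <- estimate_error_rate(cnt)
  expect_lt(abs(e_hat - 0.01), 3 * sqrt(0.01 * 0.99 / n_reads))
})

test_that("genotyping-error test matches the exact binomial oracle", {
  expect_equal(genotyping_error_test(0, 100, 0), 1)
  expect_equal(genotyping_error_test(5, 100, 0), 0)
  expect_lt(genotyping_error_test(50, 100, 0.01), 1e-10)
  expect_equal(genotyping_error_test(3, 1000, 0.005),
               oracle_binom_two_sided(3, 1000, 0.005), tolerance = 1e-10)
  withr::with_seed(43, {
    for (i in 1:50) {
      tot <- sample(10:500, 1)
      oth <- rbinom(1, tot, 0.05)
      e <- runif(1, 0.001, 0.2)
      expect_equal(genotyping_error_test(oth, tot, e),
                   oracle_binom_two_sided(oth, tot, e), tolerance = 1e-10)
    }
  })
})

test_that("each cascade stage removes exactly its engineered violator", {
  fx <- make_stage_fixture()
  res <- apply_ase_filters(fx$counts, fx$geno, fx$panel, filter_config())
  expect_equal(nrow(res$counts), 0)
  expect_equal(res$report$stage,
               c("ge1_heterozygote", "min_reads", "hwe", "genotyping_rate",
                 "mappability", "genotyping_error_test"))
  # f1 never enters counts (no heterozygote); report starts from 5 SNPs
  expect_equal(res$report$snps_in[1], 5)
  expect_equal(res$report$snps_out - res$report$snps_in,
               c(0, -1, -1, -1, -1, -1))
  # cascade is monotone
  expect_true(all(res$report$snps_out <= res$report$snps_in))
  expect_true(all(res$report$reads_out <= res$report$reads_in))
})

test_that("an all-passing table survives unchanged and thresholds are inclusive", {
  inds <- paste0("P", 1:40)
  geno <- matrix(rep(c(0L, 1L, 1L, 2L), 10), nrow = 40, ncol = 2,
                 dimnames = list(inds, c("s1", "s2")))
  panel <- tibble::tibble(snp_id = c("s1", "s2"), chrom = "chr1",
                          pos = c(100L, 200L), ref_allele = "A",
                          alt_allele = "G", mappability = 1)
  hets <- inds[geno[, 1] == 1L]
  counts <- dplyr::bind_rows(
    tibble::tibble(snp_id = "s1", individual_id = hets, ref_count = 8L,
                   alt_count = 7L, other_count = 0L),   # exactly 15 reads
    tibble::tibble(snp_id = "s2", individual_id = hets, ref_count = 7L,
                   alt_count = 7L, other_count = 0L))   # 14 reads
  res <- apply_ase_filters(counts, geno, panel, filter_config())
  expect_true(all(res$counts$snp_id == "s1"))  # 15 kept, 14 dropped
  expect_equal(nrow(res$counts), length(hets))

  # degenerate thresholds pass everything through
  res0 <- apply_ase_filters(counts, geno, panel,
                            filter_config(min_reads = 0, hwe_alpha = 0,
                                          min_genotyping_rate = 0,
                                          min_mappability = 0,
                                          error_test_alpha = 0))
  expect_equal(nrow(res0$counts), nrow(counts))
})

test_that("permuting individual order never changes the eligible set", {
  fx <- make_stage_fixture()
  res1 <- apply_ase_filters(fx$counts, fx$geno, fx$panel)
  perm <- withr::with_seed(7, sample(nrow(fx$geno)))
  res2 <- apply_ase_filters(fx$counts[sample(nrow(fx$counts)), ],
                            fx$geno[perm, ], fx$panel)
  expect_equal(sort(unique(res1$counts$snp_id)),
               sort(unique(res2$counts$snp_id)))
  expect_equal(res1$report$snps_out, res2$report$snps_out)
})

test_that("inconsistent inputs fail fast", {
  fx <- make_stage_fixture()
  bad <- dplyr::mutate(fx$counts,
                       snp_id = replace(snp_id, 1, "unknown_snp"))
  expect_error(apply_ase_filters(bad, fx$geno, fx$panel), "absent from")
})

test_that("chi-square HWE variant is offered and agrees asymptotically", {
  p_exact <- hwe_exact_test(400, 480, 120)
  fx <- make_stage_fixture()
  res <- apply_ase_filters(fx$counts, fx$geno, fx$panel,
                           filter_config(hwe_method = "chisq"))
  expect_s3_class(res, "ase_filter_result")
  # large balanced sample: exact and chi-square agree to a few percent
  p_chisq <- aseflow:::hwe_chisq_test(400, 480, 120)
  expect_lt(abs(p_exact - p_chisq) / p_chisq, 0.25)
})
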