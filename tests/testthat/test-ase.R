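test_that("reference ratio is REF/(REF+ALT) with OTHER excluded", {
  expect_equal(ref_ratio(1, 19), 0.05)
  expect_equal(ref_ratio(33, 67), 0.33)
  for (k in c(1, 5, 100)) expect_equal(ref_ratio(k, k), 0.5)
  expect_error(ref_ratio(0, 0), ">= 1")
})

test_that("binomial ASE test matches closed forms and is symmetric", {
  expect_equal(binomial_ase_test(5, 5), 1)
  expect_equal(binomial_ase_test(15, 0), 2 * 0.5^15, tolerance = 1e-12)
  expect_lt(binomial_ase_test(3383, 2305), 0.001)
  withr::with_seed(1, {
    for (i in 1:25) {
      a <- sample(0:60, 1); b <- sample(0:60, 1)
      if (a + b == 0) a <- 1
      expect_equal(binomial_ase_test(a, b), binomial_ase_test(b, a))
      expect_equal(binomial_ase_test(a, b),
                   oracle_binom_two_sided(a, a + b, 0.5), tolerance = 1e-10)
    }
  })
})

test_that("moment dispersion is zero for identical counts and recovers truth", {
  expect_equal(as.numeric(estimate_nb_dispersion(rep(10, 5), rep(10, 5))), 0)
  disp1 <- estimate_nb_dispersion(ref = 3, alt = 4)
  expect_equal(as.numeric(disp1), 0.1)
  expect_true(attr(disp1, "fallback"))
  # NB counts with true dispersion 0.1: estimates concentrate near truth
  ests <- withr::with_seed(2, vapply(1:50, function(i) {
    r <- rnbinom(200, mu = 50, size = 10)
    a <- rnbinom(200, mu = 50, size = 10)
    as.numeric(estimate_nb_dispersion(r, a))
  }, numeric(1)))
  expect_true(all(ests > 0.05 & ests < 0.2))
  # clamped to [0, 10]
  expect_lte(as.numeric(estimate_nb_dispersion(c(0, 1000), c(1000, 0))), 10)
})

test_that("NB exact test: balanced counts, binomial limit, enumeration oracle", {
  expect_equal(nb_exact_ase_test(c(10, 10), c(10, 10), phi = 0.2), 1)
  expect_lt(abs(nb_exact_ase_test(30, 10, phi = 1e-8) -
                  binomial_ase_test(30, 10)), 1e-3)
  withr::with_seed(3, {
    for (i in 1:40) {
      n <- sample(1:4, 1)
      ref <- rpois(n, 5); alt <- rpois(n, 5)
      if (sum(ref) + sum(alt) == 0 || sum(ref) + sum(alt) > 50) next
      phi <- runif(1, 0.01, 1)
      expect_equal(nb_exact_ase_test(ref, alt, phi),
                   oracle_nb_conditional(sum(ref), sum(alt), n, phi),
                   tolerance = 1e-10)
    }
  })
})

test_that("NB exact p-values decrease with imbalance at fixed depth and phi", {
  total <- 60
  p <- vapply(30:55, function(r) nb_exact_ase_test(r, total - r, phi = 0.1),
              numeric(1))
  expect_true(all(diff(p) <= 1e-12))
})

test_that("BH adjustment matches the step-up oracle and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  withr::with_seed(4, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))^2
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-14)
      expect_true(all(q >= p - 1e-15))
      # thresholding adjusted values recovers the step-up set
      alpha <- 0.2
      m <- length(p)
      k <- max(c(0, which(sort(p) <= alpha * seq_len(m) / m)))
      stepup <- if (k == 0) rep(FALSE, m) else p <= sort(p)[k]
      expect_equal(q <= alpha, stepup)
    }
  })
})

test_that("call_ase returns a sorted, FDR-annotated table per engine", {
  cfg <- sim_config(n_individuals = 30, n_snps = 40, ase_fraction = 0.3,
                    ase_ratio_range = c(0.8, 0.95), depth_mean = 60,
                    overdispersion_rho = 0, error_rate = 0, seed = 9)
  g <- simulate_genotypes(cfg)
  tr <- simulate_truth_ratios(cfg)
  cnt <- simulate_allele_counts(g$genotypes, cfg, tr)
  for (engine in c("binomial", "nb_aggregate", "nb_individual")) {
    res <- call_ase(cnt, engine = engine)
    expect_s3_class(res, "ase_result")
    expect_true(all(diff(res$p_raw) >= 0))
    expect_true(all(res$p_fdr >= res$p_raw - 1e-15))
    expect_true(all(res$engine == engine))
    expect_true(all(res$n_reads >= res$n_het))
  }
  expect_error(call_ase(cnt, engine = "bogus"))
})

test_that("a strong ASE SNP is flagged and engines agree when phi-hat is 0", {
  # 20 heterozygotes at depth 50, true ratio 0.95
  cnt <- withr::with_seed(10, tibble::tibble(
    snp_id = "s", individual_id = paste0("I", 1:20),
    ref_count = rbinom(20, 50, 0.95)))
  cnt$alt_count <- 50 - cnt$ref_count
  cnt$other_count <- 0L
  res <- call_ase(cnt, engine = "nb_individual")
  expect_true(res$significant[1])

  # identical per-individual counts force phi-hat = 0: NB == binomial
  flat <- tibble::tibble(snp_id = rep(c("a", "b"), each = 5),
                         individual_id = rep(paste0("I", 1:5), 2),
                         ref_count = rep(c(20L, 12L), each = 5),
                         alt_count = rep(c(10L, 12L), each = 5),
                         other_count = 0L)
  r_nb <- call_ase(flat, engine = "nb_individual")
  r_bi <- call_ase(flat, engine = "binomial")
  expect_equal(r_nb$p_raw, r_bi$p_raw, tolerance = 1e-9)
})

test_that("null binomial p-values are approximately uniform", {
  # pooled depth >= 500 per SNP, true ratio 0.5, no bias
  p <- withr::with_seed(11, vapply(1:1000, function(i) {
    depth <- sample(500:1500, 1)  # varying depth smooths discreteness
    ref <- rbinom(1, depth, 0.5)
    binomial_ase_test(ref, depth - ref)
  }, numeric(1)))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("bias diagnostics reproduce the skew split and depth profile", {
  skew_la <- ratio_skew_test(3383, 2305)
  expect_equal(round(skew_la$pct_above), 59)
  expect_lt(skew_la$p, 0.001)
  skew_lv <- ratio_skew_test(5539, 3103)
  expect_equal(round(skew_lv$pct_above), 64)
  expect_lt(skew_lv$p, 0.001)

  res <- tibble::tibble(
    snp_id = paste0("s", 1:6),
    n_het = 3L, n_reads = c(20L, 40L, 80L, 150L, 25L, 70L),
    ref_ratio = c(0.8, 0.7, 0.6, 0.5, 0.3, 0.9),
    p_raw = 0.001, p_fdr = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.2),
    engine = "binomial",
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  class(res) <- c("ase_result", class(res))
  cnt <- tibble::tibble(ref_count = 55, alt_count = 45, other_count = 0)
  d <- bias_diagnostics(res, cnt)
  expect_equal(d$n_above_half, 3)  # the 0.9 SNP is not significant
  expect_equal(d$n_below_half, 1)
  expect_equal(d$n_at_half, 1)
  expect_equal(d$overall_ref_ratio, 0.55)
  expect_equal(nrow(d$ratio_by_depth_bin) >= 3, TRUE)

  # no significant SNPs: diagnostics carry an empty skew test, no error
  res$significant <- FALSE
  d0 <- bias_diagnostics(res, cnt)
  expect_true(is.na(d0$skew_p))
})

test_that("unbiased synthetic data rarely trip the skew test", {
  hits <- withr::with_seed(12, vapply(1:20, function(i) {
    ratios <- rbinom(200, 400, 0.5) / 400
    above <- sum(ratios > 0.5); below <- sum(ratios < 0.5)
    ratio_skew_test(above, below)$p < 0.05
  }, logical(1)))
  expect_gte(mean(!hits), 0.9)
})
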