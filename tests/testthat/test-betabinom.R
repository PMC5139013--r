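test_that("beta-binomial log-likelihood reduces to binomial at rho = 0", {
  ref <- c(3, 7, 5); total <- c(10, 12, 9)
  expect_equal(betabinom_loglik(ref, total, 0.6, 0),
               sum(dbinom(ref, total, 0.6, log = TRUE)), tolerance = 1e-12)
  # single record at ref = total and mu -> 1: loglik -> 0 from below
  ll <- betabinom_loglik(10, 10, 1 - 1e-9, 0)
  expect_lt(ll, 0)
  expect_gt(ll, -1e-6)
  expect_error(betabinom_loglik(1, 2, 0, 0.1), "strictly in")
  expect_error(betabinom_loglik(1, 2, 0.5, 1), "rho")
})

test_that("beta-binomial pmf matches the rising-factorial oracle", {
  withr::with_seed(20, {
    for (i in 1:60) {
      n <- sample(1:30, 1)
      k <- sample(0:n, 1)
      mu <- runif(1, 0.05, 0.95)
      rho <- runif(1, 0.01, 0.6)
      ll <- betabinom_loglik(k, n, mu, rho)
      expect_equal(exp(ll), oracle_bb_pmf(k, n, mu, rho), tolerance = 1e-10)
    }
  })
  # pmf sums to one
  mu <- 0.3; rho <- 0.2; n <- 17
  total_p <- sum(vapply(0:n, function(k) exp(betabinom_loglik(k, n, mu, rho)),
                        numeric(1)))
  expect_equal(total_p, 1, tolerance = 1e-10)
})

test_that("ML fit recovers parameters and handles degenerate inputs", {
  # no between-individual variance: mu ~ 0.5, rho ~ 0
  rec <- tibble::tibble(ref_count = rep(5, 10), alt_count = rep(5, 10))
  f <- fit_betabinom(rec)
  expect_equal(unname(f$mu), 0.5, tolerance = 1e-3)
  expect_lt(f$rho, 0.01)
  expect_true(f$converged)

  # single record: rho pinned to 0 with a flag
  f1 <- fit_betabinom(tibble::tibble(ref_count = 7, alt_count = 3))
  expect_equal(f1$rho, 0)
  expect_false(f1$rho_estimable)

  # parameter recovery at mu = 0.7, rho = 0.05, n = 200
  errs <- withr::with_seed(21, vapply(1:20, function(i) {
    ref <- rbetabinom(200, 50, 0.7, 0.05)
    f <- fit_betabinom(tibble::tibble(ref_count = ref, total = 50))
    c(abs(unname(f$mu) - 0.7), abs(f$rho - 0.05))
  }, numeric(2)))
  expect_lt(max(errs[1, ]), 0.03)
  expect_lt(max(errs[2, ]), 0.03)
})

test_that("tidy and glance summarise fits broom-style", {
  rec <- tibble::tibble(ref_count = c(10, 12, 8), alt_count = c(10, 8, 12),
                        group = c("x", "x", "y"))
  f <- fit_betabinom(rec, group = rec$group)
  td <- tidy(f)
  expect_equal(td$term, c("mu_x", "mu_y", "rho"))
  gl <- glance(f)
  expect_true(all(c("logLik", "converged", "nobs") %in% names(gl)))
  expect_equal(gl$df, 3)
})

test_that("group LRT: identical groups give p ~ 1, and extreme splits reject", {
  rec <- tibble::tibble(ref_count = rep(c(10, 11, 9), 2),
                        alt_count = rep(c(10, 9, 11), 2),
                        group = rep(c("a", "b"), each = 3))
  out <- lrt_group_differential(rec)
  expect_lt(out$lrt_stat, 0.01)
  expect_gt(out$p_raw, 0.9)

  # pattern of a monoallelic hit: ratio 1.00 vs 0.50 at high depth
  rec2 <- tibble::tibble(ref_count = c(200, 100), alt_count = c(0, 100),
                         group = c("poAF", "none"))
  out2 <- lrt_group_differential(rec2)
  expect_lt(out2$p_raw, 1e-6)
  expect_true(out2$low_confidence)
  expect_equal(out2$ratio_group2, 1)  # groups ordered by factor level
  expect_equal(out2$ratio_group1, 0.5)
})

test_that("LRT is invariant to group relabeling and REF/ALT mirror", {
  rec <- tibble::tibble(ref_count = c(30, 25, 10, 12),
                        alt_count = c(10, 15, 30, 28),
                        group = c("a", "a", "b", "b"))
  out1 <- lrt_group_differential(rec)
  rec_swapped <- dplyr::mutate(rec, group = ifelse(group == "a", "b", "a"))
  out2 <- lrt_group_differential(rec_swapped)
  expect_equal(out1$lrt_stat, out2$lrt_stat, tolerance = 1e-6)
  rec_mirror <- dplyr::mutate(rec, tmp = ref_count, ref_count = alt_count,
                              alt_count = tmp)
  out3 <- lrt_group_differential(rec_mirror[, names(rec)])
  expect_equal(out1$lrt_stat, out3$lrt_stat, tolerance = 1e-4)
})

test_that("at rho = 0 with one record per group the LRT matches the two-proportion oracle", {
  withr::with_seed(22, {
    for (i in 1:20) {
      n1 <- sample(20:80, 1); n2 <- sample(20:80, 1)
      x1 <- rbinom(1, n1, 0.5); x2 <- rbinom(1, n2, 0.7)
      rec <- tibble::tibble(ref_count = c(x1, x2),
                            alt_count = c(n1 - x1, n2 - x2),
                            group = c("a", "b"))
      out <- lrt_group_differential(rec)
      oracle <- oracle_two_prop_lrt(x1, n1, x2, n2)
      # the fitted model may spend likelihood on rho >= 0; with one record
      # per group the boundary fit matches the binomial LRT closely
      expect_equal(out$lrt_stat, oracle, tolerance = 1e-4)
    }
  })
})

test_that("paired LRT handles timepoint symmetry and incomplete pairs", {
  rec <- tibble::tibble(
    snp_id = "s",
    individual_id = rep(paste0("I", 1:4), 2),
    ref_count = c(10, 12, 9, 11, 30, 28, 32, 29),
    alt_count = c(10, 8, 11, 9, 10, 12, 8, 11),
    timepoint = rep(c("baseline", "post"), each = 4))
  out <- lrt_paired_differential(rec)
  expect_lt(out$p_raw, 0.05)
  expect_equal(out$n_pairs, 4)

  # identical timepoints: p ~ 1
  rec_same <- rec
  rec_same$ref_count <- rep(c(10, 12, 9, 11), 2)
  rec_same$alt_count <- rep(c(10, 8, 11, 9), 2)
  expect_gt(lrt_paired_differential(rec_same)$p_raw, 0.9)

  # swapping timepoint labels within individuals leaves p unchanged
  rec_swap <- dplyr::mutate(rec, timepoint = ifelse(timepoint == "post",
                                                    "baseline", "post"))
  expect_equal(lrt_paired_differential(rec)$lrt_stat,
               lrt_paired_differential(rec_swap)$lrt_stat, tolerance = 1e-6)

  # an individual missing one timepoint is dropped with a message
  rec_miss <- rec[-8, ]
  expect_message(out_miss <- lrt_paired_differential(rec_miss), "dropped")
  expect_equal(out_miss$n_pairs, 3)
})

test_that("table-level differential tests BH-adjust and skip untestable SNPs", {
  cnt <- tibble::tibble(
    snp_id = rep(c("s1", "s2", "s3"), each = 4),
    individual_id = rep(paste0("I", 1:4), 3),
    ref_count = c(10, 12, 30, 29,  11, 9, 10, 12,  40, 38, 5, 6),
    alt_count = c(10, 8, 10, 11,  9, 11, 10, 8,  5, 6, 40, 39),
    other_count = 0L,
    group = rep(c("g1", "g1", "g2", "g2"), 3))
  # s3's group2 individuals removed: untestable, skipped
  cnt_miss <- cnt[!(cnt$snp_id == "s3" & cnt$group == "g2"), ]
  out <- suppressMessages(diff_ase_group(cnt_miss))
  expect_equal(sort(out$snp_id), c("s1", "s2"))
  expect_equal(attr(out, "skipped"), "s3")
  expect_equal(out$p_fdr, bh_adjust(out$p_raw))
})
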