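#' Reference sequence ratio
#'
#' REF reads divided by REF + ALT reads. OTHER reads are excluded. A ratio
#' of 0.5 means both alleles are expressed equally; a cohort-wide ratio
#' above 0.5 signals reference-genome mapping bias.
#'
#' @param ref,alt REF and ALT read counts; `ref + alt` must be at least 1.
#' @return `ref / (ref + alt)`, vectorised.
#' @export
#' @examples
#' ref_ratio(33, 67)
ref_ratio <- function(ref, alt) {
  if (any(ref + alt < 1)) abort("ref + alt must be >= 1")
  ref / (ref + alt)
}

#' Aggregate binomial test of allelic balance
#'
#' Two-sided exact binomial test of the pooled REF count among pooled
#' REF + ALT reads against a balanced ratio of 0.5, by the
#' minimum-likelihood method (outcomes no more probable than the observed
#' one).
#'
#' @param pooled_ref,pooled_alt REF and ALT counts summed over individuals.
#' @return Two-sided exact p-value.
#' @export
#' @examples
#' binomial_ase_test(15, 0)  # 2 * 0.5^15
binomial_ase_test <- function(pooled_ref, pooled_alt) {
  n <- pooled_ref + pooled_alt
  if (n < 1) abort("pooled_ref + pooled_alt must be >= 1")
  binom.test(pooled_ref, n, p = 0.5)$p.value
}

#' Method-of-moments NB dispersion for one SNP's allele counts
#'
#' Treats a SNP's per-individual REF and ALT counts as two negative-binomial
#' groups with each individual's total as exposure, fits the two group rates
#' (the pooled REF ratio and its complement), and measures excess variance
#' of the per-individual split by the Pearson statistic
#' `X^2 = sum (y - m)^2 / m` over the `2n` cells. Conditional on the totals,
#' the split of two equal-mean NB counts is beta-binomial with intraclass
#' correlation `rho = 1/(2/phi + 1)`, so `E[X^2] = (n - 1) + rho (sum t - n)`
#' under the fitted rate; the moment estimate is
#' `rho = max(0, (X^2 - (n - 1)) / (sum t - n))`, translated back to the NB
#' dispersion `phi = 2 rho / (1 - rho)` and clamped to `[0, 10]`. Under pure
#' binomial sampling the statistic sits near `n - 1` and the estimate clamps
#' to zero; for counts with true NB dispersion `phi` it is consistent.
#'
#' @param ref,alt Per-individual REF and ALT counts (equal lengths, at least
#'   2 individuals for estimation).
#' @param fallback Dispersion returned, with a `fallback` attribute, when
#'   only one individual is available (default 0.1, the fixed value of the
#'   aggregate mode).
#' @return Non-negative dispersion estimate; attribute `fallback = TRUE`
#'   when the fallback was used.
#' @export
estimate_nb_dispersion <- function(ref, alt, fallback = 0.1) {
  stopifnot(length(ref) == length(alt), all(ref >= 0), all(alt >= 0))
  keep <- (ref + alt) > 0
  ref <- ref[keep]; alt <- alt[keep]
  n <- length(ref)
  if (n < 2) return(structure(fallback, fallback = TRUE))
  t <- ref + alt
  tot <- sum(t)
  pi_hat <- sum(ref) / tot
  m <- c(pi_hat * t, (1 - pi_hat) * t)
  y <- c(ref, alt)
  ok <- m > 0
  x2 <- sum((y[ok] - m[ok])^2 / m[ok])
  rho <- max(0, (x2 - (n - 1)) / max(1, tot - n))
  rho <- min(rho, 1 - 1e-6)
  phi <- 2 * rho / (1 - rho)
  structure(min(phi, 10), fallback = FALSE)
}

# signed per-SNP moment estimate of the split correlation, for moderation:
# clamping at zero before shrinkage would bias every estimate upward
signed_split_rho <- function(ref, alt) {
  keep <- (ref + alt) > 0
  ref <- ref[keep]; alt <- alt[keep]
  n <- length(ref)
  if (n < 2) return(c(rho = NA_real_, n = n))
  t <- ref + alt
  tot <- sum(t)
  pi_hat <- sum(ref) / tot
  m <- c(pi_hat * t, (1 - pi_hat) * t)
  y <- c(ref, alt)
  ok <- m > 0
  x2 <- sum((y[ok] - m[ok])^2 / m[ok])
  c(rho = (x2 - (n - 1)) / max(1, tot - n), n = n)
}

#' Exact conditional negative-binomial test of allelic balance
#'
#' Small-sample exact test of equal means for the REF and ALT read totals of
#' one SNP, given their pooled sum. Each group total is the sum of `n`
#' per-individual NB counts with common mean and dispersion `phi`, hence
#' itself negative binomial with size `n / phi`; conditioning on the pooled
#' total `T`, the probability of each split `r : T - r` is proportional to
#' the product of the two NB densities at equal means. The two-sided p-value
#' sums split probabilities no larger than the observed one
#' (minimum-likelihood method). As `phi -> 0` the conditional law tends to
#' Binomial(T, 1/2) and the test converges to [binomial_ase_test()].
#'
#' @param ref,alt Per-individual REF and ALT counts.
#' @param phi NB dispersion (non-negative); `phi = 0` gives the exact
#'   binomial test.
#' @return Two-sided exact p-value.
#' @export
nb_exact_ase_test <- function(ref, alt, phi) {
  stopifnot(length(ref) == length(alt), phi >= 0)
  n <- length(ref)
  y_ref <- sum(ref)
  y_alt <- sum(alt)
  total <- y_ref + y_alt
  if (total == 0) abort("pooled total is zero")
  if (phi < 1e-12) return(binomial_ase_test(y_ref, y_alt))
  size <- n / phi
  mu <- total / 2
  r <- 0:total
  logp <- dnbinom(r, size = size, mu = mu, log = TRUE) +
    dnbinom(total - r, size = size, mu = mu, log = TRUE)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  p_obs <- prob[r == y_ref]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; adjusted values are monotone over the sorted
#' order, never below the raw values, and capped at 1. Thresholding the
#' adjusted values at `alpha` recovers the BH step-up rejection set exactly.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call allele-specific expression per SNP
#'
#' Tests every SNP in an eligible allele-count table for departure of the
#' REF/(REF+ALT) ratio from 0.5, with one of three engines:
#' \describe{
#'   \item{`binomial`}{exact binomial test on counts pooled over
#'     heterozygotes;}
#'   \item{`nb_aggregate`}{exact conditional NB test on the pooled counts
#'     with a fixed dispersion (default 0.1);}
#'   \item{`nb_individual`}{exact conditional NB test on per-individual
#'     counts with a per-SNP method-of-moments dispersion, moderated across
#'     SNPs (the default engine, the most conservative of the three).}
#' }
#' Raw p-values are BH-adjusted across SNPs.
#'
#' For `nb_individual` the per-SNP dispersions are shrunk towards the
#' cross-SNP median of the signed moment estimates, with weight
#' `prior_df` against the per-SNP degrees of freedom (heterozygotes minus
#' one) — the same empirical-Bayes idea count packages use for tagwise
#' dispersion. Raw per-SNP moment estimates are noisy at typical cohort
#' sizes, and plugging unshrunk values into the exact test makes it
#' needlessly conservative.
#'
#' @param counts Eligible allele-count tibble (ideally the `counts` element
#'   of [apply_ase_filters()]).
#' @param engine Test engine, see above.
#' @param fdr_alpha Significance level on the adjusted p-values.
#' @param fixed_dispersion Dispersion for `nb_aggregate` and the
#'   single-individual fallback of `nb_individual`.
#' @param prior_df Moderation weight for the `nb_individual` dispersion
#'   shrinkage (default 20; 0 disables moderation and uses the raw per-SNP
#'   estimates).
#' @return A tibble of class `ase_result`, one row per SNP, sorted by
#'   `p_raw`: `snp_id`, `n_het`, `n_reads` (pooled REF+ALT), `ref_ratio`,
#'   `p_raw`, `p_fdr`, `engine`, `significant`.
#' @export
call_ase <- function(counts, engine = c("nb_individual", "binomial",
                                        "nb_aggregate"),
                     fdr_alpha = 0.05, fixed_dispersion = 0.1,
                     prior_df = 20) {
  engine <- match.arg(engine)
  check_columns(counts, c("snp_id", "individual_id", "ref_count",
                          "alt_count"), "counts")
  if (nrow(counts) == 0) {
    out <- tibble(snp_id = character(), n_het = integer(),
                  n_reads = integer(), ref_ratio = numeric(),
                  p_raw = numeric(), p_fdr = numeric(), engine = character(),
                  significant = logical())
    return(structure(out, class = c("ase_result", class(out))))
  }
  by_snp <- counts %>%
    group_by(.data$snp_id) %>%
    summarise(n_het = dplyr::n_distinct(.data$individual_id),
              pooled_ref = sum(.data$ref_count),
              pooled_alt = sum(.data$alt_count),
              .groups = "drop") %>%
    filter(.data$pooled_ref + .data$pooled_alt >= 1)
  split_counts <- split(counts, counts$snp_id)
  phi_of <- NULL
  if (engine == "nb_individual") {
    est <- vapply(by_snp$snp_id, function(s) {
      rec <- split_counts[[s]]
      signed_split_rho(rec$ref_count, rec$alt_count)
    }, numeric(2))
    rho_s <- est[1, ]
    df_snp <- pmax(est[2, ] - 1, 0)
    if (prior_df > 0 && any(!is.na(rho_s))) {
      common <- stats::median(rho_s, na.rm = TRUE)
      rho_mod <- (df_snp * ifelse(is.na(rho_s), 0, rho_s) +
                    prior_df * common) / (df_snp + prior_df)
    } else {
      rho_mod <- rho_s
    }
    rho_mod <- pmin(pmax(rho_mod, 0), 1 - 1e-6)
    phi_of <- ifelse(is.na(rho_s), fixed_dispersion,
                     pmin(2 * rho_mod / (1 - rho_mod), 10))
    names(phi_of) <- by_snp$snp_id
  }
  p_raw <- purrr::map_dbl(seq_len(nrow(by_snp)), function(i) {
    s <- by_snp$snp_id[i]
    switch(engine,
      binomial = binomial_ase_test(by_snp$pooled_ref[i], by_snp$pooled_alt[i]),
      nb_aggregate = nb_exact_ase_test(by_snp$pooled_ref[i],
                                       by_snp$pooled_alt[i],
                                       phi = fixed_dispersion),
      nb_individual = {
        rec <- split_counts[[s]]
        nb_exact_ase_test(rec$ref_count, rec$alt_count, phi = phi_of[[s]])
      })
  })
  out <- by_snp %>%
    mutate(n_reads = .data$pooled_ref + .data$pooled_alt,
           ref_ratio = ref_ratio(.data$pooled_ref, .data$pooled_alt),
           p_raw = p_raw,
           p_fdr = bh_adjust(p_raw),
           engine = engine,
           significant = .data$p_fdr < fdr_alpha) %>%
    select("snp_id", "n_het", "n_reads", "ref_ratio", "p_raw", "p_fdr",
           "engine", "significant") %>%
    arrange(.data$p_raw)
  structure(out, class = c("ase_result", class(out)))
}

#' Two-sided binomial skew test of the above/below-0.5 split
#'
#' Among ASE SNPs, tests whether REF ratios fall above 0.5 more often than
#' below it — the signature of residual reference-genome bias.
#'
#' @param n_above,n_below Counts of SNPs with ratio above / below 0.5.
#' @return A list: `pct_above` (percentage above 0.5 among the two groups),
#'   `p` (two-sided exact binomial p-value), `n_above`, `n_below`.
#' @export
#' @examples
#' ratio_skew_test(59, 41)
ratio_skew_test <- function(n_above, n_below) {
  n <- n_above + n_below
  p <- if (n == 0) NA_real_ else binom.test(n_above, n, p = 0.5)$p.value
  list(pct_above = if (n == 0) NA_real_ else 100 * n_above / n,
       p = p, n_above = n_above, n_below = n_below)
}

#' Reference-bias diagnostics over ASE calls
#'
#' Summarises residual reference-genome bias among FDR-significant SNPs: the
#' above/below-0.5 split of REF ratios with its exact skew test, the overall
#' pooled REF ratio of the input table, and the mean REF ratio per pooled
#' read-depth bin (bias is typically strongest at low depth).
#'
#' @param results An `ase_result` table from [call_ase()].
#' @param counts The allele-count table the results were computed from.
#' @param depth_bins Increasing breakpoints of pooled REF+ALT depth; the
#'   defaults give bins [15,30), [30,60), [60,120), [120, Inf).
#' @param significant_only Restrict the skew split to FDR-significant SNPs
#'   (default TRUE).
#' @return A list of class `ase_bias`: `overall_ref_ratio`, `n_above_half`,
#'   `n_below_half`, `n_at_half`, `skew_p`, `ratio_by_depth_bin` (tibble of
#'   bin, mean ratio, n).
#' @export
bias_diagnostics <- function(results, counts,
                             depth_bins = c(15, 30, 60, 120, Inf),
                             significant_only = TRUE) {
  overall <- if (nrow(counts) > 0) {
    ref_ratio(sum(counts$ref_count), sum(counts$alt_count))
  } else NA_real_
  sel <- if (significant_only) filter(results, .data$significant) else results
  above <- sum(sel$ref_ratio > 0.5)
  below <- sum(sel$ref_ratio < 0.5)
  at <- sum(sel$ref_ratio == 0.5)
  skew <- if (above + below > 0) ratio_skew_test(above, below)$p else NA_real_
  bins <- cut(results$n_reads, breaks = c(-Inf, depth_bins), right = FALSE)
  by_depth <- tibble(depth_bin = bins, ref_ratio = results$ref_ratio) %>%
    group_by(.data$depth_bin) %>%
    summarise(mean_ref_ratio = mean(.data$ref_ratio), n = dplyr::n(),
              .groups = "drop")
  structure(list(overall_ref_ratio = overall, n_above_half = above,
                 n_below_half = below, n_at_half = at, skew_p = skew,
                 ratio_by_depth_bin = by_depth),
            class = "ase_bias")
}

#' @export
print.ase_bias <- function(x, ...) {
  cat("Reference-bias diagnostics\n")
  cat(sprintf("  overall REF ratio: %.4f\n", x$overall_ref_ratio))
  n <- x$n_above_half + x$n_below_half
  if (n > 0) {
    cat(sprintf("  ratios > 0.5: %d (%.0f%%)  < 0.5: %d (%.0f%%)  skew p = %.3g\n",
                x$n_above_half, 100 * x$n_above_half / n,
                x$n_below_half, 100 * x$n_below_half / n, x$skew_p))
  } else {
    cat("  no significant SNPs off 0.5; skew test empty\n")
  }
  invisible(x)
}

#' Write an ASE result table in the standard column layout
#'
#' TSV with the conventional report columns (SNP, chromosome, location,
#' samples, reads, REF ratio, FDR-adjusted p), joined from the panel when
#' available.
#'
#' @param results An `ase_result` table.
#' @param path Output TSV path.
#' @param panel Optional SNP panel for chrom/pos annotation.
#' @return Invisibly, `path`.
#' @export
write_ase_table <- function(results, path, panel = NULL) {
  out <- results
  if (!is.null(panel)) {
    out <- left_join(out, select(panel, "snp_id", "chrom", "pos"),
                     by = "snp_id") %>%
      select("snp_id", "chrom", "pos", samples = "n_het", reads = "n_reads",
             "ref_ratio", "p_fdr")
  }
  readr::write_tsv(out, path)
  invisible(path)
}
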