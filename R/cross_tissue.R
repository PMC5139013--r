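#' Partition ASE calls shared between two tissues
#'
#' Restricts two per-tissue ASE result tables to the SNPs eligible in both,
#' then partitions the significant SNPs into shared (significant in both),
#' tissue-A-only, and tissue-B-only sets.
#'
#' @param results_a,results_b `ase_result` tables from [call_ase()] for the
#'   two tissues.
#' @param alpha Significance level.
#' @param scale `"fdr"` thresholds the BH-adjusted p-values (default);
#'   `"raw"` thresholds the raw p-values.
#' @return A list of class `ase_sharing_partition`: `n_eligible_both`,
#'   `n_ase_either`, `n_ase_both`, `n_a_only`, `n_b_only`, and the id sets
#'   `both`, `a_only`, `b_only`, `eligible`.
#' @export
shared_ase <- function(results_a, results_b, alpha = 0.05,
                       scale = c("fdr", "raw")) {
  scale <- match.arg(scale)
  eligible <- intersect(results_a$snp_id, results_b$snp_id)
  if (length(eligible) == 0) abort("no SNP is eligible in both tissues")
  pcol <- if (scale == "fdr") "p_fdr" else "p_raw"
  sig_a <- results_a$snp_id[results_a$snp_id %in% eligible &
                              results_a[[pcol]] < alpha]
  sig_b <- results_b$snp_id[results_b$snp_id %in% eligible &
                              results_b[[pcol]] < alpha]
  both <- intersect(sig_a, sig_b)
  structure(list(
    n_eligible_both = length(eligible),
    n_ase_either = length(union(sig_a, sig_b)),
    n_ase_both = length(both),
    n_a_only = length(setdiff(sig_a, sig_b)),
    n_b_only = length(setdiff(sig_b, sig_a)),
    both = both, a_only = setdiff(sig_a, sig_b),
    b_only = setdiff(sig_b, sig_a), eligible = eligible,
    alpha = alpha, scale = scale
  ), class = "ase_sharing_partition")
}

#' @export
print.ase_sharing_partition <- function(x, ...) {
  cat(sprintf("ASE sharing: %d eligible in both tissues; %d significant in either\n",
              x$n_eligible_both, x$n_ase_either))
  cat(sprintf("  both: %d   A only: %d   B only: %d  (%s p < %g)\n",
              x$n_ase_both, x$n_a_only, x$n_b_only, x$scale, x$alpha))
  invisible(x)
}

#' Permutation test of cross-tissue ASE overlap
#'
#' Null distribution of the shared-ASE count under independent tissues: each
#' permutation draws random subsets of the eligible SNPs of the two observed
#' set sizes and records their overlap; the p-value is
#' `(1 + #\{null >= observed\}) / (B + 1)`, so it is floored at `1/(B+1)`
#' and never zero. By default both sets are re-drawn each permutation
#' (symmetric in the tissues); `redraw = "single"` holds set A fixed and
#' re-draws only set B.
#'
#' @param eligible SNP ids eligible in both tissues (or an integer count).
#' @param size_a,size_b Sizes of the two significant sets.
#' @param observed_overlap Observed shared-ASE count.
#' @param B Number of permutations (default 10000).
#' @param redraw `"both"` or `"single"`, see above.
#' @return A list of class `ase_overlap_test`: `perm_p`, `perm_null`
#'   (length-`B` integer vector), `observed`, `B`.
#' @export
permutation_overlap_test <- function(eligible, size_a, size_b,
                                     observed_overlap, B = 10000,
                                     redraw = c("both", "single")) {
  redraw <- match.arg(redraw)
  n_eligible <- if (length(eligible) == 1 && is.numeric(eligible)) {
    as.integer(eligible)
  } else {
    length(eligible)
  }
  stopifnot(B >= 1, size_a <= n_eligible, size_b <= n_eligible)
  if (observed_overlap > min(size_a, size_b)) {
    abort("observed_overlap exceeds the smaller set size")
  }
  null <- integer(B)
  if (redraw == "both") {
    # draw the larger set first so the null stream is invariant under
    # swapping the tissue labels
    s_hi <- max(size_a, size_b)
    s_lo <- min(size_a, size_b)
    for (b in seq_len(B)) {
      a <- sample.int(n_eligible, s_hi)
      bb <- sample.int(n_eligible, s_lo)
      null[b] <- sum(bb %in% a)
    }
  } else {
    a <- seq_len(size_a)
    for (b in seq_len(B)) {
      null[b] <- sum(sample.int(n_eligible, size_b) <= size_a)
    }
  }
  perm_p <- (1 + sum(null >= observed_overlap)) / (B + 1)
  structure(list(perm_p = perm_p, perm_null = null,
                 observed = observed_overlap, B = B),
            class = "ase_overlap_test")
}

#' @export
print.ase_overlap_test <- function(x, ...) {
  cat(sprintf("Permutation overlap test: observed %d vs null mean %.2f (B = %d), p = %.3g\n",
              x$observed, mean(x$perm_null), x$B, x$perm_p))
  invisible(x)
}

#' Direction concordance of REF ratios between tissues
#'
#' For each sharing group (both, A-only, B-only), the fraction of SNPs whose
#' REF ratio lies on the same side of 0.5 in both tissues; SNPs at exactly
#' 0.5 in either tissue carry no direction and are excluded from the
#' fraction. Groups are compared pairwise by Fisher's exact test on the
#' concordant/discordant split.
#'
#' @param results_a,results_b `ase_result` tables.
#' @param partition An `ase_sharing_partition` from [shared_ase()].
#' @return A list of class `ase_concordance`: `concordance` (tibble of
#'   group, concordant, discordant, fraction) and `comparisons` (tibble of
#'   pairwise Fisher p-values).
#' @export
direction_concordance <- function(results_a, results_b, partition) {
  ra <- setNames(results_a$ref_ratio, results_a$snp_id)
  rb <- setNames(results_b$ref_ratio, results_b$snp_id)
  groups <- list(both = partition$both, a_only = partition$a_only,
                 b_only = partition$b_only)
  conc <- purrr::imap(groups, function(ids, nm) {
    ids <- ids[ids %in% names(ra) & ids %in% names(rb)]
    s <- (ra[ids] - 0.5) * (rb[ids] - 0.5)
    tibble(group = nm, concordant = sum(s > 0), discordant = sum(s < 0),
           n_tied = sum(s == 0),
           fraction = ifelse(sum(s != 0) > 0,
                             sum(s > 0) / sum(s != 0), NA_real_))
  }) %>% bind_rows()
  pairs <- utils::combn(conc$group, 2, simplify = FALSE)
  comparisons <- purrr::map(pairs, function(pr) {
    m <- as.matrix(conc[match(pr, conc$group), c("concordant", "discordant")])
    p <- if (any(rowSums(m) == 0)) NA_real_ else stats::fisher.test(m)$p.value
    tibble(group1 = pr[1], group2 = pr[2], p = p)
  }) %>% bind_rows()
  structure(list(concordance = conc, comparisons = comparisons),
            class = "ase_concordance")
}

#' @export
print.ase_concordance <- function(x, ...) {
  cat("Direction concordance of REF ratios:\n")
  print(x$concordance)
  invisible(x)
}

#' Differential ASE between tissues (unpaired cohorts)
#'
#' Tests, per SNP eligible in both tissues, whether the allelic ratio
#' differs between the two (distinct) cohorts, by the beta-binomial
#' group LRT with tissue as the group label; BH-FDR across tested SNPs.
#' SNPs heterozygous in only one tissue's cohort are skipped and listed in
#' the `"skipped"` attribute.
#'
#' @param counts_a,counts_b Eligible allele-count tibbles for the two
#'   tissues.
#' @param tissues Length-2 labels attached to the two tables.
#' @return Tibble of class `ase_differential` (see [diff_ase_group()]).
#' @export
differential_ase_between_tissues <- function(counts_a, counts_b,
                                             tissues = c("A", "B")) {
  shared <- intersect(unique(counts_a$snp_id), unique(counts_b$snp_id))
  combined <- bind_rows(
    mutate(filter(counts_a, .data$snp_id %in% shared), .tissue = tissues[1]),
    mutate(filter(counts_b, .data$snp_id %in% shared), .tissue = tissues[2])
  )
  diff_ase_group(combined, group_col = ".tissue")
}

#' Export a sharing analysis as JSON
#'
#' @param partition An `ase_sharing_partition`.
#' @param overlap An `ase_overlap_test` (optional).
#' @param concordance An `ase_concordance` (optional).
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_sharing_json <- function(partition, overlap = NULL, concordance = NULL,
                               path) {
  out <- list(
    n_eligible_both = partition$n_eligible_both,
    n_ase_either = partition$n_ase_either,
    n_ase_both = partition$n_ase_both,
    n_a_only = partition$n_a_only,
    n_b_only = partition$n_b_only,
    alpha = partition$alpha, scale = partition$scale
  )
  if (!is.null(overlap)) {
    out$perm_p <- overlap$perm_p
    out$perm_null_mean <- mean(overlap$perm_null)
    out$B <- overlap$B
  }
  if (!is.null(concordance)) out$concordance <- concordance$concordance
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
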