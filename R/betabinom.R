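#' Beta-binomial log-likelihood of per-individual REF counts
#'
#' Sum over records of the beta-binomial log-pmf parameterised by mean REF
#' probability `mu` and intraclass correlation `rho`
#' (`alpha = mu (1 - rho) / rho`, `beta = (1 - mu)(1 - rho) / rho`). At
#' `rho = 0` this is exactly the binomial log-likelihood.
#'
#' @param ref Per-record REF counts.
#' @param total Per-record REF + ALT totals (each at least 1).
#' @param mu Mean REF probability, strictly inside (0, 1).
#' @param rho Intraclass correlation in [0, 1).
#' @return The log-likelihood (scalar).
#' @export
betabinom_loglik <- function(ref, total, mu, rho) {
  stopifnot(length(ref) == length(total))
  if (any(total < 1) || any(ref < 0) || any(ref > total)) {
    abort("need 0 <= ref <= total and total >= 1")
  }
  if (mu <= 0 || mu >= 1) abort("mu must lie strictly in (0, 1)")
  if (rho < 0 || rho >= 1) abort("rho must lie in [0, 1)")
  if (rho == 0) return(sum(dbinom(ref, total, mu, log = TRUE)))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(total, ref) + lbeta(ref + a, total - ref + b) - lbeta(a, b))
}

MU_EPS <- 1e-6
RHO_MAX <- 0.995

#' Maximum-likelihood beta-binomial fit
#'
#' Fits `(mu, rho)` to per-individual REF counts by bounded
#' quasi-Newton optimisation, either with one common mean or with
#' group-specific means sharing a single `rho`. `mu` is constrained to
#' `[1e-6, 1 - 1e-6]` and `rho` to `[0, 0.995]`; with a single record `rho`
#' is pinned to 0 (not estimable) and flagged. Non-convergence is flagged,
#' never silent — the best iterate is still returned.
#'
#' @param records Tibble with columns `ref_count` and either `alt_count` or
#'   `total`.
#' @param group Optional vector (length `nrow(records)`) of group labels for
#'   the group-specific-mean fit; `NULL` fits a common mean.
#' @param rho_fixed Optional fixed intraclass correlation: only the mean(s)
#'   are optimised. Used by the LRT to hold the correlation estimated under
#'   the group-specific model fixed in the common-mean fit.
#' @return An object of class `betabinom_fit`: `mu` (named per group when
#'   grouped), `rho`, `loglik`, `converged`, `rho_estimable`, `n_records`,
#'   `df` (number of free parameters).
#' @export
#' @examples
#' rec <- tibble::tibble(ref_count = c(5, 6, 4), alt_count = c(5, 4, 6))
#' glance(fit_betabinom(rec))
fit_betabinom <- function(records, group = NULL, rho_fixed = NULL) {
  check_columns(records, "ref_count", "records")
  total <- if ("total" %in% names(records)) records$total
  else records$ref_count + records$alt_count
  ref <- records$ref_count
  if (length(ref) == 0) abort("at least one record is required")
  grp <- if (is.null(group)) factor(rep("all", length(ref)))
  else factor(group)
  if (any(table(grp) == 0)) abort("every group needs at least one record")
  k <- nlevels(grp)
  idx <- split(seq_along(ref), grp)

  mu0 <- vapply(idx, function(i) {
    clamp01((sum(ref[i]) + 0.5) / (sum(total[i]) + 1), MU_EPS)
  }, numeric(1))

  ll_at <- function(mus, rho) {
    sum(vapply(seq_len(k), function(g) {
      betabinom_loglik(ref[idx[[g]]], total[idx[[g]]], mus[g], rho)
    }, numeric(1)))
  }

  estimate_rho <- is.null(rho_fixed)
  rho_estimable <- length(ref) > 1
  if (estimate_rho && !rho_estimable) {
    # a single record cannot identify rho: pin it to 0 with a flag
    mu <- clamp01(ref / total, MU_EPS)
    fit <- list(mu = setNames(rep(mu, k), levels(grp)), rho = 0,
                loglik = ll_at(rep(mu, k), 0), converged = TRUE)
  } else {
    npar <- k + as.integer(estimate_rho)
    nll <- function(par) {
      mus <- clamp01(par[seq_len(k)], MU_EPS)
      rho <- if (estimate_rho) min(max(par[k + 1], 0), RHO_MAX)
      else rho_fixed
      -ll_at(mus, rho)
    }
    lower <- c(rep(MU_EPS, k), if (estimate_rho) 0)
    upper <- c(rep(1 - MU_EPS, k), if (estimate_rho) RHO_MAX)
    starts <- if (estimate_rho) list(c(mu0, 0.005), c(mu0, 0.1))
    else list(mu0)
    best <- NULL
    for (s in starts) {
      o <- tryCatch(
        optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = 200)),
        error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) {
      fit <- list(mu = setNames(mu0, levels(grp)),
                  rho = if (estimate_rho) 0 else rho_fixed,
                  loglik = ll_at(mu0, if (estimate_rho) 0 else rho_fixed),
                  converged = FALSE)
    } else {
      fit <- list(mu = setNames(clamp01(best$par[seq_len(k)], MU_EPS),
                                levels(grp)),
                  rho = if (estimate_rho) min(max(best$par[k + 1], 0), RHO_MAX)
                  else rho_fixed,
                  loglik = -best$value,
                  converged = best$convergence == 0)
    }
  }
  structure(c(fit, list(rho_estimable = rho_estimable && estimate_rho,
                        n_records = length(ref),
                        df = k + as.integer(estimate_rho && rho_estimable),
                        grouped = !is.null(group))),
            class = "betabinom_fit")
}

#' @export
print.betabinom_fit <- function(x, ...) {
  mus <- paste(sprintf("%s = %.4f", names(x$mu), x$mu), collapse = ", ")
  cat(sprintf("Beta-binomial fit: mu (%s), rho = %.4f, logLik = %.3f%s\n",
              mus, x$rho, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.betabinom_fit <- function(x, ...) {
  tibble(term = c(paste0("mu_", names(x$mu)), "rho"),
         estimate = c(unname(x$mu), x$rho))
}

#' @exportS3Method generics::glance
glance.betabinom_fit <- function(x, ...) {
  tibble(logLik = x$loglik, df = x$df, nobs = x$n_records,
         converged = x$converged, rho_estimable = x$rho_estimable)
}

# LRT core: group-specific vs common mu on 1 df per extra mean. The
# correlation is estimated once, under the group-specific model, and held
# fixed in the common-mean fit — re-estimating it under the null would let
# overdispersion absorb the group difference and destroy power.
betabinom_lrt <- function(ref, total, grp) {
  records <- tibble(ref_count = ref, total = total)
  fit1 <- fit_betabinom(records, group = grp)
  fit0 <- fit_betabinom(records, rho_fixed = fit1$rho)
  stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
  df <- nlevels(factor(grp)) - 1L
  list(stat = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE),
       fit_null = fit0, fit_alt = fit1,
       converged = fit0$converged && fit1$converged)
}

diff_result_row <- function(snp_id, ref, total, grp, lrt, labels) {
  i1 <- grp == labels[1]
  i2 <- grp == labels[2]
  tibble(
    snp_id = snp_id,
    n_het_group1 = sum(i1), n_het_group2 = sum(i2),
    reads_total = sum(total),
    ratio_group1 = sum(ref[i1]) / sum(total[i1]),
    ratio_group2 = sum(ref[i2]) / sum(total[i2]),
    lrt_stat = lrt$stat, p_raw = lrt$p,
    converged = lrt$converged,
    low_confidence = min(sum(i1), sum(i2)) < 2
  )
}

#' Likelihood-ratio test of differential ASE between two groups (one SNP)
#'
#' Compares the allelic ratio of one SNP's heterozygotes between two groups
#' (e.g. patients with and without postoperative atrial fibrillation):
#' beta-binomial LRT of group-specific means against a common mean, with a
#' shared intraclass correlation, on 1 degree of freedom. Groups with a
#' single heterozygote are tested but flagged `low_confidence`, since a
#' lone extreme ratio is indistinguishable from a genotyping error.
#'
#' @param records Tibble for one SNP: `ref_count`, `alt_count` (or `total`),
#'   and a binary `group` column.
#' @param group_col Name of the group column (default `"group"`).
#' @return One-row tibble: group sample sizes, pooled per-group REF ratios,
#'   `lrt_stat`, `p_raw`, `converged`, `low_confidence`.
#' @export
lrt_group_differential <- function(records, group_col = "group") {
  check_columns(records, c("ref_count", group_col), "records")
  total <- if ("total" %in% names(records)) records$total
  else records$ref_count + records$alt_count
  grp <- factor(records[[group_col]])
  if (nlevels(grp) != 2) abort("exactly two group levels are required")
  if (any(table(grp) < 1)) abort("each group needs >= 1 heterozygote")
  lrt <- betabinom_lrt(records$ref_count, total, grp)
  snp <- if ("snp_id" %in% names(records)) records$snp_id[1] else NA_character_
  diff_result_row(snp, records$ref_count, total, as.character(grp), lrt,
                  levels(grp))
}

#' Paired likelihood-ratio test of differential ASE between timepoints
#'
#' Within one SNP's heterozygotes sampled at two paired timepoints (e.g.
#' baseline and post-ischemia from the same ventricle), tests
#' timepoint-specific against common mean allelic ratio by beta-binomial
#' LRT with shared correlation; each individual contributes one record per
#' timepoint, and individuals missing a timepoint are dropped with a
#' message.
#'
#' @param records Tibble for one SNP: `ref_count`, `alt_count` (or `total`),
#'   `timepoint` (two levels), `individual_id`.
#' @param timepoint_col,id_col Column names (defaults `"timepoint"`,
#'   `"individual_id"`).
#' @return One-row tibble as [lrt_group_differential()], with timepoint
#'   levels as the groups and `n_pairs` appended.
#' @export
lrt_paired_differential <- function(records, timepoint_col = "timepoint",
                                    id_col = "individual_id") {
  check_columns(records, c("ref_count", timepoint_col, id_col), "records")
  tp <- factor(records[[timepoint_col]])
  if (nlevels(tp) != 2) abort("exactly two timepoint levels are required")
  ids_by_tp <- split(records[[id_col]], tp)
  complete <- intersect(ids_by_tp[[1]], ids_by_tp[[2]])
  dropped <- setdiff(unique(records[[id_col]]), complete)
  if (length(dropped) > 0) {
    inform(sprintf("%d individual(s) missing a timepoint dropped: %s",
                   length(dropped), paste(head(dropped, 3), collapse = ", ")))
  }
  if (length(complete) == 0) abort("no individual has both timepoints")
  records <- records[records[[id_col]] %in% complete, , drop = FALSE]
  out <- lrt_group_differential(records, group_col = timepoint_col)
  out$n_pairs <- length(complete)
  out
}

# map a per-SNP differential test over a count table and BH-adjust
map_differential <- function(counts, test_fun, min_per_group_check) {
  split_counts <- split(counts, counts$snp_id)
  rows <- list()
  skipped <- character()
  for (s in names(split_counts)) {
    rec <- split_counts[[s]]
    if (!min_per_group_check(rec)) {
      skipped <- c(skipped, s)
      next
    }
    rows[[s]] <- tryCatch(test_fun(rec), error = function(e) NULL)
    if (is.null(rows[[s]])) skipped <- c(skipped, s)
  }
  if (length(skipped) > 0) {
    inform(sprintf("%d SNP(s) skipped (untestable in one stratum)",
                   length(skipped)))
  }
  out <- bind_rows(rows)
  if (nrow(out) > 0) {
    out <- out %>% mutate(p_fdr = bh_adjust(.data$p_raw)) %>%
      arrange(.data$p_raw)
  }
  attr(out, "skipped") <- skipped
  structure(out, class = c("ase_differential", class(out)))
}

#' Differential ASE between two clinical groups, across SNPs
#'
#' Runs [lrt_group_differential()] on every SNP with at least one
#' heterozygote per group and BH-adjusts the p-values across tested SNPs.
#'
#' @param counts Allele-count tibble with a `group` column.
#' @param group_col Name of the binary group column.
#' @return Tibble of class `ase_differential`, sorted by `p_raw`, with
#'   `p_fdr`; skipped SNP ids in attribute `"skipped"`.
#' @export
diff_ase_group <- function(counts, group_col = "group") {
  check_columns(counts, c("snp_id", "ref_count", "alt_count", group_col),
                "counts")
  lv <- unique(stats::na.omit(counts[[group_col]]))
  if (length(lv) != 2) abort("group column must have exactly two levels")
  map_differential(
    counts[!is.na(counts[[group_col]]), , drop = FALSE],
    function(rec) lrt_group_differential(rec, group_col),
    function(rec) length(unique(rec[[group_col]])) == 2)
}

#' Paired differential ASE between timepoints, across SNPs
#'
#' Runs [lrt_paired_differential()] on every SNP with at least one
#' individual observed at both timepoints and BH-adjusts across tested
#' SNPs.
#'
#' @param counts Allele-count tibble with `timepoint` and `individual_id`.
#' @param timepoint_col,id_col Column names.
#' @return Tibble of class `ase_differential` as [diff_ase_group()].
#' @export
diff_ase_paired <- function(counts, timepoint_col = "timepoint",
                            id_col = "individual_id") {
  check_columns(counts, c("snp_id", "ref_count", "alt_count",
                          timepoint_col, id_col), "counts")
  map_differential(
    counts[!is.na(counts[[timepoint_col]]), , drop = FALSE],
    function(rec) suppressMessages(
      lrt_paired_differential(rec, timepoint_col, id_col)),
    function(rec) {
      both <- split(rec[[id_col]], rec[[timepoint_col]])
      length(both) == 2 && length(intersect(both[[1]], both[[2]])) >= 1
    })
}
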