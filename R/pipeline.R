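#' Pipeline configuration
#'
#' Bundles every setting of an end-to-end run: input tables (or a simulated
#' study), filter thresholds, the ASE engine, the FDR level, the permutation
#' count for the sharing null, and the seed. The configuration is echoed
#' verbatim into the output directory so a run is reconstructible.
#'
#' @param filter A [filter_config()].
#' @param engine ASE engine passed to [call_ase()].
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param B Permutations for the sharing null (default 10000).
#' @param sharing_scale `"fdr"` or `"raw"` p-values for the sharing
#'   partition.
#' @param seed Integer seed governing every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_config(),
                            engine = "nb_individual",
                            fdr_alpha = 0.05, B = 10000,
                            sharing_scale = "fdr", seed = 1L) {
  structure(list(filter = filter, engine = engine, fdr_alpha = fdr_alpha,
                 B = as.integer(B), sharing_scale = sharing_scale,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the ASE pipeline end to end
#'
#' Composes the full analysis on a two-tissue study: filter cascade and ASE
#' calling per tissue, cross-tissue sharing with the permutation null and
#' direction concordance, differential ASE between tissues, between clinical
#' groups within tissue A, and between paired timepoints within tissue B.
#' Stages whose metadata are absent (no group labels, no timepoints, one
#' tissue) are skipped. All outputs are pure functions of
#' (inputs, config, seed); when `out_dir` is given every table is written as
#' TSV/JSON together with a manifest.
#'
#' @param study An `ase_study` from [simulate_study()], or a list with
#'   elements `counts` (allele-count tibble with `tissue`, and optionally
#'   `group`/`timepoint` columns), `genotypes`, `panel`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `ase_pipeline_result` with elements
#'   `filter` (per-tissue `ase_filter_result`s), `ase` (per-tissue
#'   `ase_result`s), `bias` (per-tissue diagnostics), `sharing`
#'   (partition, overlap test, concordance), `diff_tissue`, `diff_group`,
#'   `diff_paired`, and `config`.
#' @export
run_ase_pipeline <- function(study, config = pipeline_config(),
                             out_dir = NULL) {
  counts <- study$counts
  check_columns(counts, c("snp_id", "individual_id", "ref_count",
                          "alt_count", "other_count"), "study counts")
  if (!"tissue" %in% names(counts)) counts$tissue <- "all"
  known <- rownames(study$genotypes)
  bad <- setdiff(unique(counts$individual_id), known)
  if (length(bad) > 0) {
    abort(sprintf("counts reference unknown individual(s): %s",
                  paste(head(bad, 3), collapse = ", ")))
  }
  tissues <- unique(counts$tissue)
  log_msg <- function(...) inform(sprintf(...))

  filt <- list(); ase <- list(); bias <- list()
  for (tis in tissues) {
    ct <- filter(counts, .data$tissue == tis)
    # paired designs: baseline sample represents the tissue for eligibility
    f <- apply_ase_filters(ct, study$genotypes, study$panel, config$filter)
    filt[[tis]] <- f
    a <- call_ase(f$counts, engine = config$engine,
                  fdr_alpha = config$fdr_alpha)
    ase[[tis]] <- a
    bias[[tis]] <- bias_diagnostics(a, f$counts)
    log_msg("tissue %s: %d eligible SNPs, %d significant at FDR < %g",
            tis, nrow(a), sum(a$significant), config$fdr_alpha)
  }

  sharing <- NULL
  diff_tissue <- NULL
  if (length(tissues) >= 2) {
    ta <- tissues[1]; tb <- tissues[2]
    eligible_both <- intersect(ase[[ta]]$snp_id, ase[[tb]]$snp_id)
    if (length(eligible_both) > 0) {
      part <- shared_ase(ase[[ta]], ase[[tb]], alpha = config$fdr_alpha,
                         scale = config$sharing_scale)
      overlap <- withr::with_seed(config$seed, permutation_overlap_test(
        part$eligible,
        size_a = part$n_ase_both + part$n_a_only,
        size_b = part$n_ase_both + part$n_b_only,
        observed_overlap = part$n_ase_both, B = config$B))
      conc <- direction_concordance(ase[[ta]], ase[[tb]], part)
      sharing <- list(partition = part, overlap = overlap,
                      concordance = conc)
      log_msg("sharing: %d ASE in both tissues (perm p = %.3g)",
              part$n_ase_both, overlap$perm_p)
    }
    ctb <- filter(counts, .data$tissue == tb)
    if ("timepoint" %in% names(ctb) && any(!is.na(ctb$timepoint))) {
      ctb <- filter(ctb, .data$timepoint == "baseline")
    }
    diff_tissue <- suppressMessages(differential_ase_between_tissues(
      semi_join(filter(counts, .data$tissue == ta), filt[[ta]]$counts,
                by = c("snp_id", "individual_id")),
      semi_join(ctb, filt[[tb]]$counts, by = c("snp_id", "individual_id")),
      tissues = c(ta, tb)))
  }

  diff_group <- NULL
  if ("group" %in% names(counts) && any(!is.na(counts$group))) {
    cg <- filter(counts, !is.na(.data$group))
    cg <- semi_join(cg, filt[[cg$tissue[1]]]$counts,
                    by = c("snp_id", "individual_id"))
    diff_group <- suppressMessages(diff_ase_group(cg))
    log_msg("group differential: %d SNPs tested, %d at FDR < %g",
            nrow(diff_group), sum(diff_group$p_fdr < config$fdr_alpha),
            config$fdr_alpha)
  }

  diff_paired <- NULL
  if ("timepoint" %in% names(counts) && any(!is.na(counts$timepoint))) {
    cp <- filter(counts, !is.na(.data$timepoint))
    cp <- semi_join(cp, filt[[cp$tissue[1]]]$counts,
                    by = c("snp_id", "individual_id"))
    diff_paired <- suppressMessages(diff_ase_paired(cp))
    log_msg("paired differential: %d SNPs tested, %d at FDR < %g",
            nrow(diff_paired), sum(diff_paired$p_fdr < config$fdr_alpha),
            config$fdr_alpha)
  }

  result <- structure(list(filter = filt, ase = ase, bias = bias,
                           sharing = sharing, diff_tissue = diff_tissue,
                           diff_group = diff_group,
                           diff_paired = diff_paired, config = config),
                      class = "ase_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, study, out_dir)
  result
}

#' @export
print.ase_pipeline_result <- function(x, ...) {
  cat("ASE pipeline result\n")
  for (tis in names(x$ase)) {
    cat(sprintf("  %s: %d SNPs, %d significant\n", tis, nrow(x$ase[[tis]]),
                sum(x$ase[[tis]]$significant)))
  }
  if (!is.null(x$sharing)) print(x$sharing$partition)
  invisible(x)
}

write_pipeline_outputs <- function(result, study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tis in names(result$ase)) {
    write_ase_table(result$ase[[tis]],
                    file.path(out_dir, paste0("ase_", tis, ".tsv")),
                    panel = study$panel)
    write_filter_report(result$filter[[tis]],
                        file.path(out_dir, paste0("filter_", tis)))
  }
  if (!is.null(result$sharing)) {
    write_sharing_json(result$sharing$partition, result$sharing$overlap,
                       result$sharing$concordance,
                       file.path(out_dir, "sharing.json"))
  }
  for (nm in c("diff_tissue", "diff_group", "diff_paired")) {
    if (!is.null(result[[nm]]) && nrow(result[[nm]]) > 0) {
      readr::write_tsv(result[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    }
  }
  cfg <- result$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("aseflow")),
    seed = cfg$seed, engine = cfg$engine, fdr_alpha = cfg$fdr_alpha,
    B = cfg$B, filter = unclass(cfg$filter),
    n_counts = nrow(study$counts),
    n_snps = nrow(study$panel)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
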