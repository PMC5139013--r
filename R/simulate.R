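#' Simulation configuration for synthetic ASE studies
#'
#' Bundles every knob of the synthetic-data generator: cohort and panel size,
#' the minor-allele-frequency range from which per-SNP MAFs are drawn, the
#' genotyping call rate, the read-depth model (negative binomial, since real
#' RNA-seq site coverage is overdispersed), the per-base sequencing error rate
#' that produces OTHER alleles, an additive reference-bias shift on the REF
#' read probability, beta-binomial overdispersion of the allelic ratio across
#' individuals, and the fraction and effect-size range of SNPs with true
#' allele-specific expression.
#'
#' The defaults describe the study conditions the generator emulates: a cohort
#' of 62 genotyped individuals, site coverage averaging 30 reads with
#' negative-binomial shape 2, a 0.5% per-base error rate, a 98% genotyping
#' call rate, mild between-individual overdispersion (rho = 0.01), and 10% of
#' SNPs carrying true ASE with REF ratios in (0.65, 0.9) on a randomly chosen
#' side of 0.5.
#'
#' @param n_individuals Number of genotyped individuals.
#' @param n_snps Number of biallelic SNPs on the panel.
#' @param maf_range Length-2 numeric in (0, 0.5]; per-SNP minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param genotyping_rate Probability that a genotype call is non-missing.
#' @param depth_mean Mean per-heterozygote read depth.
#' @param depth_shape Negative-binomial shape (size) of the depth
#'   distribution; larger is closer to Poisson.
#' @param error_rate Probability that an observed base is neither REF nor ALT.
#' @param ref_bias Additive shift on the REF-read probability (0 = unbiased);
#'   the shifted probability is clamped to (1e-6, 1 - 1e-6).
#' @param overdispersion_rho Beta-binomial intraclass correlation in [0, 1)
#'   of the per-individual REF probability around its mean.
#' @param ase_fraction Fraction of SNPs whose true REF ratio differs from 0.5.
#' @param ase_ratio_range Length-2 numeric in (0.5, 1); ASE SNPs draw a REF
#'   ratio uniformly from this range and mirror it below 0.5 with
#'   probability 1/2.
#' @param seed Integer seed; identical (config, seed) reproduce bit-identical
#'   tables. `NULL` uses the current RNG state.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 20, n_snps = 100, seed = 1)
#' geno <- simulate_genotypes(cfg)
#' dim(geno$genotypes)
sim_config <- function(n_individuals = 62,
                       n_snps = 1000,
                       maf_range = c(0.05, 0.5),
                       genotyping_rate = 0.98,
                       depth_mean = 30,
                       depth_shape = 2,
                       error_rate = 0.005,
                       ref_bias = 0,
                       overdispersion_rho = 0.01,
                       ase_fraction = 0.1,
                       ase_ratio_range = c(0.65, 0.9),
                       seed = NULL) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range), genotyping_rate = genotyping_rate,
    depth_mean = depth_mean, depth_shape = depth_shape,
    error_rate = error_rate, ref_bias = ref_bias,
    overdispersion_rho = overdispersion_rho, ase_fraction = ase_fraction,
    ase_ratio_range = as.numeric(ase_ratio_range), seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_individuals < 1L || cfg$n_snps < 1L) {
    abort("n_individuals and n_snps must both be >= 1")
  }
  probs <- c(genotyping_rate = cfg$genotyping_rate,
             error_rate = cfg$error_rate,
             ase_fraction = cfg$ase_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("genotyping_rate, error_rate and ase_fraction must lie in [0, 1]")
  }
  if (length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    abort("maf_range must be an ordered pair within (0, 0.5]")
  }
  if (cfg$overdispersion_rho < 0 || cfg$overdispersion_rho >= 1) {
    abort("overdispersion_rho must lie in [0, 1)")
  }
  if (cfg$depth_mean <= 0 || cfg$depth_shape <= 0) {
    abort("depth_mean and depth_shape must be positive")
  }
  invisible(cfg)
}

with_sim_seed <- function(seed, offset, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed) + as.integer(offset), code)
}

fmt_ids <- function(prefix, n) sprintf("%s%0*d", prefix, max(3L, nchar(n)), seq_len(n))

#' Simulate HWE genotypes and a SNP panel
#'
#' Draws, for each SNP, a minor allele frequency uniformly from
#' `config$maf_range` and genotypes for every individual from Hardy-Weinberg
#' proportions, then masks each call as missing independently with
#' probability `1 - genotyping_rate`. REF is the major allele so the
#' minor-allele frequency is the ALT frequency. A SNP panel (chromosome,
#' position, REF/ALT bases, mappability 1) and a per-SNP truth table
#' accompany the matrix.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes` (integer matrix, individuals x SNPs,
#'   values 0 = hom-REF, 1 = het, 2 = hom-ALT, `NA` = missing), `panel`
#'   (tibble of SNP records: `snp_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `mappability`), and `truth` (tibble with per-SNP `maf`).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  n <- config$n_individuals
  m <- config$n_snps
  with_sim_seed(config$seed, 1L, {
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    ind_ids <- fmt_ids("I", n)
    snp_ids <- fmt_ids("snp", m)
    # HWE proportions with REF the major allele: p = 1 - maf
    p <- 1 - maf
    probs <- rbind(p^2, 2 * p * maf, maf^2)
    geno <- vapply(seq_len(m), function(j) {
      sample.int(3L, n, replace = TRUE, prob = probs[, j]) - 1L
    }, integer(n))
    if (config$genotyping_rate < 1) {
      miss <- matrix(runif(n * m) > config$genotyping_rate, n, m)
      geno[miss] <- NA_integer_
    }
    dimnames(geno) <- list(ind_ids, snp_ids)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    panel <- tibble(
      snp_id = snp_ids, chrom = "chr1",
      pos = seq(1000L, by = 500L, length.out = m),
      ref_allele = ref, alt_allele = unname(alt), mappability = 1
    )
    list(genotypes = geno, panel = panel,
         truth = tibble(snp_id = snp_ids, maf = maf))
  })
}

#' Draw true REF ratios for a SNP panel
#'
#' `ase_fraction` of SNPs receive a ratio drawn uniformly from
#' `ase_ratio_range`, mirrored below 0.5 with probability 1/2; the rest sit
#' at the balanced ratio 0.5.
#'
#' @param config A [sim_config()].
#' @param snp_ids SNP identifiers (default those of a fresh panel).
#' @return Tibble with `snp_id`, `true_ratio`, `is_ase`.
#' @export
simulate_truth_ratios <- function(config, snp_ids = fmt_ids("snp", config$n_snps)) {
  validate_sim_config(config)
  m <- length(snp_ids)
  with_sim_seed(config$seed, 2L, {
    is_ase <- runif(m) < config$ase_fraction
    r <- rep(0.5, m)
    k <- sum(is_ase)
    if (k > 0) {
      mag <- runif(k, config$ase_ratio_range[1], config$ase_ratio_range[2])
      flip <- runif(k) < 0.5
      r[is_ase] <- ifelse(flip, 1 - mag, mag)
    }
    tibble(snp_id = snp_ids, true_ratio = r, is_ase = is_ase)
  })
}

# one heterozygote's (ref, alt, other) split given total depth
split_depth <- function(depth, true_ratio, config) {
  other <- rbinom(length(depth), depth, config$error_rate)
  rem <- depth - other
  p_ref <- clamp01(true_ratio + config$ref_bias)
  rho <- config$overdispersion_rho
  if (rho > 0) {
    a <- p_ref * (1 - rho) / rho
    b <- (1 - p_ref) * (1 - rho) / rho
    p_i <- rbeta(length(depth), a, b)
  } else {
    p_i <- p_ref
  }
  ref <- rbinom(length(depth), rem, p_i)
  list(ref = ref, alt = rem - ref, other = other)
}

#' Simulate per-heterozygote allele counts
#'
#' For every heterozygous (SNP, individual) cell, total depth is drawn from a
#' negative binomial with mean `depth_mean` and shape `depth_shape`; OTHER
#' reads are drawn first as Binomial(depth, error_rate) so the error rate is a
#' per-base probability, and the remaining reads are split REF/ALT by a
#' beta-binomial with mean `clamp(true_ratio + ref_bias)` and intraclass
#' correlation `overdispersion_rho`. Cells with zero simulated depth emit no
#' record.
#'
#' @param genotypes Integer genotype matrix from [simulate_genotypes()].
#' @param config A [sim_config()].
#' @param truth Tibble with `snp_id`, `true_ratio` (see
#'   [simulate_truth_ratios()]); ratios must lie in (0, 1).
#' @param seed_offset Internal offset added to the seed so that repeated
#'   draws from one config differ (same offset reproduces the same table).
#' @return Tibble of allele-count records: `snp_id`, `individual_id`,
#'   `ref_count`, `alt_count`, `other_count`.
#' @export
simulate_allele_counts <- function(genotypes, config, truth, seed_offset = 3L) {
  validate_sim_config(config)
  check_columns(truth, c("snp_id", "true_ratio"), "truth")
  if (any(truth$true_ratio <= 0 | truth$true_ratio >= 1)) {
    abort("true_ratio must lie strictly in (0, 1)")
  }
  het <- which(genotypes == 1L, arr.ind = TRUE)
  if (nrow(het) == 0) {
    return(tibble(snp_id = character(), individual_id = character(),
                  ref_count = integer(), alt_count = integer(),
                  other_count = integer()))
  }
  snp_of_cell <- colnames(genotypes)[het[, 2]]
  ratio_map <- setNames(truth$true_ratio, truth$snp_id)
  if (any(!snp_of_cell %in% names(ratio_map))) {
    abort("every heterozygous SNP needs a true_ratio entry")
  }
  with_sim_seed(config$seed, seed_offset, {
    depth <- rnbinom(nrow(het), mu = config$depth_mean, size = config$depth_shape)
    parts <- split_depth(depth, unname(ratio_map[snp_of_cell]), config)
    out <- tibble(
      snp_id = snp_of_cell,
      individual_id = rownames(genotypes)[het[, 1]],
      ref_count = as.integer(parts$ref),
      alt_count = as.integer(parts$alt),
      other_count = as.integer(parts$other)
    )
    out %>%
      filter(.data$ref_count + .data$alt_count + .data$other_count > 0) %>%
      arrange(.data$snp_id, .data$individual_id)
  })
}

#' Two-tissue study design with clinical groups and paired timepoints
#'
#' Describes the sampling layout the generator emulates: one cohort sampled
#' in tissue A once (with a binary clinical label such as postoperative
#' atrial fibrillation), and a disjoint cohort sampled in tissue B at two
#' paired timepoints (baseline and post-ischemia). Every post sample has
#' exactly one baseline partner from the same individual.
#'
#' @param n_a Individuals in the tissue-A cohort (default 62).
#' @param n_b Individuals in the paired tissue-B cohort (default 76).
#' @param n_group1 Number of tissue-A individuals carrying the positive
#'   clinical label (default 21, i.e. 34% of 62).
#' @param tissues Length-2 character, tissue tags (default `c("LA", "LV")`).
#' @param group_labels Length-2 character, clinical labels
#'   (default `c("poAF", "none")`).
#' @param shared_ase_fraction Fraction of ASE SNPs whose effect is active in
#'   both tissues with the same true ratio.
#' @return A list of class `study_design` with a `samples` tibble
#'   (`sample_id`, `individual_id`, `tissue`, `group`, `timepoint`).
#' @export
study_design <- function(n_a = 62, n_b = 76, n_group1 = 21,
                         tissues = c("LA", "LV"),
                         group_labels = c("poAF", "none"),
                         shared_ase_fraction = 0.5) {
  stopifnot(n_a >= 1, n_b >= 0, n_group1 <= n_a,
            shared_ase_fraction >= 0, shared_ase_fraction <= 1)
  ids_a <- fmt_ids("A", n_a)
  ids_b <- if (n_b > 0) fmt_ids("B", n_b) else character()
  samples_a <- tibble(
    sample_id = paste0(ids_a, "_", tissues[1]),
    individual_id = ids_a, tissue = tissues[1],
    group = rep(group_labels, c(n_group1, n_a - n_group1)),
    timepoint = NA_character_
  )
  samples_b <- tibble(
    sample_id = c(paste0(ids_b, "_base"), paste0(ids_b, "_post")),
    individual_id = rep(ids_b, 2), tissue = tissues[2],
    group = NA_character_,
    timepoint = rep(c("baseline", "post"), each = length(ids_b))
  )
  structure(list(samples = bind_rows(samples_a, samples_b),
                 tissues = tissues, group_labels = group_labels,
                 shared_ase_fraction = shared_ase_fraction),
            class = "study_design")
}

#' Simulate a full two-tissue ASE study
#'
#' Generates genotypes for both cohorts over a shared SNP panel, assigns
#' per-tissue true REF ratios (a `shared_ase_fraction` of ASE SNPs carry the
#' same ratio in both tissues; the rest are balanced in the other tissue),
#' applies optional group-specific or timepoint-specific differential
#' effects, and simulates allele counts for every sample. The returned truth
#' ledger names every ASE and differential SNP so downstream tests never
#' re-derive ground truth.
#'
#' @param config A [sim_config()]; `n_individuals` is ignored in favour of
#'   the design's cohort sizes.
#' @param design A [study_design()].
#' @param effects Optional tibble of differential effects with columns
#'   `snp_id`, `type` (`"group"` applies in tissue A to the first group
#'   label; `"timepoint"` applies in tissue B post samples), and
#'   `ratio_affected`, the true REF ratio in the affected stratum.
#' @return A list of class `ase_study`: `genotypes`, `panel`, `counts`
#'   (one row per (SNP, sample) heterozygous cell with metadata columns),
#'   `samples`, `truth` (per-SNP per-tissue ratios and flags), and
#'   `effects_truth` (the differential ledger, with an `untestable` flag for
#'   effects assigned to strata with no heterozygote).
#' @export
simulate_study <- function(config, design = study_design(), effects = NULL) {
  validate_sim_config(config)
  samples <- design$samples
  individuals <- unique(samples$individual_id)
  cfg <- config
  cfg$n_individuals <- length(individuals)
  g <- simulate_genotypes(cfg)
  rownames(g$genotypes) <- individuals

  base_truth <- simulate_truth_ratios(cfg)
  # split ASE SNPs into shared / tissue-specific
  truth <- with_sim_seed(cfg$seed, 4L, {
    ase_idx <- which(base_truth$is_ase)
    shared <- rep(FALSE, nrow(base_truth))
    if (length(ase_idx) > 0) {
      n_shared <- round(design$shared_ase_fraction * length(ase_idx))
      shared_idx <- if (n_shared > 0) sample(ase_idx, n_shared) else integer()
      shared[shared_idx] <- TRUE
      specific <- setdiff(ase_idx, shared_idx)
      side_a <- if (length(specific) > 0) {
        specific[runif(length(specific)) < 0.5]
      } else integer()
    } else {
      specific <- integer(); side_a <- integer()
    }
    ratio_a <- ratio_b <- base_truth$true_ratio
    ratio_a[setdiff(specific, side_a)] <- 0.5
    ratio_b[side_a] <- 0.5
    base_truth %>%
      mutate(ratio_a = ratio_a, ratio_b = ratio_b, shared = shared)
  })

  tissues <- design$tissues
  effects_truth <- tibble(snp_id = character(), type = character(),
                          ratio_affected = numeric(), untestable = logical())
  if (!is.null(effects) && nrow(effects) > 0) {
    check_columns(effects, c("snp_id", "type", "ratio_affected"), "effects")
    bad <- setdiff(effects$snp_id, truth$snp_id)
    if (length(bad) > 0) abort(paste("unknown effect snp_id:", bad[1]))
    effects_truth <- mutate(effects, untestable = FALSE)
  }

  grp1 <- design$group_labels[1]
  affected_stratum <- function(eff) {
    if (eff$type == "group") {
      filter(samples, .data$tissue == tissues[1], .data$group == grp1)
    } else {
      filter(samples, .data$tissue == tissues[2], .data$timepoint == "post")
    }
  }

  # per-sample counts: each sample's stratum decides the true ratio in force
  counts <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    r <- if (s$tissue == tissues[1]) truth$ratio_a else truth$ratio_b
    tr <- tibble(snp_id = truth$snp_id, true_ratio = r)
    if (nrow(effects_truth) > 0) {
      for (j in seq_len(nrow(effects_truth))) {
        eff <- effects_truth[j, ]
        in_stratum <- (eff$type == "group" && s$tissue == tissues[1] &&
                         identical(s$group, grp1)) ||
          (eff$type == "timepoint" && s$tissue == tissues[2] &&
             identical(s$timepoint, "post"))
        if (in_stratum) {
          tr$true_ratio[tr$snp_id == eff$snp_id] <- eff$ratio_affected
        }
      }
    }
    geno_row <- g$genotypes[s$individual_id, , drop = FALSE]
    cnt <- simulate_allele_counts(geno_row, cfg, tr, seed_offset = 10L + i)
    if (nrow(cnt) > 0) {
      cnt <- mutate(cnt, sample_id = s$sample_id, tissue = s$tissue,
                    group = s$group, timepoint = s$timepoint)
    }
    counts[[i]] <- cnt
  }
  counts <- bind_rows(counts)

  # flag effects with no heterozygote in the affected stratum
  if (nrow(effects_truth) > 0) {
    for (j in seq_len(nrow(effects_truth))) {
      eff <- effects_truth[j, ]
      strat <- affected_stratum(eff)
      gsub <- g$genotypes[unique(strat$individual_id), eff$snp_id, drop = TRUE]
      if (!any(gsub == 1L, na.rm = TRUE)) {
        warn(sprintf("effect on %s has no heterozygote in the affected stratum; flagged untestable",
                     eff$snp_id))
        effects_truth$untestable[j] <- TRUE
      }
    }
  }

  structure(list(genotypes = g$genotypes, panel = g$panel, counts = counts,
                 samples = samples, truth = truth,
                 effects_truth = effects_truth, config = cfg,
                 design = design),
            class = "ase_study")
}

#' @export
print.ase_study <- function(x, ...) {
  cat("Synthetic ASE study:",
      nrow(x$samples), "samples,",
      ncol(x$genotypes), "SNPs,",
      nrow(x$counts), "allele-count records\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the genotype matrix as a minimal VCF (GT field only, 1-based POS)
#' and as TSV, the counts and truth tables as TSV, and a JSON echo of the
#' configuration.
#'
#' @param study An `ase_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    geno_tsv = file.path(dir, "genotypes.tsv"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.tsv"),
    config = file.path(dir, "config.json")
  )
  write_genotypes_vcf(study$genotypes, study$panel, paths[["vcf"]])
  geno_df <- as_tibble(study$genotypes, rownames = "individual_id")
  readr::write_tsv(geno_df, paths[["geno_tsv"]])
  counts <- study$counts %>%
    select("snp_id", "individual_id", "tissue", "timepoint",
           "ref_count", "alt_count", "other_count")
  readr::write_tsv(counts, paths[["counts"]])
  readr::write_tsv(study$truth, paths[["truth"]])
  cfg <- study$config
  cfg$seed <- if (is.null(cfg$seed)) NA_integer_ else cfg$seed
  jsonlite::write_json(unclass(cfg), paths[["config"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write genotypes as a minimal VCF
#'
#' GT-only VCF 4.2 with unphased diploid calls; missing genotypes become
#' `./.`.
#'
#' @param genotypes Integer genotype matrix (individuals x SNPs).
#' @param panel SNP panel tibble with `snp_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_genotypes_vcf <- function(genotypes, panel, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(panel)), function(j) {
    g <- genotypes[, panel$snp_id[j]]
    calls <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    paste(c(panel$chrom[j], panel$pos[j], panel$snp_id[j], panel$ref_allele[j],
            panel$alt_allele[j], ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Parses unphased or phased diploid GT calls into the 0/1/2/NA dosage
#' encoding used throughout the package, and the site columns into a SNP
#' panel tibble (mappability defaults to 1; supply it separately if an
#' annotation track is available).
#'
#' @param path VCF file path (plain text).
#' @return A list with `genotypes` and `panel` as in [simulate_genotypes()].
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- strsplit(lines[-1], "\t")
  inds <- hdr[-(1:9)]
  parse_gt <- function(x) {
    gt <- sub(":.*", "", x)
    a <- substr(gt, 1, 1); b <- substr(gt, 3, 3)
    out <- suppressWarnings(as.integer(a) + as.integer(b))
    out[a == "." | b == "."] <- NA_integer_
    out
  }
  geno <- vapply(body, function(f) parse_gt(f[-(1:9)]), integer(length(inds)))
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = length(inds))
  snp_ids <- vapply(body, `[`, character(1), 3)
  dimnames(geno) <- list(inds, snp_ids)
  panel <- tibble(
    snp_id = snp_ids,
    chrom = vapply(body, `[`, character(1), 1),
    pos = as.integer(vapply(body, `[`, character(1), 2)),
    ref_allele = vapply(body, `[`, character(1), 4),
    alt_allele = vapply(body, `[`, character(1), 5),
    mappability = 1
  )
  list(genotypes = geno, panel = panel)
}
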