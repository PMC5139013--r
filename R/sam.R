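#' Read aligned reads from a SAM text file
#'
#' Parses the mandatory SAM columns plus the `NH` (number of reported
#' alignments) tag into a tibble. Header lines are skipped. Inputs are
#' expected to be pre-sliced to SNP neighbourhoods; no index or random
#' access is used.
#'
#' @param path Path to a SAM file.
#' @param individual_id Optional individual identifier attached to every read.
#' @return Tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`, `nh` (NA when the tag is absent) and, if given,
#'   `individual_id`.
#' @export
read_sam <- function(path, individual_id = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0) {
    out <- tibble(qname = character(), flag = integer(), rname = character(),
                  pos = integer(), mapq = integer(), cigar = character(),
                  seq = character(), qual = character(), nh = integer())
    if (!is.null(individual_id)) out$individual_id <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nh <- vapply(fields, function(f) {
    tag <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(tag) == 0) NA_integer_ else as.integer(sub("^NH:i:", "", tag[1]))
  }, integer(1))
  out <- tibble(
    qname = vapply(fields, `[`, character(1), 1),
    flag = as.integer(vapply(fields, `[`, character(1), 2)),
    rname = vapply(fields, `[`, character(1), 3),
    pos = as.integer(vapply(fields, `[`, character(1), 4)),
    mapq = as.integer(vapply(fields, `[`, character(1), 5)),
    cigar = vapply(fields, `[`, character(1), 6),
    seq = vapply(fields, `[`, character(1), 10),
    qual = vapply(fields, `[`, character(1), 11),
    nh = nh
  )
  if (!is.null(individual_id)) out$individual_id <- individual_id
  out
}

#' Retain only uniquely mapped reads
#'
#' A read is uniquely mapped when its `NH` tag equals 1. When the tag is
#' absent, mapping quality stands in: reads with MAPQ above `mapq_threshold`
#' are retained (MAPQ 255 means "unavailable" and such reads, lacking both
#' signals, count as not uniquely mapped).
#'
#' @param reads Tibble of reads from [read_sam()].
#' @param mapq_threshold Retain `NH`-less reads with `mapq > mapq_threshold`
#'   (default 0).
#' @return A list with `reads` (the retained subset) and `n_removed`.
#' @export
#' @examples
#' rds <- tibble::tibble(qname = letters[1:3], flag = 0L, rname = "chr1",
#'   pos = 1L, mapq = c(50L, 50L, 50L), cigar = "5M",
#'   seq = "AAAAA", qual = "IIIII", nh = c(1L, 2L, 1L))
#' filter_unique_reads(rds)$n_removed
filter_unique_reads <- function(reads, mapq_threshold = 0) {
  check_columns(reads, c("mapq", "nh"), "reads")
  keep <- ifelse(!is.na(reads$nh),
                 reads$nh == 1L,
                 !is.na(reads$mapq) & reads$mapq != 255L &
                   reads$mapq > mapq_threshold)
  n_removed <- sum(!keep)
  if (any(is.na(reads$nh) & (is.na(reads$mapq) | reads$mapq == 255L))) {
    inform("reads without NH tag or usable MAPQ counted as not uniquely mapped")
  }
  list(reads = reads[keep, , drop = FALSE], n_removed = n_removed)
}

#' Read-retention bookkeeping for the unique-mapping stage
#'
#' The stage-level arithmetic of the read filter: given the number of reads
#' overlapping heterozygous SNPs and the number removed as not uniquely
#' mapped, tabulates the reads retained for analysis.
#'
#' @param n_total Reads entering the stage.
#' @param n_removed Reads removed as multi-mapping.
#' @return One-row tibble: `stage`, `reads_in`, `reads_removed`, `reads_out`.
#' @export
#' @examples
#' unique_read_report(100, 7)
unique_read_report <- function(n_total, n_removed) {
  stopifnot(n_removed >= 0, n_removed <= n_total)
  tibble(stage = "unique_mapping", reads_in = n_total,
         reads_removed = n_removed, reads_out = n_total - n_removed)
}

# walk a CIGAR string to the 1-based query index carrying ref position `pos`;
# returns NA when a deletion/skip spans the site or the read does not reach it
query_index_at <- function(pos, aln_start, cigar) {
  if (cigar == "*") return(NA_integer_)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  qpos <- 0L   # query bases consumed
  rpos <- aln_start  # next reference coordinate
  for (k in seq_along(ops)) {
    len <- lens[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      if (pos >= rpos && pos < rpos + len) return(qpos + (pos - rpos) + 1L)
      rpos <- rpos + len
      qpos <- qpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (pos >= rpos && pos < rpos + len) return(NA_integer_)
      rpos <- rpos + len
    } # H, P consume nothing
  }
  NA_integer_
}

#' Count REF/ALT/OTHER bases at one SNP
#'
#' Walks each read's CIGAR alignment to find the read base placed on the SNP
#' position (soft clips and insertions shift the query index; deletions and
#' splice skips spanning the site contribute nothing) and tallies it against
#' the SNP's REF and ALT alleles. Reads on another chromosome are skipped.
#' Base quality is ignored unless `min_base_quality > 0`.
#'
#' @param reads Tibble of (already uniqueness-filtered) reads.
#' @param snp One-row tibble or list with `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`.
#' @param min_base_quality Minimum Phred base quality (default 0 = ignore).
#' @return A list with `ref`, `alt`, `other` counts.
#' @export
count_alleles_at_site <- function(reads, snp, min_base_quality = 0) {
  stopifnot(snp$pos >= 1)
  counts <- c(ref = 0L, alt = 0L, other = 0L)
  here <- reads[reads$rname == snp$chrom &
                  reads$pos <= snp$pos, , drop = FALSE]
  for (i in seq_len(nrow(here))) {
    qi <- query_index_at(snp$pos, here$pos[i], here$cigar[i])
    if (is.na(qi) || qi > nchar(here$seq[i])) next
    if (min_base_quality > 0 && here$qual[i] != "*") {
      q <- utf8ToInt(substr(here$qual[i], qi, qi)) - 33L
      if (q < min_base_quality) next
    }
    base <- toupper(substr(here$seq[i], qi, qi))
    if (base == toupper(snp$ref_allele)) {
      counts["ref"] <- counts["ref"] + 1L
    } else if (base == toupper(snp$alt_allele)) {
      counts["alt"] <- counts["alt"] + 1L
    } else {
      counts["other"] <- counts["other"] + 1L
    }
  }
  as.list(counts)
}

#' Build the allele-count table from SAM inputs
#'
#' For every (SNP, individual) cell where the genotype matrix records a
#' heterozygote, counts REF/ALT/OTHER bases among that individual's uniquely
#' mapped reads. Only cells with at least one overlapping read emit a
#' record; rows are ordered by (chrom, pos, individual). Duplicate reads are
#' kept unless `remove_duplicates = TRUE` (then reads flagged 0x400 are
#' dropped first). SNPs in the panel but absent from the genotype matrix are
#' excluded with a message.
#'
#' @param sam Either a named character vector/list of SAM paths (names are
#'   individual ids) or a reads tibble carrying an `individual_id` column.
#' @param genotypes Integer genotype matrix (individuals x SNPs; 1 = het).
#' @param panel SNP panel tibble (`snp_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`).
#' @param unique_only Apply [filter_unique_reads()] first (default TRUE).
#' @param mapq_threshold Passed to [filter_unique_reads()].
#' @param min_base_quality Passed to [count_alleles_at_site()].
#' @param remove_duplicates Drop reads with the PCR-duplicate flag
#'   (default FALSE; duplicate removal is not part of the canonical cascade).
#' @return Tibble of allele-count records (`snp_id`, `individual_id`,
#'   `ref_count`, `alt_count`, `other_count`) with attribute
#'   `n_reads_removed` from the uniqueness filter.
#' @export
build_count_table <- function(sam, genotypes, panel, unique_only = TRUE,
                              mapq_threshold = 0, min_base_quality = 0,
                              remove_duplicates = FALSE) {
  if (is.data.frame(sam)) {
    check_columns(sam, "individual_id", "reads")
    reads <- sam
  } else {
    if (is.null(names(sam)) || any(!nzchar(names(sam)))) {
      abort("sam paths must be named by individual_id")
    }
    reads <- bind_rows(purrr::imap(as.list(sam), ~read_sam(.x, .y)))
  }
  drop <- setdiff(panel$snp_id, colnames(genotypes))
  if (length(drop) > 0) {
    inform(sprintf("%d panel SNP(s) absent from the genotype matrix; excluded: %s",
                   length(drop), paste(head(drop, 3), collapse = ", ")))
    panel <- panel[!panel$snp_id %in% drop, , drop = FALSE]
  }
  n_removed <- 0L
  if (remove_duplicates && nrow(reads) > 0) {
    reads <- reads[bitwAnd(reads$flag, 0x400L) == 0L, , drop = FALSE]
  }
  if (unique_only && nrow(reads) > 0) {
    fu <- filter_unique_reads(reads, mapq_threshold)
    reads <- fu$reads
    n_removed <- fu$n_removed
  }
  rows <- list()
  inds_with_reads <- intersect(rownames(genotypes), unique(reads$individual_id))
  for (j in seq_len(nrow(panel))) {
    snp <- panel[j, ]
    for (ind in inds_with_reads) {
      g <- genotypes[ind, snp$snp_id]
      if (is.na(g) || g != 1L) next
      cnt <- count_alleles_at_site(
        reads[reads$individual_id == ind, , drop = FALSE], snp,
        min_base_quality)
      total <- cnt$ref + cnt$alt + cnt$other
      if (total > 0) {
        rows[[length(rows) + 1L]] <- tibble(
          snp_id = snp$snp_id, individual_id = ind, chrom = snp$chrom,
          pos = snp$pos, ref_count = cnt$ref, alt_count = cnt$alt,
          other_count = cnt$other)
      }
    }
  }
  out <- if (length(rows) == 0) {
    tibble(snp_id = character(), individual_id = character(),
           chrom = character(), pos = integer(), ref_count = integer(),
           alt_count = integer(), other_count = integer())
  } else {
    bind_rows(rows) %>% arrange(.data$chrom, .data$pos, .data$individual_id)
  }
  attr(out, "n_reads_removed") <- n_removed
  out
}
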