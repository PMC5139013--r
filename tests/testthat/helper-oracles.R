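# Independent brute-force oracles. These deliberately avoid the code paths
# (and where possible the base functions) used by the implementation.

# exact HWE by full enumeration of genotype configurations with the observed
# allele counts; plain factorial arithmetic, small n only
oracle_hwe <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_ref_alleles <- 2 * n_hom_ref + n_het
  weights <- c()
  hets <- c()
  for (het in 0:n) {
    hom_ref <- (n_ref_alleles - het) / 2
    hom_alt <- n - het - hom_ref
    if (hom_ref < 0 || hom_alt < 0 || hom_ref != round(hom_ref)) next
    w <- factorial(n) / (factorial(hom_ref) * factorial(het) *
                           factorial(hom_alt)) * 2^het
    weights <- c(weights, w)
    hets <- c(hets, het)
  }
  prob <- weights / sum(weights)
  p_obs <- prob[hets == n_het]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# two-sided exact binomial (minimum-likelihood) by direct pmf summation
oracle_binom_two_sided <- function(x, n, p) {
  pmf <- dbinom(0:n, n, p)
  sum(pmf[pmf <= pmf[x + 1] * (1 + 1e-7)])
}

# BH step-up re-implementation: q_i = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# NB pmf from the explicit gamma-function formula (no dnbinom)
oracle_nb_pmf <- function(k, size, mu) {
  p <- size / (size + mu)
  exp(lgamma(k + size) - lgamma(size) - lfactorial(k) +
        size * log(p) + k * log(1 - p))
}

# conditional NB exact test: plain-space enumeration with the explicit pmf
oracle_nb_conditional <- function(y_ref, y_alt, n, phi) {
  total <- y_ref + y_alt
  size <- n / phi
  mu <- total / 2
  joint <- oracle_nb_pmf(0:total, size, mu) *
    oracle_nb_pmf(total:0, size, mu)
  prob <- joint / sum(joint)
  sum(prob[prob <= prob[y_ref + 1] * (1 + 1e-9)])
}

# beta-binomial pmf by direct product summation (rising factorials)
oracle_bb_pmf <- function(k, n, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  rising <- function(x, m) if (m == 0) 1 else prod(x + 0:(m - 1))
  choose(n, k) * rising(a, k) * rising(b, n - k) / rising(a + b, n)
}

# two-proportion binomial LRT at rho = 0, one record per group
oracle_two_prop_lrt <- function(x1, n1, x2, n2) {
  ll <- function(x, n, p) {
    if (p <= 0 || p >= 1) p <- min(max(p, 1e-12), 1 - 1e-12)
    x * log(p) + (n - x) * log(1 - p)
  }
  p0 <- (x1 + x2) / (n1 + n2)
  stat <- 2 * (ll(x1, n1, x1 / n1) + ll(x2, n2, x2 / n2) -
                 ll(x1, n1, p0) - ll(x2, n2, p0))
  max(0, stat)
}

# draw beta-binomial counts (independent of the simulator's split_depth path)
rbetabinom <- function(n, size, mu, rho) {
  if (rho == 0) return(rbinom(n, size, mu))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

# a minimal single-base SAM for round-trip tests: one 1M read per counted base
write_counts_as_sam <- function(counts, panel, path) {
  lines <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100000")
  i <- 0
  for (r in seq_len(nrow(counts))) {
    snp <- panel[panel$snp_id == counts$snp_id[r], ]
    other_base <- setdiff(c("A", "C", "G", "T"),
                          c(snp$ref_allele, snp$alt_allele))[1]
    bases <- c(rep(snp$ref_allele, counts$ref_count[r]),
               rep(snp$alt_allele, counts$alt_count[r]),
               rep(other_base, counts$other_count[r]))
    for (b in bases) {
      i <- i + 1
      lines <- c(lines, sprintf("q%06d\t0\t%s\t%d\t50\t1M\t*\t0\t0\t%s\t*\tNH:i:1",
                                i, snp$chrom, snp$pos, b))
    }
  }
  writeLines(lines, path)
  path
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "aseflow", mustWork = TRUE)
}

read_fixture_genotypes <- function() {
  g <- read.delim(fixture_path("example_genotypes.tsv"), sep = "\t")
  m <- as.matrix(g[, -1])
  rownames(m) <- g$individual_id
  storage.mode(m) <- "integer"
  m
}

read_fixture_panel <- function() {
  tibble::as_tibble(read.delim(fixture_path("example_panel.tsv"), sep = "\t"))
}
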