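# Independent oracles and small fixture builders shared across the suite.
# Each oracle takes a deliberately different computational route from the
# implementation it checks.

# Weir-Cockerham theta-hat via the ANOVA mean squares of the allele
# indicator (three-level hierarchy: population / individual / allele), the
# variance-components route of Weir (1996). Inputs: one n_i x 2 allele
# matrix per population.
anova_theta <- function(...) {
  pops <- list(...)
  r <- length(pops)
  n <- vapply(pops, nrow, 0)
  ybar_pop <- vapply(pops, mean, 0)
  ybar_all <- sum(2 * n * ybar_pop) / sum(2 * n)
  SSG <- sum(vapply(pops, function(g) sum((g[, 1] - g[, 2])^2) / 2, 0))
  SSI <- sum(vapply(seq_len(r), function(i) {
    ind <- rowMeans(pops[[i]])
    2 * sum((ind - ybar_pop[i])^2)
  }, 0))
  SSP <- sum(2 * n * (ybar_pop - ybar_all)^2)
  MSG <- SSG / sum(n)
  MSB <- SSI / (sum(n) - r)
  MSA <- SSP / (r - 1)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  sG <- MSG
  sI <- (MSB - MSG) / 2
  sP <- (MSA - MSB) / (2 * nc)
  denom <- sP + sI + sG
  if (denom == 0) return(NA_real_)
  sP / denom
}

# Brute-force EHH: among carrier rows, the fraction of all C(n,2) haplotype
# pairs identical over every visited marker between the core (exclusive)
# and the target column (inclusive).
brute_ehh <- function(x, carriers, core, target) {
  span <- if (target > core) (core + 1):target else target:(core - 1)
  n <- length(carriers)
  pairs <- utils::combn(carriers, 2)
  same <- vapply(seq_len(ncol(pairs)), function(q) {
    all(x[pairs[1, q], span] == x[pairs[2, q], span])
  }, logical(1))
  sum(same) / choose(n, 2)
}

# Exhaustive hypergeometric upper tail P(X >= k) by direct enumeration of
# the probability mass via choose().
hyper_tail_enum <- function(k, n, K, N) {
  if (k <= 0) return(1)
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Diploid genotype pair matrices -> hap_matrix + panel with populations A, B.
geno_to_hap <- function(g1, g2) {
  n1 <- nrow(g1); n2 <- nrow(g2)
  vals <- matrix(c(c(t(g1)), c(t(g2))), ncol = 1)
  hm <- hap_matrix(vals, paste0("s", seq_len(n1 + n2)))
  pan <- population_panel(paste0("s", seq_len(n1 + n2)),
                          rep(c("A", "B"), c(n1, n2)))
  list(haps = hm, panel = pan)
}

# snp_freq object straight from stated p/h/n values (one SNP per row).
freq_stat <- function(p, h, n) {
  structure(list(p = as.matrix(p), h = as.matrix(h), n = n),
            class = "snp_freq")
}

# Random small haplotype instance for EHH property tests.
rand_hap_instance <- function(n_hap = NULL, m = NULL) {
  if (is.null(n_hap)) n_hap <- sample(4:12, 1)
  if (n_hap %% 2L == 1L) n_hap <- n_hap + 1L
  if (is.null(m)) m <- sample(5:30, 1)
  x <- matrix(rbinom(n_hap * m, 1, runif(1, 0.2, 0.8)), n_hap, m)
  vt <- variant_table(rep("chr1", m), sort(sample.int(m * 1000, m)))
  list(x = x, variants = vt,
       haps = hap_matrix(x, paste0("s", seq_len(n_hap / 2))))
}

# Small multi-population simulated dataset (shared by several suites).
sim_dataset <- function(seed = 1, n_snps = 600, n_chromosomes = 1,
                        chrom_length = 3e6,
                        n_diploids = c(FOC = 12, SIS = 10, CTL = 10, OUT = 8),
                        n_founders = 10, sweeps = list()) {
  cfg <- scenario_config(n_diploids = n_diploids,
                         n_chromosomes = n_chromosomes,
                         chrom_length = chrom_length, n_snps = n_snps,
                         n_founders = n_founders, sweeps = sweeps,
                         seed = seed)
  d <- simulate_haplotypes(simulate_frequencies(cfg), cfg)
  d$config <- cfg
  d
}

# Synthetic window_stat table (for framework tests that need no genetics).
fake_windows <- function(n, score, snp_count = rep(10L, n),
                         chrom = "chr1", width = 1e5,
                         max_snp_score = score, test = "pbs") {
  d <- data.frame(chrom = chrom, start = (seq_len(n) - 1) * width,
                  end = seq_len(n) * width, snp_count = snp_count,
                  score = score,
                  max_snp_id = paste0("s", seq_len(n)),
                  max_snp_pos = (seq_len(n) - 1) * width + 1,
                  max_snp_score = max_snp_score,
                  stringsAsFactors = FALSE)
  attr(d, "test") <- test
  attr(d, "width") <- width
  class(d) <- c("window_stat", "data.frame")
  d
}
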