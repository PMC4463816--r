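# Per-SNP allele-frequency statistics: population allele frequencies and
# observed heterozygosity, the two-population Weir-Cockerham (1984)
# variance-components F_ST estimator, and the three-population branch
# statistic PBS built from log-transformed pairwise F_ST.

#' Per-SNP allele frequencies and observed heterozygosity
#'
#' For every population: the ALT-allele frequency `p` (derived frequency for
#' polarized variants where REF is ancestral), the diploid sample size `n`,
#' and the observed heterozygote proportion `h` obtained by pairing each
#' sample's two haplotype rows. Observed (not HWE-expected) heterozygosity
#' is what the Weir-Cockerham `c` component is defined on.
#'
#' @param haps A [hap_matrix()].
#' @param panel A [population_panel()]; every population must contain at
#'   least two diploids.
#' @return A list with class `snp_freq`: `p` and `h` (M x populations
#'   matrices) and `n` (named diploid counts).
#' @export
allele_freqs <- function(haps, panel) {
  pops <- unique(panel$population)
  m <- ncol(haps)
  p <- matrix(NA_real_, m, length(pops), dimnames = list(NULL, pops))
  h <- matrix(NA_real_, m, length(pops), dimnames = list(NULL, pops))
  n <- stats::setNames(integer(length(pops)), pops)
  for (pop in pops) {
    rows <- hap_rows(haps, panel, pop)
    nd <- length(rows) / 2L
    if (nd < 2) stop("population with fewer than 2 diploids: ", pop)
    odd <- rows[seq(1L, length(rows), by = 2L)]
    even <- rows[seq(2L, length(rows), by = 2L)]
    x1 <- haps[odd, , drop = FALSE]
    x2 <- haps[even, , drop = FALSE]
    p[, pop] <- (colSums(x1) + colSums(x2)) / (2 * nd)
    h[, pop] <- colMeans(x1 != x2)
    n[pop] <- nd
  }
  structure(list(p = p, h = h, n = n), class = "snp_freq")
}

#' Two-population Weir-Cockerham F_ST
#'
#' The Weir & Cockerham (1984) variance-components estimator `theta-hat` for
#' `r = 2` populations, per SNP. With `n_i`, `p_i`, `h_i` the diploid count,
#' allele frequency and observed heterozygote proportion of population `i`:
#' `nbar = mean(n_i)`, `nc = (2 nbar - sum(n_i^2)/(2 nbar))`,
#' `pbar = sum(n_i p_i)/(2 nbar)`, `s2 = sum(n_i (p_i - pbar)^2)/nbar`,
#' `hbar = sum(n_i h_i)/(2 nbar)`, and
#' `a = (nbar/nc) (s2 - (pbar(1-pbar) - s2/2 - hbar/4)/(nbar-1))`,
#' `b = (nbar/(nbar-1)) (pbar(1-pbar) - s2/2 - hbar(2 nbar - 1)/(4 nbar))`,
#' `c = hbar/2`, `theta-hat = a/(a+b+c)`.
#'
#' SNPs monomorphic in both populations have `a + b + c = 0`; their estimate
#' is undefined (`NA`) and such SNPs are excluded from windows downstream.
#'
#' @param freqs A `snp_freq` object from [allele_freqs()].
#' @param pop_a,pop_b Population labels.
#' @return A data.frame with `fst_raw` (theta-hat, may be negative) and
#'   `fst` (clamped to `[0, 1]` from below, `max(theta-hat, 0)`).
#' @export
wc_fst <- function(freqs, pop_a, pop_b) {
  stopifnot(inherits(freqs, "snp_freq"))
  for (pop in c(pop_a, pop_b)) {
    if (!pop %in% colnames(freqs$p)) stop("unknown population: ", pop)
  }
  p1 <- freqs$p[, pop_a]; p2 <- freqs$p[, pop_b]
  h1 <- freqs$h[, pop_a]; h2 <- freqs$h[, pop_b]
  n1 <- freqs$n[[pop_a]]; n2 <- freqs$n[[pop_b]]
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  raw <- ifelse(denom == 0, NA_real_, a / denom)
  data.frame(fst_raw = raw, fst = pmax(raw, 0), a = a, b = b, c = cc)
}

#' Multilocus Weir-Cockerham F_ST (ratio of sums)
#'
#' Combines the per-SNP variance components across loci the way Weir &
#' Cockerham recommend: `sum(a) / sum(a + b + c)`. Unlike the average of
#' per-SNP ratios (which is biased toward zero because each per-SNP ratio
#' is a noisy bounded quantity), the ratio of sums is a consistent
#' estimator of the drift-differentiation parameter and is what "mean
#' F_ST" refers to in multi-locus reporting.
#'
#' @inheritParams wc_fst
#' @return A single numeric value.
#' @export
wc_fst_multilocus <- function(freqs, pop_a, pop_b) {
  d <- wc_fst(freqs, pop_a, pop_b)
  sum(d$a) / sum(d$a + d$b + d$c)
}

#' PBS from three pairwise F_ST values
#'
#' Each pairwise F_ST is clamped to `[0, 1 - 1e-12]` before the natural-log
#' branch transform `T = -ln(1 - F_ST)`; the focal branch length is
#' `PBS = (T_fs + T_fo - T_so) / 2` (focal-sister, focal-outgroup,
#' sister-outgroup). PBS may be negative.
#'
#' @param fst_fs,fst_fo,fst_so Pairwise F_ST vectors (clamped internally).
#' @return Data.frame with `t_fs`, `t_fo`, `t_so`, `pbs`.
#' @export
pbs_from_fst <- function(fst_fs, fst_fo, fst_so) {
  tt <- function(f) -log(1 - pmin(pmax(f, 0), 1 - 1e-12))
  t_fs <- tt(fst_fs); t_fo <- tt(fst_fo); t_so <- tt(fst_so)
  data.frame(t_fs = t_fs, t_fo = t_fo, t_so = t_so,
             pbs = (t_fs + t_fo - t_so) / 2)
}

#' Per-SNP population branch statistic
#'
#' Computes the three pairwise Weir-Cockerham F_ST values and the PBS of the
#' focal population (see [pbs_from_fst()]). SNPs with any undefined pairwise
#' F_ST (monomorphic in both members of a pair) get `NA` and are excluded
#' from windows downstream.
#'
#' @param freqs A `snp_freq` object from [allele_freqs()].
#' @param focal,sister,outgroup Three distinct population labels.
#' @return Data.frame with the raw and clamped pairwise F_ST values, the
#'   branch transforms and `pbs`.
#' @export
pbs_scan <- function(freqs, focal, sister, outgroup) {
  pops <- c(focal, sister, outgroup)
  if (anyDuplicated(pops)) {
    stop("focal, sister and outgroup must be distinct populations")
  }
  fs <- wc_fst(freqs, focal, sister)
  fo <- wc_fst(freqs, focal, outgroup)
  so <- wc_fst(freqs, sister, outgroup)
  out <- pbs_from_fst(fs$fst, fo$fst, so$fst)
  out$pbs[is.na(fs$fst) | is.na(fo$fst) | is.na(so$fst)] <- NA_real_
  cbind(data.frame(fst_fs_raw = fs$fst_raw, fst_fs = fs$fst,
                   fst_fo_raw = fo$fst_raw, fst_fo = fo$fst,
                   fst_so_raw = so$fst_raw, fst_so = so$fst), out)
}
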