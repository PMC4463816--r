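# The generator must hand the scans data with the structure they assume:
# Balding-Nichols drift with the stated Beta moments, distance-decaying LD
# from the founder-copying model, reproducibility from one seed, and
# sweeps that lengthen haplotype homozygosity only where they are placed.

test_that("zero-drift edges copy parent frequencies exactly", {
  tr <- population_tree(c("ROOT", "ROOT"), c("A", "B"), c(0, 0.1))
  cfg <- scenario_config(n_diploids = c(A = 5, B = 5), n_chromosomes = 1,
                         n_snps = 300, tree = tr, seed = 3)
  fr <- simulate_frequencies(cfg)
  expect_identical(fr$A, fr$p_anc)
  expect_false(identical(fr$B, fr$p_anc))
})

test_that("drifted frequencies have the Balding-Nichols Beta moments", {
  # F = 0.1 from p = 0.5: variance F p (1-p) = 0.025
  tr <- population_tree("ROOT", "A", 0.1)
  cfg <- scenario_config(n_diploids = c(A = 5), n_chromosomes = 1,
                         n_snps = 100000, freq_bounds = c(0.499999, 0.5),
                         tree = tr, seed = 5)
  fr <- simulate_frequencies(cfg)
  expect_lt(abs(mean(fr$A) - 0.5), 2e-3)
  expect_lt(abs(var(fr$A) - 0.025), 5e-4)   # Monte-Carlo sd ~ 1e-4
})

test_that("the generator is deterministic given the seed", {
  cfg <- scenario_config(n_diploids = c(FOC = 4, SIS = 4, CTL = 4, OUT = 4),
                         n_chromosomes = 1, n_snps = 200, seed = 9)
  f1 <- simulate_frequencies(cfg)
  f2 <- simulate_frequencies(cfg)
  expect_identical(f1, f2)
  d1 <- simulate_haplotypes(f1, cfg)
  d2 <- simulate_haplotypes(f2, cfg)
  expect_identical(unclass(d1$haps), unclass(d2$haps))
})

test_that("copying-model limits: no switching copies founders, fast switching decorrelates", {
  tr <- population_tree("ROOT", "A", 0.05)
  base <- list(n_diploids = c(A = 10), n_chromosomes = 1, n_snps = 200,
               chrom_length = 1e6, tree = tr, seed = 21)
  # switch_rate = 0: every haplotype equals one founder exactly
  cfg0 <- do.call(scenario_config, c(base, list(switch_rate = 0,
                                                n_founders = 5)))
  d0 <- simulate_haplotypes(simulate_frequencies(cfg0), cfg0)
  x <- unclass(d0$haps)
  distinct <- unique(x)
  expect_lte(nrow(distinct), 5L)

  # switch_rate -> infinity: adjacent-SNP haplotype correlation ~ 0
  cfgI <- do.call(scenario_config, c(base, list(switch_rate = 1)))
  dI <- simulate_haplotypes(simulate_frequencies(cfgI), cfgI)
  xI <- unclass(dI$haps)
  keep <- apply(xI, 2, sd) > 0
  cors <- vapply(which(keep[-1] & head(keep, -1)), function(j)
    cor(xI[, j], xI[, j + 1]), 0)
  # signed correlations average to ~0 (|r| itself has O(1/sqrt(H)) noise)
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("LD decays with distance under default copying parameters", {
  # adjacent-SNP r2 must exceed r2 at ~10x the spacing, averaged over seeds
  r2 <- function(a, b) suppressWarnings(cor(a, b))^2
  near <- far <- numeric(0)
  for (seed in 1:20) {
    tr <- population_tree("ROOT", "A", 0.05)
    cfg <- scenario_config(n_diploids = c(A = 20), n_chromosomes = 1,
                           n_snps = 250, chrom_length = 1e6, tree = tr,
                           seed = seed)
    d <- simulate_haplotypes(simulate_frequencies(cfg), cfg)
    x <- unclass(d$haps)
    poly <- which(apply(x, 2, sd) > 0)
    poly <- poly[poly <= ncol(x) - 10]
    poly <- poly[(poly + 1) %in% which(apply(x, 2, sd) > 0) &
                   (poly + 10) %in% which(apply(x, 2, sd) > 0)]
    near <- c(near, mean(vapply(poly, function(j) r2(x[, j], x[, j + 1]), 0),
                         na.rm = TRUE))
    far <- c(far, mean(vapply(poly, function(j) r2(x[, j], x[, j + 10]), 0),
                       na.rm = TRUE))
  }
  expect_gt(mean(near), mean(far))
})

test_that("sweep injection reaches the target frequency and stays local", {
  d <- sim_dataset(seed = 31, n_snps = 400,
                   n_diploids = c(FOC = 12, SIS = 10, CTL = 10, OUT = 8))
  core <- pick_sweep_core(d, "FOC")
  rows_foc <- hap_rows(d$haps, d$panel, "FOC")
  other <- setdiff(seq_len(nrow(d$haps)), rows_foc)
  before <- unclass(d$haps)

  swept <- inject_sweep(d, sweep_spec("FOC", core, f_target = 1.0), seed = 2)
  expect_true(all(swept[rows_foc, core] == 1L))
  # non-target populations bit-identical
  expect_identical(unclass(swept)[other, ], before[other, ])

  # f_target below the current frequency is rejected
  d2 <- d
  d2$haps <- swept
  expect_error(inject_sweep(d2, sweep_spec("FOC", core, f_target = 0.5)),
               "below current")
})

test_that("sweeps raise derived-allele EHH at the core", {
  gain <- numeric(0)
  for (seed in 1:20) {
    d <- sim_dataset(seed = 100 + seed, n_snps = 300, chrom_length = 1.5e6,
                     n_diploids = c(FOC = 12, SIS = 8, CTL = 8, OUT = 8))
    core <- pick_sweep_core(d, "FOC", freq_range = c(0.2, 0.5))
    rows <- hap_rows(d$haps, d$panel, "FOC")
    mean_ehh <- function(haps) {
      cur <- ehh(haps, d$variants, core, allele = 1, rows = rows)
      mean(cur$ehh[cur$distance > 0 & cur$distance < 5e4])
    }
    e0 <- mean_ehh(d$haps)
    swept <- inject_sweep(d, sweep_spec("FOC", core, 0.9, 1e5), seed = seed)
    gain <- c(gain, mean_ehh(swept) - e0)
  }
  expect_gt(mean(gain), 0)
})

test_that("generated fixtures load back with matching dimensions, byte-stably", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- scenario_config(n_diploids = c(FOC = 5, SIS = 4, CTL = 4, OUT = 4),
                         n_chromosomes = 1, n_snps = 150, chrom_length = 2e6,
                         seed = 77)
  p1 <- generate_dataset(cfg, dir1)
  p2 <- generate_dataset(cfg, dir2)
  expect_identical(readLines(p1$vcf), readLines(p2$vcf))

  pan <- read_panel(p1$panel)
  got <- read_phased_vcf(p1$vcf, pan)
  expect_equal(dim(got$haps), c(2L * 17L, 150L))
  genes <- read_gene_bed(p1$genes)
  expect_gt(nrow(genes), 0)
  cand <- read_candidate_list(p1$candidates)
  expect_true(all(cand %in% toupper(genes$gene)))
  manifest <- jsonlite::read_json(p1$manifest)
  expect_equal(manifest$seed, 77L)

  # a different seed changes the genotypes
  cfg2 <- scenario_config(n_diploids = c(FOC = 5, SIS = 4, CTL = 4, OUT = 4),
                          n_chromosomes = 1, n_snps = 150, chrom_length = 2e6,
                          seed = 78)
  dir3 <- withr::local_tempdir()
  p3 <- generate_dataset(cfg2, dir3)
  expect_false(identical(readLines(p3$vcf), readLines(p1$vcf)))
})
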