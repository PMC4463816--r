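# The empirical-outlier window framework: tiling, SNP-count binning,
# ceiling-exact top-percentile calling with deterministic ties, the
# cross-population exclusion rule, cross-test overlaps, cut-off counts and
# the branch-length comparison -- each checked against direct set/sort
# oracles.

test_that("windows tile from coordinate 0 and drop empty regions", {
  pos <- seq(50000, 950000, by = 50000)
  w <- make_windows(rep("chr1", length(pos)), pos, 1e5)
  expect_equal(nrow(w), 10L)
  expect_equal(w$start, seq(0, 9e5, by = 1e5))
  expect_equal(sum(w$snp_count), length(pos))

  # 1-based position 100000 is 0-based 99999: window [0, 100000)
  w1 <- make_windows("chr1", 100000, 1e5)
  expect_equal(w1$start, 0)
  w2 <- make_windows("chr1", 100001, 1e5)
  expect_equal(w2$start, 1e5)

  # a SNP-free region produces no window row
  w3 <- make_windows(c("chr1", "chr1"), c(1, 900001), 1e5)
  expect_equal(nrow(w3), 2L)
  expect_equal(w3$start, c(0, 9e5))
})

test_that("window scores follow the per-test statistic", {
  snp <- data.frame(chrom = "chr1", pos = c(1e4, 2e4, 1.2e5, 1.4e5),
                    snp_id = paste0("s", 1:4),
                    ihs_std = c(2.5, -1.0, 0.5, -3.0),
                    pbs = c(0.1, 0.4, 0.2, 0.9),
                    stringsAsFactors = FALSE)
  wi <- window_stats(snp, "ihs", width = 1e5)
  expect_equal(wi$score, c(0.5, 0.5))        # fraction |ihs| > 2
  expect_equal(wi$max_snp_id, c("s1", "s4")) # largest |score| SNP
  wp <- window_stats(snp, "pbs", width = 1e5)
  expect_equal(wp$score, c(0.4, 0.9))        # window maximum
  expect_equal(wp$max_snp_id, c("s2", "s4"))
  # NA scores and invalid rows are excluded before windowing
  snp$pbs[2] <- NA
  expect_equal(window_stats(snp, "pbs", width = 1e5)$score[1], 0.1)
})

test_that("SNP-count binning is ceiling-exact and reduces to global ranking", {
  # all windows share one SNP count: binned percentile equals unbinned
  withr::with_seed(5, {
    ws <- fake_windows(200, score = rnorm(200))
    b1 <- call_outliers(bin_by_snp_count(ws, bin_floor = 50))
    b2 <- call_outliers(bin_by_snp_count(ws, scheme = "single"))
    expect_equal(b1$percentile, b2$percentile)
    expect_equal(sum(b1$top1), 2L)            # ceiling(0.01 * 200)
    expect_equal(b1$top1, rank(-ws$score) <= 2)

    # 1000 windows over several bins: flags sum to ceiling per bin
    ws <- fake_windows(1000, score = rnorm(1000),
                       snp_count = sample(5:40, 1000, TRUE))
    b <- call_outliers(bin_by_snp_count(ws, bin_floor = 50))
    per_bin <- tapply(b$top1, b$bin, sum)
    sizes <- table(b$bin)
    expect_equal(as.vector(per_bin), as.vector(ceiling(0.01 * sizes)))
    expect_true(all(tapply(seq_len(nrow(b)), b$bin, function(i)
      min(table(b$snp_count[i])) >= 0)))      # bins are count-contiguous
    expect_true(all(b$top5[b$top1]))          # top1 implies top5
    expect_true(all(tapply(b$snp_count, b$bin, length) >= 50))
  })
  expect_warning(bin_by_snp_count(fake_windows(10, score = 1:10)),
                 "single bin")
})

test_that("outlier calling is rank-based and deterministic under ties", {
  # invariance to monotone transforms of the score
  withr::with_seed(9, {
    s <- rexp(300)
    w1 <- call_outliers(bin_by_snp_count(fake_windows(300, score = s),
                                         scheme = "single"))
    w2 <- call_outliers(bin_by_snp_count(
      fake_windows(300, score = log(s + 1)), scheme = "single"))
    expect_equal(w1$top1, w2$top1)
    expect_equal(w1$rank, w2$rank)
  })
  # tie at the cut: higher max-SNP score wins, then lower chrom/start
  ws <- fake_windows(100, score = c(rep(1, 3), rep(0, 97)),
                     max_snp_score = c(3, 5, 4, rep(0, 97)))
  b <- call_outliers(bin_by_snp_count(ws, scheme = "single"))
  expect_equal(which(b$top1), 2L)             # ceiling(0.01*100) = 1 flagged
  ws2 <- fake_windows(100, score = c(rep(1, 3), rep(0, 97)),
                      max_snp_score = rep(2, 100))
  b2 <- call_outliers(bin_by_snp_count(ws2, scheme = "single"))
  expect_equal(which(b2$top1), 1L)            # falls back to lowest start
})

test_that("the exclusion rule removes focal windows vetoed by the control", {
  withr::with_seed(13, {
    f <- call_outliers(bin_by_snp_count(fake_windows(200, rnorm(200)),
                                        scheme = "single"))
    cpy <- function(scores) call_outliers(bin_by_snp_count(
      fake_windows(200, scores), scheme = "single"))
    # disjoint outlier sets: everything retained
    ctl <- cpy(-f$score)
    kept <- suppressMessages(exclusion_filter(f, ctl))
    expect_equal(nrow(kept), sum(f$top1))
    expect_equal(attr(kept, "n_removed"), 0L)
    # identical scores: every focal top-1% window is inside control top-5%
    ctl2 <- cpy(f$score)
    kept2 <- suppressMessages(exclusion_filter(f, ctl2))
    expect_equal(nrow(kept2), 0L)
    # control percentile 1.0 vetoes everything
    ctl3 <- cpy(rnorm(200))
    ctl3$top5 <- TRUE
    expect_equal(nrow(suppressMessages(exclusion_filter(f, ctl3))), 0L)
    # direct set oracle on a random control
    kept4 <- suppressMessages(exclusion_filter(f, ctl3, control_flag = "top1"))
    oracle <- setdiff(f$start[f$top1], ctl3$start[ctl3$top1])
    expect_setequal(kept4$start, oracle)
    # mismatched tiling is an error
    g <- fake_windows(50, rnorm(50), width = 2e5)
    expect_error(exclusion_filter(f, g), "tiling")
  })
})

test_that("cross-test overlaps match a direct set-intersection oracle", {
  sets <- list(ihs = c("A", "B", "C"), xpehh = c("B", "D"),
               pbs = c("B", "C", "E"), fst = character(0))
  ov <- cross_test_overlap(sets)
  expect_equal(ov$n_tests[ov$gene == "B"], 3)
  expect_equal(sort(strsplit(ov$tests[ov$gene == "B"], ",")[[1]]),
               c("ihs", "pbs", "xpehh"))
  expect_setequal(ov$gene[ov$n_tests >= 2], c("B", "C"))
  # disjoint sets: empty >= 2 summary
  ov0 <- cross_test_overlap(list(a = "X", b = "Y"))
  expect_equal(sum(ov0$n_tests >= 2), 0L)
  # randomized labels against the oracle
  withr::with_seed(21, {
    for (it in 1:20) {
      gs <- lapply(1:3, function(i) sample(LETTERS, sample(3:10, 1)))
      names(gs) <- c("t1", "t2", "t3")
      ov <- cross_test_overlap(gs)
      for (g in ov$gene) {
        expect_equal(ov$n_tests[ov$gene == g],
                     sum(vapply(gs, function(s) g %in% s, TRUE)))
      }
    }
  })
})

test_that("F_ST cut-off counts use strict inequality", {
  ws <- fake_windows(3, score = c(0.59, 0.60, 0.61))
  expect_equal(fst_cutoff_count(ws, 0.6), 1L)
  expect_equal(fst_cutoff_count(fake_windows(5, score = rep(0.1, 5)), 0.6), 0L)
})

test_that("branch-length comparison shares match a direct sort oracle", {
  withr::with_seed(33, {
    s <- rnorm(300)
    w1 <- call_outliers(bin_by_snp_count(fake_windows(300, s),
                                        scheme = "single"))
    # identical scores: strict comparison gives share 0
    expect_equal(branch_length_comparison(w1, w1)$share, 0)
    # focal-1 everywhere epsilon higher: share 1
    w2 <- call_outliers(bin_by_snp_count(fake_windows(300, s - 1e-9),
                                         scheme = "single"))
    cmp <- branch_length_comparison(w1, w2)
    expect_gt(cmp$n_overlap, 0)
    expect_equal(cmp$share, 1)
    # empty overlap: undefined
    w3 <- call_outliers(bin_by_snp_count(fake_windows(300, -s),
                                         scheme = "single"))
    cmp3 <- branch_length_comparison(w1, w3)
    if (cmp3$n_overlap == 0) expect_true(is.na(cmp3$share))
    # random independent scores: share ~ 0.5 over many overlaps
    shares <- n <- 0
    for (it in 1:200) {
      a <- call_outliers(bin_by_snp_count(
        fake_windows(100, rnorm(100)), scheme = "single"), top1 = 0.1)
      b <- call_outliers(bin_by_snp_count(
        fake_windows(100, rnorm(100)), scheme = "single"), top1 = 0.1)
      cmp <- branch_length_comparison(a, b)
      if (cmp$n_overlap > 0) {
        shares <- shares + cmp$share * cmp$n_overlap
        n <- n + cmp$n_overlap
      }
    }
    expect_gt(n, 50)
    expect_equal(shares / n, 0.5, tolerance = 0.15)
  })
})

test_that("outlier flags are uniform across SNP-count bins for count-independent scores", {
  # with scores independent of snp_count, the ceiling rule flags (almost)
  # the same fraction in every bin: chi-square flat across 20 seeds
  pvals <- vapply(1:20, function(seed) {
    withr::with_seed(1000 + seed, {
      ws <- fake_windows(600, score = rnorm(600),
                         snp_count = rpois(600, 12))
      b <- call_outliers(bin_by_snp_count(ws, bin_floor = 50))
      suppressWarnings(chisq.test(table(b$bin, b$top5))$p.value)
    })
  }, 0)
  expect_gte(sum(pvals > 0.01), 19L)
})
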