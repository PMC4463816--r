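# EHH, iHH and the standardized haplotype scores. EHH is checked against
# brute-force pair counting; iHH against hand-computed piecewise-linear
# areas; the scans against their definitional identities (bin moments,
# antisymmetry, mirror symmetry).

test_that("EHH evaluates pair homozygosity at each marker", {
  # 4 carriers splitting {3, 1} one marker right of the core: EHH = 3/6
  x <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 0, 0), c(1, 0, 0))
  vt <- variant_table(rep("chr1", 3), c(1000, 2000, 3000))
  hm <- hap_matrix(x, c("s1", "s2"))
  cur <- ehh(hm, vt, core = 1, allele = 1, direction = "right")
  expect_equal(cur$ehh, c(1, 1, 0.5))

  # identical carriers: EHH = 1 everywhere; all distinct: EHH = 0
  x2 <- rbind(c(1, 1, 0, 1), c(1, 1, 0, 1), c(1, 1, 0, 1), c(1, 1, 0, 1))
  hm2 <- hap_matrix(x2, c("s1", "s2"))
  vt2 <- variant_table(rep("chr1", 4), c(1, 1001, 2001, 3001))
  cur2 <- ehh(hm2, vt2, core = 1, allele = 1, direction = "right",
              cutoff = 0)
  expect_true(all(cur2$ehh == 1))
  x3 <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1))
  hm3 <- hap_matrix(x3, c("s1", "s2"))
  cur3 <- ehh(hm3, vt, core = 1, allele = 1, direction = "right")
  expect_equal(cur3$ehh[3], 0)
  expect_error(ehh(hm3, vt, core = 1, allele = 0), "fewer than 2")
})

test_that("EHH matches brute-force pair counting on random instances", {
  withr::with_seed(17, {
    for (it in 1:100) {
      inst <- rand_hap_instance()
      m <- ncol(inst$x)
      core <- sample(m, 1)
      al <- sample(0:1, 1)
      carriers <- which(inst$x[, core] == al)
      if (length(carriers) < 2) next
      for (dir in c("left", "right")) {
        cur <- ehh(inst$haps, inst$variants, core, allele = al,
                   direction = dir, cutoff = 0, gap_max = Inf)
        cur <- cur[cur$distance > 0, ]
        for (i in seq_len(nrow(cur))) {
          expect_equal(cur$ehh[i],
                       brute_ehh(inst$x, carriers, core, cur$snp[i]),
                       tolerance = 1e-12)
        }
      }
    }
  })
})

test_that("EHH is monotone non-increasing outward", {
  withr::with_seed(23, {
    for (it in 1:50) {
      inst <- rand_hap_instance()
      core <- sample(ncol(inst$x), 1)
      carriers <- which(inst$x[, core] == 1)
      if (length(carriers) < 2) next
      cur <- ehh(inst$haps, inst$variants, core, allele = 1, cutoff = 0,
                 gap_max = Inf)
      for (d in unique(cur$direction)) {
        expect_true(all(diff(cur$ehh[cur$direction == d]) <= 1e-12))
      }
    }
  })
})

test_that("iHH integrates the decay curve with cutoff interpolation", {
  # rectangle: EHH 1 out to 10 kb each side, nothing beyond
  expect_equal(ihh_area(10000, 1) + ihh_area(10000, 1), 20000)

  # single step 1.0 -> 0.04 over 1000 bp: trapezoid to the 0.05 crossing
  dstar <- (1 - 0.05) / (1 - 0.04) * 1000
  expect_equal(ihh_area(1000, 0.04), (1 + 0.05) / 2 * dstar)

  # independent piecewise-linear oracle on a random curve
  withr::with_seed(31, {
    d <- sort(runif(8, 100, 5000))
    e <- sort(runif(8, 0.2, 0.99), decreasing = TRUE)
    f <- approxfun(c(0, d), c(1, e))
    # quadrature segment by segment is exact on a piecewise-linear curve
    knots <- c(0, d)
    quad <- function(lo, hi) {
      ks <- knots[knots > lo & knots < hi]
      bounds <- c(lo, ks, hi)
      sum(vapply(seq_len(length(bounds) - 1L), function(i)
        integrate(f, bounds[i], bounds[i + 1L])$value, 0))
    }
    orac <- quad(0, max(d))
    expect_equal(ihh_area(d, e, truncate = FALSE), orac, tolerance = 1e-9)
    # additivity over a subdivided interval
    k <- 4
    left <- ihh_area(d[1:k], e[1:k], truncate = FALSE)
    expect_equal(ihh_area(d, e, truncate = FALSE),
                 left + quad(d[k], max(d)), tolerance = 1e-9)
  })

  # immediate collapse has zero area
  expect_equal(ihh_area(1000, 0.0), (1 + 0.05) / 2 * (0.95 * 1000))
  expect_equal(ihh_area(numeric(0), numeric(0)), 0)
})

test_that("mirrored ancestral/derived haplotype structure gives iHS = 0", {
  # 4 derived and 4 ancestral carriers with identical flank patterns
  flank <- rbind(c(0, 0, 1, 1), c(0, 1, 1, 0), c(1, 0, 0, 1), c(1, 1, 0, 0))
  x <- rbind(cbind(flank[, 1:2], 1, flank[, 3:4]),
             cbind(flank[, 1:2], 0, flank[, 3:4]))
  vt <- variant_table(rep("chr1", 5), c(1000, 2000, 3000, 4000, 5000),
                      ancestral = "A")   # ref ancestral, 1 = derived
  hm <- hap_matrix(x, paste0("s", 1:4))
  pan <- population_panel(paste0("s", 1:4), rep("P", 4))
  sc <- suppressWarnings(ihs_scan(hm, vt, pan, "P", gap_max = Inf))
  expect_equal(sc$ihs_unstd[3], 0)
  expect_equal(sc$ihh_a[3], sc$ihh_d[3])
})

test_that("iHS standardization gives mean 0 / SD 1 within every frequency bin", {
  d <- sim_dataset(seed = 41, n_snps = 900, chrom_length = 4.5e6,
                   n_diploids = c(FOC = 16, SIS = 8, CTL = 8, OUT = 8))
  sc <- ihs_scan(d$haps, d$variants, d$panel, "FOC")
  ok <- sc$valid & !is.na(sc$ihs_std)
  expect_gt(sum(ok), 100)
  for (g in unique(sc$bin[ok])) {
    sel <- ok & sc$bin == g
    expect_gte(sum(sel), 20)                      # bin floor respected
    expect_equal(mean(sc$ihs_std[sel]), 0, tolerance = 1e-9)
    expect_equal(sd(sc$ihs_std[sel]), 1, tolerance = 1e-9)
  }
  # cores outside the frequency range or unpolarized are flagged, not scored
  expect_true(all(sc$reason[!sc$valid] %in%
                    c("unpolarized", "frequency", "carriers", "gap",
                      "zero_area")))
})

test_that("iHS skips unpolarized variants and warns when none are scorable", {
  d <- sim_dataset(seed = 43, n_snps = 60,
                   n_diploids = c(FOC = 6, SIS = 4, CTL = 4, OUT = 4))
  vt <- d$variants
  vt$ancestral <- "unknown"
  expect_warning(sc <- ihs_scan(d$haps, vt, d$panel, "FOC"), "no valid core")
  expect_true(all(!sc$valid))
  expect_true(all(sc$reason == "unpolarized"))
})

test_that("XP-EHH is zero for identical populations and antisymmetric under swap", {
  d <- sim_dataset(seed = 47, n_snps = 300, chrom_length = 1.5e6,
                   n_diploids = c(FOC = 10, SIS = 10, CTL = 8, OUT = 8))
  # clone FOC haplotypes into SIS rows: identical haplotype sets
  h <- unclass(d$haps)
  rf <- hap_rows(d$haps, d$panel, "FOC")
  rs <- hap_rows(d$haps, d$panel, "SIS")
  h[rs, ] <- h[rf, ]
  same <- hap_matrix(h, attr(d$haps, "sample_ids"))
  sc0 <- xpehh_scan(same, d$variants, d$panel, "FOC", "SIS")
  expect_true(all(abs(sc0$xpehh_unstd[sc0$valid]) < 1e-12))

  sc_ab <- xpehh_scan(d$haps, d$variants, d$panel, "FOC", "SIS")
  sc_ba <- xpehh_scan(d$haps, d$variants, d$panel, "SIS", "FOC")
  expect_equal(sc_ab$xpehh_unstd, -sc_ba$xpehh_unstd, tolerance = 1e-12)

  v <- sc_ab$valid
  expect_equal(mean(sc_ab$xpehh_std[v]), 0, tolerance = 1e-9)
  expect_equal(sd(sc_ab$xpehh_std[v]), 1, tolerance = 1e-9)
})
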