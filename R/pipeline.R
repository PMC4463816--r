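# Orchestration: one configuration object drives simulate -> load -> scan
# -> windows -> outliers -> enrichment, with a JSON run manifest so every
# reported number is reproducible from the manifest alone. Identical config
# and inputs give byte-identical outputs (no timestamps, no hidden RNG).

#' Scan configuration
#'
#' @param vcf Path to the phased VCF (or a list with in-memory `variants`,
#'   `haps` as returned by [read_phased_vcf()] / [simulate_haplotypes()]).
#' @param panel Path to the panel TSV, or a [population_panel()].
#' @param genes Path to the BED4 gene annotation, or a
#'   [gene_annotation()]; optional (gene-level outputs skipped if absent).
#' @param candidates Path to the candidate-gene list, or a character
#'   vector; optional.
#' @param gene2term Path to a gene-to-term TSV, or a data.frame; optional.
#' @param roles Named list binding roles (`focal`, `sister`, `control`,
#'   `outgroup`) to population labels; merged over any roles already on the
#'   panel.
#' @param tests Character subset of `c("ihs", "xpehh", "fst", "pbs")`.
#' @param hap_window,freq_window Window widths in bp for the haplotype and
#'   frequency tests (defaults 200 kb / 100 kb).
#' @param top1,top5 Outlier percentiles (defaults 0.01 / 0.05).
#' @param ihs_threshold `|standardized iHS|` threshold for the window
#'   statistic (default 2).
#' @param ehh_cutoff EHH truncation threshold (default 0.05).
#' @param gap_max Maximum tolerated inter-SNP gap in bp (default 200 kb).
#' @param bin_floor Minimum windows per SNP-count bin (default 50).
#' @param fst_cutoff F_ST window cut-off for the super-cutoff count
#'   (default 0.6).
#' @param ease_max EASE report threshold (default 0.01).
#' @param out Optional output directory; when set, [run_scan()] writes all
#'   tables and the manifest there.
#' @param seed Integer recorded in the manifest (the scan itself is
#'   deterministic).
#' @return A list with class `scan_config`.
#' @export
scan_config <- function(vcf, panel, genes = NULL, candidates = NULL,
                        gene2term = NULL, roles = list(),
                        tests = c("ihs", "xpehh", "fst", "pbs"),
                        hap_window = 2e5, freq_window = 1e5,
                        top1 = 0.01, top5 = 0.05, ihs_threshold = 2,
                        ehh_cutoff = 0.05, gap_max = 2e5, bin_floor = 50,
                        fst_cutoff = 0.6, ease_max = 0.01, out = NULL,
                        seed = 1) {
  tests <- match.arg(tests, several.ok = TRUE)
  if (!(top1 < top5)) stop("top1 percentile must be below top5")
  if (hap_window <= 0 || freq_window <= 0) stop("window widths must be > 0")
  structure(list(vcf = vcf, panel = panel, genes = genes,
                 candidates = candidates, gene2term = gene2term,
                 roles = roles, tests = tests, hap_window = hap_window,
                 freq_window = freq_window, top1 = top1, top5 = top5,
                 ihs_threshold = ihs_threshold, ehh_cutoff = ehh_cutoff,
                 gap_max = gap_max, bin_floor = bin_floor,
                 fst_cutoff = fst_cutoff, ease_max = ease_max, out = out,
                 seed = as.integer(seed)),
            class = "scan_config")
}

scan_config_error <- function(...) {
  stop(structure(class = c("scan_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

load_input <- function(x, loader) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) loader(x) else x
}

#' Run the full selection scan
#'
#' Loads the inputs, computes the requested per-SNP statistics, collapses
#' them to fixed windows, bins and ranks the windows, flags empirical
#' outliers, applies the cross-population exclusion rule to the focal iHS
#' windows (when a `control` role is bound), assigns genes, intersects
#' them with the candidate list, summarises cross-test overlaps, counts
#' F_ST windows above the cut-off, and (when a mapping is supplied) screens
#' GO terms with the EASE score. Role requirements: `focal` always;
#' `sister` for F_ST/PBS; `outgroup` for PBS; `control` for the iHS
#' exclusion and as the XP-EHH reference (falling back to `sister`).
#' Missing roles for a requested test raise a configuration error before
#' any computation.
#'
#' @param config A [scan_config()].
#' @return A list of class `scan_result` with elements `snp_stats`,
#'   `windows` (per test, outlier-called), `excluded_ihs`, `genes` (per
#'   test), `overlap`, `candidate_enrichment`, `go_enrichment`,
#'   `fst_cutoff_count`, `universe` and `manifest`. Written to
#'   `config$out` when set.
#' @export
run_scan <- function(config) {
  stopifnot(inherits(config, "scan_config"))
  panel <- load_input(config$panel, read_panel)
  rl <- utils::modifyList(as.list(roles(panel) %||% list()),
                          as.list(config$roles))
  need_role <- function(role, why) {
    if (is.null(rl[[role]])) {
      scan_config_error("role '", role, "' is required for ", why,
                        " but is not bound")
    }
    rl[[role]]
  }
  focal <- need_role("focal", "any scan")
  if ("pbs" %in% config$tests) {
    sister <- need_role("sister", "PBS")
    outgrp <- need_role("outgroup", "PBS")
    if (anyDuplicated(c(focal, sister, outgrp))) {
      scan_config_error("focal, sister and outgroup must be distinct for PBS")
    }
  }
  if ("fst" %in% config$tests) need_role("sister", "the F_ST scan")
  xp_ref <- rl$control %||% rl$sister
  if ("xpehh" %in% config$tests && is.null(xp_ref)) {
    scan_config_error("role 'control' or 'sister' is required for XP-EHH")
  }

  gdata <- if (is.list(config$vcf) && !is.null(config$vcf$haps)) config$vcf
  else read_phased_vcf(config$vcf, panel)
  variants <- gdata$variants
  haps <- gdata$haps
  genes <- load_input(config$genes, read_gene_bed)
  candidates <- load_input(config$candidates, read_candidate_list)
  gene2term <- load_input(config$gene2term, read_gene2term)

  res <- list(windows = list(), genes = list(), candidate_enrichment = list(),
              go_enrichment = list())
  counts <- list(n_snps = nrow(variants), n_samples = nrow(panel))
  snp <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    snp_id = variants$snp_id, stringsAsFactors = FALSE)

  freqs <- NULL
  if (any(c("fst", "pbs") %in% config$tests)) {
    freqs <- allele_freqs(haps, panel)
  }
  if ("fst" %in% config$tests) {
    f <- wc_fst(freqs, focal, rl$sister)
    snp$fst_raw <- f$fst_raw
    snp$fst <- f$fst
    ws <- window_stats(snp, "fst", width = config$freq_window)
    ws <- call_outliers(bin_by_snp_count(ws, scheme = "single"),
                        config$top1, config$top5)
    res$windows$fst <- ws
    counts$fst_windows <- nrow(ws)
    res$fst_cutoff_count <- fst_cutoff_count(ws, config$fst_cutoff)
  }
  if ("pbs" %in% config$tests) {
    pb <- pbs_scan(freqs, focal, rl$sister, rl$outgroup)
    snp$pbs <- pb$pbs
    ws <- window_stats(snp, "pbs", width = config$freq_window)
    ws <- call_outliers(bin_by_snp_count(ws, scheme = "single"),
                        config$top1, config$top5)
    res$windows$pbs <- ws
    counts$pbs_windows <- nrow(ws)
  }
  if ("ihs" %in% config$tests) {
    sc <- ihs_scan(haps, variants, panel, focal, cutoff = config$ehh_cutoff,
                   gap_max = config$gap_max)
    snp$ihs_std <- sc$ihs_std
    snp$ihs_valid <- sc$valid
    ws <- window_stats(cbind(snp[, c("chrom", "pos", "snp_id")],
                             ihs_std = sc$ihs_std, valid = sc$valid),
                       "ihs", width = config$hap_window,
                       threshold = config$ihs_threshold)
    ws <- call_outliers(bin_by_snp_count(ws, bin_floor = config$bin_floor),
                        config$top1, config$top5)
    res$windows$ihs <- ws
    counts$ihs_valid_snps <- sum(sc$valid)
    if (!is.null(rl$control) && rl$control != focal) {
      ctl <- ihs_scan(haps, variants, panel, rl$control,
                      cutoff = config$ehh_cutoff, gap_max = config$gap_max)
      cw <- window_stats(cbind(snp[, c("chrom", "pos", "snp_id")],
                               ihs_std = ctl$ihs_std, valid = ctl$valid),
                         "ihs", width = config$hap_window,
                         threshold = config$ihs_threshold)
      cw <- call_outliers(bin_by_snp_count(cw, bin_floor = config$bin_floor),
                          config$top1, config$top5)
      res$excluded_ihs <- exclusion_filter(ws, cw)
      counts$ihs_excluded <- attr(res$excluded_ihs, "n_removed")
    }
  }
  if ("xpehh" %in% config$tests) {
    sc <- xpehh_scan(haps, variants, panel, focal, xp_ref,
                     cutoff = config$ehh_cutoff, gap_max = config$gap_max)
    snp$xpehh_std <- sc$xpehh_std
    snp$xpehh_valid <- sc$valid
    ws <- window_stats(cbind(snp[, c("chrom", "pos", "snp_id")],
                             xpehh_std = sc$xpehh_std, valid = sc$valid),
                       "xpehh", width = config$hap_window)
    ws <- call_outliers(bin_by_snp_count(ws, bin_floor = config$bin_floor),
                        config$top1, config$top5)
    res$windows$xpehh <- ws
    counts$xpehh_valid_snps <- sum(sc$valid)
  }
  res$snp_stats <- snp

  if (!is.null(genes)) {
    # universe: genes overlapping any scanned window (any test)
    universe <- character(0)
    for (test in names(res$windows)) {
      hit <- assign_genes(res$windows[[test]], genes, flag = "none")
      universe <- union(universe, hit$gene)
    }
    res$universe <- sort(universe)
    for (test in names(res$windows)) {
      ws <- if (test == "ihs" && !is.null(res$excluded_ihs))
        res$excluded_ihs else res$windows[[test]]
      gh <- assign_genes(ws, genes, snp_stats = snp,
                         score_col = switch(test, ihs = "ihs_std",
                                            xpehh = "xpehh_std", fst = "fst",
                                            pbs = "pbs"),
                         flag = if (is.null(ws$top1)) "none" else "top1")
      res$genes[[test]] <- gh
      if (!is.null(candidates)) {
        res$candidate_enrichment[[test]] <-
          candidate_overlap(gh$gene, candidates, res$universe,
                            name = paste0(test, "_top1"))
      }
      if (!is.null(gene2term)) {
        res$go_enrichment[[test]] <-
          go_enrichment(gh$gene, gene2term, res$universe,
                        ease_max = config$ease_max)
      }
    }
    res$overlap <- cross_test_overlap(lapply(res$genes, `[[`, "gene"))
    counts$genes_two_plus_tests <- sum(res$overlap$n_tests >= 2)
  }

  res$manifest <- list(
    tool = "sweepscan::run_scan",
    version = as.character(utils::packageVersion("sweepscan")),
    seed = config$seed,
    roles = rl,
    tests = config$tests,
    parameters = config[c("hap_window", "freq_window", "top1", "top5",
                          "ihs_threshold", "ehh_cutoff", "gap_max",
                          "bin_floor", "fst_cutoff", "ease_max")],
    counts = counts)
  class(res) <- "scan_result"
  if (!is.null(config$out)) write_scan_results(res, config$out)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic dataset (pipeline entry point)
#'
#' Thin wrapper over [generate_dataset()] exposing simulation as a pipeline
#' subcommand.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory for the fixture.
#' @return The fixture file paths, invisibly (see [generate_dataset()]).
#' @export
run_simulation <- function(config, dir) {
  generate_dataset(config, dir)
}
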