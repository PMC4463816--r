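# The fixed-window empirical-outlier framework: non-overlapping windows
# anchored at coordinate 0 (0-based half-open internally), per-window scores
# (max-SNP for the frequency tests, proportion of extreme scores for iHS,
# max for XP-EHH), SNP-count binning, top-percentile outlier calling with a
# deterministic tie rule, the cross-population exclusion rule, cross-test
# gene overlaps, F_ST cut-off counts and the focal-vs-focal branch-length
# comparison.

#' Tile scored SNPs into fixed windows
#'
#' Windows are anchored at coordinate 0 and tile each chromosome through its
#' last SNP; a SNP at 1-based position `p` falls in window
#' `[floor((p-1)/width)*width, +width)`. Windows containing no scored SNP
#' are dropped.
#'
#' @param chrom,pos Chromosome and 1-based position per scored SNP.
#' @param width Window width in bp (200 kb for the haplotype tests, 100 kb
#'   for the frequency tests).
#' @return Data.frame `chrom`, `start`, `end`, `snp_count` sorted by
#'   `(chrom, start)`, with a `width` attribute.
#' @export
make_windows <- function(chrom, pos, width) {
  stopifnot(width > 0)
  start <- floor((pos - 1) / width) * width
  key <- paste(chrom, start, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  d <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                  start = as.numeric(vapply(parts, `[`, "", 2L)),
                  snp_count = as.integer(tab), stringsAsFactors = FALSE)
  d$end <- d$start + width
  d <- d[order(d$chrom, d$start), c("chrom", "start", "end", "snp_count")]
  rownames(d) <- NULL
  attr(d, "width") <- width
  d
}

#' Per-window scores for one selection test
#'
#' Collapses a per-SNP score track to fixed windows. The window statistic
#' follows the test: for `"ihs"` the fraction of scored SNPs with
#' `|score| > threshold` (extreme-score proportion); for `"xpehh"`, `"fst"`
#' and `"pbs"` the window maximum of the per-SNP score (the frequency tests
#' emphasize maximum SNP values). Rows with `NA` scores (and rows where a
#' `valid` column is `FALSE`) are excluded before windowing; the SNP
#' attaining the window maximum (or the largest `|score|` for iHS) is
#' reported per window.
#'
#' @param snp_stats Data.frame with at least `chrom`, `pos`, `snp_id` and
#'   the score column.
#' @param test One of `"ihs"`, `"xpehh"`, `"fst"`, `"pbs"`.
#' @param score_col Score column name; defaults to `ihs_std`, `xpehh_std`,
#'   `fst`, `pbs` respectively.
#' @param width Window width in bp; defaults to 200 kb for the haplotype
#'   tests and 100 kb for the frequency tests.
#' @param threshold Extreme-score threshold for the iHS window statistic
#'   (default 2).
#' @return Data.frame of class `window_stat`: `chrom`, `start`, `end`,
#'   `snp_count`, `score`, `max_snp_id`, `max_snp_pos`, `max_snp_score`,
#'   with attributes `test` and `width`.
#' @export
window_stats <- function(snp_stats, test = c("ihs", "xpehh", "fst", "pbs"),
                         score_col = NULL, width = NULL, threshold = 2) {
  test <- match.arg(test)
  if (is.null(score_col)) {
    score_col <- c(ihs = "ihs_std", xpehh = "xpehh_std", fst = "fst",
                   pbs = "pbs")[[test]]
  }
  if (is.null(width)) width <- if (test %in% c("ihs", "xpehh")) 2e5 else 1e5
  keep <- !is.na(snp_stats[[score_col]])
  if (!is.null(snp_stats$valid)) keep <- keep & snp_stats$valid
  d <- snp_stats[keep, , drop = FALSE]
  if (!nrow(d)) stop("no scored SNPs to window")
  score <- d[[score_col]]
  win <- make_windows(d$chrom, d$pos, width)
  wkey <- paste(win$chrom, win$start, sep = "\r")
  skey <- paste(d$chrom, floor((d$pos - 1) / width) * width, sep = "\r")
  gi <- match(skey, wkey)
  n <- nrow(win)
  wscore <- numeric(n)
  max_id <- character(n); max_pos <- numeric(n); max_score <- numeric(n)
  crit <- if (test == "ihs") abs(score) else score
  for (g in seq_len(n)) {
    sel <- which(gi == g)
    imax <- sel[which.max(crit[sel])]
    max_id[g] <- d$snp_id[imax]
    max_pos[g] <- d$pos[imax]
    max_score[g] <- score[imax]
    wscore[g] <- if (test == "ihs") mean(abs(score[sel]) > threshold) else
      max(score[sel])
  }
  out <- cbind(win, data.frame(score = wscore, max_snp_id = max_id,
                               max_snp_pos = max_pos,
                               max_snp_score = max_score,
                               stringsAsFactors = FALSE))
  attr(out, "test") <- test
  attr(out, "width") <- width
  class(out) <- c("window_stat", "data.frame")
  out
}

# Deterministic ranking order within one bin: higher window score first,
# ties broken by higher max-SNP score, then lower chrom/start.
rank_order <- function(d) {
  order(-d$score, -abs(d$max_snp_score), d$chrom, d$start)
}

#' Bin windows by SNP count and rank within bins
#'
#' SNP-count binning compensates for the unequal SNP distribution of array
#' data: windows are grouped by their scored-SNP count, merging adjacent
#' counts upward until every bin holds at least `bin_floor` windows (a
#' trailing short bin is merged into its predecessor). Empirical ranks and
#' percentiles are then computed among windows of the same bin only. With
#' `scheme = "single"` all windows form one bin (global ranking; the default
#' for the max-SNP frequency tests).
#'
#' @param ws A `window_stat` data.frame from [window_stats()].
#' @param bin_floor Minimum windows per bin (default 50).
#' @param scheme `"snp_count"` or `"single"`.
#' @return `ws` with added columns `bin`, `rank` (1 = most extreme within
#'   bin) and `percentile` (`rank / bin size`, in `(0, 1]`).
#' @export
bin_by_snp_count <- function(ws, bin_floor = 50, scheme = c("snp_count",
                                                            "single")) {
  scheme <- match.arg(scheme)
  n <- nrow(ws)
  if (scheme == "single") {
    ws$bin <- 1L
  } else if (n < bin_floor) {
    warning("fewer than ", bin_floor, " windows in total; using a single bin")
    ws$bin <- 1L
  } else {
    counts <- sort(unique(ws$snp_count))
    sizes <- table(factor(ws$snp_count, levels = counts))
    bin_of_count <- integer(length(counts))
    bin <- 1L; acc <- 0L
    for (i in seq_along(counts)) {
      bin_of_count[i] <- bin
      acc <- acc + sizes[[i]]
      if (acc >= bin_floor && i < length(counts)) { bin <- bin + 1L; acc <- 0L }
    }
    if (acc < bin_floor && bin > 1L) {   # trailing short bin: merge back
      bin_of_count[bin_of_count == bin] <- bin - 1L
    }
    ws$bin <- bin_of_count[match(ws$snp_count, counts)]
  }
  ws$rank <- NA_integer_
  ws$percentile <- NA_real_
  for (g in unique(ws$bin)) {
    sel <- which(ws$bin == g)
    ord <- sel[rank_order(ws[sel, , drop = FALSE])]
    ws$rank[ord] <- seq_along(ord)
    ws$percentile[ord] <- seq_along(ord) / length(ord)
  }
  ws
}

#' Flag empirical outlier windows
#'
#' Within each bin, the windows whose rank falls in the top
#' `ceiling(percentile * bin size)` are flagged, for each requested
#' percentile. Score ties at the cut are resolved by the deterministic
#' ranking rule (higher max-SNP score, then lower chrom/start), so the
#' flagged count is ceiling-exact per bin.
#'
#' @param ws Output of [bin_by_snp_count()].
#' @param top1,top5 Flagged percentiles (defaults 0.01 and 0.05).
#' @return `ws` with logical columns `top1` and `top5` (`top1` implies
#'   `top5` whenever `top1 <= top5`).
#' @export
call_outliers <- function(ws, top1 = 0.01, top5 = 0.05) {
  stopifnot(!is.null(ws$rank))
  ws$top1 <- FALSE
  ws$top5 <- FALSE
  for (g in unique(ws$bin)) {
    sel <- ws$bin == g
    nb <- sum(sel)
    ws$top1[sel] <- ws$rank[sel] <= ceiling(top1 * nb)
    ws$top5[sel] <- ws$rank[sel] <= ceiling(top5 * nb)
  }
  ws
}

#' Cross-population exclusion of shared haplotype signals
#'
#' Retains the focal population's top-1% windows only if they are not among
#' the control population's top-5% windows of the same scan -- shared
#' extreme windows are more parsimoniously explained by shared demography
#' than by selection in the focal population. Both scans must use the same
#' window tiling (equal width, 0-anchored).
#'
#' @param focal Outlier-called `window_stat` for the focal population.
#' @param control Outlier-called `window_stat` for the control population.
#' @param focal_flag,control_flag Flag columns to use (defaults `top1` in
#'   focal, `top5` in control).
#' @return The retained focal windows (rows of `focal` flagged
#'   `focal_flag` and absent from the control `control_flag` set), with the
#'   removal count in attribute `n_removed` and reported via a message.
#' @export
exclusion_filter <- function(focal, control, focal_flag = "top1",
                             control_flag = "top5") {
  wf <- attr(focal, "width"); wc <- attr(control, "width")
  if (!is.null(wf) && !is.null(wc) && wf != wc) {
    stop("mismatched window tiling: widths ", wf, " vs ", wc)
  }
  f <- focal[focal[[focal_flag]], , drop = FALSE]
  veto <- control[control[[control_flag]], , drop = FALSE]
  fkey <- paste(f$chrom, f$start)
  vkey <- paste(veto$chrom, veto$start)
  drop <- fkey %in% vkey
  message("exclusion_filter: removed ", sum(drop), " of ", nrow(f),
          " focal windows present in the control outlier set")
  out <- f[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  attr(out, "test") <- attr(focal, "test")
  attr(out, "width") <- wf
  out
}

#' Genes by number of supporting selection tests
#'
#' @param gene_sets Named list: test name -> character vector of gene names
#'   highlighted by that test.
#' @return Data.frame `gene`, `tests` (comma-separated), `n_tests`, sorted
#'   by decreasing support then gene name.
#' @export
cross_test_overlap <- function(gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  genes <- sort(unique(unlist(gene_sets)))
  if (!length(genes)) {
    return(data.frame(gene = character(0), tests = character(0),
                      n_tests = integer(0), stringsAsFactors = FALSE))
  }
  hit <- vapply(gene_sets, function(s) genes %in% s,
                logical(length(genes)))
  hit <- matrix(hit, nrow = length(genes),
                dimnames = list(genes, names(gene_sets)))
  tests <- apply(hit, 1L, function(z) paste(colnames(hit)[z], collapse = ","))
  out <- data.frame(gene = genes, tests = tests,
                    n_tests = rowSums(hit), stringsAsFactors = FALSE)
  out <- out[order(-out$n_tests, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Count windows above an F_ST cut-off
#'
#' @param ws A `window_stat` data.frame for the F_ST scan.
#' @param cutoff Cut-off on the window (max-SNP) score; strict inequality.
#' @return Number of windows with `score > cutoff`.
#' @export
fst_cutoff_count <- function(ws, cutoff = 0.6) {
  sum(ws$score > cutoff)
}

#' Branch-length comparison between two focal scans
#'
#' For two PBS scans sharing the same sister/outgroup scheme and window
#' tiling: among windows flagged top-1% in both, the share whose focal-1
#' branch length strictly exceeds the focal-2 branch length.
#'
#' @param ws1,ws2 Outlier-called `window_stat` data.frames.
#' @param flag Flag column defining the overlap (default `"top1"`).
#' @return List with `n_overlap` and `share` (`NA` when the overlap is
#'   empty).
#' @export
branch_length_comparison <- function(ws1, ws2, flag = "top1") {
  w1 <- attr(ws1, "width"); w2 <- attr(ws2, "width")
  if (!is.null(w1) && !is.null(w2) && w1 != w2) {
    stop("mismatched window tiling: widths ", w1, " vs ", w2)
  }
  a <- ws1[ws1[[flag]], , drop = FALSE]
  b <- ws2[ws2[[flag]], , drop = FALSE]
  key_a <- paste(a$chrom, a$start)
  key_b <- paste(b$chrom, b$start)
  common <- intersect(key_a, key_b)
  if (!length(common)) return(list(n_overlap = 0L, share = NA_real_))
  s1 <- a$score[match(common, key_a)]
  s2 <- b$score[match(common, key_b)]
  list(n_overlap = length(common), share = mean(s1 > s2))
}
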