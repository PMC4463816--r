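# Gene-level reporting and enrichment: gene <-> window assignment,
# candidate-list intersection with its expected-by-chance calibration
# (hypergeometric), and GO-term enrichment via the EASE score -- the
# conservative variant of Fisher's exact one-sided p-value that removes one
# gene from the observed overlap before computing the tail.

#' Assign genes to flagged windows
#'
#' A gene is assigned to a window when their intervals overlap by at least
#' one bp (gene intervals are BED 0-based half-open; windows are 0-based
#' half-open). Each assigned gene inherits the rank of its best (lowest
#' rank) flagged window. Per gene the maximum per-SNP statistic among SNPs
#' inside the gene body is also reported; genes containing no scored SNP
#' are flagged and annotated with the distance to the nearest scored SNP.
#' An optional flank widens the window interval for nearest-gene annotation
#' (off by default so enrichment counts stay overlap-based).
#'
#' @param ws An outlier-called `window_stat` data.frame.
#' @param genes A [gene_annotation()].
#' @param snp_stats Optional per-SNP table (`chrom`, `pos`, score column)
#'   used for the within-gene maximum; the score column is taken from the
#'   window test (`attr(ws, "test")`) unless `score_col` is given.
#' @param score_col Per-SNP score column name in `snp_stats`.
#' @param flag Window flag column defining "highlighted" (default `top1`).
#' @param flank Bp added to each window side when matching genes
#'   (default 0).
#' @return Data.frame of class `gene_hit`: `gene`, `chrom`, `n_windows`,
#'   `best_rank`, `best_window_start`, `window_score`, `gene_max`,
#'   `n_snps_in_gene`, `nearest_snp_bp` (0 when the gene contains a SNP).
#' @export
assign_genes <- function(ws, genes, snp_stats = NULL, score_col = NULL,
                         flag = "top1", flank = 0) {
  fw <- if (flag %in% names(ws)) ws[ws[[flag]], , drop = FALSE] else ws
  if (!nrow(fw)) {
    return(structure(data.frame(gene = character(0)), class = c("gene_hit",
                                                                "data.frame")))
  }
  if (!is.null(snp_stats) && is.null(score_col)) {
    test <- attr(ws, "test")
    score_col <- switch(test, ihs = "ihs_std", xpehh = "xpehh_std",
                        fst = "fst", pbs = "pbs", "score")
  }
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    hit <- fw$chrom == genes$chrom[g] &
      fw$start - flank < genes$end[g] &
      fw$end + flank > genes$start[g]
    if (!any(hit)) next
    sub <- fw[hit, , drop = FALSE]
    best <- which.min(sub$rank)
    row <- data.frame(gene = genes$gene[g], chrom = genes$chrom[g],
                      n_windows = nrow(sub), best_rank = sub$rank[best],
                      best_window_start = sub$start[best],
                      window_score = sub$score[best],
                      gene_max = NA_real_, n_snps_in_gene = NA_integer_,
                      nearest_snp_bp = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(snp_stats)) {
      ok <- !is.na(snp_stats[[score_col]])
      if (!is.null(snp_stats$valid)) ok <- ok & snp_stats$valid
      s <- snp_stats[ok & snp_stats$chrom == genes$chrom[g], , drop = FALSE]
      inside <- s$pos > genes$start[g] & s$pos <= genes$end[g]
      row$n_snps_in_gene <- sum(inside)
      if (any(inside)) {
        row$gene_max <- max(s[[score_col]][inside])
        row$nearest_snp_bp <- 0
      } else if (nrow(s)) {
        row$nearest_snp_bp <- min(pmax(genes$start[g] + 1 - s$pos,
                                       s$pos - genes$end[g], 0))
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0))
  if (nrow(out)) {
    out <- out[order(out$best_rank, out$gene), ]
    rownames(out) <- NULL
  }
  class(out) <- c("gene_hit", "data.frame")
  out
}

# Hypergeometric upper tail P(X >= k) with population N, K annotated,
# n drawn.
hyper_tail <- function(k, n, K, N) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score (conservative Fisher enrichment p-value)
#'
#' One-sided Fisher exact upper-tail p-value with the observed overlap
#' penalized by one gene: `P(X >= max(k - 1, 0))` for
#' `X ~ Hypergeometric(N, K, n)`, with the selected-list margin unchanged.
#' A single-gene overlap (`k = 1`) therefore never enriches (`p = 1`), which
#' makes the score robust against categories carried by one gene.
#'
#' @param k Observed overlap (selected genes annotated to the term).
#' @param n Selected-list size (genes in top windows, within the universe).
#' @param K Annotated genes in the universe.
#' @param N Universe size.
#' @return The EASE p-value.
#' @export
ease_score <- function(k, n, K, N) {
  stopifnot(length(k) == 1, k >= 0, n >= 0, K >= 0, N >= 1)
  if (k > min(n, K)) stop("overlap k exceeds min(n, K)")
  if (n > N || K > N) stop("margins exceed universe size")
  hyper_tail(max(k - 1, 0), n, K, N)
}

#' Candidate-list overlap with expected-by-chance calibration
#'
#' Intersects the genes of the top-ranked windows with an a-priori candidate
#' list inside a gene universe (all genes overlapping any scanned window).
#' Reports the observed overlap `k`, the chance expectation `n * K / N`, the
#' enrichment ratio, and the hypergeometric upper-tail significance
#' `P(X >= k)`. Candidate genes absent from the universe are counted out of
#' the intersection and reported via a message.
#'
#' @param hit_genes Character vector of genes in top windows (e.g.
#'   `assign_genes(...)$gene`).
#' @param candidates Character vector of candidate gene names.
#' @param universe Character vector of all genes in the scan universe.
#' @param name Label for the result row.
#' @return One-row data.frame: `name`, `N`, `K` (candidates in universe),
#'   `n` (hit genes in universe), `k`, `expected`, `ratio`, `p_hyper`.
#' @export
candidate_overlap <- function(hit_genes, candidates, universe,
                              name = "candidate_list") {
  universe <- unique(toupper(universe))
  candidates <- unique(toupper(candidates))
  hit_genes <- unique(toupper(hit_genes))
  absent <- setdiff(candidates, universe)
  if (length(absent)) {
    message("candidate_overlap: ", length(absent),
            " candidate gene(s) absent from the scan universe")
  }
  N <- length(universe)
  K <- length(intersect(candidates, universe))
  n <- length(intersect(hit_genes, universe))
  k <- length(intersect(intersect(hit_genes, candidates), universe))
  expected <- n * K / N
  data.frame(name = name, N = N, K = K, n = n, k = k, expected = expected,
             ratio = if (expected > 0) k / expected else NA_real_,
             p_hyper = hyper_tail(k, n, K, N), stringsAsFactors = FALSE)
}

#' GO-term enrichment of selected genes via the EASE score
#'
#' For every term annotating at least one selected gene, reports the
#' `k/K` enrichment (selected/annotated within the universe), the
#' enrichment ratio, the EASE p-value, and a Benjamini-Hochberg column
#' (computed across all tested terms, emitted for information only). Terms
#' are filtered at `ease_max` and sorted by p-value; `keep_all = TRUE`
#' returns every tested term.
#'
#' @param selected Character vector of selected gene names.
#' @param gene2term Data.frame `gene`, `term_id`, `term_name` (one pair per
#'   row), e.g. from [read_gene2term()].
#' @param universe Character vector of all genes in the scan universe.
#' @param ease_max Report threshold on the EASE score (default 0.01).
#' @param keep_all Return all tested terms regardless of `ease_max`?
#' @return Data.frame `term_id`, `term_name`, `k`, `K`, `enrichment`
#'   (`"k/K"`), `ratio`, `ease`, `bh`, sorted by `ease`.
#' @export
go_enrichment <- function(selected, gene2term, universe, ease_max = 0.01,
                          keep_all = FALSE) {
  if (!nrow(gene2term)) stop("empty gene-to-term mapping")
  universe <- unique(toupper(universe))
  selected <- intersect(unique(toupper(selected)), universe)
  map <- gene2term[toupper(gene2term$gene) %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(selected)
  terms <- unique(map[, c("term_id", "term_name")])
  rows <- list()
  for (i in seq_len(nrow(terms))) {
    ann <- unique(toupper(map$gene[map$term_id == terms$term_id[i]]))
    K <- length(ann)
    k <- length(intersect(ann, selected))
    if (k == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = terms$term_id[i], term_name = terms$term_name[i],
      k = k, K = K, enrichment = paste0(k, "/", K),
      ratio = (k / n) / (K / N), ease = ease_score(k, n, K, N),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0),
                      enrichment = character(0), ratio = numeric(0),
                      ease = numeric(0), bh = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$bh <- stats::p.adjust(out$ease, method = "BH")
  out <- out[order(out$ease, out$term_id), ]
  rownames(out) <- NULL
  if (!keep_all) out <- out[out$ease < ease_max, , drop = FALSE]
  out
}
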