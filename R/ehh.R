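# Haplotype-homozygosity statistics: EHH decay curves, integrated EHH
# (iHH), the integrated haplotype score (iHS) with derived-frequency-bin
# standardization, and cross-population EHH (XP-EHH) with genome-wide
# normalization. Distances are physical bp (no genetic map is assumed for
# array data); the compute kernel is compiled (ehh_walk_cpp).

# First/last variant index of each variant's chromosome (variants sorted).
chrom_bounds <- function(variants) {
  r <- rle(variants$chrom)
  hi <- cumsum(r$lengths)
  lo <- c(1L, utils::head(hi, -1L) + 1L)
  idx <- rep(seq_along(r$lengths), r$lengths)
  list(lo = lo[idx], hi = hi[idx])
}

# Value (0/1) of the derived allele per variant; NA when unpolarized.
derived_value <- function(variants) {
  ifelse(variants$ancestral == "unknown", NA_integer_,
         ifelse(variants$ancestral == variants$ref, 1L, 0L))
}

#' EHH decay curve at a core SNP
#'
#' Extended haplotype homozygosity among the carriers of a core allele:
#' at marker `x`, the probability that two randomly chosen carrier
#' haplotypes are identical over every SNP from the core out to `x`
#' (`sum C(c_j, 2) / C(n, 2)` over distinct extended haplotypes). The curve
#' starts at 1 at distance 0 and is evaluated at each successive SNP outward
#' until it falls below `cutoff`, the chromosome ends, or an inter-SNP gap
#' exceeds `gap_max`.
#'
#' @param haps A [hap_matrix()] (or plain 0/1 matrix).
#' @param variants The matching [variant_table()].
#' @param core Core SNP column index.
#' @param allele Core allele defining the carrier set: `0`, `1`,
#'   `"ancestral"`, `"derived"` (requires polarization) or `"pooled"` (all
#'   haplotypes regardless of core allele).
#' @param rows Optional haplotype row subset (e.g. one population); default
#'   all rows.
#' @param direction `"left"`, `"right"` or `"both"`.
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param gap_max Maximum tolerated inter-SNP gap in bp (default 200 kb).
#' @return A data.frame with columns `direction`, `snp` (column index),
#'   `pos`, `distance` (bp from core) and `ehh`, including the
#'   distance-zero point for each direction. Attributes `reason_left` /
#'   `reason_right` record why each walk stopped (`"cutoff"`,
#'   `"chrom_end"`, `"gap"`).
#' @export
ehh <- function(haps, variants, core, allele = "derived", rows = NULL,
                direction = c("both", "left", "right"), cutoff = 0.05,
                gap_max = 2e5) {
  direction <- match.arg(direction)
  if (is.null(rows)) rows <- seq_len(nrow(haps))
  carriers <- carrier_rows(haps, variants, core, allele, rows)
  if (length(carriers) < 2L) {
    stop("fewer than 2 carrier haplotypes at core SNP ", core)
  }
  b <- chrom_bounds(variants)
  sides <- if (direction == "both") c("left", "right") else direction
  out <- list()
  reasons <- c(cutoff = "cutoff", chrom_end = "chrom_end", gap = "gap")
  for (side in sides) {
    step <- if (side == "left") -1L else 1L
    w <- ehh_walk_cpp(unclass(haps), carriers - 1L, core - 1L, step,
                      b$lo[core] - 1L, b$hi[core] - 1L, variants$pos,
                      cutoff, gap_max)
    snp <- c(core, w$col + 1L)
    d <- data.frame(direction = side, snp = snp, pos = variants$pos[snp],
                    distance = abs(variants$pos[snp] - variants$pos[core]),
                    ehh = c(1, w$ehh), stringsAsFactors = FALSE)
    attr_name <- paste0("reason_", side)
    out[[side]] <- d
    attr(out, attr_name) <- c("cutoff", "chrom_end", "gap")[w$reason + 1L]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  for (side in sides) {
    attr(res, paste0("reason_", side)) <- attr(out, paste0("reason_", side))
  }
  res
}

# Carrier rows for a core allele within a row subset.
carrier_rows <- function(haps, variants, core, allele, rows) {
  if (identical(allele, "pooled")) return(rows)
  val <- if (identical(allele, "derived")) {
    dv <- derived_value(variants)[core]
    if (is.na(dv)) stop("core SNP ", core, " is not polarized")
    dv
  } else if (identical(allele, "ancestral")) {
    dv <- derived_value(variants)[core]
    if (is.na(dv)) stop("core SNP ", core, " is not polarized")
    1L - dv
  } else {
    as.integer(allele)
  }
  rows[haps[rows, core] == val]
}

#' Integrated EHH (area under the decay curve)
#'
#' Trapezoidal integral of an EHH curve against physical distance. When
#' `truncate` is `TRUE` (the iHS convention) integration stops at the first
#' point with EHH below `cutoff`, linearly interpolating the crossing so the
#' curve is integrated exactly down to `EHH = cutoff`; when `FALSE` the full
#' curve is integrated (the XP-EHH shared-boundary convention).
#'
#' @param distance Increasing distances in bp; a leading `(0, 1)` point is
#'   added if absent.
#' @param e EHH values matching `distance`.
#' @param cutoff Truncation threshold.
#' @param truncate Interpolate and stop at the cutoff crossing?
#' @return Area in bp x EHH units (>= 0).
#' @export
ihh_area <- function(distance, e, cutoff = 0.05, truncate = TRUE) {
  if (!length(distance) || distance[1] != 0) {
    distance <- c(0, distance)
    e <- c(1, e)
  }
  if (any(diff(distance) < 0)) stop("distances must be non-decreasing")
  below <- which(e < cutoff)
  if (truncate && length(below)) {
    k <- below[1]
    if (k == 1L) return(0)
    d0 <- distance[k - 1L]; d1 <- distance[k]
    e0 <- e[k - 1L]; e1 <- e[k]
    dstar <- d0 + (e0 - cutoff) / (e0 - e1) * (d1 - d0)
    distance <- c(distance[seq_len(k - 1L)], dstar)
    e <- c(e[seq_len(k - 1L)], cutoff)
  }
  if (length(distance) < 2L) return(0)
  sum(diff(distance) * (utils::head(e, -1L) + utils::tail(e, -1L)) / 2)
}

# Two-sided iHH for one carrier set: walks left and right, integrates both
# sides. Returns area plus the gap/edge status of the pair of walks.
ihh_two_sided <- function(haps, rows, core, pos, lo, hi, cutoff, gap_max) {
  area <- 0
  gap <- FALSE
  edge <- FALSE
  for (step in c(-1L, 1L)) {
    w <- ehh_walk_cpp(haps, rows - 1L, core - 1L, step, lo - 1L, hi - 1L,
                      pos, cutoff, gap_max)
    if (w$reason == 2L) gap <- TRUE
    if (w$reason == 1L) edge <- TRUE
    d <- abs(pos[w$col + 1L] - pos[core])
    area <- area + ihh_area(d, w$ehh, cutoff, truncate = TRUE)
  }
  list(area = area, gap = gap, edge = edge)
}

# Merge small frequency bins with their nearest (by centre) neighbour until
# every remaining bin holds at least bin_min scores.
merge_bins <- function(bin, centres, bin_min) {
  map <- seq_along(centres)        # bin id -> merged group id
  repeat {
    grp <- map[bin]
    tab <- table(factor(grp, levels = unique(map)))
    tab <- tab[tab > 0]
    if (length(tab) <= 1L) break
    small <- names(tab)[tab < bin_min]
    if (!length(small)) break
    gid <- as.integer(small[which.min(tab[small])])
    # centre of a merged group = mean centre of its member bins
    gcentre <- function(g) mean(centres[map == g])
    others <- setdiff(unique(map[map %in% grp]), gid)
    near <- others[which.min(abs(vapply(others, gcentre, 0) - gcentre(gid)))]
    map[map == gid] <- near
  }
  map[bin]
}

#' iHS scan of one population
#'
#' For every polarized core SNP with derived-allele frequency inside
#' `freq_range`, computes the two-sided integrated EHH among ancestral-
#' and derived-allele carriers, the unstandardized score
#' `ln(iHH_ancestral / iHH_derived)`, and the standardized iHS obtained by
#' centring and scaling within derived-allele-frequency bins of width
#' `bin_width` (bins holding fewer than `bin_min` scores are merged with
#' their nearest bin). Cores whose walks cross a gap larger than `gap_max`
#' or collapse to zero area are flagged invalid and excluded from
#' standardization; cores whose walks reach a chromosome end are kept but
#' flagged `edge`.
#'
#' @param haps A [hap_matrix()].
#' @param variants The matching [variant_table()] (ancestral alleles set for
#'   scored SNPs).
#' @param panel A [population_panel()].
#' @param population Population label to scan.
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param gap_max Maximum tolerated inter-SNP gap in bp (default 200 kb).
#' @param freq_range Scored derived-frequency interval (default
#'   `c(0.05, 0.95)`).
#' @param bin_width Derived-frequency bin width for standardization
#'   (default 0.02).
#' @param bin_min Minimum scores per bin before merging (default 20).
#' @return A data.frame (one row per SNP) with columns `chrom`, `pos`,
#'   `snp_id`, `freq_derived`, `ihh_a`, `ihh_d`, `ihs_unstd`, `ihs_std`,
#'   `bin`, `valid`, `reason`, `edge`.
#' @export
ihs_scan <- function(haps, variants, panel, population, cutoff = 0.05,
                     gap_max = 2e5, freq_range = c(0.05, 0.95),
                     bin_width = 0.02, bin_min = 20) {
  rows <- hap_rows(haps, panel, population)
  m <- ncol(haps)
  dv <- derived_value(variants)
  x <- unclass(haps)
  cnt1 <- colSums(x[rows, , drop = FALSE])
  n_hap <- length(rows)
  p_der <- ifelse(is.na(dv), NA_real_,
                  ifelse(dv == 1L, cnt1, n_hap - cnt1) / n_hap)
  b <- chrom_bounds(variants)

  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    snp_id = variants$snp_id, freq_derived = p_der,
                    ihh_a = NA_real_, ihh_d = NA_real_,
                    ihs_unstd = NA_real_, ihs_std = NA_real_,
                    bin = NA_integer_, valid = FALSE,
                    reason = NA_character_, edge = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    if (is.na(p_der[j])) { out$reason[j] <- "unpolarized"; next }
    if (p_der[j] < freq_range[1] || p_der[j] > freq_range[2]) {
      out$reason[j] <- "frequency"; next
    }
    der <- rows[x[rows, j] == dv[j]]
    anc <- rows[x[rows, j] != dv[j]]
    if (length(der) < 2L || length(anc) < 2L) {
      out$reason[j] <- "carriers"; next
    }
    id <- ihh_two_sided(x, der, j, variants$pos, b$lo[j], b$hi[j],
                        cutoff, gap_max)
    ia <- ihh_two_sided(x, anc, j, variants$pos, b$lo[j], b$hi[j],
                        cutoff, gap_max)
    out$ihh_a[j] <- ia$area; out$ihh_d[j] <- id$area
    if (id$gap || ia$gap) { out$reason[j] <- "gap"; next }
    if (id$area == 0 || ia$area == 0) { out$reason[j] <- "zero_area"; next }
    out$ihs_unstd[j] <- log(ia$area / id$area)
    out$valid[j] <- TRUE
    out$edge[j] <- id$edge || ia$edge
  }
  if (!any(out$valid)) {
    warning("ihs_scan: no valid core SNPs in population ", population)
    return(out)
  }
  # frequency-bin standardization
  edges <- seq(freq_range[1], freq_range[2], by = bin_width)
  if (edges[length(edges)] < freq_range[2]) edges <- c(edges, freq_range[2])
  centres <- (utils::head(edges, -1L) + utils::tail(edges, -1L)) / 2
  v <- which(out$valid)
  raw_bin <- pmin(findInterval(out$freq_derived[v], edges,
                               rightmost.closed = TRUE), length(centres))
  out$bin[v] <- merge_bins(raw_bin, centres, bin_min)
  for (g in unique(out$bin[v])) {
    sel <- v[out$bin[v] == g]
    mu <- mean(out$ihs_unstd[sel])
    sd <- stats::sd(out$ihs_unstd[sel])
    out$ihs_std[sel] <- if (is.na(sd) || sd == 0) NA_real_ else
      (out$ihs_unstd[sel] - mu) / sd
  }
  out
}

#' XP-EHH scan between two populations
#'
#' For every core SNP, the pooled EHH (all haplotypes, both core alleles) of
#' the two populations combined defines a shared integration boundary per
#' side: the outermost marker at which the combined pooled EHH is still at
#' least `cutoff`. Each population's own pooled EHH curve is then
#' integrated out to that same boundary, and the unstandardized score is
#' `ln(iHH_A / iHH_B)`; positive values indicate longer haplotype
#' homozygosity in `pop_a`. Scores are standardized genome-wide to mean 0,
#' SD 1 across valid cores. Cores whose combined walk crosses a gap larger
#' than `gap_max` are invalid; walks reaching a chromosome end are flagged
#' `edge`.
#'
#' @inheritParams ihs_scan
#' @param pop_a,pop_b Population labels (each needs >= 2 haplotypes).
#' @return A data.frame with columns `chrom`, `pos`, `snp_id`, `ihh_a`,
#'   `ihh_b`, `xpehh_unstd`, `xpehh_std`, `valid`, `reason`, `edge`.
#' @export
xpehh_scan <- function(haps, variants, panel, pop_a, pop_b, cutoff = 0.05,
                       gap_max = 2e5) {
  rows_a <- hap_rows(haps, panel, pop_a)
  rows_b <- hap_rows(haps, panel, pop_b)
  if (length(rows_a) < 2L || length(rows_b) < 2L) {
    stop("both populations need at least 2 haplotypes")
  }
  rows_ab <- c(rows_a, rows_b)
  x <- unclass(haps)
  b <- chrom_bounds(variants)
  m <- ncol(haps)
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    snp_id = variants$snp_id, ihh_a = NA_real_,
                    ihh_b = NA_real_, xpehh_unstd = NA_real_,
                    xpehh_std = NA_real_, valid = FALSE,
                    reason = NA_character_, edge = FALSE,
                    stringsAsFactors = FALSE)
  pos <- variants$pos
  for (j in seq_len(m)) {
    area_a <- 0; area_b <- 0
    gap <- FALSE; edge <- FALSE; any_marker <- FALSE
    for (step in c(-1L, 1L)) {
      w <- ehh_walk_cpp(x, rows_ab - 1L, j - 1L, step, b$lo[j] - 1L,
                        b$hi[j] - 1L, pos, cutoff, gap_max)
      if (w$reason == 2L) gap <- TRUE
      if (w$reason == 1L) edge <- TRUE
      keep <- which(w$ehh >= cutoff)
      if (!length(keep)) next
      bound <- w$col[keep[length(keep)]] + 1L   # outermost marker >= cutoff
      any_marker <- TRUE
      blo <- if (step == -1L) bound else j
      bhi <- if (step == -1L) j else bound
      wa <- ehh_walk_cpp(x, rows_a - 1L, j - 1L, step, blo - 1L, bhi - 1L,
                         pos, -1, Inf)
      wb <- ehh_walk_cpp(x, rows_b - 1L, j - 1L, step, blo - 1L, bhi - 1L,
                         pos, -1, Inf)
      da <- abs(pos[wa$col + 1L] - pos[j])
      db <- abs(pos[wb$col + 1L] - pos[j])
      area_a <- area_a + ihh_area(da, wa$ehh, cutoff, truncate = FALSE)
      area_b <- area_b + ihh_area(db, wb$ehh, cutoff, truncate = FALSE)
    }
    out$ihh_a[j] <- area_a; out$ihh_b[j] <- area_b
    if (gap) { out$reason[j] <- "gap"; next }
    if (!any_marker || area_a == 0 || area_b == 0) {
      out$reason[j] <- "zero_area"; next
    }
    out$xpehh_unstd[j] <- log(area_a / area_b)
    out$valid[j] <- TRUE
    out$edge[j] <- edge
  }
  v <- out$valid
  if (!any(v)) {
    warning("xpehh_scan: no valid core SNPs")
    return(out)
  }
  mu <- mean(out$xpehh_unstd[v])
  sd <- stats::sd(out$xpehh_unstd[v])
  out$xpehh_std[v] <- if (is.na(sd) || sd == 0) NA_real_ else
    (out$xpehh_unstd[v] - mu) / sd
  out
}
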