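# Readers and writers for the formats the pipeline touches: phased VCF,
# panel TSV, BED4 gene annotations, candidate-gene lists, gene->term maps,
# a plain haplotype-matrix text format for fixtures, and the scan outputs.
# Coordinates: VCF positions are 1-based; BED intervals 0-based half-open;
# all internal window arithmetic is 0-based half-open.

#' Read phased genotypes from a VCF
#'
#' Parses a VCF with phased GT calls (pipe separator) into a
#' [variant_table()] and a [hap_matrix()]. Only biallelic SNP records with
#' fully phased, non-missing genotypes are representable; offending records
#' are an error in strict mode and are dropped (with a reported count) in
#' lenient mode. The ancestral allele is taken from the `AA` INFO tag when
#' present, else `"unknown"`.
#'
#' @param path Path to a VCF file (plain text or gzip).
#' @param panel Optional [population_panel()]; when given, all panel samples
#'   must be present in the VCF and haplotype rows follow panel sample order.
#'   When `NULL`, VCF sample order is used.
#' @param strict If `TRUE` (default) any unphased, missing or multiallelic
#'   record is a descriptive error naming the record; if `FALSE` such records
#'   are dropped and the drop count is reported via a message and the
#'   `"n_dropped"` attribute.
#' @return A list with elements `variants` ([variant_table()]) and `haps`
#'   ([hap_matrix()]).
#' @export
read_phased_vcf <- function(path, panel = NULL, strict = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF contains no genotype columns")
  samples <- colnames(gt)[-1L]
  if (is.null(panel)) {
    panel <- population_panel(samples, rep("POP1", length(samples)))
  }
  idx <- match(panel$sample_id, samples)
  if (anyNA(idx)) {
    stop("panel samples missing from VCF: ",
         paste(panel$sample_id[is.na(idx)], collapse = ", "))
  }
  chrom <- fix$CHROM
  pos <- as.numeric(fix$POS)
  label <- paste0(chrom, ":", pos)

  # GT is the leading field per VCF spec when present
  gtm <- sub(":.*$", "", gt[, idx + 1L, drop = FALSE])
  phased_ok <- rowSums(!matrix(grepl("^[0-9]+\\|[0-9]+$", gtm),
                               nrow = nrow(gtm))) == 0L
  biallelic <- !grepl(",", fix$ALT) & fix$ALT != "." &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  in_range <- phased_ok &
    rowSums(matrix(grepl("^[01]\\|[01]$", gtm), nrow = nrow(gtm))) == ncol(gtm)
  ok <- biallelic & phased_ok & in_range
  if (!all(ok)) {
    first <- which(!ok)[1]
    what <- if (!biallelic[first]) {
      "multiallelic or non-SNP record"
    } else if (!phased_ok[first]) {
      "unphased or missing genotype"
    } else {
      "allele index out of biallelic range"
    }
    if (strict) stop(what, " at ", label[first])
    message("read_phased_vcf: dropped ", sum(!ok),
            " record(s) not representable as phased biallelic SNPs")
  }
  keep <- which(ok)
  if (!length(keep)) stop("no usable phased biallelic SNP records in ", path)

  # positions must be sorted in file order (strictly increasing per chrom)
  pk <- pos[keep]; ck <- chrom[keep]
  same <- ck[-1L] == ck[-length(ck)]
  if (any(same & diff(pk) <= 0)) {
    bad <- which(same & diff(pk) <= 0)[1] + 1L
    stop("non-monotone positions within chromosome at ", label[keep][bad])
  }

  aa <- rep("unknown", length(keep))
  info <- fix$INFO[keep]
  info[is.na(info)] <- "."
  has <- grepl("(?:^|;)AA=", info, perl = TRUE)
  if (any(has)) {
    aa[has] <- sub("^;?AA=", "",
                   regmatches(info, regexpr("(?:^|;)AA=[^;]+", info,
                                            perl = TRUE)))
  }
  ref <- fix$REF[keep]; alt <- fix$ALT[keep]
  aa[!(aa == ref | aa == alt)] <- "unknown"

  vt <- variant_table(chrom = ck, pos = pk,
                      snp_id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                                      paste0(ck, ":", pk), fix$ID[keep]),
                      ref = ref, alt = alt, ancestral = aa)

  g <- gtm[keep, , drop = FALSE]
  h <- matrix(0L, nrow = 2L * ncol(g), ncol = nrow(g))
  a1 <- substr(g, 1L, 1L) == "1"
  a2 <- substr(g, 3L, 3L) == "1"
  for (s in seq_len(ncol(g))) {
    h[2L * s - 1L, ] <- as.integer(a1[, s])
    h[2L * s, ] <- as.integer(a2[, s])
  }
  haps <- hap_matrix(h, panel$sample_id)
  out <- list(variants = vt, haps = haps)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Write phased genotypes to a VCF
#'
#' Emits a minimal deterministic VCFv4.2 with phased GT calls and the
#' ancestral allele in the `AA` INFO tag for polarized variants. Output is
#' byte-stable for identical inputs (no timestamps).
#'
#' @param path Output file path.
#' @param variants A [variant_table()].
#' @param haps A matching [hap_matrix()].
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(path, variants, haps) {
  stopifnot(ncol(haps) == nrow(variants))
  ids <- attr(haps, "sample_ids")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(variants$chrom), ">"),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  odd <- seq(1L, nrow(haps), by = 2L)
  gt <- matrix(paste0(haps[odd, , drop = FALSE], "|",
                      haps[odd + 1L, , drop = FALSE]),
               nrow = length(odd))
  info <- ifelse(variants$ancestral == "unknown", ".",
                 paste0("AA=", variants$ancestral))
  body <- paste(variants$chrom, format(variants$pos, scientific = FALSE,
                                       trim = TRUE),
                variants$snp_id, variants$ref, variants$alt, ".", "PASS",
                info, "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample-to-population panel
#'
#' @param path TSV with header columns `sample_id` and `population`.
#' @param roles Optional role bindings passed to [population_panel()];
#'   roles are configuration, not part of the panel file.
#' @return A [population_panel()].
#' @export
read_panel <- function(path, roles = list()) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "population")
  if (!all(need %in% names(d))) {
    stop("panel file must have header columns: ", paste(need, collapse = ", "))
  }
  population_panel(d$sample_id, d$population, roles = roles)
}

#' Write a panel TSV
#' @param path Output path.
#' @param panel A [population_panel()].
#' @return `path`, invisibly.
#' @export
write_panel <- function(path, panel) {
  utils::write.table(panel[, c("sample_id", "population")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED4 gene annotation
#'
#' @param path 4+ column BED file (chrom, start, end, name; 0-based
#'   half-open). Malformed lines are an error naming the line number;
#'   overlapping genes are retained (no merging).
#' @return A [gene_annotation()] sorted by `(chrom, start)`.
#' @export
read_gene_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty BED file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 4L) stop("malformed BED line ", i, ": expected >= 4 columns")
    s <- suppressWarnings(as.numeric(p[2])); e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e)) stop("malformed BED line ", i, ": non-numeric bounds")
    if (s >= e) stop("malformed BED line ", i, ": start >= end (", p[4], ")")
  }
  m <- do.call(rbind, lapply(parts, function(p) p[1:4]))
  gene_annotation(m[, 1], as.numeric(m[, 2]), as.numeric(m[, 3]), m[, 4])
}

#' Write a BED4 gene annotation
#' @param path Output path.
#' @param genes A [gene_annotation()].
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(path, genes) {
  writeLines(paste(genes$chrom,
                   format(genes$start, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   genes$gene, sep = "\t"), path)
  invisible(path)
}

#' Read a candidate-gene list
#'
#' One gene symbol per line; names are case-normalized to upper case and
#' de-duplicated (with a warning when duplicates are found).
#'
#' @param path Plain-text file.
#' @return Character vector of unique upper-case gene names.
#' @export
read_candidate_list <- function(path) {
  x <- trimws(readLines(path))
  x <- toupper(x[nzchar(x) & !grepl("^#", x)])
  if (anyDuplicated(x)) {
    warning("candidate list contains ", sum(duplicated(x)),
            " duplicate name(s) after case normalization; de-duplicated")
    x <- unique(x)
  }
  x
}

#' Read a gene-to-term mapping
#'
#' @param path TSV with header columns `gene`, `term_id`, `term_name`
#'   (one gene/term pair per row).
#' @return A `data.frame` with those three character columns, genes
#'   upper-cased.
#' @export
read_gene2term <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "term_id", "term_name")
  if (!all(need %in% names(d))) {
    stop("gene-to-term file must have header columns: ",
         paste(need, collapse = ", "))
  }
  d$gene <- toupper(d$gene)
  unique(d[, need])
}

#' Read/write the plain haplotype-matrix text format
#'
#' A VCF alternative for small fixtures: a header line of tab-separated SNP
#' ids of the form `chrom:pos` (optionally `chrom:pos:id`), then one row per
#' haplotype: a haplotype label (`<sample>_1` / `<sample>_2`) followed by a
#' string of 0/1 characters, one per SNP.
#'
#' @param path File path.
#' @return For the reader, a list with `variants` and `haps` (ancestral
#'   allele is `"unknown"`; REF/ALT are placeholders `A`/`G`).
#' @export
read_hap_text <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  fields <- strsplit(ids, ":", fixed = TRUE)
  chrom <- vapply(fields, `[`, "", 1L)
  pos <- as.numeric(vapply(fields, `[`, "", 2L))
  snp_id <- vapply(fields, function(f) if (length(f) >= 3L) f[3] else
    paste0(f[1], ":", f[2]), "")
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  labs <- vapply(body, `[`, "", 1L)
  rows <- lapply(body, function(p) as.integer(strsplit(p[2], "")[[1]]))
  h <- do.call(rbind, rows)
  samples <- unique(sub("_[12]$", "", labs))
  list(variants = variant_table(chrom, pos, snp_id),
       haps = hap_matrix(h, samples))
}

#' @rdname read_hap_text
#' @param variants A [variant_table()].
#' @param haps A matching [hap_matrix()].
#' @export
write_hap_text <- function(path, variants, haps) {
  stopifnot(ncol(haps) == nrow(variants))
  ids <- attr(haps, "sample_ids")
  labs <- paste0(rep(ids, each = 2L), "_", rep(1:2, length(ids)))
  header <- paste(paste0(variants$chrom, ":",
                         format(variants$pos, scientific = FALSE, trim = TRUE),
                         ":", variants$snp_id), collapse = "\t")
  body <- paste0(labs, "\t",
                 apply(haps, 1L, paste, collapse = ""))
  writeLines(c(header, body), path)
  invisible(path)
}

# Format a numeric column at 6 significant digits for TSV output.
fmt6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

# Write a data.frame as a deterministic TSV (floats at 6 significant digits).
write_tsv6 <- function(d, path) {
  out <- d
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt6(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write scan results to a directory
#'
#' Emits fixed-column TSV files for the per-SNP statistics, the per-window
#' statistics of every test (with bin, rank, percentile and outlier flags),
#' the gene-level summaries and the enrichment tables, plus a JSON run
#' manifest. Floats are written at 6 significant digits; row order is
#' deterministic (`chrom`, `pos` / `chrom`, `start`), so re-running on
#' identical inputs yields byte-identical files.
#'
#' @param results A scan result bundle from [run_scan()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written file paths, invisibly.
#' @export
write_scan_results <- function(results, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  paths <- character(0)
  put <- function(d, name) {
    p <- file.path(dir, name)
    write_tsv6(d, p)
    paths <<- c(paths, p)
  }
  if (!is.null(results$snp_stats)) put(results$snp_stats, "snp_stats.tsv")
  for (test in names(results$windows)) {
    put(results$windows[[test]], paste0("windows_", test, ".tsv"))
  }
  for (test in names(results$genes)) {
    put(results$genes[[test]], paste0("genes_", test, ".tsv"))
  }
  if (!is.null(results$overlap)) put(results$overlap, "gene_test_overlap.tsv")
  for (test in names(results$candidate_enrichment)) {
    put(results$candidate_enrichment[[test]],
        paste0("candidate_enrichment_", test, ".tsv"))
  }
  for (test in names(results$go_enrichment)) {
    put(results$go_enrichment[[test]], paste0("go_enrichment_", test, ".tsv"))
  }
  if (!is.null(results$manifest)) {
    p <- file.path(dir, "manifest.json")
    jsonlite::write_json(results$manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
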