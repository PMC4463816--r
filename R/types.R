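# Core containers. All are thin S3 wrappers around base structures
# (data.frame / integer matrix) so downstream code stays vectorised and
# printable; validators enforce the invariants the scans rely on.

#' Variant table
#'
#' Per-SNP metadata for a set of biallelic variants: chromosome, 1-based
#' position (VCF convention), identifier, REF/ALT alleles and the ancestral
#' allele where known. Rows must be ordered by chromosome with strictly
#' increasing positions within each chromosome.
#'
#' @param chrom Character vector of chromosome labels.
#' @param pos Numeric vector of 1-based base-pair positions.
#' @param snp_id Variant identifiers; `chrom:pos` when `NULL`.
#' @param ref,alt Allele strings (recycled); every variant is biallelic.
#' @param ancestral Ancestral allele per variant: must equal `ref`, `alt` or
#'   `"unknown"`. Scans that need polarization (iHS) only score variants with
#'   a known ancestral allele.
#' @return A `data.frame` with class `variant_table` and columns
#'   `chrom`, `pos`, `snp_id`, `ref`, `alt`, `ancestral`.
#' @export
variant_table <- function(chrom, pos, snp_id = NULL, ref = "A", alt = "G",
                          ancestral = "unknown") {
  m <- length(pos)
  chrom <- rep_len(as.character(chrom), m)
  pos <- as.numeric(pos)
  ref <- rep_len(as.character(ref), m)
  alt <- rep_len(as.character(alt), m)
  ancestral <- rep_len(as.character(ancestral), m)
  if (is.null(snp_id)) snp_id <- paste0(chrom, ":", pos)
  snp_id <- rep_len(as.character(snp_id), m)

  if (anyNA(pos) || any(pos < 1)) stop("positions must be >= 1 and non-missing")
  if (any(ref == alt)) stop("ref and alt alleles must differ (biallelic SNPs)")
  bad_anc <- !(ancestral == "unknown" | ancestral == ref | ancestral == alt)
  if (any(bad_anc)) {
    stop("ancestral allele must equal ref, alt or \"unknown\" (first offender: ",
         snp_id[which(bad_anc)[1]], ")")
  }
  # chromosome blocks must be contiguous with strictly increasing positions
  r <- rle(chrom)
  if (anyDuplicated(r$values)) stop("chromosome blocks must be contiguous")
  for (block in split(pos, factor(chrom, levels = r$values))) {
    if (any(diff(block) <= 0)) {
      stop("positions must be strictly increasing within each chromosome")
    }
  }
  out <- data.frame(chrom = chrom, pos = pos, snp_id = snp_id, ref = ref,
                    alt = alt, ancestral = ancestral,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Phased haplotype matrix
#'
#' A binary H x M matrix of phased alleles: H haplotypes (two consecutive
#' rows per diploid sample, in sample order) by M variants. Entries are 0
#' (REF) / 1 (ALT); no missingness is allowed -- inputs with missing calls
#' must be filtered or rejected before construction.
#'
#' @param values Integer/numeric matrix of 0/1 values with an even number of
#'   rows.
#' @param sample_ids Character vector of length `nrow(values)/2`; sample `i`
#'   owns rows `2i-1` and `2i`.
#' @return An integer matrix with class `hap_matrix` and a `sample_ids`
#'   attribute.
#' @export
hap_matrix <- function(values, sample_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (anyNA(values)) stop("haplotype matrix must not contain missing values")
  if (!all(values == 0L | values == 1L)) stop("haplotype values must be 0/1")
  if (nrow(values) %% 2L != 0L) stop("haplotype count must be even")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values) / 2L) {
    stop("need exactly one sample id per pair of haplotype rows")
  }
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  dimnames(values) <- NULL
  attr(values, "sample_ids") <- sample_ids
  class(values) <- c("hap_matrix", class(values))
  values
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("<hap_matrix> %d haplotypes (%d diploids) x %d variants\n",
              nrow(x), nrow(x) / 2L, ncol(x)))
  invisible(x)
}

#' Population panel
#'
#' Sample-to-population assignment plus the analysis roles the scans use:
#' `focal` (scanned population), `sister` (closest reference), `control`
#' (population whose iHS top windows veto focal windows) and `outgroup`
#' (third population for PBS).
#'
#' @param sample_id Character vector of unique sample ids.
#' @param population Character vector of non-empty population labels.
#' @param roles Named list/character vector mapping a subset of
#'   `c("focal","sister","control","outgroup")` to population labels present
#'   in `population`.
#' @return A `data.frame` with class `population_panel` and a `roles`
#'   attribute.
#' @export
population_panel <- function(sample_id, population, roles = list()) {
  sample_id <- as.character(sample_id)
  population <- as.character(population)
  if (length(sample_id) != length(population)) {
    stop("sample_id and population must have equal length")
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ", sample_id[duplicated(sample_id)][1])
  }
  if (any(is.na(population) | population == "")) {
    stop("empty population label")
  }
  out <- data.frame(sample_id = sample_id, population = population,
                    stringsAsFactors = FALSE)
  class(out) <- c("population_panel", "data.frame")
  roles(out) <- roles
  out
}

#' Get or set panel roles
#' @param panel A [population_panel()].
#' @param value Named list of role -> population label.
#' @return `roles()` returns the named list of role bindings.
#' @export
roles <- function(panel) attr(panel, "roles")

#' @rdname roles
#' @export
`roles<-` <- function(panel, value) {
  value <- as.list(value)
  if (length(value)) {
    known <- c("focal", "sister", "control", "outgroup")
    if (is.null(names(value)) || !all(names(value) %in% known)) {
      stop("roles must be named with a subset of: ",
           paste(known, collapse = ", "))
    }
    pops <- unique(panel$population)
    miss <- setdiff(unlist(value), pops)
    if (length(miss)) stop("role population not in panel: ",
                           paste(miss, collapse = ", "))
  }
  attr(panel, "roles") <- value
  panel
}

#' Row indices of a population's haplotypes
#'
#' @param haps A [hap_matrix()].
#' @param panel A [population_panel()] covering all samples in `haps`.
#' @param population Population label.
#' @return Integer vector of row indices into `haps` (two per diploid).
#' @export
hap_rows <- function(haps, panel, population) {
  ids <- attr(haps, "sample_ids")
  keep <- panel$sample_id[panel$population == population]
  idx <- match(keep, ids)
  if (anyNA(idx)) stop("panel samples missing from haplotype matrix: ",
                       paste(keep[is.na(idx)], collapse = ", "))
  sort(c(2L * idx - 1L, 2L * idx))
}

#' Gene annotation
#'
#' Gene intervals in BED convention: 0-based half-open `[start, end)`.
#' Duplicated gene names are allowed (e.g. across chromosomes); intervals are
#' kept as given (no merging) but sorted by `(chrom, start)`.
#'
#' @param chrom,start,end,gene Parallel vectors describing one interval per
#'   element.
#' @return A `data.frame` with class `gene_annotation`.
#' @export
gene_annotation <- function(chrom, start, end, gene) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  gene <- as.character(gene)
  if (any(is.na(start) | is.na(end) | start < 0)) {
    stop("gene intervals must have non-negative numeric bounds")
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("gene interval with start >= end: ", gene[bad], " (", chrom[bad], ":",
         start[bad], "-", end[bad], ")")
  }
  if (any(is.na(gene) | gene == "")) stop("gene names must be non-empty")
  ord <- order(chrom, start, end, gene)
  out <- data.frame(chrom = chrom[ord], start = start[ord], end = end[ord],
                    gene = gene[ord], stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}
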