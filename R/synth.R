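# Synthetic multi-population phased genotypes with the statistical structure
# the selection scans assume: tree-structured drift (Balding-Nichols),
# distance-decaying LD (founder-copying mosaics), common-variant
# ascertainment (ancestral frequencies bounded away from 0/1) and optional
# selective sweeps stamped onto a target population. All randomness flows
# from one integer seed through per-chromosome / per-population substreams.

# Deterministic substream seed derivation; stays below 2^31.
sub_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (t in c(...)) {
    t <- if (is.character(t)) sum(utf8ToInt(t) * seq_along(utf8ToInt(t))) else
      as.double(t)
    s <- (s * 48271 + t * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}

#' Population tree with per-edge drift
#'
#' A rooted tree whose leaves are population labels; each edge carries a
#' Balding-Nichols drift parameter `F` in `[0, 1)`. Allele frequencies drift
#' independently along each edge: a child's frequency is Beta-distributed
#' with mean equal to the parent frequency `p` and variance `F p (1 - p)`
#' (`F = 0` copies the parent exactly).
#'
#' @param parent,child Character vectors defining the edges (one edge per
#'   element); exactly one node must never appear as a child (the root).
#' @param f Numeric drift parameter per edge, each in `[0, 1)`.
#' @return A list with class `population_tree`: `edges` (data.frame in
#'   topological order) and `leaves`.
#' @export
population_tree <- function(parent, child, f) {
  stopifnot(length(parent) == length(child), length(child) == length(f))
  if (any(f < 0 | f >= 1)) stop("edge drift parameters must lie in [0, 1)")
  if (anyDuplicated(child)) stop("each node may have only one parent")
  root <- setdiff(parent, child)
  if (length(root) != 1L) stop("tree must have exactly one root")
  # topological order: repeatedly emit edges whose parent is already placed
  placed <- root
  ord <- integer(0)
  remaining <- seq_along(parent)
  while (length(remaining)) {
    ready <- remaining[parent[remaining] %in% placed]
    if (!length(ready)) stop("edges do not form a rooted tree")
    ord <- c(ord, ready)
    placed <- c(placed, child[ready])
    remaining <- setdiff(remaining, ready)
  }
  edges <- data.frame(parent = parent[ord], child = child[ord], f = f[ord],
                      stringsAsFactors = FALSE)
  leaves <- setdiff(edges$child, edges$parent)
  structure(list(edges = edges, root = root, leaves = leaves),
            class = "population_tree")
}

# Default demography: an outgroup split, a lowland split, and two closely
# related terminal populations, with modest drift on every edge -- the shape
# of a focal/sister/control/outgroup SNP-array study at a few tens of
# diploids per population.
default_tree <- function() {
  population_tree(
    parent = c("ROOT", "ROOT", "AMR", "AMR", "AND", "AND"),
    child  = c("OUT",  "AMR",  "CTL", "AND", "FOC", "SIS"),
    f      = c(0.06,   0.06,   0.04,  0.02,  0.02,  0.02))
}

#' Sweep specification
#'
#' Parameters of a single hard selective sweep stamped onto one population:
#' haplotypes are converted to copies of one carrier founder around a core
#' SNP until the derived-allele frequency reaches `f_target`; each converted
#' haplotype copies the founder over an interval whose half-length is drawn
#' independently per side from an exponential distribution with mean
#' `l_sweep` bp, leaving distal sequence untouched.
#'
#' @param population Target population label (a tree leaf).
#' @param snp Target core SNP: column index into the variant table.
#' @param f_target Final derived-allele frequency in `(0, 1]`; must exceed
#'   the pre-sweep frequency.
#' @param l_sweep Founder-copying length scale in bp (mean per side).
#' @return A list with class `sweep_spec`.
#' @export
sweep_spec <- function(population, snp, f_target = 0.9, l_sweep = 1e5) {
  stopifnot(f_target > 0, f_target <= 1, l_sweep > 0, snp >= 1)
  structure(list(population = population, snp = as.integer(snp),
                 f_target = f_target, l_sweep = l_sweep),
            class = "sweep_spec")
}

#' Scenario configuration for the synthetic-data generator
#'
#' Defaults emulate a small SNP-array cohort study: three study populations
#' of 20-23 diploids plus an outgroup, dense common biallelic SNPs (about
#' one per 4 kb, the autosomal density of a 730k genome-wide array), complete
#' phased calls, ascertainment of common variants, and LD from a
#' founder-copying mosaic model.
#'
#' @param n_diploids Named integer vector: diploids per population; names
#'   must equal the tree leaves. Default `c(FOC=23, SIS=23, CTL=20, OUT=20)`.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_snps SNPs per chromosome (evenly spaced with uniform jitter).
#' @param freq_bounds Ancestral-frequency sampler bounds `(low, high)`,
#'   `0 < low < high < 1`; bounding away from 0/1 imitates array SNP
#'   ascertainment.
#' @param switch_rate Founder-switch rate per bp of the copying model; the
#'   probability of switching founders between adjacent SNPs at distance `d`
#'   is `1 - exp(-switch_rate * d)`.
#' @param n_founders Founder-pool size per population; `Inf` draws every
#'   haplotype site-independently from the population frequencies (no LD,
#'   no founder drift) -- the pure Balding-Nichols sampling regime used for
#'   frequency-statistic calibration.
#' @param tree A [population_tree()]; default [default_tree()]-shaped
#'   four-population study design.
#' @param sweeps List of [sweep_spec()] objects.
#' @param seed Integer master seed; every random draw in the generator
#'   derives from it.
#' @return A list with class `scenario_config`.
#' @export
scenario_config <- function(n_diploids = c(FOC = 23, SIS = 23, CTL = 20,
                                           OUT = 20),
                            n_chromosomes = 2, chrom_length = 1e7,
                            n_snps = 2500, freq_bounds = c(0.05, 0.95),
                            switch_rate = 2e-5, n_founders = 10,
                            tree = default_tree(), sweeps = list(),
                            seed = 1) {
  stopifnot(all(n_diploids >= 2), n_chromosomes >= 1, chrom_length > 0,
            n_snps >= 1)
  if (!(freq_bounds[1] > 0 && freq_bounds[1] < freq_bounds[2] &&
        freq_bounds[2] < 1)) {
    stop("freq_bounds must satisfy 0 < low < high < 1")
  }
  if (switch_rate < 0) stop("switch_rate must be >= 0")
  if (is.null(names(n_diploids)) ||
      !setequal(names(n_diploids), tree$leaves)) {
    stop("names(n_diploids) must equal the tree leaves: ",
         paste(tree$leaves, collapse = ", "))
  }
  if (inherits(sweeps, "sweep_spec")) sweeps <- list(sweeps)
  for (sw in sweeps) {
    if (!sw$population %in% tree$leaves) {
      stop("sweep target population is not a tree leaf: ", sw$population)
    }
  }
  structure(list(n_diploids = n_diploids, n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, n_snps = n_snps,
                 freq_bounds = freq_bounds, switch_rate = switch_rate,
                 n_founders = n_founders, tree = tree, sweeps = sweeps,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# One Balding-Nichols step along an edge with drift f. Fixed alleles
# (p exactly 0 or 1) stay fixed; drift cannot resurrect variation.
bn_step <- function(p, f) {
  if (f == 0) return(p)
  k <- 1 / f - 1
  q <- p
  sel <- p > 0 & p < 1
  q[sel] <- stats::rbeta(sum(sel), p[sel] * k, (1 - p[sel]) * k)
  q
}

#' Simulate per-population derived-allele frequencies
#'
#' Ancestral frequencies are drawn uniformly inside `freq_bounds`; each tree
#' edge with drift `F > 0` draws the child frequency from a Beta distribution
#' with mean equal to the parent frequency `p` and variance `F p (1-p)`
#' (`F = 0` edges copy the parent exactly). Deterministic given the config
#' seed (substreams per chromosome).
#'
#' @param config A [scenario_config()].
#' @return A data.frame with columns `chrom`, `p_anc` and one frequency
#'   column per leaf population.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  per_chrom <- lapply(seq_len(config$n_chromosomes), function(ci) {
    withr::with_seed(sub_seed(config$seed, "freqs", ci), {
      m <- config$n_snps
      p_anc <- stats::runif(m, config$freq_bounds[1], config$freq_bounds[2])
      node_freq <- list()
      node_freq[[config$tree$root]] <- p_anc
      e <- config$tree$edges
      for (i in seq_len(nrow(e))) {
        node_freq[[e$child[i]]] <- bn_step(node_freq[[e$parent[i]]], e$f[i])
      }
      out <- data.frame(chrom = rep(paste0("chr", ci), m), p_anc = p_anc,
                        stringsAsFactors = FALSE)
      for (leaf in config$tree$leaves) out[[leaf]] <- node_freq[[leaf]]
      out
    })
  })
  do.call(rbind, per_chrom)
}

# Evenly spaced, jittered, strictly increasing positions for one chromosome.
jitter_positions <- function(m, len) {
  spacing <- len / m
  base <- (seq_len(m) - 0.5) * spacing
  pos <- sort(round(base + stats::runif(m, -0.45, 0.45) * spacing))
  pos <- pmax(pos, 1)
  for (i in seq_len(m)[-1]) if (pos[i] <= pos[i - 1]) pos[i] <- pos[i - 1] + 1
  pos
}

# Founder-copying mosaic for one haplotype: switch founders between adjacent
# SNPs with probability 1 - exp(-rate * distance).
copy_mosaic <- function(founders, pos, rate) {
  m <- length(pos)
  k <- nrow(founders)
  if (m == 1L) return(founders[sample.int(k, 1L), , drop = TRUE])
  p_sw <- 1 - exp(-rate * diff(pos))
  sw <- stats::runif(m - 1L) < p_sw
  seg <- cumsum(c(1L, sw))
  fid <- sample.int(k, max(seg), replace = TRUE)[seg]
  founders[cbind(fid, seq_len(m))]
}

#' Simulate phased haplotypes from population frequencies
#'
#' Per population and chromosome, a founder pool of `n_founders` haplotypes
#' is drawn site-wise from the population frequencies; each sample haplotype
#' is a mosaic that copies from one founder at a time, switching founders
#' between adjacent SNPs with probability `1 - exp(-switch_rate * d)`. This
#' yields distance-decaying LD within populations. With
#' `n_founders = Inf` haplotypes are drawn site-independently instead.
#' The derived allele is encoded as 1 (ALT); the REF allele is ancestral.
#'
#' @param freqs Output of [simulate_frequencies()].
#' @param config The same [scenario_config()].
#' @return A list with `variants` ([variant_table()]), `haps`
#'   ([hap_matrix()]) and `panel` ([population_panel()]).
#' @export
simulate_haplotypes <- function(freqs, config) {
  stopifnot(inherits(config, "scenario_config"))
  pops <- config$tree$leaves
  if (!all(pops %in% names(freqs))) stop("freqs lacks population columns")
  if (any(unlist(freqs[pops]) < 0) || any(unlist(freqs[pops]) > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  chroms <- unique(freqs$chrom)

  variants <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
    m <- sum(freqs$chrom == chroms[ci])
    pos <- withr::with_seed(sub_seed(config$seed, "pos", ci),
                            jitter_positions(m, config$chrom_length))
    data.frame(chrom = chroms[ci], pos = pos,
               snp_id = sprintf("snp_%s_%05d", chroms[ci], seq_len(m)),
               stringsAsFactors = FALSE)
  }))
  vt <- variant_table(variants$chrom, variants$pos, variants$snp_id,
                      ref = "A", alt = "G", ancestral = "A")

  sample_ids <- unlist(lapply(pops, function(p)
    sprintf("%s_%02d", p, seq_len(config$n_diploids[[p]]))))
  panel <- population_panel(sample_ids, rep(pops, config$n_diploids[pops]))

  h <- matrix(0L, nrow = 2L * length(sample_ids), ncol = nrow(vt))
  row0 <- 0L
  for (p in pops) {
    n_hap <- 2L * config$n_diploids[[p]]
    for (ci in seq_along(chroms)) {
      sel <- which(freqs$chrom == chroms[ci])
      pfreq <- freqs[[p]][sel]
      pos <- vt$pos[sel]
      m <- length(sel)
      withr::with_seed(sub_seed(config$seed, "haps", ci, p), {
        if (is.infinite(config$n_founders)) {
          block <- matrix(stats::rbinom(n_hap * m, 1L, rep(pfreq, each = n_hap)),
                          nrow = n_hap)
        } else {
          k <- config$n_founders
          founders <- matrix(stats::rbinom(k * m, 1L, rep(pfreq, each = k)),
                             nrow = k)
          block <- t(vapply(seq_len(n_hap), function(i)
            copy_mosaic(founders, pos, config$switch_rate), integer(m)))
        }
        h[row0 + seq_len(n_hap), sel] <- block
      })
    }
    row0 <- row0 + n_hap
  }
  list(variants = vt, haps = hap_matrix(h, sample_ids), panel = panel)
}

#' Stamp a selective sweep onto one population
#'
#' Chooses one carrier haplotype as the sweep founder (creating one if the
#' derived allele is absent) and converts randomly chosen non-carrier
#' haplotypes of the target population to copies of the founder until the
#' derived-allele frequency at the core reaches `f_target`. Each converted
#' haplotype copies the founder over an interval around the core whose
#' half-length is drawn exponentially (mean `l_sweep` per side,
#' independently); sequence outside the interval, and every other
#' population, is untouched.
#'
#' @param data A list with `variants`, `haps`, `panel` as produced by
#'   [simulate_haplotypes()].
#' @param spec A [sweep_spec()].
#' @param seed Integer seed for the conversion draws.
#' @return The modified [hap_matrix()].
#' @export
inject_sweep <- function(data, spec, seed = 1) {
  stopifnot(inherits(spec, "sweep_spec"))
  vt <- data$variants; h <- data$haps; panel <- data$panel
  j <- spec$snp
  if (j < 1 || j > ncol(h)) stop("sweep core SNP index out of range")
  rows <- hap_rows(h, panel, spec$population)
  if (!length(rows)) stop("sweep target population has no haplotypes")
  n_hap <- length(rows)
  need <- as.integer(ceiling(spec$f_target * n_hap))
  cur <- sum(h[rows, j])
  if (spec$f_target < cur / n_hap) {
    stop("f_target (", spec$f_target, ") below current derived frequency (",
         signif(cur / n_hap, 4), ")")
  }
  chrom_sel <- vt$chrom == vt$chrom[j]

  attrs <- attributes(h)
  withr::with_seed(sub_seed(seed, "sweep", j), {
    carriers <- rows[h[rows, j] == 1L]
    if (!length(carriers)) {
      founder <- sample(rows, 1L)
      h[founder, j] <- 1L
      carriers <- founder
      cur <- 1L
    }
    founder <- if (length(carriers) == 1L) carriers else sample(carriers, 1L)
    non <- rows[h[rows, j] == 0L]
    n_convert <- max(0L, need - cur)
    conv <- if (n_convert > 0L) sample(non, n_convert) else integer(0)
    for (i in conv) {
      left <- stats::rexp(1L, 1 / spec$l_sweep)
      right <- stats::rexp(1L, 1 / spec$l_sweep)
      span <- chrom_sel & vt$pos >= vt$pos[j] - left &
        vt$pos <= vt$pos[j] + right
      h[i, span] <- h[founder, span]
      h[i, j] <- 1L
    }
  })
  attributes(h) <- attrs
  h
}

#' Choose a sweep core SNP
#'
#' Picks the SNP closest to a target position (default the centre of the
#' first chromosome) whose derived-allele frequency in the target population
#' lies inside `freq_range` -- drift can fix alleles, and a sweep needs a
#' segregating core to act on.
#'
#' @param data A list with `variants`, `haps`, `panel`.
#' @param population Target population label.
#' @param at Target position in bp (default: centre of the first
#'   chromosome).
#' @param freq_range Admissible pre-sweep derived frequency interval.
#' @return The chosen SNP column index.
#' @export
pick_sweep_core <- function(data, population, at = NULL,
                            freq_range = c(0.1, 0.5)) {
  vt <- data$variants
  rows <- hap_rows(data$haps, data$panel, population)
  chrom <- vt$chrom[1]
  sel <- which(vt$chrom == chrom)
  if (is.null(at)) at <- (min(vt$pos[sel]) + max(vt$pos[sel])) / 2
  p <- colSums(data$haps[rows, sel, drop = FALSE]) / length(rows)
  ok <- p >= freq_range[1] & p <= freq_range[2]
  if (!any(ok)) stop("no SNP with pre-sweep frequency in the target range")
  sel[ok][which.min(abs(vt$pos[sel][ok] - at))]
}

#' Generate a complete on-disk fixture
#'
#' Runs [simulate_frequencies()], [simulate_haplotypes()] and
#' [inject_sweep()] for every configured sweep, then writes a loadable
#' fixture: phased VCF, panel TSV, a synthetic tiling gene annotation (BED4),
#' a candidate gene list containing the sweep-window genes plus random
#' genes, and a JSON manifest recording the configuration and seed.
#'
#' @param config A [scenario_config()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths (`vcf`, `panel`, `genes`, `candidates`,
#'   `manifest`), invisibly; also returns the in-memory dataset via the
#'   `"data"` attribute.
#' @export
generate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "scenario_config"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  freqs <- simulate_frequencies(config)
  data <- simulate_haplotypes(freqs, config)
  for (i in seq_along(config$sweeps)) {
    data$haps <- inject_sweep(data, config$sweeps[[i]],
                              seed = sub_seed(config$seed, "sweepseed", i))
  }
  genes <- synthetic_genes(unique(data$variants$chrom), config$chrom_length)
  candidates <- synthetic_candidates(genes, data$variants, config)

  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                panel = file.path(dir, "panel.tsv"),
                genes = file.path(dir, "genes.bed"),
                candidates = file.path(dir, "candidates.txt"),
                manifest = file.path(dir, "manifest.json"))
  write_phased_vcf(paths$vcf, data$variants, data$haps)
  write_panel(paths$panel, data$panel)
  write_gene_bed(paths$genes, genes)
  writeLines(candidates, paths$candidates)
  manifest <- list(
    generator = "sweepscan::generate_dataset",
    seed = config$seed,
    n_diploids = as.list(config$n_diploids),
    n_chromosomes = config$n_chromosomes,
    chrom_length = config$chrom_length,
    n_snps = config$n_snps,
    freq_bounds = config$freq_bounds,
    switch_rate = config$switch_rate,
    n_founders = config$n_founders,
    tree = config$tree$edges,
    sweeps = lapply(config$sweeps, unclass),
    files = lapply(paths, basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  structure(paths, data = data)
}

# Tiling synthetic gene annotation: 30 kb genes every 60 kb. Names are
# synthetic (SYNG_<chrom>_<k>).
synthetic_genes <- function(chroms, chrom_length) {
  rows <- lapply(chroms, function(ch) {
    starts <- seq(5000, chrom_length - 35000, by = 60000)
    data.frame(chrom = ch, start = starts, end = starts + 30000,
               gene = sprintf("SYNG_%s_%03d", toupper(ch),
                              seq_along(starts)),
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  gene_annotation(d$chrom, d$start, d$end, d$gene)
}

# Candidate list: genes within 100 kb of every sweep core plus random genes
# up to ~1% of the annotation (the a-priori-list regime of candidate-gene
# scans, scaled to the synthetic genome).
synthetic_candidates <- function(genes, variants, config) {
  sweep_genes <- character(0)
  for (sw in config$sweeps) {
    ch <- variants$chrom[sw$snp]; p <- variants$pos[sw$snp]
    hit <- genes$chrom == ch & genes$start < p + 1e5 & genes$end > p - 1e5
    sweep_genes <- c(sweep_genes, genes$gene[hit])
  }
  n_rand <- max(5L, round(0.01 * nrow(genes)))
  rand <- withr::with_seed(sub_seed(config$seed, "cand"),
                           sample(genes$gene, min(n_rand, nrow(genes))))
  sort(unique(c(sweep_genes, rand)))
}
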