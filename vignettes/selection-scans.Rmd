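---
title: "Selection scans with sweepscan: models, parameters and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Recent positive selection leaves two complementary footprints in dense
SNP-array data. A partial sweep drags a long haplotype to intermediate or
high frequency faster than recombination can break it up, producing
*extended haplotype homozygosity* (EHH) around the selected core. And
selection restricted to one population shifts allele frequencies on that
population's branch of the tree, inflating pairwise differentiation.
`sweepscan` implements both families of statistics over phased biallelic
genotypes — iHS and XP-EHH on the haplotype side, Weir–Cockerham
F~ST~ and the population branch statistic (PBS) on the frequency side —
together with the empirical-outlier window framework commonly used to turn
per-SNP scores into candidate regions, and candidate-gene / GO-term
enrichment with the conservative EASE score. It targets small cohorts
genotyped on genome-wide arrays (a few tens of diploids per population),
where parametric nulls are unreliable and the ranking-based outlier
approach is standard.

The package operates on four analysis roles bound to population labels:

* **focal** — the scanned population;
* **sister** — the closest reference population (the F~ST~ pair and the
  PBS sister branch);
* **control** — a population whose own haplotype-test outliers veto focal
  windows (shared outliers are more parsimoniously explained by shared
  demography than by selection);
* **outgroup** — the third population for PBS.

## Statistics

### EHH, iHH, iHS

For the carriers of a core allele, EHH at marker $x$ is the probability
that two randomly drawn carrier haplotypes are identical at every SNP from
the core out to $x$:
$\mathrm{EHH}(x) = \sum_j \binom{c_j}{2} / \binom{n}{2}$ over the distinct
extended haplotypes with counts $c_j$. The curve starts at 1 and is
followed outward until it falls below a cutoff (default 0.05), the
chromosome ends, or an inter-SNP gap exceeds `gap_max` (default 200 kb).
iHH is the trapezoidal area under the curve against physical distance,
integrating both directions and interpolating the cutoff crossing
linearly. The unstandardized iHS at a core SNP is
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$ (ancestral over derived), and the
reported score is standardized to mean 0 / SD 1 within
derived-allele-frequency bins of width 0.02 (bins with fewer than 20
scores are merged with their nearest neighbour), because the expected
haplotype length depends strongly on allele frequency.

Scoring requires polarization. Ancestral alleles are read from the VCF
`AA` INFO tag; variants without one are flagged `unpolarized` and skipped
rather than guessed, and the polarization source is deliberately
injectable since array data carry no intrinsic ancestral call.

### XP-EHH

XP-EHH compares the *pooled* EHH decay (all haplotypes, both core alleles)
of two populations at the same core. Both populations are integrated out
to the same boundary — the outermost marker at which the pooled EHH of the
two populations combined is still above the cutoff — and the score is
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_B)$, standardized genome-wide. Positive
values mean longer homozygosity in population A; a sweep near fixation in
A (invisible to within-population iHS) shows up here. Swapping the two
populations negates the unstandardized score exactly; this antisymmetry is
asserted in the test suite.

### Weir–Cockerham F~ST~ and PBS

Per-SNP differentiation uses the Weir–Cockerham (1984) variance-components
estimator $\hat\theta = a/(a+b+c)$ for two populations, computed from
allele frequencies, diploid sample sizes and *observed* heterozygote
proportions (the $c$ component is defined on observed heterozygotes, so
phased diploids are paired rather than assuming Hardy–Weinberg). SNPs
monomorphic in both populations have $a+b+c=0$ and are excluded. The raw
estimate may be negative; it is reported raw and clamped at zero.

PBS isolates the focal branch from three pairwise values via the
log-transformed branch lengths $T = -\ln(1 - F_{ST})$:
$\mathrm{PBS} = (T_{fs} + T_{fo} - T_{so})/2$, using natural logs and
clamping each $F_{ST}$ into $[0, 1-10^{-12}]$ before the transform.
Negative per-SNP estimates are clamped to zero before the log because
$-\ln(1-x)$ has no meaningful value on the estimator's negative range;
the raw value remains available in the output. PBS itself may be negative.

When a *mean* F~ST~ across many loci is wanted (drift calibration,
global differentiation summaries), `wc_fst_multilocus()` combines the
variance components as a ratio of sums, $\sum a / \sum(a+b+c)$. The
average of per-SNP ratios is systematically biased toward zero (each
per-SNP ratio is a noisy, bounded quantity), while the ratio of sums is
the consistent combination and recovers simulated drift parameters to
within a few thousandths at these sample sizes.

## The window framework

Per-SNP scores are collapsed onto non-overlapping windows anchored at
coordinate zero: 200 kb windows for the haplotype tests and 100 kb for the
frequency tests. Window statistics follow each test's convention: iHS uses
the fraction of scored SNPs with $|\mathrm{iHS}| > 2$ (a regional
consistency measure robust to single outlier SNPs), while XP-EHH, F~ST~
and PBS use the window maximum (these tests emphasize extreme single
SNPs). Windows with no scored SNP are dropped.

Array SNP density is uneven, and windows with more SNPs have more chances
to contain an extreme value. Haplotype-test windows are therefore binned
by scored-SNP count — adjacent counts merged upward until every bin holds
at least 50 windows — and ranked *within* bins; the frequency tests use a
single global bin by default. The top percentile (1% by default, with a
secondary 5% tier) is flagged per bin with a ceiling rule,
$\lceil p \cdot N_{bin} \rceil$, and ties at the cut are resolved
deterministically (higher max-SNP score, then lower chromosome/start), so
the flagged count is exactly reproducible. Because ranking is the only
operation on scores, outlier calls are invariant under any monotone
transform of the statistic.

Two cross-scan summaries mirror common practice: the focal population's
top-1% iHS windows are discarded when they also sit in the control
population's top-5% windows (`exclusion_filter()`), and PBS scans of two
focal populations against a shared sister/outgroup scheme can be compared
window-by-window (`branch_length_comparison()`: among windows top-1% in
both, the share where the first focal branch is strictly longer).

## Gene-level reporting and enrichment

A gene is assigned to a window when their intervals overlap by at least
one bp (genes in BED 0-based half-open coordinates, windows likewise);
genes inherit the rank of their best flagged window, and the maximum
per-SNP statistic inside the gene body is reported separately, with genes
containing no scored SNP annotated by the distance to the nearest one. The
gene *universe* for enrichment is every gene overlapping any scanned
window — not the whole annotation — matching the empirical-outlier design.

Candidate-list intersection reports the observed overlap $k$ together with
its chance expectation $nK/N$ and a hypergeometric upper tail
$P(X \ge k)$. GO-style term screening uses the EASE score: the one-sided
Fisher exact tail recomputed after removing one gene from the observed
overlap ($k' = \max(k-1, 0)$). This makes single-gene overlaps
unreportable ($p = 1$) and is strictly conservative relative to Fisher's
p-value for $k \ge 1$ — a property the tests assert on random margins,
along with agreement with exhaustive enumeration of the hypergeometric
mass for universes up to 60 genes. Results are filtered at EASE < 0.01; a
Benjamini–Hochberg column is emitted for information only, mirroring the
screening (not testing) role this step plays.

## The synthetic-data generator

Real inputs for this kind of study are archived array genotypes; the
package ships a generator that reproduces their *statistical shape* so the
whole pipeline can be exercised and calibrated offline:

* **Drift**: allele frequencies evolve along a rooted population tree
  under the Balding–Nichols model — each edge with parameter $F$ draws the
  child frequency from a Beta distribution with mean $p$ and variance
  $F\,p(1-p)$. $F = 0$ edges copy exactly; fixed alleles stay fixed.
* **Ascertainment**: ancestral frequencies are drawn uniformly on
  (0.05, 0.95), imitating the common-variant bias of array SNP selection.
* **LD**: within each population, haplotypes are mosaics over a small
  founder pool (default 10), switching founders between adjacent SNPs with
  probability $1 - e^{-\rho d}$ ($\rho$ = `switch_rate`, default
  $2 \times 10^{-5}$/bp), which yields distance-decaying r² on a ~50 kb
  scale at the default SNP spacing. With `n_founders = Inf` haplotypes are
  drawn site-independently — the pure Balding–Nichols sampling regime.
* **Sweeps**: `inject_sweep()` stamps a hard sweep by copying one carrier
  founder haplotype into random non-carriers around a core SNP until a
  target derived frequency is reached, with exponentially distributed
  copy-interval half-lengths (mean `l_sweep` per side). Other populations
  are untouched bit-for-bit.

Default scale: four populations of 20–23 diploids (focal, sister, control,
outgroup — the sample sizes of a small altitude-cohort array study), two
chromosomes of 10 Mb with 2,500 jittered SNPs each, i.e. one SNP per
~4 kb, the autosomal density of a 730k genome-wide array. All randomness
derives from one integer seed through fixed per-chromosome/per-population
substreams, so every fixture is byte-reproducible.

What the generator does **not** emulate: realistic human demography
(growth, migration, admixture), recombination-rate variation, mutation
models, background selection, genotyping error or phasing switch errors.
Passing calibration on this generator therefore shows that the statistics
and the framework behave as designed under their own assumptions — not
that any particular empirical dataset will rank the same windows.

A deliberate consequence of the founder-pool LD model: a pool of $K$
founders adds roughly $1/K$ of apparent drift on top of the tree's $F$,
because the sampled haplotypes are correlated through the pool. Drift
*parameter-recovery* checks therefore run in the `n_founders = Inf`
regime, where the Weir–Cockerham multilocus estimate recovers
$F \in \{0.05, 0.1, 0.2\}$ within ±0.02 at 20–23 diploids per population;
the founder-pool regime is reserved for the haplotype statistics, which
are rank-based and insensitive to the inflation.

## Numerical choices and degenerate inputs

* EHH truncation at 0.05 and `gap_max` 200 kb follow the conventional
  defaults for array scans; both are configurable. Scores whose walks
  cross a larger gap are invalidated; walks that reach a chromosome end
  keep their one-sided truncation but carry an `edge` flag.
* iHH interpolates the cutoff crossing linearly so the integral is taken
  exactly down to EHH = cutoff; XP-EHH integrates both populations to the
  shared combined-EHH boundary without interpolation.
* Cores with derived frequency outside [0.05, 0.95], with fewer than two
  carriers of either allele, or with zero integrated area are flagged with
  a reason rather than scored.
* Standardization bins with zero variance yield `NA` scores rather than
  infinities; monomorphic-in-both SNPs are excluded from F~ST~ windows.
* All tie-breaks (outlier cut, max-SNP choice) are deterministic and
  documented; re-running a scan on identical inputs reproduces every
  output file byte for byte.

## Problem sizes used in the test suite

The suite calibrates against brute-force oracles at small sizes (≤ 12
haplotypes × ≤ 30 SNPs for EHH pair counting; cohorts of 2–8 diploids for
the variance-components oracle; universes ≤ 60 genes for exact
enumeration) and runs simulation checks at the default study scale: 6,000
SNPs for drift recovery and PBS calibration, and twenty generator seeds
for sweep detection with `f_target = 0.9` and `l_sweep = 100` kb. At that
scale the sweep-containing window reaches the top 1% of at least one
haplotype test in roughly two-thirds of seeds — partial sweeps at these
sample sizes are genuinely hard — while the mean near-core scores of all
three localized tests exceed their genome background clearly.

## Limitations

The package implements empirical-outlier screening, not significance
testing: top-percentile windows are candidates, and with small effective
population sizes drift alone produces extreme windows. The exclusion rule
and cross-test overlap mitigate but cannot remove this. iHS requires an
external polarization source; F~ST~/PBS results depend on the choice of
sister and outgroup; gene-level counts depend on the annotation supplied.
None of these choices are hidden — every one is a visible parameter of
`scan_config()` and is recorded in the run manifest.
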