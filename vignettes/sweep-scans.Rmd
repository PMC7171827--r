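---
title: "Selective-sweep scans with sweepscan: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective-sweep scans with sweepscan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Domestication and breed formation leave localized footprints in a
genome: at a locus under recent positive selection, the favored
haplotype rises quickly in frequency in the selected population, so that
population shows *reduced nucleotide diversity* and *elevated
allele-frequency differentiation* against related populations at that
locus, while the rest of the genome reflects only neutral drift.
`sweepscan` implements the standard two-statistic windowed scan for such
sweeps in a three-population design — a focal population carrying the
trait of interest (for example yellow-pigmented chicken breeds), a
contrast population without it (non-yellow breeds), and an outgroup
(red junglefowl) — together with the supporting population-structure and
region-visualization stages, and a fully specified synthetic-data
generator so every stage can be validated against known truth.

# Statistics

## Weir–Cockerham F~ST~ in sliding windows

Differentiation between two populations is estimated per SNP with the
Weir & Cockerham (1984) variance components \(a\) (among populations),
\(b\) (among individuals within populations) and \(c\) (within
individuals), computed from the two sample sizes, sample allele
frequencies and observed heterozygosities.  The per-site estimator is
\(\hat\theta = a/(a+b+c)\); windows combine sites as a *ratio of
averages*, \(\sum a / \sum (a+b+c)\), which is the field-standard way
to stabilize the many noisy per-site ratios.  Per-site components can
be slightly negative in finite samples; window values are **not**
clipped at zero by default, because clipping would destroy the LSBL
additivity identity below.  A display-only clipping flag exists in the
pipeline configuration.

Windows are `[k·step, k·step + size)` per chromosome (defaults: size
50 kb, step 25 kb), the final window truncated at the chromosome end;
truncated tails shorter than one step are dropped.  A window needs at
least `min_snps` informative SNPs (default 10) to receive a value —
smaller windows give unstable ratios; the cut-off is configurable and
every dropped window is visible as `NA` in the output tables.

## Locus-specific branch length

With focal A, contrast B and outgroup C, the per-window branch length
of A is

\[ \mathrm{LSBL}(A;B,C) \;=\; \tfrac12\,\bigl(F_{ST}(AB) + F_{ST}(AC) -
F_{ST}(BC)\bigr), \]

the three-point decomposition of pairwise differentiation onto the
branches of the (A,B,C) star tree.  Windows where A's branch is long
carry differentiation specific to A — the LSBL signal of a sweep on A's
lineage.  The identity \(\mathrm{LSBL}_A + \mathrm{LSBL}_B =
F_{ST}(AB)\) holds per window to machine precision and is asserted in
the test suite.

## Windowed diversity and the π-ratio

Nucleotide diversity uses the unbiased per-site estimator
\(\pi_\text{site} = 2 c_\text{alt} c_\text{ref} / (n_h (n_h - 1))\)
over the population's non-missing haplotypes (allele counts derived
from genotypes when unphased), summed over sites and divided by the
*full window length in bp* — the convention of per-window diversity in
VCF-based tools, so monomorphic and absent positions contribute zero.
The sweep statistic is the ratio \(\pi_\text{contrast} /
\pi_\text{focal}\); values well above 1 flag diversity loss in the
focal group.  Windows whose focal diversity falls below a floor
(`min_pi`, default \(10^{-5}\) per bp) are set missing rather than
producing unstable or infinite ratios; each flooring is logged.  The
floor is roughly two orders of magnitude below typical windowed
diversity in dense resequencing data, so it only catches genuinely
degenerate windows.

## Outliers, genes and the two-test overlap

Candidate sweep windows are the empirical top percentile (default
`q = 0.99`) of each statistic, using the linear-interpolation sample
quantile; ties at the threshold are all included (a documented superset
behavior).  Genes are assigned to outlier windows by interval overlap
of at least 1 bp against a BED annotation — a deliberately simple,
database-free stand-in for consequence-level annotation.  The headline
output is the set of genes flagged by *both* statistics, plus each
test's exclusive genes; requiring concordance of two tests with
different error modes is the usual guard against single-statistic
artifacts.

# Supporting stages

*LD pruning* follows the greedy windowed `--indep-pairwise` scheme
(defaults 50 SNPs, step 10, r² > 0.1 drops the later site; missing
genotypes are pairwise-excluded, and a zero-variance site has r² = 0
against all partners).  *PCA* uses GCTA-style standardization: per-site
mean imputation of missing genotypes, centering by \(2\hat p\) and
scaling by \(\sqrt{2\hat p(1-\hat p)}\); component signs are fixed by
making the largest-magnitude sample coordinate positive, so results are
reproducible under sample reordering.  Mean imputation is the simplest
policy consistent with that scaling; at the few-percent missingness
this package targets it shrinks coordinates negligibly.

Sample distances are `1 − IBS` (identity by state, the mean of
\((2-|g_i-g_j|)/2\) over shared sites); the tree is Saitou–Nei
neighbor joining (via `ape::nj`), rooted at the midpoint of the
outgroup's pendant edge — the natural reading of "rooted to the
outgroup" when no root position is given.  Support values come from
resampling *sites* with replacement, rebuilding distance and tree, and
counting bipartition recovery over (by default) 100 replicates.
Negative NJ branch-length estimates are kept in the object (they are
information about estimation error) and clamped to zero only when
serializing to Newick.

The *haplotype matrix* stage codes a region's haplotypes as
reference/alternative for display, ordered in population blocks.
Phased input contributes two rows per sample.  Unphased input falls
back to one genotype-coded row per sample with heterozygotes set
missing: re-phasing is out of scope here, and this fallback is the only
coding that never invents phase.  Within a block, rows are ordered by
sample id — a neutral, deterministic choice.

# The synthetic-data generator

The generator exists so that the full pipeline is testable with known
truth.  It emulates exactly the statistical structure the scan relies
on, and nothing more:

* **Neutral differentiation** follows the Balding–Nichols model: each
  site draws an ancestral frequency \(p \sim U(0.05, 0.95)\) and each
  population an own frequency from
  \(\mathrm{Beta}\bigl(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\bigr)\),
  i.e. mean \(p\) and variance \(p(1-p)F\), so the drift parameter
  \(F\) is the expected fixation index.  No coalescent machinery is
  needed for this: the scan statistics only require a controllable
  genome-wide differentiation level.  The bounded uniform ancestral
  distribution avoids a preponderance of sites monomorphic in every
  sample; sites that still come out monomorphic are retained so the
  analysis-side site filter is exercised.
* **Sweeps** are injected on the focal branch by (i) drawing the focal
  frequency with a larger drift parameter `F_sweep` inside the region
  and (ii) deterministically pushing it toward the nearer allele
  boundary so realized focal heterozygosity is scaled by exactly
  `pi_scale`.  This produces the two signals the scan detects — high
  focal-branch differentiation and low focal diversity — without
  forward simulation of selection.
* **Genotypes** are independent Bernoulli haplotype draws given the
  population frequency; missingness is independent per site × sample.
  The toy gene annotation tiles fixed-length genes (10 kb) with 10 kb
  gaps, so window→gene annotation has both hits and misses, and the
  truth table records the genes overlapping sweep regions.
* Substitution types are drawn with transition probability
  \(2.53/3.53\), matching the transition/transversion ratio typical of
  chicken whole-genome SNP data, so the variant-summary stage produces
  realistic numbers.

The standing demonstration dataset (`demo_sim_config()`) uses 15
chromosomes of 1 Mb at 2.5 SNPs/kb (37,500 SNPs — the order of
magnitude of real resequencing density, and enough windows, 585, for a
meaningful top-1% cut), three populations of 25 diploid samples at
F = 0.1, 1% missingness, and three 75-kb sweep regions with
`F_sweep = 0.6` and `pi_scale = 0.1`, aligned to the gene tiling so
every truth gene lies inside a sweep region.  These sizes keep the full
demo, including the 100-replicate tree bootstrap, around a minute on a
laptop while leaving the top-percentile machinery non-trivial.

What the generator deliberately does **not** emulate: linkage
disequilibrium (sites are independent given frequencies), recombination
maps, mutation-rate variation, indels/SVs, and ascertainment of real
SNP calling.  Passing tests therefore demonstrate correctness of the
statistics and the end-to-end plumbing under the stated model — not
robustness to LD-induced autocorrelation of window statistics, which on
real data mainly widens the null spread and is the usual reason for
preferring empirical over parametric thresholds in the first place.

# Numerical and degenerate-input policies

* Half-missing or mixed-ploidy genotype fields (`./1`) are treated as
  missing — unambiguous and rare.
* VCF positions are 1-based; windows and BED intervals are 0-based
  half-open internally, converted only at I/O boundaries.
* A site with fewer than two non-missing genotypes in either population
  gets `NA` F~ST~ components; a window with a non-positive component
  denominator is `NA`.
* Ts/Tv is reported as `NA` when there are no transversions.
* The F~ST~/π window minimum (`min_snps = 10`) and the π-ratio floor
  (`min_pi = 1e-5`) are the two desk-choice constants; both are
  configurable, logged, and their effects visible as `NA` windows.
* All randomness (simulation, bootstrap) flows from explicit integer
  seeds; identical configuration implies byte-identical outputs.

# Known limitations

* Only biallelic SNPs are analyzed; multi-allelic records are skipped
  (and counted) at parse time.
* The π denominator assumes all window positions are callable; an
  accessibility mask is not implemented.
* The two-population F~ST~ code is specialized to pairs (the
  three-pair LSBL design); it does not generalize to r > 2
  populations.
* Haplotype-based statistics (iHS, XP-EHH) and admixture-model fits
  are out of scope.

# A minimal session

```{r example}
library(sweepscan)

demo <- run_demo(outdir = "demo_run", seed = 1)
demo$recall_lsbl            # fraction of truth sweep windows in the LSBL top 1%
demo$recall_pi_ratio        # same for the pi-ratio scan
demo$pipeline$scan$overlap$shared   # genes flagged by both tests
```

The same stages are scriptable individually — see `?read_vcf`,
`?site_fst`, `?windowed_pi`, `?call_outliers`, `?nj_tree`,
`?extract_haplotypes` — or from the shell via the
`inst/scripts/sweepscan` entry point.
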