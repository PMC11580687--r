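---
title: "Detecting sex-linked regions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-linked regions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slrscan)
```

`slrscan` locates sex-linked regions (SLRs) on the sex chromosomes of
dioecious diploids and characterises sex-chromosome turnovers. This
vignette is the package's account of the statistics it computes, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design choices made where more than one reasonable option
existed.

## The coverage model: chromosome quotient

With short reads from sexed individuals mapped to the X haplotype of a
phased assembly, the expected per-window haploid dose is 2:2
(female:male) in pseudo-autosomal regions (PARs) and autosomes, 2:1 in
X-linked windows, and — mapping to the Y haplotype — 0:1 in Y-specific
windows. The chromosome quotient of window $w$ is

$$\mathrm{CQ}_w = \frac{F_w / \sum F}{M_w / \sum M},$$

the female:male count ratio normalised by each sex's total mapped counts.
Normalisation is on by default because sequencing effort per sex pool is
never exactly balanced in real data; it cancels in the ratio. For a single
chromosome whose windows are mostly one class (as in the simulated
acceptance runs), raw ratios (`normalize = FALSE`) map directly onto the
dose ratios 2 / 1 / 0.

Window classification uses `CQ <= 0.3` for Y-specific, `CQ >= 1.6` for
X-like and `0.7 <= CQ <= 1.3` for autosomal-like windows. These bands are
generous relative to the sampling noise of a 50-kb window at the default
simulated depth (tens of thousands of reads per window, so the CQ standard
error is well below 0.05) and are exposed as arguments because real data —
mapping bias, repeats, copy-number variation — is far noisier than the
Poisson model below.

## The differentiation model: between-sex Weir–Cockerham FST

Treating females and males as two populations ($r = 2$), each biallelic
site contributes the Weir–Cockerham variance components

$$\bar n = \tfrac{1}{2}(n_f + n_m), \qquad
  n_c = 2\bar n - \frac{n_f^2 + n_m^2}{2\bar n},$$

$$a = \frac{\bar n}{n_c}\!\left[S^2 - \frac{1}{\bar n - 1}\!\left(\bar p(1-\bar p)
      - \frac{S^2}{2} - \frac{\bar h}{4}\right)\right],\quad
  b = \frac{\bar n}{\bar n - 1}\!\left[\bar p(1-\bar p) - \frac{S^2}{2}
      - \frac{2\bar n - 1}{4\bar n}\bar h\right],\quad
  c = \frac{\bar h}{2},$$

with $\bar p$ the weighted mean alternate-allele frequency, $S^2$ the
between-sex frequency variance and $\bar h$ the weighted mean observed
heterozygosity, all over non-missing genotypes. Windowed
$\theta = \sum a / \sum(a+b+c)$ is the *weighted* (ratio-of-sums)
estimator, not a mean of per-site ratios — the two differ on heterogeneous
windows, and the test suite pins the implementation to a direct-summation
oracle at `1e-12`.

Two algebraic identities anchor the scan. At an XY-diagnostic site (all
females homozygous for the X allele, all males heterozygous, equal $n$):
$a = 1/8$, $b = -1/8$, $c = 1/4$, so $\theta = 1/2$ exactly, for any $n$.
At a fixed difference, $\theta = 1$. Sites monomorphic across both sexes
carry no information and are dropped (`NA`).

SNPs are pre-filtered by three rules applied in order: (i) mean site depth
above twice the genome-wide mean at variant sites (a proxy for collapsed
repeats; skipped with a warning when no depth is available), (ii)
non-biallelic sites, (iii) missingness above 10% and/or minor allele
frequency below 5% (a MAF of exactly 5% is retained). Rule (i) is applied
per site — the mean across samples — matching how site-level filters in
standard VCF tooling behave; a per-sample reading of the same rule would
require per-sample depth thresholds the data rarely support.

## Segmentation and boundary calling

The windowed $\theta$ series is segmented under a Gaussian mean-shift model
solved exactly by PELT with penalty

$$\beta = 2\,\hat\sigma^2\, m \,\log n, \qquad m = \mathrm{window/step}.$$

Two choices here deserve explanation:

* **Variance estimate.** $\hat\sigma^2$ is the variance of the *whole*
  series, the convention of standard mean-shift changepoint tooling. It is
  deliberately conservative when signal is present: window-to-window
  variation inside an SLR plateau (driven by local fluctuations in the
  density of diagnostic sites) is real structure under an iid noise model,
  and a noise-floor estimate (e.g. the MAD of first differences) makes PELT
  shred the plateau into many small segments. With the conservative
  estimate the series segments into the low–high–low structure the calling
  rule expects, and the jump at a true SLR boundary is still orders of
  magnitude above the penalty.
* **Overlap factor $m$.** With 100-kb windows at 10-kb steps, adjacent
  windows share ~90% of their SNPs; a noise excursion persists for about
  $m = 10$ windows and would otherwise be fitted as a segment. Scaling the
  penalty by $m$ restores the calibration an iid BIC assumes. For
  non-overlapping windows $m = 1$ and the penalty is ordinary BIC.

Segments whose mean exceeds `max(0.1, 3 * median(segment means))` are
called, adjacent qualifying segments are merged, and boundaries are then
refined in two stages:

1. **Window-level ramp fit.** A sharp boundary appears in overlapping
   windows as a linear ramp one window wide (each window's value is
   proportional to its overlap with the SLR). The boundary is the
   least-squares offset of that ramp over ±2 window widths, reported at
   window-center coordinates — which undoes the ~window/2 smearing that
   makes raw segment edges biased for any plateau height.
2. **Site-level refinement** (when per-site components are supplied).
   Diagnostic sites carry $\theta = 0.5$ exactly while the background tail
   above 0.35 is empirically empty at 20+20 samples, so the boundary is
   re-estimated as the two-rate Bernoulli changepoint of the indicator
   $\theta_i \ge 0.35$ within one window of the coarse boundary, then
   snapped to the step grid. This reaches the information limit set by the
   spacing of diagnostic sites (2.5 kb at the default simulation), and on
   the default conditions recovers the true boundaries within one 10-kb
   step in 20/20 seeded replicates (36/40 boundaries exactly).

Calls report `span_bp = end - start` exactly and a 2-decimal `span_mb`,
matching how SLR extents are conventionally printed (boundaries at 5.40 and
13.94 Mb give a span of 8.54 Mb).

## Linkage disequilibrium

LD uses the genotype (composite) $r^2$: the squared Pearson correlation of
0/1/2 allele counts over pairwise-complete samples. This is the measure
unphased resequencing data support; haplotype-based $r^2$ would require
phasing the very region whose recombination history is in question. Decay
curves bin all within-region pairs by distance (default bins of 2.5 kb up
to 50 kb — comfortably covering the ~25-kb scale that separates decayed
autosomal LD from persistent sex-linked LD); pairs per bin are capped at
50,000 by seeded subsampling. Under independence the small-sample
expectation of $r^2$ is $1/(n-1)$, which the tests verify — "low LD" in a
40-sample panel means ~0.026, not 0.

## Gametolog trees and turnover classification

Recombination suppression starts the divergence clock of X/Y (or Z/W)
gametologs, so the *topology* of a gametolog gene tree dates suppression
relative to speciation:

* **Gametolog clustering** — all X/W copies form one clade and all Y/Z
  copies another: suppression predates the species splits. X clusters with
  W and Y with Z because a 15X→15W / 15Y→15Z heterogamety transition
  preserves haplotype identity across the turnover; the classifier treats
  X/W as one pole and Y/Z as the other.
* **Species clustering** — the two gametologs are sisters within every
  species: the region still recombined after the splits.
* **Neo-Y from X** — exactly one species' Y is the earliest-branching
  ingroup lineage and all remaining sequences (including that species' X)
  form a clade in which the other species' X and Y sets each cluster: the
  other species' sex chromosome pair derives from the focal species' X,
  the signature of a turnover in which an X acquired male-determining
  factors and the ancestral Y was lost.

The decision order is exactly that — gametolog clustering, then species
clustering, then neo-Y, else `UNRESOLVED` — so every valid input maps to
one class. Classification is topology-only (branch lengths and support
values are ignored; collapsing low-support branches is left upstream), and
trees are rooted with a declared outgroup that must be monophyletic.
Tallies across single-copy orthologs report per-class counts and the
majority class among resolved trees, with ties reported as unresolved
rather than broken arbitrarily.

Tree building for self-contained use is Jukes–Cantor distances
($d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, gaps deleted pairwise,
saturated pairs flagged `Inf`) plus neighbor-joining. NJ recovers additive
trees exactly; for the simulated scenarios (species divergence
`mutation_scale`, gametolog divergence twice that, 2-kb alignments) the NJ
tree classifies to the generating scenario in ≥95% of seeded replicates,
and the classifier is exact given the true tree.

## Gene flux, duplicates and cassettes

SLR-specific gene calls use presence/absence flags against an inferred
ancestral autosome: present in both SLR haplotypes → shared; specific to
one haplotype with an ancestral homolog → loss from the other haplotype;
specific with no ancestral hit → insertion. A gene seen only in the
ancestor is a loss from both (a case the flag algebra admits and the
classifier must cover to be total). Degeneration is reported as losses per
haplotype as a percentage of X/Y-shared SLR genes. Duplicate integrity is
exon-presence: all required exons → intact; a non-empty proper subset →
partial (flagging exon 1, the configuration relevant for ARR17-like
male-determining duplicates; the intact ARR17-like gene has 5 exons and
the MSF progenitor 14, of which Y-linked copies carry 5). Cassette
detection pairs exon-1-bearing ARR17-like partials with MSF partials
within 1 Mb by default — "close physical proximity" has no published
number, so the threshold is a visible, configurable parameter.

## The inversion association test

Pairwise synteny comparisons are tabulated 2×2 (autosome–autosome vs
sex-involved × inversion present/absent) and tested with the two-sided
Fisher exact test in the standard convention: the p-value sums all tables
with the observed margins whose point probability does not exceed the
observed one (with a 1e-7 relative guard against floating-point ties).
The implementation is checked against a direct hypergeometric enumeration
oracle to `1e-12`. The sample odds ratio is reported with 0/`Inf`
sentinels at zero cells; a zero margin yields p = 1 with a warning rather
than an error, since an all-one-class table is uninformative, not
malformed.

## What the generator emulates — and what it does not

`simulate_population()` draws background SNP frequencies uniformly on
`[maf_floor, 0.5]` (so the MAF filter is satisfied by construction),
Hardy–Weinberg binomial genotypes identical in expectation across sexes,
and — inside the SLR — a fraction `diag_site_fraction` of sites fixed
between the gametologs (females homozygous, males heterozygous under XY;
mirrored under ZW, which is the exact sex-swap of XY). Coverage is Poisson
per window with mean `depth × dose × window/read_length`; an
overdispersion model is deliberately omitted (real coverage is messier;
the CQ bands, not the simulator, are where that slack lives).

Defaults: 10-Mb chromosome, SLR 4–6 Mb, 20+20 samples, 1 SNP/kb, 2%
missingness, haploid depth 50 with 150-bp reads, 50-kb coverage windows,
100-kb/10-kb FST windows. `diag_site_fraction = 0.4`: the spacing of fixed
differences, `1/(site_density × q)`, is the information limit for boundary
localisation, and 2.5 kb supports the ±1-step (10-kb) boundary recovery
the default conditions are calibrated to; at `q = 0.2` (5-kb spacing) that
recovery rate is unattainable for any estimator.

What passing tests on this generator do **not** show about real data: no
linked background structure (every background site is independent, so PAR
LD is purely the $1/(n-1)$ floor), no recombination gradient at SLR
boundaries (real boundaries can be ragged), no mapping bias or repeat
collapse in coverage, no X/Y-shared polymorphism inside the SLR, and no
gene conversion. The generator validates the statistical machinery, not
the biology of any particular dataset.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; VCF (1-based) and GFF3
  conversions happen at the I/O boundary only. Haploid-looking genotypes
  are rejected, not imputed.
* `CQ`: 0/0 → `NaN`, F/0 → `Inf`; both label as `ambiguous` unless a rule
  applies.
* Windowed θ in windows with fewer than `min_snps` usable sites is `NA`;
  `NA` windows are removed before segmentation and indices mapped back.
  Negative windowed θ is reported as computed, clipped only at −1.
* PELT with an infinite penalty returns one segment; a constant series
  short-circuits to one segment (its variance estimate is 0).
* One RNG stream per run: every `simulate_*` call seeds once from its
  `seed` argument (or inherits the caller's stream) and draws in a fixed
  documented order, so equal seeds give identical outputs.

## Problem sizes

The test-suite simulations use a 10-Mb chromosome with ~10,000 SNPs and 40
samples (seconds per replicate); boundary-recovery and topology-recovery
properties use 20 seeded replicates each; LD and Fisher properties use
10³ randomised cases. These sizes were chosen to estimate each property's
pass rate tightly while keeping the whole suite fast enough to run on
every change.
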