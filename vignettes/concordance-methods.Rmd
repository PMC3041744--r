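---
title: "Methods: differentiation scans, line-cross QTL mapping, and their concordance"
author: "diffqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differentiation scans, line-cross QTL mapping, and their concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Two routes exist for locating genes that differ between two long-separated
populations of the same species (here: two cattle breeds, a dairy type and a
beef type). A *differentiation scan* genotypes dense SNP panels in samples of
each breed and looks for loci where allele frequencies have diverged far more
than the genomic background — candidate targets of divergent selection. A
*linkage-mapping study* crosses the two breeds, measures quantitative traits
in the F2/backcross generation, and scans the genome for QTL with a
regression F-statistic. If divergent selection acted on the measured traits,
the two maps should agree. `diffqtl` implements both analyses and the
statistics that quantify their agreement, together with a synthetic-data
generator that makes the whole pipeline testable end to end.

# Differentiation statistics

For a biallelic SNP with breed allele frequencies $p_1, p_2$:

* $\delta = |p_1 - p_2| \in [0, 1]$.
* $F_{ST}$ is estimated by the two-sample Weir–Cockerham variance-components
  estimator $\hat\theta = a/(a+b+c)$, where $a$, $b$, $c$ are the among-
  population, among-individual and within-individual components computed
  from $(p_i, n_i, h_i)$ — frequency, called sample size and observed
  heterozygote proportion per breed. The estimator adjusts for the very
  unequal sample sizes of the two panels (default 49 vs 20 individuals).
  Negative estimates are clamped to 0; the raw value is kept in the output
  (`thetaRaw`) so the clamping is auditable. Loci where both breeds are
  fixed for the same allele (mean frequency exactly 0 or 1) have no defined
  $F_{ST}$ and are removed by `restrictDefinedFst()`.

A per-locus $\hat\theta$ is a noisy ratio; averaging those ratios across loci
is biased downward by Jensen's inequality (at a true $F_{ST}$ of 0.1 the mean
per-locus ratio is about 0.085). Whenever a single genome-wide estimate is
needed — including the simulator-calibration checks — the package therefore
uses the standard multilocus combination `multilocusFst()`, the ratio of
summed components $\sum_\ell a_\ell / \sum_\ell (a+b+c)_\ell$, which is
calibrated (0.100 ± 0.01 at 20,000 loci in the test conditions).

## Tracks: binning, smoothing, top fractions

Positions are rounded to the nearest 100 kb and loci sharing a rounded
position are averaged with equal weight (`binTrack()`). Ties at exactly
50 kb round *up*; this is deterministic and matches the plain reading of
"nearest", and a banker's-rounding alternative is available for sensitivity
checks. `movingAverage()` then slides an 11-value window over the
*occupied* bins of each chromosome: the smoothed value at occupied bin $i$
is the mean of bins $i-5 \dots i+5$, so each chromosome loses its first and
last 5 positions and a track of $L$ bins yields $L-10$ smoothed values.
Sliding over occupied bins (rather than fixed 100-kb grid steps with gaps)
is the default because gaps in marker coverage should not be padded with
phantom zeros; a grid-indexed mode (`mode = "grid"`, averaging occupied
bins within ±500 kb) is provided for sensitivity analysis.

`topFraction(track, q)` pools all values genome-wide, takes the empirical
$1-q$ quantile, and reports positions *strictly* above it — so a fully tied
track reports nothing, and 1,000 distinct values at $q = 0.01$ report
exactly 10 positions.

# Line-cross interval mapping

The cross is analysed under the classical line-cross assumption: the founder
breeds are fixed for alternative QTL alleles ($Q$ in line 1, $q$ in line 2),
so allele origin equals breed origin. At each grid position (every 100 kb
between the terminal markers of a chromosome) the conditional probabilities
of the three QTL genotypes are computed from the nearest informative
flanking markers by enumerating the parental gamete transmission patterns
with Haldane recombination fractions $r = (1 - e^{-2d/100})/2$ for map
distance $d$ cM — double recombinants within a flanking interval are
handled exactly, assuming no interference. Missing flank genotypes are
skipped outward to the nearest non-missing marker; a position with a single
informative flank conditions on that marker alone, and one with none falls
back to the cross-type prior (1/4, 1/2, 1/4 for F2). Backcross individuals
receive a fixed allele from the recurrent line, so only the F1 gamete is
uncertain and homozygotes for the non-recurrent line are impossible (and
rejected as data errors).

The Haley–Knott regression fits, by ordinary least squares,

$$y = \text{fixed effects} + a\,x_a + d\,x_d + e, \qquad
  x_a = P(QQ) - P(qq),\; x_d = P(Qq),$$

against the fixed-effects-only reduced model; the reported statistic is the
partial F-ratio with $q = 2$ numerator degrees of freedom. The
genetic-composition effect (F2/CB1/HB1) is always in both models; other
fixed effects are configured per trait; individuals with missing phenotype
or covariates are dropped listwise (no imputation). F2 and backcross data
are pooled in one model — dominance is estimated from the pooled design,
and if $x_d$ is confounded (a pure backcross subset) the test drops to
$q = 1$ automatically. `fMax()` records, per position, the maximum F over
all analysed traits and the trait attaining it.

Numerically the scan residualizes $y$, $x_a$ and $x_d$ against the QR basis
of the fixed-effect design once and computes each position's F from 2×2
cross-products — algebraically identical to refitting two linear models per
position (the tests verify agreement with `lm()`/`anova()` to $10^{-8}$)
but orders of magnitude faster, which is what makes the permutation
thresholds cheap. Rank deficiency is detected on the 2×2 Gram matrix with a
relative determinant tolerance of $10^{-10}$; a phenotype explained by the
fixed effects to within $10^{-12}$ of its total sum of squares yields F = 0
rather than numerical noise.

Significance thresholds follow the permutation approach standard for such
crosses: phenotype-and-covariate rows are permuted jointly against the
genotype rows — implemented as the inverse permutation of the genotype
scores, which leaves the fixed-effect basis intact — within generation
class, and the scope-wide maximum F is recorded per permutation; the
threshold is the empirical $1-\alpha$ quantile. The exact stratification
used in the original analyses of such herds is not recoverable, so this
scheme is a reconstruction; its calibration is itself tested (fresh null
scans are rejected at 4–5% for a nominal 5%). The default named thresholds
F = 5, 7, 10 correspond to approximate chromosome-wise 5%, chromosome-wise
1% and genome-wide 1% significance for a herd of ~500 individuals; the
package's own permutation estimate of the chromosome-wise 5% point on a
30-Mb chromosome is ~4–4.6, consistent with the conventional 5.

# Concordance

`alignTracks()` inner-joins the Fmax grid with the binned and smoothed
differentiation tracks on (chromosome, 100-kb position). The unsmoothed
δ/F~ST~ columns are the *bin-averaged* values: correlating raw per-locus
values against a gridded Fmax would compare quantities on different
supports. Concordance is then quantified three ways:

1. **Correlations** (`trackCorrelations()`): Fmax against each of δ,
   F~ST~, MA~δ~, MA~F_ST~, per chromosome and genome-wide. Pearson is the
   default (Spearman by flag). The genome-wide coefficient pools all rows;
   since one could also average per-chromosome coefficients, both are
   reported (`genome` and `genome_chrom_mean` rows).
2. **Threshold-grouped means** (`thresholdGroupMeans()`): positions are
   split at each F threshold into highF (strictly above; ties go to lowF)
   and lowF groups, and each measure is averaged per group per chromosome.
   Chromosomes with no highF positions are excluded for that threshold.
3. **One-tailed Wilcoxon signed-rank tests** (`concordanceTests()`): one
   pair per chromosome (highF mean vs lowF mean), alternative "highF
   greater". Zero differences are dropped with a count; tied absolute
   differences are midranked. The null distribution is exact up to 25
   pairs, computed by convolution over doubled ranks (doubling keeps
   midranks integral); beyond that a normal approximation with continuity
   and tie correction is used. The exact path is verified against full
   $2^n$ sign enumeration.

`subsetReanalysis()` rebuilds the tracks from a subset of loci selected by
SNP discovery-panel label and recomputes the correlations — the
ascertainment-bias check — and compares mean δ between retained and
excluded loci with a rank-sum test.

# The synthetic-data generator

The generator defines the study conditions under which everything above is
tested; it is first-class, tested code.

**Breeds.** Per-breed allele frequencies follow the Balding–Nichols model:
each breed's frequency at a neutral locus is an independent
$\mathrm{Beta}\!\left(p_0\frac{1-F}{F},\,(1-p_0)\frac{1-F}{F}\right)$ draw
around a shared ancestral frequency $p_0$, giving mean $p_0$ and variance
$F p_0(1-p_0)$. This is the minimal standard model matching a target
background $F_{ST}$; $F = 0$ degenerates cleanly to both breeds inheriting
$p_0$. Ancestral frequencies are uniform on (0.05, 0.95) so that few loci
are lost to the defined-$F_{ST}$ filter. "Selected" loci are set to their
target frequencies exactly — typically (1, 0), emulating loci fixed for
alternative alleles around a major gene. Genotypes are Binomial(2, p)
within breed (Hardy–Weinberg), with optional uniform missingness.

**Cross.** A three-generation pedigree mirrors a classical beef × dairy
resource herd: 7 founder sires of line 1 mated to line-2 dams give 137 F1;
8 F1 sires and F1 dams give 315 F2; backcrosses to each founder line give
88 (CB1) and 98 (HB1) individuals. Gametes are formed by a Markov walk
along each chromosome with Haldane recombination fractions between
adjacent loci. Markers are biallelic and fully informative by default
(founder lines fixed for alternative marker alleles) — a stand-in for the
multi-allelic microsatellites such studies genotyped; an option draws
founder marker alleles from per-line frequencies instead. QTL are carried
as latent loci always fixed for alternative line alleles. The default map
is linear at 1 cM per Mbp with markers every 15 cM, the sparse density
typical of microsatellite linkage studies.

**Phenotypes.** $y = \mu + \text{generation effect} + \text{fixed effects}
+ \sum_{\text{QTL}} [a(n_Q - 1) + d\,\mathbf{1}\{\text{het}\}] + N(0,
\sigma^2)$. Fixed-effect levels (e.g. sex) are assigned uniformly at
random, once per individual, consistently across traits.

**Seeds.** One global seed; each stage derives a child seed from an FNV-1a
hash of its label (`childSeed()`), so stages are independently
reproducible and bit-for-bit identical under the same configuration.

**What the generator does not emulate.** Loci are drawn independently, so
there is no linkage disequilibrium between markers *within* a breed; the
smoothing behaviour of real data, which is partly LD-driven, is therefore
only structurally exercised (selected loci placed within one window do
produce correlated bins, but background LD is absent). There is no
SNP-ascertainment model beyond the panel labels, no mutation, no X
chromosome, and no coalescent ancestry. Passing tests demonstrate the
statistics, their calibration and their wiring — not that real cattle data
would show any particular concordance level.

# Default parameters

| Parameter | Default | Why |
|---|---|---|
| breed sample sizes | 49, 20 | large dairy panel vs small beef panel, the sampling regime the estimator must adjust for |
| background $F_{ST}$ | 0.1 | typical differentiation between European cattle breeds |
| SNP density | 10 / Mbp | genome-wide SNP-array density of the era |
| QC | MAF ≥ 0.05, missing ≤ 0.10, HWE $p \ge 10^{-4}$ per population | conventional SNP-array QC; the HWE test is per-population because pooling diverged breeds rejects via the Wahlund effect, which is not a genotyping fault |
| cross design | 137 F1, 315 F2, 88 + 98 BC, 7 sires | classical resource-herd design |
| marker spacing | 15 cM | microsatellite-era linkage map density |
| bin / window / grid | 100 kb / 11 bins / 100 kb | matched coordinate system for both analyses |
| F thresholds | 5, 7, 10 | approximate chromosome-wise 5%, 1% and genome-wide 1% levels for this design |

The demonstration genome (three chromosomes of 60/50/40 Mb) and the test
problem sizes (e.g. 20,000 loci for calibration, 50 replicate herds for
localization, 20 replicate pipelines for the null check) are package
choices balancing Monte-Carlo error against a test suite that runs in
minutes on one core.

# Known limitations

* Exactly two populations; no multi-population $F_{ST}$, no
  haplotype-based statistics.
* Single-QTL scan model; no epistasis, no multi-QTL or variance-component
  mapping, no confidence intervals for QTL location.
* The trio-based genotype-error QC of array pipelines needs family data
  the package does not model; the audit table carries an `error_rate`
  category (always 0) so report formats stay stable.
* Correlation significance is not corrected for spatial autocorrelation of
  the smoothed tracks, and the Wilcoxon tests are reported at nominal
  levels without multiplicity correction across thresholds and measures.
* Phenotype variation below ~$10^{-6}$ of the phenotype's root mean square
  is treated as numerically constant by the scan.
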