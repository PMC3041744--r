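# diffqtl

Concordance between breed differentiation scans and line-cross QTL mapping.

## The problem

Dense SNP panels make it cheap to scan two populations — here, two cattle
breeds — for genomic regions of unusually strong allele-frequency
divergence, the classic signature of divergent selection. Whether such
scans actually find the regions controlling the traits that differ between
the populations is an empirical question, and answering it needs an
independent map of trait loci: a linkage-mapping experiment in a cross of
the same two breeds. `diffqtl` implements both sides of that comparison
and the statistics that quantify their agreement, for geneticists studying
the power of differentiation-based "selection mapping".

## What it computes

**Differentiation scan.** For each biallelic SNP with breed frequencies
p₁, p₂ (sample sizes n₁, n₂, observed heterozygosities h₁, h₂):

* δ = |p₁ − p₂|, and
* F_ST by the two-sample Weir–Cockerham variance-components estimator
  θ̂ = a/(a + b + c), which adjusts for unequal sample sizes; negative
  estimates are clamped to 0 and loci with mean frequency 0 or 1 are
  dropped as undefined.

Positions are rounded to the nearest 100 kb and averaged per bin, then
smoothed with an 11-position centered moving average (MA_δ, MA_F_ST);
top-1%/0.1% regions are extracted as BED/TSV.

**Interval mapping.** Haley–Knott line-cross regression for an F2 +
reciprocal-backcross herd: conditional QTL genotype probabilities from
flanking markers under Haldane recombination, phenotype regressed on
fixed effects + additive (x_a) and dominance (x_d) scores every 100 kb,
partial F-ratio per trait, and F_max — the across-trait maximum — per
position, with Churchill–Doerge-style permutation thresholds.

**Concordance.** Per-chromosome and genome-wide correlations of F_max with
δ, F_ST and their moving averages; per-chromosome highF/lowF group means at
F thresholds (default 5, 7, 10) with one-tailed exact Wilcoxon signed-rank
tests; and discovery-panel subset reanalysis for ascertainment bias.

**Synthetic data.** A Balding–Nichols two-breed simulator (target
background F_ST, loci fixed for alternative alleles around major genes)
and a three-generation cross simulator (7 founder sires, 137 F1, 315 F2,
88 + 98 backcrosses, Haldane recombination, additive + dominance QTL)
make the full pipeline reproducible without external data.

## Worked example

The bundled demonstration configuration simulates three chromosomes, two
breeds (49 + 20 individuals) at background F_ST 0.1 with five loci fixed
for alternative alleles around a major dominant QTL at 30 Mbp on
chromosome c1, and a 501-animal cross measured for three traits:

```r
library(diffqtl)
res <- runPipeline(defaultConfig(seed = 1), "demo-run")
res$panel
#> GenotypePanel: 69 individuals x 1505 loci
#>   populations: breed1 (49), breed2 (20)
#>   chromosomes: c1, c2, c3
#>   missing dosage fraction: 0.0100
res$scan
#> ScanResult: 1350 grid positions, 3 trait(s)
#>   max Fmax = 686.778 at c1:29600000 (trait coatScore)
subset(res$correlations, chrom %in% c("c1", "genome") &
                         measure %in% c("delta", "maDelta"))
#>  chrom measure         r   n
#>     c1   delta 0.1287993 354
#>     c1 maDelta 0.3441638 354
#> genome   delta 0.0792625 788
#> genome maDelta 0.2368433 788
```

The scan localizes the major QTL (peak F_max = 687 at 29.6 Mbp, true
position 30 Mbp), and the smoothed differentiation track peaks at 30.0
Mbp — the fixed-difference loci flanking the QTL. The correlations show
the study's characteristic pattern: weak genome-wide concordance between
F_max and δ (0.079), strengthened by smoothing (0.237) and strongest on
the chromosome carrying the major gene (0.344). `renderReport("demo-run")`
draws the per-chromosome F_max/MA_δ overlays, the highF-vs-lowF group-mean
scatter, and a per-chromosome summary table.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/diffqtl-run.R run --config my.yaml --out run1 --seed 7
```

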