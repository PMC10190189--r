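---
title: "GBS-MeDIP differential methylation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GBS-MeDIP differential methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbsmedip)
```

## The assay and the analysis problem

GBS-MeDIP libraries reduce a genome twice before sequencing. A restriction
digest (PstI, recognition site `CTGCAG`, cut after the fifth base) fragments
the DNA; only fragments of 200–500 bp survive size selection, so the library
interrogates a reproducible minority of the genome. Each sample's fragments
carry a barcode, the samples are pooled, and an anti-methyl-cytosine antibody
enriches the pool for fragments carrying methylated CpGs. Sequencing coverage
of a fragment is therefore a proxy for its methylation level, and a
between-group difference in coverage at a locus is evidence of differential
methylation.

The pipeline in this package takes demultiplexed, aligned fragments to
differentially methylated regions (DMRs) in five stages:

1. **Stacked-read filtering.** PCR amplification can place many identical
   read pairs on one genomic position. Per sample, the per-position read
   count is modelled as Poisson with rate `lambda` estimated as total
   fragments over distinct `(chrom, start, strand)` positions; the smallest
   count `n*` whose upper tail falls below `p = 0.001` is treated as
   amplification excess and at most `max(1, n* - 1)` reads are kept per
   position. The floor of one read reconciles the limit `lambda -> 0` (any
   duplicate is excess, but the first read is real) with the general rule.
2. **ROI calling.** Group-merged fragment pools are compared in 300 bp
   windows stepped every 100 bp. Each window is scored in both directions as
   a Poisson upper tail `P(X >= x_t)` at rate
   `max(x_c * N_t / N_c, window_bp * N_t / genome_bp)` — the depth-scaled
   control count with a genome-background floor. Windows reaching
   Benjamini–Hochberg `q <= 0.1` in either direction are merged into regions
   of interest (ROIs). Scoring both directions and taking the union keeps the
   procedure symmetric in the group labels.
3. **Counting and normalization.** Fragments are counted per ROI per sample
   (any 1 bp overlap counts). Size factors are median-of-ratios (with a
   total-count fallback below ten informative ROIs), rescaled to geometric
   mean one. The CpG *coupling* value of an ROI (its CpG count) drives a
   descriptive calibration: mean raw count per integer coupling bin, an OLS
   line through the ascending low-coupling portion (bins up to the maximum
   mean — beyond it antibody saturation bends the curve), and relative
   methylation scores `rms = count / max(predicted, predicted at c = 1)`.
   The rms layer is for display; testing runs on raw counts.
4. **Differential testing.** ROIs whose count sum over the contrast samples
   is below `minRowSum = 10` are dropped. For each remaining ROI the two
   group totals are compared with a conditional negative-binomial exact test
   (below), BH-adjusted across tested ROIs. Two significance tiers are kept
   independently: *exploratory* DMRs at `p <= 0.05` and *top* DMRs at
   `q <= 0.6`.
5. **Interpretation.** DMRs are annotated against gene models (midpoint rule,
   precedence Promoter > Exon > Intron > Downstream > Distal Intergenic;
   promoter = 3 kb upstream of the TSS in 1 kb sub-bins, downstream = 300 bp
   after the TTS; intergenic regions take the nearest gene by absolute TSS
   distance), TSS distances are binned by leading digit times power of ten,
   cross-contrast overlaps are counted on the connected components of the
   overlap graph and tested by chromosome-matched, length-preserving uniform
   relocation (`N = 100` permutations, add-one p-value estimator), and
   DMR-related genes feed a hypergeometric over-representation test against
   a GMT gene-set collection, reported at BH `q <= 0.1`.

## The conditional exact test

Let `t1, t2` be the two group totals at one ROI, `T = t1 + t2`, with `n_g`
samples and summed size factors `S_g` per group. Under the null of equal
per-sample-adjusted means, the package models the split of `T` with a
Dirichlet-multinomial kernel with sizes `r_g = n_g / phi` tilted by the
relative group rates:

$$w(t_1) \propto
\frac{\Gamma(t_1 + r_1)}{t_1!\,\Gamma(r_1)}
\frac{\Gamma(T - t_1 + r_2)}{(T - t_1)!\,\Gamma(r_2)}
\rho^{t_1},\qquad
\rho = \frac{S_1 n_2}{S_2 n_1}.$$

The two-sided p-value sums the normalized probabilities of all splits no more
probable than the observed one. As `phi -> 0` the kernel collapses exactly to
the conditional binomial with success probability `S1 / (S1 + S2)` — the
classical Poisson-limit conditional test — which is what the brute-force
oracles in the test suite enumerate. Totals above 5000 switch to a
moment-matched normal approximation (mean `T pi`, Dirichlet-multinomial
variance inflation `(a0 + T) / (a0 + 1)` with `a0 = (n1 + n2) / phi`); at the
switch point the approximation agrees with enumeration to about 1e-2 on the
p-value scale, and the tested fixtures stay in the enumeration regime.

Dispersion `phi` is estimated per ROI by method of moments on size-factor
normalized counts after centering group means, `phi = max(0, (s^2 - mu) /
mu^2)`, shrunk towards a 20%-trimmed common value with prior weight
`n0 = 10`. Shrinkage stabilizes the small-sample estimates; on Poisson data
the common dispersion lands near zero and the exact test is effectively the
conditional binomial.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested against a
known truth without any external download. It emulates, in order: an i.i.d.
background genome at a chosen GC content with planted CpG-dense islands and
planted PstI sites (mean spacing 350 bp, so a realistic share of digestion
fragments falls in the 200–500 bp selection window at desk scale); exact
in-silico digestion; a per-CpG methylome (baseline probability 0.2 outside
islands, 0.8 inside, by default) with `n_dmrs` planted fragments whose CpG
probabilities shift by `±delta` in one group; and antibody capture with the
saturating law

$$P(\text{capture} \mid m) = (1 - \varepsilon)\frac{m}{m + \kappa}
+ \varepsilon,$$

`m` the molecule's methylated CpG count, `kappa = 1` (CpGs at half
saturation) and background rate `epsilon = 0.01` by default. Molecules are
drawn multinomially over the selected fragments with these capture weights.

Two generator semantics deserve emphasis:

* **Pooled-library depth.** Per-sample depth is Poisson with mean scaled by
  the sample's total capture yield. The immunoprecipitation acts on the
  barcoded pool, so a methylome that captures more material contributes
  proportionally more read pairs. This matters statistically: if depth were
  forced equal per sample, multinomial renormalization would couple every
  null fragment to the planted ones and bias the null toward false
  positives; with yield-proportional depth the sequencing rate of unaffected
  fragments is identical across groups.
* **Two-direction planting.** Each planted DMR is assigned to a uniformly
  drawn group, so a contrast sees hyper- and hypomethylation in both
  directions — as real studies report — and the planted signal stays
  balanced, which keeps the median-of-ratios normalization unbiased. A
  fragment is only plantable when the whole `±delta` shift keeps every one
  of its CpG probabilities inside `[0, 1]`; fragments straddling an island
  boundary mix methylation levels and may support neither direction.

Reads are serialized as a multiplexed paired FASTQ pool: read 1 is
`barcode + CTGCA + fragment 5' sequence`, read 2 the reverse complement of
the fragment 3' end, 100 bp each, fixed "I" qualities, optional uniform
substitution errors. Demultiplexing requires an exact barcode + remnant
prefix match — no mismatch rescue, because determinism is worth more at desk
scale than a percent of rescued reads.

What the generator does **not** emulate: PCR duplicate structure beyond the
stacked-read phenomenon, quality-score realism, indels, alignment ambiguity
(truth alignments stand in for the external aligner), CpG-density-dependent
fragmentation biases, and copy-number variation. Passing tests on synthetic
data therefore validate the statistical machinery and the format plumbing,
not the behaviour of any aligner or the biology of a particular genome.

## Fixture designs used by the acceptance checks

The test suite fixes every simulation seed. Problem sizes were chosen once,
by the following design arguments, and then frozen:

* **Null calibration** runs 9 vs 9 samples with no planted signal on a
  2 × 1.3 Mb genome (≈2,500 selected fragments as the tested region
  universe, mean ≈20 counts per ROI and sample). The observed fraction of
  p-values at or below 0.05 must lie in `[0.03, 0.07]`; mild conservatism is
  expected from test discreteness and dispersion shrinkage.
* **Window-level false calls** are measured by calling ROIs between two
  independently sampled pools from the same methylome over 20 seeds; the
  window-space fraction inside called ROIs must stay below the nominal
  `q <= 0.1` level.
* **Planted-DMR recovery** uses a 120 kb genome (≈120 selected fragments),
  baseline methylation 0.1, `delta = 0.5`, `kappa = 1`, 20 planted DMRs,
  9 vs 9, mean ≈40 counts per ROI and sample. At `kappa = 1` the capture
  curve saturates quickly, so a `delta = 0.5` gain is a strong (≈1.4–1.6×)
  coverage effect only on a hypomethylated background — that choice is what
  makes 80% sensitivity reachable at this depth. Keeping only ≈100 null
  fragments holds the expected false-discovery proportion among p ≤ 0.05
  calls near `100 × 0.05 / (100 × 0.05 + 20) ≈ 0.2`, inside the 0.3 bound
  with margin.
* **Enrichment-score monotonicity** uses shallow sequencing (≈60 molecules
  from one sample) of a 300 kb island-rich genome. The score compares CpG
  density inside the covered interval union with the genome; at high depth
  the union saturates toward the whole selected-fragment space and the score
  trends to that space's density regardless of capture bias, so sub-saturating
  breadth is the regime in which the score is informative. `kappa = 3` and a
  strongly contrasted methylome keep the three settings ordered.

## Numerical and convention choices

* All in-memory intervals are `GRanges` (1-based closed); BED is converted at
  the file boundary (0-based half-open), GFF3 and SAM are 1-based. Region
  midpoints use the floor of the half-open midpoint, matching the worked
  promoter example (`[7500, 7600)` against a TSS at 10,000 gives −2,450).
* CpGs are counted by their start position: a CpG starting on a region's
  last base counts for that region.
* The exact test compares split probabilities on the log scale with a `1e-7`
  relative tolerance when collecting "no more probable" splits, and clamps
  the summed p-value at 1.
* Venn components merge only genuinely overlapping ranges
  (`min.gapwidth = 0`); bookended regions never merge, consistent with the
  half-open overlap rule.
* Permutation p-values use `(1 + #{perm >= obs}) / (N + 1)`, which cannot be
  zero at `N = 100`.
* ROI merging joins overlapping and bookended significant windows
  (step < window guarantees bookending within a contiguous significant run).
* The ORA universe defaults to the genes carrying at least one tested ROI,
  not the whole annotation: a reduced-representation assay can only ever
  implicate genes it covers, and a whole-genome universe would inflate
  enrichment.
* Degenerate inputs: empty gene sets annotate everything Distal Intergenic
  with `NA` gene; single-coupling-bin calibration and all-zero count
  matrices are errors; a zero-CpG molecule pool with `epsilon = 0` yields
  zero reads.

## Known limitations

* The conditional exact test treats size factors as fixed and groups as
  exchangeable given them; strong one-sided composition differences between
  groups beyond what median-of-ratios can absorb will inflate the null.
* Dispersion shrinkage with `n0 = 10` is tuned for the 4–9 samples-per-group
  regime; with many samples it over-shrinks slightly (conservative).
* The annotation is transcript-naive: one interval per gene, no UTR classes
  unless exon structure encodes them, no isoform resolution.
* The permutation null relocates regions uniformly within chromosomes (or a
  supplied universe); it does not match GC content, gaps, or local coverage
  structure.
* Windows are scored as independent in the BH step although neighbouring
  windows share fragments; the merged-ROI q is the best contributing window
  q, a display convention rather than a region-level error rate.
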