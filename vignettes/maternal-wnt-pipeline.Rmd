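---
title: "Calling direct maternal Wnt/β-catenin targets: models, parameters and design"
author: "maternalWnt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling direct maternal Wnt targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind each pipeline stage, the tunable
parameters and their defaults, what the synthetic-study generator does and
does not emulate, and the numerical choices that matter. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## The two-class model of direct maternal Wnt targets

Maternal β-catenin activity produces two temporally distinct cohorts of
zygotic target genes. First-class genes (the *siamois*/*nodal3* cohort)
switch on at the first surge of zygotic transcription (stage 7–7.5 onsets)
and show β-catenin binding *before* ZGA only. Second-class genes
(*goosecoid*, *noggin*, *chordin*-type) switch on about an hour later
(onsets after stage 8 up to 9.5) and keep β-catenin binding into
gastrulation. A direct target must satisfy both a transcriptional criterion
(knockdown-and-rescue responsive) and a binding criterion (a nearby peak at
the appropriate stages); genes regulated without stage-7 binding are called
indirect. First-class gene products feed forward onto second-class genes:
with all three edges activating, this is a coherent type-1 feedforward
loop, which the epistasis module tests genome-wide.

## Coordinate and container conventions

All intervals live in `GRanges` (1-based, closed), the canonical container
of the R genomics stack. BED input/output is converted at the file boundary
(BED is 0-based half-open on disk), GFF3 maps directly. This keeps a single
in-memory convention and delegates overlap arithmetic to IRanges. The TSS
is stored as a 1-based position, strand-aware (leftmost base for `+` genes,
rightmost for `-`). Stage labels are exact decimal codes from
`stageVocabulary()`; all ordering goes through the vocabulary index, never
through floating-point arithmetic on derived values.

## Differential expression: moderated NB Wald test

`testContrast()` normalizes by median-of-ratios size factors (geometric-mean
reference over zero-free genes; total-count fallback with a warning when no
zero-free gene exists). Per gene, the dispersion is estimated by the method
of moments within each contrast group and averaged. With triplicates this
estimator is very noisy, so it is *moderated*: shrunk halfway toward the
mean moment dispersion across all genes (`priorWeight = 0.5`), floored at
1e-8. The Wald statistic for the log ratio of group means is referred to a
t distribution with `n1 + n2 - 2 + priorDf` degrees of freedom
(`priorDf = 8`), crediting the shrinkage target with eight effective
degrees of freedom. This combination was chosen because, in null
simulations at the study's design point (3 replicates, dispersion
0.01–0.2, log-normal mean counts), its empirical type-I error at p < 0.05
sits within 0.04–0.05, whereas an unmoderated estimator with a normal
reference is badly anticonservative and an unmoderated t with residual df
is calibrated but too weak to detect the planted effects after FDR
correction. A half-count pseudo-mean regularizes fold changes; all-zero
genes return (lfc 0, p 1) by definition.

`callRegulatedGenes()` applies Benjamini–Hochberg per contrast across all
tested genes and calls a gene regulated only when the knockdown contrast is
significantly *down* and the rescue contrast significantly *up* (both
FDR < `alpha`, default 0.05). The two-contrast AND gate mirrors the
knockdown-then-rescue experimental logic; its null false-call rate is
quadratically small, which the acceptance suite verifies.

## Surge classification

Induction onset is the earliest sampled stage with expression ≥ 20,000
transcripts/embryo (inclusive crossing — the threshold definition does not
state strictness, and inclusive is the documented choice). No interpolation
is performed: onset resolution equals sampling resolution. The inclusion
filter requires < 10,000 transcripts/embryo at all stages before 6 and
> 100,000 by stage 10. Window membership: first surge closed [7, 7.5];
second surge half-open (8, 9.5], so an exact stage-8 onset falls into the
gap and is annotated `"gap"` rather than forced into either class —
boundary genes are a remark, not a third class.

## Peak integration

Peaks are assigned to the gene with the nearest TSS within 100 kb of the
peak midpoint (configurable), ties broken toward the lexicographically
smaller gene id. The stage-wise Venn partition uses a ≥ 1 bp overlap
criterion with counts reported per side (peak widths differ between sets;
the headline shared count is the maternal-side count). Two-caller consensus
keeps caller 1's coordinates for intervals overlapping caller 2 by ≥ 1 bp.

## Permutation null for co-binding

The null re-places each A interval uniformly on its own chromosome,
preserving widths and per-chromosome counts — the simplest exchangeable
null; it destroys inter-peak spacing, so a circular-shift option is
provided for correlated landscapes. The test statistic is the total number
of A base pairs covered by the B union rather than the integer count of
overlapping A peaks: a sum of near-continuous quantities is essentially
tie-free, making the permutation p-value `(1 + #{null ≥ obs})/(nPerm + 1)`
close to exact, where the tied integer count is systematically
conservative. The reported overlap fraction still counts peaks (≥ 1 bp).

## Occupancy independence

`bindingIndependence()` computes, per locus, a 95% Welch t-interval on the
mean log occupancy ratio (treated/control), back-transformed to the ratio
scale (geometric means match the log-scale symmetry of qPCR-style data). A
locus is `reduced` only when the interval's *upper* bound falls below
`1 - margin` (default margin 0.2): a ≥ 20% drop must be demonstrated, not
merely not excluded. The qualitative no-reduction claim thus becomes an
explicit, configurable decision rule.

## Motif discovery

Seeding: canonical k-mers (collapsed with reverse complements,
lexicographically smaller representative) are tested for ZOOPS presence
enrichment in targets versus background with a one-sided hypergeometric
p-value, over k = 6–10. The background is an Altschul–Erickson Euler-path
shuffle of each target, preserving dinucleotide counts exactly.

Refinement: ZOOPS EM. Each sequence carries one site at an unknown
offset/strand or none; the E-step computes posterior window
responsibilities under the current matrix, site prior γ and uniform
positional prior; the M-step is a Dirichlet MAP update (Laplace
pseudocount 0.25), so the penalized objective — data log-likelihood plus
the Dirichlet log-prior — is provably nondecreasing, which the tests
assert. Iteration stops at a max matrix change below 1e-4 or 100 rounds.

Discovery: take the best seed, refine, record, mask hit windows with N,
repeat until `nMotifs` (default 10) or no seed with p < 0.01. Hits use a
log-odds threshold of 80% of the matrix's maximum attainable score;
windows containing N score −∞. Percentages are computed on the unmasked
originals. Known-motif matching slides both strands over all ungapped
offsets with ≥ 4 overlapping columns; the score is the mean column Pearson
correlation over the aligned span, penalized by overlap/max-width, ties to
the earlier library entry. The bundled PFM library is *synthetic*
(consensus-derived matrices named after the families they represent), used
for annotation and testing only — no database matrices ship with the
package. The discovery module does not claim numerical equivalence to any
specific external motif tool's p-values; recovery of planted TCF/LEF-like
and Foxh1-like motifs in the top ranks is the qualitative contract.

## The synthetic study generator

`simulateStudy()` derives one RNG stream per generator from the master seed
via stable labels, so adding a generator never perturbs another's output,
and a fixed seed reproduces every artifact byte for byte.

Defaults encode the modelled study design, scaled to desk size:

* **500 genes: 10 class 1, 100 class 2** — the real first-class cohort is
  exactly ten genes; the second-class count matches the order of the
  second-surge cohort (118 exclusive genes in the modelled study).
* **Counts**: negative binomial, dispersion 0.05, triplicates, conditions
  control/MO/MO_rescue at stages 8 and 9, library sizes ±30%. Knockdown
  multiplies the mean by 2^−3; the rescue mean is
  `MO + 0.9 × (control − MO)` (near-complete rescue). Target genes draw
  their expressed means from log-normal(log 1000, 0.5) — induced targets
  are strongly expressed, consistent with their time-course plateaus —
  while background genes use log-normal(log 200, 1). Second-class genes
  are essentially silent at stage 8 (mean 1–10), so they carry no
  knockdown effect there.
* **Time courses**: steep logistic ramps in stage-index space,
  parameterized so the 20,000 threshold is first reached exactly at the
  planted onset; baselines 200–5,000; plateau 300,000 transcripts/embryo.
  Noise-free by default — the surge classifier's own thresholds provide
  the discretization.
* **Peaks**: width 200 bp, placed within ±2 kb of the target TSS
  (promoter-proximal, as at the validated direct-target regulatory
  elements). The generated genome enforces a minimum intergenic gap of two
  placement windows plus one peak width, which makes every planted
  peak-to-gene link identifiable under the nearest-TSS rule. 1,000 decoy
  β-catenin peaks per stage are placed near Wnt-independent genes —
  widespread non-functional binding that pressures the regulated-gene gate
  rather than the assignment step. Foxh1 co-binding: rate 0.8 at target
  peaks, 0.5 at decoys, so the overall maternal co-binding fraction lands
  near the ~54% scale observed in embryos.
* **Sequences**: i.i.d. background at 30/20/20/30 (AT-rich), with one
  instance of the TCF/LEF consensus `CTTTGWW` planted at rate 0.5 and the
  Foxh1 consensus `AATCCACA` at rate 0.6, random offset and strand,
  non-overlapping, every instance logged.

What the generator deliberately does **not** emulate: dependence between
replicates, GC/mappability biases, peak-width and score distributions of
real ChIP, enhancer–promoter looping (assignments are distance-only),
correlated decoy placement, and — most importantly — the ambiguity of real
peak-to-gene assignment. Real genomes do not guarantee identifiability of
binding targets (the modelled study itself finds only ~82% of second-surge
genes direct), so passing recovery tests here demonstrates correctness of
the integration logic, not expected field performance on real data.

## Problem sizes and determinism

The test and acceptance workloads use: 1,000-gene × 20-seed null
simulations for DE calibration; the default 500-gene study for end-to-end
recovery; 300 sequences for motif recovery; 400 independent peak-set pairs
(300 peaks each, 199 permutations) for permutation calibration; 1,000
fuzzed instances (≤ 200 intervals) for the brute-force overlap oracle.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted tolerances. Every stochastic entry point takes an explicit seed;
`runPipeline()` threads one master seed through all stages.

## Known limitations

* The DE module is a self-contained moderated Wald test, adequate at the
  simulated design point; it does not implement outlier handling, trended
  dispersion fits, or fold-change shrinkage of mature DE packages.
* Peak–gene assignment is distance-only; no chromatin-contact information.
* The uniform re-placement null ignores accessibility structure;
  the circular-shift option mitigates but does not remove this.
* ZOOPS discovery seeds only on exact k-mers; highly degenerate motifs
  with no enriched exact core can be missed.
* `bindingIndependence()` treats replicates as independent; paired designs
  would warrant a paired interval.
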