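# maternalWnt

Integrative calling of **direct maternal Wnt/β-catenin target genes** in the
early vertebrate embryo, with a fully synthetic, ground-truth-labelled study
generator that makes every analysis stage testable end to end.

## The scientific problem

Before zygotic genome activation (ZGA), maternally supplied β-catenin
dorsalizes the embryo and primes the earliest zygotic genes. β-catenin
associates with tens of thousands of genomic sites, yet only a small set of
genes responds transcriptionally. Distinguishing *direct* targets — genes
both regulated by the pathway and carrying nearby β-catenin binding — from
bystanders requires integrating several assays:

1. **Rescue-gated differential expression.** A gene counts as maternally
   Wnt-regulated only if it goes *down* under β-catenin knockdown (MO) *and*
   back *up* under mRNA rescue, each at FDR < 0.05 (Benjamini–Hochberg per
   contrast). The package implements a negative-binomial Wald test with
   median-of-ratios normalization and moderated method-of-moments
   dispersion.
2. **Surge classification.** Staged transcripts-per-embryo profiles are
   classified by their induction onset (first stage reaching 20,000
   transcripts/embryo), subject to inclusion filters (< 10,000 before stage
   6; > 100,000 by stage 10). First-surge onsets fall in stage [7, 7.5],
   second-surge onsets in (8, 9.5].
3. **Binding persistence.** β-catenin peak sets before ZGA (stage 7) and at
   gastrulation (stage 10) are partitioned by ≥ 1 bp overlap; peaks are
   assigned to the nearest TSS within 100 kb. Class 1 targets bind at stage
   7 only; class 2 targets bind at both stages.
4. **Foxh1 context.** Co-binding fractions with permutation nulls
   (width- and chromosome-preserving re-placement; the test statistic is
   total covered base pairs), response-set Venns, and a
   ratio-CI test showing β-catenin occupancy is *not* reduced by
   Foxh1/Nodal perturbation.
5. **De novo motifs.** ZOOPS k-mer seeding (canonical k-mers,
   hypergeometric enrichment vs a dinucleotide-shuffled background), EM
   refinement to a PWM, masking, and best-match annotation against a PFM
   library — a Table-1-style ranked report.
6. **Feedforward epistasis.** Knockdown of a first-class gene product (sia)
   must leave first-class genes unaffected at stage 8 while reducing
   second-class genes at stage 9, rescuably — the signature of a coherent
   type-1 feedforward loop (W→A, A→B, W→B all activating).

## Worked example

```r
library(maternalWnt)

report <- runPipeline(pipelineConfig(
  sim   = simConfig(),                       # 500 genes: 10 class1, 100 class2
  motif = motifConfig(nMotifs = 2, kRange = 7:8)))

report$vennGenes
#  st8_only   shared st9_only
#         0       10      101
report$confusion
#                   called
# truth             class1 class2 wnt_independent_or_other
#   class1              10      0                        0
#   class2               0    100                        0
#   wnt_independent      0      1                      389
round(report$context$fraction_a_in_b, 3)
# [1] 0.56
report$motifs[, c("rank", "consensus", "best_match", "match_score")]
#   rank consensus best_match match_score
# 1    1  AATCCACA      FOXH1   0.9996905
# 2    2   TaCAAAG     TCF7L2   0.9921604
```

All ten planted first-class genes are already regulated at the onset of ZGA
and contained in the stage-9 regulated set; planted classes are recovered
from the integration of regulation, surge timing and binding persistence
(one Wnt-independent gene picks up a spurious class-2 call at this seed);
just over half of the stage-7 β-catenin peaks are Foxh1 co-bound (decoy
background 0.5, targets 0.8); and the two planted motif families are
re-discovered as the top-ranked matrices with near-perfect library matches
(`TaCAAAG` is the reverse complement of the planted TCF/LEF site family).
(Numbers above are from the default master seed; other seeds vary within
the tolerances asserted in `tests/testthat/test-acceptance.R`.)

## Package layout

| Area | Files |
|------|-------|
| Domain types / IO (BED, GFF3, FASTA, JASPAR-text PFM, TSV) | `R/AllClasses.R`, `R/io.R`, `R/stages.R` |
| Synthetic study generator | `R/synthetic.R` |
| Surge classification | `R/surge.R` |
| DE + target calling | `R/de.R`, `R/targets.R` |
| Foxh1 context analysis | `R/context.R` |
| Motif discovery | `R/motifs.R` |
| Feedforward epistasis | `R/feedforward.R` |
| Orchestration / reporting | `R/pipeline.R` |

The methods vignette (`vignettes/maternal-wnt-pipeline.Rmd`) documents the
models, parameter choices, numerical details and limitations.
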