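# chromatlas

Chromatin-state segmentation and tissue-specific enhancer modules for
multi-tissue epigenomes.

`chromatlas` is for genomicists building regulatory-element atlases from
histone-mark (CUT&Tag/ChIP) and accessibility (ATAC) data across several
tissues — the kind of study that profiles five reproductive tissues with
H3K4me3, H3K4me1, H3K27ac, H3K27me3 and ATAC in replicate, segments the
genome into chromatin states, and asks which strong active enhancers
(EnhA) are specific to each tissue and which genes they regulate.

## What it computes

**Binarization.** Per tissue and mark, replicate-pooled bin counts are
called against a Poisson background: with genome-wide mean &lambda;&#770;,
a bin is "on" iff its count reaches the smallest integer *c* with
*P*(X &ge; c | Poisson(&lambda;&#770;)) &le; 10&#8315;&#8308;.

**Segmentation.** A K-state hidden Markov model with multivariate
Bernoulli emissions: each state *k* has a probability *E(k, m)* of
showing mark *m*, marks conditionally independent given the state. The
model (&pi;, *A*, *E*) is learned by Baum-Welch over all tissues jointly
(scaled forward-backward in C++), decoded per tissue by Viterbi, and
run-length-encoded into state intervals.

**State naming.** Learned states get the standard 15-label vocabulary
(TssA, TssAHet, TssBiv, TxFlnk, TxFlnkWk, TxFlnkHet, EnhA, EnhAMe,
EnhAWk, EnhAHet, EnhPois, ATAC_Is, Repr, ReprWk, Qui) in six functional
categories, via an explicit rule cascade over binarized emissions and
TSS-window fold enrichment.

**TSR modules.** Merged cross-tissue EnhA union regions are scored 0/1
per tissue by &ge;1 bp overlap (the RRAT matrix); regions present in
exactly one tissue form that tissue's specific module, regions present in
exactly the three uterine tissues form the uterine-common module. Regions
are linked to target genes that share a TAD (region midpoint and gene TSS
in the same TAD).

**Enrichment.** PWM scanning with log2-odds scores on both strands, and
one-sided hypergeometric enrichment (Benjamini-Hochberg FDR, q < 0.05,
top five reported) for motifs (per-sequence presence/absence) and gene
terms.

A seeded synthetic generator (`simulate_epigenome()`) produces the whole
study design — 5 tissues &times; 2 replicates &times; (4 marks + ATAC +
RNA) = 60 libraries — with planted tissue-specific and uterine-common
enhancer blocks, TAD-linked target genes and planted motifs, so the full
pipeline is testable against known truth.

## Worked example

```r
library(chromatlas)
cfg <- pipeline_config(outdir = "demo_run", seed = 1)
report <- run_pipeline(cfg)
```

The run writes artifacts (binarized calls, model JSON + emissions table,
BED4/BED9 segmentations, RRAT TSV, module BEDs, enrichment tables) under
`demo_run/` and prints a report (`demo_run/report.txt`) ending with:

```
TSR module counts:
       ovary_specific      oviduct_specific       cervix_specific
                   78                    68                    64
cornua_uteri_specific corpus_uteri_specific        uterine_common
                   65                    64                     9
           unassigned
                    5
Five tissue-specific modules total: 339
Planted specific-block recovery: 99.0% (100 blocks); uterine-common misclassified as single-tissue: 0 of 8
```

Reading it: of the 100 planted tissue-specific enhancer blocks, 99 were
recovered in their intended module after the full binarize &rarr; learn
&rarr; decode &rarr; label &rarr; classify chain; none of the 8 planted
uterine-common blocks leaked into a single-tissue module. Module counts
exceed the planted numbers because the background chain also produces
genuine (unplanted) tissue-specific enhancers. The per-state table above
it reports element counts, mean sizes, genome coverage and non-redundant
(cross-tissue merged) element totals per named state — e.g. the learned
EnhA state covering 1.5% of the genome with mean element size ~550 bp,
against 74.8% quiescent.

The enrichment section reports, per tissue module, the top-5 significant
motifs; the planted motif ranks first with q &asymp; 10&#8315;&#8308;&#8315;
in every tissue under the default design.

## Package layout

- `R/synthetic.R` — seeded multi-tissue epigenome generator with ground truth
- `R/signal.R` — binning, z-score QC, correlation/PCA, Poisson binarization
- `R/hmm.R`, `src/hmm.cpp` — Bernoulli-emission HMM (EM, Viterbi, posterior)
- `R/annotate.R` — state naming rules, TSS enrichment, summaries, NRRET
- `R/tsr.R` — RRAT matrix, module classification, TAD target linking
- `R/enrichment.R` — PWM scanning, hypergeometric motif/term enrichment, BH
- `R/pipeline.R` — `run_pipeline()` orchestrator and run report
- `inst/cli/chromatlas.R` — thin command-line wrapper (`simulate`, `run`)
- `vignettes/chromatlas-methods.Rmd` — model, assumptions, design choices
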