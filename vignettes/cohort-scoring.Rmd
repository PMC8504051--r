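---
title: "Scoring recurrently altered genes in two somatic-mutation cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring recurrently altered genes in two somatic-mutation cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accuscore)
```

## The problem

Small tumour cohorts — here the motivating case is effusion-associated
diffuse large B-cell lymphoma, nine samples against a 22-sample nodal
comparison cohort — do not support the usual recurrence statistics:
with n = 9, almost nothing recurs at a single base. accuscore
implements two complementary gene scores designed for this regime.

The **accumulation score** pools evidence across the cohort. A gene is
interesting either because a mutation carries high allele fraction in
many samples, or because different samples' mutations land within a few
base pairs of each other — the kataegis/regional-mutation-density
intuition that closely spaced mutations tend to share functional
impact. Both signals enter one number per mutation:

$$\mathrm{Acc}^{(i)} = \frac{1}{n}\sum_{k=1}^{n} AF_{k,i} \;+\;
\frac{1}{\log(d_{\min}(i)+1)+1},$$

with $AF_{k,i}$ the tumour variant allele fraction of mutation $i$ in
sample $k$ (0 for non-carriers) and $d_{\min}(i)$ the base-pair
distance to the nearest other distinct mutation of the same gene,
pooled over all samples of the cohort. The gene score is the maximum
over its mutations. The first term lies in [0, 1] and is maximal when
every sample carries the mutation clonally; the second lies in (0, 1]
and is maximal (exactly 1) for co-located mutations, decaying slowly
with distance.

The **consensus pathogenicity score** works per sample. Four
interpreter channels (InterVar, ClinVar, SIFT, CADD) judge each
mutation; the channels disagree routinely, and the method resolves
disagreement by optimism: the per-mutation consensus is the most
pathogenic channel's signed score. Per gene and sample, pathogenic
consensus scores (> 0) are summed; a gene with no pathogenic mutation
scores 0 if any mutation is a VUS, and otherwise keeps its least-benign
negative score. The bins benign ($s<0$), VUS ($s=0$), low
($0<s<10$), mid ($10\le s\le 20$) and high ($s>20$) drive the
gene-by-sample class matrix, and genes pathogenic in at least five
samples form the recurrence list.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `maf_threshold` | 0.01 | population-MAF cutoff; records **strictly above** it are removed. Records annotated exactly at 0.01, and records with no annotation, are retained — a frequency filter cannot reject a record that lacks frequency data. |
| `keep_consequences` | 6 protein-changing terms | exonic/splicing consequences retained; synonymous SNVs and non-exonic (`other`) records are dropped. |
| `log_base` | natural | base of the distance-term logarithm. The method's description writes an unqualified log; the base changes the decay rate (and can reorder genes whose AF terms differ), so it is an explicit, recorded knob with natural log as the default and 10 and 2 as alternatives. |
| `min_samples` | 5 | recurrence threshold, in samples, for both the pathogenic and the mutated gene lists. |
| interpreter mapping | `inst/extdata/interpreter_mapping.yaml` | raw-verdict to signed-score transformation per channel. |

## Numerical and design choices

Several points are underdetermined by the formulas above; the package
resolves them as follows.

- **Single-mutation genes.** $d_{\min}$ has no value without a
  neighbour. We take the $d_{\min}\to\infty$ limit: the distance term
  is 0 and an isolated mutation is scored by its mean allele fraction
  alone. The term exists to reward clustering; an isolated mutation has
  none.
- **Pooling.** Distances are computed on the pooled cohort (all
  samples' distinct mutations of a gene), not per sample — the score is
  built around cross-sample proximity ("a mutation in one sample lies a
  few base pairs from another sample's mutation").
- **Distinct alleles at one position** are distinct mutations at
  distance 0, giving the maximal distance term — hotspot logic.
- **Duplicate calls** of one mutation within one sample keep the
  maximum VAF (deterministic and conservative).
- **Ties** for the gene maximum break toward the smallest position,
  then the lexicographically smallest alternate allele.
- **Interpreter mapping.** The channels' raw outputs (five-tier
  categories for InterVar/ClinVar, numeric scales for SIFT and CADD)
  must become signed numbers, and no canonical transformation exists.
  The shipped default uses symmetric five-tier scores for the
  categorical channels and linear transforms around the conventional
  damaging thresholds (SIFT 0.05, lower is damaging; CADD phred 20,
  higher is damaging), clamped to a per-channel scale chosen so
  pathogenic scores fall in roughly (0, 10]. The mapping is data, not
  code: any YAML with the same shape can replace it, and every run
  manifest records the md5 of the mapping in force.
- **All-benign gene-samples** keep the *maximum* (least benign)
  negative score, mirroring most-pathogenic-wins at the gene level and
  keeping $s<0$ so the class is benign.
- **Unannotated mutations** (no interpreter call at all) are excluded
  from pathogenicity scoring and reported separately, rather than
  treated as VUS: an absent verdict is not a verdict.
- **Interpreter calls are keyed per mutation**, not per sample —
  the four channels judge a variant, not a sample's copy of it; the
  per-sample dimension enters through which samples carry the mutation.
- **Per-gene scores within pathway boxplots.** The per-set comparison
  emits one score per member gene per cohort (0 for unmutated members),
  the most literal reading of a per-pathway gene-score boxplot;
  genes absent from both cohorts can optionally be dropped.
- **Cohort sizes differ (9 vs 22).** The formula normalises the AF term
  by each cohort's own $n$, as written; no additional cross-cohort
  calibration is applied.
- No between-cohort significance test is part of the method; a
  Mann-Whitney U per gene set is available but labelled an exploratory
  extra.

## What the synthetic generator emulates

`synthetic_spec()` encodes the study conditions: cohort sizes 9 and 22;
five hot genes planted in cohort A with clustered (≤ 10 bp span),
high-VAF (Beta with mean 0.45), recurrent (7/9 samples) mutations
carrying majority-pathogenic interpreter verdicts (all four channels
concordant with probability 0.9); background genes mutating
symmetrically in both cohorts with widely spaced (≥ 10 kb), low-VAF
(Beta mean 0.15) mutations and mostly benign/VUS verdicts; and decoy
records (5 % population-MAF contamination above 1 %, 5 % synonymous)
with full bookkeeping to exercise the pre-filter. Gene models are
synthetic intervals — the scores depend only on relative positions, so
no genome build is involved. Two structural guarantees make parameter
recovery a sharp test rather than a statistical one: every hot gene's
carrier count (7) exceeds the recurrence threshold by construction, and
background genes are capped at four distinct carrier samples per
cohort, so no background gene can reach a five-sample threshold.

What the generator does **not** emulate: realistic per-sample variant
counts (hundreds per exome), germline contamination beyond the flagged
decoys, interpreter verdicts correlated with true functional impact,
overlapping genes, or chromosome-scale positional structure. Passing
the recovery tests therefore shows that the pipeline's machinery is
correct and well-separated under the planted signal; it does not show
that the scores discriminate on real tumour data.

```{r demo}
sim <- generate_cohorts(synthetic_spec(seed = 1))
fa <- filter_variants(sim$variants_a)
scores <- gene_acc_scores(fa, sim$samples_a, cohort_label = "effusion")
head(scores, 6)
```

## Problem sizes used in the checks

The test suite verifies the closed forms (saturated-VAF co-located
mutations score exactly 2 in any log base; an isolated mutation scores
its mean VAF), equivalence with brute-force reimplementations on 200
random micro-cohorts (≤ 5 genes, ≤ 12 mutations, ≤ 6 samples,
tolerance 1e-12), recovery of all planted hot genes — and no background
genes — across generator seeds 1–5 at the default spec, exact filter
bookkeeping, and the invariants (score range (0, 2], distance-term
monotonicity, sample-permutation and cohort-duplication invariance,
densification monotonicity, exhaustive mutually exclusive bins). These
sizes keep the full suite under a minute on one CPU while exercising
every code path; the scores themselves are closed-form, so larger
simulations would add runtime, not information.

## Limitations

- The accumulation score has no null model; it ranks genes but assigns
  no significance, and values are comparable only under the same log
  base and filter settings.
- Gene length biases $d_{\min}$: long genes with many scattered
  mutations get modest distance terms, short hotspot genes large ones.
  This is intrinsic to the design (it is the clustering signal), not
  corrected.
- The consensus rule is deliberately anti-conservative: one pathogenic
  channel outvotes three benign ones. Channel calibration is delegated
  entirely to the mapping config.
- Multi-gene (overlapping-gene) variants must arrive as one row per
  gene symbol; each row then counts toward each listed gene.
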