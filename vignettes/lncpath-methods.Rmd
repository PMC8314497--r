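---
title: "Methods: inferring lncRNA-associated pathways from tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring lncRNA-associated pathways from tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncpath)
```

## The inference problem

Knockdown or overexpression followed by expression profiling is the direct
way to find the pathways a long non-coding RNA (lncRNA) regulates, but such
experiments exist for only a small fraction of annotated lncRNAs, and cell
lines do not always mirror tumors. `lncpath` treats a large tumor cohort as
a natural perturbation series: across hundreds of patients the target
lncRNA's abundance varies widely, and genes whose expression tracks that
variation are candidate downstream targets. The package turns this idea into
a two-stage procedure — rank all coding genes by their association with the
lncRNA, then test gene-set collections against the ranking with pre-ranked
gene set enrichment analysis (GSEA).

The key assumptions are (i) the lncRNA-pathway relationship is monotone in
expression, (ii) the cohort is large enough that correlation or a
quantile-group contrast is informative, and (iii) gene sets summarize the
biology of interest. Nothing in the procedure uses sample labels beyond the
lncRNA's own expression, so confounding (purity, subtype, batch) propagates
into the ranking; see Limitations.

## Input handling

Matrices arrive as delimited text, genes in rows (a flag transposes
samples-in-rows exports). Duplicate gene rows — usually transcript-level
duplicates — are collapsed by keeping the row with the highest mean
abundance, a deterministic and conventional rule. lncRNA and coding
matrices quantified by different projects rarely agree on TCGA barcode
length, so `harmonize_samples()` truncates sample ids to the first
`barcode_fields = 4` dash-fields (project–TSS–participant–sample/vial) and
joins on the intersection; the joined count is reported because silent
sample loss is the classic failure of this step.

Ranking metrics operate on `log2(x + 1)` (pseudocount 1): on the raw
FPKM/TPM scale both fold changes and Pearson correlations are dominated by
a handful of extreme values. The pipeline applies the transform itself and
refuses to double-transform; users with pre-logged matrices set
`log_transformed = TRUE` on read.

## Ranking metrics

**DGE.** Patients are split at the top and bottom quantile `q` of the
target's abundance. "Top quantile" is ambiguous on real data with heavy
ties (many cohorts have samples with zero lncRNA expression), so groups are
defined by order statistics: sort samples by `(abundance, sample_id)` and
take `ceiling(q * n)` from each end. Group sizes are then exact,
deterministic, and disjoint, which makes downstream permutation tests and
fixtures reproducible. The per-gene score is the difference of group means
of log2 abundance — a log2 fold change. A plain fold change, not a
moderated-t or shrinkage estimator, is used deliberately: shrinkage changes
ranks by variance, and the ranking (not per-gene inference) is the product
here. `q = 0.25` by default, exposed as a parameter.

**GBA.** Each gene's Pearson (default) or Spearman correlation with the
target across all samples. Spearman is Pearson on midranks (average ranks
on ties). Genes with zero variance have undefined correlation and are
excluded with a reported count rather than placed at score 0, where they
would interleave with genuinely uncorrelated genes. Genes absent from every
gene set are retained in the ranking: they contribute to the "miss" walk of
pre-ranked GSEA, as they should.

When a lncRNA is silent in part of the cohort (dropout), correlations are
attenuated but the quantile split isolates exactly the expressing vs
non-expressing contrast, which is why DGE is the recommended metric for
heterogeneously expressed lncRNAs.

## Pre-ranked GSEA

The enrichment score is the classic weighted Kolmogorov–Smirnov running
sum: walking the ranked list, members increment by `|s_i|^p / N_R`
(`N_R = Σ_hits |s_i|^p`), non-members decrement by `1/(N − N_hit)`; ES is
the value of maximal absolute deviation, with the first position winning
ties so the peak is unique. `p = 1` (the standard default) weights hits by
their ranking scores; `p = 0` recovers the unweighted KS statistic. If all
hit scores are zero the hits increment uniformly — the walk stays defined.
A set covering the whole list has no misses and is rejected as degenerate.

Significance uses a gene-label permutation null: random same-size subsets
of the ranked genes. Sample permutation is not possible for a pre-ranked
engine — sample labels no longer exist at this stage. Null pools are cached
per set size, and each size draws its own sub-seed deterministically from
the run seed, so results are identical regardless of the order in which
gene sets are visited. Normalization is sign-specific,
`NES = ES / mean(|null ES| same sign)`, and `NES` is reported as undefined
(rather than silently 0) if one sign's pool happens to be empty. The
nominal p-value is the +1-corrected Monte-Carlo estimate against the
same-sign pool, with its floor `1/(1 + pool size)` stated rather than
hidden; the adaptive multilevel refinement used by modern GSEA
implementations for extreme p-values is out of scope. FDR is
Benjamini–Hochberg across all tested sets, matching the q-value semantics
of the fast pre-ranked implementations rather than the original
sign-stratified NES-based FDR.

**Permutation depth.** The Monte-Carlo floor interacts with multiple
testing: the top pathway in a collection of `m` sets can only reach
`q < 0.05` if its p-value can fall below `0.05/m`. With 50 sets that
requires a same-sign pool above 1000, and since roughly 60–70 % of null
scores share the top set's sign on typical rankings, `n_perm = 1000` cannot
certify `q < 0.05` no matter how strong the signal. The package default
stays at `n_perm = 1000` for exploration, but the validation suite and the
acceptance script use `n_perm = 4000`, chosen from this floor analysis so
that a genuinely top-ranked pathway can clear Benjamini–Hochberg at 50
sets.

The leading edge — members at or before a positive peak, at or after a
negative one, in ranking order — names the genes that actually carry the
enrichment and is reported for every set.

## Ranked-list and table concordance

Two rankings of the same genes (DGE vs GBA, or the same lncRNA under two
annotation sources) are compared with an exponentially weighted top/bottom
overlap: at each depth `n ≤ n_top` the overlaps of the two lists' first `n`
and last `n` genes are counted and weighted by `e^(−αn)`. The default
`α = log(100)/n_top` (with `n_top = 100`) lets the weight decay to 0.01 at
the depth limit — agreement matters most at the extremes, which is where
biological signal concentrates. The data-driven α tuning of the original
ordered-list literature is deliberately not reimplemented; α and `n_top`
are plain parameters.

Because two valid rankings can run in opposite directions, the statistic is
computed for the second list as given and reversed, and the larger score
wins ("same" on ties). The permutation test scores the first list against
uniformly reshuffled versions of the second, taking the same max over
orientations per permutation, so the observed statistic and its null are
identical functionals and orientation selection adds no bias;
`p = (1 + #{null ≥ observed})/(1 + n_perm)`.

Per-comparison p-values combine across lncRNAs or cohorts with Fisher's
method (`−2Σ log p ~ χ²_{2k}`), the standard choice for independent
permutation p-values and one with an exactly testable closed form. Note
Fisher's combination is only monotone-decreasing in the number of studies
when each p is below about `e^(−1)`; near-null p-values can make the
combined p rise.

Two enrichment tables are compared by ordering their shared gene sets by
NES and applying the same orientation-resolved overlap, plus the Spearman
correlation of the NES vectors.

## The synthetic cohort generator

`generate_cohort()` emulates a TCGA-like cohort: lognormal-scale
abundances, TCGA-style barcodes (with longer aliquot barcodes on the lncRNA
matrix so harmonization is always exercised), a target lncRNA with log2
abundance `Normal(lnc_mean, lnc_sd)`, and a planted gene set whose members
follow `baseline + β · lnc_log2 + Normal(0, σ)` in log2 space. The signal
model is linear-Gaussian on purpose: the expected GBA correlation has the
closed form `β·sd_lnc / sqrt(β²·sd_lnc² + σ²)` and the expected DGE fold
change is `β` times the high/low difference in mean lncRNA log2 abundance,
so every recovery expectation in the test suite is derivable rather than
guessed. An optional dropout fraction zeroes the lncRNA in part of the
cohort on the raw scale, reproducing the heterogeneous-expression scenario
where DGE outperforms GBA. Matrices are emitted on the raw scale
(`2^x − 1`, floored at 0) so the pipeline's own log transform runs.

The reference study conditions — the generator defaults — are 200 samples,
2000 coding genes, one planted 30-gene set with `β = 1` and noise SD 0.5,
and 49 null sets of 10–50 genes drawn from non-responsive genes; lncRNA
log2 abundance is `Normal(3, 1)` and per-gene baselines `Normal(5, 1)`,
magnitudes typical of moderately expressed genes in FPKM-scale data.
Validation runs 20 seeded replicates of this cohort through both metrics
(the documented problem sizes of the test suite), 8 replicates for the
metric-concordance meta-analysis, and 200 random sets or list pairs for
null calibration.

What the generator does **not** emulate: library-size and purity effects,
batch structure, correlated co-expression modules outside the planted set,
heavy-tailed noise, or real gene symbol vocabularies. Passing recovery
tests therefore demonstrate the statistical machinery — ranking,
enrichment, calibration — under a clean signal model, not robustness to the
full messiness of real cohorts.

## Numerical choices and degenerate inputs

* Ranking ties: sorted by score descending, then gene id ascending —
  rankings are total orders and reruns are byte-identical.
* Running-sum ties: first position with maximal |deviation| wins; note
  that exact `|max| = |min|` ties mean the reverse-and-negate antisymmetry
  of the unweighted ES holds only up to sign at such ties.
* Quantile-split ties: resolved by sample id as described; an all-tied
  lncRNA vector still yields disjoint groups of exact size.
* Monte-Carlo p-values never report 0: the +1 correction bounds them below
  by the stated floor.
* Degenerate inputs (constant genes, constant target, disjoint sample
  sets, duplicate gene rows, memberless GMT lines) each have a documented,
  tested behavior — exclusion with a reported count, a typed error, or a
  deterministic collapse — catalogued in `degenerate_fixtures()`.
* All randomness flows through a single seed; permutation pools derive
  per-size sub-seeds, and a local RNG scope restores the caller's
  `.Random.seed`.

## Limitations

Associations are correlational: confounders that co-vary with the lncRNA
(tumor purity, proliferation, subtype) will enrich their own pathways. The
gene-label null tests "random gene sets of equal size", not "random
biology"; inter-gene correlation within real pathways makes it
anti-conservative relative to sample permutation, a known property of all
pre-ranked GSEA. Monte-Carlo p-values have a floor set by the permutation
budget, so very small q-values require raising `n_perm` (see the floor
analysis above). The fold-change ranking uses no variance moderation, by
design; and the similarity statistic's α is fixed, not data-tuned.
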