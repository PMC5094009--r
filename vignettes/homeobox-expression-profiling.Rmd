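---
title: "Profiling tissue specificity of homeobox gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling tissue specificity of homeobox gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbxprof)
```

## The analysis model

`hbxprof` treats a gene-family expression survey as a chain of small,
individually testable decisions over a genes × samples matrix of
FPKM-like values.

**Expression calling.** The operative definition of "expressed" is a
hard floor: values below a threshold (default 2 FPKM) are set to zero,
and everything at or above it is kept unchanged. The floor exists to
keep spurious or background read counts out of every downstream
statistic; it is deliberately *not* a statistical test, because FPKM
matrices assembled from heterogeneous public runs do not carry the
replicate structure a test would need. Two boundary conventions are
found in practice — *at or above* versus *strictly above* the floor —
and they genuinely differ for values that are exactly at it, which
occur in rounded supplementary tables. The package takes `>=` as the
default (a gene at exactly 2 FPKM counts as expressed) and exposes
`cmp = "gt"` for the strict reading. Calling is idempotent and
monotone in the threshold, and both properties are asserted in the test
suite.

**Max-normalisation.** Each gene is divided by its own maximal called
value, mapping profiles to [0, 1] with maximum exactly 1. Genes with no
called expression anywhere stay all-zero rather than erroring: "no
clear expression" is a legitimate biological category that the
clustering step must be able to carry. Normalisation runs on the
*called* matrix, not the raw one, so that sub-threshold noise cannot set
a silent gene's scale; this also means a gene whose highest value is
just under the floor is indistinguishable from a fully silent gene,
which is the intended semantics of the floor.

**Clustering into expression groups.** Profiles are clustered with
agglomerative hierarchical clustering. The default metric is
Pearson-correlation distance (1 − r) on the normalised rows — the
standard choice for expression heatmaps, because after
max-normalisation the interesting signal is profile shape — with
average linkage; complete and Ward (D2) linkage and plain euclidean
distance are available. Correlation is undefined on constant rows,
which after normalisation are exactly the never-expressed genes. Rather
than splicing euclidean magnitudes into a [0, 2] correlation-distance
matrix (which makes all-zero rows spuriously close to sparse
tissue-specific profiles, since both are mostly zeros), constant rows
get distance 0 to identical constant rows and the maximal distance 2 to
every expressed profile. Silent genes therefore coalesce into their own
cluster and merge last, which is how a reader treats the blank block of
a heatmap. A matrix in which *every* row is constant has no correlation
structure at all and errors with advice to use euclidean distance.

The number of groups `k` is a user parameter (there is no unsupervised
"right" k for this kind of panel); `k = 6` suits a human-style panel
where widespread, neural, immune, reproductive/developmental,
organ-specific and silent macro-groups are expected. Cuts at successive
k are nested, and cluster recovery of planted archetypes is scored with
the Adjusted Rand Index.

**Group labels.** Groups are labelled by a three-step rule: a group of
entirely silent genes is `no_expression`; a group whose members' median
breadth covers ≥ 90% of the samples is `widespread`; otherwise the
label is the most common sample-annotation group among the members'
peak-expression sites, with lexicographic tie-breaking flagged
`ambiguous`. The widespread pre-rule is the package's own convention:
a dominant-peak-site rule alone can never produce a "widespread" label,
because even ubiquitously expressed genes peak *somewhere*.

**Breadth and class summaries.** Expression breadth — the number of
samples in which a gene is called expressed — is the package's
specificity measure; it is invariant under max-normalisation and sample
permutation, and its column dual (expressed genes per sample) satisfies
the exchange-of-summation identity `Σ_genes breadth =
Σ_samples genes_per_sample`, asserted on every fixture. Class summaries
use Tukey's five-number convention (hinges, median, whiskers at the
furthest observation within 1.5 × IQR of the hinges, outliers beyond),
matching the boxplot convention of base R that such figures are
conventionally drawn with. No tau/Gini/entropy index is computed:
breadth is the deliberate, easily auditable choice for a thresholded
matrix.

**Widespread genes.** Two routes are provided. The cluster route —
take the members of the widespread-labelled cluster — is truest to
reading the set off a clustered heatmap and is preferred when a
labelled partition is available. The breadth route — breadth ≥ 90% of
samples — is the fallback and the two agree exactly on clean synthetic
panels. The route used is recorded in the output.

**Exclusivity.** A gene is exclusive to a target sample set if it has
called expression in at least one target sample and zero called
expression in every other sample. This is a deterministic filter, not
an enrichment test, because that is what the scientific question — "is
this gene detectable *anywhere* else?" — requires. Target sets are
built from sample-annotation groups plus explicit manual additions
(mirroring the common situation where one tissue, such as ovary,
belongs biologically with a target set the clustering did not place it
in); manual additions are reported as such. Each exclusive gene's peak
sample is recorded; ties for the maximum resolve to the earliest
temporal rank when sample annotation is supplied (column order
otherwise) and are flagged. `peak_in_window()` then restricts to genes
peaking inside an inclusive rank window, e.g. 8-cell to morula; genes
peaking in unranked (adult) samples are never inside a window.

**Temporal phases.** Phase structure in a staged series is quantified
as the Jaccard distance between the expressed gene sets of consecutive
stages, with the convention that two empty sets have turnover 0.
Jaccard was chosen because it is threshold-consistent with the calling
module (it sees exactly the same expressed/silent decisions), bounded
in [0, 1], and symmetric under reversal of stage order. Boundaries are
the `n_boundaries` gaps with the largest turnover, ties to the earlier
gap; `n_boundaries = 3` (four phases) is the default for a
12-stage oocyte-to-organogenesis series, where the expected transitions
are after the zygote (maternal transcript hand-off), after the 2-cell
stage (embryonic genome activation in mouse) and at implantation. A
boundary position `p` denotes the gap between the stages of rank index
`p − 1` and `p`. The largest-turnover criterion is the package's
formalisation of what is otherwise read qualitatively off a clustered
heatmap; a gradual multi-stage shift (e.g. between e8.5 and e9.5) will
only surface as a boundary if its single-gap turnover competes with the
sharp transitions, which is the intended behaviour. Genes never
expressed in the series go to a reserved `silent` group and do not
participate in turnover.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be
validated against known truth without any external download. Two
presets mirror the scale of a realistic survey:

* **tissue panel** — 242 genes × 59 samples: seven preimplantation
  stages (oocyte … blastocyst, temporal ranks 0–6), testis, placenta
  and ovary (together the `reproductive_dev` group), 12 neural, 8
  immune and 29 other adult samples. Planted archetypes: 20 widespread,
  60 neural-, 35 immune- and 70 organ-module genes, 23
  reproductive-exclusive genes (13 with planted peaks at 8-cell or
  morula, six at other preimplantation stages, four in adult
  reproductive tissues) and 34 silent genes. Class labels are skewed so
  ANTP (101 genes) and PRD (55) fall mostly in specific archetypes
  while TALE/ZF/CERS dominate the widespread set, so the class-level
  specificity ordering is itself a testable planted feature.
* **staged series** — 278 genes × 12 stages with planted boundaries
  (2, 3, 7): maternal (oocyte–zygote), EGA-burst (2-cell only),
  cleavage-to-blastocyst, and post-implantation archetypes, plus 28
  silent genes. Arbitrary boundary vectors and phase counts are
  supported.

An expressed entry is `exp(3 + u_s + g + ε)` FPKM, where `u_s` is a
per-sample profile shared by the archetype (sd 0.6), `g` a per-gene
offset (sd 0.6) and `ε` residual noise (sd 0.5) — overall a log-normal
with location 3 and scale ≈ 1 on log-FPKM. The shared profile term
makes same-archetype genes positively correlated, as co-regulated genes
are, which is what gives the correlation-distance clustering something
real to find. Draws are clipped from below at the calling threshold so
that, before corruption, a planted expressed entry is always called
expressed: clean-data recovery is exact by construction, and all noise
is introduced explicitly. Background entries are uniform on [0, 1.5],
strictly below the 2-FPKM floor.

`corrupt_expression()` is the explicit noise channel: expressed entries
are zeroed with probability `dropout_rate`, and survivors are
multiplied by log-normal noise `exp(N(0, noise_scale))`, which can push
a value below the floor. Both corruptions act on expressed entries
only; the sub-threshold background is already the generator's noise
floor, and perturbing it would make "noise" mean planted false
expression at a rate confounded with `background_max`.

What the generator does **not** emulate: gene-length and library-size
biases inherent to FPKM, replicate structure, the continuous
within-group expression gradients of real tissues (module genes are
expressed across their whole sample group), and per-tissue expressed
gene counts calibrated to real data (module sizes make synthetic organ
samples richer in expressed genes than synthetic embryo stages).
Passing the recovery tests therefore demonstrates that the *pipeline
logic* is correct and noise-tolerant, not that real tissue panels are
this cleanly separable — on real data, group membership near cluster
borders and the immune set's sensitivity to the FPKM cut-off remain
analyst judgements.

## Numerical and design choices

* **Thresholds**: calling floor 2 FPKM, `>=` boundary; widespread
  fraction 0.9 of samples for both the cluster-label pre-rule and the
  breadth route.
* **Clustering**: correlation distance, average linkage, deterministic
  tie behaviour inherited from `stats::hclust` with input-order leaf
  ordering; constant rows handled as described above.
* **Peak ties**: earliest temporal rank (earliest column without
  annotation), always flagged rather than silently resolved.
* **Degenerate inputs**: all-zero rows normalise to all-zero; empty
  expressed sets give turnover 0; empty target sets, improper subsets,
  unranked samples in staged operations, and out-of-range windows or
  cuts all error with named offenders rather than guessing.
* **Determinism**: every stochastic operation takes an explicit seed
  and restores the caller's RNG state; workflow runs write the exact
  config (YAML), a stage-level log with gene/sample counts after each
  filter, and an md5 manifest, so identical configs produce identical
  bundles.
* **Problem sizes in the test suite**: oracle cross-checks run on 50
  random 200 × 60 fixtures; noise-robustness properties use 200
  replicate seeds on the two presets (242 × 59 and 278 × 12), sizes at
  which the full suite completes in well under a minute while the
  binomial margins on the asserted rates stay tight.

## Known limitations

* Exact group membership from any particular published heatmap cannot
  be guaranteed: hierarchical clustering outcomes depend on distance,
  linkage and cut choices that surveys rarely state, and genes with
  secondary expression sites (a ubiquitous gene elevated in embryos,
  say) can legitimately move between groups under different choices.
  The parameters are therefore explicit arguments, and recovery claims
  are made only against planted truth.
* Breadth treats all samples as equivalent columns; panels whose
  samples express radically different gene counts would need a
  per-sample calibration the package deliberately does not apply.
* The turnover statistic sees only the binary expressed/silent state;
  a phase change expressed purely as amplitude modulation above the
  floor is invisible to it.
* No between-sample normalisation (quantile, TMM) is performed; the
  package assumes the FPKM matrix is already comparable across columns.
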