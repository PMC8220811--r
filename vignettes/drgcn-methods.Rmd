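---
title: "Methods: directed graph-convolutional feature diffusion for metastasis prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed graph-convolutional feature diffusion for metastasis prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`drgcn` predicts patient-level metastasis status from bulk RNA-seq expression
by combining three inputs: a directed gene–gene regulation network, a binary
gene–cancer association matrix, and an FPKM-like expression matrix. The
pipeline has four stages:

1. **Clinical labeling** — derive a binary metastasis outcome per case from
   TCGA-CDR-style clinical fields, with explicit exclusions and a
   longest-follow-up retention filter for the negatives.
2. **Weight diffusion** — smooth the binary gene–cancer associations over the
   directed regulation network with a degree-normalized graph-convolution
   rule, producing real-valued per-gene, per-cancer weights.
3. **Feature building** — multiply each sample's expression vector by the
   diffused weight columns, giving an image-like tensor of shape
   `(m, 1, G, K)` (samples × channel × genes × cancer types).
4. **Classification** — train a small convolutional network on the tensor and
   evaluate by k-fold cross-validation with AUROC and AUPRC.

The rationale is that a gene's relevance to a cancer type is better captured
by its network neighborhood than by a sparse binary annotation alone:
diffusion transfers annotation mass onto the regulators of annotated genes,
so expression changes in those regulators become visible to the classifier.

## The diffusion model

Let `A` be the binary G×G adjacency with `A[i, j] = 1` meaning gene *i*
regulates gene *j*. The network is first augmented with self-loops,
`Ã = A + I`, so each gene retains its own signal during aggregation. Because
`A` is binary, the addition saturates: a pre-existing self-loop stays 1
rather than becoming 2.

One propagation layer maps the feature matrix `H` (G×K) to

    H' = σ( D̃⁻¹ Ã H W )

where `D̃` is the diagonal degree matrix of `Ã`, `W` is a K×K layer weight,
and `σ` an activation. Under the equal-weight assumption `W = I`, which is
the package default; no gradient training of the diffusion takes place.
Row *i* of `D̃⁻¹ Ã H` is the degree-normalized sum of the feature rows of the
genes that gene *i* regulates (out-neighbors, itself included).

**Degree convention.** On a directed network the normalizing degree is
ambiguous. The default normalizes node *i* by its **in-degree** in `Ã`, with
out-degree available as an option (`norm_mode`). On a symmetric network the
two coincide and `D̃⁻¹Ã` is exactly row-stochastic, which is the behavior the
tests pin down. The degree is the *node's own* degree, not a global degree
sum; a global reading is exposed behind the `global` flag of
`build_degree_operator()` for sensitivity analysis only, since the per-node
reading is the one that reduces to standard random-walk normalization.

**Full-rank fallback.** After self-loop augmentation every degree is at
least 1, so `D̃` is always invertible. For raw, non-augmented networks
(`allow_raw = TRUE`) a zero-degree node would make `D̃` singular; such nodes
receive the signed value `−1/|E|` (total edge count) on the diagonal instead
of zero. This branch is unreachable in the standard pipeline but implemented
because the degree rule is stated for general networks; a zero diagonal would
contradict the invertibility guarantee the normalization is meant to provide.

**Number of layers.** The default is `L = 2`: one layer moves annotation
mass onto direct regulators of annotated genes, two layers reach second-order
regulators while keeping the weights local. `L = 0` returns the raw
associations unchanged.

**Activation.** The default is the identity, keeping the diffusion a linear
operator — scaling the initial associations scales the output exactly, a
property the test suite asserts. ReLU is available; on the default pipeline
the two coincide because all inputs are non-negative and the operator
preserves non-negativity.

**Initial features.** `H⁰` is the binary G×K gene–cancer association matrix
(1 = gene annotated to that cancer type). The diffused output `Ŵ` is used
only as a per-gene weighting of expression, never as a classifier feature on
its own.

## Clinical labeling

Records carry `tumor_status` (with tumor / tumor free / not clear / NA),
`new_tumor_event_type` (Metastasis / Recurrence / New Primary / NA),
`new_tumor_event_site`, and `PFI.time` (progression-free interval, days).
Labeling proceeds in order:

* **Positive (metastasis, label 1)** if any of:
  * r1 — `tumor_status` itself names a metastatic state. The standard
    TCGA-CDR vocabulary has no such value, so r1 is a configurable predicate
    (`met_status_values`, default `METASTASIS`/`METASTATIC`) that fires only
    on extended vocabularies; with standard data r2 and r3 carry the
    labeling.
  * r2 — `tumor_status` uninformative (NOT CLEAR or NA) but the new tumor
    event type is `Metastasis`.
  * r3 — neither `tumor_status` nor the event type informative, but a new
    tumor event *site* is recorded. Any non-missing site qualifies; the site
    is not compared with the primary site because the records do not carry a
    primary-site field.
* **Excluded** otherwise when `tumor_status` is NOT CLEAR or NA
  (`unclear_tumor_status`).
* **Negative (label 0)** only when `tumor_status = TUMOR FREE` and the event
  type is NA.
* Everything else is excluded as `ambiguous_non_metastasis` (e.g. WITH TUMOR
  plus a recurrence): such cases are neither clean negatives nor metastases,
  and keeping them would dilute both classes.

Matching is case-insensitive after whitespace trimming; the literal strings
`NA`, `[Not Available]`, `[Not Applicable]`, `#N/A`, and empty cells are
normalized to missing at parse time.

**Retention filter.** A short follow-up can make a negative label temporary,
so only the longest-followed fraction (default 0.70) of label-0 cases is
kept; all label-1 cases are kept unconditionally. Negatives with missing
`PFI.time` are excluded first. The sort is total — `pfi_time` descending,
ties broken by `case_id` ascending — and `floor(fraction · n₀)` cases are
kept, so the output is byte-identical regardless of input row order. The
filter is global across cancer types by default (`per_cancer = FALSE`);
whether to stratify it per cancer is genuinely open, and both modes are
exposed.

## Feature tensor

With expression `E` (genes × samples) and diffused weights `Ŵ` (genes ×
cancer types) aligned on one gene order, the tensor entry is

    values[s, 1, g, k] = E[g, s] · Ŵ[g, k]

a per-gene broadcast product (equivalently `diag(E[, s]) Ŵ`), the only
product consistent with the `(m, 1, G, K)` output shape. Genes absent from
any of the three inputs are dropped via a sorted three-way intersection,
never zero-padded. Expression enters raw (FPKM-like) by default; a
`log2(x + 1)` flag is provided because whether expression should be
log-scaled before the classifier is not settled — the raw default is the
faithful one, and the flag makes the alternative a one-switch experiment.
Missing expression values are an error, never imputed.

## The classifier

The network is seven convolution blocks (each `conv2d` + LeakyReLU with
negative slope 0.1), a flatten layer, batch normalization, a dense layer,
dropout, and a dense softmax output over the two classes, trained with Adam
on categorical cross-entropy (labels one-hot encoded internally). The engine
is implemented in compiled code (RcppArmadillo) with batched im2col
convolutions and exact, seeded determinism: parameter initialization
(He-normal), epoch shuffling, and dropout masks all draw from one seeded
generator, so identical configurations reproduce identical training
histories bit for bit.

**Default block table.** Filters `8, 8, 16, 16, 32, 32, 64`; kernels
`(7,1) (7,1) (5,1) (5,1) (3,3) (3,3) (3,1)`; strides `(2,1)` for the first
four blocks, `(1,1)` after. Tall, narrow kernels with stride 2 shrink the
long gene axis early while preserving the narrow cancer-type axis; the two
`(3,3)` blocks mix across cancer types once the gene axis is short. The table
assumes a width of at least 6; `clamp_cnn_config()` shrinks kernels to the
running spatial shape for narrower inputs (e.g. the K = 3 synthetic fixture),
and every block parameter is overridable through `cnn_config()` or a
YAML/JSON config file. A shape-inference pass validates the chain before
training and reports the offending block on underflow.

**Optimizer defaults.** Learning rate 1e-3, batch size 32, 50 epochs,
dropout 0.5, dense width 64. Dropout sits between the two dense layers
(dense → dropout → dense). Class order is fixed as (non-metastasis,
metastasis); metastasis is the positive class in every metric.

## Evaluation

`cross_validate()` shuffles cases under a seed, deals them into k folds whose
sizes differ by at most one (plain shuffled folds by default; stratification
is an option), trains a fresh model on k−1 folds and scores the held-out
fold. Reported metrics are the **fold means** of AUROC and AUPRC; metrics on
the pooled out-of-fold scores are available behind `pooled = TRUE`, since
which convention a given study used is often unclear.

AUROC is computed by the rank (Mann–Whitney) formulation — equal to the
trapezoidal ROC integral, ties counted half — and AUPRC by the step-wise
(non-interpolated) precision envelope over distinct score thresholds. Both
are pinned to brute-force oracles (exhaustive pair comparison; exhaustive
threshold enumeration) at tolerance 1e-12 in the tests, and AUROC is
cross-checked against an independent ROC library. With constant scores AUROC
is 0.5 and AUPRC equals prevalence.

If a training split would contain a single class, the split is redrawn with
an incremented seed and a message; fold metrics for single-class *test* folds
are recorded as NA and dropped from the mean.

## The synthetic study

The generator emulates the statistical structure the pipeline assumes,
making every stage testable offline:

* **Network** — directed Erdős–Rényi (edge probability
  `mean_out_degree / (G − 1)`) or preferential attachment; no self-loops.
* **Associations** — per cancer type, `n_assoc_per_cancer` seed genes set
  to 1.
* **Expression** — i.i.d. log-normal baseline (`meanlog = 1`,
  `sdlog = noise_sd`), mimicking the skew of FPKM data; metastasis samples
  get a `+δ` log-scale shift in their cancer's informative genes.
* **Routing** — `seed_genes` plants the shift in the annotated genes
  themselves; `neighbors_only` plants it in the *regulators* of the seed
  genes (genes with an edge into a seed, seeds excluded). Regulators are the
  right neighborhood here because propagation aggregates each gene's
  out-neighbors: after one layer, exactly the genes that regulate an
  annotated gene acquire weight. Under `neighbors_only` the informative genes
  therefore carry zero weight in the raw association matrix but nonzero
  weight after diffusion — the configuration that isolates the benefit of
  diffusion from the classifier itself.
* **Clinical fixture** — `gen_clinical_table()` emits records covering all
  eight labeling branches (the three positive rules, the tumor-free negative,
  both unclear-status exclusions, the ambiguous remainder, and a
  missing-PFI negative), with ground-truth columns for test harnesses.

Default conditions: G = 500 genes, K = 3 cancer types, 100 samples per
cancer (300 total), metastasis fraction 0.4, mean out-degree 5, 10 seed
genes per cancer, δ = 1.0, noise SD 0.5. These sizes run the full 10-fold
pipeline in minutes on a single CPU while leaving the planted signal
moderate rather than trivial (per-gene effect of 2 noise SDs across ~10
genes).

**What the generator does not emulate.** Real expression data has correlated
genes, batch structure, library-size variation, heavy-tailed per-gene
dispersions, and cancer-type-specific baselines; the generator has none of
these (independent genes, one global baseline). Passing tests therefore
demonstrate that the pipeline's machinery is correct and that diffusion
recovers network-routed signal under the stated assumptions — not that the
headline numbers transfer to real cohorts.

## Numerical choices and degenerate inputs

* Degree reciprocals are computed in double precision with no zero-clipping;
  invertibility is guaranteed structurally (self-loops or the `−1/|E|`
  fallback), not by tolerance.
* Retention counts use `floor()`; one negative case at fraction 0.7 keeps
  zero negatives.
* A fully edgeless raw network has no valid `−1/|E|` fallback and errors.
* Empty prediction inputs return an empty probability matrix rather than
  erroring.
* Softmax subtracts the column maximum before exponentiation; training loss
  clamps probabilities at 1e-12 before the log.
* Batch normalization uses biased batch variance, running statistics with
  momentum 0.9, and ε = 1e-5.

## Known limitations

* The diffusion is weight-free (`W = I`); no learned layer weights, no
  multi-relational edge types, no link prediction.
* The engine is single-threaded and CPU-only, sized for desk-scale inputs
  (hundreds to a few thousand genes), not the full ~18k-gene networks.
* No normalization across samples (TPM conversion, quantile normalization)
  and no batch correction; inputs are taken as given.
* No nested cross-validation or hyperparameter search; the configuration is
  what you set it to.
* Fold-mean AUPRC on small test folds is sensitive to per-fold prevalence;
  use `pooled = TRUE` when folds are small.

## Problem sizes used by the test suite

Unit tests run on networks of 2–60 genes with oracle cross-checks; the
end-to-end checks use the default 500-gene, 300-sample fixture with 10-fold
cross-validation, and smaller 60–80-gene fixtures with 2-fold splits for
smoke coverage. These sizes were chosen so the whole suite completes in
minutes on one CPU while still exercising every code path at realistic
shapes.
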