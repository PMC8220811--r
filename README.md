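# drgcn

Network-informed prediction of cancer metastasis from bulk RNA-seq
expression.

Sparse binary gene–cancer annotations (DisGeNET-style) ignore a gene's
regulatory context: a gene that regulates several cancer-associated genes
carries signal even when it is not annotated itself. `drgcn` smooths a binary
gene–cancer association matrix over a **directed** gene-regulation network
with a degree-normalized graph-convolution rule, uses the diffused weights to
turn each patient's expression vector into an image-like tensor, and
classifies patients as metastasis / non-metastasis with a small CNN,
evaluated by k-fold cross-validation (AUROC / AUPRC). It also implements the
clinical labeling procedure for TCGA-CDR-style records (metastasis rules,
exclusions, longest-follow-up retention of negatives) and a seeded
synthetic-data generator so the whole pipeline runs and is testable with no
external downloads.

## The model

With `A` the binary adjacency (`A[i, j] = 1`: gene *i* regulates gene *j*),
self-loops are added saturating at 1 (`Ã = A + I`), and the binary
gene–cancer matrix `H⁰` (G×K) is diffused for `L` layers (default 2):

    H^(l+1) = σ( D̃⁻¹ Ã H^(l) )

where `D̃` is the diagonal degree matrix of `Ã` — in-degree by default, with
a signed `−1/|E|` fallback that keeps `D̃` full rank on raw networks — and
`σ` is the identity by default, keeping the diffusion linear. The diffused
weights `Ŵ` then scale expression per gene:
`features[s, 1, g, k] = expr[g, s] · Ŵ[g, k]`, shape `(m, 1, G, K)`. The
classifier is seven conv + LeakyReLU(0.1) blocks, flatten, batch norm, two
dense layers with dropout, softmax, trained with Adam on categorical
cross-entropy (implemented in compiled RcppArmadillo code, exactly
reproducible under a seed).

See `vignettes/drgcn-methods.Rmd` for the full account of the model,
parameter defaults, and design choices.

## Worked example

Diffusion moves annotation weight onto the *regulators* of annotated genes.
With the two-edge network TP53 → MYC → KRAS and KRAS annotated to pancreatic
adenocarcinoma:

```r
library(drgcn)

net <- regulation_network(tibble::tibble(
  source_gene = c("TP53", "MYC"), target_gene = c("MYC", "KRAS")))
h0 <- matrix(c(1, 0, 0), 3, 1, dimnames = list(net$genes, "PAAD"))  # KRAS = 1
extract_weights(net, h0, propagation_config(n_layers = 1))
#>      PAAD
#> KRAS  0.5
#> MYC   0.5
#> TP53  0.0
```

KRAS keeps half of its weight (self-loop, normalized by its in-degree of 2)
and MYC — the direct regulator of KRAS — gains the other half; TP53 is two
hops upstream and gets weight only at `L = 2`.

End to end on generated data:

```r
spec    <- synthetic_spec(n_genes = 200L, n_cancers = 2L,
                          n_samples_per_cancer = 50L, seed = 7)
network <- gen_network(spec)
assoc   <- gen_gene_cancer(spec, network)
cohort  <- gen_expression_cohort(spec, network, assoc)

weights <- extract_weights(network, assoc)          # L = 2 diffusion
tensor  <- weight_expression(cohort$expression, weights)
tensor
#> <feature_tensor> 100 samples x 1 x 200 genes x 2 cancer types

cfg <- clamp_cnn_config(cnn_config(epochs = 30L), dim(tensor$values)[-1])
cv  <- cross_validate(tensor, cohort$labels, cnn_config = cfg, k = 5, seed = 1)
cv
#> <cv_result> 5 folds | mean AUROC 0.9332 | mean AUPRC 0.8969
tidy(cv)
#> # A tibble: 5 × 4
#>    fold auroc auprc n_test
#>   <int> <dbl> <dbl>  <int>
#> 1     1 1     1         20
#> 2     2 0.891 0.761     20
#> 3     3 0.896 0.806     20
#> 4     4 0.92  0.941     20
#> 5     5 0.960 0.976     20
```

The mean AUROC of 0.93 says the classifier ranks a random metastasis sample
above a random non-metastasis sample 93% of the time on held-out folds; the
per-fold table shows the spread across the five test folds.
`autoplot(cv, "roc")` and `autoplot(cv, "pr")` draw the per-fold curves.

Clinical labeling works on TCGA-CDR-style tables:

```r
records <- read_clinical_table("clinical.tsv")
cohort  <- label_cohort(records, fraction = 0.70)   # label + retention filter
glance(cohort)                                      # counts by class and exclusions
```

A thin command-line wrapper over these functions is included at
`inst/cli/drgcn.R` (`simulate`, `label`, `diffuse`, `features`, `train`,
`evaluate`, `run-all`).

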