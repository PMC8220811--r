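# Shared fixture builders and independent oracles.

# Random directed network (no self-loops) on G genes, edge prob p.
rand_digraph <- function(G, p, seed) {
  withr::with_seed(seed, {
    A <- matrix(rbinom(G * G, 1L, p), G, G)
    diag(A) <- 0
    regulation_network(adjacency = A, genes = sprintf("g%02d", seq_len(G)))
  })
}

chain_network <- function(n = 3) {
  genes <- paste0("g", seq_len(n))
  regulation_network(
    tibble::tibble(source_gene = genes[-n], target_gene = genes[-1]),
    genes = genes
  )
}

# Symmetric triangle (all six directed edges).
triangle_network <- function() {
  e <- expand.grid(i = 1:3, j = 1:3)
  e <- e[e$i != e$j, ]
  regulation_network(
    tibble::tibble(source_gene = paste0("g", e$i), target_gene = paste0("g", e$j)),
    genes = paste0("g", 1:3)
  )
}

# Oracle: one propagation layer as an explicit per-node double loop.
propagate_loop_oracle <- function(A, d, H) {
  G <- nrow(A); K <- ncol(H)
  out <- matrix(0, G, K)
  for (i in seq_len(G)) {
    acc <- numeric(K)
    for (j in seq_len(G)) {
      if (A[i, j] == 1) acc <- acc + H[j, ]
    }
    out[i, ] <- d[i] * acc
  }
  out
}

# Oracle: AUROC by exhaustive positive-negative pair comparison.
auroc_pair_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  total / (length(pos) * length(neg))
}

# Oracle: AUPRC by exhaustive threshold enumeration (step-wise area).
auprc_threshold_oracle <- function(labels, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  recall_prev <- 0
  area <- 0
  for (t in thresholds) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    precision <- tp / (tp + fp)
    recall <- tp / sum(labels == 1)
    area <- area + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  area
}

# Small separable fixture for classifier tests: two cancer types, strong shift.
tiny_separable_fixture <- function(seed = 5L, n_per = 20L, delta = 2.0) {
  spec <- synthetic_spec(n_genes = 60L, n_cancers = 2L,
                         n_samples_per_cancer = n_per,
                         metastasis_fraction = 0.5,
                         mean_out_degree = 4, n_assoc_per_cancer = 6L,
                         effect_size = delta, noise_sd = 0.5, seed = seed)
  network <- gen_network(spec)
  gc <- gen_gene_cancer(spec, network)
  cohort <- gen_expression_cohort(spec, network, gc)
  weights <- extract_weights(network, gc)
  tensor <- weight_expression(cohort$expression, weights)
  list(spec = spec, network = network, gene_cancer = gc, cohort = cohort,
       tensor = tensor, labels = cohort$labels)
}

tiny_cnn_config <- function(input_shape, epochs = 15L, seed = 1L) {
  clamp_cnn_config(cnn_config(epochs = epochs, seed = seed), input_shape)
}

unclass_matrix_for_test <- function(x) {
  attr(x, "class") <- NULL
  x
}
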