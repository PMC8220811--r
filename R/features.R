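#' Intersect gene lists across expression, network, and association inputs
#'
#' Downstream matrices are aligned on a single deterministic gene order: the
#' lexicographically sorted intersection of the three input lists. Genes
#' missing from any input are dropped, never zero-padded.
#'
#' @param expr_genes,network_genes,gc_genes Character vectors of gene
#'   identifiers.
#' @return Sorted character vector of genes present in all three lists.
#' @export
intersect_genes <- function(expr_genes, network_genes, gc_genes) {
  if (length(expr_genes) == 0 || length(network_genes) == 0 || length(gc_genes) == 0) {
    rlang::abort("all three gene lists must be non-empty")
  }
  common <- sort(intersect(intersect(expr_genes, network_genes), gc_genes))
  if (length(common) == 0) {
    rlang::abort(sprintf(
      paste0("empty three-way gene intersection ",
             "(expr/network overlap: %d, expr/gc overlap: %d, network/gc overlap: %d)"),
      length(intersect(expr_genes, network_genes)),
      length(intersect(expr_genes, gc_genes)),
      length(intersect(network_genes, gc_genes))
    ))
  }
  common
}

#' Restrict network, weights, and expression to a common gene order
#'
#' @param network A [regulation_network()].
#' @param genes Ordered character vector (e.g. from [intersect_genes()]).
#' @return A `regulation_network` on exactly `genes`, in that order.
#' @export
subset_network <- function(network, genes) {
  stopifnot(inherits(network, "regulation_network"))
  missing <- setdiff(genes, network$genes)
  if (length(missing) > 0) {
    rlang::abort(paste0("genes absent from network: ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  idx <- match(genes, network$genes)
  regulation_network(adjacency = network$adjacency[idx, idx, drop = FALSE],
                     genes = genes, directed = network$directed)
}

#' Build the sample feature tensor by weighting expression
#'
#' Each sample's expression vector is broadcast across the K columns of the
#' diffused gene-cancer weight matrix:
#' `values[s, 1, g, k] = expr[g, s] * weights[g, k]`, giving the rank-4
#' image-like tensor `(m, 1, G, K)` consumed by the CNN.
#'
#' @param expr `expression_matrix` (genes x samples) or data frame with a
#'   leading gene column.
#' @param weights G x K numeric weight matrix with gene rownames, aligned to
#'   `expr`'s gene order.
#' @param log2_transform Apply `log2(x + 1)` to expression before weighting
#'   (default `FALSE`: raw FPKM-like values).
#' @return A `feature_tensor`: list with `values` (array `m x 1 x G x K`),
#'   `sample_ids`, `gene_ids`, `cancer_ids`.
#' @export
#' @examples
#' expr <- as_expression_matrix(matrix(c(2, 3), 2, 1,
#'   dimnames = list(c("g1", "g2"), "s1")))
#' w <- matrix(c(1, 0, 0.5, 2), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2")))
#' weight_expression(expr, w)$values[1, 1, , ]
weight_expression <- function(expr, weights, log2_transform = FALSE) {
  if (is.data.frame(expr)) expr <- as_expression_matrix(expr)
  weights <- as.matrix(weights)
  if (nrow(expr) != nrow(weights)) {
    rlang::abort(sprintf(
      "expression has %d genes but weights have %d rows",
      nrow(expr), nrow(weights)
    ))
  }
  if (!is.null(rownames(weights)) && !identical(rownames(expr), rownames(weights))) {
    first <- which(rownames(expr) != rownames(weights))[1]
    rlang::abort(sprintf(
      "gene order mismatch between expression and weights at position %d: '%s' vs '%s'",
      first, rownames(expr)[first], rownames(weights)[first]
    ))
  }
  E <- unclass_matrix(expr)
  if (log2_transform) E <- log2(E + 1)
  G <- nrow(E); m <- ncol(E); K <- ncol(weights)
  # values[s, 1, g, k] = E[g, s] * W[g, k]
  vals <- array(0, dim = c(m, 1L, G, K))
  for (k in seq_len(K)) {
    vals[, 1L, , k] <- t(E * weights[, k])
  }
  if (!all(is.finite(vals))) rlang::abort("feature tensor contains non-finite values")
  structure(
    list(values = vals,
         sample_ids = colnames(E),
         gene_ids = rownames(E),
         cancer_ids = colnames(weights)),
    class = "feature_tensor"
  )
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %d samples x 1 x %d genes x %d cancer types\n",
              d[1], d[3], d[4]))
  invisible(x)
}

#' Subset a feature tensor by sample
#'
#' @param tensor A `feature_tensor`.
#' @param idx Integer or logical sample index, or character sample ids.
#' @return A `feature_tensor` with the selected samples.
#' @export
subset_samples <- function(tensor, idx) {
  stopifnot(inherits(tensor, "feature_tensor"))
  if (is.character(idx)) idx <- match(idx, tensor$sample_ids)
  structure(
    list(values = tensor$values[idx, , , , drop = FALSE],
         sample_ids = tensor$sample_ids[idx],
         gene_ids = tensor$gene_ids,
         cancer_ids = tensor$cancer_ids),
    class = "feature_tensor"
  )
}

#' Save / load a feature tensor
#'
#' Portable container: a gzipped RDS holding the array and its id lists.
#'
#' @param tensor A `feature_tensor`.
#' @param path Output path (conventionally `.rds`).
#' @return `path` invisibly (writer); the `feature_tensor` (reader).
#' @export
write_feature_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "feature_tensor"))
  saveRDS(tensor, path)
  invisible(path)
}

#' @rdname write_feature_tensor
#' @export
read_feature_tensor <- function(path) {
  tensor <- readRDS(path)
  if (!inherits(tensor, "feature_tensor")) rlang::abort("not a feature_tensor container")
  tensor
}
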