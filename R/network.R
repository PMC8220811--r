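#' Construct a directed gene-regulation network
#'
#' Represents a directed gene-gene regulation network as a binary adjacency
#' matrix over an ordered gene list. Entry `(i, j) = 1` means gene *i*
#' regulates gene *j*.
#'
#' @param edges A two-column data frame (`source_gene`, `target_gene`) of
#'   directed edges, or `NULL` when `adjacency` is given directly.
#' @param genes Character vector of unique gene identifiers fixing the node
#'   order. When `edges` is given and `genes` is `NULL`, the sorted union of
#'   the edge endpoints is used.
#' @param adjacency Optional G x G binary matrix given instead of `edges`.
#' @param directed Logical flag recorded on the object; the adjacency is
#'   stored as given either way.
#'
#' @return A `regulation_network` object: a list with `genes` (character),
#'   `adjacency` (G x G binary matrix with dimnames), and `directed`.
#' @export
#' @examples
#' net <- regulation_network(tibble::tibble(
#'   source_gene = c("g1", "g2"),
#'   target_gene = c("g2", "g3")
#' ))
#' net$genes
regulation_network <- function(edges = NULL, genes = NULL, adjacency = NULL,
                               directed = TRUE) {
  if (is.null(adjacency)) {
    if (is.null(edges)) {
      if (is.null(genes)) {
        rlang::abort("supply `edges`, `adjacency`, or at least `genes`")
      }
      edges <- tibble::tibble(source_gene = character(), target_gene = character())
    }
    edges <- as_edge_tbl(edges)
    if (is.null(genes)) {
      genes <- sort(unique(c(edges$source_gene, edges$target_gene)))
    }
    genes <- as.character(genes)
    check_gene_list(genes)
    missing <- setdiff(unique(c(edges$source_gene, edges$target_gene)), genes)
    if (length(missing) > 0) {
      rlang::abort(paste0(
        "edge endpoints absent from `genes`: ",
        paste(utils::head(missing, 5), collapse = ", ")
      ))
    }
    G <- length(genes)
    adjacency <- matrix(0, G, G, dimnames = list(genes, genes))
    if (nrow(edges) > 0) {
      dup <- duplicated(paste(edges$source_gene, edges$target_gene, sep = "\r"))
      if (any(dup)) {
        rlang::warn(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
        edges <- edges[!dup, ]
      }
      adjacency[cbind(
        match(edges$source_gene, genes),
        match(edges$target_gene, genes)
      )] <- 1
    }
  } else {
    adjacency <- as.matrix(adjacency)
    if (is.null(genes)) {
      genes <- rownames(adjacency)
      if (is.null(genes)) genes <- paste0("g", seq_len(nrow(adjacency)))
    }
    genes <- as.character(genes)
    check_gene_list(genes)
    check_binary_adjacency(adjacency, length(genes))
    dimnames(adjacency) <- list(genes, genes)
  }
  structure(
    list(genes = genes, adjacency = adjacency, directed = isTRUE(directed)),
    class = "regulation_network"
  )
}

as_edge_tbl <- function(edges) {
  edges <- tibble::as_tibble(edges)
  if (ncol(edges) < 2) rlang::abort("edge table needs two columns (source, target)")
  tibble::tibble(
    source_gene = as.character(edges[[1]]),
    target_gene = as.character(edges[[2]])
  )
}

check_gene_list <- function(genes) {
  if (anyDuplicated(genes) > 0) {
    rlang::abort(paste0(
      "gene identifiers must be unique; duplicated: ",
      genes[anyDuplicated(genes)]
    ))
  }
  invisible(genes)
}

check_binary_adjacency <- function(adjacency, G = nrow(adjacency)) {
  if (nrow(adjacency) != ncol(adjacency)) {
    rlang::abort(sprintf(
      "adjacency must be square, got %d x %d", nrow(adjacency), ncol(adjacency)
    ))
  }
  if (nrow(adjacency) != G) {
    rlang::abort(sprintf(
      "adjacency dimension %d does not match %d genes", nrow(adjacency), G
    ))
  }
  bad <- which(!(adjacency == 0 | adjacency == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rlang::abort(sprintf(
      "adjacency must be binary; entry (%d, %d) is %s",
      bad[1, 1], bad[1, 2], format(adjacency[bad[1, 1], bad[1, 2]])
    ))
  }
  invisible(adjacency)
}

#' @export
print.regulation_network <- function(x, ...) {
  cat(sprintf(
    "<regulation_network> %d genes, %d edges, %s\n",
    length(x$genes), sum(x$adjacency),
    if (x$directed) "directed" else "undirected"
  ))
  invisible(x)
}

#' Add self-loops to a regulation network
#'
#' Augments the adjacency matrix with the identity, `A~ = A + I`, so each
#' gene aggregates its own feature during propagation. The sum saturates at 1:
#' a pre-existing self-loop stays 1, keeping the adjacency binary.
#'
#' @param network A [regulation_network()].
#' @return A `regulation_network` whose adjacency has every diagonal entry
#'   equal to 1 and off-diagonal entries unchanged.
#' @export
#' @examples
#' net <- regulation_network(genes = c("a", "b"),
#'                           adjacency = matrix(c(0, 0, 1, 0), 2))
#' add_self_loops(net)$adjacency
add_self_loops <- function(network) {
  stopifnot(inherits(network, "regulation_network"))
  A <- network$adjacency
  check_binary_adjacency(A, length(network$genes))
  diag(A) <- 1
  network$adjacency <- A
  network
}

has_self_loops <- function(network) {
  all(diag(network$adjacency) == 1)
}

#' Build the directed degree-normalization operator
#'
#' Computes the diagonal of the inverse degree matrix used by the propagation
#' rule `H^(l+1) = sigma(D~^-1 A~ H^(l))`. For node *i* the diagonal value is
#' `1 / deg(i)`, with `deg` the in-degree (default, the directed convention
#' used here) or out-degree in the augmented adjacency. After self-loop
#' augmentation every degree is at least 1, so all values are positive and the
#' operator is full rank.
#'
#' On a raw (non-augmented) network, enabled with `allow_raw = TRUE`, a node
#' of degree zero receives the signed fallback `-1/|E|` (with `|E|` the total
#' edge count) so the diagonal stays nonzero and the operator invertible.
#'
#' @param network A [regulation_network()]; must already carry self-loops
#'   unless `allow_raw = TRUE`.
#' @param mode `"in"` (default) or `"out"`: which degree normalizes each node.
#' @param allow_raw Allow zero-degree nodes (raw network) via the `-1/|E|`
#'   fallback.
#' @param global Use the global reading `1 / sum(all degrees)` for every node
#'   instead of per-node degrees (sensitivity analysis only).
#' @return A `degree_operator` object: list with `diag_values` (length-G
#'   numeric, all nonzero), `mode`, and `built_on_selfloops`.
#' @export
#' @examples
#' net <- add_self_loops(regulation_network(tibble::tibble(
#'   source_gene = c("g1", "g2"), target_gene = c("g2", "g3")
#' )))
#' build_degree_operator(net)$diag_values
build_degree_operator <- function(network, mode = c("in", "out"),
                                  allow_raw = FALSE, global = FALSE) {
  stopifnot(inherits(network, "regulation_network"))
  mode <- match.arg(mode)
  A <- network$adjacency
  selfloops <- has_self_loops(network)
  if (!selfloops && !allow_raw) {
    rlang::abort("network lacks self-loops; call add_self_loops() first or set allow_raw = TRUE")
  }
  deg <- if (mode == "in") colSums(A) else rowSums(A)
  n_edges <- sum(A)
  if (global) {
    total <- sum(deg)
    if (total == 0) rlang::abort("degenerate network: no edges at all")
    vals <- rep(1 / total, length(deg))
  } else {
    vals <- numeric(length(deg))
    zero <- deg == 0
    if (any(zero)) {
      if (n_edges == 0) {
        rlang::abort("degenerate network: no edges, cannot form -1/|E| fallback")
      }
      vals[zero] <- -1 / n_edges
    }
    vals[!zero] <- 1 / deg[!zero]
  }
  names(vals) <- network$genes
  structure(
    list(diag_values = vals, mode = mode, built_on_selfloops = selfloops),
    class = "degree_operator"
  )
}

#' Apply one graph-convolution propagation layer
#'
#' Computes `sigma(D~^-1 A~ H W)`: each node's new feature row is the
#' degree-normalized sum of the feature rows of the genes it regulates
#' (its out-neighbors in the augmented adjacency, itself included).
#'
#' @param features G x K numeric matrix `H` of node features.
#' @param network Augmented [regulation_network()].
#' @param degree [build_degree_operator()] result built on the same network.
#' @param activation `"identity"` (default) or `"relu"`.
#' @param layer_weight Optional K x K weight matrix `W`; identity when `NULL`
#'   (all genes weighted equally).
#' @return G x K numeric matrix `H'`.
#' @export
propagate_layer <- function(features, network, degree,
                            activation = c("identity", "relu"),
                            layer_weight = NULL) {
  stopifnot(inherits(network, "regulation_network"),
            inherits(degree, "degree_operator"))
  activation <- match.arg(activation)
  features <- as.matrix(features)
  G <- length(network$genes)
  if (nrow(features) != G) {
    rlang::abort(sprintf(
      "feature matrix has %d rows but the network has %d genes",
      nrow(features), G
    ))
  }
  if (length(degree$diag_values) != G) {
    rlang::abort(sprintf(
      "degree operator length %d does not match %d genes",
      length(degree$diag_values), G
    ))
  }
  out <- degree$diag_values * (network$adjacency %*% features)
  if (!is.null(layer_weight)) {
    layer_weight <- as.matrix(layer_weight)
    if (!all(dim(layer_weight) == ncol(features))) {
      rlang::abort(sprintf(
        "layer weight must be %d x %d, got %d x %d",
        ncol(features), ncol(features), nrow(layer_weight), ncol(layer_weight)
      ))
    }
    out <- out %*% layer_weight
  }
  if (activation == "relu") out <- pmax(out, 0)
  dimnames(out) <- list(network$genes, colnames(features))
  out
}

#' Propagation configuration
#'
#' @param n_layers Number of propagation layers `L` (non-negative integer;
#'   default 2).
#' @param activation `"identity"` (default; keeps the diffusion linear) or
#'   `"relu"`.
#' @param norm_mode `"in"` (default) or `"out"` degree normalization.
#' @param layer_weights Optional list of `n_layers` K x K matrices; `NULL`
#'   means identity at every layer (the equal-weight assumption).
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(n_layers = 2L,
                               activation = c("identity", "relu"),
                               norm_mode = c("in", "out"),
                               layer_weights = NULL) {
  activation <- match.arg(activation)
  norm_mode <- match.arg(norm_mode)
  n_layers <- as.integer(n_layers)
  if (is.na(n_layers) || n_layers < 0) {
    rlang::abort("`n_layers` must be a non-negative integer")
  }
  if (!is.null(layer_weights) && length(layer_weights) != n_layers) {
    rlang::abort(sprintf(
      "`layer_weights` has length %d but n_layers is %d",
      length(layer_weights), n_layers
    ))
  }
  structure(
    list(n_layers = n_layers, activation = activation,
         norm_mode = norm_mode, layer_weights = layer_weights),
    class = "propagation_config"
  )
}

#' Diffuse gene-cancer association weights over the regulation network
#'
#' The full feature-extraction step: self-loop augmentation, degree operator,
#' then `L` propagation layers applied to the initial binary gene-cancer
#' matrix `H0`. The result `W^` carries each gene's network-smoothed
#' association weight with every cancer type and is later used to weight
#' expression.
#'
#' @param network A [regulation_network()] (raw or already augmented).
#' @param initial G x K numeric matrix `H0`; rows must follow the network's
#'   gene order (checked via rownames when present).
#' @param config A [propagation_config()].
#' @return G x K numeric matrix of diffused weights, rownames = genes.
#' @export
#' @examples
#' net <- regulation_network(tibble::tibble(
#'   source_gene = c("g1", "g2"), target_gene = c("g2", "g3")
#' ))
#' h0 <- matrix(c(0, 0, 1), 3, 1, dimnames = list(net$genes, "cancer1"))
#' extract_weights(net, h0, propagation_config(n_layers = 1))
extract_weights <- function(network, initial, config = propagation_config()) {
  stopifnot(inherits(network, "regulation_network"),
            inherits(config, "propagation_config"))
  initial <- as.matrix(initial)
  if (nrow(initial) != length(network$genes)) {
    rlang::abort(sprintf(
      "initial matrix has %d rows but the network has %d genes",
      nrow(initial), length(network$genes)
    ))
  }
  if (!is.null(rownames(initial))) {
    mism <- which(rownames(initial) != network$genes)
    if (length(mism) > 0) {
      rlang::abort(sprintf(
        "gene order mismatch between network and initial matrix at position %d: '%s' vs '%s'",
        mism[1], network$genes[mism[1]], rownames(initial)[mism[1]]
      ))
    }
  }
  if (config$n_layers == 0L) return(initial)
  aug <- add_self_loops(network)
  degree <- build_degree_operator(aug, mode = config$norm_mode)
  H <- initial
  for (l in seq_len(config$n_layers)) {
    W <- if (is.null(config$layer_weights)) NULL else config$layer_weights[[l]]
    H <- propagate_layer(H, aug, degree, activation = config$activation,
                         layer_weight = W)
  }
  dimnames(H) <- list(network$genes, colnames(initial))
  H
}
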