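#' Read a directed edge list from TSV
#'
#' Two columns (source gene, target gene), tab-separated. A header row is
#' detected when the first line's fields are `source_gene`/`target_gene`
#' (case-insensitive); lines starting with `#` are skipped. Duplicate edges
#' are collapsed with a warning.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `source_gene`, `target_gene`.
#' @export
read_edge_list <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) rlang::abort(sprintf("edge list %s has fewer than 2 columns", path))
  raw <- raw[, 1:2]
  names(raw) <- c("source_gene", "target_gene")
  if (nrow(raw) > 0 &&
      tolower(raw$source_gene[1]) %in% c("source_gene", "source") &&
      tolower(raw$target_gene[1]) %in% c("target_gene", "target")) {
    raw <- raw[-1, ]
  }
  dup <- duplicated(paste(raw$source_gene, raw$target_gene, sep = "\r"))
  if (any(dup)) {
    rlang::warn(sprintf("collapsed %d duplicate edge(s) in %s", sum(dup), path))
    raw <- raw[!dup, ]
  }
  tibble::as_tibble(raw)
}

#' Write a directed edge list to TSV
#'
#' @param edges Two-column data frame or a [regulation_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "regulation_network")) {
    idx <- which(edges$adjacency == 1, arr.ind = TRUE)
    edges <- tibble::tibble(
      source_gene = edges$genes[idx[, 1]],
      target_gene = edges$genes[idx[, 2]]
    ) |> dplyr::arrange(.data$source_gene, .data$target_gene)
  }
  readr::write_tsv(as_edge_tbl(edges), path, progress = FALSE)
  invisible(path)
}

#' Read a gene-cancer association matrix from TSV
#'
#' First column holds gene identifiers, the remaining columns one cancer type
#' each, values 0/1.
#'
#' @param path Path to the TSV file.
#' @return Numeric G x K binary matrix with gene rownames and cancer colnames.
#' @export
read_gene_cancer <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(tbl) < 2) rlang::abort(sprintf("%s must have a gene column plus >=1 cancer column", path))
  genes <- as.character(tbl[[1]])
  check_gene_list(genes)
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  if (!all(mat %in% c(0, 1))) {
    rlang::abort(sprintf("%s contains non-binary association values", path))
  }
  rownames(mat) <- genes
  mat
}

#' Write a gene-by-cancer weight matrix to TSV
#'
#' @param weights Numeric matrix with gene rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  tbl <- tibble::as_tibble(weights, rownames = "gene")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Read a gene-cancer or diffused-weight matrix (real-valued)
#'
#' Like [read_gene_cancer()] but without the binary check, for reading
#' diffused weights back.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames.
#' @export
read_weights <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  genes <- as.character(tbl[[1]])
  check_gene_list(genes)
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  mat
}

#' Read a gene expression matrix from TSV
#'
#' Genes in rows, samples in columns; first column is the gene identifier and
#' the header carries sample identifiers. Values must be non-negative with no
#' missing entries (missing data is an error, never imputed).
#'
#' @param path Path to the TSV file.
#' @return An `expression_matrix`: numeric G x m matrix, gene rownames,
#'   sample colnames.
#' @export
read_expression <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(tbl) < 2) rlang::abort(sprintf("%s must have a gene column plus >=1 sample column", path))
  genes <- as.character(tbl[[1]])
  check_gene_list(genes)
  mat <- as.matrix(tbl[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- genes
  as_expression_matrix(mat)
}

#' Coerce a matrix or gene-column tibble to an expression matrix
#'
#' @param x Numeric genes x samples matrix with rownames/colnames, or a data
#'   frame whose first column is the gene identifier.
#' @return Validated `expression_matrix` (a classed numeric matrix).
#' @export
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    genes <- as.character(x[[1]])
    x <- as.matrix(x[, -1, drop = FALSE])
    mode(x) <- "numeric"
    rownames(x) <- genes
  }
  if (is.null(rownames(x))) rlang::abort("expression matrix needs gene rownames")
  if (is.null(colnames(x))) rlang::abort("expression matrix needs sample colnames")
  check_gene_list(rownames(x))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "expression matrix contains NA at gene '%s', sample '%s'; missing values are not imputed",
      rownames(x)[bad[1]], colnames(x)[bad[2]]
    ))
  }
  if (any(x < 0)) rlang::abort("expression values must be non-negative")
  class(x) <- c("expression_matrix", class(x))
  x
}

#' Write an expression matrix to TSV
#'
#' @param expr `expression_matrix` or plain genes x samples matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  tbl <- tibble::as_tibble(unclass_matrix(expr), rownames = "gene")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

unclass_matrix <- function(x) {
  attr(x, "class") <- NULL
  x
}
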