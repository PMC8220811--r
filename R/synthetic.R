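#' Specification for the synthetic study
#'
#' Defines the statistical structure of a generated dataset: a directed
#' regulation network, a sparse binary gene-cancer association matrix,
#' FPKM-like expression with a metastasis-dependent log-scale shift planted in
#' network-defined informative genes, and balanced per-cancer cohorts.
#'
#' Defaults describe the package's standard planted-signal fixture: 500 genes,
#' 3 cancer types, 100 samples per cancer, 40% metastasis prevalence, an
#' Erdos-Renyi network with mean out-degree 5, 10 seed genes per cancer, a
#' log-scale effect of 1.0 against noise SD 0.5.
#'
#' @param n_genes Number of genes G.
#' @param n_cancers Number of cancer types K.
#' @param n_samples_per_cancer Samples per cancer type.
#' @param metastasis_fraction Fraction of metastasis samples per cancer, in
#'   (0, 1).
#' @param network_model `"erdos_renyi"` or `"preferential_attachment"`.
#' @param mean_out_degree Expected out-degree per gene (sets the edge
#'   probability for Erdos-Renyi, the attachment count for preferential
#'   attachment).
#' @param n_assoc_per_cancer Seed genes per cancer (entries set to 1 in the
#'   association matrix).
#' @param effect_size Log-scale mean shift delta added to informative genes in
#'   metastasis samples; >= 0.
#' @param noise_sd Log-scale standard deviation of baseline expression.
#' @param signal_routing `"seed_genes"` (shift the associated genes
#'   themselves) or `"neighbors_only"` (shift only the regulators of seed
#'   genes, i.e. genes with an edge into a seed, excluding the seeds; these
#'   genes carry zero raw association weight but gain weight under diffusion).
#' @param seed Integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 500L,
                           n_cancers = 3L,
                           n_samples_per_cancer = 100L,
                           metastasis_fraction = 0.4,
                           network_model = c("erdos_renyi", "preferential_attachment"),
                           mean_out_degree = 5,
                           n_assoc_per_cancer = 10L,
                           effect_size = 1.0,
                           noise_sd = 0.5,
                           signal_routing = c("seed_genes", "neighbors_only"),
                           seed = 1L) {
  network_model <- match.arg(network_model)
  signal_routing <- match.arg(signal_routing)
  stopifnot(n_genes > 0, n_cancers > 0, n_samples_per_cancer > 0,
            metastasis_fraction > 0, metastasis_fraction < 1,
            mean_out_degree >= 0, n_assoc_per_cancer >= 0,
            effect_size >= 0, noise_sd > 0)
  structure(
    list(n_genes = as.integer(n_genes),
         n_cancers = as.integer(n_cancers),
         n_samples_per_cancer = as.integer(n_samples_per_cancer),
         metastasis_fraction = metastasis_fraction,
         network_model = network_model,
         mean_out_degree = mean_out_degree,
         n_assoc_per_cancer = as.integer(n_assoc_per_cancer),
         effect_size = effect_size,
         noise_sd = noise_sd,
         signal_routing = signal_routing,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

spec_genes <- function(spec) {
  sprintf("G%04d", seq_len(spec$n_genes))
}
spec_cancers <- function(spec) {
  sprintf("cancer%02d", seq_len(spec$n_cancers))
}

#' Generate a directed regulation network
#'
#' Erdos-Renyi: each ordered gene pair gets an edge independently with
#' probability `mean_out_degree / (G - 1)`. Preferential attachment: a
#' directed scale-free graph via [igraph::sample_pa()]. No self-loops in
#' either model.
#'
#' @param spec A [synthetic_spec()].
#' @return A [regulation_network()] on `spec$n_genes` genes.
#' @export
gen_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- spec_genes(spec)
  G <- spec$n_genes
  p <- if (G > 1) spec$mean_out_degree / (G - 1) else 0
  if (p > 1) {
    rlang::abort(sprintf(
      "mean_out_degree %g implies more than G*(G-1) = %d edges",
      spec$mean_out_degree, G * (G - 1)
    ))
  }
  withr::with_seed(spec$seed, {
    if (spec$network_model == "erdos_renyi") {
      A <- matrix(stats::rbinom(G * G, 1L, p), G, G)
      diag(A) <- 0
      regulation_network(adjacency = A, genes = genes)
    } else {
      g <- igraph::sample_pa(G, m = max(1, round(spec$mean_out_degree)),
                             directed = TRUE)
      el <- igraph::as_edgelist(g)
      regulation_network(
        tibble::tibble(source_gene = genes[el[, 1]],
                       target_gene = genes[el[, 2]]),
        genes = genes
      )
    }
  })
}

#' Generate the binary gene-cancer association matrix
#'
#' For each cancer type, `n_assoc_per_cancer` distinct seed genes are sampled
#' (overlap across cancers allowed) and their entries set to 1.
#'
#' @param spec A [synthetic_spec()].
#' @param network Matching [regulation_network()] (fixes the gene order).
#' @return G x K binary matrix with gene rownames and cancer colnames.
#' @export
gen_gene_cancer <- function(spec, network) {
  stopifnot(inherits(spec, "synthetic_spec"),
            inherits(network, "regulation_network"))
  genes <- network$genes
  K <- spec$n_cancers
  H0 <- matrix(0, length(genes), K,
               dimnames = list(genes, spec_cancers(spec)))
  withr::with_seed(spec$seed + 1L, {
    for (k in seq_len(K)) {
      H0[sample(length(genes), spec$n_assoc_per_cancer), k] <- 1
    }
  })
  H0
}

#' Informative genes per cancer under a routing strategy
#'
#' `seed_genes`: the associated genes themselves. `neighbors_only`: the
#' regulators of the seed genes (genes with an out-edge into a seed),
#' excluding every associated gene of any cancer — these carry zero weight in
#' every column of the raw association matrix but lie inside the diffusion
#' support after one or more propagation layers.
#'
#' @param spec A [synthetic_spec()].
#' @param network The generated network.
#' @param gene_cancer The generated association matrix.
#' @return Named list (one element per cancer) of informative gene ids.
#' @export
informative_genes <- function(spec, network, gene_cancer) {
  genes <- network$genes
  A <- network$adjacency
  # genes with any association carry nonzero raw weight in some column, so
  # neighbors_only informative genes must avoid them all to keep the raw
  # weighting signal-free
  any_seed <- genes[rowSums(gene_cancer) > 0]
  out <- lapply(seq_len(ncol(gene_cancer)), function(k) {
    seeds <- genes[gene_cancer[, k] == 1]
    if (spec$signal_routing == "seed_genes") {
      seeds
    } else {
      seed_idx <- which(gene_cancer[, k] == 1)
      reg_idx <- which(rowSums(A[, seed_idx, drop = FALSE]) > 0)
      setdiff(genes[reg_idx], any_seed)
    }
  })
  names(out) <- colnames(gene_cancer)
  if (spec$signal_routing == "neighbors_only" &&
      all(lengths(out) == 0)) {
    rlang::abort("neighbors_only routing: no seed gene has incoming edges")
  }
  out
}

#' Generate the expression cohort with planted metastasis signal
#'
#' Baseline log-expression is i.i.d. Normal(1, `noise_sd`) (log-normal FPKM
#' mimic). Within each cancer, `round(metastasis_fraction * n)` samples are
#' metastatic; their informative genes' log-expression is shifted by
#' `+effect_size`.
#'
#' @param spec A [synthetic_spec()].
#' @param network The generated network.
#' @param gene_cancer The generated association matrix.
#' @return List with `expression` (an `expression_matrix`, genes x samples),
#'   `labels` (named 0/1 vector), `cancer_assignment` (named character
#'   vector), `informative` (list from [informative_genes()]).
#' @export
gen_expression_cohort <- function(spec, network, gene_cancer) {
  stopifnot(inherits(spec, "synthetic_spec"))
  genes <- network$genes
  cancers <- colnames(gene_cancer)
  info <- informative_genes(spec, network, gene_cancer)
  n <- spec$n_samples_per_cancer
  m <- n * length(cancers)
  sample_ids <- sprintf("S%04d", seq_len(m))
  cancer_assignment <- rep(cancers, each = n)
  n_met <- round(spec$metastasis_fraction * n)
  labels <- rep(rep(c(1L, 0L), times = c(n_met, n - n_met)), length(cancers))
  withr::with_seed(spec$seed + 2L, {
    logx <- matrix(stats::rnorm(length(genes) * m, mean = 1, sd = spec$noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, sample_ids))
    for (s in which(labels == 1L)) {
      shifted <- info[[cancer_assignment[s]]]
      if (length(shifted) > 0) {
        logx[shifted, s] <- logx[shifted, s] + spec$effect_size
      }
    }
  })
  names(labels) <- sample_ids
  names(cancer_assignment) <- sample_ids
  list(
    expression = as_expression_matrix(exp(logx)),
    labels = labels,
    cancer_assignment = cancer_assignment,
    informative = info
  )
}

#' Generate a clinical-table fixture covering every labeling branch
#'
#' Emits `n_per_branch` records for each of eight branches of the labeling
#' procedure, with a ground-truth column for test harnesses:
#' metastatic `tumor_status` vocabulary (rule 1), unclear status with a
#' `Metastasis` event (rule 2), unclear status and event but a recorded site
#' (rule 3), tumor-free/no-event negatives, `NOT CLEAR` and `NA` status
#' exclusions, ambiguous remainders, and tumor-free negatives with missing
#' PFI time. PFI times are drawn uniformly on 30-3000 days.
#'
#' @param n_per_branch Records per branch (default 1).
#' @param seed Integer seed.
#' @return Tibble in clinical-table column layout plus `truth_label`
#'   (0/1/`NA`) and `truth_reason` columns.
#' @export
gen_clinical_table <- function(n_per_branch = 1L, seed = 1L) {
  branches <- tibble::tribble(
    ~tumor_status, ~new_tumor_event_type, ~new_tumor_event_site, ~truth_label, ~truth_reason,
    "METASTASIS", NA, NA, 1L, "r1_status_vocabulary",
    NA, "Metastasis", "Lung", 1L, "r2_event_type",
    "NOT CLEAR", NA, "Liver", 1L, "r3_event_site",
    "TUMOR FREE", NA, NA, 0L, "tumor_free_control",
    "NOT CLEAR", "Recurrence", NA, NA, "unclear_tumor_status",
    NA, "New Primary", NA, NA, "unclear_tumor_status",
    "WITH TUMOR", "Recurrence", NA, NA, "ambiguous_non_metastasis",
    "TUMOR FREE", NA, NA, 0L, "missing_pfi"
  )
  n_per_branch <- as.integer(n_per_branch)
  stopifnot(n_per_branch >= 1)
  rows <- branches[rep(seq_len(nrow(branches)), each = n_per_branch), ]
  n <- nrow(rows)
  withr::with_seed(seed, {
    pfi <- round(stats::runif(n, 30, 3000), 1)
  })
  pfi[rows$truth_reason == "missing_pfi"] <- NA_real_
  tibble::tibble(
    case_id = sprintf("CASE%03d", seq_len(n)),
    cancer_type = rep_len(c("BRCA", "LUAD", "SKCM"), n),
    tumor_status = rows$tumor_status,
    new_tumor_event_type = rows$new_tumor_event_type,
    new_tumor_event_site = rows$new_tumor_event_site,
    pfi_time = pfi,
    truth_label = rows$truth_label,
    truth_reason = rows$truth_reason
  )
}

#' Write a complete synthetic dataset to disk
#'
#' Writes `network.tsv`, `gene_cancer.tsv`, `expr.tsv`, `labels.tsv`,
#' `clinical.tsv`, and ground-truth tables under `dir/truth/`. The clinical
#' table encodes each expression sample's generated label through clean
#' labeling branches (metastasis -> unclear status with a `Metastasis` event;
#' non-metastasis -> tumor-free with no event), so running the clinical
#' labeler on it recovers the generated labels.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  network <- gen_network(spec)
  gc <- gen_gene_cancer(spec, network)
  cohort <- gen_expression_cohort(spec, network, gc)
  write_edge_list(network, file.path(dir, "network.tsv"))
  write_weights(gc, file.path(dir, "gene_cancer.tsv"))
  write_expression(cohort$expression, file.path(dir, "expr.tsv"))
  labels_tbl <- tibble::tibble(
    case_id = names(cohort$labels),
    cancer_type = unname(cohort$cancer_assignment),
    label = unname(cohort$labels)
  )
  readr::write_tsv(labels_tbl, file.path(dir, "labels.tsv"), progress = FALSE)
  pfi <- withr::with_seed(spec$seed + 3L,
                          round(stats::runif(nrow(labels_tbl), 30, 3000), 1))
  clinical <- tibble::tibble(
    case_id = labels_tbl$case_id,
    cancer_type = labels_tbl$cancer_type,
    tumor_status = ifelse(labels_tbl$label == 1L, "NA", "TUMOR FREE"),
    new_tumor_event_type = ifelse(labels_tbl$label == 1L, "Metastasis", "NA"),
    new_tumor_event_site = ifelse(labels_tbl$label == 1L, "Distant", "NA"),
    `PFI.time` = pfi
  )
  readr::write_tsv(clinical, file.path(dir, "clinical.tsv"), progress = FALSE)
  info_tbl <- purrr::imap_dfr(cohort$informative, function(g, k) {
    tibble::tibble(cancer = k, gene = g)
  })
  readr::write_tsv(info_tbl, file.path(dir, "truth", "informative_genes.tsv"),
                   progress = FALSE)
  branch_fixture <- gen_clinical_table(seed = spec$seed)
  readr::write_tsv(branch_fixture, file.path(dir, "truth", "clinical_branches.tsv"),
                   progress = FALSE)
  invisible(dir)
}
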