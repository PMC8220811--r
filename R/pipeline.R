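#' Pipeline configuration
#'
#' Bundles all paths and stage parameters for [run_pipeline()]. Input paths
#' are validated at construction time, before any stage runs.
#'
#' @param network_path,gene_cancer_path,expr_path,clinical_path Input TSVs.
#' @param out_dir Output directory for stage artifacts and manifests.
#' @param propagation A [propagation_config()].
#' @param cnn A [cnn_config()] or `NULL` (defaults clamped to the data shape).
#' @param retention_fraction Fraction for [retain_longest_nonmet()].
#' @param folds Cross-validation folds.
#' @param seed Global seed; per-stage seeds are derived from it
#'   deterministically.
#' @param log2_transform Apply `log2(x + 1)` to expression before weighting.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(network_path, gene_cancer_path, expr_path,
                            clinical_path, out_dir,
                            propagation = propagation_config(),
                            cnn = NULL,
                            retention_fraction = 0.70,
                            folds = 10L,
                            seed = 1L,
                            log2_transform = FALSE) {
  paths <- c(network = network_path, gene_cancer = gene_cancer_path,
             expr = expr_path, clinical = clinical_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    rlang::abort(paste0("input path(s) do not exist: ",
                        paste(sprintf("%s (%s)", missing, names(missing)),
                              collapse = ", ")))
  }
  structure(
    list(network_path = network_path, gene_cancer_path = gene_cancer_path,
         expr_path = expr_path, clinical_path = clinical_path,
         out_dir = out_dir, propagation = propagation, cnn = cnn,
         retention_fraction = retention_fraction, folds = as.integer(folds),
         seed = as.integer(seed), log2_transform = isTRUE(log2_transform)),
    class = "pipeline_config"
  )
}

#' Derive a per-stage seed from the global seed
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed, deterministic in both arguments.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 131 + sum(utf8ToInt(stage)) * 7919) %% 2147483647)
}

write_manifest <- function(out_dir, stage, inputs, outputs, seed = NULL) {
  hash_by_name <- function(paths) {
    as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
  }
  manifest <- list(
    stage = stage,
    inputs = hash_by_name(inputs),
    outputs = hash_by_name(outputs),
    seed = seed,
    package_version = as.character(utils::packageVersion("drgcn"))
  )
  path <- file.path(out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full pipeline: label, diffuse, build features, cross-validate
#'
#' Executes the stages in order, writing every intermediate artifact and a
#' manifest (input/output MD5 hashes plus the stage seed) per stage under
#' `config$out_dir`. Rerunning with an identical config reproduces identical
#' manifests. Stage errors are annotated with the stage name; partial outputs
#' are left on disk for debugging.
#'
#' @param config A [pipeline_config()].
#' @return A `cv_result` (invisibly also written under `out_dir/results/`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage,
                           conditionMessage(e)), parent = e)
    })
  }

  # -- label ---------------------------------------------------------------
  cohort <- with_stage("label", {
    records <- read_clinical_table(config$clinical_path)
    label_cohort(records, fraction = config$retention_fraction)
  })
  labels_path <- file.path(out, "labels.tsv")
  excluded_path <- file.path(out, "excluded.tsv")
  write_labeled_cohort(cohort, labels_path, excluded_path)
  write_manifest(out, "label", config$clinical_path,
                 c(labels_path, excluded_path))

  # -- diffuse -------------------------------------------------------------
  diffused <- with_stage("diffuse", {
    network <- regulation_network(read_edge_list(config$network_path))
    gc <- read_gene_cancer(config$gene_cancer_path)
    expr <- read_expression(config$expr_path)
    genes <- intersect_genes(rownames(expr), network$genes, rownames(gc))
    net_sub <- subset_network(network, genes)
    weights <- extract_weights(net_sub, gc[genes, , drop = FALSE],
                               config$propagation)
    list(weights = weights, expr = expr[genes, , drop = FALSE], genes = genes)
  })
  weights_path <- file.path(out, "weights.tsv")
  write_weights(diffused$weights, weights_path)
  write_manifest(out, "diffuse",
                 c(config$network_path, config$gene_cancer_path, config$expr_path),
                 weights_path)

  # -- features ------------------------------------------------------------
  tensor <- with_stage("features", {
    weight_expression(as_expression_matrix(diffused$expr), diffused$weights,
                      log2_transform = config$log2_transform)
  })
  tensor_path <- file.path(out, "features.rds")
  write_feature_tensor(tensor, tensor_path)
  write_manifest(out, "features", c(weights_path, config$expr_path), tensor_path)

  # -- evaluate ------------------------------------------------------------
  result <- with_stage("evaluate", {
    entries <- cohort$entries
    keep <- intersect(tensor$sample_ids, entries$case_id)
    if (length(keep) < config$folds) {
      rlang::abort(sprintf(
        "only %d labeled samples with expression; need at least %d for %d-fold CV",
        length(keep), config$folds, config$folds
      ))
    }
    sub <- subset_samples(tensor, keep)
    labs <- entries$label[match(keep, entries$case_id)]
    cross_validate(sub, labs, cnn_config = config$cnn, k = config$folds,
                   seed = stage_seed(config$seed, "evaluate"))
  })
  res_dir <- file.path(out, "results")
  write_cv_result(result, res_dir)
  write_manifest(out, "evaluate", tensor_path,
                 file.path(res_dir, "metrics.tsv"),
                 seed = stage_seed(config$seed, "evaluate"))
  result
}
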