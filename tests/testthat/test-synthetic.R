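test_that("network generation respects density, model, and seed", {
  # p = 0 -> empty edge set
  empty_spec <- synthetic_spec(n_genes = 50L, mean_out_degree = 0, seed = 1)
  expect_equal(sum(gen_network(empty_spec)$adjacency), 0)

  # same seed -> identical network; different seed -> different
  spec <- synthetic_spec(n_genes = 60L, mean_out_degree = 4, seed = 5)
  n1 <- gen_network(spec)
  n2 <- gen_network(spec)
  expect_identical(n1$adjacency, n2$adjacency)
  spec2 <- synthetic_spec(n_genes = 60L, mean_out_degree = 4, seed = 6)
  expect_false(identical(gen_network(spec2)$adjacency, n1$adjacency))

  # no self-loops in the raw output
  expect_true(all(diag(n1$adjacency) == 0))

  # edge count within 3 sd of the binomial expectation (G=200, mean deg 5)
  spec_big <- synthetic_spec(n_genes = 200L, mean_out_degree = 5, seed = 11)
  E <- sum(gen_network(spec_big)$adjacency)
  p <- 5 / 199
  n_pairs <- 200 * 199
  expect_lt(abs(E - n_pairs * p), 3 * sqrt(n_pairs * p * (1 - p)))

  # preferential attachment builds a directed network of the right size
  pa <- gen_network(synthetic_spec(n_genes = 40L, mean_out_degree = 3,
                                   network_model = "preferential_attachment",
                                   seed = 2))
  expect_equal(length(pa$genes), 40)
  expect_gt(sum(pa$adjacency), 0)

  # impossible density
  expect_error(gen_network(synthetic_spec(n_genes = 5L, mean_out_degree = 10,
                                          seed = 1)), "edges")
})

test_that("gene-cancer associations have exact column sums and are seeded", {
  spec <- synthetic_spec(n_genes = 80L, n_cancers = 4L, n_assoc_per_cancer = 7L,
                         seed = 3)
  network <- gen_network(spec)
  H0 <- gen_gene_cancer(spec, network)
  expect_equal(unname(colSums(H0)), rep(7, 4))
  expect_true(all(H0 %in% c(0, 1)))
  expect_identical(gen_gene_cancer(spec, network), H0)

  zero_spec <- synthetic_spec(n_genes = 80L, n_assoc_per_cancer = 0L, seed = 3)
  expect_equal(sum(gen_gene_cancer(zero_spec, network)), 0)
})

test_that("the planted shift appears in informative genes at the stated size", {
  # delta = 2, noise 0.5: class difference in mean log-expression of
  # informative genes within 3 sd of 2
  spec <- synthetic_spec(n_genes = 100L, n_cancers = 2L,
                         n_samples_per_cancer = 100L, effect_size = 2,
                         noise_sd = 0.5, seed = 17)
  network <- gen_network(spec)
  H0 <- gen_gene_cancer(spec, network)
  cohort <- gen_expression_cohort(spec, network, H0)
  k <- 1
  cancer_samples <- names(cohort$cancer_assignment)[cohort$cancer_assignment == "cancer01"]
  info <- cohort$informative[["cancer01"]]
  logx <- log(unclass_matrix_for_test(cohort$expression))[info,
                                                          cancer_samples, drop = FALSE]
  met <- cohort$labels[cancer_samples] == 1
  diff_mean <- mean(logx[, met]) - mean(logx[, !met])
  n_obs <- length(info) * sum(met)
  se <- 0.5 * sqrt(1 / (length(info) * sum(met)) + 1 / (length(info) * sum(!met)))
  expect_lt(abs(diff_mean - 2), 3 * se)

  expect_identical(gen_expression_cohort(spec, network, H0)$expression,
                   cohort$expression)
})


test_that("delta = 0 produces no label-associated signal", {
  spec <- synthetic_spec(n_genes = 100L, n_cancers = 1L,
                         n_samples_per_cancer = 200L, effect_size = 0,
                         noise_sd = 0.5, seed = 19)
  network <- gen_network(spec)
  H0 <- gen_gene_cancer(spec, network)
  cohort <- gen_expression_cohort(spec, network, H0)
  info <- cohort$informative[[1]]
  logx <- log(unclass_matrix_for_test(cohort$expression))
  met <- cohort$labels == 1
  p <- stats::t.test(colMeans(logx[info, met, drop = FALSE]),
                     colMeans(logx[info, !met, drop = FALSE]))$p.value
  expect_gt(p, 0.001)
})

test_that("neighbors_only routing plants signal outside the seed set", {
  spec <- synthetic_spec(n_genes = 150L, n_cancers = 2L, mean_out_degree = 5,
                         signal_routing = "neighbors_only", seed = 23)
  network <- gen_network(spec)
  H0 <- gen_gene_cancer(spec, network)
  info <- informative_genes(spec, network, H0)
  any_seed <- network$genes[rowSums(H0) > 0]
  for (k in seq_along(info)) {
    seeds <- network$genes[H0[, k] == 1]
    expect_length(intersect(info[[k]], any_seed), 0)
    # informative genes regulate at least one seed
    for (g in info[[k]]) {
      expect_gt(sum(network$adjacency[g, seeds]), 0)
    }
  }

  # error when no seed gene has incoming edges
  edgeless <- synthetic_spec(n_genes = 30L, mean_out_degree = 0,
                             signal_routing = "neighbors_only", seed = 2)
  net0 <- gen_network(edgeless)
  H0e <- gen_gene_cancer(edgeless, net0)
  expect_error(informative_genes(edgeless, net0, H0e), "incoming")
})

test_that("diffused weights cover neighbors_only informative genes; raw weights do not", {
  spec <- synthetic_spec(n_genes = 150L, n_cancers = 2L, mean_out_degree = 5,
                         signal_routing = "neighbors_only", seed = 29)
  network <- gen_network(spec)
  H0 <- gen_gene_cancer(spec, network)
  info <- informative_genes(spec, network, H0)
  diffused <- extract_weights(network, H0, propagation_config(n_layers = 2))
  raw_support <- network$genes[rowSums(H0) > 0]
  for (k in seq_along(info)) {
    diff_support <- network$genes[diffused[, k] > 0]
    expect_length(intersect(info[[k]], raw_support), 0)
    expect_setequal(intersect(info[[k]], diff_support), info[[k]])
  }
})

test_that("the clinical branch fixture matches the labeler exactly", {
  tbl <- gen_clinical_table(n_per_branch = 1, seed = 7)
  expect_equal(nrow(tbl), 8)
  expect_identical(gen_clinical_table(n_per_branch = 1, seed = 7), tbl)

  for (n_per in c(1, 3)) {
    tbl <- gen_clinical_table(n_per_branch = n_per, seed = 13)
    clin <- dplyr::select(tbl, -truth_label, -truth_reason) |>
      dplyr::rename(`PFI.time` = pfi_time)
    path <- tempfile(fileext = ".tsv")
    readr::write_tsv(clin, path, na = "NA", progress = FALSE)
    cohort <- assign_metastasis_labels(read_clinical_table(path))
    # labeled cases match the non-NA ground truth
    entries <- tidy(cohort)
    truth <- tbl[!is.na(tbl$truth_label), ]
    expect_setequal(entries$case_id, truth$case_id)
    expect_equal(entries$label[match(truth$case_id, entries$case_id)],
                 truth$truth_label)
    # exclusion reasons match the NA-truth branches
    excl_truth <- tbl[is.na(tbl$truth_label), ]
    expect_equal(
      cohort$excluded$reason[match(excl_truth$case_id, cohort$excluded$case_id)],
      excl_truth$truth_reason
    )
    # missing-PFI negatives drop at retention
    retained <- retain_longest_nonmet(cohort, fraction = 1.0)
    missing <- tbl$case_id[tbl$truth_reason == "missing_pfi"]
    expect_true(all(missing %in%
                      retained$excluded$case_id[retained$excluded$reason == "missing_pfi"]))
  }
})
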