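#' Shuffle cases into k cross-validation folds
#'
#' Cases are shuffled under the given seed, then dealt into `k` folds whose
#' sizes differ by at most one: `m %% k` folds of size `ceiling(m/k)` followed
#' by folds of size `floor(m/k)`.
#'
#' @param case_ids Character vector of unique case identifiers.
#' @param k Number of folds (default 10).
#' @param seed Integer seed governing the shuffle.
#' @param labels Optional binary labels; when given, folds are stratified so
#'   each fold has a near-proportional share of each class.
#' @return Tibble with columns `case_id`, `fold` (1..k).
#' @export
kfold_split <- function(case_ids, k = 10L, seed = 1L, labels = NULL) {
  m <- length(case_ids)
  k <- as.integer(k)
  if (anyDuplicated(case_ids) > 0) rlang::abort("case_ids must be unique")
  if (m < k) rlang::abort(sprintf("cannot split %d cases into %d folds", m, k))
  fold_sizes <- function(n) {
    base <- n %/% k
    sizes <- rep(base, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    sizes
  }
  assign_folds <- function(ids) rep(seq_len(k), fold_sizes(length(ids)))
  out <- withr::with_seed(seed, {
    if (is.null(labels)) {
      shuffled <- sample(case_ids)
      tibble::tibble(case_id = shuffled, fold = assign_folds(shuffled))
    } else {
      stopifnot(length(labels) == m)
      parts <- split(case_ids, labels)
      dplyr::bind_rows(lapply(parts, function(ids) {
        shuffled <- sample(ids)
        tibble::tibble(case_id = shuffled,
                       fold = utils::head(rep(sample(k), length.out = length(shuffled) + k),
                                          length(shuffled)))
      }))
    }
  })
  out[match(case_ids, out$case_id), ]
}

check_two_classes <- function(labels) {
  u <- unique(labels)
  if (!all(u %in% c(0, 1))) rlang::abort("labels must be 0/1")
  if (length(u) < 2) {
    rlang::abort("metric undefined: only one class present in labels")
  }
  invisible(labels)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation, which equals the
#' trapezoidal ROC integral and handles ties as half-concordant:
#' `P(score+ > score-) + P(score+ = score-) / 2`.
#'
#' @param labels Binary 0/1 vector; both classes must be present.
#' @param scores Numeric scores, higher = more likely positive.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' compute_auroc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1))
compute_auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  check_two_classes(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise convention: thresholds sweep the distinct score values from high
#' to low and the area is `sum over thresholds of (recall_t - recall_{t-1}) *
#' precision_t` (no linear interpolation between PR points; equal scores enter
#' together).
#'
#' @inheritParams compute_auroc
#' @return AUPRC in `(0, 1]`.
#' @export
#' @examples
#' compute_auprc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.1))
compute_auprc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (!all(labels %in% c(0, 1))) rlang::abort("labels must be 0/1")
  if (sum(labels == 1) == 0) rlang::abort("metric undefined: no positive labels")
  pr <- pr_points(labels, scores)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

pr_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  scores <- scores[ord]
  # cumulative counts at each distinct-score cut
  cut <- which(!duplicated(scores, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(labels == 1)[cut]
  fp <- cumsum(labels == 0)[cut]
  n1 <- sum(labels == 1)
  tibble::tibble(
    threshold = scores[cut],
    precision = tp / (tp + fp),
    recall = tp / n1
  )
}

roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  labels <- labels[ord]
  scores <- scores[ord]
  cut <- which(!duplicated(scores, fromLast = TRUE))
  tp <- cumsum(labels == 1)[cut]
  fp <- cumsum(labels == 0)[cut]
  tibble::tibble(
    threshold = c(Inf, scores[cut]),
    fpr = c(0, fp / sum(labels == 0)),
    tpr = c(0, tp / sum(labels == 1))
  )
}

#' ROC and PR curve coordinates
#'
#' @inheritParams compute_auroc
#' @return Tibble of curve coordinates: `threshold`, `fpr`, `tpr` for
#'   `roc_curve()`; `threshold`, `recall`, `precision` for `pr_curve()`.
#' @export
roc_curve <- function(labels, scores) {
  check_two_classes(labels)
  roc_points(labels, scores)
}

#' @rdname roc_curve
#' @export
pr_curve <- function(labels, scores) {
  if (sum(labels == 1) == 0) rlang::abort("no positive labels")
  pr_points(labels, scores)
}

#' Cross-validated CNN evaluation of a feature tensor
#'
#' Splits the samples into `k` shuffled folds, trains a fresh CNN on the
#' other `k - 1` folds for each fold in turn, scores the held-out samples, and
#' reports per-fold and mean AUROC/AUPRC. The positive class is metastasis
#' (label 1) throughout. If a training split would be single-class, the split
#' is redrawn with `seed + 1` (and so on), with a message.
#'
#' @param features A `feature_tensor` from [weight_expression()].
#' @param labels Binary 0/1 vector, one per sample (1 = metastasis).
#' @param cnn_config A [cnn_config()]; `NULL` uses defaults adapted to the
#'   tensor's spatial shape via [clamp_cnn_config()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed for fold shuffling and model initialization.
#' @param stratified Stratify folds by label (default `FALSE`: plain shuffled
#'   folds).
#' @param pooled Also compute metrics on the pooled out-of-fold scores.
#' @return A `cv_result`: list with `folds` (tibble: `fold`, `auroc`,
#'   `auprc`, `n_test`), `mean_auroc`, `mean_auprc`, `fold_assignments`,
#'   `scores` (tibble of out-of-fold scores), `curves` (per-fold ROC/PR
#'   coordinates), `pooled` (optional), `seed`.
#' @export
cross_validate <- function(features, labels, cnn_config = NULL, k = 10L,
                           seed = 1L, stratified = FALSE, pooled = FALSE) {
  stopifnot(inherits(features, "feature_tensor"))
  m <- dim(features$values)[1]
  if (length(labels) != m) {
    rlang::abort(sprintf("%d labels for %d samples", length(labels), m))
  }
  check_two_classes(labels)
  if (is.null(cnn_config)) {
    cnn_config <- clamp_cnn_config(cnn_config(seed = seed),
                                   input_shape = dim(features$values)[-1])
  }
  ids <- features$sample_ids
  if (is.null(ids)) ids <- as.character(seq_len(m))

  split_seed <- seed
  repeat {
    assignment <- kfold_split(ids, k = k, seed = split_seed,
                              labels = if (stratified) labels else NULL)
    ok <- vapply(seq_len(k), function(f) {
      train_lab <- labels[assignment$fold != f]
      length(unique(train_lab)) == 2
    }, logical(1))
    if (all(ok)) break
    message(sprintf("single-class training split under seed %d; redrawing with seed %d",
                    split_seed, split_seed + 1L))
    split_seed <- split_seed + 1L
  }

  fold_rows <- list()
  score_rows <- list()
  curve_rows <- list()
  for (f in seq_len(k)) {
    test_idx <- which(assignment$fold == f)
    train_idx <- which(assignment$fold != f)
    model <- train_cnn(subset_samples(features, train_idx), labels[train_idx],
                       config = cnn_config, seed = seed + f)
    prob <- predict_proba(model, subset_samples(features, test_idx))
    sc <- prob[, 2]
    lab <- labels[test_idx]
    auroc <- if (length(unique(lab)) == 2) compute_auroc(lab, sc) else NA_real_
    auprc <- if (any(lab == 1)) compute_auprc(lab, sc) else NA_real_
    fold_rows[[f]] <- tibble::tibble(fold = f, auroc = auroc, auprc = auprc,
                                     n_test = length(test_idx))
    score_rows[[f]] <- tibble::tibble(case_id = ids[test_idx], fold = f,
                                      label = lab, score = sc)
    curve_rows[[f]] <- list(
      roc = if (!is.na(auroc)) roc_curve(lab, sc) else NULL,
      pr = if (!is.na(auprc)) pr_curve(lab, sc) else NULL
    )
  }
  folds <- dplyr::bind_rows(fold_rows)
  scores <- dplyr::bind_rows(score_rows)
  res <- structure(
    list(
      folds = folds,
      mean_auroc = mean(folds$auroc, na.rm = TRUE),
      mean_auprc = mean(folds$auprc, na.rm = TRUE),
      fold_assignments = assignment,
      scores = scores,
      curves = curve_rows,
      seed = seed,
      split_seed = split_seed
    ),
    class = "cv_result"
  )
  if (pooled) {
    res$pooled <- tibble::tibble(
      auroc = compute_auroc(scores$label, scores$score),
      auprc = compute_auprc(scores$label, scores$score)
    )
  }
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds | mean AUROC %.4f | mean AUPRC %.4f\n",
              nrow(x$folds), x$mean_auroc, x$mean_auprc))
  invisible(x)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per fold: `fold`, `auroc`, `auprc`, `n_test`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' One-row cross-validation summary
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with `mean_auroc`, `mean_auprc`, `k`, `seed`.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(mean_auroc = x$mean_auroc, mean_auprc = x$mean_auprc,
                 k = nrow(x$folds), seed = x$seed)
}

#' Plot cross-validated ROC or PR curves
#'
#' @param object A `cv_result`.
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object with one curve per fold.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    d <- purrr::imap_dfr(object$curves, function(cv, f) {
      if (is.null(cv$roc)) return(NULL)
      dplyr::mutate(cv$roc, fold = factor(f))
    })
    ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$fold)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::geom_step() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC by fold (mean AUROC %.3f)", object$mean_auroc)) +
      ggplot2::theme_minimal()
  } else {
    d <- purrr::imap_dfr(object$curves, function(cv, f) {
      if (is.null(cv$pr)) return(NULL)
      dplyr::mutate(cv$pr, fold = factor(f))
    })
    ggplot2::ggplot(d, ggplot2::aes(x = .data$recall, y = .data$precision,
                                    colour = .data$fold)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("PR by fold (mean AUPRC %.3f)", object$mean_auprc)) +
      ggplot2::theme_minimal()
  }
}

#' Write cross-validation metrics and curve coordinates
#'
#' @param result A `cv_result`.
#' @param dir Output directory (created if needed); writes `metrics.tsv`,
#'   `roc_curves.csv`, `pr_curves.csv`.
#' @return `dir`, invisibly.
#' @export
write_cv_result <- function(result, dir) {
  stopifnot(inherits(result, "cv_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$folds, file.path(dir, "metrics.tsv"), progress = FALSE)
  roc <- purrr::imap_dfr(result$curves, function(cv, f) {
    if (is.null(cv$roc)) return(NULL)
    dplyr::mutate(cv$roc, fold = f)
  })
  pr <- purrr::imap_dfr(result$curves, function(cv, f) {
    if (is.null(cv$pr)) return(NULL)
    dplyr::mutate(cv$pr, fold = f)
  })
  readr::write_csv(roc, file.path(dir, "roc_curves.csv"), progress = FALSE)
  readr::write_csv(pr, file.path(dir, "pr_curves.csv"), progress = FALSE)
  invisible(dir)
}
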