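#' CNN classifier configuration
#'
#' The classifier is a stack of convolution + LeakyReLU blocks (seven by
#' default), a flatten layer, batch normalization, a dense layer with dropout,
#' and a softmax output over the two classes, trained with Adam on categorical
#' cross-entropy. The default block table shrinks the long gene axis with
#' strided tall kernels while preserving the narrow cancer-type axis.
#'
#' @param filters Integer vector, one entry per conv block.
#' @param kernels List of `c(height, width)` kernel sizes, one per block.
#' @param strides List of `c(height, width)` strides, one per block.
#' @param leaky_slope Negative-part slope of every LeakyReLU (default 0.1).
#' @param dense_units Units in the penultimate dense layer.
#' @param dropout_rate Dropout rate between the two dense layers, in `[0, 1)`.
#' @param n_classes Number of output classes (softmax units); 2.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed for parameter initialization, shuffling, dropout.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(filters = c(8L, 8L, 16L, 16L, 32L, 32L, 64L),
                       kernels = list(c(7, 1), c(7, 1), c(5, 1), c(5, 1),
                                      c(3, 3), c(3, 3), c(3, 1)),
                       strides = list(c(2, 1), c(2, 1), c(2, 1), c(2, 1),
                                      c(1, 1), c(1, 1), c(1, 1)),
                       leaky_slope = 0.1,
                       dense_units = 64L,
                       dropout_rate = 0.5,
                       n_classes = 2L,
                       learning_rate = 1e-3,
                       batch_size = 32L,
                       epochs = 50L,
                       seed = 1L) {
  n_blocks <- length(filters)
  if (length(kernels) != n_blocks || length(strides) != n_blocks) {
    rlang::abort("`filters`, `kernels`, and `strides` must have equal length")
  }
  if (n_blocks != 7L) {
    rlang::inform(sprintf("using %d conv blocks instead of the default 7", n_blocks))
  }
  if (leaky_slope <= 0) rlang::abort("`leaky_slope` must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    rlang::abort("`dropout_rate` must be in [0, 1)")
  }
  structure(
    list(
      filters = as.integer(filters),
      kernels = lapply(kernels, as.integer),
      strides = lapply(strides, as.integer),
      leaky_slope = leaky_slope,
      dense_units = as.integer(dense_units),
      dropout_rate = dropout_rate,
      n_classes = as.integer(n_classes),
      learning_rate = learning_rate,
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      seed = as.integer(seed)
    ),
    class = "cnn_config"
  )
}

config_matrices <- function(config) {
  list(
    filters = config$filters,
    kernels = do.call(rbind, config$kernels),
    strides = do.call(rbind, config$strides),
    leaky_slope = config$leaky_slope,
    dense_units = config$dense_units,
    dropout_rate = config$dropout_rate,
    learning_rate = config$learning_rate,
    batch_size = config$batch_size,
    epochs = config$epochs,
    n_classes = config$n_classes
  )
}

#' Infer the spatial shape after every conv block
#'
#' Valid-mode shape inference: block output height is
#' `floor((h - kh) / sh) + 1` (same for width). Errors when a kernel exceeds
#' the running shape, naming the offending block.
#'
#' @param config A [cnn_config()].
#' @param input_shape `c(channels, height, width)`, e.g. `c(1, G, K)`.
#' @return Tibble with one row per block: `block`, `height`, `width`,
#'   `channels`.
#' @export
cnn_shape_chain <- function(config, input_shape) {
  stopifnot(inherits(config, "cnn_config"), length(input_shape) == 3)
  cm <- config_matrices(config)
  shapes <- cpp_cnn_shapes(cm$filters, cm$kernels, cm$strides,
                           as.integer(input_shape[2]), as.integer(input_shape[3]))
  tibble::tibble(
    block = seq_len(nrow(shapes)),
    height = shapes[, 1],
    width = shapes[, 2],
    channels = shapes[, 3]
  )
}

#' Adapt kernel sizes to a narrow input
#'
#' The default block table assumes at least 6 columns (cancer types) and ~500
#' rows (genes). For narrower or shorter inputs this clamps each block's
#' kernel and stride to the running spatial shape so the model still builds;
#' the clamped table is returned as an ordinary, fully inspectable config.
#'
#' @param config A [cnn_config()].
#' @param input_shape `c(channels, height, width)`.
#' @return A `cnn_config` whose kernels/strides fit `input_shape`.
#' @export
clamp_cnn_config <- function(config, input_shape) {
  stopifnot(inherits(config, "cnn_config"), length(input_shape) == 3)
  h <- as.integer(input_shape[2]); w <- as.integer(input_shape[3])
  kernels <- config$kernels
  strides <- config$strides
  for (b in seq_along(kernels)) {
    kh <- min(kernels[[b]][1], h); kw <- min(kernels[[b]][2], w)
    sh <- strides[[b]][1]; sw <- strides[[b]][2]
    kernels[[b]] <- c(kh, kw)
    h <- (h - kh) %/% sh + 1L
    w <- (w - kw) %/% sw + 1L
  }
  config$kernels <- lapply(kernels, as.integer)
  config$strides <- lapply(strides, as.integer)
  config
}

#' @export
print.cnn_config <- function(x, ...) {
  cat(sprintf(
    "<cnn_config> %d conv blocks | LeakyReLU slope %g | dense %d | dropout %g | adam lr %g | batch %d | epochs %d\n",
    length(x$filters), x$leaky_slope, x$dense_units, x$dropout_rate,
    x$learning_rate, x$batch_size, x$epochs
  ))
  invisible(x)
}

#' Read / write a CNN configuration as YAML or JSON
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param config A [cnn_config()] (writer only).
#' @return The `cnn_config` (reader); `path` invisibly (writer).
#' @export
read_cnn_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw), names(formals(cnn_config)))]
  # JSON/YAML readers may return a blocks-by-2 matrix or a flat vector
  as_pair_list <- function(x) {
    if (is.matrix(x)) return(asplit(x, 1))
    if (!is.list(x)) return(asplit(matrix(unlist(x), ncol = 2, byrow = TRUE), 1))
    x
  }
  if (!is.null(args$kernels)) args$kernels <- as_pair_list(args$kernels)
  if (!is.null(args$strides)) args$strides <- as_pair_list(args$strides)
  do.call(cnn_config, args)
}

#' @rdname read_cnn_config
#' @export
write_cnn_config <- function(config, path) {
  stopifnot(inherits(config, "cnn_config"))
  obj <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}

#' Train the CNN classifier on a feature tensor
#'
#' Labels are one-hot encoded internally; class order is fixed as
#' `(non-metastasis, metastasis)` and the positive class for downstream
#' metrics is metastasis. Training is deterministic under `seed` (parameter
#' initialization, batch shuffling, and dropout all draw from one seeded
#' generator).
#'
#' @param features A `feature_tensor` from [weight_expression()].
#' @param labels Binary 0/1 vector with both classes present.
#' @param config A [cnn_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A `drgcn_cnn` fitted model: list with `fit` (weights and batch-norm
#'   statistics), `history` (tibble of per-epoch training loss), `config`,
#'   `class_order`, `input_shape`.
#' @export
train_cnn <- function(features, labels, config = cnn_config(), seed = NULL) {
  stopifnot(inherits(features, "feature_tensor"), inherits(config, "cnn_config"))
  m <- dim(features$values)[1]
  if (length(labels) != m) {
    rlang::abort(sprintf("%d labels for %d samples", length(labels), m))
  }
  check_two_classes(labels)
  if (!all(is.finite(features$values))) rlang::abort("features must be finite")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cnn_shape_chain(config, dim(features$values)[-1])  # validates, errors early
  fit <- cpp_cnn_train(features$values, as.integer(labels),
                       config_matrices(config), config$seed)
  structure(
    list(
      fit = fit,
      history = tibble::tibble(epoch = seq_along(fit$history),
                               loss = as.numeric(fit$history)),
      config = config,
      class_order = c("non-metastasis", "metastasis"),
      input_shape = dim(features$values)[-1]
    ),
    class = "drgcn_cnn"
  )
}

#' @export
print.drgcn_cnn <- function(x, ...) {
  cat(sprintf(
    "<drgcn_cnn> input (1, %d, %d) | %d conv blocks | final training loss %.4f\n",
    x$input_shape[2], x$input_shape[3], length(x$config$filters),
    utils::tail(x$history$loss, 1)
  ))
  invisible(x)
}

#' Predict class probabilities
#'
#' @param trained A `drgcn_cnn` from [train_cnn()].
#' @param features A `feature_tensor` with the same gene/cancer dimensions as
#'   the training tensor.
#' @return `m x 2` matrix of class probabilities; columns follow
#'   `trained$class_order` (metastasis second). Rows sum to 1.
#' @export
predict_proba <- function(trained, features) {
  stopifnot(inherits(trained, "drgcn_cnn"), inherits(features, "feature_tensor"))
  d <- dim(features$values)
  if (d[1] == 0) {
    out <- matrix(numeric(0), 0, trained$config$n_classes)
    colnames(out) <- trained$class_order
    return(out)
  }
  if (!all(d[-1] == trained$input_shape)) {
    rlang::abort(sprintf(
      "feature shape (1, %d, %d) does not match training shape (1, %d, %d)",
      d[3], d[4], trained$input_shape[2], trained$input_shape[3]
    ))
  }
  out <- cpp_cnn_predict(trained$fit, features$values,
                         config_matrices(trained$config))
  colnames(out) <- trained$class_order
  rownames(out) <- features$sample_ids
  out
}

#' @export
predict.drgcn_cnn <- function(object, features, ...) {
  predict_proba(object, features)
}

#' Tidy the training history of a fitted CNN
#'
#' @param x A `drgcn_cnn`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss`.
#' @method tidy drgcn_cnn
#' @export
tidy.drgcn_cnn <- function(x, ...) x$history

#' One-row summary of a fitted CNN
#'
#' @param x A `drgcn_cnn`.
#' @param ... Unused.
#' @return Tibble with initial/final loss, epochs, and seed.
#' @method glance drgcn_cnn
#' @export
glance.drgcn_cnn <- function(x, ...) {
  tibble::tibble(
    initial_loss = x$history$loss[1],
    final_loss = utils::tail(x$history$loss, 1),
    epochs = nrow(x$history),
    seed = x$config$seed
  )
}

#' Save / load a fitted CNN
#'
#' @param model A `drgcn_cnn`.
#' @param path Output path (`.rds`).
#' @return `path` invisibly (writer); the `drgcn_cnn` (reader).
#' @export
write_cnn <- function(model, path) {
  stopifnot(inherits(model, "drgcn_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_cnn
#' @export
read_cnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "drgcn_cnn")) rlang::abort("not a drgcn_cnn model file")
  model
}
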