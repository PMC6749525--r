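#' Declare a classifier architecture
#'
#' Builds the layer list of one of the four fully convolutional variants or
#' the dense-headed CNN baseline, for 30 x 24 single-channel input images.
#' All convolutions are 3 x 3 with 'same' padding, biases, and ReLU; max
#' pooling is 2 x 2 with floor on odd dimensions (30 x 24 -> 15 x 12 ->
#' 7 x 6). Every FCN variant ends `conv(6) -> global average pooling ->
#' softmax`, with dropout 0.25 before the last convolution; the CNN replaces
#' the last convolution and GAP with two ReLU dense layers of 256 units
#' (dropout 0.5 after each) and a softmax output layer.
#'
#' @param variant one of `"FCN-I"`, `"FCN-II"`, `"FCN-III"`, `"FCN-IV"`,
#'   `"CNN"`.
#' @param n_classes number of output classes.
#' @param input_shape height and width of the input image.
#' @return an `fcn_spec` object.
#' @export
build_spec <- function(variant = c("FCN-III", "FCN-I", "FCN-II", "FCN-IV", "CNN"),
                       n_classes = 6L, input_shape = c(30L, 24L)) {
  valid <- c("FCN-I", "FCN-II", "FCN-III", "FCN-IV", "CNN")
  if (length(variant) == 1L && !variant %in% valid)
    stop("unknown variant '", variant, "'; valid variants: ",
         paste(valid, collapse = ", "))
  variant <- match.arg(variant)
  conv <- function(f) list(type = "conv", filters = as.integer(f),
                           kernel = c(3L, 3L), padding = "same",
                           activation = "relu")
  pool <- list(type = "maxpool", size = c(2L, 2L))
  drop <- function(r) list(type = "dropout", rate = r)
  dense <- function(u, act) list(type = "dense", units = as.integer(u),
                                 activation = act)
  fcn_tail <- c(list(drop(0.25), conv(n_classes), list(type = "gap")))
  layers <- switch(
    variant,
    "FCN-I" = c(list(conv(16), conv(16), pool, conv(32), pool), fcn_tail),
    "FCN-II" = c(list(conv(32), conv(32), pool, conv(64), pool), fcn_tail),
    "FCN-III" = c(list(conv(32), conv(32), pool, conv(64), conv(64), pool),
                  fcn_tail),
    "FCN-IV" = c(list(conv(32), conv(32), conv(32), pool, conv(64), conv(64),
                      pool), fcn_tail),
    "CNN" = list(conv(32), conv(32), pool, conv(64), conv(64), pool,
                 list(type = "flatten"),
                 dense(256, "relu"), drop(0.5),
                 dense(256, "relu"), drop(0.5),
                 dense(n_classes, "linear"))
  )
  structure(list(variant = variant, layers = layers,
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape)),
            class = "fcn_spec")
}

# Lower an fcn_spec to the flat layer list the C++ engine consumes.
lower_spec <- function(spec) {
  lapply(spec$layers, function(L) {
    switch(L$type,
           conv = list(type = "conv", filters = L$filters),
           maxpool = list(type = "maxpool"),
           dropout = list(type = "dropout", rate = L$rate),
           gap = list(type = "gap"),
           flatten = list(type = "flatten"),
           dense = list(type = "dense", units = L$units,
                        activation = L$activation),
           stop("unknown layer type: ", L$type))
  })
}

#' Count trainable parameters of an architecture in closed form
#'
#' Walks the layer list tracking spatial dimensions ('same' convolutions
#' preserve them, 2 x 2 pooling floor-divides them) and sums
#' `filters * (kernel_area * in_channels + 1)` per convolution and
#' `in * out + out` per dense layer; pooling, GAP, dropout and the softmax
#' activation contribute nothing.
#'
#' @param spec an `fcn_spec` from [build_spec()].
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "fcn_spec"))
  h <- spec$input_shape[1L]; w <- spec$input_shape[2L]
  chans <- 1L
  dim_vec <- NA_integer_  # vector dimension once spatial structure collapses
  total <- 0
  for (L in spec$layers) {
    if (L$type == "conv") {
      total <- total + L$filters * (prod(L$kernel) * chans + 1L)
      chans <- L$filters
    } else if (L$type == "maxpool") {
      h <- h %/% L$size[1L]; w <- w %/% L$size[2L]
    } else if (L$type == "gap") {
      dim_vec <- chans
    } else if (L$type == "flatten") {
      dim_vec <- chans * h * w
    } else if (L$type == "dense") {
      total <- total + dim_vec * L$units + L$units
      dim_vec <- L$units
    }
  }
  as.integer(total)
}

#' @export
print.fcn_spec <- function(x, ...) {
  cat(sprintf("<fcn_spec> %s  (input %d x %d, %d classes)\n",
              x$variant, x$input_shape[1L], x$input_shape[2L], x$n_classes))
  for (i in seq_along(x$layers)) {
    L <- x$layers[[i]]
    desc <- switch(L$type,
                   conv = sprintf("Conv. %d@(%d x %d), %s, %s",
                                  L$filters, L$kernel[1L], L$kernel[2L],
                                  L$padding, L$activation),
                   maxpool = sprintf("Max Pooling (%d x %d)",
                                     L$size[1L], L$size[2L]),
                   dropout = sprintf("Dropout (%.2f)", L$rate),
                   gap = "Global Average Pooling",
                   flatten = "Flatten",
                   dense = sprintf("Dense %d, %s", L$units, L$activation))
    cat(sprintf("  %2d  %s\n", i, desc))
  }
  cat("  --  Softmax\n")
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the standard recipe for this model family: Adam with a
#' constant learning rate of 1e-4, batch size 32, at most 400 epochs with
#' early stopping on validation loss (10% of the training set held out as
#' validation), restoring the best weights.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs upper bound on epochs (0 = return initialized,
#'   untrained weights).
#' @param patience epochs without validation-loss improvement before
#'   stopping.
#' @param validation_fraction fraction of samples held out for validation;
#'   0 disables early stopping.
#' @param seed integer seed driving initialization, shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return a `training_config` object.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 32L,
                            max_epochs = 400L, patience = 20L,
                            validation_fraction = 0.10, seed = 1L,
                            verbose = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (max_epochs < 0L) stop("max_epochs must be >= 0")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in [0, 1)")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "training_config")
}

#' Train a classifier on encoded images
#'
#' Minibatch softmax cross-entropy training with Adam, optional early
#' stopping on a held-out validation split, restoring the best weights. A
#' fixed seed makes runs reproducible.
#'
#' @param spec an `fcn_spec`.
#' @param images array `height x width x n` of encoded windows.
#' @param labels character or factor vector of length n; classes are mapped
#'   to output indices in alphabetical order.
#' @param config a [training_config()].
#' @param encoding optional list describing how `images` were produced
#'   (e.g. `encode_windows()`'s `stats`); stored on the model so the same
#'   transform is applied at prediction time by [run_gated()].
#' @return a `har_model`: spec, weights, classes, per-epoch `history`,
#'   `epochs_run`, and `encoding`.
#' @export
train_model <- function(spec, images, labels, config = training_config(),
                        encoding = NULL) {
  stopifnot(inherits(spec, "fcn_spec"), inherits(config, "training_config"))
  d <- dim(images)
  if (length(d) != 3L || d[1L] != spec$input_shape[1L] ||
      d[2L] != spec$input_shape[2L])
    stop("images must be a ", spec$input_shape[1L], " x ",
         spec$input_shape[2L], " x n array")
  if (d[3L] == 0L) stop("cannot train on an empty dataset")
  if (length(labels) != d[3L]) stop("length(labels) must match dim(images)[3]")
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2L)
    stop("training requires at least 2 classes; got ", length(classes))
  if (length(classes) > spec$n_classes)
    stop("more classes in labels (", length(classes),
         ") than model outputs (", spec$n_classes, ")")
  y <- match(as.character(labels), classes) - 1L
  fit <- fcn_train_cpp(images, y, lower_spec(spec), unclass(config))
  structure(list(spec = spec, weights = fit$weights, classes = classes,
                 history = fit$history, epochs_run = fit$epochs_run,
                 config = config, encoding = encoding),
            class = "har_model")
}

#' @export
print.har_model <- function(x, ...) {
  cat(sprintf("<har_model> %s, %d classes, trained %d epoch(s)\n",
              x$spec$variant, length(x$classes), x$epochs_run))
  invisible(x)
}

#' Predict activity classes or probabilities for encoded images
#'
#' @param object a `har_model`.
#' @param images array `height x width x n`.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... unused.
#' @return character vector of labels or an n x K probability matrix with
#'   class names as columns. Argmax ties break toward the lowest class
#'   index.
#' @export
predict.har_model <- function(object, images, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  d <- dim(images)
  if (length(d) == 2L) { images <- array(images, dim = c(d, 1L)); d <- dim(images) }
  if (d[1L] != object$spec$input_shape[1L] ||
      d[2L] != object$spec$input_shape[2L])
    stop("image shape ", d[1L], " x ", d[2L], " does not match the model input ",
         object$spec$input_shape[1L], " x ", object$spec$input_shape[2L])
  P <- fcn_predict_cpp(images, lower_spec(object$spec), object$weights)
  if (ncol(P) > length(object$classes))
    P <- P[, seq_along(object$classes), drop = FALSE]
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' Deterministic fold assignment for k-fold cross-validation
#'
#' Samples are shuffled with the given seed and dealt into k folds whose
#' sizes differ by at most one; the assignment depends only on `n`, `k` and
#' `seed`.
#'
#' @param n number of samples.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k, length n.
#' @export
make_folds <- function(n, k, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k samples")
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
  fold
}

#' k-fold cross-validation of a classifier
#'
#' Random partition at the window level: each sample appears in exactly one
#' test fold. Returns the per-fold accuracies and their mean and standard
#' deviation. Note that with overlapping windows from few subjects this
#' random (non-subject-wise) partition lets windows from one subject appear
#' in both train and test folds; that caveat is inherent to the protocol.
#'
#' @param spec an `fcn_spec`.
#' @param images array `height x width x n`.
#' @param labels vector of length n.
#' @param k number of folds.
#' @param config a [training_config()]; its seed also fixes the partition.
#' @return list with `fold_accuracy`, `mean`, `sd`, `folds`.
#' @export
cross_validate <- function(spec, images, labels, k = 10L,
                           config = training_config()) {
  n <- dim(images)[3L]
  folds <- make_folds(n, k, config$seed)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- train_model(spec, images[, , tr, drop = FALSE], labels[tr], config)
    pred <- predict(fit, images[, , !tr, drop = FALSE])
    acc[f] <- mean(pred == as.character(labels)[!tr])
  }
  list(fold_accuracy = acc, mean = mean(acc), sd = sd(acc), folds = folds)
}
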