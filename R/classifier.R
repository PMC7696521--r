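# The three-layer CNN classifier over asymmetry images.

#' CNN configuration
#'
#' Defaults reproduce the reference architecture exactly: three valid-padding
#' 3x3 convolution blocks (32, 64, 128 filters) each followed by 2x2 max
#' pooling (floor division for odd inputs), batch normalization after the
#' first pool, a 256-unit ReLU dense layer with dropout, and a single
#' sigmoid output unit; trained with Adam (learning rate 1e-4) on binary
#' cross-entropy for 10 epochs of mini-batches.
#'
#' @param input_shape Image dimensions; fixed at `c(64, 64, 3)`.
#' @param conv_filters Filters per convolution block.
#' @param kernel Convolution kernel side (3).
#' @param pool Pooling window/stride (2).
#' @param dense_units Hidden dense layer width (256).
#' @param dropout_rate Dropout fraction on the hidden dense layer
#'   (default 0.5).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Training passes over the data (default 10).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed governing weight initialization, shuffling and
#'   dropout masks.
#' @param threshold Decision threshold on the sigmoid output (default 0.5).
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(input_shape = c(64L, 64L, 3L),
                       conv_filters = c(32L, 64L, 128L),
                       kernel = 3L, pool = 2L, dense_units = 256L,
                       dropout_rate = 0.5, learning_rate = 1e-4,
                       epochs = 10L, batch_size = 32L, seed = 1L,
                       threshold = 0.5) {
  if (!identical(as.integer(input_shape), c(64L, 64L, 3L)) ||
      !identical(as.integer(conv_filters), c(32L, 64L, 128L)) ||
      kernel != 3L || pool != 2L || dense_units != 256L) {
    stop(paste("this implementation is specialized to the reference",
               "architecture: 64x64x3 input, 32/64/128 conv filters,",
               "3x3 kernels, 2x2 pooling, 256 dense units"), call. = FALSE)
  }
  stopifnot(dropout_rate >= 0, dropout_rate < 1, learning_rate >= 0,
            epochs >= 1, batch_size >= 1)
  structure(
    list(input_shape = c(64L, 64L, 3L), conv_filters = c(32L, 64L, 128L),
         kernel = 3L, pool = 2L, dense_units = 256L,
         dropout_rate = dropout_rate, learning_rate = learning_rate,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         seed = as.integer(seed), threshold = threshold,
         adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-7,
         bn_momentum = 0.99, bn_eps = 1e-3),
    class = "cnn_config")
}

#' Layer-by-layer output shapes and parameter counts
#'
#' Computed from first principles (valid convolution arithmetic and
#' `(k*k*c_in + 1)*c_out` weight counting) for the default architecture.
#' Batch normalization stores scale, shift, moving mean and moving variance
#' (4 values per channel); the moving statistics are non-trainable.
#'
#' @param config A [cnn_config()].
#' @return Data frame with columns `layer`, `output_shape`, `params`.
#' @export
cnn_layer_summary <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  k <- config$kernel
  conv_params <- function(c_in, c_out) (k * k * c_in + 1L) * c_out
  h <- config$input_shape[1L]
  c_in <- config$input_shape[3L]
  rows <- list(list("Input", c(h, h, c_in), 0L))
  stage <- function(rows, h, c_in, c_out, label_c, label_p, with_bn = FALSE) {
    h2 <- h - k + 1L
    rows <- c(rows, list(list(label_c, c(h2, h2, c_out),
                              conv_params(c_in, c_out))))
    h3 <- h2 %/% config$pool
    rows <- c(rows, list(list(label_p, c(h3, h3, c_out), 0L)))
    if (with_bn) {
      rows <- c(rows, list(list("BatchNorm", c(h3, h3, c_out), 4L * c_out)))
    }
    attr(rows, "h") <- h3
    rows
  }
  f <- config$conv_filters
  rows <- stage(rows, h, c_in, f[1L], "Conv1", "Pool1", with_bn = TRUE)
  h <- attr(rows, "h")
  rows <- stage(rows, h, f[1L], f[2L], "Conv2", "Pool2")
  h <- attr(rows, "h")
  rows <- stage(rows, h, f[2L], f[3L], "Conv3", "Pool3")
  h <- attr(rows, "h")
  flat <- h * h * f[3L]
  rows <- c(rows, list(
    list("Flatten", flat, 0L),
    list("Dense1", config$dense_units,
         (flat + 1L) * config$dense_units),
    list("Dropout", config$dense_units, 0L),
    list("Output", 1L, config$dense_units + 1L)))
  data.frame(
    layer = vapply(rows, function(r) r[[1L]], character(1L)),
    output_shape = vapply(rows, function(r)
      paste(r[[2L]], collapse = "x"), character(1L)),
    params = vapply(rows, function(r) as.integer(r[[3L]]), integer(1L)),
    stringsAsFactors = FALSE)
}

#' Build an untrained CNN
#'
#' Initializes weights (Glorot-uniform, biases zero, batch-norm scale 1 /
#' shift 0) under `config$seed`.
#'
#' @param config A [cnn_config()].
#' @return An object of class `cnn_model`: list with `weights`, `config`,
#'   `history` (`NULL` until trained).
#' @export
build_cnn <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(config$seed)
  w <- cnn_init_cpp()
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(weights = w, config = config, history = NULL),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  s <- cnn_layer_summary(x$config)
  cat(sprintf("<cnn_model> %s, %s parameters\n",
              if (is.null(x$history)) "untrained" else "trained",
              format(sum(s$params), big.mark = ",")))
  print(s, row.names = FALSE)
  invisible(x)
}

# Flatten an image set / list of images / array into the n x 12288 matrix
# the C++ backend consumes, plus labels when available.
image_matrix <- function(images) {
  if (inherits(images, "image_set")) return(images$x)
  if (is.matrix(images) && ncol(images) == 64L * 64L * 3L) return(images)
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- list(images)
  }
  if (is.list(images)) {
    x <- t(vapply(images, function(im) {
      d <- dim(im)
      if (length(d) != 3L || !all(d == c(64L, 64L, 3L))) {
        stop("each image must be a 64x64x3 array", call. = FALSE)
      }
      as.vector(unclass(im))
    }, numeric(64L * 64L * 3L)))
    return(x)
  }
  if (is.array(images) && length(dim(images)) == 4L) {
    d <- dim(images)
    if (!all(d[2:4] == c(64L, 64L, 3L))) {
      stop("image array must be n x 64 x 64 x 3", call. = FALSE)
    }
    return(matrix(images, nrow = d[1L]))
  }
  stop("cannot interpret `images` as 64x64x3 RGB images", call. = FALSE)
}

#' Train the CNN
#'
#' Mini-batch Adam on binary cross-entropy.  The positive class (label 1)
#' is MDD-like; controls are 0.  Training is fully seeded: weight
#' initialization (already fixed by [build_cnn()]), epoch shuffling and
#' dropout masks are all drawn from R's RNG seeded with `config$seed`, so
#' identical runs reproduce identical weights.
#'
#' @param model A `cnn_model` from [build_cnn()].
#' @param images An `image_set`, list of 64x64x3 arrays, or n x 64 x 64 x 3
#'   array.
#' @param labels Binary labels (0/1); taken from the image set when omitted.
#' @param config Overrides the model's config when supplied.
#' @return The trained `cnn_model`; `history` holds per-epoch training loss
#'   and accuracy.
#' @export
train_cnn <- function(model, images, labels = NULL, config = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  if (!is.null(config)) model$config <- config
  cfg <- model$config
  x <- image_matrix(images)
  if (is.null(labels) && inherits(images, "image_set")) {
    labels <- images$manifest$label
  }
  labels <- as.numeric(labels)
  if (length(labels) != nrow(x)) {
    stop("need one label per image", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  set.seed(cfg$seed)
  fit <- cnn_train_cpp(model$weights, x, labels,
                       epochs = cfg$epochs, batch = cfg$batch_size,
                       lr = cfg$learning_rate, dropout = cfg$dropout_rate,
                       beta1 = cfg$adam_beta1, beta2 = cfg$adam_beta2,
                       adam_eps = cfg$adam_eps,
                       bn_momentum = cfg$bn_momentum, bn_eps = cfg$bn_eps,
                       shuffle = TRUE)
  model$weights <- fit$weights
  model$history <- data.frame(epoch = seq_along(fit$loss),
                              loss = fit$loss, accuracy = fit$accuracy)
  model
}

#' Predict per-image class probabilities
#'
#' Inference mode: dropout disabled, batch normalization uses moving
#' statistics; repeated calls on the same input give identical outputs.
#'
#' @param model A `cnn_model`.
#' @param images Images in any form accepted by [train_cnn()].
#' @param type `"prob"` for sigmoid probabilities, `"class"` for hard 0/1
#'   calls at the config threshold.
#' @return Numeric vector of probabilities (or integer class labels).
#' @export
predict_cnn <- function(model, images, type = c("prob", "class")) {
  stopifnot(inherits(model, "cnn_model"))
  type <- match.arg(type)
  x <- image_matrix(images)
  p <- cnn_predict_cpp(model$weights, x, batch = model$config$batch_size,
                       bn_eps = model$config$bn_eps)
  if (type == "class") return(as.integer(p >= model$config$threshold))
  p
}

#' Save / load a trained model
#'
#' The weight matrices are written as a JSON checkpoint with the
#' configuration embedded, so checkpoints are plain text and portable.
#'
#' @param model A `cnn_model`.
#' @param path Checkpoint path (`.json`).
#' @return `path` invisibly ([save_cnn()]); a `cnn_model` ([load_cnn()]).
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  payload <- list(
    config = model$config[setdiff(names(model$config), "input_shape")],
    input_shape = model$config$input_shape,
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), values = as.vector(w))
      else list(dim = length(w), values = as.vector(w))
    }),
    history = model$history)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(cnn_config, c(
    list(input_shape = payload$input_shape),
    payload$config[c("dropout_rate", "learning_rate", "epochs",
                     "batch_size", "seed", "threshold")]))
  weights <- lapply(payload$weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$values, w$dim[1L], w$dim[2L])
    else as.numeric(w$values)
  })
  history <- if (!is.null(payload$history) && length(payload$history)) {
    as.data.frame(payload$history)
  } else NULL
  structure(list(weights = weights, config = cfg, history = history),
            class = "cnn_model")
}
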