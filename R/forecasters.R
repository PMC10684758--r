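#' Forecaster architecture specifications
#'
#' A `forecaster_spec` is a declarative, backend-independent description
#' of a neural forecaster: an ordered list of layer descriptors plus the
#' input shape `(n_steps_in, input_dim)` where `input_dim = 3N` for `N`
#' residues. Shapes are chained analytically, so parameter counts can be
#' verified without building any weights.
#'
#' @name forecaster_spec
NULL

new_forecaster_spec <- function(model, input_dim, n_steps_in, layers) {
  spec <- structure(list(model = model, input_dim = as.integer(input_dim),
                         n_steps_in = as.integer(n_steps_in),
                         layers = layers),
                    class = "forecaster_spec")
  chain_shapes(spec)  # validates
  spec
}

#' @export
print.forecaster_spec <- function(x, ...) {
  cat(sprintf("<forecaster_spec> %s, input (%d, %d)\n", x$model,
              x$n_steps_in, x$input_dim))
  print(count_parameters(x)$table)
  invisible(x)
}

# Chain layer shapes from the input; shape = list(time, dim), time = NA
# for flat vectors. Errors on unchainable specs.
chain_shapes <- function(spec) {
  shape <- list(time = spec$n_steps_in, dim = spec$input_dim)
  in_shapes <- out_shapes <- vector("list", length(spec$layers))
  for (li in seq_along(spec$layers)) {
    layer <- spec$layers[[li]]
    in_shapes[[li]] <- shape
    shape <- switch(layer$kind,
      lstm = {
        if (is.na(shape$time)) stop("lstm needs a sequence input")
        list(time = if (layer$return_sequences) shape$time else NA,
             dim = layer$units)
      },
      `bidirectional-lstm` = {
        if (is.na(shape$time)) stop("bidirectional lstm needs a sequence")
        list(time = if (layer$return_sequences) shape$time else NA,
             dim = 2L * layer$units)
      },
      conv1d = {
        if (is.na(shape$time)) stop("conv1d needs a sequence input")
        list(time = shape$time, dim = layer$filters)  # same padding
      },
      maxpool1d = {
        t_out <- shape$time - layer$width + 1L
        if (is.na(shape$time) || t_out < 1L) {
          stop("maxpool1d: pool width ", layer$width,
               " too large for length ", shape$time)
        }
        list(time = t_out, dim = shape$dim)
      },
      dropout = shape,
      batchnorm = shape,
      flatten = {
        if (is.na(shape$time)) stop("flatten needs a sequence input")
        list(time = NA, dim = shape$time * shape$dim)
      },
      `repeat-vector` = {
        if (!is.na(shape$time)) stop("repeat-vector needs a flat input")
        list(time = 1L, dim = shape$dim)
      },
      `time-distributed-affine` = {
        if (!is.na(shape$time) && shape$time != 1L) {
          stop("time-distributed-affine supports length-1 sequences")
        }
        list(time = NA, dim = layer$units)
      },
      stop("chain_shapes: unknown layer kind ", layer$kind))
    out_shapes[[li]] <- shape
  }
  if (shape$dim != spec$input_dim) {
    stop("spec output dim ", shape$dim, " != input_dim ", spec$input_dim)
  }
  list(in_shapes = in_shapes, out_shapes = out_shapes)
}

lstm_param_count <- function(input_dim, units) {
  4 * ((input_dim + units) * units + units)
}

#' Analytic per-layer parameter counts
#'
#' Counts parameters from the layer algebra alone, independent of any
#' backend: an LSTM with input width `d` and `u` units has
#' `4*((d+u)*u + u)` parameters; a bidirectional wrapper doubles its
#' per-direction count; a 1-D convolution with kernel `k`, `c` input
#' channels and `f` filters has `(k*c + 1)*f`; batch normalisation has
#' `4*channels`, half of them (the moving statistics) non-trainable; an
#' affine map `d_in -> d_out` has `d_in*d_out + d_out`; pooling,
#' dropout, flatten and repeat-vector layers are parameter-free.
#'
#' @param spec a `forecaster_spec`.
#' @return List with `table` (one row per layer: kind, output shape,
#'   params), `total`, `trainable`, `non_trainable`.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "forecaster_spec"))
  shapes <- chain_shapes(spec)
  rows <- lapply(seq_along(spec$layers), function(li) {
    layer <- spec$layers[[li]]
    ins <- shapes$in_shapes[[li]]
    outs <- shapes$out_shapes[[li]]
    p <- switch(layer$kind,
      lstm = lstm_param_count(ins$dim, layer$units),
      `bidirectional-lstm` = 2 * lstm_param_count(ins$dim, layer$units),
      conv1d = (layer$kernel * ins$dim + 1) * layer$filters,
      batchnorm = 4 * ins$dim,
      `time-distributed-affine` = ins$dim * layer$units + layer$units,
      0)
    non_tr <- if (layer$kind == "batchnorm") 2 * ins$dim else 0
    shape_str <- if (is.na(outs$time)) {
      sprintf("(None, %d)", outs$dim)
    } else {
      sprintf("(None, %d, %d)", outs$time, outs$dim)
    }
    data.frame(layer = layer$kind, output_shape = shape_str,
               params = p, non_trainable = non_tr,
               stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, rows)
  total <- sum(table$params)
  non_trainable <- sum(table$non_trainable)
  list(table = table, total = total,
       trainable = total - non_trainable,
       non_trainable = non_trainable)
}

#' Unidirectional LSTM forecaster
#'
#' Encoder-decoder sequence-to-one regressor: an LSTM with 100 units
#' consumes the `n_steps_in`-frame window, its final state is broadcast
#' to a length-1 sequence, a second 100-unit LSTM decodes it, and a
#' time-distributed affine layer maps back to the `input_dim`
#' coordinates of the next frame.
#'
#' @param input_dim flattened feature width (3N).
#' @param n_steps_in window length (default 5).
#' @param units LSTM width (default 100).
#' @param activation cell activation (default `"relu"`; recurrent gate
#'   activations stay sigmoid).
#' @return A `forecaster_spec`.
#' @export
build_ulstm <- function(input_dim, n_steps_in = 5L, units = 100L,
                        activation = "relu") {
  stopifnot(input_dim >= 1)
  new_forecaster_spec("ulstm", input_dim, n_steps_in, list(
    list(kind = "lstm", units = units, return_sequences = FALSE,
         activation = activation),
    list(kind = "repeat-vector"),
    list(kind = "lstm", units = units, return_sequences = TRUE,
         activation = activation),
    list(kind = "time-distributed-affine", units = input_dim)
  ))
}

#' Bidirectional LSTM forecaster
#'
#' As [build_ulstm] but each LSTM layer is bidirectional with
#' `units` units per direction and the two directions concatenated, so
#' the merged width is `2 * units` (50 per direction keeps the merged
#' width at 100).
#'
#' @inheritParams build_ulstm
#' @param units units per direction (default 50).
#' @return A `forecaster_spec`.
#' @export
build_blstm <- function(input_dim, n_steps_in = 5L, units = 50L,
                        activation = "relu") {
  stopifnot(input_dim >= 1)
  new_forecaster_spec("blstm", input_dim, n_steps_in, list(
    list(kind = "bidirectional-lstm", units = units,
         return_sequences = FALSE, activation = activation),
    list(kind = "repeat-vector"),
    list(kind = "bidirectional-lstm", units = units,
         return_sequences = TRUE, activation = activation),
    list(kind = "time-distributed-affine", units = input_dim)
  ))
}

#' Convolutional LSTM forecaster
#'
#' Two same-padded 1-D convolutions (64 then 128 filters, kernel width
#' 9) with stride-1 max pooling (widths 3 then 2), dropout 0.2 and batch
#' normalisation reduce the window's time dimension 5 -> 3 -> 2; the
#' flattened 256-wide activation is broadcast to a length-1 sequence,
#' decoded by a 100-unit LSTM and mapped to the next frame by a
#' time-distributed affine layer.
#'
#' @inheritParams build_ulstm
#' @param kernel convolution kernel width (default 9).
#' @param dropout dropout rate (default 0.2).
#' @return A `forecaster_spec`.
#' @export
build_cnn_lstm <- function(input_dim, n_steps_in = 5L, kernel = 9L,
                           dropout = 0.2, activation = "relu") {
  stopifnot(input_dim >= 1)
  pool1 <- 3L; pool2 <- 2L
  if (n_steps_in != 5L) {
    # non-canonical window: re-derive a feasible pooling chain
    pool1 <- max(1L, min(3L, n_steps_in - 1L))
    pool2 <- max(1L, min(2L, n_steps_in - pool1))
    warning("build_cnn_lstm: n_steps_in != 5 is non-canonical; ",
            "pool widths re-derived as (", pool1, ", ", pool2, ")")
  }
  new_forecaster_spec("cnnlstm", input_dim, n_steps_in, list(
    list(kind = "conv1d", filters = 64L, kernel = kernel,
         activation = activation),
    list(kind = "maxpool1d", width = pool1),
    list(kind = "dropout", rate = dropout),
    list(kind = "conv1d", filters = 128L, kernel = kernel,
         activation = activation),
    list(kind = "maxpool1d", width = pool2),
    list(kind = "dropout", rate = dropout),
    list(kind = "batchnorm"),
    list(kind = "flatten"),
    list(kind = "repeat-vector"),
    list(kind = "lstm", units = 100L, return_sequences = TRUE,
         activation = activation),
    list(kind = "time-distributed-affine", units = input_dim)
  ))
}

#' Random-forest forecaster configuration
#'
#' Multi-output tree-ensemble regressor over flattened windows (each
#' sample reshaped to `n_steps_in * 3N` predictors). The maximum tree
#' depth is `3 * n_residues`, i.e. the flattened xyz feature count of
#' one frame, and the random state is fixed at 0. One forest is grown
#' per output dimension (100 trees each), which realises a multi-output
#' forest with the per-forest settings left at their defaults.
#'
#' @param n_residues number of residues N (output dim is 3N).
#' @param num_trees trees per output forest (default 100).
#' @param random_state fixed seed (default 0).
#' @return An object of class `rf_spec`.
#' @export
build_rf <- function(n_residues, num_trees = 100L, random_state = 0L) {
  stopifnot(n_residues >= 1)
  structure(list(model = "rf", n_residues = as.integer(n_residues),
                 max_depth = 3L * as.integer(n_residues),
                 num_trees = as.integer(num_trees),
                 random_state = as.integer(random_state)),
            class = "rf_spec")
}

#' Persistence baseline
#'
#' The model-free baseline that predicts the next frame to equal the
#' last observed frame of the window. Its RMSD is the per-step
#' displacement of the trajectory itself, i.e. the flexibility of the
#' molecule, and is the yardstick every trained forecaster must beat.
#'
#' @return An object of class `persistence_spec`.
#' @export
persistence_spec <- function() {
  structure(list(model = "persistence"), class = "persistence_spec")
}

#' @rdname persistence_spec
#' @param X a `window_set` or samples x n_steps_in x P array.
#' @return `persistence_forecast`: samples x P matrix equal to the last
#'   input frame of each window.
#' @export
persistence_forecast <- function(X) {
  if (inherits(X, "window_set")) return(last_frame(X))
  d <- dim(X)
  matrix(X[, d[2L], ], d[1L], d[3L])
}

#' Training configuration for neural forecasters
#'
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed RNG seed for initialisation, shuffling and dropout.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(epochs = 100L, batch_size = 32L,
                       learning_rate = 1e-3, seed = 0L) {
  stopifnot(epochs >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "fit_config")
}

#' Fit a forecaster on a training window set
#'
#' Dispatches on the spec class: neural specs are instantiated and
#' trained with minibatch Adam on mean-squared error; the random forest
#' grows one `ranger` forest per output dimension on flattened windows;
#' the persistence baseline needs no fitting. Inputs are expected in
#' normalised space; predictions are returned in the same space and the
#' caller inverts them to Angstrom before computing RMSD.
#'
#' @param spec a `forecaster_spec`, `rf_spec` or `persistence_spec`.
#' @param windows a `window_set` of training samples.
#' @param config a [fit_config].
#' @return A fitted model with a `predict` method.
#' @export
fit_forecaster <- function(spec, windows, config = fit_config()) {
  UseMethod("fit_forecaster")
}

#' @export
fit_forecaster.forecaster_spec <- function(spec, windows,
                                           config = fit_config()) {
  stopifnot(inherits(windows, "window_set"),
            dim(windows$X)[3L] == spec$input_dim)
  model <- nn_build(spec, seed = config$seed)
  nn_fit(model, windows$X, windows$y, epochs = config$epochs,
         batch_size = config$batch_size, lr = config$learning_rate,
         seed = config$seed)
}

#' @export
fit_forecaster.rf_spec <- function(spec, windows,
                                   config = fit_config()) {
  stopifnot(inherits(windows, "window_set"))
  Xf <- flatten_windows(windows)
  colnames(Xf) <- paste0("f", seq_len(ncol(Xf)))
  df <- as.data.frame(Xf)
  forests <- lapply(seq_len(ncol(windows$y)), function(j) {
    df$.y <- windows$y[, j]
    # ranger treats seed = 0 as unseeded, so the fixed random state is
    # mapped through the deterministic per-output seed derivation
    ranger::ranger(dependent.variable.name = ".y", data = df,
                   num.trees = spec$num_trees,
                   max.depth = spec$max_depth,
                   seed = derive_seed(spec$random_state + 1L, j),
                   num.threads = 1L)
  })
  structure(list(spec = spec, forests = forests,
                 n_outputs = ncol(windows$y)),
            class = "rf_model")
}

#' @export
fit_forecaster.persistence_spec <- function(spec, windows = NULL,
                                            config = NULL) {
  structure(list(spec = spec), class = "persistence_model")
}

#' @export
predict.nn_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "window_set")) newdata$X else newdata
  nn_predict(object, X)
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  ws <- if (inherits(newdata, "window_set")) newdata else
    structure(list(X = newdata), class = "window_set")
  Xf <- flatten_windows(ws)
  colnames(Xf) <- paste0("f", seq_len(ncol(Xf)))
  df <- as.data.frame(Xf)
  do.call(cbind, lapply(object$forests, function(fr) {
    stats::predict(fr, data = df, num.threads = 1L)$predictions
  }))
}

#' @export
predict.persistence_model <- function(object, newdata, ...) {
  persistence_forecast(newdata)
}
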