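#' Hyperparameter specification for the DenseNet TFBS classifier
#'
#' Defaults follow the canonical DenseNet-121 recipe applied to 1-D DNA
#' input: a stem of two width-3 convolutions with 64 filters, an average
#' pooling of stride 2, four dense blocks of 6/12/24/16 dense layers joined
#' by compressing transition layers, and a single sigmoid output unit.
#' Training uses Adam at learning rate 0.001 with binary cross-entropy for
#' at most 80 epochs. Every dense layer is a batch-normalized, ReLU
#' pre-activated bottleneck (`1x1` conv to `bottleneck_factor * growth_rate`
#' channels, then `3x1` conv to `growth_rate` channels) whose output is
#' concatenated onto everything before it in the block.
#'
#' @param stem_filters Filters in each stem convolution.
#' @param stem_kernel Stem convolution width (odd).
#' @param stem_conv_layers Number of stem convolutions.
#' @param pool_stride Stride (= width) of every average pooling.
#' @param block_layers Integer vector of dense-layer counts, one per block.
#' @param growth_rate Channels added by each dense layer.
#' @param bottleneck_factor Bottleneck width as a multiple of `growth_rate`.
#' @param transition_kernel Transition convolution width.
#' @param transition_compression Channel compression in transitions, in (0, 1].
#' @param learning_rate Adam learning rate.
#' @param weight_decay Decoupled L2 weight decay applied to convolution and
#'   dense weights each step (AdamW style); 0 disables it.
#' @param max_epochs Upper bound on training epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience on validation loss, in epochs.
#' @param seed Integer seed for weight initialization and batching.
#' @return A `densenet_spec` list.
#' @export
densenet_spec <- function(stem_filters = 64, stem_kernel = 3,
                          stem_conv_layers = 2, pool_stride = 2,
                          block_layers = c(6, 12, 24, 16), growth_rate = 32,
                          bottleneck_factor = 4, transition_kernel = 1,
                          transition_compression = 0.5, learning_rate = 0.001,
                          weight_decay = 0, max_epochs = 80, batch_size = 64,
                          patience = 5, seed = NULL) {
  spec <- list(
    stem_filters = check_count(stem_filters, "stem_filters"),
    stem_kernel = check_count(stem_kernel, "stem_kernel"),
    stem_conv_layers = check_count(stem_conv_layers, "stem_conv_layers"),
    pool_stride = check_count(pool_stride, "pool_stride"),
    block_layers = vapply(block_layers, check_count, integer(1),
                          name = "block_layers"),
    growth_rate = check_count(growth_rate, "growth_rate"),
    bottleneck_factor = check_count(bottleneck_factor, "bottleneck_factor"),
    transition_kernel = check_count(transition_kernel, "transition_kernel"),
    transition_compression = check_fraction(transition_compression,
                                            "transition_compression",
                                            lo = 1e-9, hi = 1),
    learning_rate = check_fraction(learning_rate, "learning_rate",
                                   lo = 1e-12, hi = 1),
    weight_decay = check_fraction(weight_decay, "weight_decay", lo = 0, hi = 1),
    max_epochs = check_count(max_epochs, "max_epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    patience = check_count(patience, "patience"),
    seed = seed
  )
  class(spec) <- "densenet_spec"
  spec
}

#' Build an untrained DenseNet classifier
#'
#' Compiles the layer program for a fixed input length and initializes
#' weights (He-normal, seeded from `spec$seed`). The returned object predicts
#' a single value in (0, 1) per sequence.
#'
#' @param spec A [densenet_spec()].
#' @param input_length Sequence length in bp the model accepts.
#' @return A `densenet_model` object (untrained).
#' @export
build_densenet <- function(spec, input_length) {
  stopifnot(inherits(spec, "densenet_spec"))
  input_length <- check_count(input_length, "input_length")
  net <- init_network(spec, input_length)
  model <- list(
    spec = spec,
    input_length = input_length,
    arch = net$arch,
    params = net$params,
    bn_running = net$bn_running,
    history = NULL,
    trained = FALSE
  )
  class(model) <- "densenet_model"
  model
}

#' Per-stage channel counts of a built model
#'
#' Exposes the concatenation accounting: after dense layer `l` of block `b`
#' the activation has `c_in + l * growth_rate` channels; transitions compress
#' by the configured factor.
#'
#' @param model A `densenet_model`.
#' @return Tibble with `stage`, `op`, `channels_in`, `channels_out`.
#' @export
model_channels <- function(model) {
  rows <- list()
  walk <- function(steps) {
    for (st in steps) {
      if (st$op == "conv") {
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          stage = st$name, op = "conv", channels_in = st$c_in,
          channels_out = st$c_out)
      } else if (st$op == "dense_layer") {
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          stage = st$name, op = "dense_layer", channels_in = st$c_in,
          channels_out = st$c_in + st$growth)
        walk(st$sub)
      }
    }
  }
  walk(model$arch$steps)
  dplyr::bind_rows(rows)
}

encode_batch <- function(sequences, input_length) {
  lens <- nchar(sequences)
  if (any(lens != input_length)) {
    abort(sprintf("All sequences must have length %d (got %s).",
                  input_length, paste(unique(lens), collapse = ", ")))
  }
  one_hot_batch(sequences)
}

predict_matrix <- function(model, X, B) {
  network_forward(model, X, B, model$input_length, training = FALSE,
                  with_tape = FALSE)$prob
}

#' Train a DenseNet classifier
#'
#' Minimizes binary cross-entropy with Adam on minibatches; a random
#' `validation_frac` of the training samples is held out each run for
#' early stopping on validation loss (configurable patience, best weights
#' restored). Per-epoch loss and validation AUC are recorded in the
#' model's history.
#'
#' @param model An untrained (or previously trained) `densenet_model`.
#' @param samples Tibble with columns `sequence` and `label` (0/1).
#' @param validation_frac Fraction held out for validation.
#' @param verbose Print per-epoch progress?
#' @return The trained `densenet_model` with a `history` tibble.
#' @export
train_model <- function(model, samples, validation_frac = 0.1, verbose = FALSE) {
  stopifnot(inherits(model, "densenet_model"))
  if (nrow(samples) == 0) abort("Empty training set.")
  y_all <- as.numeric(samples$label)
  if (length(unique(y_all)) < 2) {
    abort("Training data must contain both classes.")
  }
  spec <- model$spec
  L <- model$input_length
  seed <- spec$seed %||% 42L

  with_seed(stage_seed(seed, "train"), {
    n <- nrow(samples)
    n_val <- max(1L, round(validation_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(y_all[tr_idx])) < 2) {
      abort("Training split lost a class; provide more samples.")
    }
    X_all <- encode_batch(samples$sequence, L)
    row_of <- function(s) rep((s - 1L) * L, each = L) + seq_len(L)
    y_tr <- y_all[tr_idx]; y_val <- y_all[val_idx]
    X_val <- X_all[row_of(val_idx), , drop = FALSE]

    opt <- adam_init(model$params)
    best <- list(loss = Inf, params = NULL, bn = NULL, epoch = 0L)
    history <- list()
    wait <- 0L
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1L, length(ord), by = spec$batch_size)) {
        sel <- ord[start:min(start + spec$batch_size - 1L, length(ord))]
        B <- length(sel)
        Xb <- X_all[row_of(sel), , drop = FALSE]
        yb <- y_all[sel]
        fwd <- network_forward(model, Xb, B, L, training = TRUE)
        model$bn_running <- fwd$net$bn_running
        ep_loss <- ep_loss + bce_loss(fwd$prob, yb) * B
        ep_n <- ep_n + B
        dlogit <- (fwd$prob - yb) / B
        bwd <- network_backward(model, fwd, dlogit, B, L)
        upd <- adam_step(model$params, bwd$grads, opt, spec$learning_rate,
                         weight_decay = spec$weight_decay %||% 0)
        model$params <- upd$params
        opt <- upd$state
      }
      val_prob <- predict_in_batches(model, X_val, length(val_idx))
      val_loss <- bce_loss(val_prob, y_val)
      val_auc <- if (length(unique(y_val)) > 1) roc_auc(y_val, val_prob) else NA_real_
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = ep_loss / ep_n,
        val_loss = val_loss, val_auc = val_auc)
      if (verbose) {
        message(sprintf("epoch %2d  train %.4f  val %.4f  auc %s", epoch,
                        ep_loss / ep_n, val_loss,
                        ifelse(is.na(val_auc), "-", sprintf("%.4f", val_auc))))
      }
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, params = model$params,
                     bn = model$bn_running, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= spec$patience) break
      }
    }
    if (!is.null(best$params)) {
      model$params <- best$params
      model$bn_running <- best$bn
    }
    model$history <- dplyr::bind_rows(history)
    model$best_epoch <- best$epoch
    model$trained <- TRUE
    model
  })
}

# inference on a pre-encoded (n*L) x 4 matrix, chunked to bound memory
predict_in_batches <- function(model, X, n, batch_size = 128L) {
  L <- model$input_length
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    rows <- rep((sel - 1L) * L, each = L) + seq_len(L)
    out[sel] <- predict_matrix(model, X[rows, , drop = FALSE], length(sel))
  }
  out
}

#' Predicted binding intensity for DNA sequences
#'
#' @param object A trained `densenet_model`.
#' @param sequences Character vector of sequences of the model's input length.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, one per sequence,
#'   in input order.
#' @export
predict.densenet_model <- function(object, sequences, ...) {
  X <- encode_batch(sequences, object$input_length)
  predict_in_batches(object, X, length(sequences))
}

#' Predicted binding intensity (generic)
#'
#' The interpretation and global-importance functions are written against
#' this generic so that any scorer exposing it (including analytic toy
#' models in tests) can be interrogated.
#'
#' @param object A model object.
#' @param sequences Character vector of DNA sequences.
#' @return Numeric vector of predicted intensities, one per sequence.
#' @export
predict_intensity <- function(object, sequences) {
  UseMethod("predict_intensity")
}

#' @export
predict_intensity.densenet_model <- function(object, sequences) {
  predict(object, sequences)
}

#' Gradient of the predicted intensity with respect to the one-hot input
#'
#' @param object A model object.
#' @param onehot `(n * L) x 4` one-hot (or relaxed) input for `n` sequences,
#'   sample-major.
#' @param n Number of sequences in the batch.
#' @return `(n * L) x 4` matrix of `d p / d x`.
#' @export
input_gradients <- function(object, onehot, n) {
  UseMethod("input_gradients")
}

#' @export
input_gradients.densenet_model <- function(object, onehot, n) {
  L <- object$input_length
  stopifnot(nrow(onehot) == n * L)
  fwd <- network_forward(object, onehot, n, L, training = FALSE)
  dlogit <- fwd$prob * (1 - fwd$prob) # chain through the sigmoid
  network_backward(object, fwd, dlogit, n, L)$dInput
}

#' Save / load a trained model
#'
#' The checkpoint is a single RDS file holding the weights, batch-norm
#' statistics, the full hyperparameter spec, the input length and the
#' training history; [load_model()] rebuilds the model and refuses files
#' missing those fields.
#'
#' @param model A `densenet_model`.
#' @param path Checkpoint path.
#' @return `path` ([save_model()]) or the restored model ([load_model()]).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "densenet_model"))
  payload <- list(
    format = "densebind_checkpoint_v1",
    spec = unclass(model$spec),
    input_length = model$input_length,
    params = model$params,
    bn_running = model$bn_running,
    history = model$history,
    best_epoch = model$best_epoch,
    trained = model$trained
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("No checkpoint at '%s'.", path))
  payload <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("Corrupt or unreadable checkpoint '%s': %s", path,
                  conditionMessage(e)))
  })
  needed <- c("format", "spec", "input_length", "params", "bn_running")
  if (!is.list(payload) || !all(needed %in% names(payload)) ||
      !identical(payload$format, "densebind_checkpoint_v1")) {
    abort(sprintf("'%s' is not a densebind checkpoint.", path))
  }
  spec <- payload$spec
  class(spec) <- "densenet_spec"
  model <- build_densenet(spec, payload$input_length)
  if (!identical(vapply(model$params, length, integer(1)),
                 vapply(payload$params, length, integer(1)))) {
    abort("Checkpoint weights do not match the architecture metadata.")
  }
  model$params <- payload$params
  model$bn_running <- payload$bn_running
  model$history <- payload$history
  model$best_epoch <- payload$best_epoch
  model$trained <- isTRUE(payload$trained)
  model
}

#' @export
print.densenet_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<densenet_model> input %d bp, blocks [%s], growth %d, %s, %s parameters\n",
    x$input_length, paste(x$spec$block_layers, collapse = ", "),
    x$spec$growth_rate, if (x$trained) "trained" else "untrained",
    format(n_par, big.mark = ",")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted classifier
#'
#' @param x A trained `densenet_model`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`, `val_loss`,
#'   `val_auc`.
#' @export
tidy.densenet_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), train_loss = numeric(),
                                val_loss = numeric(), val_auc = numeric())
}

#' One-row summary of a fitted classifier
#'
#' @param x A `densenet_model`.
#' @param ... Unused.
#' @return Tibble with `input_length`, `n_parameters`, `epochs_run`,
#'   `best_epoch`, `best_val_loss`, `best_val_auc`.
#' @export
glance.densenet_model <- function(x, ...) {
  h <- tidy(x)
  best <- if (nrow(h)) h[which.min(h$val_loss), ] else NULL
  tibble::tibble(
    input_length = x$input_length,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    epochs_run = nrow(h),
    best_epoch = x$best_epoch %||% NA_integer_,
    best_val_loss = if (is.null(best)) NA_real_ else best$val_loss,
    best_val_auc = if (is.null(best)) NA_real_ else best$val_auc
  )
}
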