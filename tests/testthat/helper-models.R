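# Shared fixtures: analytic toy models for unit tests and one memoized
# trained DenseNet on the planted-motif benchmark for the integration and
# acceptance tests.

# a scorer that ignores its input entirely
constant_model <- function(value = 0.5, input_length = NULL) {
  structure(list(value = value, input_length = input_length),
            class = c("constant_model"))
}

predict_intensity.constant_model <- function(object, sequences) {
  rep(object$value, length(sequences))
}

input_gradients.constant_model <- function(object, onehot, n) {
  matrix(0, nrow = nrow(onehot), ncol = 4L)
}

# additive position-weight scorer: output is the sum over offsets of the
# PWM log-odds (a linear function of the one-hot input), linearly rescaled.
# Closed-form behaviour makes it the oracle for GIA's linearity property.
pwm_sum_model <- function(pwm_obj, input_length, scale = 0.01, offset = 0.5) {
  structure(list(pwm = pwm_obj, input_length = input_length, scale = scale,
                 offset = offset),
            class = "pwm_sum_model")
}

predict_intensity.pwm_sum_model <- function(object, sequences) {
  vapply(sequences, function(s) {
    sc <- position_scores(s, object$pwm, strand = "+")
    object$offset + object$scale * sum(sc, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

input_gradients.pwm_sum_model <- function(object, onehot, n) {
  # d(output)/d(x[i, b]) = scale * sum over windows covering i of lo[i - s, b]
  lo <- log_odds(object$pwm)
  L <- object$input_length
  w <- nrow(lo)
  g1 <- matrix(0, nrow = L, ncol = 4L)
  for (s in 0:(L - w)) g1[(s + 1):(s + w), ] <- g1[(s + 1):(s + w), ] + lo
  do.call(rbind, replicate(n, g1 * object$scale, simplify = FALSE))
}

registerS3method("predict_intensity", "constant_model",
                 predict_intensity.constant_model,
                 envir = asNamespace("densebind"))
registerS3method("input_gradients", "constant_model",
                 input_gradients.constant_model,
                 envir = asNamespace("densebind"))
registerS3method("predict_intensity", "pwm_sum_model",
                 predict_intensity.pwm_sum_model,
                 envir = asNamespace("densebind"))
registerS3method("input_gradients", "pwm_sum_model",
                 input_gradients.pwm_sum_model,
                 envir = asNamespace("densebind"))

# strongly informative PWM whose top-affinity k-mer is the planted motif
benchmark_pwm <- function(kmer = "GCACGTGC", conc = 0.94) {
  codes <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T"))
  probs <- matrix((1 - conc) / 3, nrow = length(codes), ncol = 4)
  probs[cbind(seq_along(codes), codes)] <- conc
  pwm(probs, name = paste0("planted_", kmer))
}

# the planted-8-mer study benchmark: 2000 + 2000 samples of 500 bp with
# GCACGTGC written at a uniform position in every positive
BENCH_SEED <- 20260923L
BENCH_MOTIF <- "GCACGTGC"

.fixture_env <- new.env(parent = emptyenv())

benchmark_data <- function() {
  if (is.null(.fixture_env$bench)) {
    bench <- make_benchmark(2000, 2000, motif = BENCH_MOTIF, seq_length = 500,
                            seed = BENCH_SEED)
    split <- split_dataset(bench$samples, 0.8, seed = BENCH_SEED + 1L)
    .fixture_env$bench <- list(samples = bench$samples, truth = bench$truth,
                               train = split$train, test = split$test)
  }
  .fixture_env$bench
}

# tiny DenseNet of the integration benchmark, trained once per test run
benchmark_model <- function() {
  if (is.null(.fixture_env$model)) {
    bd <- benchmark_data()
    spec <- densenet_spec(stem_filters = 16, block_layers = c(1, 1, 1, 1),
                          growth_rate = 8, learning_rate = 0.01,
                          max_epochs = 12, patience = 5,
                          seed = BENCH_SEED + 2L)
    model <- build_densenet(spec, 500)
    .fixture_env$model <- train_model(model, bd$train)
  }
  .fixture_env$model
}

# planted positives of the held-out test split, with their truth rows
benchmark_test_positives <- function(n) {
  bd <- benchmark_data()
  pos <- bd$test[bd$test$label == 1L, ]
  truth <- bd$truth[match(pos$id, bd$truth$sample_id), ]
  idx <- seq_len(min(n, nrow(pos)))
  list(samples = pos[idx, ], truth = truth[idx, ])
}

random_dna <- function(n, length, seed) {
  generate_background(n, length, gc = 0.5, seed = seed)
}
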