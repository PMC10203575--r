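tiny_spec <- function(seed = 5, ...) {
  densenet_spec(stem_filters = 8, block_layers = c(1, 1, 1, 1),
                growth_rate = 4, bottleneck_factor = 2, seed = seed, ...)
}

test_that("the built graph obeys the dense-connectivity channel law", {
  # defaults: stem 64, blocks 6/12/24/16, growth 32
  m <- build_densenet(densenet_spec(seed = 1), 64)
  ch <- model_channels(m)
  dl <- ch[ch$op == "dense_layer", ]
  # channels entering transition 1 = stem channels + 6 * growth
  expect_equal(dl$channels_out[6], 64 + 6 * 32)
  # every dense layer adds exactly the growth rate
  expect_true(all(dl$channels_out - dl$channels_in == 32))
  # each block's first layer continues from the compressed transition
  b2 <- dl[grepl("^b2", dl$stage), ]
  expect_equal(b2$channels_in[1], (64 + 6 * 32) / 2)
})

test_that("outputs are sigmoid probabilities and batches are order-stable", {
  m <- build_densenet(tiny_spec(), 64)
  seqs <- random_dna(6, 64, seed = 3)
  p <- predict(m, seqs)
  expect_length(p, 6)
  expect_true(all(p > 0 & p < 1))
  # permutation equivariance and purity
  expect_equal(predict(m, seqs[c(4, 1, 6)]), p[c(4, 1, 6)], tolerance = 1e-12)
  expect_equal(predict(m, rep(seqs[2], 3)), rep(p[2], 3), tolerance = 1e-12)
  expect_error(predict(m, "ACGT"), "length 64")
})

test_that("too-short inputs fail the pooling cascade with a clear error", {
  expect_error(build_densenet(tiny_spec(), 8), "at least")
})

test_that("backpropagation matches numeric finite differences", {
  spec <- tiny_spec(seed = 7)
  m <- build_densenet(spec, 32)
  seqs <- random_dna(3, 32, seed = 3)
  X <- densebind:::one_hot_batch(seqs)
  y <- c(1, 0, 1)
  fwd <- densebind:::network_forward(m, X, 3, 32, training = TRUE)
  bwd <- densebind:::network_backward(m, fwd, (fwd$prob - y) / 3, 3, 32)
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    f <- densebind:::network_forward(m2, X, 3, 32, training = TRUE)
    densebind:::bce_loss(f$prob, y)
  }
  eps <- 1e-5
  set.seed(11)
  for (nm in c("stem1.w", "b1l1_c2.w", "t1_conv.w", "b3l1_bn1.gamma", "out.w")) {
    i <- sample(length(m$params[[nm]]), 1)
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
    expect_equal(as.numeric(bwd$grads[[nm]])[i], num, tolerance = 1e-4)
  }
  # input gradients (inference mode) against finite differences
  g <- input_gradients(m, X, 3)
  f0 <- function(Xm) densebind:::network_forward(m, Xm, 3, 32, FALSE)$prob
  r <- 17L; cc <- 2L; s <- ceiling(r / 32)
  Xp <- X; Xp[r, cc] <- Xp[r, cc] + eps
  Xm2 <- X; Xm2[r, cc] <- Xm2[r, cc] - eps
  expect_equal(g[r, cc], (f0(Xp)[s] - f0(Xm2)[s]) / (2 * eps), tolerance = 1e-5)
})

test_that("training refuses degenerate inputs", {
  m <- build_densenet(tiny_spec(), 64)
  expect_error(train_model(m, tibble::tibble(sequence = character(),
                                             label = integer())),
               "Empty")
  one_class <- tibble::tibble(sequence = random_dna(10, 64, seed = 1),
                              label = rep(1L, 10))
  expect_error(train_model(m, one_class), "both classes")
})

test_that("training is deterministic under a fixed seed", {
  b <- make_benchmark(60, 60, motif = "GCACGTGC", seq_length = 64, seed = 31)
  spec <- tiny_spec(seed = 32, max_epochs = 3, patience = 3)
  m1 <- train_model(build_densenet(spec, 64), b$samples)
  m2 <- train_model(build_densenet(spec, 64), b$samples)
  expect_equal(tidy(m1)$val_loss, tidy(m2)$val_loss, tolerance = 1e-12)
  expect_equal(m1$params, m2$params, tolerance = 1e-12)
})

test_that("checkpoints round-trip exactly and reject damaged files", {
  b <- make_benchmark(40, 40, motif = "ACGTACGT", seq_length = 64, seed = 41)
  spec <- tiny_spec(seed = 42, max_epochs = 2, patience = 2)
  m <- train_model(build_densenet(spec, 64), b$samples)
  probe <- random_dna(8, 64, seed = 43)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, probe), predict(m, probe))
  expect_identical(m2$input_length, 64L)

  expect_error(load_model(tempfile()), "No checkpoint")
  junk <- tempfile(); saveRDS(list(a = 1), junk)
  expect_error(load_model(junk), "not a densebind checkpoint")

  # tampered weight metadata is refused
  payload <- readRDS(path)
  payload$params[["out.w"]] <- payload$params[["out.w"]][-1, , drop = FALSE]
  tampered <- tempfile(); saveRDS(payload, tampered)
  expect_error(load_model(tampered), "do not match")
})

test_that("tidy and glance summarize the training history", {
  b <- make_benchmark(40, 40, motif = "ACGTACGT", seq_length = 64, seed = 51)
  m <- train_model(build_densenet(tiny_spec(seed = 52, max_epochs = 2,
                                            patience = 2), 64), b$samples)
  h <- tidy(m)
  expect_named(h, c("epoch", "train_loss", "val_loss", "val_auc"))
  expect_gte(nrow(h), 1)
  g <- glance(m)
  expect_identical(g$input_length, 64L)
  expect_identical(g$epochs_run, nrow(h))
  expect_true(is.finite(g$best_val_loss))
})
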