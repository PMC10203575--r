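# Minimal 1-D convolutional network engine. Activations for a batch of B
# sequences of length L with C channels are stored as a (B*L) x C matrix,
# sample-major (rows 1..L belong to sample 1). Convolutions are im2col
# gathers followed by one BLAS matrix product; "same" padding never crosses
# sample boundaries. A forward pass records per-step caches (a tape) that
# the backward pass walks in reverse, yielding parameter gradients and,
# when asked, the gradient with respect to the one-hot input -- the
# quantity the attribution methods integrate.

.idx_cache <- new.env(parent = emptyenv())

# gather indices for a width-k same-padded convolution; index 1 points at
# the zero pad row of the augmented activation matrix
conv_indices <- function(B, L, k) {
  key <- paste(B, L, k, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  half <- (k - 1L) %/% 2L
  t_vec <- rep(seq_len(L), B)
  b_off <- rep((seq_len(B) - 1L) * L, each = L)
  idx <- matrix(1L, nrow = B * L, ncol = k)
  for (j in seq_len(k)) {
    p <- t_vec + (j - 1L - half)
    valid <- p >= 1L & p <= L
    idx[valid, j] <- p[valid] + b_off[valid] + 1L
  }
  .idx_cache[[key]] <- idx
  idx
}

pool_indices <- function(B, L, s) {
  key <- paste("p", B, L, s, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  Lo <- L %/% s
  t_vec <- rep(seq_len(Lo), B)
  b_off <- rep((seq_len(B) - 1L) * L, each = Lo)
  idx <- lapply(seq_len(s), function(j) b_off + s * (t_vec - 1L) + j)
  out <- list(Lo = Lo, idx = idx)
  .idx_cache[[key]] <- out
  out
}

conv_fwd <- function(X, W, b, k, B, L) {
  if (k == 1L) {
    Xcol <- X
  } else {
    idx <- conv_indices(B, L, k)
    Xz <- rbind(0, X)
    Xcol <- do.call(cbind, lapply(seq_len(k), function(j) Xz[idx[, j], , drop = FALSE]))
  }
  Y <- Xcol %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(out = Y, cache = list(Xcol = Xcol, k = k, B = B, L = L, C = ncol(X)))
}

conv_bwd <- function(cache, W, dY) {
  dW <- crossprod(cache$Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)
  k <- cache$k
  if (k == 1L) {
    dX <- dXcol
  } else {
    C <- cache$C
    idx <- conv_indices(cache$B, cache$L, k)
    dXz <- matrix(0, nrow = cache$B * cache$L + 1L, ncol = C)
    for (j in seq_len(k)) {
      cols <- ((j - 1L) * C + 1L):(j * C)
      tgt <- idx[, j]
      # only the discarded pad row (index 1) repeats within a column
      dXz[tgt, ] <- dXz[tgt, ] + dXcol[, cols, drop = FALSE]
    }
    dX <- dXz[-1L, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

bn_fwd <- function(X, gamma, beta, running, training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu, "-")
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, inv, "*")
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    inv <- 1 / sqrt(running$var + eps)
    xhat <- sweep(sweep(X, 2L, running$mean, "-"), 2L, inv, "*")
  }
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = Y, cache = list(xhat = xhat, inv = inv, training = training),
       running = running)
}

bn_bwd <- function(cache, gamma, dY) {
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, gamma, "*")
  if (cache$training) {
    N <- nrow(dY)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dX <- sweep(dxhat - rep(1, N) %o% m1 - cache$xhat * (rep(1, N) %o% m2),
                2L, cache$inv, "*")
  } else {
    dX <- sweep(dxhat, 2L, cache$inv, "*")
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_fwd <- function(X, s, B, L) {
  pi <- pool_indices(B, L, s)
  Y <- X[pi$idx[[1L]], , drop = FALSE]
  for (j in 2:s) Y <- Y + X[pi$idx[[j]], , drop = FALSE]
  list(out = Y / s, cache = list(s = s, B = B, L = L, Lo = pi$Lo))
}

pool_bwd <- function(cache, dY) {
  pi <- pool_indices(cache$B, cache$L, cache$s)
  dX <- matrix(0, nrow = cache$B * cache$L, ncol = ncol(dY))
  dYs <- dY / cache$s
  for (j in seq_len(cache$s)) dX[pi$idx[[j]], ] <- dYs
  dX
}

flatten_fwd <- function(X, B, L) {
  A <- array(X, dim = c(L, B, ncol(X)))
  M <- matrix(aperm(A, c(1L, 3L, 2L)), ncol = B)
  t(M)
}

flatten_bwd <- function(dF, B, L, C) {
  P <- array(t(dF), dim = c(L, C, B))
  matrix(aperm(P, c(1L, 3L, 2L)), nrow = B * L, ncol = C)
}

# ---- architecture -----------------------------------------------------

# Compile the DenseNet layer program for one input length: a nested list of
# steps with parameter names and channel bookkeeping. `dense_layer` steps
# carry the bottleneck sub-chain; their output is concatenated onto their
# input (the dense connectivity).
densenet_arch <- function(spec, input_length) {
  steps <- list()
  add <- function(step) steps[[length(steps) + 1L]] <<- step
  C <- 4L
  L <- input_length
  s <- spec$pool_stride
  for (i in seq_len(spec$stem_conv_layers)) {
    nm <- paste0("stem", i)
    add(list(op = "conv", name = nm, k = spec$stem_kernel,
             c_in = C, c_out = spec$stem_filters))
    C <- spec$stem_filters
    add(list(op = "bn", name = paste0(nm, "_bn"), c = C))
    add(list(op = "relu"))
  }
  add(list(op = "pool", s = s)); L <- L %/% s
  bottleneck <- spec$bottleneck_factor * spec$growth_rate
  for (b in seq_along(spec$block_layers)) {
    for (l in seq_len(spec$block_layers[b])) {
      nm <- sprintf("b%dl%d", b, l)
      sub <- list(
        list(op = "bn", name = paste0(nm, "_bn1"), c = C),
        list(op = "relu"),
        list(op = "conv", name = paste0(nm, "_c1"), k = 1L,
             c_in = C, c_out = bottleneck),
        list(op = "bn", name = paste0(nm, "_bn2"), c = bottleneck),
        list(op = "relu"),
        list(op = "conv", name = paste0(nm, "_c2"), k = 3L,
             c_in = bottleneck, c_out = spec$growth_rate)
      )
      add(list(op = "dense_layer", name = nm, sub = sub, c_in = C,
               growth = spec$growth_rate))
      C <- C + spec$growth_rate
    }
    if (b < length(spec$block_layers)) {
      nm <- sprintf("t%d", b)
      c_out <- max(1L, floor(C * spec$transition_compression))
      add(list(op = "bn", name = paste0(nm, "_bn"), c = C))
      add(list(op = "relu"))
      add(list(op = "conv", name = paste0(nm, "_conv"), k = spec$transition_kernel,
               c_in = C, c_out = c_out))
      C <- c_out
      add(list(op = "pool", s = s)); L <- L %/% s
    }
  }
  add(list(op = "bn", name = "head_bn", c = C))
  add(list(op = "relu"))
  if (L < 1L) {
    abort(sprintf(
      "Input length too short for the pooling cascade: need at least %d bp.",
      spec$pool_stride ^ (length(spec$block_layers))))
  }
  list(steps = steps, final_len = L, final_channels = C)
}

collect_params <- function(steps, acc = list()) {
  for (st in steps) {
    if (st$op == "conv") {
      acc[[paste0(st$name, ".w")]] <- c(st$k * st$c_in, st$c_out)
      acc[[paste0(st$name, ".b")]] <- c(1L, st$c_out)
    } else if (st$op == "bn") {
      acc[[paste0(st$name, ".gamma")]] <- c(1L, st$c)
      acc[[paste0(st$name, ".beta")]] <- c(1L, st$c)
    } else if (st$op == "dense_layer") {
      acc <- collect_params(st$sub, acc)
    }
  }
  acc
}

init_network <- function(spec, input_length) {
  arch <- densenet_arch(spec, input_length)
  shapes <- collect_params(arch$steps)
  shapes[["out.w"]] <- c(arch$final_len * arch$final_channels, 1L)
  shapes[["out.b"]] <- c(1L, 1L)
  params <- list()
  bn_running <- list()
  with_seed(spec$seed %||% 42L, {
    for (nm in names(shapes)) {
      sh <- shapes[[nm]]
      if (grepl("\\.w$", nm)) {
        fan_in <- sh[1L]
        params[[nm]] <- matrix(rnorm(prod(sh), sd = sqrt(2 / fan_in)),
                               nrow = sh[1L], ncol = sh[2L])
      } else if (grepl("\\.b$", nm) || grepl("\\.beta$", nm)) {
        params[[nm]] <- rep(0, sh[2L])
      } else { # gamma
        params[[nm]] <- rep(1, sh[2L])
      }
    }
  })
  collect_bn <- function(steps) {
    for (st in steps) {
      if (st$op == "bn") {
        bn_running[[st$name]] <<- list(mean = rep(0, st$c), var = rep(1, st$c))
      } else if (st$op == "dense_layer") collect_bn(st$sub)
    }
  }
  collect_bn(arch$steps)
  list(arch = arch, params = params, bn_running = bn_running)
}

# forward over a step list; returns output plus a tape of caches.
# with_tape = FALSE is the inference fast path: no caches are stored and
# batch norm collapses to one fused scale-and-shift.
steps_fwd <- function(steps, X, B, L, net, training, with_tape = TRUE) {
  tape <- if (with_tape) vector("list", length(steps)) else NULL
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (st$op == "conv") {
      r <- conv_fwd(X, net$params[[paste0(st$name, ".w")]],
                    net$params[[paste0(st$name, ".b")]], st$k, B, L)
      X <- r$out
      if (with_tape) tape[[i]] <- r$cache
    } else if (st$op == "bn") {
      if (!with_tape && !training) {
        run <- net$bn_running[[st$name]]
        gamma <- net$params[[paste0(st$name, ".gamma")]]
        scale <- gamma / sqrt(run$var + 1e-5)
        shift <- net$params[[paste0(st$name, ".beta")]] - run$mean * scale
        X <- sweep(sweep(X, 2L, scale, "*"), 2L, shift, "+")
      } else {
        r <- bn_fwd(X, net$params[[paste0(st$name, ".gamma")]],
                    net$params[[paste0(st$name, ".beta")]],
                    net$bn_running[[st$name]], training)
        if (training) net$bn_running[[st$name]] <- r$running
        X <- r$out
        if (with_tape) tape[[i]] <- r$cache
      }
    } else if (st$op == "relu") {
      if (with_tape) {
        mask <- X > 0
        X <- X * mask
        tape[[i]] <- list(mask = mask)
      } else {
        X[X < 0] <- 0
      }
    } else if (st$op == "pool") {
      r <- pool_fwd(X, st$s, B, L)
      X <- r$out; L <- r$cache$Lo
      if (with_tape) tape[[i]] <- r$cache
    } else if (st$op == "dense_layer") {
      r <- steps_fwd(st$sub, X, B, L, net, training, with_tape)
      net <- r$net
      if (with_tape) tape[[i]] <- list(sub = r$tape)
      X <- cbind(X, r$out)
    }
  }
  list(out = X, tape = tape, L = L, net = net)
}

steps_bwd <- function(steps, tape, dX, B, net, grads) {
  for (i in rev(seq_along(steps))) {
    st <- steps[[i]]
    if (st$op == "conv") {
      wn <- paste0(st$name, ".w"); bn_ <- paste0(st$name, ".b")
      r <- conv_bwd(tape[[i]], net$params[[wn]], dX)
      grads[[wn]] <- (grads[[wn]] %||% 0) + r$dW
      grads[[bn_]] <- (grads[[bn_]] %||% 0) + r$db
      dX <- r$dX
    } else if (st$op == "bn") {
      gn <- paste0(st$name, ".gamma"); bn_ <- paste0(st$name, ".beta")
      r <- bn_bwd(tape[[i]], net$params[[gn]], dX)
      grads[[gn]] <- (grads[[gn]] %||% 0) + r$dgamma
      grads[[bn_]] <- (grads[[bn_]] %||% 0) + r$dbeta
      dX <- r$dX
    } else if (st$op == "relu") {
      dX <- dX * tape[[i]]$mask
    } else if (st$op == "pool") {
      dX <- pool_bwd(tape[[i]], dX)
    } else if (st$op == "dense_layer") {
      c_in <- st$c_in
      d_direct <- dX[, seq_len(c_in), drop = FALSE]
      d_new <- dX[, (c_in + 1L):ncol(dX), drop = FALSE]
      r <- steps_bwd(st$sub, tape[[i]]$sub, d_new, B, net, grads)
      grads <- r$grads
      dX <- d_direct + r$dX
    }
  }
  list(dX = dX, grads = grads)
}

# full forward: one-hot batch -> sigmoid probability per sample
network_forward <- function(net, X, B, L, training = FALSE, with_tape = TRUE) {
  r <- steps_fwd(net$arch$steps, X, B, L, net, training, with_tape)
  net <- r$net
  Fl <- flatten_fwd(r$out, B, r$L)
  logit <- sweep(Fl %*% net$params[["out.w"]], 2L, net$params[["out.b"]], "+")
  prob <- 1 / (1 + exp(-logit))
  list(prob = as.numeric(prob), logit = as.numeric(logit),
       tape = r$tape, flat = Fl, L_out = r$L, net = net)
}

# backward from d(logit) down to parameter gradients and d(input)
network_backward <- function(net, fwd, dlogit, B, L_in) {
  grads <- list()
  dlogit <- matrix(dlogit, ncol = 1L)
  grads[["out.w"]] <- crossprod(fwd$flat, dlogit)
  grads[["out.b"]] <- sum(dlogit)
  dF <- dlogit %*% t(net$params[["out.w"]])
  dX <- flatten_bwd(dF, B, fwd$L_out, net$arch$final_channels)
  r <- steps_bwd(net$arch$steps, fwd$tape, dX, B, net, grads)
  list(grads = r$grads, dInput = r$dX)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1 ^ state$t
  bc2 <- 1 - beta2 ^ state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && grepl("\\.w$", nm)) {
      step <- step + lr * weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

bce_loss <- function(prob, y, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
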