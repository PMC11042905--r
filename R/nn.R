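# A compact neural-network engine for DNA sequence models, written against
# base R matrix algebra. Layers: 1D convolution (+ReLU), max pooling,
# flatten, dense (linear/ReLU/sigmoid, optional dropout), and the per-unit
# two-layer MLP used by additive architectures. Convolution is evaluated as
# a sum over kernel offsets of (B*Lout, Cin) x (Cin, F) matrix products, so
# the hot loop is k BLAS calls rather than element-wise R code.
#
# Shapes: sequence tensors are (B, L, C) arrays; dense activations are
# (B, D) matrices. All parameters are double arrays; gradients mirror them.

nn_conv1d <- function(in_channels, filters, kernel, activation = "relu") {
  list(type = "conv1d", in_channels = in_channels, filters = filters,
       kernel = kernel, activation = activation,
       params = list(W = array(0, c(kernel, in_channels, filters)),
                     b = numeric(filters)))
}

nn_maxpool <- function(pool) list(type = "maxpool", pool = pool, params = list())

nn_flatten <- function() list(type = "flatten", params = list())

nn_dense <- function(d_in, d_out, activation = "linear", dropout = 0) {
  list(type = "dense", d_in = d_in, d_out = d_out, activation = activation,
       dropout = dropout,
       params = list(W = matrix(0, d_in, d_out), b = numeric(d_out)))
}

nn_unitwise_mlp <- function(units, hidden) {
  list(type = "unitwise_mlp", units = units, hidden = hidden,
       params = list(W1 = matrix(0, units, hidden), b1 = matrix(0, units, hidden),
                     W2 = matrix(0, units, hidden), b2 = numeric(units)))
}

.init_layer <- function(layer) {
  # He initialisation for ReLU layers, Glorot for linear heads
  rnorm_arr <- function(dim, sd) array(stats::rnorm(prod(dim), sd = sd), dim)
  if (layer$type == "conv1d") {
    fan_in <- layer$kernel * layer$in_channels
    layer$params$W <- rnorm_arr(dim(layer$params$W), sqrt(2 / fan_in))
  } else if (layer$type == "dense") {
    sd <- if (layer$activation == "relu") sqrt(2 / layer$d_in) else sqrt(1 / layer$d_in)
    layer$params$W <- matrix(stats::rnorm(layer$d_in * layer$d_out, sd = sd),
                             layer$d_in, layer$d_out)
  } else if (layer$type == "unitwise_mlp") {
    layer$params$W1 <- matrix(stats::rnorm(length(layer$params$W1), sd = 1),
                              nrow(layer$params$W1))
    layer$params$W2 <- matrix(stats::rnorm(length(layer$params$W2),
                                           sd = sqrt(1 / layer$hidden)),
                              nrow(layer$params$W2))
  }
  layer
}

.relu <- function(x) { x[x < 0] <- 0; x }

# ---- forward ----------------------------------------------------------------

.fwd_conv1d <- function(layer, x) {
  d <- dim(x); B <- d[1L]; L <- d[2L]; Cin <- d[3L]
  k <- layer$kernel; Fo <- layer$filters
  Lout <- L - k + 1L
  if (Lout < 1L) rlang::abort("input shorter than convolution kernel")
  Zm <- matrix(rep(layer$params$b, each = B * Lout), B * Lout, Fo)
  for (j in seq_len(k)) {
    Xj <- matrix(x[, j:(j + Lout - 1L), , drop = FALSE], B * Lout, Cin)
    Zm <- Zm + Xj %*% matrix(layer$params$W[j, , ], Cin, Fo)
  }
  if (layer$activation == "relu") Zm <- .relu(Zm)
  out <- array(Zm, c(B, Lout, Fo))
  list(out = out, cache = list(x = x, act = Zm, Lout = Lout))
}

.fwd_maxpool <- function(layer, x) {
  d <- dim(x); B <- d[1L]; L <- d[2L]; C <- d[3L]
  pool <- if (is.finite(layer$pool)) layer$pool else L
  if (L < pool) rlang::abort("input shorter than pooling window")
  Lp <- L %/% pool
  maxv <- x[, seq(1L, by = pool, length.out = Lp), , drop = FALSE]
  argj <- array(1L, c(B, Lp, C))
  if (pool > 1L) {
    for (j in 2:pool) {
      cand <- x[, seq(j, by = pool, length.out = Lp), , drop = FALSE]
      upd <- cand > maxv
      maxv[upd] <- cand[upd]
      argj[upd] <- j
    }
  }
  list(out = maxv, cache = list(argj = argj, pool = pool, in_dim = d))
}

.fwd_flatten <- function(layer, x) {
  d <- dim(x)
  list(out = matrix(x, d[1L], prod(d[-1L])), cache = list(in_dim = d))
}

.fwd_dense <- function(layer, x, training = FALSE) {
  z <- x %*% layer$params$W + rep(layer$params$b, each = nrow(x))
  a <- switch(layer$activation,
              relu = .relu(z),
              sigmoid = 1 / (1 + exp(-z)),
              z)
  mask <- NULL
  if (training && layer$dropout > 0) {
    mask <- matrix(stats::runif(length(a)) >= layer$dropout, nrow(a)) /
      (1 - layer$dropout)
    a <- a * mask
  }
  list(out = a, cache = list(x = x, z = z, act = a, mask = mask))
}

.fwd_unitwise <- function(layer, u) {
  B <- nrow(u); U <- layer$units; K <- layer$hidden
  H <- vector("list", K)
  out <- matrix(rep(layer$params$b2, each = B), B, U)
  for (k in seq_len(K)) {
    hk <- .relu(u * rep(layer$params$W1[, k], each = B) +
                  rep(layer$params$b1[, k], each = B))
    H[[k]] <- hk
    out <- out + hk * rep(layer$params$W2[, k], each = B)
  }
  list(out = out, cache = list(u = u, H = H))
}

nn_forward <- function(model, x, training = FALSE) {
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    step <- switch(layer$type,
                   conv1d = .fwd_conv1d(layer, x),
                   maxpool = .fwd_maxpool(layer, x),
                   flatten = .fwd_flatten(layer, x),
                   dense = .fwd_dense(layer, x, training = training),
                   unitwise_mlp = .fwd_unitwise(layer, x))
    caches[[i]] <- step$cache
    x <- step$out
  }
  list(out = x, caches = caches)
}

# ---- backward ---------------------------------------------------------------

.bwd_conv1d <- function(layer, cache, dout, need_dx) {
  d <- dim(cache$x); B <- d[1L]; Cin <- d[3L]
  k <- layer$kernel; Fo <- layer$filters; Lout <- cache$Lout
  dZ <- matrix(dout, B * Lout, Fo)
  if (layer$activation == "relu") dZ[cache$act <= 0] <- 0
  gW <- array(0, dim(layer$params$W))
  dx <- if (need_dx) array(0, d) else NULL
  for (j in seq_len(k)) {
    Xj <- matrix(cache$x[, j:(j + Lout - 1L), , drop = FALSE], B * Lout, Cin)
    gW[j, , ] <- crossprod(Xj, dZ)
    if (need_dx) {
      dxj <- array(dZ %*% t(matrix(layer$params$W[j, , ], Cin, Fo)),
                   c(B, Lout, Cin))
      dx[, j:(j + Lout - 1L), ] <- dx[, j:(j + Lout - 1L), , drop = FALSE] + dxj
    }
  }
  list(grads = list(W = gW, b = colSums(dZ)), dx = dx)
}

.bwd_maxpool <- function(layer, cache, dout) {
  d <- cache$in_dim
  dx <- array(0, d)
  Lp <- dim(dout)[2L]
  for (j in seq_len(cache$pool)) {
    sel <- cache$argj == j
    if (!any(sel)) next
    slice <- array(0, dim(dout))
    slice[sel] <- dout[sel]
    cols <- seq(j, by = cache$pool, length.out = Lp)
    dx[, cols, ] <- dx[, cols, , drop = FALSE] + slice
  }
  list(grads = list(), dx = dx)
}

.bwd_flatten <- function(layer, cache, dout) {
  list(grads = list(), dx = array(dout, cache$in_dim))
}

.bwd_dense <- function(layer, cache, dout, need_dx) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  dz <- switch(layer$activation,
               relu = { d <- dout; d[cache$z <= 0] <- 0; d },
               sigmoid = dout * cache$act * (1 - cache$act),
               dout)
  list(grads = list(W = crossprod(cache$x, dz), b = colSums(dz)),
       dx = if (need_dx) dz %*% t(layer$params$W) else NULL)
}

.bwd_unitwise <- function(layer, cache, dout) {
  B <- nrow(cache$u); U <- layer$units; K <- layer$hidden
  gW1 <- matrix(0, U, K); gb1 <- matrix(0, U, K); gW2 <- matrix(0, U, K)
  du <- matrix(0, B, U)
  for (k in seq_len(K)) {
    hk <- cache$H[[k]]
    dh <- dout * rep(layer$params$W2[, k], each = B)
    dh[hk <= 0] <- 0
    gW2[, k] <- colSums(dout * hk)
    gW1[, k] <- colSums(dh * cache$u)
    gb1[, k] <- colSums(dh)
    du <- du + dh * rep(layer$params$W1[, k], each = B)
  }
  list(grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = colSums(dout)), dx = du)
}

nn_backward <- function(model, caches, dout) {
  n <- length(model$layers)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    layer <- model$layers[[i]]
    need_dx <- i > 1L
    step <- switch(layer$type,
                   conv1d = .bwd_conv1d(layer, caches[[i]], dout, need_dx),
                   maxpool = .bwd_maxpool(layer, caches[[i]], dout),
                   flatten = .bwd_flatten(layer, caches[[i]], dout),
                   dense = .bwd_dense(layer, caches[[i]], dout, need_dx),
                   unitwise_mlp = .bwd_unitwise(layer, caches[[i]], dout))
    grads[[i]] <- step$grads
    dout <- step$dx
  }
  grads
}

# ---- loss -------------------------------------------------------------------

# Both losses are means over batch x tasks; binary cross-entropy is computed
# from logits in the numerically stable form.
nn_loss <- function(logits, y, loss = c("mse", "bce")) {
  loss <- match.arg(loss)
  n <- length(y)
  if (loss == "mse") {
    r <- logits - y
    list(value = mean(r * r), dlogits = 2 * r / n)
  } else {
    val <- mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
    p <- 1 / (1 + exp(-logits))
    list(value = val, dlogits = (p - y) / n)
  }
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(model) {
  lapply(model$layers, function(l) lapply(l$params, function(p) {
    list(m = array(0, dim(p) %||% length(p)), v = array(0, dim(p) %||% length(p)))
  }))
}

adam_update <- function(model, grads, state, step, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (i in seq_along(model$layers)) {
    for (nm in names(model$layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      model$layers[[i]]$params[[nm]] <- model$layers[[i]]$params[[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(model = model, state = state)
}

get_weights <- function(model) lapply(model$layers, function(l) l$params)

set_weights <- function(model, weights) {
  for (i in seq_along(model$layers)) model$layers[[i]]$params <- weights[[i]]
  model
}
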