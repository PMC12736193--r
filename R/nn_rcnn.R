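# Internals of the 1D-convolutional regression network. Activations are
# kept as (B, L, C) arrays; position-wise operations view them as
# (B*L) x C matrices with row index b + (l-1)*B, and convolutions are
# evaluated as im2col matrix products against (k*C_in) x C_out weights.

leaky_relu <- function(x, a) ifelse(x > 0, x, a * x)
leaky_relu_grad <- function(x, a) ifelse(x > 0, 1, a)

as_bl_matrix <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

as_blc_array <- function(m, B, L) {
  dim(m) <- c(B, L, ncol(m))
  m
}

# "same" padding for kernel k: floor((k-1)/2) zeros on the left, the rest on
# the right, so output length equals input length at stride 1.
conv1d_forward <- function(x, W, b, k) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  pl <- (k - 1) %/% 2; pr <- k - 1 - pl
  xp <- array(0, c(B, L + k - 1, C))
  xp[, (pl + 1):(pl + L), ] <- x
  cols <- vector("list", k)
  for (j in seq_len(k)) {
    blk <- xp[, j:(j + L - 1), , drop = FALSE]
    dim(blk) <- c(B * L, C)
    cols[[j]] <- blk
  }
  x2 <- do.call(cbind, cols)            # (B*L) x (k*C)
  y <- x2 %*% W + rep(b, each = B * L)
  list(out = as_blc_array(y, B, L), x2 = x2, B = B, L = L, C = C)
}

conv1d_backward <- function(dout, cache, W, k) {
  B <- cache$B; L <- cache$L; C <- cache$C
  dy <- as_bl_matrix(dout)
  dW <- crossprod(cache$x2, dy)
  db <- colSums(dy)
  dx2 <- dy %*% t(W)                    # (B*L) x (k*C)
  pl <- (k - 1) %/% 2
  dxp <- array(0, c(B, L + k - 1, C))
  for (j in seq_len(k)) {
    blk <- dx2[, ((j - 1) * C + 1):(j * C), drop = FALSE]
    dim(blk) <- c(B, L, C)
    dxp[, j:(j + L - 1), ] <- dxp[, j:(j + L - 1), , drop = FALSE] + blk
  }
  dx <- dxp[, (pl + 1):(pl + L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

batchnorm_forward <- function(x, gamma, beta, rmean, rvar, training,
                              momentum = 0.9, eps = 1e-3) {
  d <- dim(x)
  m <- as_bl_matrix(x)
  if (training) {
    mu <- colMeans(m)
    var <- colMeans(sweep(m, 2, mu)^2)
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * var
  } else {
    mu <- rmean; var <- rvar
  }
  inv <- 1 / sqrt(var + eps)
  xhat <- sweep(sweep(m, 2, mu), 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = as_blc_array(y, d[1], d[2]), xhat = xhat, inv = inv,
       rmean = rmean, rvar = rvar)
}

batchnorm_backward <- function(dout, cache, gamma) {
  d <- dim(dout)
  dy <- as_bl_matrix(dout)
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  t1 <- sweep(dy, 2, colMeans(dy))
  t2 <- sweep(cache$xhat, 2, colMeans(dy * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2, gamma * cache$inv, `*`)
  list(dx = as_blc_array(dx, d[1], d[2]), dgamma = dgamma, dbeta = dbeta)
}

maxpool2_forward <- function(x) {
  d <- dim(x); Lout <- d[2] %/% 2
  a <- x[, seq(1, 2 * Lout, by = 2), , drop = FALSE]
  b <- x[, seq(2, 2 * Lout, by = 2), , drop = FALSE]
  take_a <- a >= b
  list(out = ifelse(take_a, a, b), take_a = take_a, Lin = d[2])
}

maxpool2_backward <- function(dout, cache) {
  d <- dim(dout); B <- d[1]; Lout <- d[2]; C <- d[3]
  dx <- array(0, c(B, cache$Lin, C))
  dx[, seq(1, 2 * Lout, by = 2), ] <- dout * cache$take_a
  dx[, seq(2, 2 * Lout, by = 2), ] <- dout * !cache$take_a
  dx
}

init_rcnn_params <- function(cfg, vocab_size) {
  glorot <- function(fan_in, fan_out, nr, nc) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  chans <- c(cfg$embedding_dim, cfg$filters)
  convs <- lapply(seq_len(cfg$n_conv_layers), function(i) {
    kc <- cfg$kernel_size * chans[i]
    list(W = glorot(kc, chans[i + 1], kc, chans[i + 1]),
         b = rep(0, chans[i + 1]),
         gamma = rep(1, chans[i + 1]), beta = rep(0, chans[i + 1]))
  })
  L <- attr_seq_lengths(cfg)$final
  flat <- L * chans[length(chans)]
  list(
    emb = matrix(stats::runif(vocab_size * cfg$embedding_dim, -0.05, 0.05),
                 vocab_size, cfg$embedding_dim),
    convs = convs,
    W1 = glorot(flat, cfg$dense_sizes[1], flat, cfg$dense_sizes[1]),
    b1 = rep(0, cfg$dense_sizes[1]),
    W2 = glorot(cfg$dense_sizes[1], cfg$dense_sizes[2],
                cfg$dense_sizes[1], cfg$dense_sizes[2]),
    b2 = rep(0, cfg$dense_sizes[2]),
    W3 = glorot(cfg$dense_sizes[2], 1, cfg$dense_sizes[2], 1),
    b3 = 0
  )
}

# Sequence length through the six pool-by-2 stages (floor division).
attr_seq_lengths <- function(cfg) {
  L <- cfg$input_length
  lens <- integer(cfg$n_conv_layers)
  for (i in seq_len(cfg$n_conv_layers)) {
    lens[i] <- L %/% cfg$pool_size
    L <- lens[i]
  }
  list(per_layer = lens, final = L)
}

# Full forward pass. ids: B x input_length integer matrix (0 = pad).
# Returns predictions and, in training mode, all caches for backward plus
# updated batch-norm running statistics.
rcnn_forward <- function(params, ids, cfg, bn_state, training = FALSE) {
  B <- nrow(ids); L0 <- ncol(ids)
  stopifnot(L0 == cfg$input_length)
  x <- params$emb[as.vector(ids) + 1L, , drop = FALSE]  # (B*L0) x E
  x <- as_blc_array(x, B, L0)
  caches <- list(ids = ids)
  for (i in seq_len(cfg$n_conv_layers)) {
    p <- params$convs[[i]]
    cv <- conv1d_forward(x, p$W, p$b, cfg$kernel_size)
    bn <- batchnorm_forward(cv$out, p$gamma, p$beta,
                            bn_state[[i]]$mean, bn_state[[i]]$var, training)
    if (training) bn_state[[i]] <- list(mean = bn$rmean, var = bn$rvar)
    act_in <- bn$out
    act <- leaky_relu(act_in, cfg$leaky_slope)
    mp <- maxpool2_forward(act)
    caches[[paste0("layer", i)]] <- list(cv = cv, bn = bn, act_in = act_in,
                                         mp = mp)
    x <- mp$out
  }
  d <- dim(x)
  flat <- x; dim(flat) <- c(d[1], d[2] * d[3])
  h1_pre <- flat %*% params$W1 + rep(params$b1, each = B)
  h1 <- leaky_relu(h1_pre, cfg$leaky_slope)
  h2_pre <- h1 %*% params$W2 + rep(params$b2, each = B)
  h2 <- leaky_relu(h2_pre, cfg$leaky_slope)
  pred <- drop(h2 %*% params$W3) + params$b3
  caches$head <- list(flat = flat, h1_pre = h1_pre, h1 = h1,
                      h2_pre = h2_pre, h2 = h2, dims = d)
  list(pred = pred, caches = caches, bn_state = bn_state)
}

rcnn_backward <- function(params, cfg, fw, dpred) {
  B <- length(dpred)
  hc <- fw$caches$head
  g <- list(convs = vector("list", cfg$n_conv_layers))
  g$W3 <- crossprod(hc$h2, matrix(dpred, B, 1))
  g$b3 <- sum(dpred)
  dh2 <- matrix(dpred, B, 1) %*% t(params$W3) *
    leaky_relu_grad(hc$h2_pre, cfg$leaky_slope)
  g$W2 <- crossprod(hc$h1, dh2); g$b2 <- colSums(dh2)
  dh1 <- dh2 %*% t(params$W2) * leaky_relu_grad(hc$h1_pre, cfg$leaky_slope)
  g$W1 <- crossprod(hc$flat, dh1); g$b1 <- colSums(dh1)
  dflat <- dh1 %*% t(params$W1)
  dx <- dflat; dim(dx) <- hc$dims
  for (i in rev(seq_len(cfg$n_conv_layers))) {
    lc <- fw$caches[[paste0("layer", i)]]
    p <- params$convs[[i]]
    dact <- maxpool2_backward(dx, lc$mp)
    dbn_out <- dact * leaky_relu_grad(lc$act_in, cfg$leaky_slope)
    bb <- batchnorm_backward(dbn_out, lc$bn, p$gamma)
    cb <- conv1d_backward(bb$dx, lc$cv, p$W, cfg$kernel_size)
    g$convs[[i]] <- list(W = cb$dW, b = cb$db, gamma = bb$dgamma,
                         beta = bb$dbeta)
    dx <- cb$dx
  }
  demb <- as_bl_matrix(dx)
  g$emb <- rowsum_into(demb, as.vector(fw$caches$ids) + 1L, nrow(params$emb))
  g
}

rmsprop_init <- function(params) {
  list(v = tree_map(function(x) x * 0, params))
}

tree_map3 <- function(f, a, b, c) {
  if (is.list(a)) {
    if (!is.null(names(a))) {
      if (!is.null(names(b))) b <- b[names(a)]
      if (!is.null(names(c))) c <- c[names(a)]
    }
    return(mapply(function(x, y, z) tree_map3(f, x, y, z), a, b, c,
                  SIMPLIFY = FALSE))
  }
  f(a, b, c)
}

rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-7) {
  state$v <- tree_map2(function(v, g) rho * v + (1 - rho) * g^2,
                       state$v, grads)
  params <- tree_map3(function(p, g, v) p - lr * g / (sqrt(v) + eps),
                      params, grads, state$v)
  list(params = params, state = state)
}
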