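# Decoder-only transformer (GPT-style) implemented in base R matrix algebra:
# token + learned positional embeddings, pre-norm blocks of causal multi-head
# self-attention and a GELU MLP, weight-tied output head, hand-derived
# backpropagation, AdamW with decoupled weight decay and a cosine learning
# rate schedule with linear warmup.

gelu <- function(x) {
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

gelu_grad <- function(x) {
  inner <- sqrt(2 / pi) * (x + 0.044715 * x^3)
  t <- tanh(inner)
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * sqrt(2 / pi) * (1 + 3 * 0.044715 * x^2)
}

# Row-wise layer norm; returns normalized output plus caches for backward.
ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dout, cache, g) {
  xhat <- cache$xhat
  inv <- cache$inv
  dg <- colSums(dout * xhat)
  db <- colSums(dout)
  dxhat <- sweep(dout, 2, g, `*`)
  d <- ncol(xhat)
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

rand_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

# Parameter initialization (GPT-2 style: N(0, 0.02), residual projections
# scaled by 1/sqrt(2 * n_layers)).
init_clm_params <- function(vocab_size, cfg) {
  d <- cfg$d_model
  scale <- 0.02
  res_scale <- scale / sqrt(2 * cfg$n_layers)
  layers <- lapply(seq_len(cfg$n_layers), function(l) {
    list(
      ln1_g = rep(1, d), ln1_b = rep(0, d),
      Wqkv = rand_mat(d, 3 * d, scale), bqkv = rep(0, 3 * d),
      Wo = rand_mat(d, d, res_scale), bo = rep(0, d),
      ln2_g = rep(1, d), ln2_b = rep(0, d),
      W1 = rand_mat(d, 4 * d, scale), b1 = rep(0, 4 * d),
      W2 = rand_mat(4 * d, d, res_scale), b2 = rep(0, d)
    )
  })
  list(tok = rand_mat(vocab_size, d, scale),
       pos = rand_mat(cfg$context_window, d, 0.01),
       layers = layers,
       lnf_g = rep(1, d), lnf_b = rep(0, d))
}

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# Forward (and optionally backward) pass over a batch of equal-length
# sequences. ids, targets: B x L integer matrices (1-based ids; targets of 0
# are masked out of the loss). Returns loss and, if requested, gradients
# with the same shape as the parameters.
clm_loss_and_grad <- function(params, ids, targets, cfg, want_grad = TRUE) {
  B <- nrow(ids); L <- ncol(ids); d <- cfg$d_model
  nh <- cfg$n_heads; dh <- d %/% nh
  stopifnot(nh * dh == d, L <= cfg$context_window)
  N <- B * L
  flat_ids <- as.integer(t(ids))            # seq-major: (b1 t1..tL, b2 ...)
  x <- params$tok[flat_ids, , drop = FALSE] +
    params$pos[rep(seq_len(L), B), , drop = FALSE]

  seq_rows <- function(b) ((b - 1) * L + 1):(b * L)
  mask <- matrix(-Inf, L, L); mask[lower.tri(mask, diag = TRUE)] <- 0

  caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    p <- params$layers[[l]]
    c1 <- ln_forward(x, p$ln1_g, p$ln1_b)
    qkv <- c1$out %*% p$Wqkv + rep(p$bqkv, each = N)
    attn_out <- matrix(0, N, d)
    Pmats <- vector("list", B * nh)
    for (b in seq_len(B)) {
      rows <- seq_rows(b)
      for (h in seq_len(nh)) {
        cq <- ((h - 1) * dh + 1):(h * dh)
        Q <- qkv[rows, cq, drop = FALSE]
        K <- qkv[rows, d + cq, drop = FALSE]
        V <- qkv[rows, 2 * d + cq, drop = FALSE]
        S <- tcrossprod(Q, K) / sqrt(dh) + mask
        P <- softmax_rows(S)
        attn_out[rows, cq] <- P %*% V
        Pmats[[(b - 1) * nh + h]] <- P
      }
    }
    proj <- attn_out %*% p$Wo + rep(p$bo, each = N)
    x2 <- x + proj
    c2 <- ln_forward(x2, p$ln2_g, p$ln2_b)
    h_pre <- c2$out %*% p$W1 + rep(p$b1, each = N)
    h_act <- gelu(h_pre)
    mlp <- h_act %*% p$W2 + rep(p$b2, each = N)
    x_new <- x2 + mlp
    caches[[l]] <- list(x_in = x, c1 = c1, qkv = qkv, attn_out = attn_out,
                        Pmats = Pmats, x2 = x2, c2 = c2, h_pre = h_pre,
                        h_act = h_act)
    x <- x_new
  }
  cf <- ln_forward(x, params$lnf_g, params$lnf_b)
  logits <- tcrossprod(cf$out, params$tok)   # N x V (tied head)

  flat_tgt <- as.integer(t(targets))
  valid <- flat_tgt > 0
  n_valid <- sum(valid)
  if (n_valid == 0) stop("no unmasked target positions in batch", call. = FALSE)
  lmax <- apply(logits, 1, max)
  lse <- lmax + log(rowSums(exp(logits - lmax)))
  picked <- logits[cbind(seq_len(N), pmax(flat_tgt, 1L))]
  loss <- sum((lse - picked)[valid]) / n_valid
  if (!want_grad) return(list(loss = loss))

  probs <- exp(logits - lse)
  dlogits <- probs
  dlogits[cbind(seq_len(N), pmax(flat_tgt, 1L))] <-
    dlogits[cbind(seq_len(N), pmax(flat_tgt, 1L))] - 1
  dlogits[!valid, ] <- 0
  dlogits <- dlogits / n_valid

  g <- list(tok = crossprod(dlogits, cf$out),   # V x d (head side of tying)
            pos = matrix(0, nrow(params$pos), d),
            layers = vector("list", cfg$n_layers))
  dcf <- dlogits %*% params$tok
  lb <- ln_backward(dcf, cf, params$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dx <- lb$dx

  for (l in rev(seq_len(cfg$n_layers))) {
    p <- params$layers[[l]]
    cc <- caches[[l]]
    gl <- list()
    # MLP branch
    dmlp <- dx
    gl$W2 <- crossprod(cc$h_act, dmlp); gl$b2 <- colSums(dmlp)
    dh_act <- dmlp %*% t(p$W2)
    dh_pre <- dh_act * gelu_grad(cc$h_pre)
    gl$W1 <- crossprod(cc$c2$out, dh_pre); gl$b1 <- colSums(dh_pre)
    dc2 <- dh_pre %*% t(p$W1)
    lb2 <- ln_backward(dc2, cc$c2, p$ln2_g)
    gl$ln2_g <- lb2$dg; gl$ln2_b <- lb2$db
    dx2 <- dx + lb2$dx
    # attention branch
    dproj <- dx2
    gl$Wo <- crossprod(cc$attn_out, dproj); gl$bo <- colSums(dproj)
    dattn <- dproj %*% t(p$Wo)
    dqkv <- matrix(0, N, 3 * d)
    for (b in seq_len(B)) {
      rows <- seq_rows(b)
      for (h in seq_len(nh)) {
        cq <- ((h - 1) * dh + 1):(h * dh)
        Q <- cc$qkv[rows, cq, drop = FALSE]
        K <- cc$qkv[rows, d + cq, drop = FALSE]
        V <- cc$qkv[rows, 2 * d + cq, drop = FALSE]
        P <- cc$Pmats[[(b - 1) * nh + h]]
        dO <- dattn[rows, cq, drop = FALSE]
        dP <- tcrossprod(dO, V)
        dV <- crossprod(P, dO)
        dS <- P * (dP - rowSums(dP * P))
        dS <- dS / sqrt(dh)
        dqkv[rows, cq] <- dS %*% K
        dqkv[rows, d + cq] <- crossprod(dS, Q)
        dqkv[rows, 2 * d + cq] <- dV
      }
    }
    gl$Wqkv <- crossprod(cc$c1$out, dqkv); gl$bqkv <- colSums(dqkv)
    dc1 <- dqkv %*% t(p$Wqkv)
    lb1 <- ln_backward(dc1, cc$c1, p$ln1_g)
    gl$ln1_g <- lb1$dg; gl$ln1_b <- lb1$db
    dx <- dx2 + lb1$dx
    g$layers[[l]] <- gl
  }
  # embedding gradients: input lookup side (+ head side already in g$tok)
  g$tok <- g$tok + rowsum_into(dx, flat_ids, nrow(params$tok))
  g$pos[seq_len(L), ] <- rowsum_into(dx, rep(seq_len(L), B), L)
  list(loss = loss, grad = g)
}

# Accumulate rows of `m` into `nbins` bins given by `idx`.
rowsum_into <- function(m, idx, nbins) {
  out <- matrix(0, nbins, ncol(m))
  rs <- rowsum(m, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# Forward pass for one sequence (no padding); returns logits at the final
# position only — used by sampling.
clm_logits_last <- function(params, ids, cfg) {
  L <- length(ids); d <- cfg$d_model; nh <- cfg$n_heads; dh <- d %/% nh
  x <- params$tok[ids, , drop = FALSE] + params$pos[seq_len(L), , drop = FALSE]
  mask <- matrix(-Inf, L, L); mask[lower.tri(mask, diag = TRUE)] <- 0
  for (l in seq_len(cfg$n_layers)) {
    p <- params$layers[[l]]
    a <- ln_forward(x, p$ln1_g, p$ln1_b)$out
    qkv <- a %*% p$Wqkv + rep(p$bqkv, each = L)
    attn_out <- matrix(0, L, d)
    for (h in seq_len(nh)) {
      cq <- ((h - 1) * dh + 1):(h * dh)
      Q <- qkv[, cq, drop = FALSE]
      K <- qkv[, d + cq, drop = FALSE]
      V <- qkv[, 2 * d + cq, drop = FALSE]
      P <- softmax_rows(tcrossprod(Q, K) / sqrt(dh) + mask)
      attn_out[, cq] <- P %*% V
    }
    x <- x + attn_out %*% p$Wo + rep(p$bo, each = L)
    a2 <- ln_forward(x, p$ln2_g, p$ln2_b)$out
    x <- x + gelu(a2 %*% p$W1 + rep(p$b1, each = L)) %*% p$W2 +
      rep(p$b2, each = L)
  }
  f <- ln_forward(x, params$lnf_g, params$lnf_b)$out
  drop(params$tok %*% f[L, ])
}

# --- generic parameter-tree utilities (shared with the RCNN) ---------------

tree_map <- function(f, a) {
  if (is.list(a)) return(lapply(a, function(x) tree_map(f, x)))
  f(a)
}

# Zip two parameter trees; named list levels are aligned by name so the
# field order of gradient trees need not match the parameter tree.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    return(mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE))
  }
  f(a, b)
}

adamw_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0)
}

# Decoupled weight decay is applied to matrices only (embeddings and linear
# maps), never to biases or layer-norm gains.
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) {
    wd <- if (is.matrix(p)) weight_decay else 0
    p - lr * (u + wd * p)
  }, params, upd)
  list(params = params, state = state)
}

# Cosine schedule with linear warmup, as a multiplier on the base rate.
lr_multiplier <- function(step, warmup_steps, total_steps) {
  if (warmup_steps > 0 && step <= warmup_steps) return(step / warmup_steps)
  denom <- max(total_steps - warmup_steps, 1)
  progress <- min((step - warmup_steps) / denom, 1)
  0.5 * (1 + cos(pi * progress))
}
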