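test_that("the architecture has the stated shapes and pooling arithmetic", {
  cfg <- rcnn_config()
  # 800 -> 400 -> 200 -> 100 -> 50 -> 25 -> 12 under floor division
  lens <- attr_seq_lengths(cfg)
  expect_equal(lens$per_layer, c(400, 200, 100, 50, 25, 12))
  expect_equal(lens$final, 12)
  m <- build_rcnn(cfg, vocab_size = 30)
  # forward on an all-pad sequence yields one finite real
  p <- predict_pki(m, rep(0L, 800))
  expect_length(p, 1)
  expect_true(is.finite(p))
  # wrong input length is a shape error
  expect_error(predict_pki(m, rep(0L, 799)), "length 800")
  # config invariants
  expect_error(rcnn_config(filters = c(32, 32)), "length")
  expect_error(rcnn_config(filters = c(16, 32, 32, 64, 64, 64)), "\\[32, 64\\]")
})

test_that("RCNN gradients agree with finite differences", {
  set.seed(7)
  cfg <- rcnn_config(n_conv_layers = 2, filters = c(32, 32), input_length = 32,
                     dense_sizes = c(16, 4), batch_size = 4, seed = 1)
  m <- build_rcnn(cfg, vocab_size = 12)
  ids <- matrix(sample(0:11, 5 * 32, replace = TRUE), 5, 32)
  y <- rnorm(5, 5)
  loss_at <- function(params) {
    fw <- rcnn_forward(params, ids, cfg, m$bn_state, training = TRUE)
    mean((fw$pred - y)^2)
  }
  fw <- rcnn_forward(m$params, ids, cfg, m$bn_state, training = TRUE)
  g <- rcnn_backward(m$params, cfg, fw, 2 * (fw$pred - y) / 5)
  coords <- list(
    list(get = function(p) p$emb, set = function(p, v) { p$emb[] <- v; p },
         g = g$emb),
    list(get = function(p) p$convs[[1]]$W,
         set = function(p, v) { p$convs[[1]]$W[] <- v; p }, g = g$convs[[1]]$W),
    list(get = function(p) p$convs[[2]]$gamma,
         set = function(p, v) { p$convs[[2]]$gamma <- v; p },
         g = g$convs[[2]]$gamma),
    list(get = function(p) p$W1, set = function(p, v) { p$W1[] <- v; p },
         g = g$W1))
  eps <- 1e-5
  for (co in coords) {
    v0 <- co$get(m$params)
    i <- sample(length(v0), 1)
    vp <- v0; vp[i] <- vp[i] + eps
    vm <- v0; vm[i] <- vm[i] - eps
    num <- (loss_at(co$set(m$params, vp)) - loss_at(co$set(m$params, vm))) /
      (2 * eps)
    expect_equal(co$g[i], num, tolerance = 1e-4)
  }
})

test_that("evaluate_regression matches a brute-force recomputation", {
  # hand-derived case
  ev <- evaluate_regression(c(0, 1, 2, 3), c(0.5, 1.5, 2.5, 3.5))
  expect_equal(ev$rmse, 0.5)
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$r_squared, 0.8)
  # identity and mean-predictor baselines
  id <- evaluate_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(id$pearson_r, id$r_squared, id$rmse), c(1, 1, 0))
  base <- evaluate_regression(c(1, 2, 3), rep(2, 3))
  expect_equal(base$r_squared, 0)
  expect_true(is.na(base$pearson_r))  # constant prediction: undefined R
  # independent brute-force oracle on random vectors
  brute <- function(y, f) {
    n <- length(y)
    my <- sum(y) / n; mf <- sum(f) / n
    cov <- sum((y - my) * (f - mf)) / (n - 1)
    r <- cov / sqrt(sum((y - my)^2) / (n - 1)) / sqrt(sum((f - mf)^2) / (n - 1))
    list(r = r, r2 = 1 - sum((y - f)^2) / sum((y - my)^2),
         rmse = sqrt(sum((y - f)^2) / n))
  }
  set.seed(31)
  for (k in 1:100) {
    n <- sample(2:40, 1)
    y <- rnorm(n); f <- rnorm(n)
    if (sd(y) == 0) next
    ev <- evaluate_regression(y, f)
    or <- brute(y, f)
    expect_equal(ev$pearson_r, or$r, tolerance = 1e-9)
    expect_equal(ev$r_squared, or$r2, tolerance = 1e-9)
    expect_equal(ev$rmse, or$rmse, tolerance = 1e-9)
  }
  expect_error(evaluate_regression(1:3, 1:4), "equal length")
  expect_error(evaluate_regression(c(2, 2, 2), 1:3), "constant")
})

test_that("a small RCNN memorizes five pairs and predicts deterministically", {
  tm <- tiny_models()
  X <- encode_for_rcnn(tm$five$protein_seq, tm$five$smiles, tm$vocab,
                       length_out = 128)
  pred <- predict_pki(tm$rcnn, X)
  expect_true(all(abs(pred - tm$five$pki) < 0.2))
  # prediction is invariant to batch composition
  expect_equal(predict_pki(tm$rcnn, X[c(1, 1, 2), , drop = FALSE]),
               pred[c(1, 1, 2)], tolerance = 1e-12)
  expect_equal(predict_pki(tm$rcnn, X, batch_size = 2), pred,
               tolerance = 1e-12)
  # training history shows learning
  h <- tidy(tm$rcnn)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("training is seed-reproducible and validates its inputs", {
  pairs <- make_paired_corpus(30, seed = 13)
  vocab <- build_char_vocab(pairs)
  cfg <- rcnn_config(n_conv_layers = 2, filters = c(32, 32),
                     input_length = 64, dense_sizes = c(32, 8),
                     epochs = 3, batch_size = 8, seed = 5)
  X <- encode_for_rcnn(pairs$protein_seq, pairs$smiles, vocab, length_out = 64)
  m1 <- train_rcnn(build_rcnn(cfg, length(vocab) + 1), X, pairs$pki)
  m2 <- train_rcnn(build_rcnn(cfg, length(vocab) + 1), X, pairs$pki)
  expect_equal(m1$history$train_loss, m2$history$train_loss, tolerance = 1e-12)
  expect_error(train_rcnn(build_rcnn(cfg, 10), X[0, ], numeric(0)), "empty")
  expect_error(train_rcnn(build_rcnn(cfg, 10), X, pairs$pki[-1]), "differ")
})

test_that("repeat_experiment summarizes metrics over randomized partitions", {
  pairs <- make_paired_corpus(40, seed = 17)
  vocab <- build_char_vocab(pairs)
  cfg <- rcnn_config(n_conv_layers = 2, filters = c(32, 32),
                     input_length = 64, dense_sizes = c(32, 8),
                     epochs = 2, batch_size = 8)
  rep2 <- repeat_experiment(pairs, vocab, cfg, seeds = c(1, 2))
  expect_equal(nrow(rep2$runs), 2)
  expect_true(all(rep2$summary$n_repeats == 2))
  expect_true(all(c("val_r", "val_r2_ep1", "train_loss") %in%
                    rep2$summary$metric))
  expect_true(all(rep2$summary$sd >= 0, na.rm = TRUE))
  # identical seeds give zero spread
  rep0 <- repeat_experiment(pairs, vocab, cfg, seeds = c(3, 3))
  expect_true(all(abs(rep0$summary$sd) < 1e-9, na.rm = TRUE))
})

test_that("RCNN checkpoints restore predictions exactly", {
  tm <- tiny_models()
  X <- encode_for_rcnn(tm$five$protein_seq, tm$five$smiles, tm$vocab,
                       length_out = 128)
  path <- tempfile(fileext = ".json")
  save_rcnn(tm$rcnn, path)
  m2 <- load_rcnn(path)
  expect_equal(predict_pki(m2, X), predict_pki(tm$rcnn, X), tolerance = 1e-12)
})

test_that("affinity noise degrades validation accuracy", {
  vocab_len <- 128
  cfg <- rcnn_config(n_conv_layers = 4, filters = c(32, 32, 64, 64),
                     input_length = vocab_len, dense_sizes = c(64, 10),
                     epochs = 10, batch_size = 16, loss = "mae", seed = 1)
  val_rmse <- function(noise) {
    corpus <- make_paired_corpus(200, noise_sd = noise, seed = 29)
    vocab <- build_char_vocab(corpus)
    sp <- split_dataset(corpus, 0.7, seed = 1)
    Xtr <- encode_for_rcnn(sp$train$protein_seq, sp$train$smiles, vocab,
                           length_out = vocab_len)
    Xva <- encode_for_rcnn(sp$val$protein_seq, sp$val$smiles, vocab,
                           length_out = vocab_len)
    m <- train_rcnn(build_rcnn(cfg, length(vocab) + 1), Xtr, sp$train$pki,
                    Xva, sp$val$pki)
    m$history$val_rmse[nrow(m$history)]
  }
  expect_gt(val_rmse(1.0), val_rmse(0))
})
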