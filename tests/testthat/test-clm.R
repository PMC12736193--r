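test_that("transformer gradients agree with finite differences", {
  set.seed(42)
  cfg <- clm_config(preset = "tiny", d_model = 16, n_heads = 2, n_layers = 2,
                    context_window = 32, max_length = 12)
  V <- 11
  params <- with_seed(1, init_clm_params(V, cfg))
  ids <- matrix(sample(1:V, 3 * 8, replace = TRUE), 3, 8)
  tgt <- cbind(ids[, -1], 0L)
  tgt[2, 5:7] <- 0L  # some masked positions
  fb <- clm_loss_and_grad(params, ids, tgt, cfg)
  loss_at <- function(p) clm_loss_and_grad(p, ids, tgt, cfg, want_grad = FALSE)$loss
  eps <- 1e-5
  coords <- list(
    list(get = function(p) p$tok, set = function(p, v) { p$tok[] <- v; p },
         g = fb$grad$tok),
    list(get = function(p) p$layers[[1]]$Wqkv,
         set = function(p, v) { p$layers[[1]]$Wqkv[] <- v; p },
         g = fb$grad$layers[[1]]$Wqkv),
    list(get = function(p) p$layers[[2]]$W2,
         set = function(p, v) { p$layers[[2]]$W2[] <- v; p },
         g = fb$grad$layers[[2]]$W2),
    list(get = function(p) p$lnf_g,
         set = function(p, v) { p$lnf_g <- v; p }, g = fb$grad$lnf_g))
  for (co in coords) {
    v0 <- co$get(params)
    i <- sample(length(v0), 1)
    vp <- v0; vp[i] <- vp[i] + eps
    vm <- v0; vm[i] <- vm[i] - eps
    num <- (loss_at(co$set(params, vp)) - loss_at(co$set(params, vm))) / (2 * eps)
    expect_equal(co$g[i], num, tolerance = 1e-5)
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  pairs <- toy_corpus()[1:20, ]
  tok <- train_bpe(paste(pairs$protein_seq, pairs$smiles), vocab_size = 150)
  cfg <- clm_config(preset = "tiny", d_model = 32, n_heads = 2, epochs = 4,
                    batch_size = 10, grad_accumulation = 1,
                    learning_rate = 2e-3, warmup_steps = 4, max_length = 64,
                    context_window = 96, eval_every_steps = 1000, seed = 9)
  m <- train_clm(pairs, pairs[1:5, ], tok, cfg)
  losses <- m$log$train_loss[!is.na(m$log$train_loss)]
  expect_lt(utils::tail(losses, 1), losses[1])
  expect_true(all(is.finite(losses)) && all(losses >= 0))
  # the final validation loss is logged
  expect_false(is.na(utils::tail(m$log$val_loss, 1)))
  # identical seeds give identical loss curves
  m2 <- train_clm(pairs, pairs[1:5, ], tok, cfg)
  expect_equal(m$log$train_loss, m2$log$train_loss, tolerance = 1e-12)
  expect_error(train_clm(pairs[0, ], NULL, tok, cfg), "empty")
})

test_that("generation respects the token budget, seeding, and eos stop", {
  tm <- tiny_models()
  gcfg <- generation_config(max_new_tokens = 5, temperature = 1, seed = 2)
  g <- generate_raw(tm$clm, tm$tok, tm$pair$protein_seq, gcfg)
  # at most 5 new tokens decoded
  expect_lte(length(bpe_encode(tm$tok, g)), 5)
  expect_identical(g, generate_raw(tm$clm, tm$tok, tm$pair$protein_seq, gcfg))
  # near-greedy decoding on the memorized pair reproduces the training SMILES
  greedy <- generation_config(max_new_tokens = 100, temperature = 1e-6, seed = 1)
  out <- generate_raw(tm$clm, tm$tok, tm$pair$protein_seq, greedy)
  expect_identical(out, tm$pair$smiles)
})

test_that("over-long prompts and bad sampling configs are rejected", {
  tm <- tiny_models()
  long_protein <- strrep("MKTAYWVDFH", 40)  # far beyond the 128 context
  expect_error(generate_raw(tm$clm, tm$tok, long_protein), "context window")
  expect_error(generation_config(temperature = 0), "> 0")
  expect_error(generation_config(max_new_tokens = 0), ">= 1")
})

test_that("trimming returns the longest valid-or-empty prefix", {
  expect_identical(trim_to_valid("CCO"), "CCO")      # already valid: unchanged
  expect_identical(trim_to_valid("CCO("), "CCO")     # dangling branch removed
  expect_identical(trim_to_valid("(((("), "")        # nothing parses
  expect_identical(trim_to_valid(c("NCCN)x", "")), c("NCCN", ""))
  # vectorized property over random corruptions of valid fixture molecules
  base <- gen_toy_smiles(60, seed = 4)
  junk <- c("(", ")", "[", "=", "#", "%", "@")
  corrupted <- with_seed(8, paste0(base, vapply(seq_along(base), function(i) {
    paste(sample(junk, sample(1:3, 1), replace = TRUE), collapse = "")
  }, character(1))))
  tr <- trim_to_valid(corrupted)
  expect_true(all(tr == "" | smiles_is_valid(tr)))
  expect_true(all(substr(corrupted, 1, nchar(tr)) == tr))  # prefix property
  expect_true(all(nchar(tr) <= nchar(corrupted)))
})

test_that("batch generation preserves order and post-trim validity", {
  tm <- tiny_models()
  prots <- rep(tm$pair$protein_seq, 6)
  res <- generate_batch(tm$clm, tm$tok, prots,
                        generation_config(max_new_tokens = 40,
                                          temperature = 0.5, seed = 3))
  expect_equal(nrow(res), 6)
  expect_identical(res$protein_seq, prots)
  kept <- res$trimmed[nzchar(res$trimmed)]
  expect_true(all(smiles_is_valid(kept)))
  # already-valid raw strings pass through trimming unchanged
  ok <- smiles_is_valid(res$raw[nzchar(res$raw)])
  expect_identical(res$trimmed[nzchar(res$raw)][ok], res$raw[nzchar(res$raw)][ok])
  expect_true(attr(res, "pretrim_validity") >= 0 &&
                attr(res, "pretrim_validity") <= 1)
  # empty input gives an empty result
  expect_equal(nrow(generate_batch(tm$clm, tm$tok, character(0))), 0)
})

test_that("language models survive JSON checkpointing", {
  tm <- tiny_models()
  path <- tempfile(fileext = ".json")
  save_clm(tm$clm, path)
  m2 <- load_clm(path)
  greedy <- generation_config(max_new_tokens = 50, temperature = 1e-6, seed = 1)
  expect_identical(generate_raw(m2, tm$tok, tm$pair$protein_seq, greedy),
                   generate_raw(tm$clm, tm$tok, tm$pair$protein_seq, greedy))
})
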