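# The chemical language model: training, sampling, and the trimming repair.

#' Chemical language model configuration
#'
#' Training hyperparameters for the decoder-only transformer. The defaults
#' are the full-scale training recipe (10 epochs, batch 64, learning rate
#' 5e-4, cosine schedule with 1000 warmup steps, weight decay 0.1, gradient
#' accumulation 8, evaluation every 5000 steps, 1024-token context window);
#' `preset = "tiny"` switches to a 2-layer, 64-wide model with a short
#' schedule suitable for fixture-scale corpora.
#'
#' @param context_window Maximum sequence length the model can attend over.
#' @param n_layers,n_heads,d_model Transformer depth, attention heads, width.
#' @param epochs,batch_size,learning_rate,warmup_steps,weight_decay,grad_accumulation,eval_every_steps
#'   Optimization settings.
#' @param max_length Token length pairs are padded/truncated to (default 128).
#' @param seed Integer seed for initialization and batch shuffling.
#' @param preset `"paper"` (small-GPT-2-like: 12 layers, 12 heads, width
#'   768) or `"tiny"` (2 layers, 4 heads, width 64; warmup 20 steps).
#' @return A list of class `clm_config`.
#' @export
clm_config <- function(preset = c("tiny", "paper"), context_window = 1024,
                       n_layers = NULL, n_heads = NULL, d_model = NULL,
                       epochs = 10, batch_size = 64, learning_rate = 5e-4,
                       warmup_steps = NULL, weight_decay = 0.1,
                       grad_accumulation = 8, eval_every_steps = 5000,
                       max_length = 128, seed = 1) {
  preset <- match.arg(preset)
  def <- if (preset == "paper") list(n_layers = 12, n_heads = 12,
                                     d_model = 768, warmup = 1000)
         else list(n_layers = 2, n_heads = 4, d_model = 64, warmup = 20)
  cfg <- list(
    context_window = check_count(context_window),
    n_layers = check_count(n_layers %||% def$n_layers),
    n_heads = check_count(n_heads %||% def$n_heads),
    d_model = check_count(d_model %||% def$d_model),
    epochs = check_count(epochs),
    batch_size = check_count(batch_size),
    learning_rate = learning_rate,
    warmup_steps = check_count(warmup_steps %||% def$warmup, min = 0),
    weight_decay = weight_decay,
    grad_accumulation = check_count(grad_accumulation),
    eval_every_steps = check_count(eval_every_steps),
    max_length = check_count(max_length),
    seed = seed
  )
  if (cfg$learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (cfg$d_model %% cfg$n_heads != 0) {
    stop("`d_model` must be divisible by `n_heads`", call. = FALSE)
  }
  structure(cfg, class = "clm_config")
}

#' Generation configuration
#'
#' @param max_new_tokens Sampling budget per prompt (default 100).
#' @param temperature Softmax temperature (> 0; default 1). Values below
#'   1e-3 are treated as greedy decoding.
#' @param early_stopping Stop at the `<eos>` token (default TRUE).
#' @param seed Integer seed for the sampling stream.
#' @return A list of class `generation_config`.
#' @export
generation_config <- function(max_new_tokens = 100, temperature = 1,
                              early_stopping = TRUE, seed = 1) {
  check_count(max_new_tokens)
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("`temperature` must be > 0", call. = FALSE)
  }
  structure(list(max_new_tokens = as.integer(max_new_tokens),
                 temperature = temperature,
                 early_stopping = isTRUE(early_stopping), seed = seed),
            class = "generation_config")
}

encode_corpus <- function(pairs, tokenizer, max_length) {
  n <- nrow(pairs)
  out <- matrix(special_id(tokenizer, "<pad>"), n, max_length)
  truncated <- logical(n)
  for (i in seq_len(n)) {
    e <- encode_for_clm(pairs$protein_seq[i], pairs$smiles[i], tokenizer,
                        max_length = max_length)
    out[i, ] <- e
    truncated[i] <- attr(e, "truncated")
  }
  attr(out, "truncated") <- truncated
  out
}

#' Train the chemical language model
#'
#' Autoregressive next-token training (shifted labels, pad positions masked
#' out of the loss) on protein-conditioned pairs laid out as
#' `<bos> protein smiles <eos>`. Optimization is AdamW with decoupled weight
#' decay, gradient accumulation, and a cosine learning-rate schedule with
#' linear warmup. Validation loss is computed every `eval_every_steps`
#' optimizer steps and at the end of training.
#'
#' @param train,val Pairs tibbles (see [read_pairs()]); `val` may be `NULL`.
#' @param tokenizer A [train_bpe()] tokenizer covering the training corpus.
#' @param config A [clm_config()].
#' @return An object of class `clm_model`: parameters, config, and a
#'   training log tibble (`step`, `epoch`, `lr`, `train_loss`, `val_loss`).
#' @export
train_clm <- function(train, val = NULL, tokenizer, config = clm_config()) {
  stopifnot(is.data.frame(train), inherits(tokenizer, "bpe_tokenizer"),
            inherits(config, "clm_config"))
  if (nrow(train) == 0) stop("training dataset is empty", call. = FALSE)
  pad <- special_id(tokenizer, "<pad>")
  X <- encode_corpus(train, tokenizer, config$max_length)
  Xval <- if (!is.null(val) && nrow(val) > 0) {
    encode_corpus(val, tokenizer, config$max_length)
  } else NULL
  V <- length(tokenizer$vocab)

  shift_targets <- function(M) {
    tgt <- cbind(M[, -1, drop = FALSE], pad)
    tgt[tgt == pad] <- 0L
    tgt
  }
  val_loss <- function(params) {
    if (is.null(Xval)) return(NA_real_)
    bs <- min(64, nrow(Xval))
    losses <- c(); ns <- c()
    for (s in split(seq_len(nrow(Xval)), ceiling(seq_len(nrow(Xval)) / bs))) {
      M <- Xval[s, , drop = FALSE]
      losses <- c(losses, clm_loss_and_grad(params, M, shift_targets(M),
                                            config, want_grad = FALSE)$loss)
      ns <- c(ns, length(s))
    }
    sum(losses * ns) / sum(ns)
  }

  n <- nrow(X)
  micro <- max(1, config$batch_size %/% config$grad_accumulation)
  steps_per_epoch <- max(1, ceiling(n / (micro * config$grad_accumulation)))
  total_steps <- steps_per_epoch * config$epochs

  log <- list()
  with_seed(config$seed, {
    params <- init_clm_params(V, config)
    opt <- adamw_init(params)
    step <- 0
    for (epoch in seq_len(config$epochs)) {
      order <- sample.int(n)
      i <- 1
      while (i <= n) {
        acc_grad <- NULL; acc_loss <- 0; k <- 0
        while (k < config$grad_accumulation && i <= n) {
          take <- order[i:min(i + micro - 1, n)]
          i <- i + micro
          M <- X[take, , drop = FALSE]
          fb <- clm_loss_and_grad(params, M, shift_targets(M), config)
          acc_grad <- if (is.null(acc_grad)) fb$grad else
            tree_map2(`+`, acc_grad, fb$grad)
          acc_loss <- acc_loss + fb$loss
          k <- k + 1
        }
        grads <- tree_map(function(gm) gm / k, acc_grad)
        step <- step + 1
        lr <- config$learning_rate *
          lr_multiplier(step, config$warmup_steps, total_steps)
        res <- adamw_step(params, grads, opt, lr,
                          weight_decay = config$weight_decay)
        params <- res$params; opt <- res$state
        vl <- if (step %% config$eval_every_steps == 0) val_loss(params) else NA_real_
        log[[length(log) + 1]] <- tibble::tibble(
          step = step, epoch = epoch, lr = lr,
          train_loss = acc_loss / k, val_loss = vl)
      }
    }
    final_val <- val_loss(params)
    log[[length(log) + 1]] <- tibble::tibble(
      step = step, epoch = config$epochs, lr = 0,
      train_loss = NA_real_, val_loss = final_val)
    structure(list(params = params, config = config,
                   vocab_size = V,
                   log = dplyr::bind_rows(log)),
              class = "clm_model")
  })
}

#' @export
print.clm_model <- function(x, ...) {
  n_par <- sum(unlist(tree_map(length, x$params)))
  cat("<clm_model>", x$config$n_layers, "layers, d_model",
      x$config$d_model, ",", format(n_par, big.mark = ","), "parameters\n")
  tl <- x$log$train_loss[!is.na(x$log$train_loss)]
  if (length(tl)) cat("  final train loss:", round(utils::tail(tl, 1), 4), "\n")
  invisible(x)
}

#' Sample a raw continuation for a protein prompt
#'
#' Encodes the prompt `<bos> protein-tokens`, samples autoregressively at
#' the configured temperature (greedy when temperature is below 1e-3),
#' stops at `<eos>` when early stopping is on, and decodes only the newly
#' generated tokens. The returned string is the raw model output for the
#' SMILES field; it may contain a trailing word boundary which is trimmed.
#'
#' @param model A trained [train_clm()] model.
#' @param tokenizer The tokenizer the model was trained with.
#' @param protein Amino-acid string to condition on.
#' @param gcfg A [generation_config()].
#' @return Character scalar: the raw generated string (possibly invalid
#'   SMILES; see [trim_to_valid()]).
#' @export
generate_raw <- function(model, tokenizer, protein,
                         gcfg = generation_config()) {
  stopifnot(inherits(model, "clm_model"), inherits(tokenizer, "bpe_tokenizer"))
  prompt <- encode_for_clm(protein, "", tokenizer,
                           max_length = model$config$context_window)
  if (length(prompt) + 1 > model$config$context_window) {
    stop("prompt alone exceeds the model context window", call. = FALSE)
  }
  eos <- special_id(tokenizer, "<eos>")
  ids <- as.integer(prompt)
  new_ids <- integer(0)
  with_seed(gcfg$seed, {
    for (t in seq_len(gcfg$max_new_tokens)) {
      if (length(ids) >= model$config$context_window) break
      logits <- clm_logits_last(model$params, ids, model$config)
      nxt <- if (gcfg$temperature < 1e-3) {
        which.max(logits)
      } else {
        z <- logits / gcfg$temperature
        p <- exp(z - max(z)); p <- p / sum(p)
        sample.int(length(p), 1, prob = p)
      }
      if (gcfg$early_stopping && nxt == eos) break
      ids <- c(ids, nxt)
      new_ids <- c(new_ids, nxt)
    }
  })
  if (length(new_ids) == 0) return("")
  bpe_decode(tokenizer, new_ids)
}

#' Trim a raw generation to a valid SMILES
#'
#' Iteratively shortens the string from the end, removing one character at a
#' time, until the validity oracle (a sanitizing SMILES parser) accepts it
#' or the string becomes empty. Already-valid inputs are returned unchanged.
#' Equivalently, the result is the longest valid prefix of the input (the
#' empty string when no prefix parses); all candidate prefixes are checked
#' in a single batched oracle call.
#'
#' @param s Character vector of raw strings.
#' @return Character vector: valid SMILES or `""`, one per input.
#' @export
#' @examples \dontrun{
#' trim_to_valid(c("CCO", "CCO(", "(((("))  # "CCO" "CCO" ""
#' }
trim_to_valid <- function(s) {
  stopifnot(is.character(s))
  s[is.na(s)] <- ""
  # all prefixes of all inputs, checked in one oracle batch
  reps <- nchar(s)
  if (sum(reps) == 0) return(rep("", length(s)))
  grp <- rep(seq_along(s), reps)
  pref <- unlist(lapply(s[reps > 0], function(x) substring(x, 1, nchar(x):1)))
  ok <- smiles_is_valid(pref)
  out <- rep("", length(s))
  for (i in which(reps > 0)) {
    sel <- which(grp == i)
    hit <- sel[ok[sel]]
    if (length(hit)) out[i] <- pref[hit[1]]
  }
  out
}

# Generated text may contain a word boundary (the training layout separates
# protein and SMILES by whitespace); a SMILES cannot contain spaces, so
# everything from the first whitespace onward is dropped before trimming.
strip_after_whitespace <- function(s) {
  sub("[[:space:]].*$", "", s)
}

#' Generate and repair a batch of molecules
#'
#' Runs [generate_raw()] for each protein (one seed per item, derived from
#' the configuration seed so items are independent and the batch is
#' reproducible), normalizes each raw string by dropping anything after the
#' first whitespace, then applies [trim_to_valid()]. Input order is
#' preserved; a failed generation for one protein becomes an empty result
#' rather than aborting the batch.
#'
#' @param model,tokenizer,gcfg As in [generate_raw()].
#' @param proteins Character vector of amino-acid sequences.
#' @return A tibble with columns `protein_seq`, `raw`, `trimmed`, plus the
#'   pre-trim validity fraction as attribute `pretrim_validity`.
#' @export
generate_batch <- function(model, tokenizer, proteins,
                           gcfg = generation_config()) {
  stopifnot(is.character(proteins))
  if (length(proteins) == 0) {
    return(tibble::tibble(protein_seq = character(0), raw = character(0),
                          trimmed = character(0)))
  }
  raw <- vapply(seq_along(proteins), function(i) {
    g <- gcfg; g$seed <- gcfg$seed + i - 1
    tryCatch(generate_raw(model, tokenizer, proteins[i], g),
             error = function(e) "")
  }, character(1))
  norm <- strip_after_whitespace(raw)
  trimmed <- trim_to_valid(norm)
  out <- tibble::tibble(protein_seq = proteins, raw = raw, trimmed = trimmed)
  nonempty <- nzchar(norm)
  attr(out, "pretrim_validity") <-
    if (any(nonempty)) mean(smiles_is_valid(norm[nonempty])) else 0
  out
}

#' Save / load a trained language model
#'
#' The checkpoint is a single JSON file holding the configuration and all
#' weight matrices.
#'
#' @param model A `clm_model`.
#' @param path Checkpoint path (JSON).
#' @return `path` (save) or the restored `clm_model` (load).
#' @export
save_clm <- function(model, path) {
  jsonlite::write_json(list(
    type = "clm_model", config = unclass(model$config),
    vocab_size = model$vocab_size,
    params = pack_params(model$params), log = as.list(model$log)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_clm
#' @export
load_clm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(x$type, "clm_model")) {
    stop(path, " is not a clm_model checkpoint", call. = FALSE)
  }
  cfg <- structure(as.list(x$config), class = "clm_config")
  structure(list(params = unpack_params(x$params), config = cfg,
                 vocab_size = x$vocab_size,
                 log = tibble::as_tibble(x$log)),
            class = "clm_model")
}

# Flatten a parameter tree for JSON (matrices carry their dim).
pack_params <- function(p) {
  if (is.matrix(p)) return(list(.dim = dim(p), .data = as.numeric(p)))
  if (is.list(p)) return(lapply(p, pack_params))
  as.numeric(p)
}

unpack_params <- function(p) {
  if (is.list(p) && !is.null(p$.dim)) {
    return(matrix(as.numeric(p$.data), p$.dim[1], p$.dim[2]))
  }
  if (is.list(p)) return(lapply(p, unpack_params))
  as.numeric(p)
}
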