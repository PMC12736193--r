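# Regression convolutional network: pKi from character-encoded pairs.

#' RCNN configuration
#'
#' Architecture and training hyperparameters of the affinity regressor:
#' an 8-dimensional embedding, six 1D convolution blocks (kernel 8, filters
#' 32..64, batch normalization, leaky-ReLU 0.01, max-pool 2), dense layers
#' of 512 and 10 units, a linear scalar output, RMSprop at learning rate
#' 0.001. The full-scale recipe trains for 200 epochs; tests use far fewer.
#'
#' @param embedding_dim Embedding width (default 8).
#' @param n_conv_layers Number of conv blocks (default 6).
#' @param kernel_size Convolution kernel (default 8).
#' @param filters Integer vector of per-block filter counts, all within
#'   \[32, 64\] (default `c(32, 32, 32, 64, 64, 64)`).
#' @param pool_size Max-pool width (default 2).
#' @param leaky_slope Negative-side slope of the activation (default 0.01).
#' @param dense_sizes Sizes of the two dense layers (default `c(512, 10)`).
#' @param learning_rate RMSprop learning rate (default 0.001).
#' @param epochs Training epochs (default 200).
#' @param loss `"mse"` or `"mae"`.
#' @param batch_size Minibatch size (default 32).
#' @param input_length Encoded sequence length (default 800).
#' @param seed Integer seed for initialization and shuffling.
#' @return A list of class `rcnn_config`.
#' @export
rcnn_config <- function(embedding_dim = 8, n_conv_layers = 6, kernel_size = 8,
                        filters = c(32, 32, 32, 64, 64, 64), pool_size = 2,
                        leaky_slope = 0.01, dense_sizes = c(512, 10),
                        learning_rate = 0.001, epochs = 200,
                        loss = c("mse", "mae"), batch_size = 32,
                        input_length = 800, seed = 1) {
  loss <- match.arg(loss)
  if (length(filters) != n_conv_layers) {
    stop("`filters` must have length `n_conv_layers`", call. = FALSE)
  }
  if (any(filters < 32 | filters > 64)) {
    stop("every filter count must lie in [32, 64]", call. = FALSE)
  }
  structure(list(embedding_dim = check_count(embedding_dim),
                 n_conv_layers = check_count(n_conv_layers),
                 kernel_size = check_count(kernel_size),
                 filters = as.integer(filters),
                 pool_size = check_count(pool_size),
                 leaky_slope = leaky_slope,
                 dense_sizes = as.integer(dense_sizes),
                 learning_rate = learning_rate,
                 epochs = check_count(epochs), loss = loss,
                 batch_size = check_count(batch_size),
                 input_length = check_count(input_length), seed = seed),
            class = "rcnn_config")
}

#' Build an untrained RCNN
#'
#' Instantiates parameters and batch-norm state for a given character
#' vocabulary size (codes 0..`vocab_size - 1`, 0 being pad).
#'
#' @param cfg An [rcnn_config()].
#' @param vocab_size Number of distinct integer codes including pad.
#' @return An object of class `rcnn_model` (untrained).
#' @export
build_rcnn <- function(cfg = rcnn_config(), vocab_size) {
  stopifnot(inherits(cfg, "rcnn_config"))
  check_count(vocab_size, "vocab_size", min = 2)
  params <- with_seed(cfg$seed, init_rcnn_params(cfg, vocab_size))
  bn_state <- lapply(cfg$filters, function(f) {
    list(mean = rep(0, f), var = rep(1, f))
  })
  structure(list(params = params, bn_state = bn_state, config = cfg,
                 vocab_size = vocab_size, history = NULL),
            class = "rcnn_model")
}

#' @export
print.rcnn_model <- function(x, ...) {
  n_par <- sum(unlist(tree_map(length, x$params)))
  cat("<rcnn_model>", x$config$n_conv_layers, "conv blocks,",
      format(n_par, big.mark = ","), "parameters,",
      if (is.null(x$history)) "untrained" else
        paste0("trained ", max(x$history$epoch), " epochs"), "\n")
  invisible(x)
}

#' Predict pKi for encoded pairs
#'
#' @param model A trained (or untrained) `rcnn_model`.
#' @param encoded Integer vector of length `input_length`, or a matrix with
#'   one row per pair (as from [encode_for_rcnn()]).
#' @param batch_size Forward-pass batch size.
#' @return Numeric vector of predicted pKi, one per row. Predictions use the
#'   batch-norm running statistics, so they do not depend on batch
#'   composition.
#' @export
predict_pki <- function(model, encoded, batch_size = 128) {
  stopifnot(inherits(model, "rcnn_model"))
  if (is.vector(encoded)) encoded <- matrix(encoded, nrow = 1)
  if (ncol(encoded) != model$config$input_length) {
    stop("encoded input must have length ", model$config$input_length,
         ", got ", ncol(encoded), call. = FALSE)
  }
  n <- nrow(encoded)
  out <- numeric(n)
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fw <- rcnn_forward(model$params, encoded[s, , drop = FALSE],
                       model$config, model$bn_state, training = FALSE)
    out[s] <- fw$pred
  }
  out
}

#' Regression evaluation metrics
#'
#' Pearson correlation, coefficient of determination (R^2 = 1 -
#' SS_res/SS_tot), and root mean squared error.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return A one-row tibble with `pearson_r`, `r_squared`, `rmse`, `n`.
#' @export
#' @examples
#' evaluate_regression(c(0, 1, 2, 3), c(0.5, 1.5, 2.5, 3.5))
evaluate_regression <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (length(y_true) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(y_true) == 0) {
    stop("`y_true` is constant; correlation is undefined", call. = FALSE)
  }
  res <- y_true - y_pred
  ss_res <- sum(res^2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  tibble::tibble(
    # a constant prediction has no defined correlation; report NA quietly
    pearson_r = if (stats::sd(y_pred) == 0) NA_real_ else
      stats::cor(y_true, y_pred),
    r_squared = 1 - ss_res / ss_tot,
    rmse = sqrt(mean(res^2)),
    n = length(y_true)
  )
}

rcnn_loss_grad <- function(pred, y, loss) {
  n <- length(y)
  if (loss == "mse") {
    list(loss = mean((pred - y)^2), dpred = 2 * (pred - y) / n)
  } else {
    list(loss = mean(abs(pred - y)), dpred = sign(pred - y) / n)
  }
}

#' Train the RCNN
#'
#' Minimizes the configured loss with RMSprop. After every epoch the model
#' is evaluated (loss, RMSE, R^2, Pearson R) on the training set and, when
#' given, the validation set; the per-epoch history makes the standard
#' "after 1 epoch" vs "after final epoch" comparison available directly.
#'
#' @param model An `rcnn_model` from [build_rcnn()].
#' @param train_ids,val_ids Integer matrices from [encode_for_rcnn()]
#'   (`val_ids` may be `NULL`).
#' @param train_y,val_y Numeric pKi targets.
#' @param cfg Optional [rcnn_config()] override; defaults to the model's.
#' @param quiet Suppress the per-epoch progress message.
#' @return The trained `rcnn_model` with a `history` tibble (`epoch`,
#'   `train_loss`, `train_rmse`, `train_r2`, `train_r`, `val_loss`,
#'   `val_rmse`, `val_r2`, `val_r`).
#' @export
train_rcnn <- function(model, train_ids, train_y, val_ids = NULL,
                       val_y = NULL, cfg = model$config, quiet = TRUE) {
  stopifnot(inherits(model, "rcnn_model"), is.matrix(train_ids))
  if (nrow(train_ids) == 0) stop("training set is empty", call. = FALSE)
  if (nrow(train_ids) != length(train_y)) {
    stop("`train_ids` rows and `train_y` length differ", call. = FALSE)
  }
  params <- model$params
  # Center the linear output on the training-target mean before the first
  # step: the network then only has to learn deviations from the mean, which
  # removes a long slow drift of the scalar offset under RMSprop's
  # magnitude-normalized updates.
  if (is.null(model$history) && identical(params$b3, 0)) {
    params$b3 <- mean(train_y)
  }
  bn_state <- model$bn_state
  opt <- rmsprop_init(params)
  n <- nrow(train_ids)
  history <- list()

  eval_split <- function(ids, y) {
    m <- model; m$params <- params; m$bn_state <- bn_state
    pred <- predict_pki(m, ids)
    lg <- rcnn_loss_grad(pred, y, cfg$loss)
    ev <- evaluate_regression(y, pred)
    c(loss = lg$loss, rmse = ev$rmse, r2 = ev$r_squared, r = ev$pearson_r)
  }

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      order <- sample.int(n)
      for (s in split(order, ceiling(seq_along(order) / cfg$batch_size))) {
        fw <- rcnn_forward(params, train_ids[s, , drop = FALSE], cfg,
                           bn_state, training = TRUE)
        bn_state <- fw$bn_state
        lg <- rcnn_loss_grad(fw$pred, train_y[s], cfg$loss)
        grads <- rcnn_backward(params, cfg, fw, lg$dpred)
        res <- rmsprop_step(params, grads, opt, cfg$learning_rate)
        params <- res$params; opt <- res$state
      }
      tr <- eval_split(train_ids, train_y)
      va <- if (!is.null(val_ids)) eval_split(val_ids, val_y) else
        c(loss = NA, rmse = NA, r2 = NA, r = NA)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tr["loss"], train_rmse = tr["rmse"],
        train_r2 = tr["r2"], train_r = tr["r"], val_loss = va["loss"],
        val_rmse = va["rmse"], val_r2 = va["r2"], val_r = va["r"])
      if (!quiet) {
        message(sprintf("epoch %d: train %s %.4f val %s %.4f", epoch,
                        cfg$loss, tr["loss"], cfg$loss, va["loss"]))
      }
    }
  })
  model$params <- params
  model$bn_state <- bn_state
  model$config <- cfg
  model$history <- dplyr::bind_rows(history)
  model
}

#' Repeat the training experiment over randomized partitions
#'
#' For each seed: re-split the dataset 70/30, train a fresh model, and
#' record loss, RMSE, R^2 and Pearson R on both sets after the first and
#' the final epoch. Returns the per-repeat table and the mean (SD) summary
#' in the conventional layout.
#'
#' @param pairs A pairs tibble.
#' @param vocab A [build_char_vocab()] vocabulary.
#' @param cfg An [rcnn_config()].
#' @param seeds Integer vector, one seed per repeat (default `1:5`).
#' @param train_fraction Train share of each split (default 0.7).
#' @return A list of class `rcnn_repeat`: `runs` (per-repeat tibble) and
#'   `summary` (per-metric mean and SD over repeats).
#' @export
repeat_experiment <- function(pairs, vocab, cfg = rcnn_config(),
                              seeds = 1:5, train_fraction = 0.7) {
  stopifnot(is.data.frame(pairs), length(seeds) >= 1)
  runs <- purrr::map_dfr(seq_along(seeds), function(i) {
    seed <- seeds[i]
    sp <- split_dataset(pairs, train_fraction, seed = seed)
    Xtr <- encode_for_rcnn(sp$train$protein_seq, sp$train$smiles, vocab,
                           length_out = cfg$input_length)
    Xva <- encode_for_rcnn(sp$val$protein_seq, sp$val$smiles, vocab,
                           length_out = cfg$input_length)
    cfg_i <- cfg; cfg_i$seed <- seed
    model <- build_rcnn(cfg_i, vocab_size = length(vocab) + 1)
    model <- train_rcnn(model, Xtr, sp$train$pki, Xva, sp$val$pki, cfg_i)
    h1 <- model$history[1, ]
    hF <- model$history[nrow(model$history), ]
    tibble::tibble(
      repeat_id = i, seed = seed,
      train_r = hF$train_r, val_r = hF$val_r,
      train_rmse = hF$train_rmse, val_rmse = hF$val_rmse,
      train_rmse_ep1 = h1$train_rmse, val_rmse_ep1 = h1$val_rmse,
      train_r2 = hF$train_r2, val_r2 = hF$val_r2,
      train_r2_ep1 = h1$train_r2, val_r2_ep1 = h1$val_r2,
      train_loss = hF$train_loss, val_loss = hF$val_loss,
      train_loss_ep1 = h1$train_loss, val_loss_ep1 = h1$val_loss)
  })
  metrics <- setdiff(names(runs), c("repeat_id", "seed"))
  summary <- tidyr::pivot_longer(runs, dplyr::all_of(metrics),
                                 names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n_repeats = dplyr::n(), .groups = "drop")
  structure(list(runs = runs, summary = summary), class = "rcnn_repeat")
}

#' @export
print.rcnn_repeat <- function(x, ...) {
  cat("<rcnn_repeat>", nrow(x$runs), "repeats\n")
  print(x$summary)
  invisible(x)
}

#' Save / load a trained RCNN
#'
#' @param model An `rcnn_model`.
#' @param path Checkpoint path (JSON).
#' @return `path` (save) or the restored model (load).
#' @export
save_rcnn <- function(model, path) {
  jsonlite::write_json(list(
    type = "rcnn_model", config = unclass(model$config),
    vocab_size = model$vocab_size,
    params = pack_params(model$params),
    bn_state = model$bn_state,
    history = if (is.null(model$history)) NULL else as.list(model$history)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_rcnn
#' @export
load_rcnn <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(x$type, "rcnn_model")) {
    stop(path, " is not an rcnn_model checkpoint", call. = FALSE)
  }
  cfg <- structure(as.list(x$config), class = "rcnn_config")
  cfg$filters <- as.integer(unlist(cfg$filters))
  cfg$dense_sizes <- as.integer(unlist(cfg$dense_sizes))
  structure(list(params = unpack_params(x$params),
                 bn_state = lapply(x$bn_state, function(s) {
                   list(mean = as.numeric(s$mean), var = as.numeric(s$var))
                 }),
                 config = cfg, vocab_size = x$vocab_size,
                 history = if (is.null(x$history)) NULL else
                   tibble::as_tibble(x$history)),
            class = "rcnn_model")
}
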