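# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small noise-free corpus shared by data/tokenizer tests.
toy_corpus <- function() {
  cached("toy_corpus", function() make_paired_corpus(50, seed = 7))
}

toy_tokenizer <- function() {
  cached("toy_tokenizer", function() {
    pairs <- toy_corpus()
    train_bpe(paste(pairs$protein_seq, pairs$smiles), vocab_size = 300)
  })
}

# One pair memorized by a tiny language model, plus an RCNN overfit to five
# pairs: the smallest trained models that exercise the full pipeline.
tiny_models <- function() {
  cached("tiny_models", function() {
    pair <- make_paired_corpus(1, seed = 3)
    train <- pair[rep(1, 32), ]
    tok <- train_bpe(paste(train$protein_seq, train$smiles), vocab_size = 200)
    cfg <- clm_config(preset = "tiny", epochs = 30, batch_size = 8,
                      grad_accumulation = 1, learning_rate = 1e-3,
                      warmup_steps = 10, max_length = 64,
                      context_window = 128, eval_every_steps = 1000, seed = 1)
    clm <- train_clm(train, NULL, tok, cfg)

    five <- make_paired_corpus(5, seed = 21)
    vocab <- build_char_vocab(five)
    rcfg <- rcnn_config(n_conv_layers = 3, filters = c(32, 32, 64),
                        input_length = 128, dense_sizes = c(64, 10),
                        epochs = 250, batch_size = 5, seed = 2)
    X <- encode_for_rcnn(five$protein_seq, five$smiles, vocab,
                         length_out = 128)
    rcnn <- build_rcnn(rcfg, vocab_size = length(vocab) + 1)
    rcnn <- train_rcnn(rcnn, X, five$pki)
    list(pair = pair, tok = tok, clm = clm,
         five = five, vocab = vocab, rcnn = rcnn)
  })
}

# Write a small delimited file and return its path.
write_temp_table <- function(df, ext = "csv") {
  path <- tempfile(fileext = paste0(".", ext))
  readr::write_delim(df, path, delim = if (ext == "tsv") "\t" else ",")
  path
}
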