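# Byte-pair-encoding tokenizer, trained from scratch.
#
# Classic BPE over whitespace pre-tokenized words: each word is split into
# characters, the final character carries an end-of-word marker ("</w>"),
# and the most frequent adjacent symbol pair is merged iteratively until the
# vocabulary budget is reached or no pair attains the minimum frequency.
# Whitespace pre-tokenization guarantees that protein and SMILES fields
# never merge across their separator. Ties between equally frequent pairs
# break lexicographically, which makes training deterministic.

EOW <- "</w>"
SPECIAL_TOKENS <- c("<bos>", "<eos>", "<pad>", "<unk>")

word_to_symbols <- function(word) {
  syms <- strsplit(word, "", fixed = FALSE)[[1]]
  syms[length(syms)] <- paste0(syms[length(syms)], EOW)
  syms
}

#' Train a byte-pair-encoding tokenizer
#'
#' @param lines Character vector: the training corpus, one record per line.
#'   Lines are whitespace pre-tokenized into words.
#' @param vocab_size Maximum number of token types including the four special
#'   tokens (default 30000).
#' @param min_frequency Minimum pair frequency required to perform a merge
#'   (default 2).
#' @param max_length Default sequence length for [encode_for_clm()]
#'   (default 128); stored on the tokenizer.
#' @return An object of class `bpe_tokenizer` with the vocabulary (token ->
#'   1-based id; `<bos>`, `<eos>`, `<pad>`, `<unk>` occupy ids 1-4), the
#'   ordered merge list, and the configuration.
#' @export
train_bpe <- function(lines, vocab_size = 30000, min_frequency = 2,
                      max_length = 128) {
  lines <- lines[!is.na(lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("training corpus is empty", call. = FALSE)
  check_count(vocab_size, "vocab_size", min = 8)
  check_count(min_frequency, "min_frequency")

  words_all <- unlist(strsplit(trimws(lines), "[[:space:]]+"))
  wtab <- table(words_all)
  words <- lapply(names(wtab), word_to_symbols)
  freq <- as.numeric(wtab)

  base_syms <- sort(unique(unlist(words)))
  vocab <- c(SPECIAL_TOKENS, base_syms)
  merges <- character(0)

  repeat {
    if (length(vocab) >= vocab_size) break
    # pair counts over adjacent symbols, weighted by word frequency
    pair_lists <- lapply(words, function(s) {
      if (length(s) < 2) character(0) else paste(s[-length(s)], s[-1], sep = "\u0001")
    })
    lens <- lengths(pair_lists)
    if (all(lens == 0)) break
    counts <- rowsum(rep(freq, lens), unlist(pair_lists))
    best_n <- max(counts)
    if (best_n < min_frequency) break
    cand <- sort(rownames(counts)[counts == best_n])[1]
    pair <- strsplit(cand, "\u0001", fixed = TRUE)[[1]]
    merged <- paste0(pair[1], pair[2])
    merges <- c(merges, cand)
    vocab <- c(vocab, merged)
    words <- lapply(words, merge_pair_in_word, a = pair[1], b = pair[2],
                    ab = merged)
  }

  structure(list(
    vocab = stats::setNames(seq_along(vocab), vocab),
    merges = merges,
    vocab_size = vocab_size,
    min_frequency = min_frequency,
    max_length = max_length
  ), class = "bpe_tokenizer")
}

merge_pair_in_word <- function(s, a, b, ab) {
  if (length(s) < 2) return(s)
  hit <- which(s[-length(s)] == a & s[-1] == b)
  if (length(hit) == 0) return(s)
  # left-to-right, skipping overlaps (e.g. "aaa" with pair (a,a) -> "aa","a")
  keep <- hit[1]
  for (h in hit[-1]) if (h > keep[length(keep)] + 1) keep <- c(keep, h)
  s[keep] <- ab
  s[-(keep + 1)]
}

#' @export
print.bpe_tokenizer <- function(x, ...) {
  cat("<bpe_tokenizer>", length(x$vocab), "token types,",
      length(x$merges), "merges, max_length", x$max_length, "\n")
  invisible(x)
}

special_id <- function(tokenizer, token) {
  unname(tokenizer$vocab[[token]])
}

# Encode one word by replaying the learned merges in training order.
encode_word <- function(tokenizer, word) {
  s <- word_to_symbols(word)
  ranks <- stats::setNames(seq_along(tokenizer$merges), tokenizer$merges)
  repeat {
    if (length(s) < 2) break
    pairs <- paste(s[-length(s)], s[-1], sep = "\u0001")
    r <- ranks[pairs]
    if (all(is.na(r))) break
    i <- which.min(ifelse(is.na(r), Inf, r))
    s <- c(s[seq_len(i - 1)], paste0(s[i], s[i + 1]),
           if (i + 2 <= length(s)) s[(i + 2):length(s)])
  }
  ids <- tokenizer$vocab[s]
  ids[is.na(ids)] <- special_id(tokenizer, "<unk>")
  unname(ids)
}

#' Encode text with a trained BPE tokenizer
#'
#' @param tokenizer A `bpe_tokenizer`.
#' @param text Character scalar; whitespace-separated words are encoded
#'   independently and concatenated. Symbols never seen in training map to
#'   `<unk>`.
#' @return Integer vector of 1-based token ids (no special tokens added).
#' @export
bpe_encode <- function(tokenizer, text) {
  stopifnot(inherits(tokenizer, "bpe_tokenizer"), is.character(text),
            length(text) == 1)
  words <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  words <- words[nzchar(words)]
  if (length(words) == 0) return(integer(0))
  unlist(lapply(words, function(w) encode_word(tokenizer, w)))
}

#' Decode token ids back to text
#'
#' Inverse of [bpe_encode()] for corpus-seen text: symbols are concatenated
#' and end-of-word markers become single spaces.
#'
#' @param tokenizer A `bpe_tokenizer`.
#' @param ids Integer vector of token ids.
#' @param skip_special Drop `<bos>`/`<eos>`/`<pad>` tokens (default TRUE).
#' @return Character scalar.
#' @export
bpe_decode <- function(tokenizer, ids, skip_special = TRUE) {
  stopifnot(inherits(tokenizer, "bpe_tokenizer"))
  toks <- names(tokenizer$vocab)[ids]
  if (skip_special) toks <- toks[!toks %in% c("<bos>", "<eos>", "<pad>")]
  out <- gsub(EOW, " ", paste(toks, collapse = ""), fixed = TRUE)
  trimws(out)
}

#' Serialize a BPE tokenizer to JSON
#'
#' @param tokenizer A `bpe_tokenizer`.
#' @param path Output path for the JSON artifact.
#' @return `path`, invisibly.
#' @export
save_bpe <- function(tokenizer, path) {
  jsonlite::write_json(list(
    type = "bpe_tokenizer",
    vocab = as.list(tokenizer$vocab),
    merges = tokenizer$merges,
    vocab_size = tokenizer$vocab_size,
    min_frequency = tokenizer$min_frequency,
    max_length = tokenizer$max_length
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a BPE tokenizer from JSON
#'
#' @param path Path written by [save_bpe()].
#' @return A `bpe_tokenizer`.
#' @export
load_bpe <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$type, "bpe_tokenizer")) {
    stop(path, " is not a serialized bpe_tokenizer", call. = FALSE)
  }
  structure(list(
    vocab = stats::setNames(as.integer(unlist(x$vocab)), names(x$vocab)),
    merges = as.character(unlist(x$merges %||% list())),
    vocab_size = x$vocab_size,
    min_frequency = x$min_frequency,
    max_length = x$max_length
  ), class = "bpe_tokenizer")
}
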