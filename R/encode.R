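# Sequence encoders for the two models: BPE token ids for the language
# model, character-integer codes for the regression network.

#' Encode a protein/SMILES pair for the language model
#'
#' Layout: `<bos>` protein-tokens smiles-tokens `<eos>`, truncated or padded
#' with `<pad>` to `max_length`. The whitespace separator between the two
#' fields is carried by the protein's end-of-word token, so an autoregressive
#' model prompted with the protein continues with a fresh word — the SMILES.
#' With an empty `smiles`, the unpadded generation prompt
#' (`<bos>` protein-tokens) is returned instead.
#'
#' @param protein Non-empty amino-acid string.
#' @param smiles SMILES string, or `""` to build a generation prompt.
#' @param tokenizer A trained [train_bpe()] tokenizer.
#' @param max_length Output length for full pairs (default: the tokenizer's
#'   `max_length`, 128).
#' @return Integer vector of token ids with attribute `truncated` (logical:
#'   did the pair exceed `max_length` before padding?).
#' @export
encode_for_clm <- function(protein, smiles = "", tokenizer,
                           max_length = tokenizer$max_length) {
  stopifnot(is.character(protein), length(protein) == 1, nzchar(protein),
            inherits(tokenizer, "bpe_tokenizer"))
  bos <- special_id(tokenizer, "<bos>")
  eos <- special_id(tokenizer, "<eos>")
  pad <- special_id(tokenizer, "<pad>")
  prot_ids <- bpe_encode(tokenizer, protein)
  if (!nzchar(smiles)) {
    ids <- c(bos, prot_ids)
    attr(ids, "truncated") <- length(ids) > max_length
    return(ids)
  }
  ids <- c(bos, prot_ids, bpe_encode(tokenizer, smiles), eos)
  truncated <- length(ids) > max_length
  if (truncated) ids <- ids[seq_len(max_length)]
  if (length(ids) < max_length) ids <- c(ids, rep(pad, max_length - length(ids)))
  attr(ids, "truncated") <- truncated
  ids
}

#' Build a character vocabulary from a pairs dataset
#'
#' Assigns integer codes 1..K to the distinct characters appearing in the
#' concatenated protein + SMILES strings, in first-seen order over rows.
#' Code 0 is reserved for padding and never collides with a corpus
#' character. At most 70 distinct characters are allowed.
#'
#' @param pairs A non-empty pairs tibble with `smiles` and `protein_seq`.
#' @param max_chars Vocabulary budget excluding the pad code (default 70).
#' @return An object of class `char_vocab`: a named integer vector mapping
#'   characters to codes, with `pad_id` 0 and `max_length` 800 attributes.
#' @export
build_char_vocab <- function(pairs, max_chars = 70) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0) stop("cannot build a vocabulary from an empty dataset",
                             call. = FALSE)
  chars <- unique(unlist(strsplit(paste0(pairs$protein_seq, pairs$smiles), "")))
  if (length(chars) > max_chars) {
    stop("character vocabulary overflow: ", length(chars), " distinct ",
         "characters exceed the budget of ", max_chars, "; surplus: ",
         paste(utils::tail(chars, length(chars) - max_chars), collapse = " "),
         call. = FALSE)
  }
  structure(stats::setNames(seq_along(chars), chars),
            pad_id = 0L, max_length = 800L, class = "char_vocab")
}

#' @export
print.char_vocab <- function(x, ...) {
  cat("<char_vocab>", length(x), "characters + pad(0), max_length",
      attr(x, "max_length"), "\n")
  invisible(x)
}

#' Character-encode a pair for the regression network
#'
#' Concatenates protein sequence and SMILES (no separator symbol), maps each
#' character to its integer code (unknown characters map to the pad code 0),
#' and pads with 0 or truncates to exactly `length_out` positions.
#'
#' @param protein,smiles Character scalars, or equal-length vectors for the
#'   matrix form.
#' @param vocab A [build_char_vocab()] vocabulary.
#' @param length_out Encoded length (default: the vocabulary's `max_length`,
#'   800).
#' @return For scalar inputs an integer vector of length `length_out`; for
#'   vector inputs an n x `length_out` integer matrix.
#' @export
encode_for_rcnn <- function(protein, smiles, vocab,
                            length_out = attr(vocab, "max_length")) {
  stopifnot(inherits(vocab, "char_vocab"), length(protein) == length(smiles))
  enc1 <- function(p, s) {
    chars <- strsplit(paste0(p, s), "")[[1]]
    ids <- unname(vocab[chars])
    ids[is.na(ids)] <- 0L
    n <- length(ids)
    if (n >= length_out) ids[seq_len(length_out)] else c(ids, rep(0L, length_out - n))
  }
  if (length(protein) == 1) return(enc1(protein, smiles))
  out <- matrix(0L, nrow = length(protein), ncol = length_out)
  for (i in seq_along(protein)) out[i, ] <- enc1(protein[i], smiles[i])
  out
}

#' Serialize a character vocabulary to JSON
#' @param vocab A `char_vocab`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_char_vocab <- function(vocab, path) {
  jsonlite::write_json(list(type = "char_vocab",
                            chars = as.list(unclass(vocab)),
                            max_length = attr(vocab, "max_length")),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a character vocabulary from JSON
#' @param path Path written by [save_char_vocab()].
#' @return A `char_vocab`.
#' @export
load_char_vocab <- function(path) {
  x <- jsonlite::read_json(path)
  if (!identical(x$type, "char_vocab")) {
    stop(path, " is not a serialized char_vocab", call. = FALSE)
  }
  structure(stats::setNames(as.integer(unlist(x$chars)), names(x$chars)),
            pad_id = 0L, max_length = as.integer(x$max_length),
            class = "char_vocab")
}
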