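#' Convert an inhibition constant in nanomolar to pKi
#'
#' pKi is the negative base-10 logarithm of Ki on the molar scale, so for Ki
#' given in nM, pKi = 9 - log10(Ki). Higher pKi means tighter binding:
#' 1 nM -> 9, 0.1 nM -> 10, 1 M (1e9 nM) -> 0.
#'
#' @param ki_nM Numeric vector of positive Ki values in nanomolar.
#' @return Numeric vector of pKi values.
#' @seealso [pki_to_ki()] for the inverse transform.
#' @export
#' @examples
#' ki_to_pki(c(1, 0.1, 1e9))
ki_to_pki <- function(ki_nM) {
  if (!is.numeric(ki_nM)) stop("`ki_nM` must be numeric", call. = FALSE)
  if (any(!is.finite(ki_nM)) || any(ki_nM <= 0)) {
    stop("`ki_nM` must be finite and > 0", call. = FALSE)
  }
  9 - log10(ki_nM)
}

#' Convert pKi back to Ki in nanomolar
#'
#' @param pki Numeric vector of pKi values.
#' @return Numeric vector of Ki in nM.
#' @export
pki_to_ki <- function(pki) {
  if (!is.numeric(pki) || any(!is.finite(pki))) {
    stop("`pki` must be finite numeric", call. = FALSE)
  }
  10^(9 - pki)
}

# Build the canonical pairs tibble from raw columns, dropping rows whose
# ligand, protein or affinity is missing or unusable; returns the tibble with
# a `drop_log` attribute counting each drop reason.
as_pairs_tibble <- function(smiles, protein_seq, ki_nM, provenance = NA_character_) {
  smiles <- as.character(smiles)
  protein_seq <- as.character(protein_seq)
  ki <- suppressWarnings(as.numeric(ki_nM))
  bad_smiles <- is.na(smiles) | !nzchar(trimws(smiles))
  bad_seq <- is.na(protein_seq) | !nzchar(trimws(protein_seq))
  bad_ki <- is.na(ki) | !is.finite(ki) | ki <= 0
  keep <- !(bad_smiles | bad_seq | bad_ki)
  out <- tibble::tibble(
    smiles = trimws(smiles[keep]),
    protein_seq = toupper(trimws(protein_seq[keep])),
    ki_nM = ki[keep]
  )
  out$pki <- ki_to_pki(out$ki_nM)
  out$pair_length <- nchar(out$smiles) + nchar(out$protein_seq)
  attr(out, "provenance") <- provenance
  attr(out, "drop_log") <- c(
    missing_smiles = sum(bad_smiles),
    missing_sequence = sum(bad_seq & !bad_smiles),
    bad_ki = sum(bad_ki & !bad_smiles & !bad_seq)
  )
  out
}

#' Read a ligand-protein affinity table
#'
#' Reads a delimited export (BindingDB-style TSV/CSV) with one row per
#' ligand-protein measurement and returns a tidy pairs tibble with columns
#' `smiles`, `protein_seq`, `ki_nM`, `pki` (computed as 9 - log10 Ki) and
#' `pair_length` (combined SMILES + protein character length). Rows with a
#' missing or empty SMILES or sequence, or a missing/non-positive Ki, are
#' dropped; counts per reason are attached as the `drop_log` attribute and
#' reported via a message.
#'
#' @param path Path to a CSV or TSV file.
#' @param smiles_col,seq_col,ki_col Names of the ligand SMILES, protein
#'   sequence and Ki (nM) columns.
#' @param delim Field delimiter; `NULL` (default) picks tab for `.tsv`/`.txt`
#'   files and comma otherwise.
#' @param quiet Suppress the drop-count message.
#' @return A tibble of pairs (see above).
#' @export
read_pairs <- function(path, smiles_col = "smiles", seq_col = "sequence",
                       ki_col = "ki", delim = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||% (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  for (col in c(smiles_col, seq_col, ki_col)) {
    if (!col %in% names(raw)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  out <- as_pairs_tibble(raw[[smiles_col]], raw[[seq_col]], raw[[ki_col]],
                         provenance = path)
  dropped <- sum(attr(out, "drop_log"))
  if (!quiet && dropped > 0) {
    message("read_pairs: dropped ", dropped, " of ", nrow(raw), " rows (",
            paste(names(attr(out, "drop_log")), attr(out, "drop_log"),
                  sep = "=", collapse = ", "), ")")
  }
  out
}

#' Filter pairs on combined length and affinity
#'
#' Retains pairs whose combined SMILES + protein length is at most
#' `max_pair_length` and whose pKi is at most `max_pki` (both bounds
#' inclusive: pairs *longer than* 800 characters and pKi values *greater
#' than* 10 are excluded). Row order is preserved and per-reason exclusion
#' counts are attached as the `filter_log` attribute.
#'
#' @param pairs A pairs tibble with `pair_length` and `pki` columns.
#' @param max_pair_length Maximum combined character length (default 800).
#' @param max_pki Maximum pKi (default 10).
#' @return The filtered tibble.
#' @export
filter_pairs <- function(pairs, max_pair_length = 800, max_pki = 10) {
  stopifnot(is.data.frame(pairs))
  if (!all(c("pair_length", "pki") %in% names(pairs))) {
    stop("`pairs` must have `pair_length` and `pki` columns", call. = FALSE)
  }
  if (any(is.na(pairs$pki))) {
    stop("every pair must have a pKi before filtering; found ",
         sum(is.na(pairs$pki)), " missing", call. = FALSE)
  }
  too_long <- pairs$pair_length > max_pair_length
  too_strong <- pairs$pki > max_pki
  out <- pairs[!(too_long | too_strong), , drop = FALSE]
  attr(out, "provenance") <- attr(pairs, "provenance")
  attr(out, "filter_log") <- c(over_length = sum(too_long),
                               over_pki = sum(too_strong))
  out
}

#' Split pairs into training and validation sets
#'
#' Deterministic, seed-reproducible partition at the pair level. The training
#' set receives `floor(n * train_fraction)` pairs sampled uniformly without
#' replacement; the remainder forms the validation set.
#'
#' @param pairs A pairs tibble.
#' @param train_fraction Fraction of pairs for training, in (0, 1). Default 0.7.
#' @param seed Integer seed controlling the shuffle.
#' @return A list with elements `train` and `val`, both tibbles.
#' @export
split_dataset <- function(pairs, train_fraction = 0.7, seed = 1) {
  stopifnot(is.data.frame(pairs))
  if (!is.numeric(train_fraction) || length(train_fraction) != 1 ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  n <- nrow(pairs)
  n_train <- floor(n * train_fraction)
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = pairs[sort(idx), , drop = FALSE],
       val = pairs[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}

#' Descriptive statistics of a pairs dataset
#'
#' One row per variable (`pair_length`, `pki`) with the sample mean, standard
#' deviation, minimum, quartiles and maximum — the usual preprocessing
#' summary reported for affinity corpora.
#'
#' @param pairs A non-empty pairs tibble.
#' @return A tibble with columns `variable`, `n`, `mean`, `sd`, `min`,
#'   `q25`, `median`, `q75`, `max`.
#' @export
summarize_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  if (nrow(pairs) == 0) stop("cannot summarize an empty dataset", call. = FALSE)
  one <- function(name, x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(variable = name, n = length(x), mean = mean(x),
                   sd = if (length(x) < 2) 0 else stats::sd(x),
                   min = min(x), q25 = q[1],
                   median = q[2], q75 = q[3], max = max(x))
  }
  dplyr::bind_rows(one("pair_length", pairs$pair_length), one("pki", pairs$pki))
}

#' Write a pairs tibble back to disk
#'
#' Writes the tabular schema `read_pairs()` consumes (columns `smiles`,
#' `sequence`, `ki`) so preprocessed datasets round-trip.
#'
#' @param pairs A pairs tibble.
#' @param path Output path; `.tsv` writes tab-separated, otherwise comma.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  out <- tibble::tibble(smiles = pairs$smiles, sequence = pairs$protein_seq,
                        ki = pairs$ki_nM)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}
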