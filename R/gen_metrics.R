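# Batch-level quality metrics for generated molecules: validity,
# uniqueness, internal diversity, and mean QED.

#' Fraction of syntactically valid SMILES
#'
#' Number of strings accepted by the sanitizing parser divided by the list
#' length. Empty strings count as invalid.
#'
#' @param smiles_list Character vector (may contain empty strings).
#' @return A fraction in \[0, 1\].
#' @export
validity <- function(smiles_list) {
  if (length(smiles_list) == 0) stop("empty molecule list", call. = FALSE)
  mean(smiles_is_valid(smiles_list))
}

#' Fraction of unique molecules among valid ones
#'
#' Distinct canonical forms divided by the number of valid entries, so two
#' spellings of one molecule ("CCO", "OCC") count once.
#'
#' @param smiles_list Character vector.
#' @return A fraction in (0, 1\].
#' @export
uniqueness <- function(smiles_list) {
  canon <- smiles_canonical(smiles_list)
  canon <- canon[!is.na(canon)]
  if (length(canon) == 0) stop("no valid molecules in list", call. = FALSE)
  length(unique(canon)) / length(canon)
}

#' Internal diversity of a molecule set
#'
#' One minus the mean pairwise Tanimoto similarity of radius-2, 2048-bit
#' Morgan (circular) fingerprints over all unordered pairs of valid
#' molecules. 0 for a homogeneous set, approaching 1 for structurally
#' unrelated molecules.
#'
#' @param smiles_list Character vector with at least 2 valid entries.
#' @return A value in \[0, 1\].
#' @export
internal_diversity <- function(smiles_list) {
  ann <- smiles_annotate(smiles_list)
  fps <- ann$fp[ann$valid]
  m <- length(fps)
  if (m < 2) stop("need at least 2 valid molecules", call. = FALSE)
  total <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      total <- total + tanimoto_bits(fps[[i]], fps[[j]])
    }
  }
  1 - total / (m * (m - 1) / 2)
}

#' Mean drug-likeness (QED) of valid molecules
#'
#' @param smiles_list Character vector with at least 1 valid entry.
#' @return Arithmetic mean of per-molecule QED scores, in \[0, 1\].
#' @export
mean_qed <- function(smiles_list) {
  ann <- smiles_annotate(smiles_list)
  q <- ann$qed[ann$valid & !is.na(ann$qed)]
  if (length(q) == 0) stop("no valid molecules in list", call. = FALSE)
  mean(q)
}

#' Full generation quality report
#'
#' Bundles the four metrics with the underlying counts, all computed on one
#' consistent annotation pass. `validity` is taken over all inputs;
#' `validity_nonempty` restricts the denominator to non-empty strings (the
#' natural reading when empty generations are discarded before scoring).
#'
#' @param smiles_list Non-empty character vector.
#' @return A one-row tibble of class `generation_report` with columns
#'   `n_input`, `n_valid`, `n_unique`, `validity`, `validity_nonempty`,
#'   `uniqueness`, `diversity`, `mean_qed`.
#' @export
generation_report <- function(smiles_list) {
  if (length(smiles_list) == 0) stop("empty molecule list", call. = FALSE)
  ann <- smiles_annotate(smiles_list)
  n_input <- nrow(ann)
  n_valid <- sum(ann$valid)
  canon <- ann$canonical[ann$valid]
  n_unique <- length(unique(canon))
  nonempty <- nzchar(smiles_list)
  fps <- ann$fp[ann$valid]
  div <- if (n_valid >= 2) {
    total <- 0
    for (i in seq_len(n_valid - 1)) {
      for (j in (i + 1):n_valid) total <- total + tanimoto_bits(fps[[i]], fps[[j]])
    }
    1 - total / (n_valid * (n_valid - 1) / 2)
  } else NA_real_
  q <- ann$qed[ann$valid & !is.na(ann$qed)]
  out <- tibble::tibble(
    n_input = n_input, n_valid = n_valid, n_unique = n_unique,
    validity = n_valid / n_input,
    validity_nonempty = if (any(nonempty)) {
      sum(ann$valid & nonempty) / sum(nonempty)
    } else 0,
    uniqueness = if (n_valid > 0) n_unique / n_valid else NA_real_,
    diversity = div,
    mean_qed = if (length(q)) mean(q) else NA_real_
  )
  class(out) <- c("generation_report", class(out))
  out
}
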