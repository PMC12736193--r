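# Chemistry services: SMILES parsing, canonicalization, Morgan fingerprints
# and QED, provided by the rdkit toolkit through a batched subprocess bridge
# (inst/python/chem_bridge.py). One python process handles a whole vector of
# SMILES, and results are cached per session, so repeated validity checks
# (e.g. during trimming) stay cheap.

.chem_cache <- new.env(parent = emptyenv())

chem_python <- function() {
  py <- getOption("seq2mol.python", Sys.getenv("SEQ2MOL_PYTHON", "python"))
  if (!nzchar(Sys.which(py))) {
    stop("python interpreter '", py, "' not found on PATH; ",
         "set options(seq2mol.python=) to a python with rdkit installed",
         call. = FALSE)
  }
  py
}

chem_bridge_path <- function() {
  p <- system.file("python", "chem_bridge.py", package = "seq2mol")
  if (!nzchar(p)) stop("chem_bridge.py not found in the installed package", call. = FALSE)
  p
}

# Run the bridge on a character vector; returns a data.frame with one row per
# input. op = "check" (valid, canonical) or "full" (+ qed, fingerprint bits).
chem_bridge <- function(smiles, op = c("check", "full")) {
  op <- match.arg(op)
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) {
    return(data.frame(valid = logical(0), canonical = character(0),
                      stringsAsFactors = FALSE))
  }
  if (any(grepl("[[:space:]]", smiles))) {
    stop("SMILES strings must not contain whitespace", call. = FALSE)
  }
  key <- paste0(op, "", smiles)
  miss <- !vapply(key, exists, logical(1), envir = .chem_cache, USE.NAMES = FALSE)
  todo <- unique(smiles[miss])
  if (length(todo) > 0) {
    out <- system2(chem_python(), c(shQuote(chem_bridge_path()), op),
                   input = todo, stdout = TRUE, stderr = FALSE)
    if (!is.null(attr(out, "status")) && attr(out, "status") != 0) {
      stop("chemistry bridge failed (exit status ", attr(out, "status"), ")",
           call. = FALSE)
    }
    if (length(out) != length(todo)) {
      stop("chemistry bridge returned ", length(out), " rows for ",
           length(todo), " inputs", call. = FALSE)
    }
    for (i in seq_along(todo)) {
      assign(paste0(op, "", todo[i]), out[i], envir = .chem_cache)
    }
  }
  rows <- vapply(key, get, character(1), envir = .chem_cache, USE.NAMES = FALSE)
  parts <- strsplit(rows, "\t", fixed = TRUE)
  valid <- vapply(parts, function(p) identical(p[1], "1"), logical(1))
  canonical <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "", character(1))
  res <- data.frame(valid = valid, canonical = canonical, stringsAsFactors = FALSE)
  res$canonical[!valid] <- NA_character_
  if (op == "full") {
    res$qed <- vapply(parts, function(p) {
      if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else NA_real_
    }, numeric(1))
    res$fp <- lapply(parts, function(p) {
      if (length(p) < 4 || !nzchar(p[4])) return(NULL)
      if (identical(p[4], "-")) return(integer(0))
      as.integer(strsplit(p[4], ",", fixed = TRUE)[[1]])
    })
  }
  res
}

#' Check SMILES syntactic validity
#'
#' A string is valid when the sanitizing parser of the chemistry toolkit
#' accepts it (parse + sanitize). The empty string is counted as invalid.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Logical vector, one element per input.
#' @export
#' @examples \dontrun{smiles_is_valid(c("CCO", "CCO(", ""))}
smiles_is_valid <- function(smiles) {
  chem_bridge(smiles, "check")$valid
}

#' Canonicalize SMILES
#'
#' Maps each valid SMILES to the toolkit's canonical form, used to detect
#' duplicate molecules written differently (e.g. "OCC" and "CCO").
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` for invalid inputs.
#' @export
smiles_canonical <- function(smiles) {
  chem_bridge(smiles, "check")$canonical
}

#' Full per-molecule chemistry annotation
#'
#' Validity, canonical SMILES, QED drug-likeness score, and the set bit
#' indices of the radius-2 2048-bit Morgan (circular) fingerprint.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A tibble with columns `smiles`, `valid`, `canonical`, `qed`,
#'   and `fp` (list column of 0-based bit indices; `NULL` when invalid).
#' @export
smiles_annotate <- function(smiles) {
  res <- chem_bridge(smiles, "full")
  tibble::tibble(smiles = smiles, valid = res$valid, canonical = res$canonical,
                 qed = res$qed, fp = res$fp)
}

# Tanimoto similarity between two fingerprints given as sorted bit-index sets.
# Two all-zero fingerprints have similarity 0 (toolkit convention).
tanimoto_bits <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
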