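# Pipeline orchestration: query -> literature retrieval -> target-name
# extraction -> sequence lookup -> molecule generation -> trimming -> pKi
# prediction, over pluggable providers so the whole graph runs offline.

EXTRACTION_INSTRUCTION <- paste(
  "extract all best matches protein name abbreviations from a given text",
  "and list them using * (your output should only be this list without any",
  "other words and sentences)")

#' Build the target-extraction prompt
#'
#' Appends the extraction instruction to the retrieved context text. The
#' instruction asks the language model to return only a `*`-bulleted list of
#' protein name abbreviations.
#'
#' @param context_text Concatenated abstracts (may be empty).
#' @return Character scalar prompt.
#' @export
build_extraction_prompt <- function(context_text = "") {
  if (!nzchar(context_text)) return(EXTRACTION_INSTRUCTION)
  paste0(context_text, "\n\n", EXTRACTION_INSTRUCTION)
}

#' Parse a star-bulleted list of protein names
#'
#' Keeps lines that begin with `*` (after leading whitespace), strips the
#' bullet and surrounding whitespace, drops empties, and preserves order.
#' Non-bulleted lines are discarded; no names is an empty result, not an
#' error.
#'
#' @param llm_output Raw text returned by the language model.
#' @return Character vector of names (possibly empty).
#' @export
#' @examples
#' parse_star_list("Here are proteins:\n* EGFR\n* KRAS")
parse_star_list <- function(llm_output) {
  if (is.null(llm_output) || is.na(llm_output)) return(character(0))
  lines <- strsplit(llm_output, "\n", fixed = TRUE)[[1]]
  starred <- grep("^[[:space:]]*\\*", lines, value = TRUE)
  names <- trimws(sub("^[[:space:]]*\\*+[[:space:]]*", "", starred))
  names[nzchar(names)]
}

#' Extract protein names from retrieved texts
#'
#' Concatenates the texts, builds the extraction prompt, invokes the
#' language-model provider once, parses the star list, and deduplicates
#' preserving first occurrence.
#'
#' @param texts Character vector of abstracts.
#' @param llm A function `prompt -> text`.
#' @return Character vector of unique protein names, in order of first
#'   mention.
#' @export
extract_protein_names <- function(texts, llm) {
  stopifnot(is.function(llm))
  prompt <- build_extraction_prompt(paste(texts, collapse = "\n\n"))
  unique(parse_star_list(llm(prompt)))
}

#' Fetch the first sequence record for a protein name
#'
#' @param name Protein name.
#' @param sequence_source A function `name -> character vector of sequences`
#'   (ordered as the upstream database returns them).
#' @return The first record, uppercased; validated against the 20-letter
#'   amino-acid alphabet plus X.
#' @export
fetch_first_sequence <- function(name, sequence_source) {
  stopifnot(is.function(sequence_source))
  recs <- sequence_source(name)
  if (is.null(recs) || length(recs) == 0 || all(is.na(recs))) {
    stop("no sequence records found for '", name, "'", call. = FALSE)
  }
  seq <- toupper(trimws(recs[1]))
  if (!nzchar(seq) || grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seq)) {
    stop("sequence record for '", name, "' contains invalid characters",
         call. = FALSE)
  }
  seq
}

#' Offline provider bundle backed by in-memory fixtures
#'
#' Builds the three provider contracts the pipeline needs from plain R
#' objects (or JSON files with the same shape), so the full graph runs
#' without any network access.
#'
#' @param abstracts Named list: query (or `"default"`) -> character vector
#'   of abstract texts.
#' @param sequences Named list: protein name -> character vector of
#'   sequence records (first record wins).
#' @param llm_response Either a fixed response string or a function
#'   `prompt -> text`; the default extracts capitalized tokens followed by
#'   digits from the prompt context (a crude stand-in for a live model).
#' @return A list with function elements `llm`, `retriever`,
#'   `sequence_source`.
#' @export
mock_providers <- function(abstracts = list(), sequences = list(),
                           llm_response = NULL) {
  retriever <- function(query) {
    hit <- abstracts[[query]] %||% abstracts[["default"]]
    as.character(hit %||% character(0))
  }
  llm <- if (is.function(llm_response)) {
    llm_response
  } else if (is.character(llm_response)) {
    function(prompt) llm_response
  } else {
    function(prompt) {
      toks <- unique(unlist(stringr::str_extract_all(prompt,
                                                     "\\b[A-Z][A-Z0-9]{2,9}\\b")))
      paste0("* ", toks, collapse = "\n")
    }
  }
  sequence_source <- function(name) as.character(sequences[[name]] %||% character(0))
  list(llm = llm, retriever = retriever, sequence_source = sequence_source)
}

agent_stage <- function(state, stage, fun) {
  if (state$failed) return(state)
  res <- tryCatch(list(ok = TRUE, value = fun()),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  if (res$ok) {
    state$trace <- dplyr::bind_rows(state$trace, tibble::tibble(
      stage = stage, status = "ok", message = ""))
    state$value <- res$value
  } else {
    state$trace <- dplyr::bind_rows(state$trace, tibble::tibble(
      stage = stage, status = "failed", message = res$value))
    state$failed <- TRUE
  }
  state
}

#' Run the end-to-end discovery pipeline
#'
#' Executes the stages in order: retrieve literature, extract protein names,
#' choose the first name, fetch its first sequence, generate a raw SMILES,
#' trim it to validity, and predict pKi with the regression network. Each
#' stage appends to the trace; a failing stage halts all downstream stages
#' and marks the state failed without raising. An empty trimming result
#' completes with a warning status and no predicted pKi.
#'
#' @param query Free-text user query.
#' @param providers A provider bundle (see [mock_providers()]).
#' @param clm,tokenizer Trained language model and its tokenizer.
#' @param rcnn,char_vocab Trained regression model and its character
#'   vocabulary.
#' @param gcfg A [generation_config()].
#' @return An object of class `agent_state`: query, retrieved texts,
#'   protein names, chosen protein and sequence, raw and trimmed SMILES,
#'   predicted pKi (`NA` unless a valid molecule was obtained), `failed`
#'   flag, and the stage trace tibble.
#' @export
run_pipeline <- function(query, providers, clm, tokenizer, rcnn, char_vocab,
                         gcfg = generation_config()) {
  state <- list(query = query, retrieved_texts = character(0),
                protein_names = character(0), chosen_protein = NA_character_,
                protein_sequence = NA_character_, raw_smiles = NA_character_,
                trimmed_smiles = NA_character_, predicted_pki = NA_real_,
                failed = FALSE,
                trace = tibble::tibble(stage = character(0),
                                       status = character(0),
                                       message = character(0)))
  class(state) <- "agent_state"

  state <- agent_stage(state, "retrieve", function() {
    texts <- providers$retriever(query)
    if (length(texts) == 0) stop("retriever returned no documents")
    texts
  })
  if (!state$failed) state$retrieved_texts <- state$value

  state <- agent_stage(state, "extract_names", function() {
    names <- extract_protein_names(state$retrieved_texts, providers$llm)
    if (length(names) == 0) stop("no protein names extracted")
    names
  })
  if (!state$failed) {
    state$protein_names <- state$value
    state$chosen_protein <- state$value[1]
  }

  state <- agent_stage(state, "fetch_sequence", function() {
    fetch_first_sequence(state$chosen_protein, providers$sequence_source)
  })
  if (!state$failed) state$protein_sequence <- state$value

  state <- agent_stage(state, "generate", function() {
    strip_after_whitespace(
      generate_raw(clm, tokenizer, state$protein_sequence, gcfg))
  })
  if (!state$failed) state$raw_smiles <- state$value

  state <- agent_stage(state, "trim", function() {
    trim_to_valid(state$raw_smiles)
  })
  if (!state$failed) state$trimmed_smiles <- state$value

  if (!state$failed) {
    if (nzchar(state$trimmed_smiles)) {
      state <- agent_stage(state, "predict_pki", function() {
        enc <- encode_for_rcnn(state$protein_sequence, state$trimmed_smiles,
                               char_vocab,
                               length_out = rcnn$config$input_length)
        predict_pki(rcnn, enc)
      })
      if (!state$failed) state$predicted_pki <- state$value
    } else {
      state$trace <- dplyr::bind_rows(state$trace, tibble::tibble(
        stage = "predict_pki", status = "skipped",
        message = "trimming produced an empty molecule"))
    }
  }
  state$value <- NULL
  state
}

#' @export
print.agent_state <- function(x, ...) {
  cat("<agent_state>", if (x$failed) "FAILED" else "completed", "\n")
  cat("  query:", x$query, "\n")
  if (!is.na(x$chosen_protein)) cat("  target:", x$chosen_protein, "\n")
  if (!is.na(x$trimmed_smiles)) cat("  molecule:", x$trimmed_smiles, "\n")
  if (!is.na(x$predicted_pki)) {
    cat("  predicted pKi:", round(x$predicted_pki, 3), "\n")
  }
  print(x$trace)
  invisible(x)
}

#' Serialize an agent state to JSON
#'
#' @param state An `agent_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_agent_state <- function(state, path) {
  out <- unclass(state)
  out$trace <- as.list(state$trace)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
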