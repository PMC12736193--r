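test_that("the extraction prompt appends the instruction verbatim", {
  p <- build_extraction_prompt("EGFR is mutated in lung adenocarcinoma.")
  expect_true(startsWith(p, "EGFR is mutated"))
  expect_true(endsWith(p, "without any other words and sentences)"))
  expect_true(grepl("list them using *", p, fixed = TRUE))
  # empty context: the instruction alone
  expect_true(startsWith(build_extraction_prompt(""), "extract all best"))
})

test_that("parse_star_list keeps only bulleted names, in order", {
  expect_equal(parse_star_list("* EGFR\n* KRAS"), c("EGFR", "KRAS"))
  expect_equal(parse_star_list("Here are proteins:\n* SP100"), "SP100")
  expect_equal(parse_star_list("no list here"), character(0))
  expect_equal(parse_star_list("  * A \n text \n*B\n* "), c("A", "B"))
  # rendering a list and parsing it back is the identity
  names <- c("EGFR", "TP53", "SP100")
  expect_equal(parse_star_list(paste0("* ", names, collapse = "\n")), names)
})

test_that("extract_protein_names invokes the provider once and dedups", {
  calls <- 0
  llm <- function(prompt) { calls <<- calls + 1; "* A\n* A\n* B" }
  expect_equal(extract_protein_names(c("t1", "t2"), llm), c("A", "B"))
  expect_equal(calls, 1)
  fixed <- mock_providers(llm_response = "* SP100")$llm
  expect_equal(extract_protein_names("anything", fixed), "SP100")
})

test_that("fetch_first_sequence takes the first record and validates it", {
  src <- function(name) {
    list(SP100 = c("mktaywvdfh", "ALTERNATE"))[[name]]
  }
  expect_equal(fetch_first_sequence("SP100", src), "MKTAYWVDFH")
  expect_error(fetch_first_sequence("UNKNOWN", src), "no sequence records")
  bad <- function(name) "MKT123"
  expect_error(fetch_first_sequence("X", bad), "invalid characters")
})

test_that("the pipeline completes end-to-end under mocked providers", {
  tm <- tiny_models()
  providers <- mock_providers(
    abstracts = list(default = "TARGETX binds small molecules."),
    sequences = stats::setNames(list(tm$pair$protein_seq), "TARGETX"),
    llm_response = "* TARGETX")
  st <- run_pipeline("test query", providers, tm$clm, tm$tok, tm$rcnn,
                     tm$vocab,
                     generation_config(max_new_tokens = 50,
                                       temperature = 1e-6, seed = 1))
  expect_false(st$failed)
  expect_equal(st$chosen_protein, "TARGETX")
  expect_equal(st$protein_sequence, tm$pair$protein_seq)
  expect_true(nzchar(st$trimmed_smiles))
  expect_true(smiles_is_valid(st$trimmed_smiles))
  expect_true(is.finite(st$predicted_pki))
  # stages appear in pipeline order
  expect_equal(st$trace$stage,
               c("retrieve", "extract_names", "fetch_sequence", "generate",
                 "trim", "predict_pki"))
  expect_true(all(st$trace$status == "ok"))
  # determinism: same inputs, same state
  st2 <- run_pipeline("test query", providers, tm$clm, tm$tok, tm$rcnn,
                      tm$vocab,
                      generation_config(max_new_tokens = 50,
                                        temperature = 1e-6, seed = 1))
  expect_equal(st$predicted_pki, st2$predicted_pki)
  expect_identical(st$trimmed_smiles, st2$trimmed_smiles)
  # JSON serialization
  f <- tempfile(fileext = ".json")
  save_agent_state(st, f)
  expect_equal(jsonlite::read_json(f)$trimmed_smiles, st$trimmed_smiles)
})

test_that("failures halt the pipeline at the right stage", {
  tm <- tiny_models()
  # retriever returns nothing: fail at retrieve, nothing downstream
  empty <- mock_providers(abstracts = list(), llm_response = "* X")
  st <- run_pipeline("q", empty, tm$clm, tm$tok, tm$rcnn, tm$vocab)
  expect_true(st$failed)
  expect_equal(st$trace$stage[st$trace$status == "failed"], "retrieve")
  expect_equal(nrow(st$trace), 1)  # no stage after the failure
  expect_true(is.na(st$predicted_pki))

  # LLM yields no names: fail at extraction, retrieval already recorded
  providers <- mock_providers(abstracts = list(default = "text"),
                              llm_response = "nothing bulleted")
  st2 <- run_pipeline("q", providers, tm$clm, tm$tok, tm$rcnn, tm$vocab)
  expect_true(st2$failed)
  expect_equal(st2$trace$stage, c("retrieve", "extract_names"))
  expect_true(is.na(st2$protein_sequence))

  # unknown protein: fail at sequence fetch
  providers3 <- mock_providers(abstracts = list(default = "text"),
                               sequences = list(), llm_response = "* GHOST")
  st3 <- run_pipeline("q", providers3, tm$clm, tm$tok, tm$rcnn, tm$vocab)
  expect_equal(utils::tail(st3$trace$stage, 1), "fetch_sequence")
  expect_true(st3$failed)
})
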