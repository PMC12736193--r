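test_that("the Ki to pKi transform matches the -log10 molar convention", {
  expect_equal(ki_to_pki(1), 9)
  expect_equal(ki_to_pki(0.1), 10)
  expect_equal(ki_to_pki(1e9), 0)
  expect_error(ki_to_pki(0), "> 0")
  expect_error(ki_to_pki(-5), "> 0")
  # round trip over a pKi grid
  p <- seq(0, 12, by = 0.25)
  expect_equal(ki_to_pki(10^(9 - p)), p, tolerance = 1e-12)
  expect_equal(ki_to_pki(pki_to_ki(p)), p, tolerance = 1e-12)
  # monotonically decreasing in Ki
  ki <- sort(10^runif(50, -3, 9))
  expect_true(all(diff(ki_to_pki(ki)) <= 0))
})

test_that("read_pairs ingests tables, drops bad rows, and enforces schema", {
  df <- tibble::tibble(smiles = c("CCO", "CCN", "CCC"),
                       sequence = c("MKT", "ACD", "WYV"),
                       ki = c("1", "10", "100"))
  pairs <- read_pairs(write_temp_table(df), quiet = TRUE)
  expect_equal(nrow(pairs), 3)
  expect_equal(pairs$pki, c(9, 8, 7))
  expect_equal(pairs$pair_length, rep(6, 3))

  # a missing Ki cell drops exactly that row and logs the drop
  df$ki[2] <- NA
  pairs2 <- read_pairs(write_temp_table(df), quiet = TRUE)
  expect_equal(nrow(pairs2), 2)
  expect_equal(sum(attr(pairs2, "drop_log")), 1)
  expect_equal(unname(attr(pairs2, "drop_log")["bad_ki"]), 1)

  # missing column is a schema error naming the column
  df3 <- df[, c("smiles", "ki")]
  expect_error(read_pairs(write_temp_table(df3), quiet = TRUE), "sequence")
  expect_error(read_pairs(tempfile(), quiet = TRUE), "not found")

  # TSV round trip through write_pairs
  tsv <- tempfile(fileext = ".tsv")
  write_pairs(pairs, tsv)
  expect_equal(read_pairs(tsv, quiet = TRUE)$smiles, pairs$smiles)
})

test_that("filter_pairs applies inclusive length and pKi bounds in order", {
  mk <- function(len_extra, pki) {
    tibble::tibble(smiles = "C", protein_seq = strrep("A", len_extra),
                   ki_nM = pki_to_ki(pki), pki = pki,
                   pair_length = 1 + len_extra)
  }
  pairs <- dplyr::bind_rows(mk(100, 5), mk(800, 6),  # 801 chars: out
                            mk(300, 10.5),           # pKi 10.5: out
                            mk(799, 10),             # both at boundary: in
                            mk(10, 2))
  kept <- filter_pairs(pairs)
  expect_equal(nrow(kept), 3)
  expect_equal(attr(kept, "filter_log"),
               c(over_length = 1, over_pki = 1))
  expect_equal(kept$pki, c(5, 10, 2))  # order preserved
  # boundary pair (length exactly 800, pKi exactly 10) is retained
  expect_true(any(kept$pair_length == 800 & kept$pki == 10))
  # idempotent
  expect_identical(filter_pairs(kept)$pki, kept$pki)
  # missing pKi is a state error
  pairs$pki[1] <- NA
  expect_error(filter_pairs(pairs), "missing")
})

test_that("split_dataset yields disjoint, seed-reproducible partitions", {
  pairs <- make_paired_corpus(10, seed = 1)
  sp <- split_dataset(pairs, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$val), 3)
  key <- function(d) paste(d$smiles, d$protein_seq, d$ki_nM)
  expect_length(intersect(key(sp$train), key(sp$val)), 0)
  expect_setequal(c(key(sp$train), key(sp$val)), key(pairs))

  # determinism and seed sensitivity
  sp2 <- split_dataset(pairs, 0.7, seed = 1)
  expect_identical(sp$train, sp2$train)
  big <- make_paired_corpus(100, seed = 2)
  s1 <- split_dataset(big, 0.7, seed = 1)
  s2 <- split_dataset(big, 0.7, seed = 2)
  expect_false(identical(key(s1$train), key(s2$train)))
  expect_error(split_dataset(pairs, 1.2), "in \\(0, 1\\)")
})

test_that("summarize_pairs reproduces hand-computed sample statistics", {
  # strings engineered so pair lengths are 2, 4, 6, 8, 10
  pairs <- tibble::tibble(
    smiles = c("C", "CC", "CCC", "CCCC", "CCCCC"),
    protein_seq = c("M", "MK", "MKT", "MKTA", "MKTAY"),
    ki_nM = pki_to_ki(c(2, 4, 6, 8, 10)),
    pki = c(2, 4, 6, 8, 10))
  pairs$pair_length <- nchar(pairs$smiles) + nchar(pairs$protein_seq)
  s <- summarize_pairs(pairs)
  len <- s[s$variable == "pair_length", ]
  expect_equal(len$mean, 6)
  expect_equal(len$sd, sqrt(10))
  expect_equal(c(len$min, len$q25, len$median, len$q75, len$max),
               c(2, 4, 6, 8, 10))
  pki <- s[s$variable == "pki", ]
  expect_equal(pki$mean, 6)
  expect_equal(c(pki$min, pki$max), c(2, 10))
  # degenerate single-pair dataset: all stats equal the single value
  s1 <- summarize_pairs(pairs[3, ])
  expect_true(all(s1[s1$variable == "pki",
                     c("mean", "min", "q25", "median", "q75", "max")] == 6))
  expect_equal(s1$sd, c(0, 0))
  expect_error(summarize_pairs(pairs[0, ]), "empty")
})

test_that("summaries of filtered data respect the filter bounds", {
  pairs <- make_paired_corpus(100, noise_sd = 2, seed = 5)
  s <- summarize_pairs(filter_pairs(pairs))
  expect_lte(s$max[s$variable == "pair_length"], 800)
  expect_lte(s$max[s$variable == "pki"], 10)
})
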