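write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("FASTA reading normalises U and case, preserves order", {
  p <- write_tmp_fasta(c(">l1", "acgu", ">l2 some description", "GGTT"))
  s <- read_fasta_sequences(p)
  expect_equal(s$id, c("l1", "l2"))
  expect_equal(s$sequence, c("ACGT", "GGTT"))

  expect_equal(nrow(read_fasta_sequences(write_tmp_fasta(character(0)))), 0L)
  expect_error(read_fasta_sequences(write_tmp_fasta(c("ACGT", ">l1", "AA"))),
               "header")
})

test_that("k-mer tokenization follows the overlap and stride rules", {
  expect_equal(kmer_tokenize("AGCTA", k = 3), c("AGC", "GCT", "CTA"))
  expect_equal(kmer_tokenize("AGCTA", k = 2, stride = 2), c("AG", "CT"))
  expect_equal(kmer_tokenize("AAAA", k = 4), "AAAA")
  # count contract with stride 1
  expect_length(kmer_tokenize(strrep("ACGT", 10), k = 3), 40 - 3 + 1)
  # N-containing tokens are dropped
  expect_equal(kmer_tokenize("ACNGT", k = 2), c("AC", "GT"))
  expect_error(kmer_tokenize("AG", k = 3, id = "l9"), "l9")
})

test_that("tokenization is a pure function and order-sensitive", {
  s <- "ACGGTACCA"
  expect_identical(kmer_tokenize(s, 3), kmer_tokenize(s, 3))
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_false(identical(sort(kmer_tokenize(s, 3)),
                         sort(kmer_tokenize(rev_s, 3))))
})

test_that("embedding vectors have the configured shape and are finite", {
  corpus <- withr::with_seed(1, purrr::map(1:10, function(i) {
    sample(c("AAA", "ACG", "TTT", "GGC", "CAT"), 30, replace = TRUE)
  }))
  emb <- fit_kmer_embedding(corpus, dim = 4)
  expect_equal(dim(emb$tokens), c(5L, 4L))
  expect_true(all(is.finite(emb$tokens)))
  # determinism: refit gives identical vectors
  expect_identical(fit_kmer_embedding(corpus, dim = 4)$tokens, emb$tokens)
  expect_error(fit_kmer_embedding(list(), dim = 4), "empty")
})

test_that("relabelling the vocabulary permutes but preserves vectors", {
  corpus <- withr::with_seed(42, purrr::map(1:12, function(i) {
    sample(c("AAT", "ACG", "TTG", "GGC"), 25, replace = TRUE)
  }))
  relabel <- c(AAT = "TTG", ACG = "GGC", TTG = "AAT", GGC = "ACG")
  corpus2 <- purrr::map(corpus, function(x) unname(relabel[x]))
  e1 <- fit_kmer_embedding(corpus, dim = 3)
  e2 <- fit_kmer_embedding(corpus2, dim = 3)
  for (tok in names(relabel)) {
    expect_equal(e2$tokens[relabel[[tok]], ], e1$tokens[tok, ],
                 tolerance = 1e-10)
  }
})

test_that("pooled features are token-vector means", {
  corpus <- list(c("AAA", "CCC"), c("AAA", "GGG"), c("CCC", "GGG", "AAA"))
  emb <- fit_kmer_embedding(corpus, dim = 3)
  # sequence with all tokens equal -> pooled feature is that token's vector
  s1 <- tibble::tibble(id = "x", sequence = "AAAAA")
  f1 <- embed_sequences(emb, s1, k = 3)
  expect_equal(unname(f1["x", ]), unname(emb$tokens["AAA", ]))
  # two-token sequence -> midpoint of the two vectors
  s2 <- tibble::tibble(id = "y", sequence = "AAACCC")
  # tokens: AAA AAC ACC CCC; AAC/ACC unknown and skipped
  f2 <- embed_sequences(emb, s2, k = 3)
  expect_equal(unname(f2["y", ]),
               unname((emb$tokens["AAA", ] + emb$tokens["CCC", ]) / 2))
  # all tokens unknown -> error
  expect_error(
    embed_sequences(emb, tibble::tibble(id = "z", sequence = "TTTTT"), k = 3),
    "vocabulary")
})

test_that("stacked mode pads with zero rows to the configured height", {
  corpus <- list(c("AA", "CC"), c("GG", "AA"))
  emb <- fit_kmer_embedding(corpus, dim = 2)
  st <- embed_sequences(emb, tibble::tibble(id = "x", sequence = "AACC"),
                        k = 2, stride = 2, mode = "stacked", pad_rows = 4)
  expect_equal(dim(st[[1]]$stacked), c(4L, 2L))
  expect_equal(st[[1]]$stacked[3:4, ], matrix(0, 2, 2))
  expect_equal(st[[1]]$pooled,
               unname(colMeans(emb$tokens[c("AA", "CC"), ])))
})

test_that("feature tables round-trip through TSV", {
  corpus <- withr::with_seed(5, purrr::map(1:6, function(i) {
    sample(c("AC", "GT", "CA"), 15, replace = TRUE)
  }))
  emb <- fit_kmer_embedding(corpus, dim = 3)
  seqs <- tibble::tibble(id = c("a", "b"),
                         sequence = c("ACACGT", "GTCAGT"))
  f <- embed_sequences(emb, seqs, k = 2, stride = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(f, path)
  expect_equal(read_feature_table(path), f, tolerance = 1e-8)
})

test_that("residue shuffling preserves composition, destroys order", {
  seqs <- tibble::tibble(id = "s", sequence = "AAACCCGGGTTT")
  sh <- shuffle_residues(seqs, seed = 3)
  expect_equal(sort(strsplit(sh$sequence, "")[[1]]),
               sort(strsplit(seqs$sequence, "")[[1]]))
  expect_identical(shuffle_residues(seqs, seed = 3)$sequence, sh$sequence)
})
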