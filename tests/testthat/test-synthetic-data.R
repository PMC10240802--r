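test_that("spec validation enforces the invariants", {
  expect_error(synthetic_spec(density = 0), "density")
  expect_error(synthetic_spec(density = 1), "density")
  expect_error(synthetic_spec(rank = 0), "rank")
  expect_error(synthetic_spec(motif_set = c("ACG", "AC")), "length")
  expect_error(synthetic_spec(motif_set = c("ACG", "ACG")), "distinct")
  expect_error(synthetic_spec(motif_set = c("ACG", "AXG")), "A/C/G/T")
  # motif groups pin the rank
  expect_equal(synthetic_spec(motif_set = c("ACG", "TGC"), rank = 5)$rank, 2L)
})

test_that("simulated matrices hit the target density and are reproducible", {
  spec <- synthetic_spec(L = 150, D = 80, density = 0.07, seed = 5)
  sim <- simulate_associations(spec)
  expect_true(abs(mean(sim$truth) - 0.07) <= 0.005)
  # realized density within 3 binomial standard errors of the target
  n <- length(sim$truth)
  se <- sqrt(0.07 * 0.93 / n)
  expect_lt(abs(mean(unclass(sim$matrix)) - 0.07), 3 * se + 0.005)
  sim2 <- simulate_associations(spec)
  expect_identical(unclass(sim2$matrix), unclass(sim$matrix))
  expect_equal(sim2$truth, sim$truth)
})

test_that("rank-1 equal factors give identical row probabilities", {
  # direct construction of the degenerate case: all factors equal
  P <- plogis(-2 + matrix(1, 5, 1) %*% t(matrix(1, 4, 1)))
  expect_true(all(P == P[1, 1]))
})

test_that("motif planting follows the realized group counts", {
  spec <- synthetic_spec(L = 30, D = 20, density = 0.1,
                         motif_set = c("ACG", "TGC"), seq_len = 600,
                         plant_rate = 20, seed = 8)
  sim <- simulate_associations(spec)
  seqs <- simulate_sequences(spec, sim$matrix)
  expect_equal(seqs$id, rownames(sim$matrix))
  expect_true(all(nchar(seqs$sequence) == 600))

  groups <- sort(rep_len(1:2, 20))
  X <- unclass(sim$matrix)
  count_motif <- function(s, motif) {
    length(gregexpr(motif, s, fixed = TRUE)[[1]][
      gregexpr(motif, s, fixed = TRUE)[[1]] > 0])
  }
  # background occurrence rate of one 3-mer in 600 uniform bases
  bg <- (600 - 2) / 64
  zero_rows <- which(rowSums(X) == 0)
  if (length(zero_rows) > 0) {
    cnt <- count_motif(seqs$sequence[zero_rows[1]], "ACG")
    expect_lt(cnt, bg + 5 * sqrt(bg))
  }
  rich <- which(rowSums(X[, groups == 1, drop = FALSE]) >= 2)
  expect_true(length(rich) > 0)
  for (i in head(rich, 3)) {
    planted <- sum(X[i, groups == 1]) * 20
    cnt <- count_motif(seqs$sequence[i], "ACG")
    expect_gt(cnt, planted - 5 * sqrt(planted + bg))
    expect_gt(cnt, bg)  # exceeds background
  }
  # determinism
  expect_identical(simulate_sequences(spec, sim$matrix)$sequence,
                   seqs$sequence)
})

test_that("too-short sequences are refused", {
  spec <- synthetic_spec(L = 10, D = 8, density = 0.5,
                         motif_set = c("ACGT"), seq_len = 30,
                         plant_rate = 10, seed = 2)
  sim <- simulate_associations(spec)
  expect_error(simulate_sequences(spec, sim$matrix), "too short")
})

test_that("truth_auc gives the oracle and uninformative limits", {
  spec <- synthetic_spec(L = 40, D = 25, density = 0.1, seed = 3)
  sim <- simulate_associations(spec)
  pos <- which(unclass(sim$matrix) == 1L, arr.ind = TRUE)
  held <- pos[1:10, ]
  # truth = realized matrix itself -> perfect
  expect_equal(truth_auc(unclass(sim$matrix) * 1.0, sim$matrix, held), 1)
  # constant truth -> uninformative
  expect_equal(truth_auc(matrix(0.5, 40, 25), sim$matrix, held), 0.5)
  # planted truth is well above chance
  expect_gt(truth_auc(sim$truth, sim$matrix, held), 0.7)
  expect_error(truth_auc(sim$truth, sim$matrix,
                         which(unclass(sim$matrix) == 0L)[1]),
               "positive")
})

test_that("default planted spec has a high recoverable ceiling", {
  spec <- synthetic_spec()  # L=200, D=100, rank=5, density=0.05
  sim <- simulate_associations(spec)
  split <- kfold_split(sim$matrix, 5, seed = 1)
  a <- dplyr::filter(split$assignments, fold == 1)
  expect_gt(truth_auc(sim$truth, sim$matrix, cbind(a$row, a$col)), 0.9)
})

test_that("FASTA writer round-trips simulated sequences", {
  spec <- synthetic_spec(L = 5, D = 8, density = 0.2,
                         motif_set = c("ACG", "TGA"), seq_len = 100,
                         plant_rate = 5, seed = 4)
  sim <- simulate_associations(spec)
  seqs <- simulate_sequences(spec, sim$matrix)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_sequences(seqs, path)
  back <- read_fasta_sequences(path)
  expect_equal(back$id, seqs$id)
  expect_equal(back$sequence, seqs$sequence)
})
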