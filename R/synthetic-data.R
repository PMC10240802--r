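#' Specification of a synthetic lncRNA-disease study
#'
#' Describes a sparse 0/1 bipartite association matrix with planted
#' low-rank structure and, optionally, nucleotide sequences whose k-mer
#' composition statistically determines each lncRNA's disease profile.
#' The generator returns the planted probability matrix alongside the
#' realized data, so every downstream statistic can be compared to a
#' computable ceiling ([truth_auc()]).
#'
#' Latent factors are exponential (heavy-tailed), emulating the skewed
#' degree distributions of curated association databases.  When
#' `motif_set` is non-empty the truth becomes a bipartite stochastic
#' block model instead: diseases are partitioned into
#' `length(motif_set)` exchangeable groups with uniform loadings (rank =
#' number of groups), so all columns are equal in expectation and the
#' only plantable ranking signal is the lncRNA-side group preference --
#' the part of the truth a cold-start lncRNA's sequence can encode.
#'
#' @param L,D lncRNA and disease counts.
#' @param rank Latent factor count (ignored, with a message, when
#'   `motif_set` is given: rank is then the number of motif groups).
#' @param density Expected fraction of 1-entries (0 < density < 1).
#' @param motif_set Character vector of equal-length nucleotide motifs,
#'   one per disease group; `NULL` for association-only data.
#' @param seq_len Length of each generated sequence.
#' @param plant_rate Motif copies planted per realized association in
#'   the motif's group.
#' @param seed RNG seed; all outputs are reproducible from the spec.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(L = 200L, D = 100L, rank = 5L, density = 0.05,
                           motif_set = NULL, seq_len = 2500L,
                           plant_rate = 8L, seed = 1L) {
  if (density <= 0 || density >= 1) abort("density must be in (0,1)")
  if (rank < 1) abort("rank must be >= 1")
  if (L < 1 || D < 1) abort("L and D must be >= 1")
  if (!is.null(motif_set)) {
    klen <- unique(nchar(motif_set))
    if (length(klen) != 1) abort("motifs must share one length")
    if (anyDuplicated(motif_set)) abort("motifs must be distinct")
    if (!all(grepl("^[ACGT]+$", motif_set))) {
      abort("motifs must be A/C/G/T strings")
    }
    if (rank != length(motif_set)) {
      rank <- length(motif_set)
    }
  }
  out <- list(L = as.integer(L), D = as.integer(D), rank = as.integer(rank),
              density = density, motif_set = motif_set,
              seq_len = as.integer(seq_len),
              plant_rate = as.integer(plant_rate), seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  out
}

#' Simulate an association matrix with planted low-rank structure
#'
#' Draws non-negative latent factors U (L x rank) and V (D x rank) with
#' standard-exponential entries, forms the logistic low-rank probability
#' matrix `P = plogis(c + U V')` with the intercept `c` calibrated by
#' bisection so that `mean(P)` matches the requested density (within
#' 0.005), and samples each entry independently as 1 with probability
#' `P`.  With a motif set, V is block-structured: disease j loads only
#' on the factor of its group.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (an [assoc_matrix()] with ids
#'   `lnc1..lncL`, `dis1..disD`), `truth` (the L x D probability matrix
#'   P), and `groups` (per-disease group index, or NULL).
#' @export
simulate_associations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    U <- matrix(rexp(spec$L * spec$rank), spec$L, spec$rank)
    groups <- NULL
    if (!is.null(spec$motif_set)) {
      # bipartite stochastic-block truth: diseases in a group are
      # exchangeable (uniform loadings), so all columns are equal in
      # expectation and only the lncRNA-side group preferences -- the
      # part a sequence can encode -- carry ranking information
      groups <- disease_groups(spec$D, spec$rank)
      V <- matrix(0, spec$D, spec$rank)
      V[cbind(seq_len(spec$D), groups)] <- spec$rank
    } else {
      V <- matrix(rexp(spec$D * spec$rank), spec$D, spec$rank)
    }
    M <- U %*% t(V)
    f <- function(c0) mean(plogis(c0 + M)) - spec$density
    lo <- -80; hi <- 20
    if (f(lo) > 0 || f(hi) < 0) {
      abort("density calibration failed to bracket the target")
    }
    c0 <- uniroot(f, c(lo, hi), tol = 1e-10)$root
    P <- plogis(c0 + M)
    if (abs(mean(P) - spec$density) > 0.005) {
      abort("density calibration did not converge")
    }
    X <- matrix(rbinom(spec$L * spec$D, 1L, P), spec$L, spec$D)
    ids <- list(sprintf("lnc%03d", seq_len(spec$L)),
                sprintf("dis%03d", seq_len(spec$D)))
    dimnames(X) <- ids
    dimnames(P) <- ids
    list(matrix = assoc_matrix(X), truth = P, groups = groups)
  })
}

disease_groups <- function(D, n_groups) {
  sort(rep_len(seq_len(n_groups), D))
}

#' Simulate nucleotide sequences carrying the planted disease signal
#'
#' Diseases are partitioned into one group per motif (contiguous blocks
#' of columns).  For each lncRNA, `plant_rate` copies of motif g are
#' planted per realized association in group g; the remainder of the
#' sequence is uniform random A/C/G/T, and motif copies are interleaved
#' uniformly at random with the background.  An lncRNA with no
#' associations is pure background, so its motif counts sit at the
#' background rate.  Thereby the sequence's k-mer composition
#' statistically determines the disease profile.
#'
#' @param spec A [synthetic_spec()] with a non-empty `motif_set`.
#' @param m The realized [assoc_matrix()] from
#'   [simulate_associations()].
#' @return A tibble (`id`, `sequence`) in row order of `m`.
#' @export
simulate_sequences <- function(spec, m) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(spec$motif_set)) abort("spec has no motif_set")
  X <- unclass(m)
  n_g <- length(spec$motif_set)
  groups <- disease_groups(ncol(X), n_g)
  klen <- nchar(spec$motif_set[1])
  counts <- t(vapply(seq_len(nrow(X)), function(i) {
    as.numeric(tapply(X[i, ], groups, sum))
  }, numeric(n_g)))
  copies <- counts * spec$plant_rate
  need <- rowSums(copies) * klen
  if (any(need > spec$seq_len)) {
    bad <- rownames(X)[which.max(need)]
    abort(sprintf("seq_len = %d too short for '%s' (%d motif bases needed)",
                  spec$seq_len, bad, max(need)))
  }
  withr::with_seed(spec$seed + 1L, {
    seqs <- vapply(seq_len(nrow(X)), function(i) {
      units <- c(rep(spec$motif_set, times = copies[i, ]),
                 sample(c("A", "C", "G", "T"),
                        spec$seq_len - sum(copies[i, ]) * klen,
                        replace = TRUE))
      paste(sample(units), collapse = "")
    }, character(1))
  })
  tibble(id = rownames(X), sequence = seqs)
}

#' Write simulated sequences as FASTA
#'
#' @param seqs Tibble (`id`, `sequence`).
#' @param path Output path.
#' @export
write_fasta_sequences <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs$sequence)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Ranking ceiling given the planted truth
#'
#' AUC of the true planted probabilities on a held-out set of positive
#' entries against all never-positive entries: the Bayes-optimal
#' ceiling any trained model's held-out AUC is compared against.
#'
#' @param truth The planted L x D probability matrix.
#' @param m The realized [assoc_matrix()].
#' @param held_out Held-out positive entries: a two-column (row, col)
#'   matrix / data frame, or a vector of linear indices.
#' @return AUC value.
#' @export
truth_auc <- function(truth, m, held_out) {
  X <- unclass(m)
  if (is.data.frame(held_out)) held_out <- as.matrix(held_out[, 1:2])
  idx <- if (is.matrix(held_out)) {
    (held_out[, 2] - 1L) * nrow(X) + held_out[, 1]
  } else {
    held_out
  }
  if (any(X[idx] != 1L)) abort("held_out must be positive entries of m")
  neg <- which(X == 0L)
  roc_auc(c(truth[idx], truth[neg]),
          c(rep(1, length(idx)), rep(0, length(neg))))
}
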