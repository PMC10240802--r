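#' Read lncRNA nucleotide sequences from a FASTA file
#'
#' Sequences are uppercased and RNA-style `U` residues are mapped to `T`,
#' so downstream tokenization works over the DNA alphabet A/C/G/T (plus
#' `N` for ambiguous calls, which never enters a token).
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id` (first word of the header) and
#'   `sequence`, in file order.  An empty file yields an empty tibble.
#' @export
read_fasta_sequences <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(lines))) {
    return(tibble(id = character(0), sequence = character(0)))
  }
  if (!startsWith(trimws(lines[nzchar(trimws(lines))][1]), ">")) {
    abort(sprintf("'%s': sequence line before any FASTA header", path))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  tibble(id = ids, sequence = unname(seqs))
}

#' Split a nucleotide sequence into k-mer tokens
#'
#' Tokens preserve sequence order.  With `stride = 1` (the default) the
#' split is overlapping and yields `nchar(x) - k + 1` tokens; with
#' `stride = k` it is the non-overlapping split and a trailing remainder
#' shorter than `k` is dropped.  Tokens containing `N` are dropped.
#'
#' @param x A single sequence string (A/C/G/T/N after normalization).
#' @param k Substring length (>= 1).
#' @param stride Step between consecutive token starts (>= 1).
#' @param id Optional identifier used in error messages.
#' @return Character vector of k-mer tokens in sequence order.
#' @examples
#' kmer_tokenize("AGCTA", k = 3)            # "AGC" "GCT" "CTA"
#' kmer_tokenize("AGCTA", k = 2, stride = 2) # "AG" "CT"
#' @export
kmer_tokenize <- function(x, k = 3L, stride = 1L, id = NULL) {
  stopifnot(length(x) == 1, k >= 1, stride >= 1)
  n <- nchar(x)
  if (n < k) {
    abort(sprintf("sequence%s of length %d is shorter than k = %d",
                  if (is.null(id)) "" else paste0(" '", id, "'"), n, k))
  }
  starts <- seq.int(1L, n - k + 1L, by = stride)
  tok <- substring(x, starts, starts + k - 1L)
  tok[!grepl("N", tok, fixed = TRUE)]
}

#' Fit a k-mer document embedding over a sequence corpus
#'
#' Learns a fixed-length vector for every k-mer token (and hence, by
#' averaging, for every document) from the document-by-token frequency
#' matrix via a truncated singular value decomposition -- a spectral
#' document embedding in the LSA family.  Token vectors are the leading
#' right singular vectors; a document's vector is the mean of its tokens'
#' vectors, which equals the projection of its token-frequency profile
#' onto the same basis.  Sign of each component is fixed by a
#' deterministic convention (the entry of largest magnitude is made
#' positive), so refitting on the same corpus reproduces identical
#' vectors, and relabelling the vocabulary permutes token vectors without
#' changing them.
#'
#' @param corpus A list of token character vectors, one per document.
#' @param dim Embedding dimension E.  If the corpus supports fewer than
#'   `dim` components, the remaining coordinates are zero.
#' @param seed RNG seed, kept for interface stability; the decomposition
#'   itself is deterministic.
#' @param epochs Unused by the spectral fit; kept for interface
#'   stability with iterative embedding trainers.
#' @return A `kmer_embedding` model: token vocabulary, E, and the
#'   token-by-E matrix of vectors.
#' @export
fit_kmer_embedding <- function(corpus, dim = 64L, seed = 1L, epochs = 40L) {
  if (length(corpus) == 0) abort("corpus is empty")
  if (dim < 1) abort("embedding dimension must be >= 1")
  vocab <- sort(unique(unlist(corpus)))
  if (length(vocab) == 0) abort("corpus contains no tokens")
  X <- matrix(0, length(corpus), length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(corpus)) {
    tb <- table(factor(corpus[[i]], levels = vocab))
    X[i, ] <- as.numeric(tb) / max(1L, length(corpus[[i]]))
  }
  r <- min(dim, nrow(X), ncol(X))
  sv <- svd(X, nu = 0, nv = r)
  V <- sv$v
  # deterministic sign: largest-|.| entry of each component made positive
  for (j in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, j]))
    if (V[piv, j] < 0) V[, j] <- -V[, j]
  }
  tokens <- matrix(0, length(vocab), dim,
                   dimnames = list(vocab, NULL))
  tokens[, seq_len(r)] <- V
  out <- list(vocab = vocab, dim = as.integer(dim), tokens = tokens,
              n_docs = length(corpus), seed = seed)
  class(out) <- "kmer_embedding"
  out
}

#' @export
print.kmer_embedding <- function(x, ...) {
  cat(sprintf("<kmer_embedding> %d tokens -> E = %d (fit on %d documents)\n",
              length(x$vocab), x$dim, x$n_docs))
  invisible(x)
}

#' Embed lncRNA sequences with a fitted k-mer embedding
#'
#' Each sequence is tokenized and its per-token vectors are combined:
#' `mode = "pooled"` (default) returns their mean, a fixed-length E
#' vector per lncRNA; `mode = "stacked"` additionally returns the
#' row-stacked token-vector matrix padded with zero rows (or truncated)
#' to `pad_rows` rows.  Tokens absent from the frozen vocabulary are
#' skipped; a sequence whose tokens are all unknown is an error.
#'
#' @param model A [fit_kmer_embedding()] model.
#' @param seqs Tibble with columns `id`, `sequence` (as returned by
#'   [read_fasta_sequences()]).
#' @param k,stride Tokenization parameters, see [kmer_tokenize()].
#' @param mode `"pooled"` or `"stacked"`.
#' @param pad_rows Row count of the stacked matrix when
#'   `mode = "stacked"`.
#' @return For `"pooled"`, a numeric matrix (lncRNA x E) with sequence
#'   ids as rownames.  For `"stacked"`, a list per lncRNA with elements
#'   `pooled` (E vector) and `stacked` (`pad_rows` x E matrix).
#' @export
embed_sequences <- function(model, seqs, k = 3L, stride = 1L,
                            mode = c("pooled", "stacked"), pad_rows = 256L) {
  stopifnot(inherits(model, "kmer_embedding"))
  mode <- match.arg(mode)
  if (anyDuplicated(seqs$id)) abort("duplicate sequence ids")
  one <- function(id, s) {
    tok <- kmer_tokenize(s, k = k, stride = stride, id = id)
    tok <- tok[tok %in% model$vocab]
    if (length(tok) == 0) {
      abort(sprintf("sequence '%s': no token in the embedding vocabulary", id))
    }
    model$tokens[tok, , drop = FALSE]
  }
  if (mode == "pooled") {
    out <- matrix(0, nrow(seqs), model$dim, dimnames = list(seqs$id, NULL))
    for (i in seq_len(nrow(seqs))) {
      out[i, ] <- colMeans(one(seqs$id[i], seqs$sequence[i]))
    }
    return(out)
  }
  purrr::map(seq_len(nrow(seqs)), function(i) {
    tv <- one(seqs$id[i], seqs$sequence[i])
    st <- matrix(0, pad_rows, model$dim)
    take <- min(nrow(tv), pad_rows)
    st[seq_len(take), ] <- tv[seq_len(take), , drop = FALSE]
    list(id = seqs$id[i], pooled = colMeans(tv), stacked = st)
  })
}

#' Write / read a pooled feature table
#'
#' TSV with an `id` column followed by the E embedding coordinates.
#'
#' @param features Pooled feature matrix from [embed_sequences()].
#' @param path Output path.
#' @export
write_feature_table <- function(features, path) {
  df <- dplyr::bind_cols(tibble(id = rownames(features)),
                         as_tibble(as.data.frame(features),
                                   .name_repair = "minimal"))
  names(df) <- c("id", paste0("e", seq_len(ncol(features))))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  colnames(m) <- NULL
  m
}

#' Shuffle residues within each sequence
#'
#' Permutes the nucleotides of every sequence independently, preserving
#' mononucleotide composition while destroying k-mer (k > 1) structure.
#' The standard null control for sequence-driven predictions.
#'
#' @param seqs Tibble with columns `id`, `sequence`.
#' @param seed RNG seed.
#' @return A tibble of the same shape with shuffled sequences.
#' @export
shuffle_residues <- function(seqs, seed = 1L) {
  withr::with_seed(seed, {
    seqs$sequence <- vapply(seqs$sequence, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  seqs
}
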