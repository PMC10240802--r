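#' Construct an lncRNA-disease association matrix
#'
#' The association matrix is the central container of the package: a 0/1
#' matrix with lncRNAs on the rows and diseases on the columns, where a 1
#' records a curated association and a 0 conflates "no association" with
#' "unknown".  The constructor accepts either an edge table (one row per
#' association, first column the lncRNA identifier, second the disease
#' identifier) or a 0/1 matrix with unique row and column names.
#'
#' Identifiers are matched case-sensitively and axes are sorted
#' lexicographically when built from edges; duplicate edges collapse to a
#' single 1.
#'
#' @param x A data frame of edges or a 0/1 matrix with dimnames.
#' @return An `assoc_matrix`: an integer 0/1 matrix with unique dimnames.
#' @examples
#' edges <- tibble::tibble(lncRNA_id = c("l1", "l1", "l2"),
#'                         disease_id = c("d1", "d2", "d1"))
#' m <- assoc_matrix(edges)
#' sum(m)
#' @export
assoc_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) {
      abort("edge table needs two columns (lncRNA_id, disease_id)")
    }
    lnc <- as.character(x[[1]])
    dis <- as.character(x[[2]])
    if (any(is.na(lnc) | lnc == "") || any(is.na(dis) | dis == "")) {
      abort("edge table contains empty identifiers")
    }
    lnc_ids <- sort(unique(lnc))
    dis_ids <- sort(unique(dis))
    m <- matrix(0L, length(lnc_ids), length(dis_ids),
                dimnames = list(lnc_ids, dis_ids))
    m[cbind(match(lnc, lnc_ids), match(dis, dis_ids))] <- 1L
    return(new_assoc_matrix(m))
  }
  if (is.matrix(x)) {
    return(new_assoc_matrix(x))
  }
  abort("`x` must be an edge data frame or a 0/1 matrix")
}

new_assoc_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort("association matrix needs row (lncRNA) and column (disease) names")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    abort("association matrix identifiers must be unique")
  }
  if (nrow(m) < 1 || ncol(m) < 1) {
    abort("association matrix must have at least one row and column")
  }
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m == 0L | m == 1L)) {
    abort("association matrix entries must be exactly 0 or 1")
  }
  class(m) <- c("assoc_matrix", class(matrix()))
  m
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("<assoc_matrix> %d lncRNAs x %d diseases, %d associations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' @rdname assoc_matrix
#' @export
lnc_ids <- function(x) rownames(x)

#' @rdname assoc_matrix
#' @export
disease_ids <- function(x) colnames(x)

#' Turn an association matrix back into an edge table
#'
#' @param x An `assoc_matrix`.
#' @param ... Ignored.
#' @return A tibble with columns `lncRNA_id`, `disease_id`, one row per
#'   association, ordered by lncRNA then disease.
#' @method as_tibble assoc_matrix
#' @export
as_tibble.assoc_matrix <- function(x, ...) {
  idx <- which(unclass(x) == 1L, arr.ind = TRUE)
  out <- tibble(lncRNA_id = rownames(x)[idx[, 1]],
                disease_id = colnames(x)[idx[, 2]])
  dplyr::arrange(out, .data$lncRNA_id, .data$disease_id)
}

#' Read an edge-list TSV of lncRNA-disease associations
#'
#' The canonical on-disk format: two tab-separated string columns
#' (lncRNA identifier, disease identifier), optionally preceded by a
#' header line `lncRNA_id<TAB>disease_id`.  Duplicate edges collapse to a
#' single association.  Parsing is strict: any line without two non-empty
#' fields raises an error naming the line number.
#'
#' @param path Path to the TSV file.
#' @return An [assoc_matrix()] with sorted-unique identifier axes and an
#'   attribute `n_associations` giving the number of distinct edges.
#' @export
read_association_edges <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  lines <- readLines(path)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    abort(sprintf("'%s' is empty: no associations to read", path))
  }
  start <- 1L
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 2 && identical(tolower(first[1:2]),
                                      c("lncrna_id", "disease_id"))) {
    start <- 2L
  }
  lnc <- character(0)
  dis <- character(0)
  for (i in seq(start, length(lines))) {
    if (!nzchar(trimws(lines[i]))) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2])) {
      abort(sprintf("malformed edge at line %d of '%s': need two non-empty tab-separated fields",
                    i, path))
    }
    lnc <- c(lnc, f[1])
    dis <- c(dis, f[2])
  }
  if (length(lnc) == 0) {
    abort(sprintf("'%s' is empty: no associations to read", path))
  }
  m <- assoc_matrix(tibble(lncRNA_id = lnc, disease_id = dis))
  attr(m, "n_associations") <- sum(m)
  m
}

#' Write an association matrix as an edge-list TSV
#'
#' @param m An [assoc_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_edges <- function(m, path) {
  readr::write_tsv(as_tibble(m), path)
  invisible(path)
}

#' Read / write a dense labelled 0/1 association matrix as CSV
#'
#' Secondary on-disk format: a CSV whose first column holds lncRNA
#' identifiers and whose remaining column names are disease identifiers.
#'
#' @param path CSV path.
#' @return An [assoc_matrix()].
#' @export
read_association_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  assoc_matrix(m)
}

#' @rdname read_association_csv
#' @param m An [assoc_matrix()].
#' @export
write_association_csv <- function(m, path) {
  df <- dplyr::bind_cols(tibble(lncRNA_id = rownames(m)),
                         as_tibble(as.data.frame(unclass(m))))
  readr::write_csv(df, path)
  invisible(path)
}

#' Partition the positive entries into cross-validation folds
#'
#' Positive entries (associations) are shuffled with the given seed and
#' dealt round-robin into `k` folds, so fold sizes differ by at most one.
#' Folds are over entries, not over lncRNA rows, matching entry-level
#' evaluation.  Fold indices are 1-based.
#'
#' @param m An [assoc_matrix()].
#' @param k Number of folds (>= 2).
#' @param seed RNG seed; the split is deterministic given the seed.
#' @return A `fold_split`: list with `k` and `assignments`, a tibble with
#'   columns `lncRNA_id`, `disease_id`, `row`, `col`, `fold`.
#' @export
kfold_split <- function(m, k, seed = 1L) {
  stopifnot(inherits(m, "assoc_matrix"))
  if (k < 2) abort("`k` must be at least 2")
  pos <- which(unclass(m) == 1L, arr.ind = TRUE)
  n <- nrow(pos)
  if (n < k) abort(sprintf("cannot split %d positives into %d folds", n, k))
  ord <- withr::with_seed(seed, sample.int(n))
  pos <- pos[ord, , drop = FALSE]
  fold <- rep_len(seq_len(k), n)
  out <- list(
    k = as.integer(k),
    assignments = tibble(
      lncRNA_id = rownames(m)[pos[, 1]],
      disease_id = colnames(m)[pos[, 2]],
      row = as.integer(pos[, 1]),
      col = as.integer(pos[, 2]),
      fold = as.integer(fold)
    )
  )
  class(out) <- "fold_split"
  out
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d positives in %d folds\n",
              nrow(x$assignments), x$k))
  invisible(x)
}

#' Mask the test fold of a split out of an association matrix
#'
#' Returns a training matrix equal to `m` with the positive entries of
#' fold `fold` set to 0; `m` itself is unmodified and no entry is ever
#' turned into a 1.
#'
#' @param m The full [assoc_matrix()] the split was built from.
#' @param split A [kfold_split()] result.
#' @param fold Fold index in `1..k`.
#' @return An [assoc_matrix()] with the test fold zeroed.
#' @export
mask_test_fold <- function(m, split, fold) {
  stopifnot(inherits(split, "fold_split"))
  if (!(fold %in% seq_len(split$k))) {
    abort(sprintf("fold must be in 1..%d, got %s", split$k, fold))
  }
  a <- dplyr::filter(split$assignments, .data$fold == !!fold)
  out <- unclass(m)
  out[cbind(a$row, a$col)] <- 0L
  new_assoc_matrix(out)
}
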