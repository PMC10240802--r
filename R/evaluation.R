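#' Area under the ROC curve
#'
#' Computed in the rank (Mann-Whitney) form: the probability that a
#' random positive outscores a random negative, with ties credited 0.5.
#' Equivalent to trapezoidal integration of the ROC curve and invariant
#' under strictly increasing transforms of the scores.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 labels of the same length; both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0))  # 1
#' roc_auc(c(0.5, 0.5), c(1, 0))          # 0.5
#' @export
roc_auc <- function(scores, labels) {
  check_binary(scores, labels, need_both = TRUE)
  r <- rank(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Area of the precision-recall step curve over all distinct score
#' thresholds (descending), i.e. the sum of precision times the recall
#' increment at each threshold -- the tie-aware average-precision form.
#'
#' @inheritParams roc_auc
#' @return AUPR in (0, 1\]; requires at least one positive.
#' @export
aupr <- function(scores, labels) {
  check_binary(scores, labels, need_both = FALSE)
  if (sum(labels == 1) == 0) abort("aupr needs at least one positive label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group ties: cumulative counts at each distinct threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  n_pred <- last
  prec <- tp / n_pred
  rec <- tp / sum(labels == 1)
  sum(diff(c(0, rec)) * prec)
}

check_binary <- function(scores, labels, need_both) {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length")
  }
  if (!all(labels %in% c(0, 1))) abort("labels must be 0 or 1")
  if (need_both && (all(labels == 1) || all(labels == 0))) {
    abort("both classes must be present")
  }
  invisible(TRUE)
}

#' Confusion-curve points over all thresholds
#'
#' One row per distinct score threshold (descending): entries scoring
#' at or above the threshold are predicted positive.  Reports FPR =
#' FP/(TN+FP), TPR = recall = TP/(TP+FN) and precision = TP/(TP+FP).
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `fpr`, `tpr`, `recall`, `precision`.
#' @export
curve_points <- function(scores, labels) {
  check_binary(scores, labels, need_both = TRUE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- last - tp
  P <- sum(labels == 1); N <- sum(labels == 0)
  tibble(threshold = s[last], tp = tp, fp = fp,
         tn = N - fp, fn = P - tp,
         fpr = fp / N, tpr = tp / P, recall = tp / P,
         precision = tp / last)
}

#' Entry-level k-fold cross-validation
#'
#' Positive entries are partitioned into `k` folds; for each fold the
#' model is trained on the matrix with that fold's positives masked to
#' 0, every entry is scored, and the held-out positives are ranked
#' against all never-positive entries (entries that are 0 in the full
#' matrix; training positives are excluded from evaluation).  Reports
#' per-fold and mean AUC / AUPR.
#'
#' @param m The full [assoc_matrix()].
#' @param features Optional pooled sequence features (sequence mode).
#' @param config A [gan_config()]; each fold trains with seed
#'   `config$seed + fold`.
#' @param k Number of folds.
#' @param seed Seed of the fold split.
#' @param scorer Scoring backend: a
#'   `function(train_matrix, features, config)` returning an L x D
#'   score matrix.  The default trains an [ldaf_gan()] on the training
#'   matrix and scores it with [score_associations()]; supplying e.g. an
#'   oracle or random scorer gives reference points.
#' @return An `ldaf_cv` object: tibble of per-fold metrics, their
#'   means, and the split parameters.
#' @export
cross_validate <- function(m, features = NULL, config = gan_config(),
                           k = 5L, seed = 1L, scorer = NULL) {
  if (k < 2) abort("`k` must be at least 2")
  split <- kfold_split(m, k, seed = seed)
  scorer <- scorer %||% gan_scorer()
  never_pos <- which(unclass(m) == 0L)
  folds <- purrr::map_dfr(seq_len(k), function(f) {
    train <- mask_test_fold(m, split, f)
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    S <- scorer(train, features, cfg_f)
    a <- dplyr::filter(split$assignments, .data$fold == f)
    test_idx <- (a$col - 1L) * nrow(m) + a$row
    sc <- c(S[test_idx], S[never_pos])
    lb <- c(rep(1, length(test_idx)), rep(0, length(never_pos)))
    tibble(fold = f, n_test = length(test_idx),
           auc = roc_auc(sc, lb), aupr = aupr(sc, lb))
  })
  out <- list(folds = folds, mean_auc = mean(folds$auc),
              mean_aupr = mean(folds$aupr), k = as.integer(k),
              seed = seed, split = split)
  class(out) <- "ldaf_cv"
  out
}

#' Scoring backends for [cross_validate()]
#'
#' `gan_scorer()` trains the adversarial model on each fold's training
#' matrix and scores with [score_associations()].  `oracle_scorer(P)`
#' returns the fixed matrix `P` (e.g. the planted truth, an upper
#' bound).  `random_scorer(seed)` returns uniform noise (the
#' permutation-null reference).
#'
#' @return A `function(train_matrix, features, config)` usable as the
#'   `scorer` argument of [cross_validate()].
#' @export
gan_scorer <- function() {
  function(train, features, config) {
    model <- ldaf_gan(train, features = features, config = config)
    score_associations(model, m = train, features = features,
                       seed = config$seed)
  }
}

#' @rdname gan_scorer
#' @param P Fixed score matrix to return.
#' @export
oracle_scorer <- function(P) function(train, features, config) P

#' @rdname gan_scorer
#' @param seed RNG seed of the uniform scores.
#' @export
random_scorer <- function(seed = 1L) {
  function(train, features, config) {
    withr::with_seed(seed + config$seed,
      matrix(runif(length(train)), nrow(train), ncol(train),
             dimnames = dimnames(train)))
  }
}

#' @export
print.ldaf_cv <- function(x, ...) {
  cat(sprintf("<ldaf_cv> %d-fold: mean AUC %.4f, mean AUPR %.4f\n",
              x$k, x$mean_auc, x$mean_aupr))
  print(x$folds)
  invisible(x)
}

#' Write a cross-validation report as TSV
#'
#' One row per fold plus a `mean` summary row.
#'
#' @param cv An `ldaf_cv` object.
#' @param path Output path.
#' @export
write_cv_report <- function(cv, path) {
  df <- dplyr::bind_rows(
    dplyr::mutate(cv$folds, fold = as.character(.data$fold)),
    tibble(fold = "mean", n_test = sum(cv$folds$n_test),
           auc = cv$mean_auc, aupr = cv$mean_aupr))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Cold-start evaluation of the sequence-conditioned model
#'
#' Holds a set of lncRNAs out of training entirely, fits the k-mer
#' embedding on the training sequences only, trains the
#' sequence-conditioned model on the remaining rows, then scores each
#' held-out lncRNA from its sequence feature alone ([predict_new()]
#' protocol), ranking its realized positives against its zeros; the
#' reported AUC/AUPR are macro-averages over the held-out lncRNAs with
#' both classes present.  With `shuffle_heldout = TRUE` the held-out
#' sequences are residue-shuffled first -- the null control in which
#' the sequence carries no k-mer signal.
#'
#' @param m Full [assoc_matrix()] including the held-out rows.
#' @param seqs Sequence tibble (`id`, `sequence`) covering all rows.
#' @param holdout Character vector of lncRNA ids to hold out, or an
#'   integer count to sample (seeded).
#' @param config A [gan_config()] with `use_sequence = TRUE`.
#' @param k,stride,embed_dim Tokenization / embedding parameters.
#' @param seed Seed for hold-out sampling, prediction noise and the
#'   shuffle control.
#' @param shuffle_heldout Residue-shuffle the held-out sequences before
#'   embedding (null control).  Training never sees the held-out
#'   sequences, so the same trained model serves both the primary and
#'   the shuffled evaluation; `with_null = TRUE` reports both at once.
#' @param with_null Also evaluate the residue-shuffled null through the
#'   same trained model, reported as `null_auc` / `null_aupr`.
#' @param draws Noise draws averaged per held-out prediction.
#' @return List with `auc`, `aupr` (and `null_auc`, `null_aupr` when
#'   requested), the held-out ids, and the trained model.
#' @export
evaluate_cold_start <- function(m, seqs, holdout = 20L,
                                config = gan_config(use_sequence = TRUE),
                                k = 3L, stride = 1L, embed_dim = 64L,
                                seed = 1L, shuffle_heldout = FALSE,
                                with_null = FALSE, draws = 8L) {
  if (!config$use_sequence) abort("config must have use_sequence = TRUE")
  ids <- rownames(m)
  if (is.numeric(holdout)) {
    holdout <- withr::with_seed(seed, sample(ids, holdout))
  }
  if (!all(holdout %in% ids)) abort("holdout ids not in the matrix")
  train_ids <- setdiff(ids, holdout)
  seqs_train <- dplyr::filter(seqs, .data$id %in% train_ids)
  seqs_hold <- dplyr::filter(seqs, .data$id %in% holdout)
  if (shuffle_heldout) {
    seqs_hold <- shuffle_residues(seqs_hold, seed = seed + 1L)
  }
  corpus <- purrr::map(seqs_train$sequence, kmer_tokenize,
                       k = k, stride = stride)
  emb <- fit_kmer_embedding(corpus, dim = embed_dim, seed = seed)
  feats <- embed_sequences(emb, dplyr::bind_rows(seqs_train, seqs_hold),
                           k = k, stride = stride)
  m_train <- assoc_matrix(unclass(m)[train_ids, , drop = FALSE])
  model <- ldaf_gan(m_train, features = feats, config = config)
  X_hold <- unclass(m)[holdout, , drop = FALSE]

  # macro-average over held-out lncRNAs: each row is ranked internally,
  # so a global score shift for one lncRNA cannot masquerade as signal
  score_holdout <- function(hold_feats) {
    aucs <- numeric(0); auprs <- numeric(0)
    for (i in seq_along(holdout)) {
      y <- X_hold[i, ]
      if (sum(y) == 0 || sum(y) == length(y)) next
      pr <- predict_new(model, hold_feats[holdout[i], ], top_k = ncol(m),
                        seed = seed + i, draws = draws)
      s <- pr$entries$score[match(colnames(m), pr$entries$disease_id)]
      aucs <- c(aucs, roc_auc(s, y))
      auprs <- c(auprs, aupr(s, y))
    }
    list(auc = mean(aucs), aupr = mean(auprs), n_rows = length(aucs))
  }

  out <- score_holdout(feats)
  out$holdout <- holdout
  out$model <- model
  if (with_null) {
    shuf <- shuffle_residues(seqs_hold, seed = seed + 1L)
    null_feats <- embed_sequences(emb, shuf, k = k, stride = stride)
    nl <- score_holdout(null_feats)
    out$null_auc <- nl$auc
    out$null_aupr <- nl$aupr
  }
  out
}
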