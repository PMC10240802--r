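#' Rank diseases for an lncRNA with known associations
#'
#' The case-study protocol for lncRNAs already in the training matrix:
#' the known 0/1 association vector is fed into the generator in place
#' of its stochastic input, the output is normalised to scores in
#' (0,1), diseases already known to be associated are excluded, and the
#' remaining diseases are ranked by descending score (ties broken by
#' disease order).
#'
#' @param model A trained [ldaf_gan()] in no-sequence mode with
#'   `noise_dim` equal to the disease count.
#' @param known_row 0/1 vector of length D (optionally named by
#'   disease); 1 marks known associations.
#' @param top_k Number of predictions to return.  If fewer unknown
#'   diseases remain, the list is truncated with a warning.
#' @param draws Noise draws averaged into the input when > 0: the
#'   alternative protocol feeding `known_row` plus seeded Gaussian
#'   noise, averaged over `draws` (default 0, the literal protocol).
#' @param seed Seed for the optional noise draws.
#' @return A `ranked_predictions` object: `entries` tibble
#'   (`disease_id`, `score`, `rank`) and `excluded` (known diseases).
#' @export
predict_known <- function(model, known_row, top_k = 10L,
                          draws = 0L, seed = 1L) {
  if (model$config$use_sequence) {
    abort("predict_known applies to the no-sequence model; use predict_new")
  }
  if (length(known_row) != model$dims$D) {
    abort(sprintf("known_row has length %d, expected %d",
                  length(known_row), model$dims$D))
  }
  if (model$dims$noise_dim != model$dims$D) {
    abort("predict_known needs noise_dim equal to the disease count")
  }
  if (!all(known_row %in% c(0, 1))) abort("known_row must be 0/1")
  x <- as.numeric(known_row)
  if (draws > 0) {
    S <- matrix(0, 1, model$dims$D)
    for (d in seq_len(draws)) {
      z <- x + sample_noise(1, model$dims$D, seed = seed + d - 1L,
                            sd = model$config$noise_sd)
      S <- S + generator_forward(model, z)$scores
    }
    scores <- as.vector(S / draws)
  } else {
    scores <- as.vector(generator_forward(model, x)$scores)
  }
  excluded <- model$disease_ids[known_row == 1]
  rank_predictions(scores, model$disease_ids, excluded, top_k,
                   lnc_id = NA_character_)
}

#' Rank diseases for a new lncRNA from its sequence feature
#'
#' The cold-start protocol: seeded random noise is concatenated with
#' the lncRNA's sequence feature and fed through the trained
#' sequence-conditioned generator; all D diseases are ranked (nothing
#' is excluded -- the lncRNA has no known associations).
#'
#' @param model A trained [ldaf_gan()] with `use_sequence = TRUE`.
#' @param feature Pooled sequence feature vector of length E.
#' @param top_k Number of predictions to return.
#' @param seed Seed of the noise draw(s); identical seeds give
#'   identical rankings.
#' @param draws Number of noise draws whose scores are averaged
#'   (default 1, the single-draw protocol).
#' @return A `ranked_predictions` object.
#' @export
predict_new <- function(model, feature, top_k = 10L, seed = 1L,
                        draws = 1L) {
  if (!model$config$use_sequence) {
    abort("model was not trained in sequence mode")
  }
  if (length(feature) != model$dims$E) {
    abort(sprintf("feature has length %d, expected %d",
                  length(feature), model$dims$E))
  }
  C <- matrix(as.numeric(feature), 1, model$dims$E)
  S <- matrix(0, 1, model$dims$D)
  for (d in seq_len(draws)) {
    z <- sample_noise(1, model$dims$noise_dim, seed = seed + d - 1L)
    S <- S + generator_forward(model, z, C)$scores
  }
  rank_predictions(as.vector(S / draws), model$disease_ids,
                   excluded = character(0), top_k,
                   lnc_id = NA_character_)
}

rank_predictions <- function(scores, disease_ids, excluded, top_k,
                             lnc_id = NA_character_) {
  keep <- !(disease_ids %in% excluded)
  df <- tibble(disease_id = disease_ids[keep], score = scores[keep])
  # descending score, ties broken by disease position for reproducibility
  df <- df[order(-df$score, seq_len(nrow(df))), ]
  if (top_k > nrow(df)) {
    warn(sprintf("only %d unknown diseases available; truncating top_k = %d",
                 nrow(df), top_k))
    top_k <- nrow(df)
  }
  df <- utils::head(df, top_k)
  df$rank <- seq_len(nrow(df))
  out <- list(lnc_id = lnc_id, entries = df, excluded = excluded)
  class(out) <- "ranked_predictions"
  out
}

#' @export
print.ranked_predictions <- function(x, ...) {
  cat(sprintf("<ranked_predictions>%s %d diseases ranked, %d excluded as known\n",
              if (is.na(x$lnc_id)) "" else paste0(" ", x$lnc_id, ":"),
              nrow(x$entries), length(x$excluded)))
  print(x$entries)
  invisible(x)
}

#' Write ranked predictions as TSV
#'
#' @param pred A `ranked_predictions` object.
#' @param path Output path.
#' @param lnc_id Identifier written in the first column.
#' @export
write_predictions <- function(pred, path, lnc_id = pred$lnc_id) {
  df <- dplyr::mutate(pred$entries, lnc_id = lnc_id, .before = 1)
  readr::write_tsv(df, path)
  invisible(path)
}
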