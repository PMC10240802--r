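#' Tidy a fitted adversarial model
#'
#' Returns the per-epoch loss log in long-friendly wide form.
#'
#' @param x An [ldaf_gan()] model.
#' @param ... Ignored.
#' @return Tibble with columns `epoch`, `g_loss`, `d_loss`.
#' @method tidy ldaf_gan
#' @export
tidy.ldaf_gan <- function(x, ...) x$loss_log

#' @rdname tidy.ldaf_gan
#' @method glance ldaf_gan
#' @export
glance.ldaf_gan <- function(x, ...) {
  tibble(
    n_lnc = x$dims$L, n_disease = x$dims$D,
    use_sequence = x$config$use_sequence,
    input_mode = x$config$input_mode,
    alpha = x$config$alpha,
    epochs = nrow(x$loss_log),
    final_g_loss = if (nrow(x$loss_log)) x$loss_log$g_loss[nrow(x$loss_log)]
                   else NA_real_,
    final_d_loss = if (nrow(x$loss_log)) x$loss_log$d_loss[nrow(x$loss_log)]
                   else NA_real_
  )
}

#' Tidy cross-validation results
#'
#' @param x An `ldaf_cv` from [cross_validate()].
#' @param ... Ignored.
#' @return Per-fold tibble (`fold`, `n_test`, `auc`, `aupr`).
#' @method tidy ldaf_cv
#' @export
tidy.ldaf_cv <- function(x, ...) x$folds

#' @rdname tidy.ldaf_cv
#' @method glance ldaf_cv
#' @export
glance.ldaf_cv <- function(x, ...) {
  tibble(k = x$k, mean_auc = x$mean_auc, mean_aupr = x$mean_aupr,
         sd_auc = sd(x$folds$auc), sd_aupr = sd(x$folds$aupr))
}

#' Tidy ranked predictions
#'
#' @param x A `ranked_predictions` object.
#' @param ... Ignored.
#' @return The entries tibble (`disease_id`, `score`, `rank`).
#' @method tidy ranked_predictions
#' @export
tidy.ranked_predictions <- function(x, ...) x$entries
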