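#' Plot training losses
#'
#' Generator and discriminator loss per epoch.
#'
#' @param object An [ldaf_gan()] model.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot ldaf_gan
#' @export
autoplot.ldaf_gan <- function(object, ...) {
  df <- tidyr::pivot_longer(object$loss_log, c("g_loss", "d_loss"),
                            names_to = "network", values_to = "loss")
  ggplot(df, aes(x = .data$epoch, y = .data$loss,
                 colour = .data$network)) +
    geom_line() +
    scale_colour_manual(values = c(g_loss = "#D55E00", d_loss = "#0072B2"),
                        labels = c(g_loss = "generator",
                                   d_loss = "discriminator")) +
    labs(x = "epoch", y = "loss", colour = NULL) +
    theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `ldaf_cv` from [cross_validate()].
#' @param ... Ignored.
#' @return A ggplot of per-fold AUC and AUPR with mean lines.
#' @method autoplot ldaf_cv
#' @export
autoplot.ldaf_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds, c("auc", "aupr"),
                            names_to = "metric", values_to = "value")
  means <- tibble(metric = c("auc", "aupr"),
                  value = c(object$mean_auc, object$mean_aupr))
  ggplot(df, aes(x = factor(.data$fold), y = .data$value)) +
    geom_col(fill = "#0072B2") +
    geom_hline(data = means, aes(yintercept = .data$value),
               linetype = 2, colour = "#D55E00") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "fold", y = NULL) +
    theme_minimal()
}

#' ROC and precision-recall curves for a scored evaluation
#'
#' @param scores,labels As in [roc_auc()].
#' @param type `"roc"` or `"pr"`.
#' @return A ggplot of the chosen curve.
#' @export
plot_curve <- function(scores, labels, type = c("roc", "pr")) {
  type <- match.arg(type)
  pts <- curve_points(scores, labels)
  if (type == "roc") {
    ggplot(pts, aes(x = .data$fpr, y = .data$tpr)) +
      geom_step() +
      geom_abline(slope = 1, intercept = 0, linetype = 3) +
      labs(x = "false positive rate", y = "true positive rate") +
      theme_minimal()
  } else {
    ggplot(pts, aes(x = .data$recall, y = .data$precision)) +
      geom_step(direction = "vh") +
      labs(x = "recall", y = "precision") +
      theme_minimal()
  }
}
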