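#' Training configuration for the adversarial model
#'
#' Collects every tunable of the generator/discriminator pair and the
#' training loop.  Defaults are desk-scale: two rectified hidden layers
#' per network, Adam full-batch updates, balanced per-row negative
#' sampling, and the squared-error regulariser at `alpha = 0.1`.
#'
#' @param noise_dim Length of the generator's stochastic input `z`.
#'   `NULL` (default) resolves to the disease count D at fit time, so the
#'   generator input and output dimensions agree and a known association
#'   row can be fed in place of noise at inference.
#' @param hidden_g,hidden_d Hidden layer widths of generator and
#'   discriminator.
#' @param alpha Weight of the reconstruction regulariser that ties
#'   generated scores to 1 on positives and 0 on sampled negatives
#'   (>= 0).
#' @param n_sample Negatives sampled per lncRNA row.  `NULL` (default)
#'   uses the balanced rule: as many negatives as the row has positives,
#'   floor 1.  `0` disables negative sampling (the filtering mask then
#'   reduces to the known positives).
#' @param lr_g,lr_d Adam step sizes for generator and discriminator.
#' @param epochs Training epochs (full-batch alternating updates).
#' @param seed RNG seed; the whole run is deterministic given the seed.
#' @param normalization `"sigmoid"` (default) maps each generated score
#'   independently into (0,1), so positives can approach 1 while sampled
#'   negatives approach 0; `"softmax"` normalises each row to sum to 1
#'   (the literal row-normalised reading).
#' @param use_sequence Condition both networks on a per-lncRNA sequence
#'   feature vector (the sequence-fused variant).
#' @param input_mode Generator input for the no-sequence model:
#'   `"row"` (default) feeds the lncRNA's training association row under
#'   dropout corruption plus additive Gaussian noise, the conditioned
#'   protocol that supports per-lncRNA prediction and matches feeding a
#'   known association vector at inference; `"noise"` feeds pure
#'   Gaussian noise (the unconditioned protocol).  Sequence mode always
#'   uses `"noise"` (row identity enters through the sequence feature).
#' @param input_dropout In `input_mode = "row"`, the probability that a
#'   positive input entry is zeroed during training (denoising
#'   corruption, preventing an identity shortcut).
#' @param noise_sd Standard deviation of the additive Gaussian noise on
#'   the conditioned input (row mode), and of `z` itself in noise mode
#'   (where it is fixed at 1).
#' @param filter_mode Mask used by the association filter on generated
#'   rows before the discriminator: `"sample"` (default) keeps positives
#'   plus sampled negatives; `"positives"` keeps known positives only.
#' @param resample_negatives Resample the per-row negatives every epoch
#'   (default) or fix one mask for the whole run.
#' @param feat_hidden Width of the sequence-feature sub-network present
#'   in both networks in sequence mode.
#' @param n_draws Noise draws averaged when scoring with a stochastic
#'   input (noise or sequence mode).
#' @return A validated `gan_config` list.
#' @export
gan_config <- function(noise_dim = NULL,
                       hidden_g = c(128L, 256L),
                       hidden_d = c(256L, 128L),
                       alpha = 0.1,
                       n_sample = NULL,
                       lr_g = 1e-3,
                       lr_d = 1e-3,
                       epochs = 800L,
                       seed = 1L,
                       normalization = c("sigmoid", "softmax"),
                       use_sequence = FALSE,
                       input_mode = NULL,
                       input_dropout = 0.5,
                       noise_sd = 0.1,
                       filter_mode = c("sample", "positives"),
                       resample_negatives = TRUE,
                       feat_hidden = 128L,
                       n_draws = 8L) {
  normalization <- match.arg(normalization)
  filter_mode <- match.arg(filter_mode)
  if (is.null(input_mode)) input_mode <- if (use_sequence) "noise" else "row"
  input_mode <- match.arg(input_mode, c("row", "noise"))
  if (use_sequence && input_mode == "row") {
    abort("sequence mode uses input_mode = \"noise\"")
  }
  if (alpha < 0) abort("alpha must be >= 0")
  if (!is.null(n_sample) && n_sample < 0) abort("n_sample must be >= 0")
  if (!is.null(noise_dim) && noise_dim < 1) abort("noise_dim must be >= 1")
  if (epochs < 0) abort("epochs must be >= 0")
  out <- list(noise_dim = noise_dim, hidden_g = hidden_g,
              hidden_d = hidden_d, alpha = alpha, n_sample = n_sample,
              lr_g = lr_g, lr_d = lr_d, epochs = as.integer(epochs),
              seed = as.integer(seed), normalization = normalization,
              use_sequence = use_sequence, input_mode = input_mode,
              input_dropout = input_dropout, noise_sd = noise_sd,
              filter_mode = filter_mode,
              resample_negatives = resample_negatives,
              feat_hidden = as.integer(feat_hidden),
              n_draws = as.integer(n_draws))
  class(out) <- "gan_config"
  out
}

#' Read / write a training configuration as YAML
#'
#' @param path YAML file of `gan_config` fields; unknown keys are
#'   rejected.
#' @return A [gan_config()].
#' @export
read_gan_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(gan_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  }
  do.call(gan_config, vals)
}

#' @rdname read_gan_config
#' @param config A [gan_config()].
#' @export
write_gan_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}
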