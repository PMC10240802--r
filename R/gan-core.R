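#' Draw generator noise vectors
#'
#' Independent standard-normal draws, deterministic for a fixed seed.
#'
#' @param n_rows Number of vectors.
#' @param noise_dim Length of each vector.
#' @param seed RNG seed.
#' @param sd Standard deviation of the draws.
#' @return An `n_rows` x `noise_dim` matrix.
#' @export
sample_noise <- function(n_rows, noise_dim, seed = 1L, sd = 1) {
  stopifnot(n_rows >= 1, noise_dim >= 1)
  withr::with_seed(seed,
    matrix(rnorm(n_rows * noise_dim, sd = sd), n_rows, noise_dim))
}

#' Sample per-row negative entries from the unknown region
#'
#' For every lncRNA row, draws `n_sample` of its 0-entries uniformly
#' without replacement and marks them as assumed non-associations.  The
#' combined mask (positives plus sampled negatives) is the association
#' filter used before the discriminator, and the target matrix carries
#' the regulariser's targets: 1 on positives, 0 on sampled negatives.
#'
#' @param m An [assoc_matrix()] (or 0/1 matrix).
#' @param n_sample Negatives per row; `NULL` for the balanced rule
#'   (row's positive count, floor 1); rows with fewer zeros take all
#'   their zeros.
#' @param seed RNG seed.
#' @return A `negative_mask`: list of 0/1 matrices `positives`,
#'   `sampled`, `combined` and `target` (= `positives`).
#' @export
sample_negatives <- function(m, n_sample = NULL, seed = 1L) {
  X <- unclass(m)
  L <- nrow(X); D <- ncol(X)
  pos_count <- rowSums(X)
  n_per_row <- if (is.null(n_sample)) pmax(1L, pos_count)
               else rep(as.integer(n_sample), L)
  sampled <- matrix(0L, L, D, dimnames = dimnames(X))
  withr::with_seed(seed, {
    for (i in seq_len(L)) {
      zeros <- which(X[i, ] == 0L)
      take <- min(n_per_row[i], length(zeros))
      if (take > 0) {
        sampled[i, zeros[sample.int(length(zeros), take)]] <- 1L
      }
    }
  })
  out <- list(positives = X, sampled = sampled,
              combined = pmax(X, sampled), target = X)
  class(out) <- "negative_mask"
  out
}

#' Association filtering (FUA)
#'
#' Elementwise product of generated scores with the 0/1 mask of entries
#' whose status is defined (known positives, plus sampled negatives when
#' negative sampling is on), so the discriminator only sees those
#' entries.  Idempotent for a fixed mask.
#'
#' @param scores Numeric vector or matrix of generated scores.
#' @param mask 0/1 vector or matrix of the same shape (or a
#'   `negative_mask`, whose `combined` matrix is used).
#' @return `scores * mask`.
#' @export
fua_filter <- function(scores, mask) {
  if (inherits(mask, "negative_mask")) mask <- mask$combined
  if (length(scores) != length(mask)) {
    abort("scores and mask have different lengths")
  }
  scores * mask
}

#' Reconstruction regulariser of the generator loss
#'
#' `alpha` times the batch mean of the per-row squared error between the
#' 0/1 target (1 on positives, 0 on sampled negatives) and the generated
#' scores, summed over the defined entries only.  Exactly 0 when the
#' scores match the targets on every masked entry.
#'
#' @param scores Generated score matrix (rows matching the mask).
#' @param mask A [sample_negatives()] mask.
#' @param alpha Regulariser weight.
#' @return Scalar penalty.
#' @export
regular_term <- function(scores, mask, alpha) {
  stopifnot(inherits(mask, "negative_mask"))
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  alpha * mean(rowSums(mask$combined * (mask$target - scores)^2))
}

resolve_dims <- function(m, features, config) {
  D <- ncol(m)
  noise_dim <- config$noise_dim %||% D
  if (config$input_mode == "row" && noise_dim != D) {
    abort("input_mode = \"row\" requires noise_dim equal to the disease count")
  }
  E <- if (config$use_sequence) ncol(features) else 0L
  list(L = nrow(m), D = D, E = E, noise_dim = as.integer(noise_dim))
}

init_gan <- function(dims, config) {
  g_in <- dims$noise_dim + if (config$use_sequence) config$feat_hidden else 0L
  d_in <- dims$D + if (config$use_sequence) config$feat_hidden else 0L
  withr::with_seed(config$seed, {
    gen <- list(
      feat = if (config$use_sequence) mlp_init(c(dims$E, config$feat_hidden)),
      main = mlp_init(c(g_in, config$hidden_g, dims$D))
    )
    dis <- list(
      feat = if (config$use_sequence) mlp_init(c(dims$E, config$feat_hidden)),
      main = mlp_init(c(d_in, config$hidden_d, 1L))
    )
    list(generator = gen, discriminator = dis)
  })
}

feat_forward <- function(layers, X) {
  fw <- mlp_forward(layers, X)
  list(out = pmax(fw$out, 0), acts = fw$acts, pre = fw$out)
}

normalize_scores <- function(raw, normalization) {
  if (normalization == "softmax") row_softmax(raw) else sigmoid(raw)
}

standardize_feats <- function(model, c_seq) {
  # feature coordinates live on the embedding's scale, far below the
  # unit-variance noise; standardize with the moments of the training
  # features so the feature pathway carries comparable signal
  if (is.null(model$feat_center)) return(c_seq)
  sweep(sweep(c_seq, 2L, model$feat_center, "-"), 2L, model$feat_scale, "/")
}

gen_forward_full <- function(model, z, c_seq = NULL) {
  cfg <- model$config
  if (cfg$use_sequence) {
    if (is.null(c_seq)) abort("sequence mode needs c_seq features")
    if (ncol(c_seq) != model$dims$E) {
      abort(sprintf("c_seq has dimension %d, expected %d",
                    ncol(c_seq), model$dims$E))
    }
    c_seq <- standardize_feats(model, c_seq)
    fc <- feat_forward(model$generator$feat, c_seq)
    inp <- cbind(z, fc$out)
  } else {
    fc <- NULL
    inp <- z
  }
  if (ncol(inp) != model$dims$noise_dim +
      (if (cfg$use_sequence) cfg$feat_hidden else 0L)) {
    abort("generator input dimension mismatch")
  }
  fw <- mlp_forward(model$generator$main, inp)
  list(raw = fw$out,
       scores = normalize_scores(fw$out, cfg$normalization),
       acts = fw$acts, feat = fc)
}

dis_forward_full <- function(model, v, c_seq = NULL) {
  cfg <- model$config
  if (!is.matrix(v)) v <- matrix(v, nrow = 1)
  if (ncol(v) != model$dims$D) {
    abort(sprintf("discriminator input has length %d, expected %d",
                  ncol(v), model$dims$D))
  }
  if (cfg$use_sequence) {
    if (is.null(c_seq)) abort("sequence mode needs c_seq features")
    c_seq <- standardize_feats(model, c_seq)
    fc <- feat_forward(model$discriminator$feat, c_seq)
    inp <- cbind(v, fc$out)
  } else {
    fc <- NULL
    inp <- v
  }
  fw <- mlp_forward(model$discriminator$main, inp)
  list(p = as.vector(sigmoid(fw$out)), logit = fw$out,
       acts = fw$acts, feat = fc)
}

#' Generator forward pass
#'
#' Maps a batch of input vectors (noise, a corrupted or known
#' association row, optionally concatenated with the extracted sequence
#' feature) to a disease-score row each.  Scores lie strictly in (0,1):
#' elementwise under `"sigmoid"` normalisation, summing to 1 per row
#' under `"softmax"`.
#'
#' @param model A fitted or initialised [ldaf_gan()] model.
#' @param z Input matrix (rows = batch) or single vector of length
#'   `noise_dim`.
#' @param c_seq Sequence feature matrix (rows matching `z`) in sequence
#'   mode.
#' @return List with `raw` (pre-normalisation) and `scores` matrices,
#'   one row per input, D columns.
#' @export
generator_forward <- function(model, z, c_seq = NULL) {
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  if (!is.null(c_seq) && !is.matrix(c_seq)) c_seq <- matrix(c_seq, nrow = 1)
  fw <- gen_forward_full(model, z, c_seq)
  list(raw = fw$raw, scores = fw$scores)
}

#' Discriminator forward pass
#'
#' Scores each input row (a real association row or a filtered generated
#' row, optionally conditioned on the sequence feature) with a single
#' probability in (0,1).
#'
#' @inheritParams generator_forward
#' @param v Input matrix (rows = batch) or single vector of length D.
#' @return Numeric vector of probabilities, one per row.
#' @export
discriminator_forward <- function(model, v, c_seq = NULL) {
  if (!is.null(c_seq) && !is.matrix(c_seq)) c_seq <- matrix(c_seq, nrow = 1)
  dis_forward_full(model, v, c_seq)$p
}

#' Generator loss
#'
#' Mean over the batch of `log(1 - D(filtered scores))` plus `alpha`
#' times the per-row squared error between the 0/1 target and the
#' generated scores, restricted to the defined entries (positives and
#' sampled negatives).  With `alpha = 0` and no sampled negatives this
#' reduces to the plain adversarial generator loss.
#'
#' @param model An [ldaf_gan()] model.
#' @param mask A [sample_negatives()] mask for the batch rows.
#' @param z Generator input batch (see [generator_forward()]).
#' @param c_seq Optional sequence features for the batch.
#' @return Scalar loss, with attributes `adversarial` and `regular`
#'   holding the two components.
#' @export
generator_loss <- function(model, mask, z, c_seq = NULL) {
  stopifnot(inherits(mask, "negative_mask"))
  if (!is.matrix(z)) z <- matrix(z, nrow = 1)
  fw <- gen_forward_full(model, z, c_seq)
  fmask <- filter_mask(mask, model$config$filter_mode)
  fake <- fw$scores * fmask
  p <- dis_forward_full(model, fake, c_seq)$p
  adv <- mean(safe_log(1 - p))
  reg <- regular_term(fw$scores, mask, model$config$alpha)
  out <- adv + reg
  attr(out, "adversarial") <- adv
  attr(out, "regular") <- reg
  out
}

filter_mask <- function(mask, filter_mode) {
  if (filter_mode == "positives") mask$positives else mask$combined
}

#' Discriminator loss
#'
#' Mean of `-log D(real) - log(1 - D(generated filtered))` over equal
#' batches of real association rows and filtered generated rows (the
#' minimised negation of the adversarial maximisation objective).
#' Non-negative for any discriminator output in (0,1) and 0 only at the
#' optimum `D(real) = 1`, `D(fake) = 0`.
#'
#' @param model An [ldaf_gan()] model.
#' @param real Matrix of real 0/1 association rows.
#' @param fake_filtered Matrix of generated, association-filtered rows.
#' @param c_seq Optional sequence features (shared by the paired real
#'   and generated rows).
#' @return Scalar loss.
#' @export
discriminator_loss <- function(model, real, fake_filtered, c_seq = NULL) {
  if (!is.matrix(real)) real <- matrix(real, nrow = 1)
  if (!is.matrix(fake_filtered)) fake_filtered <- matrix(fake_filtered, nrow = 1)
  if (nrow(real) != nrow(fake_filtered)) {
    abort("real and generated batches must have equal size")
  }
  pr <- dis_forward_full(model, real, c_seq)$p
  pf <- dis_forward_full(model, fake_filtered, c_seq)$p
  mean(-safe_log(pr) - safe_log(1 - pf))
}

#' Fit the association-filtering adversarial model
#'
#' Trains the generator/discriminator pair on an lncRNA-disease
#' association matrix by alternating full-batch updates: each epoch the
#' per-row negatives are (re)sampled, the generator produces one
#' disease-score row per lncRNA, the association filter masks the
#' generated rows to the defined entries, the discriminator takes one
#' Adam step against real vs filtered-generated rows, and the generator
#' takes one Adam step on its adversarial plus reconstruction loss.
#' Fully deterministic for a fixed seed.
#'
#' @param m An [assoc_matrix()] with at least one positive entry.
#' @param features Pooled sequence-feature matrix (rownames = lncRNA
#'   ids) covering every row of `m`; required when
#'   `config$use_sequence`.
#' @param config A [gan_config()].
#' @return An `ldaf_gan` object: generator and discriminator weights,
#'   resolved configuration, axis identifiers, and the per-epoch loss
#'   log (tibble `epoch`, `g_loss`, `d_loss`).
#' @export
ldaf_gan <- function(m, features = NULL, config = gan_config()) {
  stopifnot(inherits(m, "assoc_matrix"))
  if (sum(m) < 1) abort("association matrix has no positive entries")
  cfg <- config
  C <- NULL
  if (cfg$use_sequence) {
    if (is.null(features)) abort("sequence mode needs a feature matrix")
    missing <- setdiff(rownames(m), rownames(features))
    if (length(missing)) {
      abort(sprintf("no sequence feature for lncRNA '%s'", missing[1]))
    }
    C <- features[rownames(m), , drop = FALSE]
  }
  dims <- resolve_dims(m, C, cfg)
  cfg$noise_dim <- dims$noise_dim
  nets <- init_gan(dims, cfg)
  model <- list(generator = nets$generator,
                discriminator = nets$discriminator,
                config = cfg, dims = dims,
                lnc_ids = rownames(m), disease_ids = colnames(m),
                loss_log = tibble(epoch = integer(0), g_loss = numeric(0),
                                  d_loss = numeric(0)))
  if (cfg$use_sequence) {
    sds <- apply(C, 2L, sd)
    model$feat_center <- colMeans(C)
    model$feat_scale <- ifelse(sds > 0, sds, 1)
  }
  class(model) <- "ldaf_gan"
  if (cfg$epochs == 0L) return(model)

  X <- unclass(m) * 1.0
  L <- dims$L
  ad_g <- list(main = adam_init(model$generator$main),
               feat = if (cfg$use_sequence) adam_init(model$generator$feat))
  ad_d <- list(main = adam_init(model$discriminator$main),
               feat = if (cfg$use_sequence) adam_init(model$discriminator$feat))
  mask <- sample_negatives(m, cfg$n_sample, seed = cfg$seed + 1L)
  log_e <- integer(cfg$epochs); log_g <- numeric(cfg$epochs)
  log_d <- numeric(cfg$epochs)

  withr::with_seed(cfg$seed, for (e in seq_len(cfg$epochs)) {
    if (cfg$resample_negatives && e > 1L) {
      mask <- sample_negatives(m, cfg$n_sample, seed = cfg$seed + e)
    }
    fmask <- filter_mask(mask, cfg$filter_mode)
    Z <- if (cfg$input_mode == "row") {
      keep <- matrix(runif(L * dims$D) >= cfg$input_dropout, L, dims$D)
      X * keep + cfg$noise_sd * matrix(rnorm(L * dims$D), L, dims$D)
    } else {
      matrix(rnorm(L * dims$noise_dim), L, dims$noise_dim)
    }

    gfw <- gen_forward_full(model, Z, C)
    Fk <- gfw$scores * fmask

    ## ---- discriminator step
    dr <- dis_forward_full(model, X, C)
    df <- dis_forward_full(model, Fk, C)
    d_loss <- mean(-safe_log(dr$p) - safe_log(1 - df$p))
    dlog_r <- matrix((dr$p - 1) / L, ncol = 1)
    dlog_f <- matrix(df$p / L, ncol = 1)
    bw_r <- mlp_backward(model$discriminator$main, dr$acts, dlog_r)
    bw_f <- mlp_backward(model$discriminator$main, df$acts, dlog_f)
    gr_main <- add_grads(bw_r$grads, bw_f$grads)
    up <- adam_step(model$discriminator$main, gr_main, ad_d$main,
                    cfg$lr_d, e)
    model$discriminator$main <- up$layers; ad_d$main <- up$state
    if (cfg$use_sequence) {
      nfh <- cfg$feat_hidden
      dfeat_r <- bw_r$dX[, dims$D + seq_len(nfh), drop = FALSE] *
        (dr$feat$pre > 0)
      dfeat_f <- bw_f$dX[, dims$D + seq_len(nfh), drop = FALSE] *
        (df$feat$pre > 0)
      fb_r <- mlp_backward(model$discriminator$feat, dr$feat$acts, dfeat_r)
      fb_f <- mlp_backward(model$discriminator$feat, df$feat$acts, dfeat_f)
      up <- adam_step(model$discriminator$feat,
                      add_grads(fb_r$grads, fb_f$grads), ad_d$feat,
                      cfg$lr_d, e)
      model$discriminator$feat <- up$layers; ad_d$feat <- up$state
    }

    ## ---- generator step (through the updated discriminator)
    df2 <- dis_forward_full(model, Fk, C)
    adv <- mean(safe_log(1 - df2$p))
    reg <- regular_term(gfw$scores, mask, cfg$alpha)
    bw_d <- mlp_backward(model$discriminator$main, df2$acts,
                         matrix(-df2$p / L, ncol = 1))
    dS <- bw_d$dX[, seq_len(dims$D), drop = FALSE] * fmask +
      cfg$alpha * 2 * mask$combined * (gfw$scores - mask$target) / L
    dRaw <- if (cfg$normalization == "softmax") {
      gfw$scores * (dS - rowSums(dS * gfw$scores))
    } else {
      dS * gfw$scores * (1 - gfw$scores)
    }
    bw_g <- mlp_backward(model$generator$main, gfw$acts, dRaw)
    up <- adam_step(model$generator$main, bw_g$grads, ad_g$main, cfg$lr_g, e)
    model$generator$main <- up$layers; ad_g$main <- up$state
    if (cfg$use_sequence) {
      nfh <- cfg$feat_hidden
      dfeat <- bw_g$dX[, dims$noise_dim + seq_len(nfh), drop = FALSE] *
        (gfw$feat$pre > 0)
      fb <- mlp_backward(model$generator$feat, gfw$feat$acts, dfeat)
      up <- adam_step(model$generator$feat, fb$grads, ad_g$feat, cfg$lr_g, e)
      model$generator$feat <- up$layers; ad_g$feat <- up$state
    }

    log_e[e] <- e; log_g[e] <- adv + reg; log_d[e] <- d_loss
  })
  model$loss_log <- tibble(epoch = log_e, g_loss = log_g, d_loss = log_d)
  model
}

add_grads <- function(a, b) {
  for (i in seq_along(a)) {
    a[[i]]$W <- a[[i]]$W + b[[i]]$W
    a[[i]]$b <- a[[i]]$b + b[[i]]$b
  }
  a
}

#' @export
print.ldaf_gan <- function(x, ...) {
  cat(sprintf(
    "<ldaf_gan> %d lncRNAs x %d diseases%s, %s input, %d epochs trained\n",
    x$dims$L, x$dims$D,
    if (x$config$use_sequence) sprintf(", E = %d sequence features", x$dims$E)
    else "",
    x$config$input_mode, nrow(x$loss_log)))
  invisible(x)
}

#' Score every lncRNA-disease entry with a trained model
#'
#' In row-conditioned mode each lncRNA's (training) association row is
#' fed through the generator, giving a deterministic score row.  In
#' noise and sequence modes the generator is evaluated on `n_draws`
#' seeded noise draws and the scores are averaged.
#'
#' @param model A trained [ldaf_gan()].
#' @param m The association matrix whose rows are fed as generator
#'   input in row mode (typically the training matrix).
#' @param features Pooled sequence features covering the model's
#'   lncRNAs (sequence mode).
#' @param n_draws Noise draws to average (stochastic input modes).
#' @param seed Seed for the noise draws.
#' @return An L x D numeric score matrix with the model's identifiers
#'   as dimnames.
#' @export
score_associations <- function(model, m = NULL, features = NULL,
                               n_draws = NULL, seed = 1L) {
  cfg <- model$config
  n_draws <- n_draws %||% cfg$n_draws
  L <- model$dims$L; D <- model$dims$D
  C <- NULL
  if (cfg$use_sequence) {
    if (is.null(features)) abort("sequence mode needs features")
    C <- features[model$lnc_ids, , drop = FALSE]
  }
  if (cfg$input_mode == "row" && !cfg$use_sequence) {
    if (is.null(m)) abort("row mode needs the association matrix to score")
    # feed the expected value of the corrupted training input, so the
    # scoring input matches the distribution the generator was fit on
    S <- gen_forward_full(model,
                          unclass(m) * (1 - cfg$input_dropout), C)$scores
  } else {
    S <- matrix(0, L, D)
    for (d in seq_len(n_draws)) {
      Z <- sample_noise(L, model$dims$noise_dim, seed = seed + d - 1L)
      S <- S + gen_forward_full(model, Z, C)$scores
    }
    S <- S / n_draws
  }
  dimnames(S) <- list(model$lnc_ids, model$disease_ids)
  S
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding weights, configuration and axis
#' identifiers.
#'
#' @param model An [ldaf_gan()] model.
#' @param path Checkpoint file path.
#' @export
save_ldaf_gan <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ldaf_gan
#' @export
load_ldaf_gan <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ldaf_gan")) abort("not an ldaf_gan checkpoint")
  model
}
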