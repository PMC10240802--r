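small_cfg <- function(..., seed = 3) {
  gan_config(hidden_g = c(12, 10), hidden_d = c(12, 10), seed = seed, ...)
}

test_that("sample_noise is seeded and shaped", {
  z1 <- sample_noise(10, 5, seed = 4)
  expect_equal(dim(z1), c(10L, 5L))
  expect_identical(sample_noise(10, 5, seed = 4), z1)
  expect_false(identical(sample_noise(10, 5, seed = 5), z1))
})

test_that("noise draws follow a standard normal", {
  z <- sample_noise(20000, 5, seed = 1)
  expect_lt(abs(mean(z)), 0.02)
  expect_lt(abs(sd(z) - 1), 0.02)
})

test_that("negative sampling stays inside the unknown region", {
  m <- assoc_matrix(matrix(c(1, 0, 0, 1, 0), 1, 5,
                           dimnames = list("l1", paste0("d", 1:5))))
  nm <- sample_negatives(m, n_sample = 2, seed = 1)
  expect_equal(sum(nm$sampled), 2)
  expect_true(all(nm$sampled[nm$positives == 1] == 0))
  expect_equal(nm$combined, pmax(nm$positives, nm$sampled))

  # n_sample = 0 degenerates to the positives-only filter
  nm0 <- sample_negatives(m, n_sample = 0, seed = 1)
  expect_equal(nm0$combined, nm0$positives)

  # clamping: more requested than zeros available
  nm5 <- sample_negatives(m, n_sample = 5, seed = 1)
  expect_equal(sum(nm5$sampled), 3)

  # balanced default: per-row positive count, floor 1
  m2 <- random_assoc(6, 10, 9, seed = 2)
  nmb <- sample_negatives(m2, seed = 7)
  expect_equal(rowSums(nmb$sampled),
               pmax(1, rowSums(unclass(m2))), ignore_attr = TRUE)
  expect_identical(sample_negatives(m2, seed = 7)$sampled, nmb$sampled)
})

test_that("fua_filter is the masked product, identity and idempotent", {
  expect_equal(fua_filter(c(0.4, 0.7, 0.2), c(1, 0, 1)), c(0.4, 0, 0.2))
  s <- withr::with_seed(1, runif(20))
  expect_equal(fua_filter(s, rep(1, 20)), s)
  expect_equal(fua_filter(s, rep(0, 20)), rep(0, 20))
  msk <- withr::with_seed(2, rbinom(20, 1, 0.5))
  once <- fua_filter(s, msk)
  expect_identical(fua_filter(once, msk), once)
  expect_error(fua_filter(s, c(1, 0)), "length")
})

test_that("generator output is in range, correctly shaped and pure", {
  m <- random_assoc(8, 6, 10, seed = 1)
  model <- ldaf_gan(m, config = small_cfg(epochs = 0L))
  z <- sample_noise(3, 6, seed = 2)
  g <- generator_forward(model, z)
  expect_equal(dim(g$scores), c(3L, 6L))
  expect_true(all(g$scores > 0 & g$scores < 1))
  expect_identical(generator_forward(model, z)$scores, g$scores)

  sm <- ldaf_gan(m, config = small_cfg(epochs = 0L,
                                       normalization = "softmax"))
  gs <- generator_forward(sm, z)
  expect_equal(rowSums(gs$scores), rep(1, 3), tolerance = 1e-9)
  expect_error(generator_forward(model, matrix(0, 1, 4)), "dimension")
})

test_that("discriminator outputs a probability and 0.5 at zero weights", {
  m <- random_assoc(8, 6, 10, seed = 1)
  model <- constant_half_model(m, small_cfg(epochs = 0L))
  v <- withr::with_seed(3, rnorm(6))
  expect_equal(discriminator_forward(model, v), 0.5)
  full <- ldaf_gan(m, config = small_cfg(epochs = 0L))
  p <- discriminator_forward(full, rbind(v, v * 2))
  expect_length(p, 2)
  expect_true(all(p > 0 & p < 1))
  expect_error(discriminator_forward(full, rnorm(4)), "length")
})

test_that("losses take their analytic values when D is constant 0.5", {
  m <- random_assoc(10, 7, 12, seed = 2)
  model <- constant_half_model(m, small_cfg(epochs = 0L))
  mask <- sample_negatives(m, seed = 5)
  z <- unclass(m) + sample_noise(10, 7, seed = 6, sd = 0.1)
  gl <- generator_loss(model, mask, z)
  expect_equal(attr(gl, "adversarial"), log(0.5), tolerance = 1e-9)
  S <- generator_forward(model, z)$scores
  d <- discriminator_loss(model, unclass(m) * 1.0, S * mask$combined)
  expect_equal(d, 2 * log(2), tolerance = 1e-9)
})

test_that("regular term vanishes when scores match targets on the mask", {
  m <- random_assoc(6, 5, 8, seed = 3)
  model <- ldaf_gan(m, config = small_cfg(epochs = 0L, alpha = 0.7))
  mask <- sample_negatives(m, seed = 2)
  fake_scores <- mask$target + 0.5 * (1 - mask$combined)  # match on mask
  reg <- model$config$alpha *
    mean(rowSums(mask$combined * (mask$target - fake_scores)^2))
  expect_equal(reg, 0)
})

test_that("with alpha=0 and n_sample=0 the losses reduce to the plain forms", {
  # oracle: direct transcription of the unregularised adversarial losses
  plain_g <- function(model, X, z) {
    S <- generator_forward(model, z)$scores
    p <- discriminator_forward(model, S * X)
    mean(log(1 - p))
  }
  plain_d <- function(model, X, z) {
    S <- generator_forward(model, z)$scores
    pr <- discriminator_forward(model, X)
    pf <- discriminator_forward(model, S * X)
    mean(-log(pr) - log(1 - pf))
  }
  for (case in 1:10) {
    m <- random_assoc(7, 6, 10, seed = 20 + case)
    model <- ldaf_gan(m, config = small_cfg(epochs = 0L, alpha = 0,
                                            seed = case))
    X <- unclass(m) * 1.0
    mask <- sample_negatives(m, n_sample = 0, seed = case)
    z <- sample_noise(7, 6, seed = case)
    gl <- generator_loss(model, mask, z)
    expect_equal(as.numeric(gl), plain_g(model, X, z), tolerance = 1e-9)
    S <- generator_forward(model, z)$scores
    dl <- discriminator_loss(model, X, S * mask$combined)
    expect_equal(dl, plain_d(model, X, z), tolerance = 1e-9)
  }
})

test_that("sequence-mode losses reduce the same way", {
  m <- random_assoc(6, 5, 9, seed = 31)
  E <- 4
  feats <- withr::with_seed(8, matrix(rnorm(6 * E), 6, E,
                                      dimnames = list(rownames(m), NULL)))
  cfg <- small_cfg(epochs = 0L, alpha = 0, use_sequence = TRUE)
  model <- ldaf_gan(m, features = feats, config = cfg)
  X <- unclass(m) * 1.0
  mask <- sample_negatives(m, n_sample = 0, seed = 4)
  z <- sample_noise(6, 5, seed = 4)
  gl <- generator_loss(model, mask, z, c_seq = feats)
  S <- generator_forward(model, z, feats)$scores
  pf <- discriminator_forward(model, S * X, feats)
  expect_equal(as.numeric(gl), mean(log(1 - pf)), tolerance = 1e-9)
  dl <- discriminator_loss(model, X, S * X, c_seq = feats)
  pr <- discriminator_forward(model, X, feats)
  expect_equal(dl, mean(-log(pr) - log(1 - pf)), tolerance = 1e-9)
})

test_that("training is deterministic, finite, and a no-op at 0 epochs", {
  m <- random_assoc(12, 8, 20, seed = 9)
  cfg0 <- small_cfg(epochs = 0L)
  m0a <- ldaf_gan(m, config = cfg0)
  m0b <- ldaf_gan(m, config = cfg0)
  expect_identical(m0a$generator, m0b$generator)
  expect_equal(nrow(m0a$loss_log), 0L)

  cfg <- small_cfg(epochs = 15L)
  r1 <- ldaf_gan(m, config = cfg)
  r2 <- ldaf_gan(m, config = cfg)
  expect_identical(r1$loss_log, r2$loss_log)
  expect_identical(r1$generator, r2$generator)
  expect_true(all(is.finite(r1$loss_log$g_loss)))
  expect_true(all(is.finite(r1$loss_log$d_loss)))
  # generator outputs stay in (0,1) after training
  S <- score_associations(r1, m = m)
  expect_true(all(S > 0 & S < 1))
})

test_that("training separates a trivially separable column structure", {
  X <- matrix(0L, 20, 10,
              dimnames = list(sprintf("l%02d", 1:20), sprintf("d%02d", 1:10)))
  X[, 4] <- 1L
  m <- assoc_matrix(X)
  cfg <- gan_config(hidden_g = c(16, 16), hidden_d = c(16, 16),
                    epochs = 150L, lr_g = 1e-2, lr_d = 1e-2, seed = 2)
  model <- ldaf_gan(m, config = cfg)
  S <- score_associations(model, m = m)
  mask <- sample_negatives(m, seed = 3)
  expect_gt(mean(S[mask$positives == 1]), mean(S[mask$sampled == 1]))
})

test_that("checkpoints round-trip and missing features are reported", {
  m <- random_assoc(6, 5, 9, seed = 12)
  model <- ldaf_gan(m, config = small_cfg(epochs = 2L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_ldaf_gan(model, path)
  expect_identical(load_ldaf_gan(path)$generator, model$generator)

  feats <- matrix(0, 2, 3, dimnames = list(rownames(m)[1:2], NULL))
  expect_error(
    ldaf_gan(m, features = feats,
             config = small_cfg(use_sequence = TRUE)),
    rownames(m)[3])
})

test_that("config validation catches bad values and YAML round-trips", {
  expect_error(gan_config(alpha = -1), "alpha")
  expect_error(gan_config(n_sample = -2), "n_sample")
  expect_error(gan_config(use_sequence = TRUE, input_mode = "row"),
               "noise")
  cfg <- gan_config(alpha = 0.3, epochs = 12L, normalization = "softmax")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gan_config(cfg, path)
  cfg2 <- read_gan_config(path)
  expect_equal(cfg2$alpha, 0.3)
  expect_equal(cfg2$epochs, 12L)
  expect_equal(cfg2$normalization, "softmax")
  writeLines("bogus_key: 1", path)
  expect_error(read_gan_config(path), "bogus_key")
})
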