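# In-code fixtures shared across test files.

tiny_edges <- function() {
  tibble::tibble(
    lncRNA_id = c("l1", "l1", "l2"),
    disease_id = c("d1", "d2", "d1")
  )
}

tiny_matrix <- function() assoc_matrix(tiny_edges())

# deterministic sparse matrix with a fixed positive count
random_assoc <- function(L, D, n_pos, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(0L, L, D,
                dimnames = list(sprintf("l%02d", seq_len(L)),
                                sprintf("d%02d", seq_len(D))))
    X[sample.int(L * D, n_pos)] <- 1L
    assoc_matrix(X)
  })
}

write_tmp_edges <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# a tiny untrained model whose discriminator outputs exactly 0.5
constant_half_model <- function(m, config = gan_config(epochs = 0L,
                                                       seed = 7L)) {
  model <- ldaf_gan(m, config = config)
  nl <- length(model$discriminator$main)
  model$discriminator$main[[nl]]$W[] <- 0
  model$discriminator$main[[nl]]$b[] <- 0
  model
}

# brute-force metric oracles (independent of the package implementations)
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

sweep_aupr <- function(scores, labels) {
  P <- sum(labels == 1)
  area <- 0
  prev_rec <- 0
  for (t in sort(unique(scores), decreasing = TRUE)) {
    pred <- scores >= t
    tp <- sum(labels == 1 & pred)
    rec <- tp / P
    prec <- tp / sum(pred)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}
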