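# Minimal fully connected network machinery used by both the generator
# and the discriminator: He-initialised linear layers with rectified
# hidden units, explicit backward pass, and Adam updates.  Full-batch
# matrix operations only, so training is deterministic for a fixed seed
# under a fixed BLAS.

mlp_init <- function(sizes) {
  # sizes: c(in, hidden..., out); RNG state of the caller is used
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers)) {
    fan_in <- sizes[i]
    layers[[i]] <- list(
      W = matrix(rnorm(fan_in * sizes[i + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[i + 1L]),
      b = rep(0, sizes[i + 1L])
    )
  }
  layers
}

mlp_forward <- function(layers, X) {
  # returns final linear pre-activation and the per-layer activations
  acts <- vector("list", length(layers) + 1L)
  acts[[1L]] <- X
  H <- X
  nl <- length(layers)
  for (i in seq_len(nl)) {
    Z <- H %*% layers[[i]]$W
    b <- layers[[i]]$b
    Z <- Z + matrix(b, nrow(Z), length(b), byrow = TRUE)
    H <- if (i < nl) Z * (Z > 0) else Z
    acts[[i + 1L]] <- H
  }
  list(out = H, acts = acts)
}

mlp_backward <- function(layers, acts, dOut) {
  # dOut: gradient wrt the final linear output; returns parameter
  # gradients and the gradient wrt the input
  nl <- length(layers)
  grads <- vector("list", nl)
  delta <- dOut
  for (i in rev(seq_len(nl))) {
    A <- acts[[i]]
    grads[[i]] <- list(W = crossprod(A, delta), b = colSums(delta))
    dA <- tcrossprod(delta, layers[[i]]$W)
    if (i > 1L) dA <- dA * (acts[[i]] > 0)  # ReLU gate of layer i-1 output
    delta <- dA
  }
  list(grads = grads, dX = delta)
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0
  ))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# numerically safe log of probabilities
safe_log <- function(p, eps = 1e-7) log(pmin(pmax(p, eps), 1 - eps))

sigmoid <- function(x) plogis(x)

row_softmax <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}
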