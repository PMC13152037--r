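# Layer primitives for the CNN engine. Activations are H x W x C x N
# arrays (column-major); conv/pool kernels live in src/, everything here is
# vectorised R. Each *_fwd returns what its matching *_bwd needs.

conv_fwd <- function(x, w, stride = 1L, pad = 0L) {
  conv2d_forward_cpp(x, dim(x), w, dim(w), as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, w, gout, stride = 1L, pad = 0L) {
  conv2d_backward_cpp(x, dim(x), w, dim(w), gout, as.integer(stride), as.integer(pad))
}

maxpool_fwd <- function(x, k = 3L, stride = 2L, pad = 1L) {
  maxpool_forward_cpp(x, dim(x), as.integer(k), as.integer(stride), as.integer(pad))
}

maxpool_bwd <- function(argmax, gout, xdim) {
  maxpool_backward_cpp(argmax, gout, as.integer(xdim))
}

# Batch normalization over (H, W, N) per channel. Per-channel vectors are
# expanded to length H*W*C once and recycled across the batch dimension by
# R's arithmetic (the array operand keeps its dim).
bn_fwd <- function(x, gamma, beta, running, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (training) {
    per_pos <- rowSums(matrix(x, nrow = hw * C))            # sum over N
    mu <- colSums(matrix(per_pos, nrow = hw)) / (hw * N)    # per channel
    xc <- x - rep(mu, each = hw)
    v_pos <- rowSums(matrix(xc^2, nrow = hw * C))
    va <- colSums(matrix(v_pos, nrow = hw)) / (hw * N)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va * (hw * N) / max(1, hw * N - 1)
  } else {
    mu <- running$mean; va <- running$var
    xc <- x - rep(mu, each = hw)
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(inv_sd, each = hw)
  y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  list(y = y, cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, dim = d),
       running = running)
}

bn_bwd <- function(gout, cache) {
  d <- cache$dim; hw <- d[1] * d[2]; m <- hw * d[4]
  xhat <- cache$xhat
  dgamma <- channel_sum(gout * xhat, d)
  dbeta <- channel_sum(gout, d)
  gxhat <- gout * rep(cache$gamma, each = hw)
  # standard batchnorm input gradient
  gx <- (gxhat - rep(dbeta * cache$gamma / m, each = hw) -
           xhat * rep(channel_sum(gxhat * xhat, d) / m, each = hw)) *
        rep(cache$inv_sd, each = hw)
  list(grad_x = gx, grad_gamma = dgamma, grad_beta = dbeta)
}

# Sum an (H, W, C, N) array over H, W, N per channel.
channel_sum <- function(x, d) {
  per_pos <- rowSums(matrix(x, nrow = d[1] * d[2] * d[3]))
  colSums(matrix(per_pos, nrow = d[1] * d[2]))
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

relu_bwd <- function(gout, mask) gout * mask

# Global average pooling (H, W, C, N) -> (C, N).
gap_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2])           # cols indexed by (c, n)
  matrix(colMeans(m), nrow = d[3], ncol = d[4])
}

gap_bwd <- function(gout, xdim) {
  array(rep(as.vector(gout), each = xdim[1] * xdim[2]) / (xdim[1] * xdim[2]), dim = xdim)
}

fc_fwd <- function(v, w, b) w %*% v + b     # v: (C, N); w: (K, C); b: (K)

fc_bwd <- function(v, w, gout) {
  list(grad_v = crossprod(w, gout), grad_w = tcrossprod(gout, v),
       grad_b = rowSums(gout))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Softmax over class scores
#'
#' Maps real-valued scores to a probability vector by normalized
#' exponentials; numerically guarded by max-subtraction so it is invariant
#' to adding a constant to all scores.
#'
#' @param logits Numeric vector, or matrix with one column per sample.
#' @return Probabilities of the same shape; each column sums to 1.
#' @export
softmax_scores <- function(logits) {
  if (any(!is.finite(logits))) stopf("softmax: non-finite logits")
  if (is.matrix(logits)) {
    z <- exp(sweep(logits, 2, apply(logits, 2, max)))
    sweep(z, 2, colSums(z), `/`)
  } else {
    z <- exp(logits - max(logits))
    z / sum(z)
  }
}

#' Global pooling of a feature map along its spatial dimensions
#'
#' Per-channel maximum or mean over all H x W positions — the squeeze step
#' of the channel attention mechanism.
#'
#' @param f Feature map: H x W x C array (one sample) or H x W x C x N.
#' @param mode "max" or "avg".
#' @return Length-C vector (one sample) or C x N matrix.
#' @export
global_pool <- function(f, mode = c("max", "avg")) {
  mode <- match.arg(mode)
  single <- length(dim(f)) == 3
  if (single) dim(f) <- c(dim(f), 1L)
  d <- dim(f)
  m <- matrix(f, nrow = d[1] * d[2])  # columns = (channel, sample)
  v <- if (mode == "avg") colMeans(m)
       else m[cbind(max.col(t(m), ties.method = "first"), seq_len(ncol(m)))]
  out <- matrix(v, nrow = d[3], ncol = d[4])
  if (single) drop(out) else out
}

# Pooling with argmax bookkeeping, used inside the network backward pass.
global_pool_train <- function(f) {
  d <- dim(f)
  m <- matrix(f, nrow = d[1] * d[2])
  amax <- max.col(t(m), ties.method = "first")
  list(avg = matrix(colMeans(m), d[3], d[4]),
       max = matrix(m[cbind(amax, seq_len(ncol(m)))], d[3], d[4]),
       argmax = amax)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
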