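# Channel attention mechanism: squeeze by global max/avg pooling, a shared
# multilayer perceptron, sigmoid gating, and channel re-weighting applied to
# the residual sum.

#' Initialize shared-MLP parameters for a channel attention module
#'
#' The shared perceptron maps a length-C pooled descriptor through hidden
#' layers (defaults 256 then 128 neurons, ReLU) back to C outputs; the same
#' parameters process the max-pooled and avg-pooled branches.
#'
#' @param channels Number of feature-map channels C.
#' @param hidden_sizes Hidden layer widths (default c(256, 128)).
#' @return List of weight matrices/bias vectors `w0,b0,w1,b1,w2,b2`.
#' @export
cam_mlp_params <- function(channels, hidden_sizes = c(256, 128)) {
  stopifnot(length(hidden_sizes) == 2)
  he <- function(nout, nin) matrix(rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
  list(w0 = he(hidden_sizes[1], channels), b0 = numeric(hidden_sizes[1]),
       w1 = he(hidden_sizes[2], hidden_sizes[1]), b1 = numeric(hidden_sizes[2]),
       w2 = he(channels, hidden_sizes[2]), b2 = numeric(channels))
}

cam_mlp_fwd <- function(p, params) {
  a0 <- params$w0 %*% p + params$b0
  h0 <- a0 * (a0 > 0)
  a1 <- params$w1 %*% h0 + params$b1
  h1 <- a1 * (a1 > 0)
  out <- params$w2 %*% h1 + params$b2
  list(out = out, cache = list(p = p, h0 = h0, m0 = a0 > 0, h1 = h1, m1 = a1 > 0))
}

# Returns grad wrt the pooled input and accumulates parameter grads.
cam_mlp_bwd <- function(gout, params, cache) {
  gw2 <- tcrossprod(gout, cache$h1); gb2 <- rowSums(gout)
  gh1 <- crossprod(params$w2, gout) * cache$m1
  gw1 <- tcrossprod(gh1, cache$h0); gb1 <- rowSums(gh1)
  gh0 <- crossprod(params$w1, gh1) * cache$m0
  gw0 <- tcrossprod(gh0, cache$p); gb0 <- rowSums(gh0)
  list(grad_p = crossprod(params$w0, gh0),
       grads = list(w0 = gw0, b0 = gb0, w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2))
}

#' Compute channel attention weights for a feature map
#'
#' weights = sigmoid(MLP(avg_pool(F)) + MLP(max_pool(F))) with one shared
#' MLP for both pooled descriptors; every weight is strictly in (0, 1).
#'
#' @param f Feature map, H x W x C array (or H x W x C x N batch).
#' @param params Shared-MLP parameters from [cam_mlp_params()].
#' @return Length-C vector (or C x N matrix) of channel weights.
#' @export
channel_attention <- function(f, params) {
  single <- length(dim(f)) == 3
  if (single) dim(f) <- c(dim(f), 1L)
  C <- dim(f)[3]
  if (ncol(params$w0) != C)
    stopf("attention MLP expects %d channels, feature map has %d", ncol(params$w0), C)
  s <- cam_mlp_fwd(global_pool(f, "avg"), params)$out +
       cam_mlp_fwd(global_pool(f, "max"), params)$out
  w <- sigmoid(s)
  if (single) drop(w) else w
}

#' Re-weight a residual block output by channel attention
#'
#' Z[h,w,c] = Mc[c] * (F_out[h,w,c] + x_skip[h,w,c]): the attention weights
#' multiply the feature map after the skip addition.
#'
#' @param f_out Block output, H x W x C array (or H x W x C x N).
#' @param x_skip Skip-connection input of identical shape.
#' @param mc Channel weights: length-C vector or C x N matrix.
#' @return Re-weighted feature map of the same shape.
#' @export
apply_attention <- function(f_out, x_skip, mc) {
  if (!identical(dim(f_out), dim(x_skip)))
    stopf("apply_attention: shapes differ (%s vs %s)",
          paste(dim(f_out), collapse = "x"), paste(dim(x_skip), collapse = "x"))
  d <- dim(f_out)
  single <- length(d) == 3
  if (single) d <- c(d, 1L)
  C <- d[3]
  mcm <- if (is.matrix(mc)) mc else matrix(mc, C, d[4])
  if (nrow(mcm) != C) stopf("apply_attention: %d weights for %d channels", nrow(mcm), C)
  # recycled multiplier keeps the dim attribute of the array operand
  (f_out + x_skip) * rep(as.vector(mcm), each = d[1] * d[2])
}

# Full CAM forward inside the network (batch): returns Mc and caches.
cam_block_fwd <- function(f, params) {
  d <- dim(f)
  pools <- global_pool_train(f)
  avg_m <- cam_mlp_fwd(pools$avg, params)
  max_m <- cam_mlp_fwd(pools$max, params)
  mc <- sigmoid(avg_m$out + max_m$out)
  list(mc = mc, cache = list(dim = d, argmax = pools$argmax,
                             avg = avg_m$cache, max = max_m$cache, mc = mc))
}

# Backward through Mc into the feature map and the shared MLP parameters.
cam_block_bwd <- function(gmc, params, cache) {
  d <- cache$dim; hw <- d[1] * d[2]
  gs <- gmc * cache$mc * (1 - cache$mc)
  bavg <- cam_mlp_bwd(gs, params, cache$avg)
  bmax <- cam_mlp_bwd(gs, params, cache$max)
  grads <- mapply(`+`, bavg$grads, bmax$grads, SIMPLIFY = FALSE)
  # avg-pool branch: spread evenly; max-pool branch: route to argmax cells
  gf <- array(rep(as.vector(bavg$grad_p), each = hw) / hw, dim = d)
  flat <- matrix(gf, nrow = hw)
  flat[cbind(cache$argmax, seq_len(ncol(flat)))] <-
    flat[cbind(cache$argmax, seq_len(ncol(flat)))] + as.vector(bmax$grad_p)
  list(grad_f = array(flat, dim = d), grads = grads)
}
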