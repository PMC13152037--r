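# CAM-ResNet18: a 7x7/2 stem, 3x3/2 max-pool, four stages of two basic
# residual blocks (64/128/256/512 channels, stride-2 projection at each
# stage change), a channel attention module on every block's convolutional
# output, global average pooling, and a fully connected classifier.

#' Network configuration
#'
#' @param num_classes Output classes (default 5).
#' @param input_channels Image channels of the stem (spectrograms are
#'   single-channel, so 1).
#' @param input_size Expected input image size in pixels (informational; the
#'   network is fully convolutional up to the pooling head).
#' @param stage_channels Channel widths of the four stages.
#' @param blocks_per_stage Residual blocks per stage (2 for the 18-layer net).
#' @param attention_enabled Include the channel attention module in every
#'   block (FALSE gives the plain 18-layer residual network).
#' @param attention_position "post_sum" multiplies the weights after the
#'   skip addition, Z = Mc * (F(x) + x); "pre_sum" weights F(x) before the
#'   addition as conventional channel-attention blocks do.
#' @param hidden_sizes Hidden widths of the shared attention MLP.
#' @param batch_norm Include batch normalization (default TRUE).
#' @return A `network_config` list.
#' @export
network_config <- function(num_classes = 5, input_channels = 1, input_size = 224,
                           stage_channels = c(64, 128, 256, 512),
                           blocks_per_stage = 2,
                           attention_enabled = TRUE,
                           attention_position = c("post_sum", "pre_sum"),
                           hidden_sizes = c(256, 128),
                           batch_norm = TRUE) {
  if (length(stage_channels) != 4 || any(stage_channels < 1))
    stopf("stage_channels must be four positive widths")
  if (blocks_per_stage < 1) stopf("blocks_per_stage must be >= 1")
  structure(list(num_classes = as.integer(num_classes),
                 input_channels = as.integer(input_channels),
                 input_size = as.integer(input_size),
                 stage_channels = as.integer(stage_channels),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 attention_enabled = isTRUE(attention_enabled),
                 attention_position = match.arg(attention_position),
                 hidden_sizes = as.integer(hidden_sizes),
                 batch_norm = isTRUE(batch_norm)),
            class = "network_config")
}

he_conv <- function(kh, kw, cin, cout) {
  # He initialization, fan-out mode with ReLU gain
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cout))),
        dim = c(kh, kw, cin, cout))
}

block_spec <- function(cfg) {
  # Flat list of block descriptors: stage, block, in/out channels, stride.
  out <- list()
  in_ch <- cfg$stage_channels[1]
  for (s in 1:4) {
    for (b in seq_len(cfg$blocks_per_stage)) {
      stride <- if (s > 1 && b == 1) 2L else 1L
      out_ch <- cfg$stage_channels[s]
      out[[length(out) + 1]] <- list(name = sprintf("s%d.b%d", s, b),
                                     in_ch = in_ch, out_ch = out_ch,
                                     stride = stride,
                                     project = (stride != 1L || in_ch != out_ch))
      in_ch <- out_ch
    }
  }
  out
}

#' Build a CAM-ResNet18 model
#'
#' Weights are He-initialized (fan-out, ReLU gain) from `seed`; batch-norm
#' scale starts at 1, shift at 0. The same seed always yields the same
#' weights.
#'
#' @param cfg A [network_config()].
#' @param seed Integer RNG seed for initialization.
#' @return A `cam_resnet` model: list with `cfg`, `params` (named arrays),
#'   `running` (batch-norm running statistics), `seed`.
#' @export
build_cam_resnet18 <- function(cfg = network_config(), seed = 1) {
  stopifnot(inherits(cfg, "network_config"))
  with_local_seed(seed, {
    params <- list()
    running <- list()
    add_bn <- function(name, C) {
      params[[paste0(name, ".gamma")]] <<- rep(1, C)
      params[[paste0(name, ".beta")]] <<- rep(0, C)
      running[[name]] <<- list(mean = rep(0, C), var = rep(1, C))
    }
    params[["stem.conv.w"]] <- he_conv(7, 7, cfg$input_channels, cfg$stage_channels[1])
    if (cfg$batch_norm) add_bn("stem.bn", cfg$stage_channels[1])

    for (bs in block_spec(cfg)) {
      nm <- bs$name
      params[[paste0(nm, ".conv1.w")]] <- he_conv(3, 3, bs$in_ch, bs$out_ch)
      if (cfg$batch_norm) add_bn(paste0(nm, ".bn1"), bs$out_ch)
      params[[paste0(nm, ".conv2.w")]] <- he_conv(3, 3, bs$out_ch, bs$out_ch)
      if (cfg$batch_norm) add_bn(paste0(nm, ".bn2"), bs$out_ch)
      if (bs$project) {
        params[[paste0(nm, ".ds.conv.w")]] <- he_conv(1, 1, bs$in_ch, bs$out_ch)
        if (cfg$batch_norm) add_bn(paste0(nm, ".ds.bn"), bs$out_ch)
      }
      if (cfg$attention_enabled) {
        mlp <- cam_mlp_params(bs$out_ch, cfg$hidden_sizes)
        for (k in names(mlp)) params[[paste0(nm, ".cam.", k)]] <- mlp[[k]]
      }
    }
    cl <- cfg$stage_channels[4]
    params[["fc.w"]] <- matrix(rnorm(cfg$num_classes * cl, 0, sqrt(2 / cl)),
                               cfg$num_classes, cl)
    params[["fc.b"]] <- rep(0, cfg$num_classes)
    structure(list(cfg = cfg, params = params, running = running, seed = seed),
              class = "cam_resnet")
  })
}

#' @export
print.cam_resnet <- function(x, ...) {
  cat(sprintf("<CAM-ResNet18: %d classes, %d-channel input, attention %s (%s), %s parameters>\n",
              x$cfg$num_classes, x$cfg$input_channels,
              if (x$cfg$attention_enabled) "on" else "off",
              x$cfg$attention_position,
              format(model_num_params(x), big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters in a model
#'
#' @param model A `cam_resnet` model.
#' @return Integer parameter count (batch-norm running stats excluded).
#' @export
model_num_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

cam_params_of <- function(params, nm) {
  list(w0 = params[[paste0(nm, ".cam.w0")]], b0 = params[[paste0(nm, ".cam.b0")]],
       w1 = params[[paste0(nm, ".cam.w1")]], b1 = params[[paste0(nm, ".cam.b1")]],
       w2 = params[[paste0(nm, ".cam.w2")]], b2 = params[[paste0(nm, ".cam.b2")]])
}

bn_apply <- function(model, name, x, training, running_env) {
  if (!model$cfg$batch_norm)
    return(list(y = x, cache = NULL))
  r <- bn_fwd(x, model$params[[paste0(name, ".gamma")]],
              model$params[[paste0(name, ".beta")]],
              running_env$running[[name]], training)
  if (training) running_env$running[[name]] <- r$running
  list(y = r$y, cache = r$cache)
}

#' Forward pass of the network
#'
#' @param model A `cam_resnet` model.
#' @param x Input batch: H x W x C x N array (an H x W matrix or H x W x N
#'   array of single-channel images is promoted).
#' @param training Use batch statistics and keep caches for the backward
#'   pass (TRUE) or running statistics (FALSE).
#' @param attention_override If non-NULL, every channel attention weight is
#'   replaced by this constant (1 recovers the plain residual network); used
#'   for ablation checks.
#' @return List with `logits` (num_classes x N), `cache` (when training),
#'   and `running` (updated batch-norm statistics when training).
#' @export
model_forward <- function(model, x, training = FALSE, attention_override = NULL) {
  cfg <- model$cfg
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3) {
    d <- dim(x)
    if (cfg$input_channels == 1) dim(x) <- c(d[1], d[2], 1L, d[3])
    else dim(x) <- c(d, 1L)
  }
  if (dim(x)[3] != cfg$input_channels)
    stopf("input has %d channels, network stem expects %d", dim(x)[3], cfg$input_channels)
  p <- model$params
  renv <- new.env(parent = emptyenv())
  renv$running <- model$running
  cache <- if (training) list() else NULL

  # stem
  x_in <- x
  a <- conv_fwd(x, p[["stem.conv.w"]], 2L, 3L)
  bn <- bn_apply(model, "stem.bn", a, training, renv)
  r <- relu_fwd(bn$y)
  mp <- maxpool_fwd(r$y, 3L, 2L, 1L)
  h <- mp$out
  if (training) cache$stem <- list(x = x_in, bn = bn$cache, mask = r$mask,
                                   argmax = mp$argmax, pre_pool_dim = dim(r$y))

  for (bs in block_spec(cfg)) {
    nm <- bs$name
    blk_in <- h
    a1 <- conv_fwd(blk_in, p[[paste0(nm, ".conv1.w")]], bs$stride, 1L)
    bn1 <- bn_apply(model, paste0(nm, ".bn1"), a1, training, renv)
    r1 <- relu_fwd(bn1$y)
    a2 <- conv_fwd(r1$y, p[[paste0(nm, ".conv2.w")]], 1L, 1L)
    bn2 <- bn_apply(model, paste0(nm, ".bn2"), a2, training, renv)
    fx <- bn2$y

    if (bs$project) {
      ds_a <- conv_fwd(blk_in, p[[paste0(nm, ".ds.conv.w")]], bs$stride, 0L)
      ds_bn <- bn_apply(model, paste0(nm, ".ds.bn"), ds_a, training, renv)
      skip <- ds_bn$y
    } else {
      ds_bn <- NULL
      skip <- blk_in
    }

    cam <- NULL
    d <- dim(fx)
    if (cfg$attention_enabled && is.null(attention_override)) {
      cam <- cam_block_fwd(fx, cam_params_of(p, nm))
      mc_arr <- rep(as.vector(cam$mc), each = d[1] * d[2])  # recycled over fx
    } else if (!is.null(attention_override)) {
      mc_arr <- attention_override
    } else {
      mc_arr <- NULL
    }

    if (is.null(mc_arr)) {
      z <- fx + skip
    } else if (cfg$attention_position == "post_sum") {
      z <- (fx + skip) * mc_arr
    } else {
      z <- fx * mc_arr + skip
    }
    rz <- relu_fwd(z)
    if (training) cache[[nm]] <- list(x = blk_in, bn1 = bn1$cache, mask1 = r1$mask,
                                      h1 = r1$y, bn2 = bn2$cache, fx = fx,
                                      skip = skip, ds_bn = if (bs$project) ds_bn$cache,
                                      cam = if (!is.null(cam)) cam$cache,
                                      mask = rz$mask, spec = bs)
    h <- rz$y
  }

  v <- gap_fwd(h)
  logits <- fc_fwd(v, p[["fc.w"]], p[["fc.b"]])
  if (training) cache$head <- list(v = v, hdim = dim(h))
  list(logits = logits, cache = cache, running = renv$running)
}

# Backward pass: gradient of the batch loss wrt every parameter.
model_backward <- function(model, cache, glogits) {
  cfg <- model$cfg
  p <- model$params
  grads <- list()
  bn_back <- function(name, gout, bn_cache) {
    if (!cfg$batch_norm) return(gout)
    b <- bn_bwd(gout, bn_cache)
    grads[[paste0(name, ".gamma")]] <<- b$grad_gamma
    grads[[paste0(name, ".beta")]] <<- b$grad_beta
    b$grad_x
  }

  fb <- fc_bwd(cache$head$v, p[["fc.w"]], glogits)
  grads[["fc.w"]] <- fb$grad_w
  grads[["fc.b"]] <- fb$grad_b
  gh <- gap_bwd(fb$grad_v, cache$head$hdim)

  for (bs in rev(block_spec(cfg))) {
    nm <- bs$name
    bc <- cache[[nm]]
    gz <- relu_bwd(gh, bc$mask)
    d <- dim(bc$fx)
    hw <- d[1] * d[2]

    if (!is.null(bc$cam)) {
      mc_arr <- rep(as.vector(bc$cam$mc), each = hw)
      if (cfg$attention_position == "post_sum") {
        s_sum <- bc$fx + bc$skip
        gmc <- matrix(colSums(matrix(gz * s_sum, nrow = hw)), d[3], d[4])
        gsum <- gz * mc_arr
        gfx_lin <- gsum; gskip <- gsum
      } else {
        gmc <- matrix(colSums(matrix(gz * bc$fx, nrow = hw)), d[3], d[4])
        gfx_lin <- gz * mc_arr; gskip <- gz
      }
      cb <- cam_block_bwd(gmc, cam_params_of(p, nm), bc$cam)
      for (k in names(cb$grads)) grads[[paste0(nm, ".cam.", k)]] <- cb$grads[[k]]
      gfx <- gfx_lin + cb$grad_f
    } else {
      gfx <- gz; gskip <- gz
    }

    # main path
    ga2 <- bn_back(paste0(nm, ".bn2"), gfx, bc$bn2)
    cb2 <- conv_bwd(bc$h1, p[[paste0(nm, ".conv2.w")]], ga2, 1L, 1L)
    grads[[paste0(nm, ".conv2.w")]] <- cb2$grad_w
    ga1 <- relu_bwd(cb2$grad_x, bc$mask1)
    ga1 <- bn_back(paste0(nm, ".bn1"), ga1, bc$bn1)
    cb1 <- conv_bwd(bc$x, p[[paste0(nm, ".conv1.w")]], ga1, bs$stride, 1L)
    grads[[paste0(nm, ".conv1.w")]] <- cb1$grad_w
    gx <- cb1$grad_x

    # skip path
    if (bs$project) {
      gds <- bn_back(paste0(nm, ".ds.bn"), gskip, bc$ds_bn)
      cbd <- conv_bwd(bc$x, p[[paste0(nm, ".ds.conv.w")]], gds, bs$stride, 0L)
      grads[[paste0(nm, ".ds.conv.w")]] <- cbd$grad_w
      gx <- gx + cbd$grad_x
    } else {
      gx <- gx + gskip
    }
    gh <- gx
  }

  # stem
  gmp <- maxpool_bwd(cache$stem$argmax, gh, cache$stem$pre_pool_dim)
  ga <- relu_bwd(gmp, cache$stem$mask)
  ga <- bn_back("stem.bn", ga, cache$stem$bn)
  cbs <- conv_bwd(cache$stem$x, p[["stem.conv.w"]], ga, 2L, 3L)
  grads[["stem.conv.w"]] <- cbs$grad_w
  grads
}

# Softmax cross-entropy: batch loss and logit gradient.
softmax_xent <- function(logits, y) {
  probs <- softmax_scores(logits)
  n <- ncol(probs)
  idx <- cbind(y, seq_len(n))
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  g <- probs
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n, probs = probs)
}

#' Classify a batch of feature images
#'
#' Runs the network in evaluation mode and applies softmax; the predicted
#' class is the arg-max probability, ties broken toward the lowest class
#' index.
#'
#' @param model A `cam_resnet` model (or loaded checkpoint model).
#' @param inputs H x W x N array of feature images (single channel).
#' @param batch_size Mini-batch size for the forward passes.
#' @return List with `class` (integer vector, 1-based indices into
#'   [cough_classes()]) and `prob` (num_classes x N matrix).
#' @export
predict_classes <- function(model, inputs, batch_size = 32) {
  if (is.matrix(inputs)) dim(inputs) <- c(dim(inputs), 1L)
  n <- dim(inputs)[3]
  K <- model$cfg$num_classes
  prob <- matrix(NA_real_, K, n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    xb <- inputs[, , idx, drop = FALSE]
    out <- model_forward(model, xb, training = FALSE)
    prob[, idx] <- softmax_scores(out$logits)
  }
  list(class = apply(prob, 2, which.max), prob = prob)
}

#' Save a model checkpoint
#'
#' Stores weights, batch-norm statistics, configuration and seed, plus a
#' JSON metadata sidecar describing the checkpoint schema.
#'
#' @param model A `cam_resnet` model.
#' @param path Output path (.rds).
#' @param meta Optional named list of extra metadata.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  obj <- list(schema = "coughscope-checkpoint-1",
              cfg = unclass(model$cfg), params = model$params,
              running = model$running, seed = model$seed, meta = meta)
  saveRDS(obj, path)
  jsonlite::write_json(list(schema = obj$schema, cfg = obj$cfg, seed = obj$seed,
                            meta = meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "coughscope-checkpoint-1"))
    stopf("unrecognized checkpoint schema in %s", path)
  cfg <- do.call(network_config, obj$cfg[setdiff(names(obj$cfg), character())])
  structure(list(cfg = cfg, params = obj$params, running = obj$running,
                 seed = obj$seed, meta = obj$meta),
            class = "cam_resnet")
}
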