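# Network assembly: shapes, ablation equivalence, determinism, softmax,
# parameter accounting, and optimization sanity.

test_that("forward pass maps a batch of images to finite class scores", {
  m <- build_cam_resnet18(network_config(), seed = 3)
  x <- random_inputs(224, 2, seed = 51)
  out <- model_forward(m, x)
  expect_identical(dim(out$logits), c(5L, 2L))
  expect_true(all(is.finite(out$logits)))
})

test_that("attention-disabled build equals the attention-forced-to-1 build", {
  cam <- build_cam_resnet18(network_config(input_size = 32), seed = 4)
  plain <- build_cam_resnet18(network_config(input_size = 32,
                                             attention_enabled = FALSE), seed = 4)
  # share the backbone weights so only the attention path differs
  for (k in names(plain$params)) plain$params[[k]] <- cam$params[[k]]
  x <- random_inputs(32, 3, seed = 52)
  l_forced <- model_forward(cam, x, attention_override = 1)$logits
  l_plain <- model_forward(plain, x)$logits
  expect_identical(l_forced, l_plain)
})

test_that("builds are deterministic in the seed", {
  cfg <- tiny_net_cfg()
  x <- random_inputs(16, 2, seed = 53)
  m1 <- build_cam_resnet18(cfg, seed = 9)
  m2 <- build_cam_resnet18(cfg, seed = 9)
  m3 <- build_cam_resnet18(cfg, seed = 10)
  expect_identical(model_forward(m1, x)$logits, model_forward(m2, x)$logits)
  expect_false(identical(model_forward(m1, x)$logits, model_forward(m3, x)$logits))
})

test_that("attention-off parameter count matches independent layer accounting", {
  m <- build_cam_resnet18(network_config(attention_enabled = FALSE), seed = 1)
  # layer-by-layer accounting for the 18-layer backbone, 1-channel stem,
  # 5-way classifier
  acc <- 7 * 7 * 1 * 64 + 2 * 64                       # stem conv + BN
  ch <- c(64, 128, 256, 512)
  inc <- 64
  for (s in 1:4) for (b in 1:2) {
    oc <- ch[s]
    acc <- acc + 9 * inc * oc + 2 * oc                 # conv1 + bn1
    acc <- acc + 9 * oc * oc + 2 * oc                  # conv2 + bn2
    if (inc != oc || (s > 1 && b == 1))
      acc <- acc + inc * oc + 2 * oc                   # 1x1 projection + BN
    inc <- oc
  }
  acc <- acc + 512 * 5 + 5                             # classifier
  expect_equal(model_num_params(m), acc)
  expect_equal(acc, 11172805)                          # frozen regression value
})

test_that("softmax is symmetric, shift-invariant and matches direct evaluation", {
  expect_equal(softmax_scores(rep(0, 5)), rep(0.2, 5))
  set.seed(54)
  l <- rnorm(5)
  expect_equal(softmax_scores(l), softmax_scores(l + 1000), tolerance = 1e-9)
  expect_equal(softmax_scores(l), exp(l) / sum(exp(l)), tolerance = 1e-12)
  expect_equal(sum(softmax_scores(l)), 1, tolerance = 1e-9)
  expect_error(softmax_scores(c(1, NA, 0, 0, 0)), "finite")
})

test_that("analytic gradients agree with central differences", {
  cfg <- tiny_net_cfg(num_classes = 3)
  m <- build_cam_resnet18(cfg, seed = 11)
  set.seed(55)
  x <- array(rnorm(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  y <- c(1, 3)
  fw <- model_forward(m, x, training = TRUE)
  le <- coughscope:::softmax_xent(fw$logits, y)
  gr <- coughscope:::model_backward(m, fw$cache, le$grad)
  loss_of <- function(mm) {
    f <- model_forward(mm, x, training = TRUE)
    coughscope:::softmax_xent(f$logits, y)$loss
  }
  eps <- 1e-5
  picks <- c("stem.conv.w", "s1.b1.cam.w0", "s2.b1.ds.conv.w", "s3.b2.conv2.w",
             "s4.b2.bn2.gamma", "s4.b1.cam.b2", "fc.w")
  for (nm in picks) {
    i <- sample(length(m$params[[nm]]), 1)
    mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + eps
    mm2 <- m; mm2$params[[nm]][i] <- mm2$params[[nm]][i] - eps
    num <- (loss_of(mp) - loss_of(mm2)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-3)
  }
})

test_that("one small Adam step on a fixed batch almost always lowers the loss", {
  # geometry keeps every batch-norm reduction well-populated (the last stage
  # still sees 2x2 maps over the batch of 8); narrow widths only for speed
  cfg <- network_config(stage_channels = c(16, 32, 64, 128), input_size = 64,
                        hidden_sizes = c(32, 16))
  ok <- 0
  for (trial in 1:100) {
    m <- build_cam_resnet18(cfg, seed = 200 + trial)
    set.seed(300 + trial)
    x <- array(runif(64 * 64 * 8), c(64, 64, 1, 8))
    y <- sample(1:5, 8, replace = TRUE)
    fw <- model_forward(m, x, training = TRUE)
    l0 <- coughscope:::softmax_xent(fw$logits, y)
    gr <- coughscope:::model_backward(m, fw$cache, l0$grad)
    st <- coughscope:::adam_init(m$params)
    up <- coughscope:::adam_step(m$params, gr, st, lr = 1e-4)
    m$params <- up$params
    l1 <- coughscope:::softmax_xent(model_forward(m, x, training = TRUE)$logits, y)
    if (l1$loss < l0$loss) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("checkpoints roundtrip weights, config and metadata", {
  m <- build_cam_resnet18(tiny_net_cfg(), seed = 12)
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, p, meta = list(note = "unit"))
  back <- load_checkpoint(p)
  x <- random_inputs(16, 2, seed = 56)
  expect_identical(model_forward(back, x)$logits, model_forward(m, x)$logits)
  expect_identical(back$meta$note, "unit")
  expect_true(file.exists(paste0(p, ".json")))
})
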