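test_that("depthwise convolution: identity kernels, channel count, locality", {
  set.seed(21)
  x <- rand_tensor(2, 5, 6, 6)
  ident <- array(0, c(5, 3, 3))
  ident[, 2, 2] <- 1
  expect_equal(depthwise_conv2d(x, ident, stride = 1, pad = 1), x,
               tolerance = 1e-12)

  # one filter per channel: output channel count equals input channel count
  x64 <- rand_tensor(1, 64, 8, 8)
  y <- depthwise_conv2d(x64, array(rnorm(64 * 9), c(64, 3, 3)), pad = 1)
  expect_equal(dim(y), c(1, 64, 8, 8))

  # perturbing input channel i changes only output channel i
  k <- array(rnorm(5 * 9), c(5, 3, 3))
  base <- depthwise_conv2d(x, k, pad = 1)
  x2 <- x
  x2[, 3, , ] <- x2[, 3, , ] + rnorm(2 * 36)
  pert <- depthwise_conv2d(x2, k, pad = 1)
  changed <- vapply(1:5, function(c) any(abs(pert[, c, , ] - base[, c, , ])
                                         > 1e-12), logical(1))
  expect_equal(changed, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  expect_error(depthwise_conv2d(x, array(0, c(4, 3, 3))), "filter count")
})

test_that("pointwise convolution is a per-pixel channel mixing", {
  set.seed(22)
  x <- rand_tensor(2, 3, 4, 4)
  expect_equal(pointwise_conv2d(x, diag(3)), x, tolerance = 1e-12)

  # forced by linearity: mixing [[1,0,0],[0,1,1]] on the pixel (2,3,5)
  px <- array(c(2, 3, 5), c(1, 3, 1, 1))
  mix <- rbind(c(1, 0, 0), c(0, 1, 1))
  expect_equal(as.vector(pointwise_conv2d(px, mix)), c(2, 8))

  # per-pixel matrix-vector product oracle
  mix2 <- matrix(rnorm(2 * 3), 2, 3)
  got <- pointwise_conv2d(x, mix2)
  for (h in 1:4) for (w in 1:4)
    expect_equal(got[1, , h, w], as.vector(mix2 %*% x[1, , h, w]),
                 tolerance = 1e-12)
  expect_error(pointwise_conv2d(x, matrix(0, 2, 4)), "input channels")
})

test_that("grouped/standard convolutions match the quadruple-loop oracle", {
  set.seed(23)
  for (i in 1:10) {
    C <- sample(c(2, 4), 1)
    Cout <- sample(c(2, 4, 6), 1)
    k <- sample(c(1, 3), 1)
    stride <- sample(1:2, 1)
    pad <- sample(0:1, 1)
    x <- array(sample(-5:5, 2 * C * 25, TRUE), c(2, C, 5, 5))
    w <- array(rnorm(Cout * C * k * k), c(Cout, C, k, k))
    b <- rnorm(Cout)
    expect_equal(conv2d(x, w, b, stride, pad),
                 naive_conv2d(x, w, b, stride, pad)$y, tolerance = 1e-10)
  }
})

test_that("a depthwise+pointwise pair reproduces a rank-1 standard convolution", {
  set.seed(24)
  C <- 3; Cout <- 4
  d <- array(rnorm(C * 9), c(C, 3, 3))
  mix <- matrix(rnorm(Cout * C), Cout, C)
  x <- rand_tensor(2, C, 6, 6)
  sep <- pointwise_conv2d(depthwise_conv2d(x, d, pad = 1), mix)
  wstd <- array(0, c(Cout, C, 3, 3))
  for (o in 1:Cout) for (c in 1:C) wstd[o, c, , ] <- mix[o, c] * d[c, , ]
  expect_equal(sep, naive_conv2d(x, wstd, NULL, 1, 1)$y, tolerance = 1e-10)
})

test_that("residual block shapes and the separable parameter saving", {
  spec <- architecture_spec(num_classes = 5)
  blk <- make_ds_block(64, 64, 1, spec)
  shp <- esaresnet:::infer_shapes(blk$graph, c(1, 64, 14, 14))
  expect_equal(shp[[length(shp)]], c(1L, 64L, 14L, 14L))

  blk2 <- make_ds_block(64, 128, 2, spec)
  shp2 <- esaresnet:::infer_shapes(blk2$graph, c(1, 64, 56, 56))
  expect_equal(shp2[[length(shp2)]], c(1L, 128L, 28L, 28L))

  # block body (convolution slots only): 2*(3*3*64 + 64*64) vs 2*3*3*64*64
  conv_params <- function(model, pattern) {
    nodes <- Filter(function(n) grepl(pattern, n$name) && n$kind == "conv",
                    model$graph$nodes)
    sum(vapply(nodes, esaresnet:::node_param_count, numeric(1)))
  }
  expect_equal(conv_params(blk, "\\.c[12]\\."), 9344)
  std <- make_ds_block(64, 64, 1,
                       architecture_spec(num_classes = 5,
                                         use_depthwise = FALSE))
  expect_equal(conv_params(std, "\\.c[12]\\."), 73728)
  expect_error(make_ds_block(64, 64, 3, spec), "stride")
})

test_that("with all enhancements off the network is layer-for-layer ResNet34", {
  plain <- architecture_spec(use_esa = FALSE, use_depthwise = FALSE,
                             dropout_rate = 0)
  ours_off <- build_esa_resnet34(plain, initialize = FALSE)
  ref <- build_reference_model("resnet34", 61)
  expect_identical(layer_table(ours_off), layer_table(ref))
  expect_equal(count_parameters(ours_off), count_parameters(ref))
})

test_that("spatial downsampling is once per stage transition, 32x overall", {
  m <- build_esa_resnet34(architecture_spec(), initialize = FALSE)
  shp <- esaresnet:::infer_shapes(m$graph, c(1, 3, 224, 224))
  expect_equal(shp[["stem.pool"]][3:4], c(56L, 56L))
  for (s in 1:4) {
    last_block <- sum(m$spec$stage_block_counts[1:s] * 0) +
      m$spec$stage_block_counts[s]
    nm <- sprintf("stage%d.block%d.relu2", s, last_block)
    expect_equal(shp[[nm]][3:4], rep(c(56L, 28L, 14L, 7L)[s], 2))
  }
  # main-branch downsampling (the 1x1 skip projections mirror the stride):
  # stem conv + stem pool + one stride-2 conv per stage transition = 32x
  main <- Filter(function(n) n$kind %in% c("conv", "maxpool") &&
                   !grepl("\\.down$", n$name), m$graph$nodes)
  strides <- vapply(main, function(n) n$stride, integer(1))
  expect_equal(sum(log2(strides[strides > 1])), 5)
  for (s in 2:4) {
    in_stage <- strides[grepl(sprintf("^stage%d\\.", s), names(strides))]
    expect_equal(sum(in_stage > 1), 1)
  }
})

test_that("a forward pass of the full classifier yields 61 logits", {
  set_global_seed(99)
  m <- build_esa_resnet34(architecture_spec())
  logits <- predict(m, array(runif(1 * 3 * 224 * 224), c(1, 3, 224, 224)))
  expect_equal(dim(logits), c(1L, 61L))
  expect_true(all(is.finite(logits)))
})

test_that("reference builders give the documented parameter counts", {
  expect_equal(count_parameters(build_reference_model("resnet18", 61)),
               11207805)  # 11.21 M
  expect_equal(count_parameters(build_reference_model("vgg16", 61)),
               134510461)  # 134.51 M
  # head arithmetic for a single-linear-head network
  d <- count_parameters(build_reference_model("resnet18", 1000)) -
    count_parameters(build_reference_model("resnet18", 61))
  expect_equal(d, (512 + 1) * 939)
})

test_that("invalid specifications and names are rejected informatively", {
  expect_error(architecture_spec(stage_widths = c(64, 128, 256, 500)),
               "doubling")
  expect_error(architecture_spec(num_classes = 1), ">= 2")
  expect_error(architecture_spec(dropout_rate = 1), "\\[0, 1\\)")
  expect_error(build_reference_model("resnet99"), "valid names")
  expect_error(build_reference_model("resnet99"), "mobilenet")
})
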