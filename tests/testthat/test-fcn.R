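# fcn_core: architecture, forward pass, softmax, and the two-step layer
# breakdown (spatial aggregation + information synthesis).

test_that("baseline spec matches the published architecture description", {
  spec <- fcn_spec()
  expect_equal(spec$channels, c(16, 16, 32, 32, 64, 64, 32, 32, 16, 16))
  expect_equal(spec$dilations, c(1, 1, 2, 2, 4, 4, 2, 2, 1, 1))
  expect_equal(spec$in_channels, 3L)
  expect_equal(spec$n_classes, 4L)
})

test_that("parameter count of the baseline FCN is within 2% of 320k", {
  pc <- param_count(fcn_spec())
  expect_lt(abs(pc$total - 320000) / 320000, 0.02)
  # closed-form oracle recomputed independently: 27 C_in C_out + C_out conv
  # bias + 2 C_out batch-norm affine per block, plus the 1x1x1 head
  ch <- c(3, 16, 16, 32, 32, 64, 64, 32, 32, 16, 16)
  manual <- sum(27 * ch[-11] * ch[-1] + ch[-1] + 2 * ch[-1]) + (16 * 4 + 4)
  expect_equal(pc$total, manual)
})

test_that("param_count agrees with the number of weights actually allocated", {
  spec <- fcn_spec(channels = c(4, 5, 6), dilations = c(1, 2, 1))
  net <- build_fcn(spec, seed = 1)
  n_alloc <- sum(vapply(net$layers, function(ly)
    length(ly$W) + length(ly$b) + length(ly$gamma) + length(ly$beta), 0)) +
    length(net$out$W) + length(net$out$b)
  expect_equal(param_count(spec)$total, n_alloc)
})

test_that("build_fcn is deterministic in the seed and initializes BN neutrally", {
  a <- build_fcn(fcn_spec(channels = c(4, 4), dilations = c(1, 2)), seed = 3)
  b <- build_fcn(fcn_spec(channels = c(4, 4), dilations = c(1, 2)), seed = 3)
  c <- build_fcn(fcn_spec(channels = c(4, 4), dilations = c(1, 2)), seed = 4)
  expect_identical(a$layers[[1]]$W, b$layers[[1]]$W)
  expect_false(identical(a$layers[[1]]$W, c$layers[[1]]$W))
  for (ly in a$layers) {
    expect_equal(ly$gamma, rep(1, length(ly$gamma)))
    expect_equal(ly$beta, rep(0, length(ly$beta)))
    expect_equal(ly$running_mean, rep(0, length(ly$running_mean)))
    expect_equal(ly$running_var, rep(1, length(ly$running_var)))
  }
})

test_that("forward pass preserves spatial dimensions and emits a simplex", {
  net <- build_fcn(fcn_spec(channels = c(4, 6, 4), dilations = c(1, 2, 1)), seed = 1)
  x <- array(with_seed(2, rnorm(3 * 7 * 6 * 5)), c(3, 7, 6, 5))
  map <- fcn_predict(net, x)
  expect_s3_class(map, "probability_map")
  expect_equal(dim(map$values), c(7L, 6L, 5L))
  prob <- attr(map, "class_probs")
  expect_equal(dim(prob), c(4L, 7L * 6L * 5L))
  expect_equal(colSums(prob), rep(1, ncol(prob)), tolerance = 1e-12)
  expect_true(all(prob >= 0))
  # anomaly score = viable + necrosis mass
  expect_equal(as.vector(map$values), prob[3, ] + prob[4, ], tolerance = 1e-12)
})

test_that("the same network accepts different spatial sizes (fully convolutional)", {
  net <- build_fcn(fcn_spec(channels = c(4, 4), dilations = c(1, 2)), seed = 1)
  for (d in list(c(5, 5, 5), c(9, 6, 5), c(12, 12, 12))) {
    x <- array(rnorm(3 * prod(d)), c(3, d))
    expect_equal(dim(fcn_predict(net, x)$values), as.integer(d))
  }
})

test_that("softmax columns are shift-invariant and numerically stable", {
  z <- matrix(c(1000, 1001, 999, 1000, -1000, -999, -1001, -1000), nrow = 4)
  p <- layercal:::softmax_cols(z)
  expect_true(all(is.finite(p)))
  expect_equal(colSums(p), c(1, 1), tolerance = 1e-12)
  expect_equal(layercal:::softmax_cols(z + 5), p, tolerance = 1e-12)
})

test_that("channel mismatch is rejected", {
  net <- build_fcn(fcn_spec(channels = c(4, 4), dilations = c(1, 2)), seed = 1)
  x <- array(rnorm(2 * 5^3), c(2, 5, 5, 5))
  expect_error(fcn_predict(net, x), "channels")
})

test_that("spatial_aggregate matches a brute-force zero-padded neighbor gather", {
  # independent oracle: loop over voxels and 27 offsets explicitly
  grid <- c(5, 4, 3); C <- 3
  vals <- matrix(with_seed(8, rnorm(prod(grid) * C)), ncol = C)
  rep1 <- layer_representation(1, "post", vals, grid)
  for (dil in c(1L, 2L)) {
    agg <- spatial_aggregate(rep1, dilation = dil)
    expect_equal(ncol(agg$values), 27 * C)
    expect_equal(agg$stage, "pre")
    vol <- array(t(vals), c(C, grid))  # channel-first array view
    oracle <- matrix(0, prod(grid), 27 * C)
    vox <- 0L
    for (z in 1:grid[3]) for (y in 1:grid[2]) for (x in 1:grid[1]) {
      vox <- vox + 1L
      o <- 0L
      for (dz in c(-dil, 0L, dil)) for (dy in c(-dil, 0L, dil)) for (dx in c(-dil, 0L, dil)) {
        o <- o + 1L
        p <- c(x + dx, y + dy, z + dz)
        oracle[vox, ((o - 1) * C + 1):(o * C)] <-
          if (all(p >= 1 & p <= grid)) vol[, p[1], p[2], p[3]] else rep(0, C)
      }
    }
    expect_equal(agg$values, oracle, tolerance = 1e-12)
  }
})

test_that("information_synthesize applies conv + BN + ReLU on hand cases", {
  # single voxel, 2 input features, 1 output channel, identity-ish BN
  pre <- layer_representation(2, "pre", matrix(c(1, 2), nrow = 1), c(1, 1, 1))
  W <- matrix(c(3, -1), nrow = 1)        # z = 3*1 - 1*2 = 1
  bn <- list(gamma = 2, beta = 0.5, mean = 0, var = 1)
  out <- information_synthesize(pre, W, bias = 1, bn = bn)
  # z + b = 2; BN: 2 * 2/sqrt(1+eps) + 0.5 ~ 4.5; ReLU passthrough
  expect_equal(out$values[1, 1], 2 * 2 / sqrt(1 + layercal:::bn_eps) + 0.5,
               tolerance = 1e-9)
  # negative pre-activation clamps to zero
  bn0 <- list(gamma = 1, beta = 0, mean = 0, var = 1)
  out0 <- information_synthesize(pre, -W, bias = -1, bn = bn0)
  expect_equal(out0$values[1, 1], 0)
  expect_equal(out0$stage, "post")
})

test_that("breakdown equivalence: aggregate+synthesize reproduce every layer", {
  # acceptance-grade check on a random 7^3 input through the full-width
  # baseline: the two-step breakdown must match the network's own
  # representations within 1e-5 at every layer
  net <- build_fcn(fcn_spec(), seed = 5)
  x <- array(with_seed(6, rnorm(3 * 7^3)), c(3, 7, 7, 7))
  fr <- forward_with_representations(net, x)
  for (l in seq_along(net$layers)) {
    prev <- if (l == 1) {
      layer_representation(0, "post", matrix(x, nrow = 3) |> t(), c(7, 7, 7))
    } else fr$reps[[paste0("l", l - 1, "_post")]]
    pre <- spatial_aggregate(prev, net$layers[[l]]$dilation)
    post <- breakdown_step(net, prev)
    ref_pre <- fr$reps[[paste0("l", l, "_pre")]]$values
    ref_post <- fr$reps[[paste0("l", l, "_post")]]$values
    expect_identical(dim(pre$values), dim(ref_pre))
    expect_identical(dim(post$values), dim(ref_post))
    expect_lt(max(abs(pre$values - ref_pre)), 1e-5)
    expect_lt(max(abs(post$values - ref_post)), 1e-5)
  }
})

test_that("representation widths follow the architecture", {
  net <- build_fcn(fcn_spec(channels = c(4, 6), dilations = c(1, 2)), seed = 2)
  x <- array(rnorm(3 * 5^3), c(3, 5, 5, 5))
  fr <- forward_with_representations(net, x)
  expect_named(fr$reps, c("l1_pre", "l1_post", "l2_pre", "l2_post"))
  expect_equal(ncol(fr$reps$l1_pre$values), 27 * 3)
  expect_equal(ncol(fr$reps$l1_post$values), 4)
  expect_equal(ncol(fr$reps$l2_pre$values), 27 * 4)
  expect_equal(ncol(fr$reps$l2_post$values), 6)
  for (r in fr$reps) expect_equal(nrow(r$values), 125)
})

test_that("dropout draws are controlled by the caller's seed and scale correctly", {
  spec <- fcn_spec(channels = c(8, 8), dilations = c(1, 1), use_dropout = TRUE, dropout_rate = 0.5)
  net <- build_fcn(spec, seed = 1)
  x <- array(with_seed(3, rnorm(3 * 5^3)), c(3, 5, 5, 5))
  inp <- layercal:::as_input_matrix(x, spec)
  p1 <- with_seed(7, layercal:::fcn_pass(net, inp$mat, inp$dims, dropout = TRUE)$prob)
  p2 <- with_seed(7, layercal:::fcn_pass(net, inp$mat, inp$dims, dropout = TRUE)$prob)
  p3 <- with_seed(8, layercal:::fcn_pass(net, inp$mat, inp$dims, dropout = TRUE)$prob)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  # deterministic pass ignores dropout entirely
  d1 <- layercal:::fcn_pass(net, inp$mat, inp$dims)$prob
  d2 <- layercal:::fcn_pass(net, inp$mat, inp$dims)$prob
  expect_identical(d1, d2)
})
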