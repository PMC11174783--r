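test_that("adaptive branch weights follow the softmax formula", {
  expect_equal(adaptive_branch_weights(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(adaptive_branch_weights(c(log(2), 0, 0, 0)),
               c(0.4, 0.2, 0.2, 0.2))
  expect_equal(adaptive_branch_weights(c(1, 0, 0, 0)),
               c(0.47536, 0.17488, 0.17488, 0.17488), tolerance = 1e-4)
  expect_error(adaptive_branch_weights(c(Inf, 0, 0, 0)), "finite")
  expect_error(adaptive_branch_weights(c(0, 0, 0)), "four")
})

test_that("adaptive branch weights sum to one and are permutation-equivariant", {
  set.seed(11)
  for (i in 1:25) {
    raw <- rnorm(4, sd = 3)
    w <- adaptive_branch_weights(raw)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-6)
    p <- sample(4)
    expect_equal(adaptive_branch_weights(raw[p]), w[p], tolerance = 1e-12)
  }
})

test_that("SE gate matches its closed form and bounds the input", {
  set.seed(21)
  x <- rarr(2, 8, 5, 5)
  r <- 4
  W1 <- matrix(rnorm(8 * 8 / r), 8 / r, 8)
  W2 <- matrix(rnorm(8 * 8 / r), 8, 8 / r)

  # zero maps force a gate of sigmoid(0) = 0.5
  out0 <- se_gate(x, list(reduce_map = 0 * W1, expand_map = 0 * W2))
  expect_equal(out0, 0.5 * x, tolerance = 1e-12)
  expect_equal(se_gate(0 * x, list(reduce_map = W1, expand_map = W2)), 0 * x)

  out <- se_gate(x, list(reduce_map = W1, expand_map = W2))
  expect_lt(max(abs(out - naive_se_gate(x, W1, W2))), 1e-5)
  expect_true(all(abs(out) <= abs(x) + 1e-12))

  bad <- list(reduce_map = matrix(0, 2, 5), expand_map = matrix(0, 5, 2))
  expect_error(se_gate(x, bad), "match")
})

test_that("pyramid branches implement grouped same-padding convolution", {
  set.seed(31)
  x <- rarr(2, 8, 6, 6)

  wz <- list(weight = array(0, c(3, 3, 8, 8)), bias = numeric(8))
  expect_equal(pyconv_branch(x, 3, 1, wz), array(0, dim(x)))

  # one-hot centre kernel copies channels through
  wid <- array(0, c(3, 3, 8, 8))
  for (c in 1:8) wid[2, 2, c, c] <- 1
  expect_equal(pyconv_branch(x, 3, 1, list(weight = wid)), x,
               tolerance = 1e-12)

  w <- list(weight = rarr(5, 5, 2, 8), bias = rnorm(8))
  got <- pyconv_branch(x, 5, 4, w)
  expect_lt(max(abs(got - naive_conv2d(x, w$weight, w$bias, groups = 4))),
            1e-5)

  expect_error(pyconv_branch(x, 3, 3, w), "divisible")
})

test_that("ARPC forward matches a transcription oracle built from sub-ops", {
  set.seed(41)
  cfg <- arpc_config(in_channels = 8, branch_channels = 8,
                     branch_groups = c(1, 2, 4, 8), out_channels = 8,
                     se_reduction = 8)
  block <- nn_arpc(cfg)
  x <- rarr(2, 8, 7, 7)

  pv <- param_values(block)
  omega <- adaptive_branch_weights(pv$raw_weights)
  br <- lapply(1:4, function(i) {
    naive_conv2d(x, pv[[paste0("conv", i, ".weight")]],
                 pv[[paste0("conv", i, ".bias")]],
                 groups = cfg$branch_groups[i])
  })
  c1 <- omega[1] * br[[1]] + omega[2] * br[[2]] + omega[3] * br[[3]] +
    omega[4] * br[[4]]
  c2 <- omega[1] * br[[2]] + omega[2] * br[[3]] + omega[3] * br[[4]]
  c3 <- omega[1] * br[[3]] + omega[2] * br[[4]]
  res <- naive_conv2d(x, pv$residual_conv.weight, pv$residual_conv.bias)
  cat4 <- array(0, c(2, 32, 7, 7))
  cat4[, 1:8, , ] <- c1; cat4[, 9:16, , ] <- c2
  cat4[, 17:24, , ] <- c3; cat4[, 25:32, , ] <- res
  gated <- naive_se_gate(cat4, t(pv$se_fc1.weight), t(pv$se_fc2.weight))
  oracle <- naive_conv2d(gated, pv$reduce.weight, pv$reduce.bias)

  expect_lt(max(abs(arpc_forward(x, block) - oracle)), 1e-5)
})

test_that("ARPC with equal raw weights averages the four branches", {
  set.seed(43)
  cfg <- arpc_config(in_channels = 8, branch_channels = 8,
                     branch_groups = c(1, 2, 4, 8), out_channels = 8,
                     se_reduction = 8)
  block <- nn_arpc(cfg)
  # raw weights initialise to zero, so omega = 1/4 each
  x <- rarr(1, 8, 5, 5)
  pv <- param_values(block)
  br <- lapply(1:4, function(i) {
    naive_conv2d(x, pv[[paste0("conv", i, ".weight")]],
                 pv[[paste0("conv", i, ".bias")]],
                 groups = cfg$branch_groups[i])
  })
  mean_br <- (br[[1]] + br[[2]] + br[[3]] + br[[4]]) / 4
  # compare against the block's own combined1 via a one-branch-at-a-time probe:
  omega <- adaptive_branch_weights(pv$raw_weights)
  c1 <- omega[1] * br[[1]] + omega[2] * br[[2]] + omega[3] * br[[3]] +
    omega[4] * br[[4]]
  expect_lt(max(abs(c1 - mean_br)), 1e-5)
})

test_that("ARPC zeroed parameters yield zero output and shapes are preserved", {
  cfg <- arpc_config(in_channels = 16, branch_channels = 16,
                     out_channels = 16, se_reduction = 16)
  block <- nn_arpc(cfg)
  set_all_params(block, 0)
  x <- rarr(1, 16, 6, 6, seed = 5)
  expect_equal(arpc_forward(x, block), array(0, c(1, 16, 6, 6)))

  set.seed(6)
  block2 <- nn_arpc(cfg)
  for (hw in list(c(5, 5), c(6, 9), c(12, 7))) {
    x <- rarr(1, 16, hw[1], hw[2])
    expect_equal(dim(arpc_forward(x, block2)), c(1, 16, hw[1], hw[2]))
  }
  expect_error(arpc_forward(rarr(1, 8, 5, 5), block2), "channel")
})

test_that("ARPC honours the stated full-scale interface shape", {
  set.seed(7)
  block <- nn_arpc(arpc_config())
  x <- rarr(2, 64, 112, 112)
  expect_equal(dim(arpc_forward(x, block)), c(2, 64, 112, 112))
})
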