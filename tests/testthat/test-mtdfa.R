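test_that("soft pooling is a softmax-weighted average", {
  expect_equal(soft_pool(rep(3.7, 10)), 3.7)
  expect_equal(soft_pool(c(0, 0)), 0)
  expect_equal(soft_pool(c(1, 2)), 1.73106, tolerance = 1e-5)
  expect_error(soft_pool(numeric(0)), "empty")
  expect_error(soft_pool(c(1, NA)), "finite")
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(sample(2:12, 1), sd = 2)
    sp <- soft_pool(v)
    expect_gte(sp, mean(v) - 1e-12)
    expect_lte(sp, max(v) + 1e-12)
    expect_equal(sp, naive_soft_pool(v), tolerance = 1e-12)
  }
})

test_that("S-Pool compresses channels into max and soft-pool planes", {
  x <- array(2.5, c(2, 4, 3, 3))
  sp <- s_pool(x)
  expect_equal(dim(sp), c(2, 2, 3, 3))
  expect_equal(sp[, 1, , ], array(2.5, c(2, 3, 3)))
  expect_equal(sp[, 2, , ], array(2.5, c(2, 3, 3)))

  x2 <- array(0, c(1, 2, 1, 1))
  x2[1, , 1, 1] <- c(1, 2)
  expect_equal(s_pool(x2)[1, , 1, 1], c(2, 1.73106), tolerance = 1e-5)

  set.seed(2)
  xr <- rarr(2, 6, 4, 5)
  spr <- s_pool(xr)
  mean_c <- apply(xr, c(1, 3, 4), mean)
  max_c <- apply(xr, c(1, 3, 4), max)
  expect_true(all(spr[, 2, , ] >= mean_c - 1e-12))
  expect_true(all(spr[, 2, , ] <= spr[, 1, , ] + 1e-12))
  expect_equal(spr[, 1, , ], max_c)
  expect_error(s_pool(matrix(0, 2, 2)), "rank-4")
})

test_that("orientation views are exact involutions", {
  set.seed(3)
  x <- rarr(2, 5, 4, 3)
  for (tag in c("CW", "HC", "HW")) {
    v <- orientation_view(tag)
    expect_identical(aperm(aperm(x, v$forward), v$inverse), x)
  }
  expect_equal(dim(aperm(x, orientation_view("CW")$forward)), c(2, 4, 3, 5))
  expect_equal(dim(aperm(x, orientation_view("HC")$forward)), c(2, 3, 4, 5))
})

test_that("Drsc is depthwise-pointwise convolution plus a BN shortcut", {
  set.seed(4)
  blk <- nn_drsc(4, 3, kernel = 5)
  x <- rarr(2, 4, 6, 6)
  out <- drsc_forward(x, blk)
  expect_equal(dim(out), c(2, 3, 6, 6))

  pv <- param_values(blk)
  depth <- naive_conv2d(x, pv$depth.weight, pv$depth.bias, groups = 4)
  point <- naive_conv2d(depth, pv$point.weight, pv$point.bias)
  short <- naive_conv2d(x, pv$shortcut.weight)
  # eval-mode BN with fresh running stats (mean 0, var 1) is an affine identity
  eps <- 1e-5
  for (c in 1:3) {
    short[, c, , ] <- pv$shortcut_bn.gamma[c] * short[, c, , ] / sqrt(1 + eps) +
      pv$shortcut_bn.beta[c]
  }
  expect_lt(max(abs(out - (point + short))), 1e-5)

  set_all_params(blk, 0)
  expect_equal(drsc_forward(x, blk), array(0, c(2, 3, 6, 6)))
})

test_that("attention gate weights sum to one and degrade to uniform", {
  set.seed(5)
  gate <- nn_attention_gate(drsc_kernel = 5)
  # ones input exposes the weight map: output[b,c,,] sums to 1 per channel
  ones <- array(1, c(2, 6, 5, 7))
  out <- attention_gate_forward(ones, gate)
  sums <- apply(out, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, 12), tolerance = 1e-6)

  # zeroed gate convolution -> constant logit map -> uniform weights
  set_all_params(gate, 0)
  x <- rarr(1, 4, 5, 5)
  expect_equal(attention_gate_forward(x, gate), x / 25, tolerance = 1e-10)
})

test_that("attention gate matches the composed S-Pool/Drsc/softmax oracle", {
  set.seed(6)
  gate <- nn_attention_gate(drsc_kernel = 7)
  x <- rarr(2, 5, 6, 6)
  sp <- s_pool(x)
  logit <- drsc_forward(sp, gate$children$drsc)
  w <- array(0, dim(logit))
  for (b in 1:2) w[b, 1, , ] <- array(naive_softmax(as.vector(logit[b, 1, , ])),
                                      c(6, 6))
  oracle <- x
  for (c in 1:5) oracle[, c, , ] <- x[, c, , ] * w[, 1, , ]
  expect_lt(max(abs(attention_gate_forward(x, gate) - oracle)), 1e-5)
})

test_that("local-window attention softmax rows are normalised", {
  set.seed(7)
  a <- matrix(rnorm(9 * 4 * 50), 9 * 4, 50)
  sm <- amwnet:::cpp_softmax_groups_fw(a, 9L)
  dim(sm) <- c(9, 4 * 50)
  expect_equal(colSums(sm), rep(1, 4 * 50), tolerance = 1e-6)
})

test_that("uniform local attention averages each window", {
  set.seed(8)
  cfg <- mtdfa_config(channels = 4, num_heads = 2, dropout_rate = 0)
  ma <- nn_minor_attention(cfg)
  # zero attention map parameters -> uniform softmax over each window
  pv <- amwnet:::nn_parameters(ma)
  pv$attn.weight$value <- 0 * pv$attn.weight$value
  pv$attn.bias$value <- 0 * pv$attn.bias$value

  x <- rarr(1, 4, 5, 5)
  out <- minor_attention_forward(x, ma)

  # oracle: v = W_v x per position; each window output = mean over the window
  # of v; fold with overlap-count normalisation; project.
  Wv <- pv$v_pj.weight$value
  H <- 5; W <- 5
  v <- array(0, dim(x))
  for (h in 1:H) for (w in 1:W) v[1, , h, w] <- Wv %*% x[1, , h, w]
  winmean <- array(0, dim(x))
  acc <- array(0, dim(x)); cnt <- matrix(0, H, W)
  for (h in 1:H) for (w in 1:W) {
    vals <- array(0, c(4, 0))
    for (dh in -1:1) for (dw in -1:1) {
      hi <- h + dh; wi <- w + dw
      vals <- cbind(vals, if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        v[1, , hi, wi] else rep(0, 4))
    }
    m <- rowMeans(vals)  # zero padding contributes to the uniform average
    for (dh in -1:1) for (dw in -1:1) {
      hi <- h + dh; wi <- w + dw
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
        acc[1, , hi, wi] <- acc[1, , hi, wi] + m
        cnt[hi, wi] <- cnt[hi, wi] + 1
      }
    }
  }
  folded <- acc
  for (h in 1:H) for (w in 1:W) folded[1, , h, w] <- acc[1, , h, w] / cnt[h, w]
  Wp <- pv$proj.weight$value; bp <- pv$proj.bias$value
  oracle <- array(0, dim(x))
  for (h in 1:H) for (w in 1:W) {
    oracle[1, , h, w] <- Wp %*% folded[1, , h, w] + bp
  }
  expect_lt(max(abs(out - oracle)), 1e-5)
})

test_that("local-window attention keeps its shape and rejects bad heads", {
  set.seed(9)
  ma <- nn_minor_attention(mtdfa_config(channels = 64, num_heads = 4,
                                        dropout_rate = 0))
  x <- rarr(2, 64, 14, 14)
  expect_equal(dim(minor_attention_forward(x, ma)), c(2, 64, 14, 14))
  expect_error(mtdfa_config(channels = 10, num_heads = 4), "divisible")
})

test_that("MTDFA forward equals the hand-assembled branch composition", {
  set.seed(10)
  cfg <- mtdfa_config(channels = 8, num_heads = 2, dropout_rate = 0)
  mod <- nn_mtdfa(cfg)
  x <- rarr(2, 8, 6, 6)

  ch <- mod$children
  ocw <- orientation_view("CW"); ohc <- orientation_view("HC")
  xcw <- aperm(attention_gate_forward(aperm(x, ocw$forward), ch$gate_cw),
               ocw$inverse)
  xhc <- aperm(attention_gate_forward(aperm(x, ohc$forward), ch$gate_hc),
               ohc$inverse)
  xhw <- attention_gate_forward(x, ch$gate_hw)
  y <- minor_attention_forward(x, ch$minor)
  f1 <- 0.5 * (xcw + xhc)
  f2 <- 0.5 * (xhw + y)
  cat2 <- array(0, c(2, 16, 6, 6))
  cat2[, 1:8, , ] <- f1; cat2[, 9:16, , ] <- f2
  pv <- param_values(ch$fuse)
  oracle <- naive_conv2d(cat2, pv$weight, pv$bias)

  expect_lt(max(abs(mtdfa_forward(x, mod) - oracle)), 1e-5)
})

test_that("stubbed equal channel branches pass through fusion unchanged", {
  # Eq-style check: x_fusion1 = 0.5 (A + A) = A
  A <- rarr(1, 3, 4, 4, seed = 11)
  expect_equal(0.5 * (A + A), A)
})

test_that("MTDFA is deterministic in evaluation mode and keeps shape", {
  set.seed(12)
  mod <- nn_mtdfa(mtdfa_config(channels = 16, num_heads = 4))
  x <- rarr(2, 16, 8, 8)
  o1 <- mtdfa_forward(x, mod, training = FALSE)
  o2 <- mtdfa_forward(x, mod, training = FALSE)
  expect_identical(o1, o2)
  expect_equal(dim(o1), dim(x))
})

test_that("MTDFA honours the stated full-scale interface shape", {
  set.seed(13)
  mod <- nn_mtdfa(mtdfa_config())
  x <- rarr(2, 64, 112, 112)
  expect_equal(dim(mtdfa_forward(x, mod)), c(2, 64, 112, 112))
})
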