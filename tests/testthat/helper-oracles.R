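# Independent oracles: literal, slow transcriptions used to cross-check the
# optimised implementations.

# Naive grouped 2-D convolution with same/strided padding, nested loops.
naive_conv2d <- function(x, w, bias = NULL, stride = 1L, pad = NULL,
                         groups = 1L) {
  d <- dim(x); B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  wd <- dim(w); KH <- wd[1]; KW <- wd[2]; Cg <- wd[3]; Cout <- wd[4]
  if (is.null(pad)) pad <- (KH - 1L) %/% 2L
  Ho <- (H + 2 * pad - KH) %/% stride + 1L
  Wo <- (W + 2 * pad - KW) %/% stride + 1L
  Coutg <- Cout %/% groups
  y <- array(0, c(B, Cout, Ho, Wo))
  for (b in 1:B) for (co in 1:Cout) {
    g <- (co - 1) %/% Coutg
    for (ho in 1:Ho) for (wo in 1:Wo) {
      acc <- if (is.null(bias)) 0 else bias[co]
      for (cl in 1:Cg) for (kh in 1:KH) for (kw in 1:KW) {
        hi <- (ho - 1) * stride - pad + kh
        wi <- (wo - 1) * stride - pad + kw
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
          acc <- acc + x[b, g * Cg + cl, hi, wi] * w[kh, kw, cl, co]
        }
      }
      y[b, co, ho, wo] <- acc
    }
  }
  y
}

# Softmax of a vector.
naive_softmax <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# Step-by-step squeeze-and-excitation oracle.
naive_se_gate <- function(x, W1, W2) {
  d <- dim(x)
  y <- x
  for (b in 1:d[1]) {
    pooled <- vapply(1:d[2], function(c) mean(x[b, c, , ]), numeric(1))
    h <- pmax(W1 %*% pooled, 0)
    g <- 1 / (1 + exp(-(W2 %*% h)))
    for (c in 1:d[2]) y[b, c, , ] <- x[b, c, , ] * g[c]
  }
  y
}

# Soft pooling of a region.
naive_soft_pool <- function(v) sum(naive_softmax(v) * v)

# Build a zero array with the dims of a parameter value.
set_all_params <- function(mod, value = 0) {
  for (p in amwnet:::nn_parameters(mod)) {
    p$value <- array(value, dim(p$value) %||% length(p$value))
    if (is.null(dim(p$value))) p$value <- rep(value, length(p$value))
  }
  invisible(mod)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Snapshot of all parameter values of a module (named list of arrays).
param_values <- function(mod) {
  lapply(amwnet:::nn_parameters(mod), function(p) p$value)
}

# Stride-1 same average pooling, naive loops.
naive_avgpool_same <- function(x, k) {
  d <- dim(x); pad <- (k - 1) %/% 2
  y <- array(0, d)
  for (b in 1:d[1]) for (c in 1:d[2]) for (h in 1:d[3]) for (w in 1:d[4]) {
    vals <- c()
    for (dh in -pad:pad) for (dw in -pad:pad) {
      hi <- h + dh; wi <- w + dw
      if (hi >= 1 && hi <= d[3] && wi >= 1 && wi <= d[4]) {
        vals <- c(vals, x[b, c, hi, wi])
      }
    }
    y[b, c, h, w] <- mean(vals)
  }
  y
}

# Deterministic small random arrays.
rarr <- function(..., seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- c(...)
  array(stats::rnorm(prod(d)), d)
}
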