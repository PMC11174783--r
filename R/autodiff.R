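#' @useDynLib amwnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Minimal reverse-mode autodiff tape.
#
# A tape records nodes in creation order; because every edge points from a
# lower id to a higher id, walking ids in reverse is a valid topological order
# for backpropagation.  Node values are plain R arrays/matrices; the heavy
# operators call the C++ kernels in src/ops.cpp.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$param <- NULL
  nd$tape <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_const <- function(tape, value) ad_node(tape, value)

# Trainable parameter: a persistent environment carrying value, accumulated
# gradient and optimizer state.
nn_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  class(p) <- "nn_param"
  p
}

is_param <- function(x) inherits(x, "nn_param")
is_node <- function(x) is.environment(x) && !is.null(x$tape)

# Coerce a parameter / plain array to a tape node.
as_node <- function(tape, x) {
  if (is_param(x)) {
    nd <- ad_node(tape, x$value)
    nd$param <- x
    nd
  } else if (is_node(x)) {
    x
  } else {
    ad_const(tape, x)
  }
}

.acc_grad <- function(target, g) {
  if (is.null(target$grad)) target$grad <- g else target$grad <- target$grad + g
}

# Backpropagate from a scalar loss node.
ad_backward <- function(loss) {
  tape <- loss$tape
  loss$grad <- 1
  for (i in seq(loss$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad)) next
    if (!is.null(nd$param)) .acc_grad(nd$param, nd$grad)
    if (is.null(nd$backward)) next
    gs <- nd$backward(nd, nd$grad)
    for (k in seq_along(nd$parents)) {
      if (!is.null(gs[[k]])) .acc_grad(nd$parents[[k]], gs[[k]])
    }
    nd$grad <- NULL  # release memory as we go
    nd$value <- NULL
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Primitive operators
# ---------------------------------------------------------------------------

ad_conv2d <- function(x, weight, bias = NULL, stride = 1L, pad = NULL,
                      groups = 1L) {
  tp <- x$tape
  w <- as_node(tp, weight)
  k <- dim(w$value)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  has_bias <- !is.null(bias)
  b <- if (has_bias) as_node(tp, bias) else NULL
  bvec <- if (has_bias) b$value else numeric(0)
  fast1x1 <- k == 1L && stride == 1L && groups == 1L
  y <- if (fast1x1) {
    cpp_conv1x1_fw(x$value, w$value, bvec)
  } else {
    cpp_conv2d_fw(x$value, w$value, bvec, as.integer(stride),
                  as.integer(pad), as.integer(groups))
  }
  parents <- if (has_bias) list(x, w, b) else list(x, w)
  ad_node(tp, y, parents, function(nd, g) {
    bw <- if (fast1x1) {
      cpp_conv1x1_bw(nd$.x, nd$.w, g, has_bias)
    } else {
      cpp_conv2d_bw(nd$.x, nd$.w, g, as.integer(stride), as.integer(pad),
                    as.integer(groups), has_bias)
    }
    if (has_bias) list(bw$dx, bw$dw, bw$db) else list(bw$dx, bw$dw)
  }) -> nd
  nd$.x <- x$value
  nd$.w <- w$value
  nd
}

ad_relu <- function(x) {
  nd <- ad_node(x$tape, cpp_relu_fw(x$value), list(x), function(nd, g) {
    list(cpp_relu_bw(nd$.x, g))
  })
  nd$.x <- x$value
  nd
}

ad_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  nd <- ad_node(x$tape, y, list(x), function(nd, g) list(g * nd$.y * (1 - nd$.y)))
  nd$.y <- y
  nd
}

ad_add <- function(x, y) {
  ad_node(x$tape, x$value + y$value, list(x, y), function(nd, g) list(g, g))
}

ad_scale <- function(x, s) {
  ad_node(x$tape, x$value * s, list(x), function(nd, g) list(g * s))
}

# y = sum_k w[idx[k]] * x_k, for a list of equally shaped arrays and a weight
# vector node (the adaptive branch fusion of the pyramid block).
ad_weighted_sum <- function(xs, wnode, idx) {
  tp <- xs[[1]]$tape
  wv <- wnode$value
  y <- xs[[1]]$value * wv[idx[1]]
  if (length(xs) > 1) {
    for (k in 2:length(xs)) y <- y + xs[[k]]$value * wv[idx[k]]
  }
  nd <- ad_node(tp, y, c(xs, list(wnode)), function(nd, g) {
    out <- vector("list", length(nd$.idx) + 1L)
    dw <- numeric(length(nd$.wv))
    for (k in seq_along(nd$.idx)) {
      out[[k]] <- g * nd$.wv[nd$.idx[k]]
      dw[nd$.idx[k]] <- dw[nd$.idx[k]] + sum(g * nd$.xs[[k]])
    }
    out[[length(out)]] <- dw
    out
  })
  nd$.idx <- idx
  nd$.wv <- wv
  nd$.xs <- lapply(xs, function(n) n$value)
  nd
}

ad_concat_channels <- function(xs) {
  tp <- xs[[1]]$tape
  dims <- lapply(xs, function(n) dim(n$value))
  cs <- vapply(dims, function(d) d[2], numeric(1))
  d0 <- dims[[1]]
  y <- array(0, c(d0[1], sum(cs), d0[3], d0[4]))
  off <- 0L
  for (k in seq_along(xs)) {
    y[, (off + 1):(off + cs[k]), , ] <- xs[[k]]$value
    off <- off + cs[k]
  }
  nd <- ad_node(tp, y, xs, function(nd, g) {
    out <- vector("list", length(nd$.cs))
    off <- 0L
    for (k in seq_along(nd$.cs)) {
      out[[k]] <- g[, (off + 1):(off + nd$.cs[k]), , , drop = FALSE]
      off <- off + nd$.cs[k]
    }
    out
  })
  nd$.cs <- cs
  nd
}

ad_permute <- function(x, perm) {
  nd <- ad_node(x$tape, aperm(x$value, perm), list(x),
                function(nd, g) list(aperm(g, nd$.inv)))
  nd$.inv <- order(perm)
  nd
}

ad_reshape <- function(x, new_dim) {
  old <- dim(x$value)
  y <- x$value
  dim(y) <- new_dim
  nd <- ad_node(x$tape, y, list(x), function(nd, g) {
    dim(g) <- nd$.old
    list(g)
  })
  nd$.old <- old
  nd
}

ad_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  fw <- cpp_maxpool_fw(x$value, as.integer(k), as.integer(stride),
                       as.integer(pad))
  nd <- ad_node(x$tape, fw$y, list(x), function(nd, g) {
    list(cpp_maxpool_bw(nd$.idx, g, nd$.xdim))
  })
  nd$.idx <- fw$idx
  nd$.xdim <- dim(x$value)
  nd
}

ad_avgpool_same <- function(x, k = 3L) {
  y <- cpp_avgpool_same(x$value, as.integer(k), FALSE)
  ad_node(x$tape, y, list(x), function(nd, g) {
    list(cpp_avgpool_same(g, as.integer(k), TRUE))
  })
}

ad_gap <- function(x) {
  nd <- ad_node(x$tape, cpp_gap_fw(x$value), list(x), function(nd, g) {
    list(cpp_gap_bw(g, nd$.h, nd$.w))
  })
  nd$.h <- dim(x$value)[3]
  nd$.w <- dim(x$value)[4]
  nd
}

# Dense layer on row-major design matrices: x (N, F), weight (F, O).
ad_linear <- function(x, weight, bias = NULL) {
  tp <- x$tape
  w <- as_node(tp, weight)
  y <- x$value %*% w$value
  has_bias <- !is.null(bias)
  if (has_bias) {
    b <- as_node(tp, bias)
    y <- sweep(y, 2, b$value, "+")
    parents <- list(x, w, b)
  } else {
    parents <- list(x, w)
  }
  nd <- ad_node(tp, y, parents, function(nd, g) {
    dx <- g %*% t(nd$.w)
    dw <- t(nd$.x) %*% g
    if (has_bias) list(dx, dw, colSums(g)) else list(dx, dw)
  })
  nd$.x <- x$value
  nd$.w <- w$value
  nd
}

# Per-position linear map on a (C, N) matrix view: y = W x (+ b per row).
ad_linear_cmat <- function(x, weight, bias = NULL) {
  tp <- x$tape
  w <- as_node(tp, weight)
  y <- w$value %*% x$value
  has_bias <- !is.null(bias)
  if (has_bias) {
    b <- as_node(tp, bias)
    y <- y + b$value  # recycled down columns
    parents <- list(x, w, b)
  } else {
    parents <- list(x, w)
  }
  nd <- ad_node(tp, y, parents, function(nd, g) {
    dx <- crossprod(nd$.w, g)
    dw <- tcrossprod(g, nd$.x)
    if (has_bias) list(dx, dw, rowSums(g)) else list(dx, dw)
  })
  nd$.x <- x$value
  nd$.w <- w$value
  nd
}

ad_cmat <- function(x) {
  d <- dim(x$value)
  nd <- ad_node(x$tape, cpp_nchw_to_cmat(x$value), list(x), function(nd, g) {
    list(cpp_cmat_to_nchw(g, nd$.b, nd$.h, nd$.w))
  })
  nd$.b <- d[1]; nd$.h <- d[3]; nd$.w <- d[4]
  nd
}

ad_from_cmat <- function(x, B, H, W) {
  ad_node(x$tape, cpp_cmat_to_nchw(x$value, as.integer(B), as.integer(H),
                                   as.integer(W)),
          list(x), function(nd, g) list(cpp_nchw_to_cmat(g)))
}

# Row-wise softmax of a matrix with few rows or few columns; numerically
# stabilised per row.
softmax_rows_value <- function(x) {
  mx <- apply(x, 1, max)
  e <- exp(x - mx)  # mx recycles down columns
  e / rowSums(e)
}

ad_softmax_rows <- function(x) {
  y <- softmax_rows_value(x$value)
  nd <- ad_node(x$tape, y, list(x), function(nd, g) {
    s <- rowSums(g * nd$.y)
    list(nd$.y * (g - s))
  })
  nd$.y <- y
  nd
}

# Column-wise softmax (over the first axis); the number of rows is small.
ad_softmax_cols <- function(x) {
  y <- cpp_softmax_cols_fw(x$value)
  nd <- ad_node(x$tape, y, list(x), function(nd, g) {
    list(cpp_softmax_cols_bw(nd$.y, g))
  })
  nd$.y <- y
  nd
}

ad_softmax_vec <- function(x) {
  v <- x$value
  e <- exp(v - max(v))
  y <- e / sum(e)
  nd <- ad_node(x$tape, y, list(x), function(nd, g) {
    list(nd$.y * (g - sum(g * nd$.y)))
  })
  nd$.y <- y
  nd
}

ad_scale_channels <- function(x, g) {
  nd <- ad_node(x$tape, cpp_scale_bc(x$value, g$value), list(x, g),
                function(nd, gr) {
                  list(cpp_scale_bc(gr, nd$.g), cpp_dot_bc(nd$.x, gr))
                })
  nd$.x <- x$value
  nd$.g <- g$value
  nd
}

ad_scale_spatial <- function(x, wmap) {
  nd <- ad_node(x$tape, cpp_scale_spatial(x$value, wmap$value), list(x, wmap),
                function(nd, g) {
                  list(cpp_scale_spatial(g, nd$.w), cpp_dot_spatial(nd$.x, g))
                })
  nd$.x <- x$value
  nd$.w <- wmap$value
  nd
}

ad_chanmax <- function(x) {
  fw <- cpp_chanmax_fw(x$value)
  nd <- ad_node(x$tape, fw$y, list(x), function(nd, g) {
    list(cpp_maxpool_bw(nd$.idx, g, nd$.xdim))
  })
  nd$.idx <- fw$idx
  nd$.xdim <- dim(x$value)
  nd
}

ad_softpool_channels <- function(x) {
  nd <- ad_node(x$tape, cpp_softpool_fw(x$value), list(x), function(nd, g) {
    list(cpp_softpool_bw(nd$.x, g))
  })
  nd$.x <- x$value
  nd
}

ad_unfold <- function(x, k) {
  nd <- ad_node(x$tape, cpp_unfold(x$value, as.integer(k)), list(x),
                function(nd, g) {
                  list(cpp_fold_raw(g, nd$.c, nd$.h, nd$.w, as.integer(k)))
                })
  d <- dim(x$value)
  nd$.c <- as.integer(d[2]); nd$.h <- as.integer(d[3]); nd$.w <- as.integer(d[4])
  nd
}

# Fold with overlap-count normalisation: a constant unfold buffer maps back to
# the same constant map.
ad_fold_mean <- function(col, C, H, W, k) {
  cnt <- cpp_overlap_count(as.integer(H), as.integer(W), as.integer(k))
  y <- cpp_fold_raw(col$value, as.integer(C), as.integer(H), as.integer(W),
                    as.integer(k))
  y <- sweep(y, c(3, 4), cnt, "/")
  nd <- ad_node(col$tape, y, list(col), function(nd, g) {
    gn <- sweep(g, c(3, 4), nd$.cnt, "/")
    list(cpp_unfold(gn, as.integer(k)))
  })
  nd$.cnt <- cnt
  nd
}

ad_attn_agg <- function(A, V, k2, heads, hd) {
  nd <- ad_node(A$tape,
                cpp_attn_agg_fw(A$value, V$value, as.integer(k2),
                                as.integer(heads), as.integer(hd)),
                list(A, V), function(nd, g) {
                  bw <- cpp_attn_agg_bw(nd$.A, nd$.V, g, as.integer(k2),
                                        as.integer(heads), as.integer(hd))
                  list(bw$dA, bw$dV)
                })
  nd$.A <- A$value
  nd$.V <- V$value
  nd
}

ad_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  mask <- (stats::runif(length(x$value)) >= rate) / (1 - rate)
  dim(mask) <- dim(x$value)
  nd <- ad_node(x$tape, x$value * mask, list(x),
                function(nd, g) list(g * nd$.m))
  nd$.m <- mask
  nd
}

# Batch normalisation over (B, H, W) per channel.  `state` carries running
# statistics across calls.
ad_bn2d <- function(x, gamma, beta, state, training, momentum = 0.1,
                    eps = 1e-5) {
  tp <- x$tape
  gnode <- as_node(tp, gamma)
  bnode <- as_node(tp, beta)
  d <- dim(x$value)
  m <- prod(d[c(1, 3, 4)])
  if (training) {
    s1 <- cpp_channel_sums(x$value, FALSE)
    s2 <- cpp_channel_sums(x$value, TRUE)
    mu <- s1 / m
    var <- pmax(s2 / m - mu^2, 0)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    ub <- if (m > 1) var * m / (m - 1) else var
    state$running_var <- (1 - momentum) * state$running_var + momentum * ub
  } else {
    mu <- state$running_mean
    var <- state$running_var
  }
  invstd <- 1 / sqrt(var + eps)
  gv <- gnode$value
  y <- cpp_channel_affine(x$value, gv * invstd, bnode$value - gv * invstd * mu)
  nd <- ad_node(tp, y, list(x, gnode, bnode), function(nd, g) {
    dbeta <- cpp_channel_sums(g, FALSE)
    xhat <- cpp_channel_affine(nd$.x, nd$.invstd, -nd$.mu * nd$.invstd)
    dgamma <- cpp_channel_sum_prod(g, xhat)
    a <- nd$.g * nd$.invstd
    if (nd$.training) {
      dx <- cpp_channel_affine(g, a, -a * dbeta / nd$.m) -
        cpp_channel_affine(xhat, a * dgamma / nd$.m, numeric(length(a)) * 0)
    } else {
      dx <- cpp_channel_affine(g, a, numeric(length(a)) * 0)
    }
    list(dx, dgamma, dbeta)
  })
  nd$.x <- x$value
  nd$.mu <- mu
  nd$.invstd <- invstd
  nd$.g <- gv
  nd$.m <- m
  nd$.training <- training
  nd
}

# Softmax over contiguous row blocks of size k (no reshape copies).
ad_softmax_groups <- function(x, k) {
  y <- cpp_softmax_groups_fw(x$value, as.integer(k))
  nd <- ad_node(x$tape, y, list(x), function(nd, g) {
    list(cpp_softmax_groups_bw(nd$.y, g, as.integer(k)))
  })
  nd$.y <- y
  nd
}
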