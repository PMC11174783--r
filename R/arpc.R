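#' Configuration for the adaptive residual pyramid convolution block
#'
#' ARPC runs four grouped convolutions with growing kernels (3/5/7/9 by
#' default) in parallel, fuses them with softmax-normalised adaptive weights,
#' concatenates the fused maps with a residual convolution of the input,
#' applies squeeze-and-excitation channel gating, and reduces back to
#' `out_channels` with a 1x1 convolution.
#'
#' @param in_channels Input channel count.
#' @param branch_kernels Four odd kernel sizes, one per pyramid branch.
#' @param branch_groups Four group counts, one per branch.
#' @param branch_channels Output channels of every branch.
#' @param out_channels Channels after the final 1x1 reduction.
#' @param se_reduction Squeeze-and-excitation bottleneck ratio; must divide
#'   `4 * branch_channels`.
#' @return A list of class `arpc_config`.
#' @export
arpc_config <- function(in_channels = 64L, branch_kernels = c(3L, 5L, 7L, 9L),
                        branch_groups = c(1L, 4L, 8L, 16L),
                        branch_channels = 64L, out_channels = 64L,
                        se_reduction = 16L) {
  if (length(branch_kernels) != 4 || length(branch_groups) != 4) {
    stop("exactly four pyramid branches are required", call. = FALSE)
  }
  if (any(branch_kernels %% 2 == 0)) {
    stop("branch kernels must be odd for same-padding", call. = FALSE)
  }
  if (any(branch_channels %% branch_groups != 0) ||
      any(in_channels %% branch_groups != 0)) {
    stop("branch_channels and in_channels must be divisible by every group count",
         call. = FALSE)
  }
  if ((4L * branch_channels) %% se_reduction != 0) {
    stop("se_reduction must divide 4 * branch_channels", call. = FALSE)
  }
  structure(list(in_channels = as.integer(in_channels),
                 branch_kernels = as.integer(branch_kernels),
                 branch_groups = as.integer(branch_groups),
                 branch_channels = as.integer(branch_channels),
                 out_channels = as.integer(out_channels),
                 se_reduction = as.integer(se_reduction)),
            class = "arpc_config")
}

#' Softmax-normalised adaptive branch weights
#'
#' Maps the raw 4-vector of branch logits onto the probability simplex,
#' `out_i = exp(w_i) / sum_j exp(w_j)`.
#'
#' @param raw Numeric vector of four finite branch logits.
#' @return Length-4 non-negative vector summing to one.
#' @export
adaptive_branch_weights <- function(raw) {
  if (length(raw) != 4 || !all(is.finite(raw))) {
    stop("`raw` must be four finite numbers", call. = FALSE)
  }
  e <- exp(raw - max(raw))
  e / sum(e)
}

#' Squeeze-and-excitation channel gate
#'
#' Computes `sigma(W2 %*% relu(W1 %*% avgpool(x)))` per sample and rescales
#' every channel of `x` by the resulting gate in (0, 1).
#'
#' @param x Feature map, a `(B, C, H, W)` array.
#' @param params List with `reduce_map` (`C/r x C`) and `expand_map`
#'   (`C x C/r`) matrices.
#' @return Array of the same shape as `x`.
#' @export
se_gate <- function(x, params) {
  C <- dim(x)[2]
  if (ncol(params$reduce_map) != C || nrow(params$expand_map) != C) {
    stop("SE parameter shapes do not match the channel count", call. = FALSE)
  }
  pooled <- cpp_gap_fw(x)                        # B x C
  h <- pmax(pooled %*% t(params$reduce_map), 0)  # B x C/r
  g <- 1 / (1 + exp(-(h %*% t(params$expand_map))))
  cpp_scale_bc(x, g)
}

#' Single pyramid-convolution branch
#'
#' Grouped 2-D convolution with same padding; a thin functional wrapper used
#' by tests and by the block itself.
#'
#' @param x Feature map `(B, C, H, W)`.
#' @param kernel Odd kernel size.
#' @param groups Group count dividing the input channels.
#' @param weights List with `weight` array `(k, k, C/groups, C_out)` and
#'   optional `bias` vector.
#' @return Convolved feature map with unchanged spatial size.
#' @export
pyconv_branch <- function(x, kernel, groups, weights) {
  if (dim(x)[2] %% groups != 0) {
    stop("input channels are not divisible by `groups`", call. = FALSE)
  }
  bias <- weights$bias %||% numeric(0)
  cpp_conv2d_fw(x, weights$weight, bias, 1L, (kernel - 1L) %/% 2L,
                as.integer(groups))
}

#' Build an ARPC block
#'
#' @param cfg An [arpc_config()].
#' @return An `nn_module` whose forward maps `(B, in_channels, H, W)` to
#'   `(B, out_channels, H, W)`.
#' @export
nn_arpc <- function(cfg = arpc_config()) {
  raw <- nn_param(numeric(4))  # uniform branches at initialisation
  convs <- lapply(1:4, function(i) {
    nn_conv2d(cfg$in_channels, cfg$branch_channels, cfg$branch_kernels[i],
              groups = cfg$branch_groups[i])
  })
  residual <- nn_conv2d(cfg$in_channels, cfg$branch_channels, 3L)
  cat_ch <- 4L * cfg$branch_channels
  se_fc1 <- nn_linear(cat_ch, cat_ch %/% cfg$se_reduction, bias = FALSE)
  se_fc2 <- nn_linear(cat_ch %/% cfg$se_reduction, cat_ch, bias = FALSE)
  reduce <- nn_conv2d(cat_ch, cfg$out_channels, 1L)

  fwd <- function(x, training = FALSE) {
    if (dim(x$value)[2] != cfg$in_channels) {
      stop("ARPC input channel mismatch", call. = FALSE)
    }
    w <- ad_softmax_vec(as_node(x$tape, raw))
    br <- lapply(convs, function(cv) cv$forward(x, training))
    combined1 <- ad_weighted_sum(br, w, 1:4)
    combined2 <- ad_weighted_sum(br[2:4], w, 1:3)
    combined3 <- ad_weighted_sum(br[3:4], w, 1:2)
    res <- residual$forward(x, training)
    cat <- ad_concat_channels(list(combined1, combined2, combined3, res))
    pooled <- ad_gap(cat)
    gate <- ad_sigmoid(se_fc2$forward(ad_relu(se_fc1$forward(pooled))))
    gated <- ad_scale_channels(cat, gate)
    reduce$forward(gated, training)
  }

  new_module("arpc",
             params = list(raw_weights = raw),
             children = list(conv1 = convs[[1]], conv2 = convs[[2]],
                             conv3 = convs[[3]], conv4 = convs[[4]],
                             residual_conv = residual, se_fc1 = se_fc1,
                             se_fc2 = se_fc2, reduce = reduce),
             forward = fwd, meta = list(cfg = cfg))
}

#' Forward pass through an ARPC block on a plain array
#'
#' @param x `(B, in_channels, H, W)` array.
#' @param block Module from [nn_arpc()].
#' @param training Use batch statistics and dropout (none here) if `TRUE`.
#' @return `(B, out_channels, H, W)` array.
#' @export
arpc_forward <- function(x, block, training = FALSE) {
  module_apply(block, x, training)
}
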