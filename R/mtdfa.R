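#' Configuration for the triplet disease-focus attention module
#'
#' MTDFA applies an attention gate along three permuted orientations of the
#' feature map — channel-width (CW), height-channel (HC) and height-width
#' (HW) — plus a local-window attention branch for minute lesions, and fuses
#' the four branches with averaging and a 1x1 convolution.
#'
#' @param channels Feature channels; must be divisible by `num_heads`.
#' @param num_heads Attention heads of the local-window branch.
#' @param kernel_size Odd local window size.
#' @param drsc_kernel Odd depthwise kernel of the gate's separable convolution.
#' @param dropout_rate Dropout applied after the local-window projection.
#' @param scale Attention logit scale; defaults to `head_dim^(-1/2)`.
#' @return A list of class `mtdfa_config`.
#' @export
mtdfa_config <- function(channels = 64L, num_heads = 4L, kernel_size = 3L,
                         drsc_kernel = 7L, dropout_rate = 0.1, scale = NULL) {
  if (channels %% num_heads != 0) {
    stop("`channels` must be divisible by `num_heads`", call. = FALSE)
  }
  if (kernel_size %% 2 == 0 || drsc_kernel %% 2 == 0) {
    stop("kernel sizes must be odd", call. = FALSE)
  }
  head_dim <- channels %/% num_heads
  structure(list(channels = as.integer(channels),
                 num_heads = as.integer(num_heads),
                 kernel_size = as.integer(kernel_size),
                 drsc_kernel = as.integer(drsc_kernel),
                 dropout_rate = dropout_rate,
                 head_dim = head_dim,
                 scale = scale %||% head_dim^(-0.5)),
            class = "mtdfa_config")
}

#' Orientation views of a feature map
#'
#' Returns the forward and inverse axis permutations that move a `(B, C, H,
#' W)` map into the CW, HC or HW layout; `inverse` applied after `forward` is
#' the identity.
#'
#' @param tag One of `"CW"`, `"HC"`, `"HW"`.
#' @return List with `tag`, `forward` and `inverse` permutation vectors.
#' @export
orientation_view <- function(tag = c("CW", "HC", "HW")) {
  tag <- match.arg(tag)
  fwd <- switch(tag,
                CW = c(1L, 3L, 4L, 2L),  # (B,H,W,C)
                HC = c(1L, 4L, 3L, 2L),  # (B,W,H,C)
                HW = c(1L, 2L, 3L, 4L))
  list(tag = tag, forward = fwd, inverse = order(fwd))
}

#' Softmax-weighted pooling of a region
#'
#' `sum_i softmax(a)_i * a_i`: a smooth compromise between average and max
#' pooling that favours large activations.
#'
#' @param values Non-empty finite numeric vector.
#' @return Scalar in `[mean(values), max(values)]`.
#' @export
soft_pool <- function(values) {
  if (length(values) == 0) stop("empty pooling region", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite pooling values", call. = FALSE)
  e <- exp(values - max(values))
  sum(e * values) / sum(e)
}

#' Two-channel compression (S-Pool)
#'
#' Compresses the channel axis of an oriented feature map into a max-pool
#' plane and a softmax-weighted ("soft") pool plane.
#'
#' @param x `(B, C, H, W)` array in the branch's oriented layout.
#' @return `(B, 2, H, W)` array: channel 1 max, channel 2 soft pool.
#' @export
s_pool <- function(x) {
  if (length(dim(x)) != 4) stop("`x` must be a rank-4 array", call. = FALSE)
  mx <- cpp_chanmax_fw(x)$y
  sp <- cpp_softpool_fw(x)
  d <- dim(x)
  out <- array(0, c(d[1], 2L, d[3], d[4]))
  out[, 1, , ] <- mx
  out[, 2, , ] <- sp
  out
}

#' Depthwise-separable convolution with a projected shortcut
#'
#' Depthwise convolution (same padding) followed by a pointwise 1x1
#' convolution, plus a 1x1 convolution + batch normalisation shortcut.
#'
#' @param in_ch,out_ch Channel counts.
#' @param kernel Odd depthwise kernel size.
#' @return An `nn_module`.
#' @export
nn_drsc <- function(in_ch, out_ch, kernel = 7L) {
  depth <- nn_conv2d(in_ch, in_ch, kernel, groups = in_ch)
  point <- nn_conv2d(in_ch, out_ch, 1L)
  short <- nn_conv2d(in_ch, out_ch, 1L, bias = FALSE)
  short_bn <- nn_bn2d(out_ch)
  new_module("drsc",
             children = list(depth = depth, point = point, shortcut = short,
                             shortcut_bn = short_bn),
             forward = function(x, training = FALSE) {
               main <- point$forward(depth$forward(x, training), training)
               sc <- short_bn$forward(short$forward(x, training), training)
               ad_add(main, sc)
             })
}

#' Attention gate over one orientation
#'
#' S-Pool compresses the leading non-batch axis to two planes, a
#' depthwise-separable convolution with shortcut reduces them to a single
#' logit map, a softmax over all spatial positions turns it into a weight map
#' summing to one per sample, and the input is rescaled by the broadcast map.
#'
#' @param drsc_kernel Depthwise kernel of the gate convolution.
#' @return An `nn_module` mapping `(B, C, H, W)` to the same shape.
#' @export
nn_attention_gate <- function(drsc_kernel = 7L) {
  gate_conv <- nn_drsc(2L, 1L, drsc_kernel)
  new_module("attention_gate", children = list(drsc = gate_conv),
             forward = function(x, training = FALSE) {
               d <- dim(x$value)
               mx <- ad_chanmax(x)
               sp <- ad_softpool_channels(x)
               pooled <- ad_concat_channels(list(mx, sp))
               logit <- gate_conv$forward(pooled, training)  # (B,1,H,W)
               flat <- ad_reshape(logit, c(d[1], d[3] * d[4]))
               wmap <- ad_reshape(ad_softmax_rows(flat), c(d[1], 1L, d[3], d[4]))
               ad_scale_spatial(x, wmap)
             })
}

#' Local-window (outlook-style) attention for minute lesions
#'
#' A value projection is unfolded into k x k windows; per-position, per-head
#' k^2 x k^2 attention logits are produced from average-pooled features,
#' softmax-normalised over the source axis, used to aggregate the window
#' values, folded back with overlap normalisation, and projected.
#'
#' @param cfg An [mtdfa_config()].
#' @return An `nn_module` preserving the input shape.
#' @export
nn_minor_attention <- function(cfg = mtdfa_config()) {
  C <- cfg$channels
  k <- cfg$kernel_size
  k2 <- k * k
  heads <- cfg$num_heads
  hd <- cfg$head_dim
  v_pj <- nn_linear(C, C, bias = FALSE, layout = "cmat")
  attn <- nn_linear(C, heads * k2 * k2, layout = "cmat")
  proj <- nn_linear(C, C, layout = "cmat")
  new_module("minor_attention",
             children = list(v_pj = v_pj, attn = attn, proj = proj),
             meta = list(cfg = cfg),
             forward = function(x, training = FALSE) {
               d <- dim(x$value)
               if (d[2] != C) stop("channel mismatch in MinorAttention",
                                   call. = FALSE)
               B <- d[1]; H <- d[3]; W <- d[4]; N <- B * H * W
               v <- ad_from_cmat(v_pj$forward(ad_cmat(x)), B, H, W)
               vu <- ad_unfold(v, k)                       # (B, C*k2, L)
               pooled <- ad_avgpool_same(x, k)
               logits <- attn$forward(ad_cmat(pooled))     # (heads*k2*k2, N)
               scaled <- ad_scale(logits, cfg$scale)
               amat <- ad_softmax_groups(scaled, k2)
               agg <- ad_attn_agg(amat, vu, k2, heads, hd)
               folded <- ad_fold_mean(agg, C, H, W, k)
               y <- ad_from_cmat(proj$forward(ad_cmat(folded)), B, H, W)
               ad_dropout(y, cfg$dropout_rate, training)
             })
}

#' Build the full MTDFA module
#'
#' @param cfg An [mtdfa_config()].
#' @return An `nn_module` mapping `(B, channels, H, W)` to the same shape.
#' @export
nn_mtdfa <- function(cfg = mtdfa_config()) {
  gate_cw <- nn_attention_gate(cfg$drsc_kernel)
  gate_hc <- nn_attention_gate(cfg$drsc_kernel)
  gate_hw <- nn_attention_gate(cfg$drsc_kernel)
  minor <- nn_minor_attention(cfg)
  fuse <- nn_conv2d(2L * cfg$channels, cfg$channels, 1L)
  ocw <- orientation_view("CW")
  ohc <- orientation_view("HC")
  new_module("mtdfa",
             children = list(gate_cw = gate_cw, gate_hc = gate_hc,
                             gate_hw = gate_hw, minor = minor, fuse = fuse),
             meta = list(cfg = cfg),
             forward = function(x, training = FALSE) {
               if (dim(x$value)[2] != cfg$channels) {
                 stop("MTDFA input channel mismatch", call. = FALSE)
               }
               xcw <- ad_permute(gate_cw$forward(ad_permute(x, ocw$forward),
                                                 training), ocw$inverse)
               xhc <- ad_permute(gate_hc$forward(ad_permute(x, ohc$forward),
                                                 training), ohc$inverse)
               xhw <- gate_hw$forward(x, training)
               y <- minor$forward(x, training)
               f1 <- ad_scale(ad_add(xcw, xhc), 0.5)
               f2 <- ad_scale(ad_add(xhw, y), 0.5)
               fuse$forward(ad_concat_channels(list(f1, f2)), training)
             })
}

#' Forward passes on plain arrays
#'
#' Convenience wrappers running a built module on an array input.
#'
#' @param x `(B, C, H, W)` array.
#' @param block Module built by the matching constructor.
#' @param training Logical; enables dropout and batch statistics.
#' @return Output array.
#' @export
mtdfa_forward <- function(x, block, training = FALSE) {
  module_apply(block, x, training)
}

#' @rdname mtdfa_forward
#' @export
attention_gate_forward <- function(x, block, training = FALSE) {
  module_apply(block, x, training)
}

#' @rdname mtdfa_forward
#' @export
minor_attention_forward <- function(x, block, training = FALSE) {
  module_apply(block, x, training)
}

#' @rdname mtdfa_forward
#' @export
drsc_forward <- function(x, block, training = FALSE) {
  module_apply(block, x, training)
}
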