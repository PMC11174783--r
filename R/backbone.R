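#' Network configuration
#'
#' The classifier is a ResNeXt-style backbone with the two custom blocks in
#' front: a stride-2 7x7 stem, the adaptive residual pyramid convolution
#' block, the triplet disease-focus attention module, a 3x3/2 max pool, four
#' grouped-convolution bottleneck stages and a global-average-pool linear
#' head.
#'
#' @param input_size Square input side; must be divisible by 32.
#' @param num_classes Output classes.
#' @param stem_channels Channels after the stem at width 1.
#' @param stage_blocks Bottleneck counts of the four stages.
#' @param cardinality Groups of the 3x3 bottleneck convolutions.
#' @param width_multiplier Uniform channel scaling (1, 0.5 or 0.25); 0.25 is
#'   the desk-scale profile used by the tests.
#' @param dropout_rate MTDFA dropout rate.
#' @return A list of class `amwnet_config`.
#' @export
amwnet_config <- function(input_size = 224L, num_classes = 5L,
                          stem_channels = 64L, stage_blocks = c(3L, 4L, 6L, 3L),
                          cardinality = 32L, width_multiplier = 1,
                          dropout_rate = 0.1) {
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32",
                                  call. = FALSE)
  if (num_classes < 2) stop("need at least two classes", call. = FALSE)
  ch <- function(x) as.integer(round(x * width_multiplier))
  stem <- ch(stem_channels)
  if (stem %% 16 != 0) {
    stop("width_multiplier must keep the stem divisible by 16", call. = FALSE)
  }
  structure(list(input_size = as.integer(input_size),
                 num_classes = as.integer(num_classes),
                 stem_channels = stem,
                 stage_blocks = as.integer(stage_blocks),
                 cardinality = as.integer(cardinality),
                 width_multiplier = width_multiplier,
                 stage_out = ch(c(256L, 512L, 1024L, 2048L)),
                 stage_mid = ch(c(128L, 256L, 512L, 1024L)),
                 dropout_rate = dropout_rate),
            class = "amwnet_config")
}

#' Grouped-convolution bottleneck block
#'
#' 1x1 reduce, 3x3 grouped (cardinality groups, stride at stage entry), 1x1
#' expand, each followed by batch normalisation; a projected shortcut when the
#' shape changes; ReLU after the residual sum.
#'
#' @param in_ch,mid_ch,out_ch Channel plan.
#' @param stride Spatial stride of the 3x3 convolution.
#' @param cardinality Group count.
#' @return An `nn_module`.
#' @export
nn_bottleneck <- function(in_ch, mid_ch, out_ch, stride = 1L,
                          cardinality = 32L) {
  if (mid_ch %% cardinality != 0) {
    stop("bottleneck width must be divisible by the cardinality", call. = FALSE)
  }
  c1 <- nn_conv2d(in_ch, mid_ch, 1L, bias = FALSE)
  b1 <- nn_bn2d(mid_ch)
  c2 <- nn_conv2d(mid_ch, mid_ch, 3L, stride = stride, groups = cardinality,
                  bias = FALSE)
  b2 <- nn_bn2d(mid_ch)
  c3 <- nn_conv2d(mid_ch, out_ch, 1L, bias = FALSE)
  b3 <- nn_bn2d(out_ch)
  # zero-init the last BN scale so every block starts as an identity mapping;
  # this makes the 16-block network trainable in few optimisation steps
  b3$params$gamma$value <- rep(0, out_ch)
  project <- (stride != 1L) || (in_ch != out_ch)
  sc <- if (project) nn_conv2d(in_ch, out_ch, 1L, stride = stride, bias = FALSE)
  sbn <- if (project) nn_bn2d(out_ch)
  new_module("bottleneck",
             children = Filter(Negate(is.null),
                               list(conv1 = c1, bn1 = b1, conv2 = c2, bn2 = b2,
                                    conv3 = c3, bn3 = b3, shortcut = sc,
                                    shortcut_bn = sbn)),
             meta = list(stride = stride),
             forward = function(x, training = FALSE) {
               h <- ad_relu(b1$forward(c1$forward(x), training))
               h <- ad_relu(b2$forward(c2$forward(h), training))
               h <- b3$forward(c3$forward(h), training)
               s <- if (project) {
                 sbn$forward(sc$forward(x), training)
               } else {
                 x
               }
               ad_relu(ad_add(h, s))
             })
}

.make_stage <- function(in_ch, mid_ch, out_ch, n_blocks, stride, cardinality) {
  blocks <- vector("list", n_blocks)
  blocks[[1]] <- nn_bottleneck(in_ch, mid_ch, out_ch, stride, cardinality)
  if (n_blocks > 1) {
    for (i in 2:n_blocks) {
      blocks[[i]] <- nn_bottleneck(out_ch, mid_ch, out_ch, 1L, cardinality)
    }
  }
  names(blocks) <- paste0("block", seq_len(n_blocks))
  do.call(nn_sequential, blocks)
}

#' Build the full network
#'
#' @param cfg An [amwnet_config()].
#' @return An `nn_module` mapping `(B, 3, S, S)` images to `(B, num_classes)`
#'   logits.
#' @export
nn_amwnet <- function(cfg = amwnet_config()) {
  st <- cfg$stem_channels
  stem <- nn_conv2d(3L, st, 7L, stride = 2L, bias = FALSE)
  stem_bn <- nn_bn2d(st)
  arpc <- nn_arpc(arpc_config(in_channels = st, branch_channels = st,
                              out_channels = st,
                              se_reduction = min(16L, 4L * st)))
  mtdfa <- nn_mtdfa(mtdfa_config(channels = st,
                                 dropout_rate = cfg$dropout_rate))
  stages <- list(
    .make_stage(st, cfg$stage_mid[1], cfg$stage_out[1], cfg$stage_blocks[1],
                1L, cfg$cardinality),
    .make_stage(cfg$stage_out[1], cfg$stage_mid[2], cfg$stage_out[2],
                cfg$stage_blocks[2], 2L, cfg$cardinality),
    .make_stage(cfg$stage_out[2], cfg$stage_mid[3], cfg$stage_out[3],
                cfg$stage_blocks[3], 2L, cfg$cardinality),
    .make_stage(cfg$stage_out[3], cfg$stage_mid[4], cfg$stage_out[4],
                cfg$stage_blocks[4], 2L, cfg$cardinality))
  fc <- nn_linear(cfg$stage_out[4], cfg$num_classes)
  new_module("amwnet",
             children = list(stem = stem, stem_bn = stem_bn, arpc = arpc,
                             mtdfa = mtdfa, stage1 = stages[[1]],
                             stage2 = stages[[2]], stage3 = stages[[3]],
                             stage4 = stages[[4]], fc = fc),
             meta = list(cfg = cfg),
             forward = function(x, training = FALSE) {
               if (dim(x$value)[2] != 3) stop("expected 3-channel input",
                                              call. = FALSE)
               h <- ad_relu(stem_bn$forward(stem$forward(x), training))
               h <- arpc$forward(h, training)
               h <- mtdfa$forward(h, training)
               h <- ad_maxpool(h, 3L, 2L, 1L)
               for (sgl in stages) h <- sgl$forward(h, training)
               fc$forward(ad_gap(h))
             })
}

#' Forward pass to class logits
#'
#' @param images `(B, 3, S, S)` array.
#' @param model Module from [nn_amwnet()].
#' @param training Logical.
#' @return `(B, num_classes)` logit matrix.
#' @export
amwnet_forward <- function(images, model, training = FALSE) {
  module_apply(model, images, training)
}

#' Bottleneck forward on a plain array
#' @inheritParams amwnet_forward
#' @param block Module from [nn_bottleneck()].
#' @export
bottleneck_forward <- function(images, block, training = FALSE) {
  module_apply(block, images, training)
}
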