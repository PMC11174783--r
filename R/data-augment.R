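#' Augmentation / preprocessing configuration
#'
#' Training images get a random resized crop (scale and aspect jitter) and a
#' horizontal flip; evaluation images are resized and centre-cropped. Both
#' paths scale to `[0, 1]` and normalise channel-wise.
#'
#' @param crop_size Output side in pixels.
#' @param resize_side Evaluation resize side before the centre crop.
#' @param hflip_probability Horizontal flip probability for training.
#' @param crop Enable the random resized crop (disable to keep the full frame).
#' @param scale_range Area fraction range of the random crop.
#' @param aspect_range Aspect-ratio range of the random crop.
#' @param mean,std Channel-wise normalisation constants (ImageNet defaults).
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(crop_size = 224L, resize_side = 256L,
                                hflip_probability = 0.5, crop = TRUE,
                                scale_range = c(0.6, 1.0),
                                aspect_range = c(3 / 4, 4 / 3),
                                mean = c(0.485, 0.456, 0.406),
                                std = c(0.229, 0.224, 0.225)) {
  if (hflip_probability < 0 || hflip_probability > 1) {
    stop("hflip_probability must lie in [0, 1]", call. = FALSE)
  }
  structure(list(crop_size = as.integer(crop_size),
                 resize_side = as.integer(resize_side),
                 hflip_probability = hflip_probability, crop = crop,
                 scale_range = scale_range, aspect_range = aspect_range,
                 mean = mean, std = std),
            class = "augmentation_config")
}

.check_image <- function(image, min_side = 8L) {
  d <- dim(image)
  if (length(d) != 3 || d[3] < 3) stop("expected an (H, W, 3) image", call. = FALSE)
  if (min(d[1:2]) < min_side) stop("image smaller than the minimum side",
                                   call. = FALSE)
  invisible(d)
}

# (H, W, 3) in [0,1] -> normalised (3, S, S)
.to_tensor <- function(img, mean, std) {
  s <- dim(img)[1]
  out <- array(0, c(3L, s, dim(img)[2]))
  for (ch in 1:3) out[ch, , ] <- (img[, , ch] - mean[ch]) / std[ch]
  out
}

#' Training augmentation
#'
#' Random resized crop to `crop_size` (area in `scale_range`, aspect in
#' `aspect_range`), horizontal flip with probability `hflip_probability`,
#' then channel-wise normalisation. Randomness is drawn from the global RNG,
#' so seeding the session makes the pipeline reproducible.
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param cfg An [augmentation_config()].
#' @return Normalised `(3, crop_size, crop_size)` array.
#' @export
augment_train <- function(image, cfg = augmentation_config()) {
  d <- .check_image(image)
  H <- d[1]; W <- d[2]
  if (cfg$crop) {
    area <- H * W
    for (attempt in 1:10) {
      ta <- area * stats::runif(1, cfg$scale_range[1], cfg$scale_range[2])
      ar <- exp(stats::runif(1, log(cfg$aspect_range[1]), log(cfg$aspect_range[2])))
      cw <- round(sqrt(ta * ar))
      chh <- round(sqrt(ta / ar))
      if (cw <= W && chh <= H && cw >= 1 && chh >= 1) break
      cw <- min(W, H); chh <- min(W, H)
    }
    y0 <- sample.int(H - chh + 1L, 1L)
    x0 <- sample.int(W - cw + 1L, 1L)
    img <- image[y0:(y0 + chh - 1L), x0:(x0 + cw - 1L), 1:3, drop = FALSE]
  } else {
    img <- image[, , 1:3, drop = FALSE]
  }
  if (any(dim(img)[1:2] != cfg$crop_size)) {
    img <- cpp_resize_bilinear(img, cfg$crop_size, cfg$crop_size)
  }
  if (stats::runif(1) < cfg$hflip_probability) {
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  }
  .to_tensor(img, cfg$mean, cfg$std)
}

#' Deterministic evaluation preprocessing
#'
#' Resize to `resize_side`, centre-crop to `crop_size`, normalise.
#'
#' @inheritParams augment_train
#' @return Normalised `(3, crop_size, crop_size)` array.
#' @export
preprocess_eval <- function(image, cfg = augmentation_config()) {
  .check_image(image)
  img <- image[, , 1:3, drop = FALSE]
  if (any(dim(img)[1:2] != cfg$resize_side)) {
    img <- cpp_resize_bilinear(img, cfg$resize_side, cfg$resize_side)
  }
  off <- (cfg$resize_side - cfg$crop_size) %/% 2L
  sel <- (off + 1L):(off + cfg$crop_size)
  .to_tensor(img[sel, sel, , drop = FALSE], cfg$mean, cfg$std)
}
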