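#' Disease classes emulated by the synthetic generator
#' @export
amwnet_classes <- c("Anthracnose", "Phytophthora_blight", "Healthy",
                    "Bacterial_spot", "Mosaic_virus")

#' Specification of the synthetic leaf-lesion image generator
#'
#' The generator draws a green leaf on a dark background and overlays
#' class-specific lesion primitives: large dark blotches with blurred edges
#' (anthracnose), grey water-soaked irregular patches (phytophthora blight),
#' nothing (healthy), many pixel-scale dark specks (bacterial spot) and
#' yellow-green mottling (mosaic virus). The morphologies are synthetic
#' fixtures that echo the recognition challenges of field photographs —
#' blurred lesion boundaries and minute lesions — not biology.
#'
#' @param side Image side in pixels.
#' @param proportions Per-class shares of the generated set (default: the
#'   post-augmentation shares 21/18/21/21/19% of the five classes).
#' @param seed RNG seed; the full dataset is a pure function of it.
#' @return A list of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(side = 256L,
                                 proportions = c(0.21, 0.18, 0.21, 0.21, 0.19),
                                 seed = 1L) {
  if (length(proportions) != 5 || abs(sum(proportions) - 1) > 0.02) {
    stop("five class proportions summing to ~1 are required", call. = FALSE)
  }
  structure(list(side = as.integer(side), proportions = proportions,
                 classes = amwnet_classes, seed = as.integer(seed)),
            class = "synthetic_image_spec")
}

# Soft-edged disk alpha mask on a pixel grid; sigma controls edge blur.
.soft_disk <- function(gx, gy, cx, cy, r, sigma) {
  d <- sqrt((gx - cx)^2 + (gy - cy)^2)
  1 / (1 + exp((d - r) / sigma))
}

.blend <- function(img, alpha, color) {
  for (ch in 1:3) {
    img[, , ch] <- img[, , ch] * (1 - alpha) + color[ch] * alpha
  }
  img
}

# Render one leaf image as an (side, side, 3) array in [0, 1]; lesion
# primitives are counted so healthy images can be asserted lesion-free.
.render_leaf <- function(class_id, side) {
  s <- side
  gx <- matrix(rep(seq_len(s), each = s), s, s)   # column index
  gy <- matrix(rep(seq_len(s), times = s), s, s)  # row index
  img <- array(0, c(s, s, 3))
  img[, , 1] <- 0.08; img[, , 2] <- 0.07; img[, , 3] <- 0.06  # soil background

  # leaf: rotated ellipse with mild radius jitter
  ang <- stats::runif(1, -0.5, 0.5)
  ca <- cos(ang); sa <- sin(ang)
  cx <- s / 2 + stats::runif(1, -s * 0.03, s * 0.03)
  cy <- s / 2 + stats::runif(1, -s * 0.03, s * 0.03)
  a <- s * stats::runif(1, 0.36, 0.44)
  b <- s * stats::runif(1, 0.26, 0.33)
  xr <- (gx - cx) * ca + (gy - cy) * sa
  yr <- -(gx - cx) * sa + (gy - cy) * ca
  leaf_alpha <- 1 / (1 + exp((sqrt((xr / a)^2 + (yr / b)^2) - 1) * s * 0.15))
  green <- c(stats::runif(1, 0.13, 0.20), stats::runif(1, 0.42, 0.55),
             stats::runif(1, 0.10, 0.16))
  img <- .blend(img, leaf_alpha, green)
  # midrib vein
  vein <- exp(-(yr / (s * 0.008))^2) * leaf_alpha * (abs(xr) < a * 0.9)
  img <- .blend(img, vein * 0.5, green * 0.6)
  # fine texture noise
  img <- img + array(stats::rnorm(s * s, sd = 0.012), c(s, s, 3))

  n_lesions <- 0L
  lesion_at <- function() {
    repeat {
      lx <- cx + stats::runif(1, -0.8, 0.8) * a * ca
      ly <- cy + stats::runif(1, -0.7, 0.7) * b
      if (leaf_alpha[round(pmin(pmax(ly, 1), s)), round(pmin(pmax(lx, 1), s))] > 0.6) {
        return(c(lx, ly))
      }
    }
  }

  cls <- amwnet_classes[class_id + 1L]
  if (cls == "Anthracnose") {
    # few large dark blotches with heavily blurred boundaries
    for (k in seq_len(sample(1:3, 1))) {
      p <- lesion_at()
      r <- s * stats::runif(1, 0.09, 0.16)
      al <- .soft_disk(gx, gy, p[1], p[2], r, sigma = r * 0.45) * leaf_alpha
      ring <- .soft_disk(gx, gy, p[1], p[2], r * 1.25, sigma = r * 0.5) * leaf_alpha
      img <- .blend(img, ring * 0.5, c(0.45, 0.30, 0.10))  # chlorotic halo
      img <- .blend(img, al * 0.95, c(0.26, 0.13, 0.05))
      n_lesions <- n_lesions + 1L
    }
  } else if (cls == "Phytophthora_blight") {
    # grey-brown water-soaked irregular patches
    for (k in seq_len(sample(1:3, 1))) {
      p <- lesion_at()
      r0 <- s * stats::runif(1, 0.08, 0.14)
      theta <- atan2(gy - p[2], gx - p[1])
      ph <- stats::runif(3, 0, 2 * pi)
      wob <- 1 + 0.35 * sin(2 * theta + ph[1]) * 0.6 +
        0.25 * sin(3 * theta + ph[2]) + 0.15 * sin(5 * theta + ph[3])
      d <- sqrt((gx - p[1])^2 + (gy - p[2])^2)
      al <- (1 / (1 + exp((d - r0 * wob) / (s * 0.006)))) * leaf_alpha
      img <- .blend(img, al * 0.9, c(0.47, 0.43, 0.36))
      n_lesions <- n_lesions + 1L
    }
  } else if (cls == "Bacterial_spot") {
    # many minute dark specks (the tiny-feature challenge)
    for (k in seq_len(sample(18:35, 1))) {
      p <- lesion_at()
      r <- max(1, s * stats::runif(1, 0.006, 0.015))
      al <- .soft_disk(gx, gy, p[1], p[2], r, sigma = max(0.6, r * 0.3)) * leaf_alpha
      img <- .blend(img, al * 0.9, c(0.12, 0.09, 0.04))
      n_lesions <- n_lesions + 1L
    }
  } else if (cls == "Mosaic_virus") {
    # low-frequency yellow-green mottling over the blade
    field <- matrix(0, s, s)
    for (k in seq_len(8)) {
      p <- lesion_at()
      r <- s * stats::runif(1, 0.08, 0.18)
      field <- field + .soft_disk(gx, gy, p[1], p[2], r, sigma = r * 0.5)
      n_lesions <- n_lesions + 1L
    }
    mot <- pmin(field, 1) * leaf_alpha
    img <- .blend(img, mot * 0.65, c(0.72, 0.72, 0.22))
  }
  list(img = pmin(pmax(img, 0), 1), n_lesions = n_lesions)
}

.class_counts <- function(total, proportions) {
  n <- round(total * proportions)
  # keep the total exact by adjusting the largest class
  n[which.max(n)] <- n[which.max(n)] + (total - sum(n))
  as.integer(n)
}

#' Generate a synthetic leaf-lesion dataset
#'
#' Writes PNG images to `out_dir` and returns (and writes) a manifest. The
#' whole dataset is deterministic in `spec$seed`.
#'
#' @param spec A [synthetic_image_spec()].
#' @param total Total number of images (>= 25 so every class is populated).
#' @param out_dir Output directory; created if missing.
#' @return A tibble manifest with `path`, `class_id`, `class_name`, `split`
#'   (initially `NA`), also written to `manifest.csv` in `out_dir`.
#' @export
generate_synthetic_dataset <- function(spec, total, out_dir) {
  if (total < 5 * length(spec$classes)) {
    stop("need at least 5 images per class", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  counts <- .class_counts(total, spec$proportions)
  withr::local_seed(spec$seed)
  rows <- vector("list", total)
  i <- 0L
  for (cl in seq_along(spec$classes) - 1L) {
    for (k in seq_len(counts[cl + 1L])) {
      i <- i + 1L
      rl <- .render_leaf(cl, spec$side)
      if (spec$classes[cl + 1L] == "Healthy" && rl$n_lesions != 0L) {
        stop("internal: healthy image received lesion primitives", call. = FALSE)
      }
      fn <- file.path(out_dir, sprintf("%s_%04d.png", spec$classes[cl + 1L], k))
      png::writePNG(rl$img, fn)
      rows[[i]] <- tibble::tibble(path = fn, class_id = cl,
                                  class_name = spec$classes[cl + 1L],
                                  split = NA_character_)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Load a PNG image as an (H, W, 3) array in [0, 1]
#' @param path File path.
#' @return Numeric array.
#' @export
load_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
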