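test_that("class counts follow the stated proportions", {
  counts <- amwnet:::.class_counts(1000, c(0.21, 0.18, 0.21, 0.21, 0.19))
  expect_equal(counts, c(210L, 180L, 210L, 210L, 190L))
  expect_equal(sum(amwnet:::.class_counts(997, rep(0.2, 5))), 997L)
})

test_that("the generator is deterministic and healthy leaves are lesion-free", {
  spec <- synthetic_image_spec(side = 32, seed = 77)
  d1 <- file.path(tempdir(), "gen_a")
  d2 <- file.path(tempdir(), "gen_b")
  m1 <- generate_synthetic_dataset(spec, 30, d1)
  m2 <- generate_synthetic_dataset(spec, 30, d2)
  expect_equal(nrow(m1), 30)
  expect_true(all(file.exists(m1$path)))
  expect_identical(unname(tools::md5sum(m1$path)),
                   unname(tools::md5sum(m2$path)))
  expect_identical(m1$class_id, m2$class_id)
  expect_true(!anyDuplicated(m1$path))
  expect_true(file.exists(file.path(d1, "manifest.csv")))

  # healthy renders never receive lesion primitives
  set.seed(1)
  for (i in 1:5) {
    rl <- amwnet:::.render_leaf(2L, 32L)  # class id 2 = Healthy
    expect_identical(rl$n_lesions, 0L)
  }
  set.seed(2)
  expect_gt(amwnet:::.render_leaf(3L, 32L)$n_lesions, 10)

  expect_error(generate_synthetic_dataset(spec, 10, tempdir()), "at least")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the stratified split is disjoint, covering and near-ratio", {
  man <- tibble::tibble(path = sprintf("p%04d", 1:1000),
                        class_id = rep(0:4, times = c(210, 180, 210, 210, 190)),
                        class_name = "x", split = NA_character_)
  sp <- split_dataset(man, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 800)
  expect_equal(nrow(sp$test), 200)
  expect_length(intersect(sp$train$path, sp$test$path), 0)
  expect_setequal(c(sp$train$path, sp$test$path), man$path)
  per_class <- table(man$class_id)
  tr_class <- table(sp$train$class_id)
  expect_true(all(abs(tr_class - 0.8 * per_class) <= 1))

  expect_error(split_dataset(tibble::tibble(class_id = c(0, 0, 1)), 0.8),
               "at least 2")
  expect_error(split_dataset(man, 1.2), "ratio")
})

test_that("training augmentation crops, flips and normalises", {
  set.seed(4)
  img <- array(runif(48 * 48 * 3), c(48, 48, 3))
  cfg <- augmentation_config(crop_size = 32, resize_side = 48)
  out <- augment_train(img, cfg)
  expect_equal(dim(out), c(3, 32, 32))

  # flip with probability one and no crop reverses columns
  cfgf <- augmentation_config(crop_size = 48, resize_side = 48,
                              hflip_probability = 1, crop = FALSE)
  flipped <- augment_train(img, cfgf)
  manual <- amwnet:::.to_tensor(img[, 48:1, ], cfgf$mean, cfgf$std)
  expect_equal(flipped, manual)

  # seeded reproducibility
  set.seed(9); a <- augment_train(img, cfg)
  set.seed(9); b <- augment_train(img, cfg)
  expect_identical(a, b)

  # output bounded by the normalised range of [0,1] inputs
  lo <- (0 - cfg$mean) / cfg$std
  hi <- (1 - cfg$mean) / cfg$std
  for (ch in 1:3) {
    expect_gte(min(out[ch, , ]), lo[ch] - 1e-9)
    expect_lte(max(out[ch, , ]), hi[ch] + 1e-9)
  }
  expect_error(augment_train(array(0, c(4, 4, 3)), cfg), "minimum side")
})

test_that("evaluation preprocessing is deterministic and keeps the centre", {
  img <- array(0, c(512, 512, 3))
  img[255:258, 255:258, ] <- 1  # centred marker
  cfg <- augmentation_config(crop_size = 224, resize_side = 256)
  a <- preprocess_eval(img, cfg)
  b <- preprocess_eval(img, cfg)
  expect_identical(a, b)
  expect_equal(dim(a), c(3, 224, 224))
  peak <- which(a[1, , ] == max(a[1, , ]), arr.ind = TRUE)
  centre <- colMeans(peak)
  expect_lt(max(abs(centre - 112.5)), 2)
})

test_that("manifest summaries reproduce per-class count arithmetic", {
  # record-style manifest
  man <- tibble::tibble(path = sprintf("p%d", 1:100),
                        class_id = rep(0:4, each = 20),
                        class_name = rep(amwnet_classes, each = 20))
  sm <- manifest_summary(man)
  expect_equal(nrow(sm), 6)
  expect_equal(sm$n[6], 100L)
  expect_equal(sm$proportion_pct[1:5], rep(20L, 5))

  # expansion metadata: before + expanded = after, whole-percent shares
  tab <- tibble::tibble(
    class_name = amwnet_classes,
    n_before = c(912L, 687L, 944L, 976L, 691L),
    n_expanded = c(384L, 457L, 380L, 347L, 537L))
  sm2 <- manifest_summary(tab)
  expect_equal(sm2$n[1], 1296L)
  expect_equal(sm2$n[1:5], c(1296L, 1144L, 1324L, 1323L, 1228L))
  expect_equal(sm2$n[6], 6315L)
  expect_equal(sm2$n_before[6], 4210L)
  expect_equal(sm2$proportion_pct, c(21L, 18L, 21L, 21L, 19L, 100L))
})
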