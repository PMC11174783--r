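test_that("experiment configurations validate their schema", {
  cfg <- experiment_config("full")
  expect_equal(cfg$optim$batch_size, 32L)
  expect_equal(cfg$optim$epochs, 200L)
  expect_equal(cfg$optim$learning_rate, 1e-3)
  expect_equal(cfg$optim$optimizer, "adam")
  expect_equal(cfg$tpsao$N, 50L)
  expect_equal(cfg$tpsao$maxiter, 100L)
  expect_equal(cfg$tpsao$lower_bound, 1e-4)
  expect_equal(cfg$tpsao$upper_bound, 1e-2)

  desk <- experiment_config("desk")
  expect_equal(desk$optim$epochs, 15L)
  expect_equal(desk$model$width_multiplier, 0.25)
  expect_equal(desk$model$input_size, 64L)

  over <- experiment_config("desk", overrides = list(optim = list(epochs = 3L)))
  expect_equal(over$optim$epochs, 3L)
  expect_equal(over$optim$batch_size, 32L)

  expect_error(experiment_config("desk", overrides = list(foo = 1)), "unknown")
  expect_error(experiment_config("desk",
                                 overrides = list(optim = list(warp = 9))),
               "unknown")
})

test_that("yaml configuration files round-trip through the reader", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("optim:", "  epochs: 4", "  learning_rate: 0.002",
               "seed: 7"), f)
  cfg <- read_experiment_config(f, "desk")
  expect_equal(cfg$optim$epochs, 4)
  expect_equal(cfg$optim$learning_rate, 0.002)
  expect_equal(cfg$seed, 7)
  unlink(f)
})

test_that("short training runs learn, log and resume", {
  spec <- synthetic_image_spec(side = 32, seed = 5)
  dir <- file.path(tempdir(), "train_smoke")
  man <- generate_synthetic_dataset(spec, 50, dir)
  sp <- split_dataset(man, 0.8, seed = 5)
  cfg <- amwnet_config(input_size = 32, width_multiplier = 0.25)

  fit <- train_amwnet(sp$train, sp$test, model_cfg = cfg, epochs = 2,
                      batch_size = 16, seed = 11, verbose = FALSE)
  expect_s3_class(fit, "amwnet_fit")
  expect_equal(fit$history$epoch, 1:2)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(fit$history$test_accuracy >= 0 &
                    fit$history$test_accuracy <= 1))

  # the derived class weights follow the manifest proportions
  expect_length(fit$loss_cfg$class_weights, 5)
  expect_true(all(fit$loss_cfg$class_weights >= 1 &
                    fit$loss_cfg$class_weights <= 1.3))

  # resuming continues the epoch numbering
  fit2 <- train_amwnet(sp$train, sp$test, resume = fit, epochs = 1,
                       batch_size = 16, seed = 12, verbose = FALSE)
  expect_equal(fit2$history$epoch, 1:3)

  # prediction pipeline produces a distribution per record
  pred <- predict_amwnet(fit$model, sp$test)
  expect_equal(nrow(pred), nrow(sp$test))
  pm <- as.matrix(pred[, paste0("p", 0:4)])
  expect_equal(unname(rowSums(pm)), rep(1, nrow(pred)), tolerance = 1e-6)

  rep_ <- evaluate_amwnet(fit$model, sp$test)
  expect_s3_class(tidy(rep_), "tbl_df")
  expect_equal(sum(rep_$confusion), nrow(sp$test))

  gl <- glance(fit)
  expect_equal(gl$epochs, 2)
  unlink(dir, recursive = TRUE)
})

test_that("seeded training is reproducible", {
  spec <- synthetic_image_spec(side = 32, seed = 6)
  dir <- file.path(tempdir(), "train_repro")
  man <- generate_synthetic_dataset(spec, 30, dir)
  cfg <- amwnet_config(input_size = 32, width_multiplier = 0.25)
  f1 <- train_amwnet(man, NULL, model_cfg = cfg, epochs = 1, batch_size = 10,
                     seed = 21, verbose = FALSE)
  f2 <- train_amwnet(man, NULL, model_cfg = cfg, epochs = 1, batch_size = 10,
                     seed = 21, verbose = FALSE)
  expect_equal(f1$history$train_loss, f2$history$train_loss, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("the command-line entry point generates data and searches rates", {
  cli <- system.file("cli", "amwnet.R", package = "amwnet")
  expect_true(nzchar(cli))
  out_dir <- file.path(tempdir(), "cli_data")
  lib_env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  res <- system2("Rscript", c(cli, "generate-data", "--total", "30",
                              "--seed", "3", "--side", "32",
                              "--out", out_dir),
                 stdout = TRUE, stderr = TRUE, env = lib_env)
  expect_equal(attr(res, "status") %||% 0L, 0L)
  expect_true(file.exists(file.path(out_dir, "manifest.csv")))
  expect_equal(nrow(read_manifest(file.path(out_dir, "manifest.csv"))), 30)

  trace_file <- file.path(tempdir(), "trace.json")
  res2 <- system2("Rscript", c(cli, "tpsao-search", "--objective", "quadratic",
                               "--n", "10", "--maxiter", "5", "--seed", "2",
                               "--out", trace_file),
                  stdout = TRUE, stderr = TRUE, env = lib_env)
  expect_equal(attr(res2, "status") %||% 0L, 0L)
  tr <- jsonlite::read_json(trace_file, simplifyVector = TRUE)
  expect_equal(length(tr$trace$best_fitness), 5)
  expect_gte(tr$best_position, 1e-4)
  unlink(c(out_dir, trace_file), recursive = TRUE)
})
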