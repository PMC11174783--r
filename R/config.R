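#' Experiment configuration
#'
#' A validated nested configuration covering the model, loss, data,
#' optimisation, learning-rate-search and metrics sections. The `"desk"`
#' profile (width 0.25, 64 px, 15 epochs) is the default test-scale path; the
#' `"full"` profile keeps the full-scale settings (batch 32, 200 epochs,
#' initial learning rate 0.001, Adam).
#'
#' @param profile `"desk"` or `"full"`.
#' @param overrides Named nested list of overrides; unknown keys are rejected.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(profile = c("desk", "full"),
                              overrides = list()) {
  profile <- match.arg(profile)
  desk <- profile == "desk"
  base <- list(
    model = list(input_size = if (desk) 64L else 224L, num_classes = 5L,
                 width_multiplier = if (desk) 0.25 else 1,
                 dropout_rate = 0.1),
    loss = list(gamma = 2, beta = 1e-4, l2_mode = "inputs",
                class_weights = "auto"),
    data = list(total = if (desk) 625L else 6315L,
                side = if (desk) 64L else 256L, split_ratio = 0.8,
                hflip_probability = 0.5),
    optim = list(batch_size = 32L, epochs = if (desk) 15L else 200L,
                 learning_rate = 1e-3, optimizer = "adam"),
    tpsao = list(N = 50L, maxiter = 100L, lower_bound = 1e-4,
                 upper_bound = 1e-2),
    metrics = list(k_folds = 10L),
    seed = 42L,
    profile = profile)
  cfg <- .merge_config(base, overrides, path = "")
  if (!identical(cfg$optim$optimizer, "adam")) {
    stop("only the Adam optimizer is supported", call. = FALSE)
  }
  structure(cfg, class = "experiment_config")
}

.merge_config <- function(base, overrides, path) {
  if (length(overrides) == 0) return(base)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    stop("configuration overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(nms, names(base))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in nms) {
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(overrides[[nm]])) {
        stop("configuration section '", path, nm, "' must be a list",
             call. = FALSE)
      }
      base[[nm]] <- .merge_config(base[[nm]], overrides[[nm]],
                                  paste0(path, nm, "."))
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read an experiment configuration from YAML or JSON
#'
#' The file holds overrides of the chosen profile's defaults; unknown keys are
#' rejected before anything runs.
#'
#' @param path File path (`.yaml`/`.yml`/`.json`).
#' @param profile Base profile to override.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path, profile = "desk") {
  overrides <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  experiment_config(profile, overrides = overrides %||% list())
}
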