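# Module framework: a module is a list with named trainable `params`
# (nn_param environments), named `children` modules, an optional `state`
# environment (running statistics), and a `forward(x, training)` closure that
# maps a tape node to a tape node.

new_module <- function(kind, params = list(), children = list(),
                       forward = NULL, state = NULL, meta = list()) {
  mod <- list(kind = kind, params = params, children = children,
              forward = forward, state = state, meta = meta)
  class(mod) <- "nn_module"
  mod
}

#' @export
print.nn_module <- function(x, ...) {
  np <- sum(vapply(nn_parameters(x), function(p) length(p$value), numeric(1)))
  cat(sprintf("<nn_module:%s> %s trainable values\n", x$kind,
              format(np, big.mark = ",")))
  invisible(x)
}

# Flat named list of nn_param environments.
nn_parameters <- function(mod, prefix = "") {
  out <- list()
  for (nm in names(mod$params)) {
    if (!is.null(mod$params[[nm]])) out[[paste0(prefix, nm)]] <- mod$params[[nm]]
  }
  for (nm in names(mod$children)) {
    ch <- mod$children[[nm]]
    if (!is.null(ch)) {
      out <- c(out, nn_parameters(ch, paste0(prefix, nm, ".")))
    }
  }
  out
}

n_parameters <- function(mod) {
  sum(vapply(nn_parameters(mod), function(p) length(p$value), numeric(1)))
}

# Serializable snapshot: parameter values plus batch-norm running statistics.
nn_state_dict <- function(mod, prefix = "") {
  out <- lapply(nn_parameters(mod, prefix), function(p) p$value)
  collect_state <- function(m, pre) {
    res <- list()
    if (!is.null(m$state)) {
      for (nm in ls(m$state)) {
        res[[paste0(pre, ".", nm)]] <- get(nm, envir = m$state)
      }
    }
    for (nm in names(m$children)) {
      ch <- m$children[[nm]]
      if (!is.null(ch)) res <- c(res, collect_state(ch, paste0(pre, nm, ".")))
    }
    res
  }
  c(out, collect_state(mod, prefix))
}

nn_load_state_dict <- function(mod, sd) {
  params <- nn_parameters(mod)
  for (nm in names(params)) {
    if (!is.null(sd[[nm]])) params[[nm]]$value <- sd[[nm]]
  }
  restore_state <- function(m, pre) {
    if (!is.null(m$state)) {
      for (nm in ls(m$state)) {
        key <- paste0(pre, ".", nm)
        if (!is.null(sd[[key]])) assign(nm, sd[[key]], envir = m$state)
      }
    }
    for (nm in names(m$children)) {
      ch <- m$children[[nm]]
      if (!is.null(ch)) restore_state(ch, paste0(pre, nm, "."))
    }
  }
  restore_state(mod, "")
  invisible(mod)
}

# ---------------------------------------------------------------------------
# Elementary layers
# ---------------------------------------------------------------------------

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

nn_conv2d <- function(in_ch, out_ch, kernel, stride = 1L, groups = 1L,
                      bias = TRUE, pad = NULL) {
  if (in_ch %% groups != 0 || out_ch %% groups != 0) {
    stop("conv2d: channel counts must be divisible by `groups`", call. = FALSE)
  }
  cg <- in_ch %/% groups
  w <- nn_param(he_init(c(kernel, kernel, cg, out_ch), kernel * kernel * cg))
  b <- if (bias) nn_param(numeric(out_ch)) else NULL
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  new_module("conv2d", params = list(weight = w, bias = b),
             meta = list(in_ch = in_ch, out_ch = out_ch, kernel = kernel,
                         stride = stride, groups = groups, pad = pad),
             forward = function(x, training = FALSE) {
               ad_conv2d(x, w, b, stride = stride, pad = pad, groups = groups)
             })
}

nn_bn2d <- function(C, momentum = 0.1, eps = 1e-5) {
  g <- nn_param(rep(1, C))
  b <- nn_param(numeric(C))
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(C)
  st$running_var <- rep(1, C)
  new_module("bn2d", params = list(gamma = g, beta = b), state = st,
             forward = function(x, training = FALSE) {
               ad_bn2d(x, g, b, st, training, momentum = momentum, eps = eps)
             })
}

# layout "nf": x is (N, features); layout "cmat": x is (C_in, N).
nn_linear <- function(in_f, out_f, bias = TRUE, layout = c("nf", "cmat")) {
  layout <- match.arg(layout)
  if (layout == "nf") {
    w <- nn_param(he_init(c(in_f, out_f), in_f))
  } else {
    w <- nn_param(he_init(c(out_f, in_f), in_f))
  }
  b <- if (bias) nn_param(numeric(out_f)) else NULL
  new_module("linear", params = list(weight = w, bias = b),
             meta = list(in_f = in_f, out_f = out_f, layout = layout),
             forward = function(x, training = FALSE) {
               if (layout == "nf") ad_linear(x, w, b) else ad_linear_cmat(x, w, b)
             })
}

nn_sequential <- function(...) {
  mods <- list(...)
  if (is.null(names(mods)) || any(names(mods) == "")) {
    names(mods) <- paste0("m", seq_along(mods))
  }
  new_module("sequential", children = mods,
             forward = function(x, training = FALSE) {
               for (m in mods) x <- m$forward(x, training)
               x
             })
}

# Run a module on a plain array, returning a plain array (evaluation helper).
module_apply <- function(mod, x, training = FALSE) {
  tp <- ad_tape()
  mod$forward(ad_const(tp, x), training)$value
}

# ---------------------------------------------------------------------------
# Adam optimizer on nn_param environments
# ---------------------------------------------------------------------------

adam_state <- function(params) {
  for (p in params) {
    p$m <- 0 * p$value
    p$v <- 0 * p$value
  }
  env <- new.env(parent = emptyenv())
  env$t <- 0L
  env$params <- params
  class(env) <- "adam_state"
  env
}

adam_step <- function(opt, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (p in opt$params) {
    if (is.null(p$grad)) next
    g <- p$grad
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  invisible(opt)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
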