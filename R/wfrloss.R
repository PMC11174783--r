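#' Hybrid loss configuration: class-weighted focal loss plus L2 regularisation
#'
#' @param class_weights Per-class weight vector `alpha_t`, or `NULL` to derive
#'   it from training-set proportions with
#'   [class_weights_from_proportions()].
#' @param gamma Focusing parameter (>= 0); 0 recovers cross-entropy.
#' @param beta Weight of the L2 term (>= 0).
#' @param l2_mode `"inputs"` penalises the squared norm of the logits entering
#'   the loss (averaged over the batch); `"weights"` penalises all trainable
#'   parameters.
#' @param reduction `"mean"` or `"sum"` over the batch.
#' @return A list of class `wfr_config`.
#' @export
wfr_config <- function(class_weights = NULL, gamma = 2, beta = 1e-4,
                       l2_mode = c("inputs", "weights"),
                       reduction = c("mean", "sum")) {
  if (gamma < 0 || beta < 0) stop("gamma and beta must be >= 0", call. = FALSE)
  if (!is.null(class_weights) && any(class_weights < 0)) {
    stop("class weights must be non-negative", call. = FALSE)
  }
  structure(list(class_weights = class_weights, gamma = gamma, beta = beta,
                 l2_mode = match.arg(l2_mode), reduction = match.arg(reduction)),
            class = "wfr_config")
}

#' Class weights from class proportions
#'
#' Anchors: a share of 20% (or more) maps to weight 1.0, 19% to 1.2 and 18%
#' (or less) to 1.3, with linear interpolation in between.
#'
#' @param proportions Positive per-class proportions summing to ~1.
#' @return Numeric weight vector of the same length.
#' @export
class_weights_from_proportions <- function(proportions) {
  if (any(proportions <= 0)) {
    stop("class proportions must be positive", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 0.02) {
    stop("class proportions must sum to ~1", call. = FALSE)
  }
  p <- pmin(pmax(proportions, 0.18), 0.20)
  stats::approx(x = c(0.18, 0.19, 0.20), y = c(1.3, 1.2, 1.0), xout = p)$y
}

#' Class-weighted focal loss
#'
#' Per-sample loss `-alpha_t (1 - p_t)^gamma log(p_t)` where `p_t` is the
#' predicted probability of the true class; `p_t` is clamped at 1e-12 (with a
#' warning) so degenerate predictions stay finite.
#'
#' @param probabilities `n x K` matrix of class distributions (rows sum to 1).
#' @param labels Integer class ids in `0:(K-1)`.
#' @param cfg A [wfr_config()]; `class_weights` defaults to all ones.
#' @return Scalar loss (mean or sum over samples per `cfg$reduction`).
#' @export
weighted_focal <- function(probabilities, labels, cfg = wfr_config()) {
  probabilities <- rbind(probabilities)
  n <- nrow(probabilities)
  K <- ncol(probabilities)
  if (length(labels) != n) stop("label/probability length mismatch", call. = FALSE)
  if (any(labels < 0 | labels >= K)) stop("labels out of range", call. = FALSE)
  if (any(abs(rowSums(probabilities) - 1) > 1e-5)) {
    stop("probability rows must sum to 1", call. = FALSE)
  }
  alpha <- cfg$class_weights %||% rep(1, K)
  pt <- probabilities[cbind(seq_len(n), labels + 1L)]
  if (any(pt < 1e-12)) {
    warning("true-class probability clamped at 1e-12", call. = FALSE)
    pt <- pmax(pt, 1e-12)
  }
  per <- -alpha[labels + 1L] * (1 - pt)^cfg$gamma * log(pt)
  if (cfg$reduction == "mean") mean(per) else sum(per)
}

#' L2 penalty
#'
#' `beta` times the squared L2 norm: for a matrix of per-sample logits the
#' norm is averaged over rows (batch); for a list of parameter arrays it is
#' summed over all elements.
#'
#' @param inputs_or_params Numeric vector/matrix of logits, or a list of
#'   parameter arrays.
#' @param beta Non-negative regularisation weight.
#' @return Scalar penalty.
#' @export
l2_penalty <- function(inputs_or_params, beta) {
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (beta == 0) return(0)
  if (is.list(inputs_or_params)) {
    beta * sum(vapply(inputs_or_params, function(w) sum(w^2), numeric(1)))
  } else {
    m <- rbind(inputs_or_params)
    beta * sum(m^2) / nrow(m)
  }
}

#' Full hybrid loss
#'
#' @inheritParams weighted_focal
#' @param reg_quantity The quantity entering the L2 term: the logit matrix in
#'   `"inputs"` mode or a list of parameter arrays in `"weights"` mode.
#' @return Scalar `weighted_focal + l2_penalty`.
#' @export
wfr_loss <- function(probabilities, labels, reg_quantity, cfg = wfr_config()) {
  weighted_focal(probabilities, labels, cfg) + l2_penalty(reg_quantity, cfg$beta)
}

# Autodiff version used by the training loop: takes a logits node, builds
# softmax probabilities, the focal term and (in inputs mode) the L2 term on
# the same tape.  Returns list(loss_node, probs_value).
ad_wfr_loss <- function(logits, labels, cfg) {
  probs <- ad_softmax_rows(logits)
  pv <- probs$value
  n <- nrow(pv)
  K <- ncol(pv)
  alpha <- cfg$class_weights %||% rep(1, K)
  sel <- cbind(seq_len(n), labels + 1L)
  pt <- pmax(pv[sel], 1e-12)
  a <- alpha[labels + 1L]
  per <- -a * (1 - pt)^cfg$gamma * log(pt)
  red <- if (cfg$reduction == "mean") 1 / n else 1
  focal_val <- sum(per) * red
  focal <- ad_node(logits$tape, focal_val, list(probs), function(nd, g) {
    # d/dp [-a (1-p)^gamma log p] = a * (gamma (1-p)^(gamma-1) log p - (1-p)^gamma / p)
    dpt <- nd$.a * (nd$.gamma * (1 - nd$.pt)^(max(nd$.gamma - 1, 0)) * log(nd$.pt) -
                      (1 - nd$.pt)^nd$.gamma / nd$.pt)
    dP <- matrix(0, nd$.n, nd$.K)
    dP[nd$.sel] <- g * nd$.red * dpt
    list(dP)
  })
  focal$.a <- a; focal$.gamma <- cfg$gamma; focal$.pt <- pt
  focal$.sel <- sel; focal$.n <- n; focal$.K <- K; focal$.red <- red
  if (cfg$l2_mode == "inputs" && cfg$beta > 0) {
    zv <- logits$value
    l2 <- ad_node(logits$tape, cfg$beta * sum(zv^2) / n, list(logits),
                  function(nd, g) list(g * 2 * cfg$beta * nd$.z / nd$.n))
    l2$.z <- zv
    l2$.n <- n
    loss <- ad_add(focal, l2)
  } else {
    loss <- focal
  }
  list(loss = loss, probs = pv)
}
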