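#' Configuration of the tent-chaos particle snow-ablation optimizer
#'
#' TPSAO is a bounded black-box minimiser. A tent-chaotic map diversifies the
#' initial population; each iteration splits the swarm into an exploration
#' subpopulation (moves around a randomly drawn elite) and an exploitation
#' subpopulation (contracts towards the global best at the melt rate), then
#' adds a particle-swarm velocity so particles also track personal bests.
#'
#' @param dim Problem dimension.
#' @param Lb,Ub Per-dimension lower/upper bounds (scalars are recycled).
#' @param N Population size (>= 4; the elite set needs three ranked
#'   individuals plus a centroid).
#' @param tmax Number of iterations.
#' @param tent_alpha Tent-map parameter in (0, 1).
#' @param w Inertia weight: length-2 vector giving a linear decay start/end.
#' @param c1,c2 Cognitive/social acceleration factors.
#' @param seed Optional RNG seed for a bit-reproducible run.
#' @return A list of class `tpsao_config`.
#' @export
tpsao_config <- function(dim, Lb, Ub, N = 50L, tmax = 100L, tent_alpha = 0.5,
                         w = c(0.9, 0.4), c1 = 2, c2 = 2, seed = NULL) {
  Lb <- rep_len(as.numeric(Lb), dim)
  Ub <- rep_len(as.numeric(Ub), dim)
  if (any(Lb >= Ub)) stop("bounds must satisfy Lb < Ub", call. = FALSE)
  if (N < 4) stop("population size must be at least 4", call. = FALSE)
  if (tmax < 1) stop("tmax must be >= 1", call. = FALSE)
  if (tent_alpha <= 0 || tent_alpha >= 1) {
    stop("tent_alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(dim = as.integer(dim), Lb = Lb, Ub = Ub, N = as.integer(N),
                 tmax = as.integer(tmax), tent_alpha = tent_alpha,
                 w = rep_len(w, 2), c1 = c1, c2 = c2, seed = seed),
            class = "tpsao_config")
}

#' Normalised tent chaotic map
#'
#' `x / alpha` below the break point, `(1 - x) / (1 - alpha)` above; maps
#' `[0, 1]` onto itself and preserves uniformity of iterates for any alpha.
#'
#' @param x Value(s) in `[0, 1]`.
#' @param alpha Break point in (0, 1).
#' @return Mapped value(s) in `[0, 1]`.
#' @export
tent_map <- function(x, alpha = 0.5) {
  if (any(x < 0 | x > 1)) stop("tent map input outside [0, 1]", call. = FALSE)
  ifelse(x < alpha, x / alpha, (1 - x) / (1 - alpha))
}

#' Tent-chaotic population initialisation
#'
#' Uniform draws on `[0, 1]` pass once through the tent map and are rescaled
#' to the search box `[Lb, Ub]`.
#'
#' @param cfg A [tpsao_config()].
#' @return `N x dim` position matrix within bounds.
#' @export
tent_init <- function(cfg) {
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  u <- matrix(stats::runif(cfg$N * cfg$dim), cfg$N, cfg$dim)
  z <- tent_map(u, cfg$tent_alpha)
  sweep(sweep(z, 2, cfg$Ub - cfg$Lb, "*"), 2, cfg$Lb, "+")
}

#' Snow melt rate schedule
#'
#' `M(t) = (0.35 + 0.25 * (exp(t/tmax) - 1) / (e - 1)) * exp(-t/tmax)`,
#' decreasing from 0.35 at `t = 0` to `0.6 / e` at `t = tmax`.
#'
#' @param t Iteration in `[0, tmax]`.
#' @param tmax Maximum iteration count.
#' @return Melt rate scalar.
#' @export
melt_rate <- function(t, tmax) {
  r <- t / tmax
  (0.35 + 0.25 * (exp(r) - 1) / (exp(1) - 1)) * exp(-r)
}

#' Draw one elite position
#'
#' The elite set holds the global best, the second and third best individuals
#' of the current population, and the centroid of the top half by fitness;
#' one of the four is returned uniformly at random.
#'
#' @param state A swarm state list (see [tpsao_optimize()]); needs
#'   `positions`, `fitness`, `gbest_pos`.
#' @return A position vector.
#' @export
elite_select <- function(state) {
  N <- nrow(state$positions)
  if (N < 4) stop("elite selection needs at least 4 particles", call. = FALSE)
  ord <- order(state$fitness)
  n1 <- ceiling(N / 2)
  xc <- colMeans(state$positions[ord[seq_len(n1)], , drop = FALSE])
  cands <- list(state$gbest_pos,
                state$positions[ord[2], ],
                state$positions[ord[3], ],
                xc)
  cands[[sample.int(4L, 1L)]]
}

#' Snow-ablation position candidate for one particle
#'
#' Exploration rows move around an elite with Brownian (Gaussian) steps scaled
#' by the distances to the global best and the population centroid;
#' exploitation rows contract towards `M * G`.
#'
#' @param state Swarm state with `positions`, `fitness`, `gbest_pos`, `xbar`,
#'   `M` and the index sets `indexa`, `indexb`.
#' @param i Particle index.
#' @return Unbounded candidate position vector.
#' @export
sao_candidate <- function(state, i) {
  xi <- state$positions[i, ]
  G <- state$gbest_pos
  RB <- stats::rnorm(length(xi))
  if (i %in% state$indexa) {
    r1 <- stats::runif(1)
    elite_select(state) + RB * (r1 * (G - xi) + (1 - r1) * (state$xbar - xi))
  } else {
    r2 <- stats::runif(1, -1, 1)
    state$M * G + RB * (r2 * (G - xi) + (1 - r2) * (state$xbar - xi))
  }
}

#' Particle-swarm velocity update with bound-preserving clipping
#'
#' `v <- w v + c1 r1 (p_i - x_i) + c2 r2 (G - x_i)` using the pre-update
#' position as reference, clipped elementwise to `[Lb - cand, Ub - cand]` so
#' adding it to the snow-ablation candidate cannot leave the box.
#'
#' @param state Swarm state with `velocities`, `pbest_pos`, `gbest_pos`,
#'   `positions` and the current inertia `w_t`.
#' @param i Particle index.
#' @param candidate The snow-ablation candidate the velocity will be added to.
#' @param cfg A [tpsao_config()].
#' @return Clipped velocity vector.
#' @export
pso_velocity <- function(state, i, candidate, cfg) {
  xi <- state$positions[i, ]
  v <- state$w_t * state$velocities[i, ] +
    cfg$c1 * stats::runif(1) * (state$pbest_pos[i, ] - xi) +
    cfg$c2 * stats::runif(1) * (state$gbest_pos - xi)
  pmin(pmax(v, cfg$Lb - candidate), cfg$Ub - candidate)
}

.eval_objective <- function(objective, X) {
  f <- apply(X, 1, objective)
  bad <- !is.finite(f)
  if (any(bad)) {
    warning(sum(bad), " non-finite objective value(s) set to +Inf",
            call. = FALSE)
    f[bad] <- Inf
  }
  f
}

#' Run the TPSAO loop
#'
#' @param objective Function mapping a position vector in the box to a finite
#'   fitness (lower is better); non-finite returns are treated as `+Inf`.
#' @param cfg A [tpsao_config()].
#' @return A list of class `tpsao_result` with `best_position`,
#'   `best_fitness`, a per-iteration `history` tibble and the evaluation
#'   count.
#' @export
tpsao_optimize <- function(objective, cfg) {
  if (!is.null(cfg$seed)) withr::local_seed(cfg$seed)
  N <- cfg$N
  tmax <- cfg$tmax
  cfg_noseed <- cfg
  cfg_noseed$seed <- NULL  # the run is already seeded; draw from the stream
  X <- tent_init(cfg_noseed)
  V <- matrix(0, N, cfg$dim)
  fit <- .eval_objective(objective, X)
  n_evals <- N
  pbest_pos <- X
  pbest_fit <- fit
  gi <- which.min(fit)
  gbest_pos <- X[gi, ]
  gbest_fit <- fit[gi]
  history <- numeric(tmax)

  for (t in seq_len(tmax)) {
    w_t <- if (tmax > 1) {
      cfg$w[1] - (cfg$w[1] - cfg$w[2]) * (t - 1) / (tmax - 1)
    } else {
      cfg$w[1]
    }
    Nb <- max(1L, round((N / 2) * (1 - t / tmax)))
    Na <- N - Nb
    perm <- sample.int(N)
    state <- list(positions = X, velocities = V, fitness = fit,
                  pbest_pos = pbest_pos, gbest_pos = gbest_pos,
                  xbar = colMeans(X), M = melt_rate(t, tmax), w_t = w_t,
                  indexa = perm[seq_len(Na)],
                  indexb = if (Nb > 0) perm[(Na + 1):N] else integer(0))
    Xn <- X
    Vn <- V
    for (i in seq_len(N)) {
      cand <- sao_candidate(state, i)
      v <- pso_velocity(state, i, cand, cfg)
      Xn[i, ] <- pmin(pmax(cand + v, cfg$Lb), cfg$Ub)
      Vn[i, ] <- v
    }
    X <- Xn
    V <- Vn
    fit <- .eval_objective(objective, X)
    n_evals <- n_evals + N
    improved <- fit < pbest_fit
    pbest_pos[improved, ] <- X[improved, , drop = FALSE]
    pbest_fit[improved] <- fit[improved]
    gi <- which.min(pbest_fit)
    if (pbest_fit[gi] < gbest_fit) {
      gbest_fit <- pbest_fit[gi]
      gbest_pos <- pbest_pos[gi, ]
    }
    history[t] <- gbest_fit
  }

  hist_tbl <- tibble::tibble(iteration = seq_len(tmax), best_fitness = history)
  structure(list(best_position = gbest_pos, best_fitness = gbest_fit,
                 history = hist_tbl, n_evals = n_evals, config = cfg),
            class = "tpsao_result")
}

#' @export
print.tpsao_result <- function(x, ...) {
  cat("TPSAO result: best fitness", format(x$best_fitness, digits = 6),
      "at position", paste(format(x$best_position, digits = 6), collapse = ", "),
      "\n")
  invisible(x)
}

#' Learning-rate search
#'
#' One-dimensional TPSAO over a learning-rate interval; the objective maps a
#' learning rate to a validation loss.
#'
#' @param train_eval_fn Function `lr -> validation loss`.
#' @param lower,upper Learning-rate bounds.
#' @param N,tmax,seed Passed to [tpsao_config()].
#' @return A list of class `lr_search_result` with `best_lr`, `best_fitness`
#'   and the search `trace` tibble (length `tmax`).
#' @export
lr_search <- function(train_eval_fn, lower = 1e-4, upper = 1e-2, N = 50L,
                      tmax = 100L, seed = NULL) {
  if (lower >= upper) stop("lower bound must be below upper bound", call. = FALSE)
  cfg <- tpsao_config(dim = 1L, Lb = lower, Ub = upper, N = N, tmax = tmax,
                      seed = seed)
  res <- tpsao_optimize(function(x) train_eval_fn(x[1]), cfg)
  structure(list(best_lr = res$best_position[1],
                 best_fitness = res$best_fitness,
                 trace = res$history, bounds = c(lower, upper),
                 config = cfg),
            class = "lr_search_result")
}
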