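test_that("the tent map folds the unit interval onto itself", {
  expect_equal(tent_map(0.25, 0.5), 0.5)
  expect_equal(tent_map(0.75, 0.5), 0.5)
  expect_equal(tent_map(0.7, 0.7), 1.0)
  expect_equal(tent_map(0, 0.3), 0)
  expect_equal(tent_map(1, 0.3), 0)
  expect_error(tent_map(1.2), "outside")
  set.seed(1)
  u <- runif(200)
  expect_true(all(tent_map(u, 0.37) >= 0 & tent_map(u, 0.37) <= 1))
})

test_that("tent initialisation is bounded, reproducible and well spread", {
  cfg <- tpsao_config(dim = 3, Lb = c(-1, 0, 10), Ub = c(1, 5, 20), N = 40,
                      seed = 9)
  X1 <- tent_init(cfg)
  X2 <- tent_init(cfg)
  expect_identical(X1, X2)
  expect_true(all(sweep(X1, 2, cfg$Lb, ">=")))
  expect_true(all(sweep(X1, 2, cfg$Ub, "<=")))

  cfg1 <- tpsao_config(dim = 1, Lb = 0, Ub = 1, N = 200, seed = 4)
  x <- tent_init(cfg1)[, 1]
  bins <- table(cut(x, breaks = seq(0, 1, by = 0.1)))
  expect_gte(sum(bins > 0), 8)
})

test_that("the melt rate decays from 0.35 to 0.6/e", {
  expect_equal(melt_rate(0, 100), 0.35)
  expect_equal(melt_rate(100, 100), 0.6 * exp(-1))
  expect_lt(abs(0.6 * exp(-1) - 0.220728), 1e-6)
  m <- melt_rate(seq(0, 50, length.out = 1000), 50)
  expect_true(all(diff(m) <= 1e-12))
})

test_that("elite selection draws from the four-candidate set", {
  # identical particles: every candidate is that point
  st <- list(positions = matrix(2, 6, 2), fitness = rep(1, 6),
             gbest_pos = c(2, 2))
  set.seed(5)
  expect_equal(elite_select(st), c(2, 2))

  # ranked scalars: centroid of the best two is 1.5
  st2 <- list(positions = matrix(1:4, 4, 1), fitness = 1:4,
              gbest_pos = 1)
  set.seed(6)
  seen <- replicate(4000, elite_select(st2))
  expect_setequal(sort(unique(seen)), c(1, 1.5, 2, 3))

  # uniform selection frequencies 0.25 +/- 0.02
  freq <- table(factor(seen, levels = c(1, 1.5, 2, 3))) / length(seen)
  expect_true(all(abs(freq - 0.25) < 0.02))

  expect_error(elite_select(list(positions = matrix(1:3, 3, 1),
                                 fitness = 1:3, gbest_pos = 1)), "4")
})

test_that("candidate and velocity updates match a literal transcription", {
  cfg <- tpsao_config(dim = 3, Lb = rep(-2, 3), Ub = rep(2, 3), N = 6,
                      tmax = 10, c1 = 2, c2 = 2)
  set.seed(7)
  X <- matrix(runif(18, -2, 2), 6, 3)
  st <- list(positions = X, velocities = matrix(0.3, 6, 3),
             fitness = rnorm(6), pbest_pos = X + 0.1,
             gbest_pos = X[2, ], xbar = colMeans(X),
             M = melt_rate(3, 10), w_t = 0.8,
             indexa = c(1, 3, 5), indexb = c(2, 4, 6))

  # exploration branch
  set.seed(100)
  got_a <- sao_candidate(st, 1)
  set.seed(100)
  RB <- rnorm(3); r1 <- runif(1)
  k <- sample.int(4, 1)
  ord <- order(st$fitness); n1 <- ceiling(6 / 2)
  cands <- list(st$gbest_pos, st$positions[ord[2], ], st$positions[ord[3], ],
                colMeans(st$positions[ord[1:n1], ]))
  exp_a <- cands[[k]] +
    RB * (r1 * (st$gbest_pos - X[1, ]) + (1 - r1) * (st$xbar - X[1, ]))
  expect_equal(got_a, exp_a)

  # exploitation branch
  set.seed(101)
  got_b <- sao_candidate(st, 2)
  set.seed(101)
  RB <- rnorm(3); r2 <- runif(1, -1, 1)
  exp_b <- st$M * st$gbest_pos +
    RB * (r2 * (st$gbest_pos - X[2, ]) + (1 - r2) * (st$xbar - X[2, ]))
  expect_equal(got_b, exp_b)

  # velocity transcription and clipping
  cand <- got_a
  set.seed(102)
  v_got <- pso_velocity(st, 1, cand, cfg)
  set.seed(102)
  ru1 <- runif(1); ru2 <- runif(1)
  v_exp <- 0.8 * st$velocities[1, ] + 2 * ru1 * (st$pbest_pos[1, ] - X[1, ]) +
    2 * ru2 * (st$gbest_pos - X[1, ])
  v_exp <- pmin(pmax(v_exp, cfg$Lb - cand), cfg$Ub - cand)
  expect_equal(v_got, v_exp)

  # inertia-only update keeps the velocity
  cfg0 <- tpsao_config(dim = 1, Lb = -100, Ub = 100, N = 4, c1 = 0, c2 = 0)
  st1 <- list(positions = matrix(0, 4, 1), velocities = matrix(5, 4, 1),
              fitness = 1:4, pbest_pos = matrix(0, 4, 1), gbest_pos = 0,
              xbar = 0, M = 0.3, w_t = 1, indexa = 1:2, indexb = 3:4)
  expect_equal(pso_velocity(st1, 1, 0, cfg0), 5)
  # clip against the upper bound: V = 5, candidate 0.5, box [0, 1]
  cfg01 <- tpsao_config(dim = 1, Lb = 0, Ub = 1, N = 4, c1 = 0, c2 = 0)
  expect_equal(pso_velocity(st1, 1, 0.5, cfg01), 0.5)
})

test_that("the optimizer stays in bounds, improves monotonically and is reproducible", {
  viol <- 0
  obj <- function(x) {
    viol <<- max(viol, max(x - 0.01), max(1e-4 - x))
    (x[1] - 0.003)^2
  }
  cfg <- tpsao_config(dim = 1, Lb = 1e-4, Ub = 0.01, N = 20, tmax = 30,
                      seed = 11)
  res <- tpsao_optimize(obj, cfg)
  expect_lte(viol, 0)
  expect_true(all(diff(res$history$best_fitness) <= 0))
  expect_equal(nrow(res$history), 30)
  expect_gte(res$best_position, 1e-4)
  expect_lte(res$best_position, 0.01)

  res2 <- tpsao_optimize(function(x) (x[1] - 0.003)^2, cfg)
  expect_identical(res$best_position, res2$best_position)
  expect_identical(res$history$best_fitness, res2$history$best_fitness)

  # quadratic recovery on a few seeds
  for (s in 1:5) {
    cfg_s <- tpsao_config(dim = 1, Lb = 1e-4, Ub = 0.01, N = 30, tmax = 50,
                          seed = s)
    r <- tpsao_optimize(function(x) (x[1] - 0.003)^2, cfg_s)
    expect_lt(abs(r$best_position - 0.003), 1e-4)
  }

  # 2-D sphere: the median best fitness over ten seeds falls three orders
  # of magnitude below the ~17 expected under uniform initialisation
  sph <- vapply(1:10, function(s) {
    tpsao_optimize(function(x) sum(x^2),
                   tpsao_config(dim = 2, Lb = -5, Ub = 5, N = 30, tmax = 100,
                                seed = s))$best_fitness
  }, numeric(1))
  expect_lt(median(sph), 0.02)

  expect_warning(
    tpsao_optimize(function(x) if (x[1] > 0.005) NaN else x[1]^2,
                   tpsao_config(dim = 1, Lb = 1e-4, Ub = 0.01, N = 10,
                                tmax = 5, seed = 2)),
    "non-finite")
})

test_that("learning-rate search respects its interval and converges", {
  sr <- lr_search(function(lr) (lr - 0.002)^2 + rnorm(1, sd = 1e-8),
                  N = 30, tmax = 40, seed = 21)
  expect_gte(sr$best_lr, 1e-4)
  expect_lte(sr$best_lr, 1e-2)
  expect_equal(nrow(sr$trace), 40)
  expect_lt(abs(sr$best_lr - 0.002), 2e-4)
  expect_error(lr_search(function(lr) lr, lower = 0.1, upper = 0.01),
               "below")

  tl <- tidy(sr)
  expect_s3_class(tl, "tbl_df")
  gl <- glance(sr)
  expect_equal(gl$lower_bound, 1e-4)
})

test_that("the subpopulation schedule shrinks the exploitation group", {
  N <- 20; tmax <- 10
  nb <- vapply(seq_len(tmax), function(t) max(1, round((N / 2) * (1 - t / tmax))),
               numeric(1))
  expect_true(all(diff(nb) <= 0))
  expect_true(all(nb >= 1 & nb + (N - nb) == N))
})
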