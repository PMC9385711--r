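test_that("logistic map hits its extremes and stays bounded", {
  expect_identical(logistic_step(0.5, 4), 1)
  expect_identical(logistic_step(0, 4), 0)
  expect_identical(logistic_step(1, 4), 0)
  l <- 0.3
  for (i in 1:10000) {
    l <- logistic_step(l, 4)
    if (l < 0 || l > 1) break
  }
  expect_true(l >= 0 && l <= 1)
  expect_error(logistic_step(1.5), "0, 1")
})

test_that("inertia schedules respect endpoints, bounds and monotonicity", {
  withr::local_seed(3)
  for (i in 1:20) {
    wmin <- stats::runif(1, 0.05, 0.5)
    wmax <- wmin + stats::runif(1, 0.1, 0.6)
    kmax <- sample(5:200, 1)
    ks <- 0:kmax
    for (fn in list(inertia_linear, inertia_concave1, inertia_concave2)) {
      w <- fn(ks, kmax, wmin, wmax)
      expect_equal(w[1], wmax)
      expect_true(all(diff(w) < 0))
      expect_true(all(w >= wmin - 1e-12 & w <= wmax + 1e-12))
    }
    expect_equal(inertia_linear(kmax, kmax, wmin, wmax), wmin)
    expect_equal(inertia_concave2(kmax, kmax, wmin, wmax), wmin)
    expect_equal(inertia_concave1(kmax, kmax, wmin, wmax),
                 wmin * (wmax / wmin)^(1 / 11))
  }
  expect_equal(inertia_linear(5, 10, 0.4, 0.9), 0.65)
  expect_equal(inertia_concave2(5, 10, 0.4, 0.9), 0.9 - 0.5 + 0.125)
  expect_equal(inertia_concave1(11, 11, 0.4, 0.9), 0.4 * 2.25^(1 / 11))
  expect_error(inertia_linear(-1, 10), "k must")
  expect_error(inertia_concave1(2, 10, 0.9, 0.4), "omega_min")
})

test_that("chaotic inertia lies in [alpha, 1] with the stated edge cases", {
  expect_equal(inertia_chaotic(3, 10, 0.2, 0.8, l = 0),
               0.8 - 0.6 * 0.3)                      # omega = alpha
  expect_identical(inertia_chaotic(3, 10, 0.2, 0.8, l = 1), 1)
  expect_equal(inertia_chaotic(5, 10, 0.2, 0.8, l = 0.5), 0.75)
  withr::local_seed(5)
  for (i in 1:200) {
    k <- sample(0:50, 1); l <- stats::runif(1)
    alpha <- 0.8 - 0.6 * k / 50
    w <- inertia_chaotic(k, 50, 0.2, 0.8, l)
    expect_gte(w, alpha - 1e-12)
    expect_lte(w, 1)
  }
  expect_error(inertia_chaotic(1, 10, 0.5, 1.2, l = 0.5), "alpha")
})

test_that("swarm_config validates its invariants", {
  expect_error(swarm_config(lo = c(0, 0), hi = c(1, -1)), "lo < hi")
  expect_error(swarm_config(lo = 0, hi = 1, n = 1), "at least 2")
  expect_error(swarm_config(lo = 0, hi = 1, omega_min = 0.9, omega_max = 0.4),
               "omega_min")
  expect_error(swarm_config(lo = 0, hi = 1, k_max = 0), "k_max")
})

test_that("the improved optimizer solves the sphere benchmark", {
  hits <- vapply(1:10, function(s) {
    cfg <- swarm_config(lo = rep(-5, 3), hi = rep(5, 3), n = 30, k_max = 50,
                        q_stop = 1e-12, scheme = "improved", seed = s)
    run_pso(function(x) sum(x^2), cfg)$best_q < 1e-3
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("gbest is non-increasing for every scheme and runs are seed-reproducible", {
  obj <- function(x) sum((x - c(1, -2))^2) + 0.5 * sin(3 * x[1])^2
  for (scheme in c("improved", "constant", "linear", "concave1", "concave2")) {
    cfg <- swarm_config(lo = c(-4, -4), hi = c(4, 4), n = 12, k_max = 30,
                        q_stop = 1e-12, scheme = scheme, seed = 99)
    f1 <- run_pso(obj, cfg)
    expect_true(all(diff(f1$history$gbest_q) <= 0))
    expect_true(all(vapply(seq_len(nrow(f1$history)), function(i)
      f1$history$gbest_q[i] <= f1$history$q_avg[i] + 1e-12, logical(1))))
    f2 <- run_pso(obj, cfg)
    expect_identical(f1$history, f2$history)
    expect_identical(f1$best_x, f2$best_x)
  }
})

test_that("a constant objective leaves the global best unchanged after iteration 1", {
  cfg <- swarm_config(lo = -1, hi = 1, n = 5, k_max = 10, q_stop = -1,
                      scheme = "improved", seed = 2)
  fit <- run_pso(function(x) 7, cfg)
  expect_true(all(fit$history$gbest_q == 7))
  expect_identical(fit$termination, "max_iter")
})

test_that("particles stay inside the box and frozen dynamics freeze the swarm", {
  seen <- new.env(); seen$bad <- 0L
  cfg <- swarm_config(lo = c(-2, 0), hi = c(3, 1), n = 8, k_max = 25,
                      q_stop = 1e-15, seed = 4)
  run_pso(function(x) {
    if (any(x < c(-2, 0) - 1e-9) || any(x > c(3, 1) + 1e-9))
      seen$bad <- seen$bad + 1L
    sum(x^2)
  }, cfg)
  expect_identical(seen$bad, 0L)
  # omega = 0 and c1 = c2 = 0: velocities vanish after one move
  cfg0 <- swarm_config(lo = -1, hi = 1, n = 4, k_max = 6, q_stop = -1,
                       scheme = "constant", omega_const = 0, c1 = 0, c2 = 0,
                       seed = 8)
  f0 <- run_pso(function(x) sum(x^2), cfg0)
  expect_true(all(f0$history$gbest_q[-1] == f0$history$gbest_q[2]))
})

test_that("non-finite objective values are rejected, not propagated", {
  cfg <- swarm_config(lo = -1, hi = 1, n = 6, k_max = 10, q_stop = -1, seed = 5)
  fit <- run_pso(function(x) if (x[1] > 0) NaN else sum(x^2), cfg)
  expect_true(is.finite(fit$best_q))
  expect_gt(fit$n_nonfinite, 0)
})

test_that("PSO beats an exhaustive coarse grid on the TC objective", {
  ref <- build_reference(tc_params(), stimulus_square(), quick_config())
  obj <- tc_objective(ref)
  grid <- expand.grid(i = seq(-10, 0, length.out = 5),
                      g = seq(0, 10, length.out = 5),
                      e = seq(90, 140, length.out = 5))
  grid_min <- min(apply(grid, 1, function(z) obj(as.numeric(z))))
  cfg <- swarm_config(lo = c(-10, 0, 90), hi = c(0, 10, 140), n = 15,
                      k_max = 20, q_stop = 1e-15, scheme = "improved",
                      seed = 31)
  fit <- run_pso(obj, cfg)
  expect_lte(fit$best_q, grid_min)
})
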