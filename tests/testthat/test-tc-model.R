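test_that("gating sigmoids hit 0.5 exactly at their midpoints", {
  g <- gating_steady_states(c(-37, -60, -41, -84))
  expect_identical(g$m_inf[1], 0.5)
  expect_identical(g$p_inf[2], 0.5)
  expect_identical(g$h_inf[3], 0.5)
  expect_identical(g$r_inf[4], 0.5)
  expect_equal(gating_steady_states(-30)$m_inf, 1 / (1 + exp(-1)))
})

test_that("gating curves are bounded, monotone, with positive time constants", {
  v <- seq(-120, 60, by = 0.5)
  g <- gating_steady_states(v)
  for (col in c("m_inf", "p_inf", "h_inf", "r_inf")) {
    expect_true(all(g[[col]] > 0 & g[[col]] < 1))
  }
  expect_true(all(diff(g$m_inf) > 0))
  expect_true(all(diff(g$p_inf) > 0))
  expect_true(all(diff(g$h_inf) < 0))
  expect_true(all(diff(g$r_inf) < 0))
  tau <- gating_time_constants(v)
  expect_true(all(tau$tau_h > 0))
  expect_true(all(tau$tau_r > 28))
  expect_error(gating_steady_states(NaN), "finite")
  expect_error(gating_time_constants(Inf), "finite")
})

test_that("time constants match closed-form values and asymptotes", {
  expect_identical(gating_time_constants(-25)$tau_r, 29)
  expect_equal(gating_time_constants(-46)$tau_h,
               1 / (0.128 + 4 / (1 + exp(4.6))))
  # a_h -> 0, b_h -> 4 at depolarized voltages
  expect_equal(gating_time_constants(300)$tau_h, 0.25, tolerance = 1e-6)
})

test_that("ionic currents vanish and scale as the model dictates", {
  p <- tc_params()
  expect_identical(ionic_currents(p$e_l, 0.5, 0.5, p)$i_l, 0)
  expect_identical(ionic_currents(-50, 1, 0.5, p)$i_k, 0)
  # T current at the p_inf midpoint: 3 * 0.25 * 0.5 * (-60 - 120)
  p2 <- tc_params(g_t = 3, e_t = 120)
  expect_equal(ionic_currents(-60, 0.5, 0.5, p2)$i_t, -67.5)
  expect_identical(ionic_currents(-60, 0.5, 0, p2)$i_t, 0)
})

test_that("derivatives have the gate fixed points and the rest condition", {
  p <- tc_params()
  g <- gating_steady_states(-55)
  d <- tc_derivatives(-55, g$h_inf, g$r_inf, i_sm = 0, p)
  expect_equal(d$dh, 0)
  expect_equal(d$dr, 0)
  # no conductances, no applied currents: membrane is inert
  p0 <- tc_params(i_gi = 0, g_t = 0, g_l = 0, g_na = 0, g_k = 0)
  expect_identical(tc_derivatives(-40, 0.3, 0.7, i_sm = 0, p0)$dv, 0)
})

test_that("tc_params validates its invariants", {
  expect_error(tc_params(c_m = 0), "c_m")
  expect_error(tc_params(g_t = -1), "nonnegative")
  expect_error(tc_params(e_na = -80, e_k = -75), "e_na")
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(t_discard = 1000, t_total = 1000), "t_discard")
})

test_that("a simulation started at the resting fixed point stays there", {
  p <- tc_params(i_gi = 0)
  rest <- tc_rest_state(p)
  cfg <- sim_config(dt = 0.05, t_total = 100, t_discard = 0,
                    v0 = rest$v, h0 = rest$h, r0 = rest$r)
  sim <- simulate_tc(p, stimulus_square(a_sm = 0), cfg)
  expect_lt(diff(range(sim$v)), 1e-6)
  expect_false(attr(sim, "gate_excursion"))
})

test_that("gate relaxation at frozen voltage matches the analytic solution at 4th order", {
  # all conductances zero and no input: V stays put, gates relax like
  # h(t) = h_inf + (h0 - h_inf) exp(-t / tau_h)
  p <- tc_params(i_gi = 0, g_t = 0, g_l = 0, g_na = 0, g_k = 0)
  v0 <- -55
  g <- gating_steady_states(v0)
  tau <- gating_time_constants(v0)
  t_end <- 40
  analytic_h <- g$h_inf + (0.2 - g$h_inf) * exp(-t_end / tau$tau_h)
  analytic_r <- g$r_inf + (0.9 - g$r_inf) * exp(-2.5 * t_end / tau$tau_r)
  err <- vapply(c(0.4, 0.2), function(dt) {
    cfg <- sim_config(dt = dt, t_total = t_end, t_discard = 0,
                      v0 = v0, h0 = 0.2, r0 = 0.9)
    sim <- simulate_tc(p, stimulus_square(a_sm = 0), cfg)
    n <- nrow(sim)
    expect_equal(sim$v[n], v0)
    abs(sim$h[n] - analytic_h) + abs(sim$r[n] - analytic_r)
  }, numeric(1))
  expect_lt(err[1], 1e-8)
  # halving dt cuts the global error by ~2^4
  expect_gt(err[1] / err[2], 8)
  expect_lt(err[1] / err[2], 32)
})

test_that("step halving on the full system shows 4th-order convergence", {
  p <- tc_params(i_gi = -0.5)
  v_end <- vapply(c(0.08, 0.04, 0.02), function(dt) {
    cfg <- sim_config(dt = dt, t_total = 20, t_discard = 0)
    sim <- simulate_tc(p, stimulus_square(a_sm = 0), cfg)
    sim$v[nrow(sim)]
  }, numeric(1))
  d1 <- abs(v_end[1] - v_end[2])
  d2 <- abs(v_end[2] - v_end[3])
  expect_gt(d1 / d2, 6)
  expect_lt(d1 / d2, 40)
})

test_that("simulation is bit-reproducible and guards against divergence", {
  cfg <- quick_config()
  s1 <- simulate_tc(tc_params(), stimulus_square(), cfg)
  s2 <- simulate_tc(tc_params(), stimulus_square(), cfg)
  expect_identical(s1$v, s2$v)
  expect_true(all(abs(diff(s1$time) - cfg$dt) < 1e-12))
  expect_error(
    simulate_tc(tc_params(i_gi = 500), stimulus_square(), cfg),
    "integration failure")
})

test_that("simulations export to CSV with a JSON sidecar", {
  cfg <- sim_config(dt = 0.1, t_total = 30, t_discard = 0)
  sim <- simulate_tc(tc_params(), stimulus_square(), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tc_sim(sim, path)
  back <- utils::read.csv(path)
  expect_equal(back$v_mv, sim$v)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$params$i_gi, -3.5)
  expect_equal(meta$pulse_onsets, attr(sim, "pulse_onsets"))
})
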