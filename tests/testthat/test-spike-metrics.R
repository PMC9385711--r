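test_that("spike detection finds one spike per excursion at the apex", {
  flat <- triangle_trace(n = 500)
  expect_identical(nrow(detect_spikes(flat, threshold = -25)), 0L)
  tr <- triangle_trace(n = 1000, apex_idx = c(100, 400, 800),
                       apex_v = c(-10, -5, 0))
  sp <- detect_spikes(tr, threshold = -25)
  expect_identical(nrow(sp), 3L)
  expect_equal(sp$time, tr$time[c(100, 400, 800)])
  expect_equal(sp$peak, c(-10, -5, 0))
  expect_true(all(diff(sp$time) > 0))
})

test_that("an excursion touching the threshold at a single sample counts", {
  tr <- tibble::tibble(time = 0:10, v = c(rep(-65, 5), -25, rep(-65, 5)))
  sp <- detect_spikes(tr, threshold = -25)
  expect_identical(nrow(sp), 1L)
  expect_equal(sp$time, 5)
})

test_that("detection respects the discard transient", {
  tr <- triangle_trace(n = 1000, apex_idx = c(100, 800), apex_v = c(-5, -5))
  sp <- detect_spikes(tr, threshold = -25, t_min = 50)
  expect_identical(nrow(sp), 1L)
})

test_that("relay classification handles the canonical cases", {
  onsets <- seq(0, by = 25, length.out = 10)
  perfect <- tibble::tibble(time = onsets + 3)
  r <- classify_relay(perfect, onsets, 25)
  expect_equal(r$ri, 1)
  expect_equal(r$missed + r$bad, 0)

  r0 <- classify_relay(tibble::tibble(time = numeric(0)), onsets, 25)
  expect_equal(r0$ri, 0)
  expect_equal(r0$missed, 10)

  # 2 doubled windows + 3 empty windows among 10 -> error index 0.5
  mixed <- tibble::tibble(time = sort(c(
    onsets[1] + c(2, 9), onsets[2] + c(1, 8),  # two bad
    onsets[6:10] + 4)))                        # 3..5 missed, rest correct
  rm_ <- classify_relay(mixed, onsets, 25)
  expect_equal(rm_$bad, 2)
  expect_equal(rm_$missed, 3)
  expect_equal(rm_$error_index, 0.5)
  expect_equal(rm_$ri, 0.5)
})

test_that("relay report identities hold and match a brute-force recount", {
  withr::local_seed(7)
  for (i in 1:1000) {
    fx <- random_relay_fixture()
    got <- suppressWarnings(classify_relay(fx$spikes, fx$onsets, 25))
    want <- brute_relay(fx$spikes, fx$onsets, 25)
    expect_identical(got$missed, want$missed)
    expect_identical(got$bad, want$bad)
    expect_equal(got$ri + got$error_index, 1)
    expect_gte(got$ri, 0)
    expect_lte(got$ri, 1)
  }
})

test_that("relay state classification uses the RI boundaries", {
  expect_identical(classify_state(c(0.95, 0.3, 0.7)),
                   c("normal", "parkinsonian", "indeterminate"))
  expect_error(classify_state(1.2), "0, 1")
})

test_that("feature extraction matches hand-computed values", {
  tr <- triangle_trace(n = 200, apex_idx = c(50, 150), apex_v = c(10, 20))
  sp <- detect_spikes(tr, threshold = -25, t_min = 0)
  relay <- classify_relay(sp, c(4, 14), window = 2, warn_truncate = FALSE)
  f <- extract_features(tr, sp, relay, threshold = -25, t_min = 0)
  expect_equal(f$pk, 15)  # mean of 10 and 20
  expect_equal(f$n, 2)
  expect_equal(f$st, mean(tr$v[tr$v < -25]))

  flat <- triangle_trace(n = 100)
  sp0 <- detect_spikes(flat, threshold = -25, t_min = 0)
  relay0 <- classify_relay(sp0, c(1), window = 2)
  f0 <- extract_features(flat, sp0, relay0, threshold = -25, t_min = 0)
  expect_equal(f0$n, 0)
  expect_equal(f0$st, -65)
  expect_equal(f0$pk, -25)  # zero-spike sentinel: the threshold
})

test_that("a trace with no subthreshold samples is rejected as degenerate", {
  hot <- tibble::tibble(time = 0:9, v = rep(0, 10))
  sp <- detect_spikes(hot, threshold = -25, t_min = 0)
  relay <- classify_relay(sp, c(1), window = 2)
  expect_error(extract_features(hot, sp, relay, threshold = -25, t_min = 0),
               "degenerate")
})

test_that("the feature fitness follows the weighted squared-difference form", {
  mk <- function(ri, n, pk, st) {
    f <- tibble::tibble(ri = ri, n = n, pk = pk, st = st)
    class(f) <- c("tc_features", class(f))
    f
  }
  ori <- mk(0.4, 40, -10, -60)
  expect_identical(spike_fitness(ori, ori), 0)
  rec <- mk(0.5, 42, -8.5, -59.5)
  expect_equal(spike_fitness(rec, ori), 0.01 + 4 + 2.25 + 0.25)
  w2 <- fitness_weights(2, 2, 2, 2)
  expect_equal(spike_fitness(rec, ori, w2), 2 * 6.51)
  # multi-trial sums are invariant to trial ordering
  ori2 <- mk(c(0.4, 0.6), c(40, 35), c(-10, -12), c(-60, -61))
  rec2 <- mk(c(0.5, 0.7), c(42, 36), c(-8.5, -11), c(-59.5, -60))
  expect_equal(spike_fitness(rec2, ori2), spike_fitness(rec2[2:1, ], ori2[2:1, ]))
  expect_gt(spike_fitness(rec2, ori2), 0)
  expect_error(spike_fitness(rec2, ori), "same positive number")
  expect_error(fitness_weights(0, 0, 0, 0), "not all zero")
})

test_that("parameter error is the three-term squared sum", {
  expect_identical(parameter_error(c(-3.5, 3, 120), c(-3.5, 3, 120)), 0)
  withr::local_seed(11)
  for (i in 1:100) {
    a <- stats::rnorm(3, sd = 10); b <- stats::rnorm(3, sd = 10)
    naive <- (a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2
    expect_equal(parameter_error(a, b), naive)
  }
  # the recovered triple reported for the chaotic-concave optimizer
  e <- parameter_error(c(-3.4991, 3.0215, 119.6532), c(-3.5, 3, 120))
  expect_lt(log(e), -2)
  expect_equal(round(log(e), 2), -2.11)
})

test_that("sim_features agrees with the assembled pipeline calls", {
  cfg <- quick_config()
  sim <- simulate_tc(tc_params(), stimulus_square(), cfg)
  f <- sim_features(sim)
  sp <- detect_spikes(sim, threshold = -25)
  onsets <- attr(sim, "pulse_onsets")
  onsets <- onsets[onsets >= cfg$t_discard & onsets < cfg$t_total]
  relay <- classify_relay(sp, onsets, 25)
  f2 <- extract_features(sim, sp, relay, threshold = -25)
  expect_equal(f$ri, f2$ri)
  expect_equal(f$n, f2$n)
  expect_equal(f$pk, f2$pk)
  expect_equal(f$st, f2$st)
})
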