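# Shared fixtures, all built in code.

# A flat voltage trace with triangular spike-like excursions inserted at
# given apex indices (10-sample rise/fall), returned as a minimal data frame
# compatible with detect_spikes().
triangle_trace <- function(n = 1000, dt = 0.1, base = -65,
                           apex_idx = integer(0), apex_v = numeric(0)) {
  v <- rep(base, n)
  for (j in seq_along(apex_idx)) {
    i <- apex_idx[j]
    for (k in -10:10) {
      ii <- i + k
      if (ii >= 1 && ii <= n)
        v[ii] <- max(v[ii], apex_v[j] - abs(k) * (apex_v[j] - base) / 10)
    }
  }
  tibble::tibble(time = seq(0, by = dt, length.out = n), v = v)
}

# Random relay fixture: sorted pulse onsets with a minimum gap, plus spike
# times scattered in and around the windows.
random_relay_fixture <- function() {
  n_on <- sample(3:12, 1)
  onsets <- cumsum(stats::runif(n_on, 6, 40))
  n_spk <- sample(0:25, 1)
  spikes <- tibble::tibble(
    time = sort(stats::runif(n_spk, 0, max(onsets) + 30)))
  list(onsets = onsets, spikes = spikes)
}

# Brute-force relay recount: literal per-window loop over the definition.
brute_relay <- function(spikes, onsets, window) {
  gaps <- diff(onsets)
  win <- pmin(window, c(gaps, window))
  missed <- 0L; bad <- 0L
  for (i in seq_along(onsets)) {
    cnt <- sum(spikes$time >= onsets[i] & spikes$time < onsets[i] + win[i])
    if (cnt == 0) missed <- missed + 1L
    if (cnt >= 2) bad <- bad + 1L
  }
  err <- (missed + bad) / length(onsets)
  list(missed = missed, bad = bad, error_index = err, ri = 1 - err)
}

# Small, fast simulation setup shared by pipeline tests.
quick_config <- function() sim_config(dt = 0.05, t_total = 200, t_discard = 50)
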