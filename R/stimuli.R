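#' Heaviside step function
#'
#' Right-continuous convention: `H(0) = 1`.
#'
#' @param x numeric vector; must be finite.
#' @return 0/1 numeric vector of the same length.
#' @examples
#' heaviside(c(-0.001, 0, 5))  # 0 1 1
#' @export
heaviside <- function(x) {
  if (!is.numeric(x) || !all(is.finite(x))) stop("x must be finite numeric")
  as.numeric(x >= 0)
}

#' Square-wave pulse stimulus specification
#'
#' A periodic rectangular pulse train built from two Heaviside-gated sine
#' factors: `I(t) = A * H(sin(2 pi t / rho)) * (1 - H(sin(2 pi (t + delta) / rho)))`.
#' Each period of length `rho` contains exactly one ON window of width
#' `delta`; with the defaults (amplitude 5 pA/um^2, period 25 ms, width 5 ms)
#' the window within each period spans `(7.5, 12.5]` ms.
#'
#' @param a_sm pulse amplitude, pA/um^2 (>= 0).
#' @param rho_sm pulse period, ms.
#' @param delta_sm pulse duration, ms; `0 < delta_sm < rho_sm`.
#' @return An object of class `c("tc_stimulus_square", "tc_stimulus")`.
#' @export
stimulus_square <- function(a_sm = 5, rho_sm = 25, delta_sm = 5) {
  if (a_sm < 0) stop("a_sm must be nonnegative")
  if (!(delta_sm > 0 && delta_sm < rho_sm))
    stop("delta_sm must satisfy 0 < delta_sm < rho_sm")
  structure(list(kind = "square", a_sm = a_sm, rho_sm = rho_sm,
                 delta_sm = delta_sm),
            class = c("tc_stimulus_square", "tc_stimulus"))
}

#' Poisson pulse-train stimulus specification
#'
#' Rectangular pulses of fixed amplitude and width whose inter-onset gaps are
#' i.i.d. exponential with mean `mean_interval`; gaps shorter than the pulse
#' width are redrawn so pulses never overlap (the realized mean gap is
#' therefore `mean_interval + delta_sm` by memorylessness). Defaults reuse
#' the square-wave amplitude and width, with a mean interval equal to the
#' square-wave period, so the two input regimes are comparable.
#'
#' @param a_sm pulse amplitude, pA/um^2.
#' @param delta_sm pulse width, ms.
#' @param mean_interval mean of the exponential gap distribution, ms.
#' @param seed integer RNG seed; the realized train is a pure function of the
#'   spec (including this seed) and the horizon.
#' @return An object of class `c("tc_stimulus_poisson", "tc_stimulus")`.
#' @export
stimulus_poisson <- function(a_sm = 5, delta_sm = 5, mean_interval = 25,
                             seed = 1L) {
  if (a_sm < 0) stop("a_sm must be nonnegative")
  if (delta_sm <= 0) stop("delta_sm must be positive")
  if (mean_interval <= 0) stop("mean_interval must be positive")
  structure(list(kind = "poisson", a_sm = a_sm, delta_sm = delta_sm,
                 mean_interval = mean_interval, seed = as.integer(seed)),
            class = c("tc_stimulus_poisson", "tc_stimulus"))
}

#' Evaluate the square-wave current at arbitrary times
#'
#' Direct evaluation of the Heaviside-gated sine form; exact (no sampling).
#'
#' @param t time(s), ms.
#' @param spec a [stimulus_square()] specification.
#' @return Current value(s), each 0 or `a_sm`.
#' @examples
#' square_wave_current(10, stimulus_square())  # inside the ON window: 5
#' square_wave_current(0, stimulus_square())   # 0
#' @export
square_wave_current <- function(t, spec = stimulus_square()) {
  stopifnot(inherits(spec, "tc_stimulus_square"))
  spec$a_sm * heaviside(sin(2 * pi * t / spec$rho_sm)) *
    (1 - heaviside(sin(2 * pi * (t + spec$delta_sm) / spec$rho_sm)))
}

#' Pulse onset times of a stimulus over a horizon
#'
#' For the square wave the onsets are analytic: the ON window of period `k`
#' starts at `rho/2 - delta + k * rho`. For the Poisson train the onsets are
#' drawn from the spec's seed: exponential gaps with mean `mean_interval`,
#' redrawn while shorter than `delta_sm`.
#'
#' @param spec a `tc_stimulus` specification.
#' @param t_total horizon, ms; onsets are kept only if the full pulse fits.
#' @return Strictly increasing numeric vector of onset times, ms (may be
#'   empty, with a warning, if the horizon admits no pulse).
#' @export
stimulus_onsets <- function(spec, t_total) {
  stopifnot(inherits(spec, "tc_stimulus"), t_total > 0)
  if (inherits(spec, "tc_stimulus_square")) {
    first <- spec$rho_sm / 2 - spec$delta_sm
    last <- t_total - spec$delta_sm
    on <- if (first > last) numeric(0) else seq(first, last, by = spec$rho_sm)
  } else {
    on <- withr::with_seed(spec$seed, {
      # exponential gaps, redrawn while shorter than the pulse width
      acc <- numeric(ceiling(t_total / spec$mean_interval) + 16L)
      n_acc <- 0L
      t <- 0
      repeat {
        gap <- stats::rexp(1, rate = 1 / spec$mean_interval)
        if (gap < spec$delta_sm) next
        t <- t + gap
        if (t > t_total - spec$delta_sm) break
        n_acc <- n_acc + 1L
        if (n_acc > length(acc)) acc <- c(acc, numeric(length(acc)))
        acc[n_acc] <- t
      }
      acc[seq_len(n_acc)]
    })
  }
  if (length(on) == 0)
    warning("horizon too short for a single pulse; empty onset list")
  on
}

# Sample a stimulus on the RK4 half grid for a sim_config.
# Returns list(i_sm_half, onsets): i_sm_half has 2n + 1 values at spacing dt/2.
stimulus_on_grid <- function(spec, config) {
  stopifnot(inherits(spec, "tc_stimulus"), inherits(config, "sim_config"))
  n <- round(config$t_total / config$dt)
  th <- seq(0, by = config$dt / 2, length.out = 2L * n + 1L)
  if (inherits(spec, "tc_stimulus_square")) {
    vals <- square_wave_current(th, spec)
    onsets <- stimulus_onsets(spec, config$t_total)
  } else {
    onsets <- stimulus_onsets(spec, config$t_total)
    vals <- numeric(length(th))
    if (length(onsets)) {
      idx <- findInterval(th, onsets)
      hit <- idx >= 1L
      hit[hit] <- th[hit] < onsets[idx[hit]] + spec$delta_sm
      vals[hit] <- spec$a_sm
    }
  }
  list(i_sm_half = vals, onsets = onsets)
}

#' Render a stimulus on a simulation grid
#'
#' Samples the analytic square wave, or a realized Poisson train, at the
#' integration step of `config` and records the pulse onsets alongside.
#'
#' @param spec a `tc_stimulus` specification.
#' @param config a [sim_config()] object supplying the grid.
#' @return A tibble of class `tc_trace` with columns `time`, `i_sm` and
#'   attributes `pulse_onsets` and `spec`.
#' @export
render_stimulus <- function(spec, config = sim_config()) {
  st <- stimulus_on_grid(spec, config)
  n <- (length(st$i_sm_half) - 1L) / 2L
  res <- tibble::tibble(
    time = seq(0, by = config$dt, length.out = n + 1L),
    i_sm = st$i_sm_half[seq(1L, length(st$i_sm_half), by = 2L)])
  attr(res, "pulse_onsets") <- st$onsets
  attr(res, "spec") <- spec
  class(res) <- c("tc_trace", class(res))
  res
}

#' Export a stimulus trace as CSV plus JSON sidecar
#'
#' @param trace a `tc_trace` tibble from [render_stimulus()].
#' @param path output CSV path (`time_ms`, `i_sm`); onsets and the spec go to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_tc_trace <- function(trace, path) {
  stopifnot(inherits(trace, "tc_trace"))
  utils::write.csv(data.frame(time_ms = trace$time, i_sm = trace$i_sm),
                   path, row.names = FALSE)
  jsonlite::write_json(
    list(pulse_onsets = attr(trace, "pulse_onsets"),
         spec = unclass(attr(trace, "spec"))),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
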