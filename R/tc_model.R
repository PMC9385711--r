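#' Parameters of the single-compartment thalamocortical relay neuron
#'
#' Bundles the membrane capacitance, maximal conductances, reversal potentials
#' and the constant pallidal inhibitory drive of the reduced TC relay model.
#' The three *key* parameters fitted by the optimizer are `i_gi` (the
#' inhibitory current from the internal globus pallidus, pA/um^2), `g_t` (the
#' maximal T-type calcium conductance) and `e_t` (the calcium reversal
#' potential, mV). The remaining values default to literature-typical constants
#' for the reduced TC model and are held fixed during fitting; all are
#' overridable.
#'
#' The membrane equation subtracts both applied currents,
#' `C dV/dt = -I_L - I_Na - I_K - I_T - I_Gi - I_SM`. Because the sensorimotor
#' input is conventionally reported with a positive amplitude while it
#' depolarizes the cell, `flip_sign_sm = TRUE` by default so the square-wave
#' pulses enter with a `+` sign. `flip_sign_gi = FALSE` keeps the literal `-`
#' on the pallidal term, under which the conventional negative `i_gi` values
#' raise the operating point of the cell; see the package vignette for the
#' discussion of this convention.
#'
#' @param i_gi constant inhibitory current density from GPi, pA/um^2
#'   (fitted; Parkinsonian reference value -3.5).
#' @param g_t maximal T-type calcium conductance (fitted; reference 3).
#' @param e_t calcium reversal potential, mV (fitted; reference 120).
#' @param c_m membrane capacitance per area (> 0).
#' @param g_l,e_l leak conductance and reversal.
#' @param g_na,e_na sodium maximal conductance and reversal.
#' @param g_k,e_k potassium maximal conductance and reversal.
#' @param flip_sign_sm,flip_sign_gi flip the sign with which the applied
#'   sensorimotor / pallidal current enters the membrane equation.
#' @return An object of class `tc_params` (named list).
#' @examples
#' tc_params()                      # Parkinsonian reference point
#' tc_params(i_gi = -1.2, g_t = 1)  # a normally relaying operating point
#' @export
tc_params <- function(i_gi = -3.5, g_t = 3, e_t = 120,
                      c_m = 1, g_l = 0.05, e_l = -70,
                      g_na = 3, e_na = 50, g_k = 5, e_k = -75,
                      flip_sign_sm = TRUE, flip_sign_gi = FALSE) {
  vals <- c(i_gi = i_gi, g_t = g_t, e_t = e_t, c_m = c_m, g_l = g_l,
            e_l = e_l, g_na = g_na, e_na = e_na, g_k = g_k, e_k = e_k)
  if (!all(is.finite(vals))) stop("all TC parameters must be finite numbers")
  if (c_m <= 0) stop("c_m must be positive")
  if (any(c(g_l, g_na, g_k, g_t) < 0)) stop("conductances must be nonnegative")
  if (e_na <= e_k) stop("e_na must exceed e_k")
  structure(
    list(i_gi = i_gi, g_t = g_t, e_t = e_t, c_m = c_m, g_l = g_l, e_l = e_l,
         g_na = g_na, e_na = e_na, g_k = g_k, e_k = e_k,
         flip_sign_sm = isTRUE(flip_sign_sm), flip_sign_gi = isTRUE(flip_sign_gi)),
    class = "tc_params")
}

#' @export
print.tc_params <- function(x, ...) {
  cat("<tc_params>\n")
  cat(sprintf("  key:   i_gi = %g, g_t = %g, e_t = %g\n", x$i_gi, x$g_t, x$e_t))
  cat(sprintf("  fixed: c_m = %g, g_l = %g, e_l = %g, g_na = %g, e_na = %g, g_k = %g, e_k = %g\n",
              x$c_m, x$g_l, x$e_l, x$g_na, x$e_na, x$g_k, x$e_k))
  cat(sprintf("  signs: flip_sign_sm = %s, flip_sign_gi = %s\n",
              x$flip_sign_sm, x$flip_sign_gi))
  invisible(x)
}

#' Replace the three key parameters of a `tc_params` object
#'
#' @param params a [tc_params()] object.
#' @param key numeric vector `c(i_gi, g_t, e_t)`.
#' @return A `tc_params` object with the key triple replaced.
#' @export
set_key_params <- function(params, key) {
  stopifnot(inherits(params, "tc_params"), is.numeric(key), length(key) == 3)
  params$i_gi <- key[[1]]
  params$g_t <- max(key[[2]], 0)   # PSO may propose slightly negative conductances
  params$e_t <- key[[3]]
  params
}

#' Steady-state activation/inactivation curves of the TC gating variables
#'
#' Evaluates the four voltage-dependent sigmoids of the model: sodium
#' activation `m_inf` (midpoint -37 mV), T-current activation `p_inf`
#' (midpoint -60 mV), the shared sodium/potassium inactivation gate `h_inf`
#' (midpoint -41 mV, decreasing) and the T-current inactivation gate `r_inf`
#' (midpoint -84 mV, decreasing).
#'
#' @param v membrane potential(s), mV; must be finite.
#' @return A tibble with columns `v`, `m_inf`, `p_inf`, `h_inf`, `r_inf`,
#'   one row per input voltage; all gate values lie in (0, 1).
#' @examples
#' gating_steady_states(c(-84, -60, -41, -37))
#' @export
gating_steady_states <- function(v) {
  if (!is.numeric(v) || length(v) == 0 || !all(is.finite(v)))
    stop("v must be a finite numeric vector")
  tibble::tibble(
    v = as.numeric(v),
    m_inf = 1 / (1 + exp(-(v + 37) / 7)),
    p_inf = 1 / (1 + exp(-(v + 60) / 6.2)),
    h_inf = 1 / (1 + exp((v + 41) / 4)),
    r_inf = 1 / (1 + exp((v + 84) / 4)))
}

#' Voltage-dependent time constants of the TC gating variables
#'
#' `tau_h` follows the rate form `1/(a_h + b_h)` with
#' `a_h = 0.128 exp(-(V+46)/18)` and `b_h = 4/(1 + exp(-(V+23)/5))`;
#' `tau_r = 28 + exp(-(V+25)/10.5)` so it is bounded below by 28 ms.
#'
#' @inheritParams gating_steady_states
#' @return A tibble with columns `v`, `tau_h`, `tau_r` (ms); both positive.
#' @examples
#' gating_time_constants(-25)  # tau_r is exactly 29 ms here
#' @export
gating_time_constants <- function(v) {
  if (!is.numeric(v) || length(v) == 0 || !all(is.finite(v)))
    stop("v must be a finite numeric vector")
  a_h <- 0.128 * exp(-(v + 46) / 18)
  b_h <- 4 / (1 + exp(-(v + 23) / 5))
  tibble::tibble(v = as.numeric(v),
                 tau_h = 1 / (a_h + b_h),
                 tau_r = 28 + exp(-(v + 25) / 10.5))
}

#' Ionic membrane currents of the TC model
#'
#' Leak, transient sodium, potassium and low-threshold calcium current
#' densities at the given state. The potassium current reuses the sodium
#' inactivation gate through the factor `0.75 (1 - h)^4`; the T current is
#' `g_t * p_inf(V)^2 * r * (V - e_t)`.
#'
#' @param v,h,r membrane potential (mV) and the two gating variables;
#'   vectors of a common length (scalars recycled).
#' @param params a [tc_params()] object.
#' @return A tibble with columns `i_l`, `i_na`, `i_k`, `i_t` (pA/um^2).
#' @export
ionic_currents <- function(v, h, r, params = tc_params()) {
  stopifnot(inherits(params, "tc_params"))
  n <- max(length(v), length(h), length(r))
  v <- rep_len(as.numeric(v), n); h <- rep_len(as.numeric(h), n)
  r <- rep_len(as.numeric(r), n)
  g <- gating_steady_states(v)
  tibble::tibble(
    i_l = params$g_l * (v - params$e_l),
    i_na = params$g_na * g$m_inf^3 * h * (v - params$e_na),
    i_k = params$g_k * 0.75 * (1 - h)^4 * (v - params$e_k),
    i_t = params$g_t * g$p_inf^2 * r * (v - params$e_t))
}

#' Time derivatives of the TC state
#'
#' Right-hand side of the three model ODEs: the current-balance equation for
#' `V` and first-order relaxation of the gates `h` and `r` toward their
#' steady states (the `r` gate relaxes at 2.5 times its nominal rate).
#' This is the reference R implementation; the integrator uses a compiled
#' equivalent.
#'
#' @inheritParams ionic_currents
#' @param i_sm applied sensorimotor current density at this instant.
#' @return A tibble with columns `dv`, `dh`, `dr` (per ms).
#' @export
tc_derivatives <- function(v, h, r, i_sm = 0, params = tc_params()) {
  cur <- ionic_currents(v, h, r, params)
  g <- gating_steady_states(v)
  tau <- gating_time_constants(v)
  s_gi <- if (params$flip_sign_gi) -1 else 1
  s_sm <- if (params$flip_sign_sm) -1 else 1
  tibble::tibble(
    dv = (-cur$i_l - cur$i_na - cur$i_k - cur$i_t -
            s_gi * params$i_gi - s_sm * i_sm) / params$c_m,
    dh = (g$h_inf - h) / tau$tau_h,
    dr = 2.5 * (g$r_inf - r) / tau$tau_r)
}

#' Simulation configuration
#'
#' @param dt integration step, ms (fixed-step 4th-order Runge-Kutta).
#' @param t_total simulated duration, ms.
#' @param t_discard initial transient excluded from spike-feature analysis, ms.
#' @param v0 initial membrane potential, mV.
#' @param h0,r0 initial gate values; `NULL` starts each gate at its
#'   steady-state value for `v0`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01, t_total = 1000, t_discard = 100,
                       v0 = -65, h0 = NULL, r0 = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (t_discard < 0 || t_discard >= t_total)
    stop("t_discard must satisfy 0 <= t_discard < t_total")
  g <- gating_steady_states(v0)
  structure(list(dt = dt, t_total = t_total, t_discard = t_discard,
                 v0 = v0,
                 h0 = if (is.null(h0)) g$h_inf else h0,
                 r0 = if (is.null(r0)) g$r_inf else r0),
            class = "sim_config")
}

# Fast path used inside the optimizer loop: plain vectors, no tibble overhead.
# `i_sm_half` must be sampled on the half grid (length 2n + 1).
simulate_tc_raw <- function(params, i_sm_half, config) {
  par <- c(params$c_m, params$g_l, params$e_l, params$g_na, params$e_na,
           params$g_k, params$e_k, params$g_t, params$e_t, params$i_gi,
           if (params$flip_sign_gi) -1 else 1,
           if (params$flip_sign_sm) -1 else 1)
  .tc_rk4_cpp(par, i_sm_half, config$dt, config$v0, config$h0, config$r0)
}

#' Simulate the TC relay neuron
#'
#' Integrates the three-variable TC model with a fixed-step classical
#' Runge-Kutta scheme under the given stimulus. The run is fully
#' deterministic given `(params, stimulus, config)`; a Poisson stimulus is
#' realized from its own seed. Integration aborts with an error if the
#' voltage leaves [-200, 200] mV.
#'
#' @param params a [tc_params()] object.
#' @param stimulus a stimulus specification from [stimulus_square()] or
#'   [stimulus_poisson()].
#' @param config a [sim_config()] object.
#' @return A tibble of class `tc_sim` with columns `time` (ms), `v` (mV),
#'   `h`, `r`, `i_sm`, and attributes `params`, `config`, `pulse_onsets`
#'   and `gate_excursion` (TRUE if a gate left [0, 1] by more than 1e-6).
#' @examples
#' sim <- simulate_tc(tc_params(), stimulus_square(),
#'                    sim_config(dt = 0.05, t_total = 200, t_discard = 0))
#' @export
simulate_tc <- function(params, stimulus = stimulus_square(),
                        config = sim_config()) {
  stopifnot(inherits(params, "tc_params"), inherits(config, "sim_config"))
  st <- stimulus_on_grid(stimulus, config)
  out <- simulate_tc_raw(params, st$i_sm_half, config)
  n <- length(out$v)
  res <- tibble::tibble(
    time = seq(0, by = config$dt, length.out = n),
    v = out$v, h = out$h, r = out$r,
    i_sm = st$i_sm_half[seq(1, length(st$i_sm_half), by = 2)])
  attr(res, "params") <- params
  attr(res, "config") <- config
  attr(res, "pulse_onsets") <- st$onsets
  attr(res, "gate_excursion") <- out$gate_excursion
  class(res) <- c("tc_sim", class(res))
  res
}

#' Locate the resting state of the model without applied input
#'
#' Solves the current-balance equation `dV/dt = 0` (with gates at steady
#' state) by root bracketing on a voltage grid; used for equilibrium checks
#' and for choosing initial conditions.
#'
#' @param params a [tc_params()] object.
#' @param interval search interval for the root, mV.
#' @return A one-row tibble with columns `v`, `h`, `r` at the fixed point.
#' @export
tc_rest_state <- function(params = tc_params(), interval = c(-120, 0)) {
  f <- function(v) {
    g <- gating_steady_states(v)
    tc_derivatives(v, g$h_inf, g$r_inf, i_sm = 0, params)$dv
  }
  root <- stats::uniroot(f, interval = interval, tol = 1e-12)$root
  g <- gating_steady_states(root)
  tibble::tibble(v = root, h = g$h_inf, r = g$r_inf)
}

#' Export a simulation to CSV with a JSON metadata sidecar
#'
#' Writes the trace columns (`time_ms`, `v_mv`, `h`, `r`, `i_sm`) to `path`
#' and the parameters, configuration and pulse onsets to `<path>.json`.
#'
#' @param sim a `tc_sim` tibble from [simulate_tc()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tc_sim <- function(sim, path) {
  stopifnot(inherits(sim, "tc_sim"))
  df <- data.frame(time_ms = sim$time, v_mv = sim$v, h = sim$h, r = sim$r,
                   i_sm = sim$i_sm)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(params = unclass(attr(sim, "params")),
               config = unclass(attr(sim, "config")),
               pulse_onsets = attr(sim, "pulse_onsets"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
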