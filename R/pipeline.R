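#' Default evaluation-trial protocol
#'
#' The stimulus trials the feature fitness is summed over: the standard
#' square-wave pulse train plus two fixed-seed Poisson pulse trains. A
#' single aggregate feature vector does not pin down all three key
#' parameters (a larger T conductance can compensate a lower calcium
#' reversal almost exactly under one input), so the default protocol
#' requires the candidate to match the features of three input patterns
#' simultaneously. The Poisson seeds are constants of the protocol: the
#' reference data they define are the same in every fit.
#'
#' @return Named list of `tc_stimulus` specifications.
#' @export
tc_default_trials <- function() {
  list(square = stimulus_square(),
       poisson1 = stimulus_poisson(seed = 101L),
       poisson2 = stimulus_poisson(seed = 202L))
}

#' Build the reference (standard) data set for fitting
#'
#' Simulates the TC model at the given parameters under each evaluation
#' trial and extracts the reference spike features the optimizer will
#' match. This is the "standard data" of the fitting experiment: the model
#' with known key parameters plays the role of the biological recording.
#'
#' @param params a [tc_params()] object holding the given (true) parameters.
#' @param trials a single `tc_stimulus` specification or a (named) list of
#'   them, one per evaluation trial; see [tc_default_trials()].
#' @param config a [sim_config()] object.
#' @param threshold spike detection threshold, mV.
#' @param window relay response window, ms.
#' @return An object of class `tc_reference`: list with the inputs plus
#'   `sims` (one `tc_sim` per trial), `sim` (the first trial's trace) and
#'   `features` (a `tc_features` tibble, one row per trial).
#' @examples
#' ref <- build_reference(tc_params(), stimulus_square(),
#'                        sim_config(dt = 0.05, t_total = 500))
#' ref$features
#' @export
build_reference <- function(params = tc_params(), trials = tc_default_trials(),
                            config = sim_config(), threshold = -25,
                            window = 25) {
  if (inherits(trials, "tc_stimulus")) trials <- list(trials)
  if (is.null(names(trials))) names(trials) <- paste0("trial", seq_along(trials))
  stopifnot(length(trials) >= 1,
            all(vapply(trials, inherits, logical(1), "tc_stimulus")))
  sims <- purrr::map(trials, simulate_tc, params = params, config = config)
  features <- purrr::map(sims, sim_features, threshold = threshold,
                         window = window, warn_truncate = FALSE) |>
    dplyr::bind_rows(.id = "trial")
  class(features) <- c("tc_features", class(features))
  structure(list(params = params, trials = trials, stimulus = trials[[1]],
                 config = config, threshold = threshold, window = window,
                 sims = sims, sim = sims[[1]], features = features),
            class = "tc_reference")
}

#' @export
print.tc_reference <- function(x, ...) {
  cat("<tc_reference> truth triple:",
      sprintf("[%g, %g, %g]\n", x$params$i_gi, x$params$g_t, x$params$e_t))
  print(x$features)
  invisible(x)
}

# Lean feature extraction on plain vectors; the workhorse of the PSO
# objective (same arithmetic as detect_spikes + classify_relay +
# extract_features, minus the tibble plumbing). Returns NULL for a
# degenerate trace with no subthreshold samples.
fast_features <- function(v, dt, t_discard, onsets, win, threshold) {
  i0 <- as.integer(round(t_discard / dt)) + 1L
  vv <- v[i0:length(v)]
  sub <- vv[vv < threshold]
  if (length(sub) == 0) return(NULL)
  above <- vv >= threshold
  n_spk <- 0L; spk_t <- numeric(0); pk <- threshold
  if (any(above)) {
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    s <- starts[runs$values]; e <- ends[runs$values]
    apex <- integer(length(s))
    for (j in seq_along(s)) apex[j] <- s[j] + which.max(vv[s[j]:e[j]]) - 1L
    n_spk <- length(apex)
    spk_t <- (i0 - 1L + apex - 1L) * dt
    pk <- mean(vv[apex])
  }
  idx <- findInterval(spk_t, onsets)
  inwin <- idx >= 1L & spk_t < onsets[pmax(idx, 1L)] + win[pmax(idx, 1L)]
  counts <- tabulate(idx[inwin], nbins = length(onsets))
  err <- (sum(counts == 0L) + sum(counts >= 2L)) / length(onsets)
  list(ri = 1 - err, n = n_spk, pk = pk, st = mean(sub))
}

#' Objective function for key-parameter fitting
#'
#' Returns a closure mapping a key triple `c(i_gi, g_t, e_t)` to the
#' four-feature fitness against the reference: the candidate model is
#' simulated under every reference trial, its features extracted, and the
#' weighted squared feature differences summed over features and trials.
#' Divergent or degenerate candidates get `+Inf` (the optimizer rejects
#' them).
#'
#' @param reference a `tc_reference` from [build_reference()].
#' @param weights a [fitness_weights()] object; the default scales each term
#'   by the reference feature magnitude via
#'   [fitness_weights_from_reference()].
#' @return A function `numeric(3) -> scalar fitness`.
#' @export
tc_objective <- function(reference,
                         weights = fitness_weights_from_reference(reference$features)) {
  stopifnot(inherits(reference, "tc_reference"),
            inherits(weights, "fitness_weights"))
  cfg <- reference$config
  prep <- purrr::map(reference$trials, function(spec) {
    st <- stimulus_on_grid(spec, cfg)
    onsets <- st$onsets
    onsets <- onsets[onsets >= cfg$t_discard & onsets + 1e-9 < cfg$t_total]
    gaps <- diff(onsets)
    list(i_sm_half = st$i_sm_half, onsets = onsets,
         win = pmin(reference$window, c(gaps, reference$window)))
  })
  ref_rows <- purrr::transpose(reference$features[c("ri", "n", "pk", "st")])
  base <- reference$params
  thr <- reference$threshold
  force(weights)
  function(key) {
    p <- set_key_params(base, key)
    q <- 0
    for (j in seq_along(prep)) {
      out <- tryCatch(simulate_tc_raw(p, prep[[j]]$i_sm_half, cfg),
                      error = function(e) NULL)
      if (is.null(out)) return(Inf)
      f <- fast_features(out$v, cfg$dt, cfg$t_discard, prep[[j]]$onsets,
                         prep[[j]]$win, thr)
      if (is.null(f)) return(Inf)
      r <- ref_rows[[j]]
      q <- q + weights$w_ri * (f$ri - r$ri)^2 + weights$w_n * (f$n - r$n)^2 +
        weights$w_pk * (f$pk - r$pk)^2 + weights$w_st * (f$st - r$st)^2
    }
    q
  }
}

#' Fit the three key parameters of the TC model
#'
#' Runs the particle swarm optimizer on the feature-matching objective and
#' records the squared parameter error against the reference truth.
#'
#' @param reference a `tc_reference` from [build_reference()].
#' @param scheme inertia scheme tag (see [swarm_config()]).
#' @param seed integer seed for this fit.
#' @param weights a [fitness_weights()] object (default: scale-matched to
#'   the reference).
#' @param lo,hi search bounds for `c(i_gi, g_t, e_t)`; the defaults bracket
#'   both relay regimes.
#' @param n,k_max,q_stop swarm size, iteration cap, stopping fitness.
#' @param ... further arguments passed to [swarm_config()].
#' @return A `tc_fit` object (see [run_pso()]); `best_x` is the fitted
#'   `c(i_gi, g_t, e_t)` and `ln_e_t` the log squared parameter error.
#' @export
fit_key_parameters <- function(reference, scheme = "improved", seed = 1L,
                               weights = fitness_weights_from_reference(reference$features),
                               lo = c(-10, 0, 90), hi = c(0, 10, 140),
                               n = 30, k_max = 50, q_stop = 1e-8, ...) {
  obj <- tc_objective(reference, weights)
  cfg <- swarm_config(lo = lo, hi = hi, n = n, k_max = k_max,
                      q_stop = q_stop, scheme = scheme, seed = seed, ...)
  truth <- c(reference$params$i_gi, reference$params$g_t, reference$params$e_t)
  fit <- run_pso(obj, cfg, truth = truth)
  names(fit$best_x) <- c("i_gi", "g_t", "e_t")
  fit
}

#' Reconstruct the fitted model and compare spiking against the original
#'
#' Re-simulates the TC model with the fitted key triple alongside the
#' original (given-parameter) model under both the square-wave and the
#' Poisson pulse input, and tabulates the four spike features of every
#' trace. When a normal-state key triple (and optionally a fit of it) is
#' supplied, the same comparison is run at the normal operating point.
#'
#' @param reference a `tc_reference` (the Parkinsonian operating point).
#' @param fit a `tc_fit` from [fit_key_parameters()], or a numeric key triple.
#' @param normal_key optional key triple of the normally relaying operating
#'   point ([tc_normal_key()] by default); `NULL` skips the normal point.
#' @param normal_fit optional `tc_fit` (or triple) for the normal point.
#' @param poisson a [stimulus_poisson()] specification for the second input.
#' @return A tibble of class `tc_overlay`: one row per (operating point,
#'   input kind, model) with the feature columns and the relay state label;
#'   the simulated traces are attached as attribute `traces` (named list).
#' @export
reconstruct_and_compare <- function(reference, fit,
                                    normal_key = tc_normal_key(),
                                    normal_fit = NULL,
                                    poisson = stimulus_poisson()) {
  stopifnot(inherits(reference, "tc_reference"))
  key_of <- function(f) if (inherits(f, "tc_fit")) f$best_x else as.numeric(f)
  cfg <- reference$config
  inputs <- list(square = reference$stimulus, poisson = poisson)

  points <- list(parkinsonian = list(
    original = reference$params,
    reconstructed = set_key_params(reference$params, key_of(fit))))
  if (!is.null(normal_key)) {
    np <- list(original = set_key_params(reference$params, as.numeric(normal_key)))
    if (!is.null(normal_fit))
      np$reconstructed <- set_key_params(reference$params, key_of(normal_fit))
    points$normal <- np
  }

  traces <- list()
  rows <- list()
  for (pt in names(points)) {
    for (inp in names(inputs)) {
      for (mod in names(points[[pt]])) {
        sim <- simulate_tc(points[[pt]][[mod]], inputs[[inp]], cfg)
        f <- sim_features(sim, threshold = reference$threshold,
                          window = reference$window, warn_truncate = FALSE)
        traces[[paste(pt, inp, mod, sep = ".")]] <- sim
        rows[[length(rows) + 1L]] <- tibble::tibble(
          operating_point = pt, input = inp, model = mod,
          ri = f$ri, n = f$n, pk = f$pk, st = f$st,
          state = classify_state(f$ri))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  # feature deltas: reconstructed minus original, where both exist
  deltas <- out |>
    tidyr::pivot_wider(id_cols = c("operating_point", "input"),
                       names_from = "model",
                       values_from = c("ri", "n", "pk", "st")) |>
    dplyr::filter(!is.na(.data$ri_reconstructed)) |>
    dplyr::transmute(.data$operating_point, .data$input,
                     d_ri = .data$ri_reconstructed - .data$ri_original,
                     d_n = .data$n_reconstructed - .data$n_original,
                     d_pk = .data$pk_reconstructed - .data$pk_original,
                     d_st = .data$st_reconstructed - .data$st_original)
  attr(out, "deltas") <- deltas
  attr(out, "traces") <- traces
  class(out) <- c("tc_overlay", class(out))
  out
}

#' Default normally relaying key triple
#'
#' A key-parameter triple `c(i_gi, g_t, e_t)` at which the model relays the
#' standard square-wave input with `RI > 0.9` (the normal state): weaker
#' pallidal inhibition and a smaller T-current conductance than the
#' Parkinsonian reference, with the calcium reversal unchanged.
#'
#' @return Named numeric 3-vector.
#' @export
tc_normal_key <- function() c(i_gi = -1, g_t = 0.6, e_t = 120)

#' Compare the five inertia schemes on the fitting problem
#'
#' Runs [fit_key_parameters()] for every scheme and every seed and tabulates
#' the fitted triples, final fitness, squared parameter error (log scale)
#' and iteration counts. PSO outcomes are stochastic, so the comparison is
#' run over replicate seeds and summarized by medians.
#'
#' @param reference a `tc_reference`.
#' @param schemes character vector of scheme tags.
#' @param seeds integer vector of seeds (one fit per scheme x seed).
#' @param ... passed on to [fit_key_parameters()] (bounds, swarm size, ...).
#' @return A tibble of class `tc_comparison`: columns `scheme`, `seed`,
#'   `i_gi_hat`, `g_t_hat`, `e_t_hat`, `best_q`, `err`, `ln_err`,
#'   `iterations`, `termination`; fitness histories attached as attribute
#'   `curves` (tibble with `scheme`, `seed`, `k`, `gbest_q`).
#' @export
run_comparison <- function(reference,
                           schemes = c("improved", "constant", "linear",
                                       "concave1", "concave2"),
                           seeds = 1:5, ...) {
  stopifnot(inherits(reference, "tc_reference"), length(schemes) > 0)
  grid <- tidyr::expand_grid(scheme = schemes, seed = as.integer(seeds))
  fits <- purrr::pmap(grid, function(scheme, seed) {
    fit_key_parameters(reference, scheme = scheme, seed = seed, ...)
  })
  rows <- purrr::map2(fits, seq_len(nrow(grid)), function(f, i) {
    tibble::tibble(scheme = grid$scheme[i], seed = grid$seed[i],
                   i_gi_hat = f$best_x[[1]], g_t_hat = f$best_x[[2]],
                   e_t_hat = f$best_x[[3]], best_q = f$best_q,
                   err = f$e_t, ln_err = f$ln_e_t,
                   iterations = f$iterations_used,
                   termination = f$termination)
  })
  out <- dplyr::bind_rows(rows)
  curves <- purrr::map2(fits, seq_len(nrow(grid)), function(f, i) {
    tibble::tibble(scheme = grid$scheme[i], seed = grid$seed[i],
                   k = f$history$k, gbest_q = f$history$gbest_q)
  }) |> dplyr::bind_rows()
  attr(out, "curves") <- curves
  class(out) <- c("tc_comparison", class(out))
  out
}

#' Summarize a scheme comparison
#'
#' @param comparison a `tc_comparison` tibble from [run_comparison()].
#' @return A tibble with one row per scheme: median and spread of the log
#'   parameter error, median final fitness and iteration count, ordered
#'   best first.
#' @export
comparison_summary <- function(comparison) {
  stopifnot(inherits(comparison, "tc_comparison"))
  comparison |>
    dplyr::group_by(.data$scheme) |>
    dplyr::summarise(n_fits = dplyr::n(),
                     median_ln_err = stats::median(.data$ln_err),
                     iqr_ln_err = stats::IQR(.data$ln_err),
                     median_q = stats::median(.data$best_q),
                     median_iterations = stats::median(.data$iterations)) |>
    dplyr::arrange(.data$median_ln_err)
}
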