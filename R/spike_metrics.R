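#' Detect spikes in a voltage trace
#'
#' One spike per maximal contiguous excursion at or above the threshold; the
#' spike time and peak are taken at the sample where the excursion attains
#' its maximum voltage. Samples before `t_min` (by default the configured
#' transient `t_discard` of the simulation) are ignored.
#'
#' @param sim a `tc_sim` tibble from [simulate_tc()], or any data frame with
#'   `time` and `v` columns.
#' @param threshold spike detection threshold, mV.
#' @param t_min analyze only samples with `time >= t_min`; defaults to the
#'   simulation's `t_discard` when available, else 0.
#' @return A tibble of class `tc_spikes` with columns `time` and `peak`
#'   (strictly increasing times), possibly empty.
#' @export
detect_spikes <- function(sim, threshold = -25, t_min = NULL) {
  stopifnot(is.data.frame(sim), all(c("time", "v") %in% names(sim)))
  if (is.null(t_min)) {
    cfg <- attr(sim, "config")
    t_min <- if (!is.null(cfg)) cfg$t_discard else 0
  }
  keep <- sim$time >= t_min
  tt <- sim$time[keep]; vv <- sim$v[keep]
  if (length(vv) == 0) stop("no samples at or after t_min")
  above <- vv >= threshold
  res <- tibble::tibble(time = numeric(0), peak = numeric(0))
  if (any(above)) {
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    s <- starts[runs$values]; e <- ends[runs$values]
    apex <- purrr::map2_int(s, e, function(a, b) a + which.max(vv[a:b]) - 1L)
    res <- tibble::tibble(time = tt[apex], peak = vv[apex])
  }
  attr(res, "threshold") <- threshold
  class(res) <- c("tc_spikes", class(res))
  res
}

#' Score relay reliability of a spike train against input pulses
#'
#' Each input pulse opens a response window starting at its onset; a pulse
#' answered by exactly one spike is a correct relay, a pulse with no spike in
#' its window is a *missed* input and a pulse with two or more spikes is a
#' *bad* relay. Each input contributes at most one error. The error index is
#' `(missed + bad) / total_inputs` and the reliability index is
#' `RI = 1 - error index`.
#'
#' Windows are truncated at the next onset so they never overlap (a warning
#' is raised when the nominal `window` exceeds the smallest gap). With
#' `strict = TRUE`, spikes falling outside every window also count as bad
#' relays of their nearest preceding input.
#'
#' @param spikes a `tc_spikes` tibble from [detect_spikes()] (or a data frame
#'   with a `time` column).
#' @param onsets strictly increasing pulse onset times, ms; nonempty.
#' @param window nominal response-window length, ms; defaults to the
#'   square-wave period of 25 ms.
#' @param strict also flag orphan spikes between windows as bad inputs.
#' @param warn_truncate warn when the nominal window is truncated; internal
#'   callers that truncate by design silence this.
#' @return A one-row tibble of class `tc_relay` with columns `total_inputs`,
#'   `missed`, `bad`, `error_index`, `ri`.
#' @examples
#' classify_relay(tibble::tibble(time = c(10, 35, 60)), c(7, 32, 57), 25)
#' @export
classify_relay <- function(spikes, onsets, window = 25, strict = FALSE,
                           warn_truncate = TRUE) {
  stopifnot(is.data.frame(spikes), "time" %in% names(spikes))
  if (length(onsets) == 0) stop("onsets must be nonempty")
  if (is.unsorted(onsets, strictly = TRUE)) stop("onsets must be strictly increasing")
  if (window <= 0) stop("window must be positive")
  gaps <- diff(onsets)
  if (warn_truncate && length(gaps) && window > min(gaps))
    warning("window exceeds the smallest onset gap; windows truncated at the next onset")
  win <- pmin(window, c(gaps, window))
  st <- spikes$time
  idx <- findInterval(st, onsets)              # window of the preceding onset
  inwin <- idx >= 1L & st < onsets[pmax(idx, 1L)] + win[pmax(idx, 1L)]
  counts <- tabulate(idx[inwin], nbins = length(onsets))
  missed <- sum(counts == 0L)
  bad <- sum(counts >= 2L)
  if (strict) {
    orphan_owner <- unique(idx[!inwin & idx >= 1L])
    bad <- bad + sum(counts[orphan_owner] == 1L)   # singleton owners spoiled
    missed <- missed - sum(counts[orphan_owner] == 0L) # cannot be both
    bad <- bad + sum(counts[orphan_owner] == 0L)
  }
  total <- length(onsets)
  err <- (missed + bad) / total
  res <- tibble::tibble(total_inputs = total, missed = missed, bad = bad,
                        error_index = err, ri = 1 - err)
  class(res) <- c("tc_relay", class(res))
  res
}

#' Classify the relay regime from the reliability index
#'
#' The model is regarded as relaying normally when `RI > 0.9` and as
#' Parkinsonian when `RI < 0.5`; between the two there is no sharp boundary.
#'
#' @param ri reliability index in \[0, 1\] (vectorized).
#' @return Character vector in `{"normal", "parkinsonian", "indeterminate"}`.
#' @export
classify_state <- function(ri) {
  if (!is.numeric(ri) || any(!is.finite(ri)) || any(ri < 0 | ri > 1))
    stop("ri must lie in [0, 1]")
  dplyr::case_when(ri > 0.9 ~ "normal",
                   ri < 0.5 ~ "parkinsonian",
                   TRUE ~ "indeterminate")
}

#' Extract the four spike-train features entering the fitness
#'
#' Relay reliability `ri`, spike count `n`, mean spike peak `pk` (mV) and
#' mean subthreshold voltage `st` (mV; mean over samples strictly below the
#' detection threshold, after the discard transient). For a spikeless trace
#' `pk` falls back to the detection threshold so the fitness stays defined
#' during optimizer exploration.
#'
#' @param sim a `tc_sim` tibble.
#' @param spikes a `tc_spikes` tibble from [detect_spikes()] on `sim`.
#' @param relay a `tc_relay` row from [classify_relay()].
#' @param threshold detection threshold used for `spikes`, mV.
#' @param t_min see [detect_spikes()].
#' @return A one-row tibble of class `tc_features` with columns `ri`, `n`,
#'   `pk`, `st`.
#' @export
extract_features <- function(sim, spikes, relay, threshold = -25, t_min = NULL) {
  stopifnot(is.data.frame(sim), inherits(relay, "tc_relay"))
  if (is.null(t_min)) {
    cfg <- attr(sim, "config")
    t_min <- if (!is.null(cfg)) cfg$t_discard else 0
  }
  vv <- sim$v[sim$time >= t_min]
  sub <- vv[vv < threshold]
  if (length(sub) == 0)
    stop("degenerate trace: no subthreshold samples below the threshold")
  n <- nrow(spikes)
  res <- tibble::tibble(
    ri = relay$ri,
    n = n,
    pk = if (n > 0) mean(spikes$peak) else threshold,
    st = mean(sub))
  class(res) <- c("tc_features", class(res))
  res
}

#' Fitness weights for the four-feature objective
#'
#' @param w_ri,w_n,w_pk,w_st nonnegative weights on the squared differences
#'   in reliability, spike count, mean peak and mean subthreshold voltage.
#' @return An object of class `fitness_weights`.
#' @export
fitness_weights <- function(w_ri = 1, w_n = 1, w_pk = 1, w_st = 1) {
  w <- c(w_ri = w_ri, w_n = w_n, w_pk = w_pk, w_st = w_st)
  if (any(w < 0) || all(w == 0)) stop("weights must be nonnegative, not all zero")
  structure(as.list(w), class = "fitness_weights")
}

#' Scale-matched fitness weights from reference features
#'
#' Sets each weight to `1 / scale^2` with the scale taken from the reference
#' feature (floored at 1), so all four terms are O(1) at initialization:
#' reliability lives in \[0, 1\] while spike counts and voltages are tens of
#' units, and raw unit weights would let a single term dominate.
#'
#' @param ref a `tc_features` row for the reference (standard) data.
#' @return A [fitness_weights()] object.
#' @export
fitness_weights_from_reference <- function(ref) {
  stopifnot(inherits(ref, "tc_features"))
  ref <- ref[1, ]   # scales from the first (square-wave) trial
  fitness_weights(w_ri = 1,
                  w_n = 1 / max(abs(ref$n), 1)^2,
                  w_pk = 1 / max(abs(ref$pk), 1)^2,
                  w_st = 1 / max(abs(ref$st), 1)^2)
}

#' Spike-feature fitness between reconstructed and original models
#'
#' Weighted sum of squared feature differences,
#' `q = w_ri sum (RI_rec - RI_ori)^2 + w_n sum (N_rec - N_ori)^2 +
#'  w_pk sum (PK_rec - PK_ori)^2 + w_st sum (ST_rec - ST_ori)^2`,
#' summed over evaluation trials (the rows of the feature tables). Zero iff
#' the feature tables agree exactly on every positively weighted feature.
#'
#' @param rec,ori `tc_features` tibbles with matching row counts (one row per
#'   stimulus trial).
#' @param w a [fitness_weights()] object.
#' @return Nonnegative scalar fitness.
#' @export
spike_fitness <- function(rec, ori, w = fitness_weights()) {
  stopifnot(is.data.frame(rec), is.data.frame(ori),
            inherits(w, "fitness_weights"))
  if (nrow(rec) != nrow(ori) || nrow(rec) == 0)
    stop("rec and ori must have the same positive number of trials")
  w$w_ri * sum((rec$ri - ori$ri)^2) +
    w$w_n * sum((rec$n - ori$n)^2) +
    w$w_pk * sum((rec$pk - ori$pk)^2) +
    w$w_st * sum((rec$st - ori$st)^2)
}

#' Squared parameter error of a fitted key triple
#'
#' `e = (i_gi_fit - i_gi)^2 + (g_t_fit - g_t)^2 + (e_t_fit - e_t)^2`, the sum
#' of squared componentwise differences between the fitted and given values
#' of the three key parameters (ordered `i_gi`, `g_t`, `e_t`). Usually
#' reported on the natural-log scale.
#'
#' @param fitted,given numeric 3-vectors `c(i_gi, g_t, e_t)`.
#' @return Nonnegative scalar; zero iff the triples are equal.
#' @examples
#' log(parameter_error(c(-3.4991, 3.0215, 119.6532), c(-3.5, 3, 120)))
#' @export
parameter_error <- function(fitted, given) {
  stopifnot(is.numeric(fitted), is.numeric(given),
            length(fitted) == 3, length(given) == 3)
  sum((fitted - given)^2)
}

#' Run the whole feature pipeline on one simulation
#'
#' Convenience wrapper: spike detection, relay scoring against the
#' simulation's recorded pulse onsets (restricted to the analysis window)
#' and feature extraction.
#'
#' @param sim a `tc_sim` tibble carrying `pulse_onsets`.
#' @param threshold spike detection threshold, mV.
#' @param window relay response window, ms.
#' @param warn_truncate see [classify_relay()].
#' @return A one-row `tc_features` tibble; the `tc_relay` row and the spike
#'   train are attached as attributes `relay` and `spikes`.
#' @export
sim_features <- function(sim, threshold = -25, window = 25,
                         warn_truncate = TRUE) {
  cfg <- attr(sim, "config")
  onsets <- attr(sim, "pulse_onsets")
  if (is.null(onsets)) stop("sim carries no pulse_onsets attribute")
  onsets <- onsets[onsets >= cfg$t_discard & onsets + 1e-9 < cfg$t_total]
  spikes <- detect_spikes(sim, threshold = threshold)
  relay <- classify_relay(spikes, onsets, window = window,
                          warn_truncate = warn_truncate)
  feats <- extract_features(sim, spikes, relay, threshold = threshold)
  attr(feats, "relay") <- relay
  attr(feats, "spikes") <- spikes
  feats
}
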