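#' One step of the Logistic chaotic map
#'
#' `L <- r * L * (1 - L)`. At `r = 4` the map is fully chaotic on \[0, 1\]
#' and supplies the non-deterministic component of the chaotic inertia
#' schedule.
#'
#' @param l current map value in \[0, 1\].
#' @param r map parameter (0, 4\]; the default 4 is the fully chaotic regime.
#' @return The next map value; stays in \[0, 1\] for `r <= 4`.
#' @examples
#' logistic_step(0.5)        # map maximum: 1
#' logistic_step(0.3, r = 4)
#' @export
logistic_step <- function(l, r = 4) {
  if (!is.numeric(l) || any(!is.finite(l)) || any(l < 0 | l > 1))
    stop("l must lie in [0, 1]")
  r * l * (1 - l)
}

#' Inertia-weight schedules
#'
#' The five inertia rules compared by the optimizer. All schedules map the
#' iteration counter `k in [0, k_max]` to a weight:
#' * `inertia_constant()`: the classical fixed weight (default 0.7);
#' * `inertia_linear()`: linear descent from `omega_max` to `omega_min`;
#' * `inertia_concave1()`: the nonlinear concave schedule
#'   `omega_min * (omega_max/omega_min)^(1 / (1 + 10 k/k_max))` — steep early
#'   (global search), flat late (fine search);
#' * `inertia_concave2()`: the quadratic concave schedule
#'   `(omega_max - omega_min) (k/k_max)^2 + 2 (omega_min - omega_max) (k/k_max) + omega_max`;
#' * `inertia_chaotic()`: `alpha + (1 - alpha) L` with the adjustment factor
#'   `alpha = alpha_max - (alpha_max - alpha_min) k/k_max` and `L` the current
#'   Logistic map value, so the weight is random-like in `[alpha, 1]`.
#'
#' @param k current iteration, `0 <= k <= k_max`.
#' @param k_max maximum iteration count (>= 1).
#' @param omega_min,omega_max inertia bounds, `0 < omega_min < omega_max`.
#' @param alpha_min,alpha_max bounds of the chaotic adjustment factor in \[0, 1\].
#' @param l current Logistic map value in \[0, 1\].
#' @param omega the constant weight.
#' @return The inertia weight (scalar or vectorized over `k`).
#' @name inertia
NULL

check_schedule_args <- function(k, k_max, omega_min, omega_max) {
  if (k_max < 1) stop("k_max must be at least 1")
  if (any(k < 0 | k > k_max)) stop("k must lie in [0, k_max]")
  if (!(omega_min > 0 && omega_min < omega_max))
    stop("need 0 < omega_min < omega_max")
}

#' @rdname inertia
#' @export
inertia_constant <- function(omega = 0.7) omega

#' @rdname inertia
#' @export
inertia_linear <- function(k, k_max, omega_min = 0.4, omega_max = 0.9) {
  check_schedule_args(k, k_max, omega_min, omega_max)
  omega_max - (omega_max - omega_min) * (k / k_max)
}

#' @rdname inertia
#' @export
inertia_concave1 <- function(k, k_max, omega_min = 0.4, omega_max = 0.9) {
  check_schedule_args(k, k_max, omega_min, omega_max)
  omega_min * (omega_max / omega_min)^(1 / (1 + 10 * k / k_max))
}

#' @rdname inertia
#' @export
inertia_concave2 <- function(k, k_max, omega_min = 0.4, omega_max = 0.9) {
  check_schedule_args(k, k_max, omega_min, omega_max)
  u <- k / k_max
  (omega_max - omega_min) * u^2 + 2 * (omega_min - omega_max) * u + omega_max
}

#' @rdname inertia
#' @export
inertia_chaotic <- function(k, k_max, alpha_min = 0.2, alpha_max = 0.8, l) {
  if (k_max < 1) stop("k_max must be at least 1")
  if (!(alpha_min >= 0 && alpha_min <= alpha_max && alpha_max <= 1))
    stop("need 0 <= alpha_min <= alpha_max <= 1")
  if (any(l < 0 | l > 1)) stop("l must lie in [0, 1]")
  alpha <- alpha_max - (alpha_max - alpha_min) * (k / k_max)
  alpha + (1 - alpha) * l
}

#' Swarm configuration
#'
#' @param lo,hi numeric vectors of per-dimension position bounds
#'   (`lo < hi` elementwise); their length sets the search dimension.
#' @param n swarm size (>= 2).
#' @param v_max per-dimension speed cap; default 0.2 of the box width.
#' @param c1,c2 cognitive and social acceleration factors (classically 2).
#' @param omega_min,omega_max inertia bounds for the scheduled rules.
#' @param alpha_min,alpha_max chaotic adjustment-factor bounds.
#' @param omega_const weight used by the constant scheme.
#' @param k_max maximum iteration count.
#' @param q_stop terminate once the global best fitness drops below this.
#' @param scheme one of `"improved"`, `"constant"`, `"linear"`, `"concave1"`,
#'   `"concave2"`. The improved rule switches per particle between the
#'   concave schedule (fitness better than the swarm mean) and the chaotic
#'   rule (worse than the mean).
#' @param logistic_r Logistic map parameter.
#' @param seed integer seed; the full run is a deterministic function of it.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(lo, hi, n = 30, v_max = NULL, c1 = 2, c2 = 2,
                         omega_min = 0.4, omega_max = 0.9,
                         alpha_min = 0.2, alpha_max = 0.8,
                         omega_const = 0.7, k_max = 50, q_stop = 1e-8,
                         scheme = c("improved", "constant", "linear",
                                    "concave1", "concave2"),
                         logistic_r = 4, seed = 1L) {
  scheme <- match.arg(scheme)
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (length(lo) != length(hi) || length(lo) == 0 || any(lo >= hi))
    stop("lo and hi must be equal-length vectors with lo < hi")
  if (n < 2) stop("swarm size n must be at least 2")
  if (k_max < 1) stop("k_max must be at least 1")
  if (!(omega_min > 0 && omega_min < omega_max))
    stop("need 0 < omega_min < omega_max")
  if (!(alpha_min >= 0 && alpha_min <= alpha_max && alpha_max <= 1))
    stop("need 0 <= alpha_min <= alpha_max <= 1")
  if (is.null(v_max)) v_max <- 0.2 * (hi - lo)
  v_max <- rep_len(as.numeric(v_max), length(lo))
  if (any(v_max <= 0)) stop("v_max must be positive")
  structure(list(lo = lo, hi = hi, d = length(lo), n = as.integer(n),
                 v_max = v_max, c1 = c1, c2 = c2,
                 omega_min = omega_min, omega_max = omega_max,
                 alpha_min = alpha_min, alpha_max = alpha_max,
                 omega_const = omega_const, k_max = as.integer(k_max),
                 q_stop = q_stop, scheme = scheme, logistic_r = logistic_r,
                 seed = as.integer(seed)),
            class = "swarm_config")
}

# Draw the initial Logistic map value, avoiding the fixed/periodic points
# {0, 0.25, 0.5, 0.75, 1} of the r = 4 map.
draw_logistic_seed <- function() {
  repeat {
    l <- stats::runif(1)
    if (min(abs(l - c(0, 0.25, 0.5, 0.75, 1))) > 0.01) return(l)
  }
}

#' Run the particle swarm optimizer
#'
#' Minimizes `objective` over the box `[cfg$lo, cfg$hi]`. Positions are
#' initialized uniformly in the box and velocities uniformly within the speed
#' cap. Each iteration evaluates every particle once, updates the personal
#' and global bests, then moves the swarm with the velocity rule
#' `v <- omega v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with fresh
#' `r1, r2 ~ U(0, 1)` per particle and per update; speeds are clamped
#' componentwise to `v_max` and positions to the box (the velocity component
#' is zeroed on a clamped dimension). Under the improved scheme a particle
#' whose fitness is at or below the swarm average gets the concave inertia
#' schedule, a worse-than-average particle gets the chaotic weight, with the
#' swarm-global Logistic map advanced once per chaotic draw. Iteration stops
#' at `k_max` or as soon as the global best fitness drops below `q_stop`.
#' Non-finite objective values are treated as `+Inf` (rejected) and counted.
#'
#' @param objective function mapping a length-`d` numeric position to a
#'   scalar fitness (lower is better); deterministic for a fixed position.
#' @param cfg a [swarm_config()] object.
#' @param truth optional true parameter vector; when supplied the squared
#'   parameter error of the final best position is recorded.
#' @param init_positions optional `n x d` matrix of starting positions
#'   (overrides the uniform draw; velocities still drawn).
#' @return An object of class `tc_fit`: a list with `best_x`, `best_q`,
#'   `history` (one row per iteration: `k`, `q_avg`, `gbest_q`, branch
#'   counts and the global-best position), `iterations_used`, `termination`
#'   (`"threshold"` or `"max_iter"`), `scheme`, `e_t`/`ln_e_t` (when `truth`
#'   given), `n_nonfinite` and the `cfg` used.
#' @examples
#' cfg <- swarm_config(lo = rep(-5, 3), hi = rep(5, 3), k_max = 40, seed = 7)
#' fit <- run_pso(function(x) sum(x^2), cfg)
#' glance(fit)
#' @export
run_pso <- function(objective, cfg, truth = NULL, init_positions = NULL) {
  stopifnot(inherits(cfg, "swarm_config"), is.function(objective))
  d <- cfg$d; n <- cfg$n
  withr::with_seed(cfg$seed, {
    if (is.null(init_positions)) {
      x <- matrix(stats::runif(n * d, rep(cfg$lo, each = n),
                               rep(cfg$hi, each = n)), n, d)
    } else {
      x <- matrix(as.numeric(init_positions), n, d)
    }
    v <- matrix(stats::runif(n * d, rep(-cfg$v_max, each = n),
                             rep(cfg$v_max, each = n)), n, d)
    l_map <- draw_logistic_seed()

    pbest_x <- x
    pbest_q <- rep(Inf, n)
    gbest_x <- x[1, ]
    gbest_q <- Inf
    n_nonfinite <- 0L
    hist <- vector("list", cfg$k_max)
    termination <- "max_iter"
    iterations_used <- cfg$k_max

    for (k in seq_len(cfg$k_max)) {
      q <- vapply(seq_len(n), function(i) {
        qi <- objective(x[i, ])
        if (!is.finite(qi)) { n_nonfinite <<- n_nonfinite + 1L; Inf } else qi
      }, numeric(1))

      improved <- q < pbest_q
      pbest_q[improved] <- q[improved]
      pbest_x[improved, ] <- x[improved, , drop = FALSE]
      b <- which.min(pbest_q)
      gbest_q <- pbest_q[b]
      gbest_x <- pbest_x[b, ]

      q_avg <- if (any(is.finite(q))) mean(q[is.finite(q)]) else Inf

      # inertia weight per particle
      if (cfg$scheme == "improved") {
        fast <- q <= q_avg      # ties take the concave (exploitation) branch
        omega <- numeric(n)
        omega[fast] <- inertia_concave1(k, cfg$k_max, cfg$omega_min, cfg$omega_max)
        for (i in which(!fast)) {
          l_map <- logistic_step(l_map, cfg$logistic_r)
          omega[i] <- inertia_chaotic(k, cfg$k_max, cfg$alpha_min,
                                      cfg$alpha_max, l_map)
        }
        n_concave <- sum(fast); n_chaotic <- n - n_concave
      } else {
        omega <- rep(switch(cfg$scheme,
          constant = inertia_constant(cfg$omega_const),
          linear = inertia_linear(k, cfg$k_max, cfg$omega_min, cfg$omega_max),
          concave1 = inertia_concave1(k, cfg$k_max, cfg$omega_min, cfg$omega_max),
          concave2 = inertia_concave2(k, cfg$k_max, cfg$omega_min, cfg$omega_max)), n)
        n_concave <- NA_integer_; n_chaotic <- NA_integer_
      }

      hist[[k]] <- c(k = k, q_avg = q_avg, gbest_q = gbest_q,
                     n_concave = n_concave, n_chaotic = n_chaotic,
                     stats::setNames(gbest_x, paste0("x", seq_len(d))))

      if (gbest_q < cfg$q_stop) {
        termination <- "threshold"
        iterations_used <- k
        break
      }

      # r1, r2 are scalar per particle and update (shared across dimensions)
      r1 <- matrix(stats::runif(n), n, d)
      r2 <- matrix(stats::runif(n), n, d)
      gb_m <- matrix(gbest_x, n, d, byrow = TRUE)
      v <- omega * v + cfg$c1 * r1 * (pbest_x - x) + cfg$c2 * r2 * (gb_m - x)
      vcap <- matrix(cfg$v_max, n, d, byrow = TRUE)
      v <- pmin(pmax(v, -vcap), vcap)
      x <- x + v
      lo_m <- matrix(cfg$lo, n, d, byrow = TRUE)
      hi_m <- matrix(cfg$hi, n, d, byrow = TRUE)
      clamped <- x < lo_m | x > hi_m
      x <- pmin(pmax(x, lo_m), hi_m)
      v[clamped] <- 0
    }

    history <- tibble::as_tibble(do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
    res <- list(best_x = gbest_x, best_q = gbest_q, history = history,
                iterations_used = iterations_used, termination = termination,
                scheme = cfg$scheme, n_nonfinite = n_nonfinite, cfg = cfg)
    if (!is.null(truth)) {
      res$e_t <- sum((gbest_x - truth)^2)
      res$ln_e_t <- log(res$e_t)
      res$truth <- truth
    }
    structure(res, class = "tc_fit")
  })
}

#' @export
print.tc_fit <- function(x, ...) {
  cat("<tc_fit>", x$scheme, "scheme\n")
  cat(sprintf("  best_x: [%s]\n", paste(signif(x$best_x, 6), collapse = ", ")))
  cat(sprintf("  best_q: %.6g after %d iterations (%s)\n",
              x$best_q, x$iterations_used, x$termination))
  if (!is.null(x$ln_e_t))
    cat(sprintf("  ln e_T: %.4f against the supplied truth\n", x$ln_e_t))
  invisible(x)
}

#' Export a fit history as CSV
#'
#' Writes the per-iteration record (`k`, `q_avg`, `gbest_q`, branch counts,
#' global-best position) for trajectory and convergence plots.
#'
#' @param fit a `tc_fit` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tc_fit <- function(fit, path) {
  stopifnot(inherits(fit, "tc_fit"))
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
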