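#' Simulation and estimation protocol
#'
#' Exact stochastic simulation (Gillespie) of the capped-lattice process,
#' the burn-in/censoring protocol for sampling extinction times from
#' approximate quasistationarity, the censored-exponential maximum
#' likelihood estimator of the mean time to extinction, and the empirical
#' (occupation-time) quasistationary distribution.
#'
#' @name simulate
NULL

#' Simulation protocol specification
#'
#' Runs start at `x0` (default: the ceiling of `N * ystar`), are discarded
#' and re-run if extinct before the end of the burn-in `t0`, and are
#' right-censored at `t_max`.
#'
#' @param n_runs number of retained runs.
#' @param t0 burn-in time.
#' @param t_max censoring horizon (total simulated time per run).
#' @param x0 optional starting state; default ceiling of `N * ystar`.
#' @param seed integer seed.
#' @param max_attempts restart budget, as a multiple of `n_runs`.
#' @return an object of class `sim_protocol`.
#' @export
sim_protocol <- function(n_runs = 100L, t0 = 10, t_max = 50000, x0 = NULL,
                         seed = 1L, max_attempts = 100L) {
  stopifnot(t0 > 0, t_max > t0, n_runs >= 1)
  structure(list(n_runs = as.integer(n_runs), t0 = t0, t_max = t_max,
                 x0 = x0, seed = as.integer(seed),
                 max_attempts = as.integer(max_attempts)),
            class = "sim_protocol")
}

sim_table <- function(model, N, c = 3, cap = NULL) {
  caps <- lattice_caps(model, N, c = c, cap = cap)
  rate_table(model, N, caps)
}

#' Gillespie simulation of one trajectory
#'
#' Exact continuous-time simulation under the scaled transition rates,
#' run until absorption at the origin or `t_end`.  Unbounded models are
#' simulated on the same reflecting capped lattice as the exact oracle
#' (cap multiple `c` of the equilibrium; the cap is far outside the bulk
#' of the quasistationary distribution).  Reproducible under `set.seed()`.
#'
#' @param model a `population_process`.
#' @param N scale parameter.
#' @param x0 integer starting state.
#' @param t_end time horizon.
#' @param c,cap truncation policy for unbounded models (see
#'   [lattice_caps()]).
#' @param record logical: keep the full event sequence.
#' @param table optional precomputed `rate_table` (for repeated calls).
#' @return list with `extinct`, `time` (extinction time or `NA`),
#'   `t_end`, and when `record = TRUE` the matrices `states` (visited
#'   states, one per row) and vector `times`.
#' @export
gillespie <- function(model, N, x0, t_end, c = 3, cap = NULL,
                      record = TRUE, table = NULL) {
  tab <- if (is.null(table)) sim_table(model, N, c = c, cap = cap) else table
  x0 <- as.integer(x0)
  if (any(x0 < 0) || any(x0 > tab$caps)) stop("x0 outside the simulated lattice")
  i0 <- state_index(matrix(x0, 1), tab$caps)
  if (i0 != tab$origin && sum(tab$rates[i0, ]) <= 0) {
    stop_qswkb("model", "total rate zero at nonzero starting state")
  }
  res <- ssa_run(tab$rates, tab$target, i0, tab$origin, t_end, 0,
                 occupy = FALSE, record = record)
  out <- list(extinct = res$extinct, time = res$time, t_end = res$t_end)
  if (record) {
    out$times <- res$event_times
    out$states <- tab$states[res$event_states, , drop = FALSE]
  }
  out
}

#' Sample extinction times from approximate quasistationarity
#'
#' Runs the burn-in/censoring protocol: each retained run starts at
#' `ceiling(N * ystar)`, survives the burn-in `t0` (runs extinct earlier
#' are discarded and re-run with fresh randomness), and contributes the
#' duration from `t0` to extinction, right-censored at `t_max - t0`.
#'
#' @param model a `population_process`.
#' @param N scale parameter.
#' @param protocol a [sim_protocol()].
#' @param c,cap truncation policy for unbounded models.
#' @return An object of class `extinction_sample`: list with `durations`,
#'   `censored` (parallel logical), `n_attempts`, `protocol`.
#' @export
sample_extinction_times <- function(model, N, protocol, c = 3, cap = NULL) {
  tab <- sim_table(model, N, c = c, cap = cap)
  x0 <- protocol$x0
  if (is.null(x0)) x0 <- ceiling(N * equilibrium_point(model))
  i0 <- state_index(matrix(as.integer(x0), 1), tab$caps)
  set.seed(protocol$seed)
  durations <- numeric(protocol$n_runs)
  censored <- logical(protocol$n_runs)
  attempts <- 0L
  budget <- protocol$max_attempts * protocol$n_runs
  got <- 0L
  while (got < protocol$n_runs) {
    attempts <- attempts + 1L
    if (attempts > budget) {
      stop_qswkb("protocol",
                 "restart budget exceeded: quasistationarity unreachable ",
                 "before the burn-in at this N")
    }
    res <- ssa_run(tab$rates, tab$target, i0, tab$origin,
                   protocol$t_max, protocol$t0, occupy = FALSE, record = FALSE)
    if (res$extinct && res$time <= protocol$t0) next  # died in burn-in: re-run
    got <- got + 1L
    if (res$extinct) {
      durations[got] <- res$time - protocol$t0
      censored[got] <- FALSE
    } else {
      durations[got] <- protocol$t_max - protocol$t0
      censored[got] <- TRUE
    }
  }
  structure(list(durations = durations, censored = censored,
                 n_attempts = attempts, protocol = protocol),
            class = "extinction_sample")
}

#' Censored-exponential maximum likelihood estimate of tau
#'
#' The time from quasistationarity to extinction is exponential, so with
#' total observed time \eqn{T} (censored durations included) and \eqn{d}
#' observed extinctions, \eqn{\hat\tau = T/d}, with the chi-squared pivot
#' confidence interval
#' \eqn{[2T/\chi^2_{1-\alpha/2}(2d+2),\; 2T/\chi^2_{\alpha/2}(2d)]}.
#'
#' @param sample an `extinction_sample` (or list with `durations` and
#'   `censored`).
#' @param level confidence level.
#' @return An object of class `tau_estimate`: list with `tau_hat`,
#'   `ci_low`, `ci_high`, `n_events`, `total_time`, `level`.
#' @export
censored_exp_mle <- function(sample, level = 0.95) {
  d <- sum(!sample$censored)
  if (d == 0) stop_qswkb("all_censored", "no uncensored extinction times")
  T <- sum(sample$durations)
  a <- 1 - level
  est <- list(tau_hat = T / d,
              ci_low = 2 * T / stats::qchisq(1 - a / 2, df = 2 * d + 2),
              ci_high = 2 * T / stats::qchisq(a / 2, df = 2 * d),
              n_events = d, total_time = T, level = level)
  structure(est, class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  cat(sprintf("<tau_estimate> tau_hat = %.6g  [%.6g, %.6g] (%d events, %g%% CI)\n",
              x$tau_hat, x$ci_low, x$ci_high, x$n_events, 100 * x$level))
  invisible(x)
}

#' Empirical (occupation-time) quasistationary distribution
#'
#' For each nonzero state, the total time spent there between the end of
#' the burn-in and the earlier of extinction and `t_max`, summed over
#' runs and normalised to 1.  With `alive_at_end_only = TRUE` only runs
#' surviving to `t_max` contribute (the stricter reading; the default
#' uses all post-burn-in alive time, which retains far more data).
#'
#' @param model a `population_process`.
#' @param N scale parameter.
#' @param protocol a [sim_protocol()] (`n_runs` is the number of retained
#'   runs).
#' @param c,cap truncation policy for unbounded models.
#' @param alive_at_end_only occupancy inclusion rule (see above).
#' @return list with `states` (matrix of nonzero states with positive
#'   mass), `mass` (summing to 1), `mode` (state of maximal mass),
#'   `total_time`.
#' @export
empirical_qsd <- function(model, N, protocol, c = 3, cap = NULL,
                          alive_at_end_only = FALSE) {
  tab <- sim_table(model, N, c = c, cap = cap)
  x0 <- protocol$x0
  if (is.null(x0)) x0 <- ceiling(N * equilibrium_point(model))
  i0 <- state_index(matrix(as.integer(x0), 1), tab$caps)
  set.seed(protocol$seed)
  occ <- numeric(nrow(tab$states))
  attempts <- 0L
  budget <- protocol$max_attempts * protocol$n_runs
  got <- 0L
  while (got < protocol$n_runs) {
    attempts <- attempts + 1L
    if (attempts > budget) stop_qswkb("protocol", "restart budget exceeded")
    res <- ssa_run(tab$rates, tab$target, i0, tab$origin,
                   protocol$t_max, protocol$t0, occupy = TRUE, record = FALSE)
    if (res$extinct && res$time <= protocol$t0) next
    if (alive_at_end_only && res$extinct) { got <- got + 1L; next }
    got <- got + 1L
    occ <- occ + res$occupation
  }
  occ[tab$origin] <- 0
  total <- sum(occ)
  if (total <= 0) stop_qswkb("protocol", "no surviving occupation time recorded")
  keep <- occ > 0
  mass <- occ[keep] / total
  states <- tab$states[keep, , drop = FALSE]
  list(states = states, mass = mass,
       mode = states[which.max(mass), ], total_time = total)
}
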