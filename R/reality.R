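#' Quadratic seasonal rate modulator
#'
#' The fixed multiplicative trend
#' \deqn{g(t) = 1 - ((t - 5)^2 / 25 - 0.5) / 10}
#' applied to all three rates of the stochastic reality generator. It is a
#' subtle seasonal effect: `g(5) = 1.05`, `g(0) = g(10) = 0.95`.
#'
#' @param t Time (vectorized).
#' @return The modulating factor.
#' @export
quadratic_modulator <- function(t) {
  1 - ((t - 5)^2 / 25 - 0.5) / 10
}

#' Stochastic Lotka-Volterra simulation (Gillespie algorithm)
#'
#' Exact stochastic simulation of the continuous-time Markov jump process
#' whose mean-field limit is the deterministic predator-prey system, with
#' three reactions: prey birth (hazard `g(t) x1 f1`), conversion of prey to
#' predator (hazard `g(t) x2 f1 f2`; decrements prey, increments predator)
#' and predator death (hazard `g(t) x3 f2`). The single interaction term
#' appears in both species' dynamics, so it is one conversion event, not two
#' reactions.
#'
#' Time-varying hazards are handled by a piecewise-constant-rate
#' approximation: the modulator is refreshed every `refresh` time units
#' (default 0.01) and the simulation is exact for the refreshed hazards.
#' For the slowly varying modulators used here, the drift error within a
#' refresh interval is below 0.1%.
#'
#' @param x Input point (rates); zero components are allowed here so that
#'   degenerate processes (e.g. a pure birth process) can be simulated.
#' @param init Positive integer initial populations `(prey, predator)`.
#' @param modulator `NULL`, an `lv_modulator`, or a function of time; applied
#'   to all three rates, as in `x -> g(t) x`.
#' @param t_max Simulation horizon (default 10).
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param refresh Hazard refresh step (time units).
#' @param cap Population cap; exceeding it is an explicit failure.
#' @param kind Trajectory label, `"stochastic"` by default.
#' @return An `lv_trajectory` recorded on the refresh grid, with attributes
#'   `n_events` and `extinct`.
#' @export
gillespie_lv <- function(x, init = c(1910, 710), modulator = NULL,
                         t_max = 10, seed = NULL, refresh = 0.01,
                         cap = 1e7, kind = "stochastic") {
  x <- unname(as.numeric(x))
  if (length(x) != 3L || any(x < 0) || any(!is.finite(x)))
    stop("rates must be three non-negative numbers")
  init <- unname(as.numeric(init))
  if (length(init) != 2L || any(init < 0) || any(init != round(init)))
    stop("initial populations must be non-negative integers")
  if (!is.null(seed)) set.seed(seed)
  grid <- seq(0, t_max, by = refresh)
  if (grid[length(grid)] < t_max) grid <- c(grid, t_max)
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  gvals <- eval_modulator(modulator, mids)
  if (any(gvals <= 0)) stop("modulator must stay strictly positive")
  res <- .Call("gillespie_lv_c", x, init, grid, gvals, as.numeric(cap),
               PACKAGE = "strucdisc")
  if (res$capped)
    stop(sprintf("population exceeded cap %g at input (%g, %g, %g)",
                 cap, x[1], x[2], x[3]))
  traj <- new_trajectory(grid, res$prey, res$pred, kind)
  attr(traj, "n_events") <- res$n_events
  attr(traj, "extinct") <- any(res$prey == 0) || any(res$pred == 0)
  traj
}

#' Default input point of the pseudo-reality generator
#'
#' The rate vector `(1.0, 4.0e-4, 1.8)` used inside the stochastic reality
#' generator -- the same mid-region exemplar point used for the
#' demonstration trajectory, producing the classic two-peak oscillation
#' within the `[0, 10]` horizon with its first peak before the present day.
#' Only the data it produces, never this value, enters the discrepancy
#' analysis.
#' @return Numeric length-3 vector.
#' @export
reality_x <- function() c(1.0, 4.0e-4, 1.8)

#' Generate the synthetic "real system" trajectory
#'
#' One Gillespie run of the stochastic predator-prey system with the
#' quadratic seasonal modulator and initial populations `(1910, 710)` --
#' deliberately different from the simulator's fixed `(2000, 800)` -- so the
#' resulting system outputs cannot be perfectly recreated by the
#' deterministic simulator at any input.
#'
#' @param x Rates driving the generator (default [reality_x()]).
#' @param init Initial populations, default `(1910, 710)`.
#' @param seed Integer seed fixing the realized path.
#' @param t_max Horizon.
#' @return An `lv_trajectory` with `kind = "reality"`.
#' @export
make_reality <- function(x = reality_x(), init = c(1910, 710), seed = 101,
                         t_max = 10) {
  gillespie_lv(x, init = init, modulator = modulator_quadratic(),
               t_max = t_max, seed = seed, kind = "reality")
}

#' Noisy observations of a trajectory
#'
#' Observations `z = y + e` where `y` is the trajectory value at the
#' observation times (nearest grid point) and `e` is independent zero-mean
#' Gaussian noise with standard deviation `sigma_e` per observation, for
#' both species. Values are not clipped at zero, keeping the error model
#' exactly additive.
#'
#' @param traj Trajectory to observe (usually the reality run).
#' @param obs_times Observation times within the trajectory span; default 11
#'   equally spaced times on `[0, 10]`.
#' @param sigma_e Observation-error standard deviation (counts), default 50.
#' @param seed Integer seed.
#' @param history_cutoff Time separating historical from future data
#'   (default 5, the "present day"); observations at or before it are
#'   flagged `is_history`.
#' @return An object of class `lv_observations`: data frame with columns
#'   `time`, `species`, `y`, `z`, `sigma_e`, `is_history`.
#' @export
make_observations <- function(traj, obs_times = seq(0, 10, by = 1),
                              sigma_e = 50, seed = 202,
                              history_cutoff = 5) {
  if (sigma_e < 0) stop("sigma_e must be non-negative")
  yv <- trajectory_at(traj, obs_times)
  if (!is.null(seed)) set.seed(seed)
  n <- length(obs_times)
  e <- rnorm(2L * n, 0, sigma_e)
  obs <- data.frame(
    time = rep(obs_times, 2L),
    species = rep(c("prey", "predator"), each = n),
    y = c(yv[, "prey"], yv[, "predator"]),
    z = c(yv[, "prey"], yv[, "predator"]) + e,
    sigma_e = sigma_e,
    is_history = rep(obs_times <= history_cutoff, 2L))
  class(obs) <- c("lv_observations", "data.frame")
  attr(obs, "history_cutoff") <- history_cutoff
  obs
}

#' @export
print.lv_observations <- function(x, ...) {
  cat(sprintf("<lv_observations> %d observations (%d historical), sigma_e=%g\n",
              nrow(x), sum(x$is_history), x$sigma_e[1]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write / read observations as CSV
#' @param obs An `lv_observations` object.
#' @param path File path.
#' @export
write_observations <- function(obs, path) {
  d <- as.data.frame(obs)
  d$history_cutoff <- attr(obs, "history_cutoff")
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  d <- read.csv(path)
  cutoff <- d$history_cutoff[1]
  d$history_cutoff <- NULL
  class(d) <- c("lv_observations", "data.frame")
  attr(d, "history_cutoff") <- cutoff
  d
}
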