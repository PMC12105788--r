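#' @useDynLib strucdisc
#' @importFrom stats coef fitted lm.fit median pnorm predict quantile rnorm
#'   runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

#' Default input-parameter ranges for the predator-prey simulator
#'
#' The three rate parameters are the prey reproduction rate `x1`, the
#' predator-prey interaction rate `x2` and the predator death rate `x3`.
#' The default ranges encode partially informed prior knowledge about
#' plausible rates for the study system.
#'
#' @return Named list of length-2 numeric vectors (lower, upper).
#' @export
lvpp_ranges <- function() {
  list(x1 = c(0.7, 1.3), x2 = c(3.1e-5, 5.7e-4), x3 = c(1.3, 2.3))
}

# validate and normalise an input point x = (x1, x2, x3)
as_input_point <- function(x) {
  x <- unname(as.numeric(x))
  if (length(x) != 3L || any(!is.finite(x)) || any(x <= 0))
    stop("input point must be three strictly positive rates (x1, x2, x3)")
  x
}

#' Rate modulators
#'
#' A modulator is a positive multiplicative factor `g(t)` applied to one of
#' the simulator's rate parameters, turning a constant rate `x_i` into the
#' time-varying rate `g_i(t) x_i`. Three parametric families are supported
#' in compiled code: the identity `g(t) = 1`; the sinusoidal perturbation
#' `g(t) = 1 + c sin(2 pi (t - a) b / T)` used for internal-discrepancy
#' experiments; and the fixed quadratic seasonal trend
#' `g(t) = 1 - ((t - 5)^2 / 25 - 0.5) / 10` driving the synthetic reality.
#' Arbitrary R functions of time are also accepted (handled by a pure-R
#' solver path).
#'
#' @param a,b,c Phase (time units), frequency factor (dimensionless) and
#'   amplitude (dimensionless) of the sinusoidal family.
#' @param period Period constant `T` (time units), default 10.
#' @return An object of class `lv_modulator`.
#' @export
modulator_identity <- function() {
  structure(list(type = 0L, pars = c(0, 0, 0)), class = "lv_modulator")
}

#' @rdname modulator_identity
#' @export
modulator_sinusoidal <- function(a, b, c, period = 10) {
  structure(list(type = 1L, pars = c(a, b, c), period = period),
            class = "lv_modulator")
}

#' @rdname modulator_identity
#' @export
modulator_quadratic <- function() {
  structure(list(type = 2L, pars = c(0, 0, 0)), class = "lv_modulator")
}

# evaluate a modulator (lv_modulator object, plain function, or NULL) at t
eval_modulator <- function(m, t) {
  if (is.null(m)) return(rep(1, length(t)))
  if (is.function(m)) return(vapply(t, m, numeric(1)))
  switch(m$type + 1L,
         rep(1, length(t)),
         1 + m$pars[3] * sin(2 * pi * (t - m$pars[1]) * m$pars[2] / m$period),
         quadratic_modulator(t))
}

is_parametric_modulator <- function(m) is.null(m) || inherits(m, "lv_modulator")

# pack x + three modulators into the 16-slot parms vector of the C RHS
pack_parms <- function(x, modulators) {
  p <- numeric(16)
  p[1:3] <- x
  period <- 10
  for (i in 1:3) {
    m <- modulators[[i]]
    off <- 4L * i
    if (is.null(m)) next
    p[off] <- m$type
    p[off + 1:3] <- m$pars
    if (!is.null(m$period)) period <- m$period
  }
  p[16] <- period
  p
}

#' Simulate the Lotka-Volterra predator-prey model
#'
#' Numerically integrates the deterministic predator-prey system
#' \deqn{df_1/dt = g_1(t) x_1 f_1 - g_2(t) x_2 f_1 f_2, \quad
#'       df_2/dt = g_2(t) x_2 f_1 f_2 - g_3(t) x_3 f_2,}
#' with `f1` the prey and `f2` the predator population, on a user-supplied
#' time grid. Populations are treated as continuous. With parametric
#' modulators (or none) the right-hand side is evaluated in compiled code;
#' arbitrary function modulators fall back to an R right-hand side.
#'
#' @param x Input point `(x1, x2, x3)` of strictly positive rates.
#' @param init Positive initial populations `(prey, predator)`.
#' @param times Strictly increasing time grid starting at 0 (default 1001
#'   points on `[0, 10]`).
#' @param modulators Either `NULL` (no time variation) or a list of three
#'   modulators (see [modulator_identity()]), one per rate.
#' @param rtol,atol Solver tolerances, default `1e-8`; tight enough that the
#'   conserved quantity of the unmodulated system is flat to about `1e-9`
#'   relative over `[0, 10]`.
#' @return An object of class `lv_trajectory`: list with `times`, `prey`,
#'   `predator`, `kind = "deterministic"`.
#' @seealso [lv_invariant()], [lvpp_equilibrium()], [gillespie_lv()]
#' @examples
#' tr <- simulate_lvpp(c(1.0, 4e-4, 1.8), init = c(2000, 800))
#' range(tr$prey)
#' @export
simulate_lvpp <- function(x, init = c(2000, 800),
                          times = seq(0, 10, length.out = 1001),
                          modulators = NULL, rtol = 1e-8, atol = 1e-8) {
  x <- as_input_point(x)
  init <- unname(as.numeric(init))
  if (length(init) != 2L || any(init <= 0) || any(!is.finite(init)))
    stop("initial populations must be two positive numbers")
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (!is.null(modulators)) {
    if (inherits(modulators, "lv_modulator") || is.function(modulators))
      modulators <- list(modulators, modulators, modulators)
    if (length(modulators) != 3L)
      stop("modulators must be NULL or a list of three modulators")
  } else modulators <- vector("list", 3L)

  y0 <- c(prey = init[1], predator = init[2])
  if (all(vapply(modulators, is_parametric_modulator, logical(1)))) {
    sol <- deSolve::ode(y = y0, times = times, func = "lvpp_derivs",
                        parms = pack_parms(x, modulators),
                        dllname = "strucdisc", initfunc = "lvpp_init",
                        rtol = rtol, atol = atol)
  } else {
    rhs <- function(t, y, p) {
      g <- c(eval_modulator(modulators[[1]], t),
             eval_modulator(modulators[[2]], t),
             eval_modulator(modulators[[3]], t))
      inter <- g[2] * x[2] * y[1] * y[2]
      list(c(g[1] * x[1] * y[1] - inter, inter - g[3] * x[3] * y[2]))
    }
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  }
  if (nrow(sol) < length(times) || any(!is.finite(sol[, 2:3])))
    stop(sprintf("solver failure at input point (%.6g, %.6g, %.6g)",
                 x[1], x[2], x[3]))
  new_trajectory(times = times, prey = unname(sol[, 2]),
                 predator = unname(sol[, 3]), kind = "deterministic")
}

new_trajectory <- function(times, prey, predator, kind) {
  structure(list(times = times, prey = prey, predator = predator,
                 kind = kind),
            class = "lv_trajectory")
}

#' @export
print.lv_trajectory <- function(x, ...) {
  cat(sprintf("<lv_trajectory> kind=%s, %d points on [%g, %g]\n",
              x$kind, length(x$times), min(x$times), max(x$times)))
  cat(sprintf("  prey %.1f..%.1f  predator %.1f..%.1f\n",
              min(x$prey), max(x$prey), min(x$predator), max(x$predator)))
  invisible(x)
}

#' @export
as.data.frame.lv_trajectory <- function(x, ...) {
  data.frame(time = x$times, prey = x$prey, predator = x$predator,
             kind = x$kind)
}

#' @export
plot.lv_trajectory <- function(x, ...) {
  graphics::matplot(x$times, cbind(x$prey, x$predator), type = "l",
                    lty = 1, col = c("purple", "orange"),
                    xlab = "time", ylab = "population", ...)
  graphics::legend("topright", c("prey", "predator"), lty = 1,
                   col = c("purple", "orange"), bty = "n")
  invisible(x)
}

# evaluate a trajectory at arbitrary times by nearest-grid-point lookup
trajectory_at <- function(traj, at) {
  if (any(at < min(traj$times) - 1e-9) || any(at > max(traj$times) + 1e-9))
    stop("requested times outside the trajectory span")
  idx <- vapply(at, function(t) which.min(abs(traj$times - t)), integer(1))
  cbind(prey = traj$prey[idx], predator = traj$predator[idx])
}

#' Conserved quantity of the unmodulated predator-prey system
#'
#' Along exact solutions of the unmodulated system the quantity
#' \deqn{H = x_2 f_1 - x_3 \log f_1 + x_2 f_2 - x_1 \log f_2}
#' is constant (its time derivative vanishes identically), which makes it a
#' sharp solver-validation oracle: the relative range of `H` along a
#' numerical trajectory measures integration error directly.
#'
#' @param f1,f2 Positive prey and predator values (vectorized).
#' @param x Input point.
#' @return Numeric vector of `H` values.
#' @export
lv_invariant <- function(f1, f2, x) {
  x <- as_input_point(x)
  if (any(f1 <= 0) || any(f2 <= 0))
    stop("populations must be strictly positive")
  x[2] * f1 - x[3] * log(f1) + x[2] * f2 - x[1] * log(f2)
}

#' Non-trivial equilibrium of the predator-prey system
#'
#' @param x Input point.
#' @return Named vector `(prey = x3/x2, predator = x1/x2)`, the stationary
#'   point at which both derivatives vanish.
#' @export
lvpp_equilibrium <- function(x) {
  x <- as_input_point(x)
  c(prey = x[3] / x[2], predator = x[1] / x[2])
}

#' Write / read a trajectory as CSV
#'
#' @param traj An `lv_trajectory`.
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- read.csv(path)
  new_trajectory(d$time, d$prey, d$predator, as.character(d$kind[1]))
}
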