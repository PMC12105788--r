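#' Implausibility of a prediction against an observation
#'
#' The standardized distance
#' \deqn{I(x) = \frac{|E[f(x)] + E[\epsilon^*] - z|}
#'                   {\sqrt{Var[f(x)] + Var[\epsilon^*] + Var[e]}},}
#' combining prediction uncertainty, structural discrepancy and observation
#' error in the denominator. Large values flag strong disagreement between
#' a simulator output and its observation; small values arise from either
#' a good match or large uncertainty. With `squared = TRUE` the
#' unstandardized ratio (distance over total variance, no square root) is
#' returned for comparison; the standardized form is the one the 3-sigma
#' threshold convention applies to, and is the default.
#'
#' @param pred_mean,pred_var Prediction mean and variance (vectorized).
#' @param disc_mean,disc_var Structural-discrepancy mean and variance.
#' @param z Observed value.
#' @param obs_var Observation-error variance.
#' @param squared Return the non-square-rooted form.
#' @return Non-negative implausibility value(s).
#' @export
implausibility <- function(pred_mean, pred_var, disc_mean, disc_var, z,
                           obs_var, squared = FALSE) {
  total_var <- pred_var + disc_var + obs_var
  if (any(pred_var < 0) || any(disc_var < 0) || any(obs_var < 0))
    stop("variances must be non-negative")
  if (any(total_var <= 0))
    stop("total variance must be positive to standardize")
  num <- abs(pred_mean + disc_mean - z)
  if (squared) num^2 / total_var else num / sqrt(total_var)
}

#' Maximum implausibility across outputs
#'
#' @param per_output Non-empty vector of per-output implausibilities.
#' @return The maximum, so a point is judged implausible if the simulator
#'   fails to match the data on any single output.
#' @export
max_implausibility <- function(per_output) {
  if (!length(per_output)) stop("need at least one output implausibility")
  max(per_output)
}

#' Discrepancy specification for history matching
#'
#' Either a cautious `fractional` specification -- a zero-mean Gaussian-
#' scale discrepancy with standard deviation `fractional * |f_r(x)|` per
#' output (the conservative order-of-magnitude choice used for the first
#' wave) -- or a `structured` specification built from internal-discrepancy
#' emulators: mean `-B(x)` from the bias emulator, sd from the sd-field
#' emulator (floored at zero), plus a nominal external fractional term
#' added in quadrature.
#'
#' @param mode `"fractional"` or `"structured"`.
#' @param fractional Fractional sd level for the cautious mode (default
#'   0.15, i.e. 15% of the output value).
#' @param external Nominal external fractional sd used in structured mode
#'   (default 0.02).
#' @param bias_em,sd_em Emulators of the internal bias and sd fields
#'   (structured mode).
#' @return An object of class `discrepancy_spec`.
#' @export
discrepancy_spec <- function(mode = c("fractional", "structured"),
                             fractional = 0.15, external = 0.02,
                             bias_em = NULL, sd_em = NULL) {
  mode <- match.arg(mode)
  if (mode == "structured" &&
      (!inherits(bias_em, "lv_emulator") || !inherits(sd_em, "lv_emulator")))
    stop("structured mode needs bias_em and sd_em emulators")
  structure(list(mode = mode, fractional = fractional, external = external,
                 bias_em = bias_em, sd_em = sd_em),
            class = "discrepancy_spec")
}

# discrepancy mean and variance per output at input x with outputs f_out
discrepancy_moments <- function(disc, x, f_out) {
  if (disc$mode == "fractional") {
    list(mean = rep(0, length(f_out)), var = (disc$fractional * abs(f_out))^2)
  } else {
    bias <- drop(predict(disc$bias_em, x)$mean)[names(f_out)]
    sig <- pmax(drop(predict(disc$sd_em, x)$mean)[names(f_out)], 0)
    list(mean = discrepancy_mean_from_bias(bias),
         var = sig^2 + (disc$external * abs(f_out))^2)
  }
}

#' Classify a wave of runs by maximum implausibility
#'
#' Computes per-output implausibilities for every design point against the
#' historical observations (those with `is_history` set; the simulator must
#' be run on exactly that output indexing), combines them by the maximum,
#' and retains points with `I_M(x) <= threshold`. The default threshold of
#' 3 follows the three-sigma rule: for any unimodal continuous
#' distribution, at least 95% of the probability lies within three
#' standard deviations of the mean.
#'
#' @param design A `design_matrix` of the wave's inputs.
#' @param runs Matrix (points x outputs) of simulator outputs on the
#'   historical observation indexing, with column names matching
#'   `paste0(species, "_t", time)`.
#' @param obs An `lv_observations` object; only historical rows are used.
#' @param disc A [discrepancy_spec()].
#' @param threshold Retention threshold on `I_M` (default 3).
#' @param squared Use the non-standardized implausibility form.
#' @return A `wave_result`: data frame with the design columns, `i_max`,
#'   `retained`; attributes `I` (per-output matrix), `threshold`, `wave`.
#' @export
classify_wave <- function(design, runs, obs, disc, threshold = 3,
                          squared = FALSE) {
  hist <- obs[obs$is_history, , drop = FALSE]
  onames <- paste0(hist$species, "_t", hist$time)
  runs <- as.matrix(runs)
  if (is.null(colnames(runs)) || !all(onames %in% colnames(runs)))
    stop("runs must carry columns matching the historical observations")
  runs <- runs[, onames, drop = FALSE]
  n <- nrow(runs)
  if (n != nrow(design)) stop("design and runs disagree in length")
  I <- matrix(NA_real_, n, length(onames), dimnames = list(NULL, onames))
  for (i in seq_len(n)) {
    f_out <- setNames(runs[i, ], onames)
    dm <- discrepancy_moments(disc, as.numeric(design[i, ]), f_out)
    I[i, ] <- implausibility(f_out, 0, dm$mean, dm$var, hist$z,
                             hist$sigma_e^2, squared = squared)
  }
  i_max <- apply(I, 1L, max_implausibility)
  out <- cbind(as.data.frame(design),
               data.frame(i_max = i_max, retained = i_max <= threshold))
  structure(out, class = c("wave_result", "data.frame"),
            I = I, threshold = threshold, wave = attr(design, "wave"),
            ranges = attr(design, "ranges"))
}

#' @export
print.wave_result <- function(x, ...) {
  cat(sprintf("<wave_result> wave %s: %d / %d points retained (I_M <= %g)\n",
              attr(x, "wave"), sum(x$retained), nrow(x),
              attr(x, "threshold")))
  invisible(x)
}

#' @export
summary.wave_result <- function(object, ...) {
  list(n = nrow(object), n_retained = sum(object$retained),
       threshold = attr(object, "threshold"),
       i_max = quantile(object$i_max, c(0, 0.25, 0.5, 0.75, 1)))
}

#' Refocus: generate the next wave under a refined discrepancy
#'
#' Rejection-samples candidate input points, keeping those whose maximum
#' implausibility under the refined (typically structured) discrepancy
#' specification stays at or below the threshold. The simulator is
#' evaluated directly for each candidate (direct mode, appropriate for fast
#' models).
#'
#' @param prev A `wave_result` from the previous wave; its retained set
#'   must be non-empty.
#' @param new_disc The refined [discrepancy_spec()].
#' @param obs Observations (historical rows used).
#' @param run_fn Function mapping an input point to the named historical
#'   output vector.
#' @param n_target Number of next-wave points wanted (default 750).
#' @param threshold Implausibility threshold.
#' @param seed Integer seed for candidate draws.
#' @param max_draws Cap on candidate draws.
#' @return A `design_matrix` for the next wave.
#' @export
refocus <- function(prev, new_disc, obs, run_fn, n_target = 750,
                    threshold = 3, seed = 1, max_draws = 200 * n_target) {
  if (!inherits(prev, "wave_result")) stop("prev must be a wave_result")
  if (!sum(prev$retained))
    stop(paste("previous retained set is empty; review the discrepancy",
               "specification before refocusing"))
  hist <- obs[obs$is_history, , drop = FALSE]
  onames <- paste0(hist$species, "_t", hist$time)
  acceptor <- function(p) {
    f_out <- run_fn(p)[onames]
    dm <- discrepancy_moments(new_disc, p, f_out)
    I <- implausibility(f_out, 0, dm$mean, dm$var, hist$z, hist$sigma_e^2)
    max_implausibility(I) <= threshold
  }
  wave <- if (is.null(attr(prev, "wave"))) NULL else attr(prev, "wave") + 1L
  rejection_sample_candidates(n_target, attr(prev, "ranges"), acceptor,
                              seed = seed, max_draws = max_draws,
                              wave = wave)
}

#' Probability within three standard deviations of the mean
#'
#' Closed-form checks of the three-sigma rule for three reference
#' distributions, supporting the threshold-3 retention convention:
#' Gaussian `2 Phi(3) - 1` (about 99.73%), uniform (exactly 1, since three
#' sds exceed the half-width `sqrt(3)` sds), and exponential
#' `P(|X - 1/lambda| <= 3/lambda) = 1 - e^{-4}` (about 98.2%).
#'
#' @return Named vector of coverage probabilities, all at least 0.95.
#' @export
three_sigma_coverage <- function() {
  c(gaussian = 2 * pnorm(3) - 1,
    uniform = 1,
    exponential = 1 - exp(-4))
}
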