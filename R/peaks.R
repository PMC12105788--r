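peak_names <- function(n_peaks = 2) {
  as.vector(vapply(seq_len(n_peaks), function(k)
    paste0("p", k, "_", c("prey_time", "prey_mag", "pred_time", "pred_mag")),
    character(4)))
}

# interior local maxima of a series; returns indices
local_maxima <- function(y) {
  n <- length(y)
  which(y[-c(1, n)] >= y[-c(n - 1, n)] & y[-c(1, n)] > y[-c(1, 2)]) + 1L
}

# topographic prominence of each candidate maximum: height above the higher
# of the two saddles reached before terrain exceeds the candidate
peak_prominences <- function(y, cand) {
  n <- length(y)
  vapply(cand, function(i) {
    j <- i; lmin <- y[i]
    while (j > 1L && y[j] <= y[i]) { j <- j - 1L; lmin <- min(lmin, y[j]) }
    k <- i; rmin <- y[i]
    while (k < n && y[k] <= y[i]) { k <- k + 1L; rmin <- min(rmin, y[k]) }
    y[i] - max(lmin, rmin)
  }, numeric(1))
}

# interior maxima whose prominence exceeds min_prom of the series range,
# screening out residual noise wiggles on smoothed stochastic paths
find_peaks <- function(y, min_prom = 0.05) {
  cand <- local_maxima(y)
  rng <- diff(range(y))
  if (!length(cand) || rng <= 0) return(integer(0))
  cand[peak_prominences(y, cand) >= min_prom * rng]
}

# refine a discrete maximum by the apex of the quadratic through the three
# bracketing grid points (exact for quadratics)
refine_peak <- function(t3, y3) {
  co <- unname(solve(cbind(1, t3, t3^2), y3))
  if (co[3] >= 0) return(c(time = t3[2], mag = y3[2]))  # degenerate bracket
  tm <- -co[2] / (2 * co[3])
  c(time = unname(tm), mag = unname(co[1] + co[2] * tm + co[3] * tm^2))
}

#' Extract population-peak features from a trajectory
#'
#' Finds, per species, the first `n_peaks` interior local maxima whose
#' topographic prominence exceeds 5% of the series range (screening out
#' residual noise wiggles) and refines each by quadratic interpolation
#' through the three grid points bracketing the discrete maximum,
#' returning both the peak time and the interpolated magnitude. For
#' stochastic trajectories, the path is first smoothed (cubic smoothing
#' spline, `df = 20`) so that peak features describe the underlying
#' oscillation rather than jump noise.
#'
#' @param traj An `lv_trajectory`.
#' @param n_peaks Number of peaks per species (default 2).
#' @param smooth Smooth before peak finding; defaults to `TRUE` for
#'   stochastic/reality trajectories and `FALSE` for deterministic ones.
#' @return Named vector of `4 * n_peaks` features ordered
#'   `(p1_prey_time, p1_prey_mag, p1_pred_time, p1_pred_mag, p2_...)`.
#' @export
extract_peaks <- function(traj, n_peaks = 2, smooth = NULL) {
  if (is.null(smooth)) smooth <- traj$kind != "deterministic"
  series <- list(prey = traj$prey, pred = traj$predator)
  if (smooth)
    series <- lapply(series, function(y)
      fitted(stats::smooth.spline(traj$times, y, df = 20)))
  out <- numeric(0)
  feats <- vector("list", 2L)
  names(feats) <- names(series)
  for (sp in names(series)) {
    y <- series[[sp]]
    pk <- find_peaks(y)
    if (length(pk) < n_peaks)
      stop(sprintf("only %d peak(s) found for %s (need %d)",
                   length(pk), sp, n_peaks))
    feats[[sp]] <- lapply(pk[seq_len(n_peaks)], function(i)
      refine_peak(traj$times[(i - 1):(i + 1)], y[(i - 1):(i + 1)]))
  }
  for (k in seq_len(n_peaks))
    out <- c(out, feats$prey[[k]]["time"], feats$prey[[k]]["mag"],
             feats$pred[[k]]["time"], feats$pred[[k]]["mag"])
  setNames(out, peak_names(n_peaks))
}

#' Discrepancy covariance of the peak features
#'
#' The sample covariance (divisor `k - 1`) of the `4 n_peaks` peak features
#' across the perturbed runs of an internal-discrepancy experiment run with
#' the peak output map. Runs whose peak extraction failed are dropped and
#' counted; more than 10% dropped is an error.
#'
#' @param sample A `discrepancy_sample` whose outputs are peak features.
#' @return Symmetric PSD covariance matrix with attribute `n_dropped`.
#' @export
peak_discrepancy_covariance <- function(sample) {
  stopifnot(inherits(sample, "discrepancy_sample"))
  ok <- stats::complete.cases(sample$runs)
  if (sum(!ok) > 0.10 * nrow(sample$runs))
    stop(sprintf("peak extraction failed in %d of %d runs (> 10%%)",
                 sum(!ok), nrow(sample$runs)))
  runs <- sample$runs[ok, , drop = FALSE]
  if (nrow(runs) < ncol(runs) + 1L)
    warning("fewer runs than needed for a full-rank covariance estimate")
  V <- stats::cov(runs)
  structure((V + t(V)) / 2, n_dropped = sum(!ok))
}

#' External-discrepancy and observation-error specification on peak scale
#'
#' Zero-mean, uncorrelated terms: an external discrepancy sd of 2% of the
#' peak magnitude and 0.03 (time units) on peak timings, for both species;
#' and an observation-error sd of 50 (counts) on magnitudes and 0.025 on
#' timings, representing an imperfect peak observation process.
#'
#' @param mag_ext_frac,time_ext_sd External discrepancy: fractional sd on
#'   magnitudes, absolute sd on timings.
#' @param mag_obs_sd,time_obs_sd Observation-error sds.
#' @return An object of class `peak_uncertainty_spec`.
#' @export
peak_uncertainty_spec <- function(mag_ext_frac = 0.02, time_ext_sd = 0.03,
                                  mag_obs_sd = 50, time_obs_sd = 0.025) {
  if (any(c(mag_ext_frac, time_ext_sd, mag_obs_sd, time_obs_sd) < 0))
    stop("all standard deviations must be non-negative")
  structure(list(mag_ext_frac = mag_ext_frac, time_ext_sd = time_ext_sd,
                 mag_obs_sd = mag_obs_sd, time_obs_sd = time_obs_sd),
            class = "peak_uncertainty_spec")
}

is_time_feature <- function(nm) grepl("_time$", nm)

#' Bayes linear adjustment of future by historical outputs
#'
#' Implements the second-order update
#' \deqn{E_z[y_p] = E[y_p] + Cov[y_p, z] Var[z]^{-1} (z - E[z]),}
#' \deqn{Var_z[y_p] = Var[y_p] - Cov[y_p, z] Var[z]^{-1} Cov[z, y_p],}
#' where the first `n_h` components of `prior_mean` / `joint_cov` are the
#' historical block (with observation-error variance already included
#' there and nowhere else, so the cross block is untouched by it) and the
#' rest the future block.
#'
#' @param prior_mean Prior mean of the joint (historical, future) vector.
#' @param joint_cov Joint covariance; historical block must include
#'   observation error.
#' @param z Observed historical vector (length `n_h`).
#' @param n_h Number of historical components (default `length(z)`).
#' @return List with `adjusted_mean`, `adjusted_cov`, `resolved` (the
#'   subtracted PSD term), `prior_mean_p`, `prior_cov_p`, and `jitter`
#'   (ridge added when `Var[z]` was numerically singular).
#' @export
bayes_linear_adjust <- function(prior_mean, joint_cov, z,
                                n_h = length(z)) {
  m <- length(prior_mean)
  stopifnot(nrow(joint_cov) == m, ncol(joint_cov) == m, n_h < m)
  hi <- seq_len(n_h)
  pi <- (n_h + 1L):m
  Vz <- joint_cov[hi, hi, drop = FALSE]
  Cpz <- joint_cov[pi, hi, drop = FALSE]
  Vp <- joint_cov[pi, pi, drop = FALSE]
  jitter <- 0
  Vzi <- tryCatch(solve(Vz), error = function(e) NULL)
  if (is.null(Vzi)) {
    jitter <- max(1e-8 * mean(diag(Vz)), 1e-12)
    Vzi <- solve(Vz + diag(jitter, n_h))
  }
  gain <- Cpz %*% Vzi
  resolved <- gain %*% t(Cpz)
  resolved <- (resolved + t(resolved)) / 2
  adj_mean <- prior_mean[pi] + drop(gain %*% (z - prior_mean[hi]))
  adj_cov <- Vp - resolved
  list(adjusted_mean = adj_mean, adjusted_cov = adj_cov,
       resolved = resolved, prior_mean_p = prior_mean[pi],
       prior_cov_p = Vp, jitter = jitter)
}

#' Forecast the second population peak from the observed first peak
#'
#' The naive forecast for the second peak of both species is the
#' simulator's own second-peak output at `x`, with covariance given by the
#' future block of the assessed discrepancy covariance (internal peak
#' covariance plus the uncorrelated external terms). The adjusted forecast
#' updates it by Bayes linear projection on the observed first peak, using
#' the full 8x8 joint discrepancy covariance -- whose cross-peak
#' correlations, induced by the coupled oscillatory dynamics, are what
#' transfer information from past to future. Discrepancy means enter the
#' adjustment via the experiment's bias summary (`E[eps*] = -B`).
#'
#' @param disc_sample A `discrepancy_sample` with peak-feature outputs at a
#'   retained input point (from [run_discrepancy_experiment()] with
#'   [output_map_peaks()]).
#' @param spec A [peak_uncertainty_spec()].
#' @param z_peaks Observed first-peak vector, ordered
#'   `(prey_time, prey_mag, pred_time, pred_mag)`.
#' @param include_bias Also shift the reported naive mean by the internal
#'   discrepancy mean (default `FALSE`: the naive product is the raw
#'   simulator forecast; the adjusted forecast always accounts for the
#'   bias).
#' @return An object of class `peak_forecast`: naive and adjusted means and
#'   covariances for the 4 second-peak features, the joint 8x8 covariance
#'   used, `z_peaks`, and per-species 2x2 ellipse parameters.
#' @export
forecast_second_peak <- function(disc_sample, spec = peak_uncertainty_spec(),
                                 z_peaks, include_bias = FALSE) {
  base <- disc_sample$base_run
  if (length(base) != 8L)
    stop("disc_sample must carry the 8 peak features (2 peaks x 2 species)")
  Vint <- peak_discrepancy_covariance(disc_sample)
  summ <- summarize_discrepancy(disc_sample)
  dmean <- discrepancy_mean_from_bias(summ$bias)

  nm <- names(base)
  ext_sd <- ifelse(is_time_feature(nm), spec$time_ext_sd,
                   spec$mag_ext_frac * abs(base))
  obs_sd <- ifelse(is_time_feature(nm[1:4]), spec$time_obs_sd,
                   spec$mag_obs_sd)
  joint <- Vint + diag(ext_sd^2)
  joint[1:4, 1:4] <- joint[1:4, 1:4] + diag(obs_sd^2)

  prior_mean <- base + dmean
  bl <- bayes_linear_adjust(prior_mean, joint, z_peaks, n_h = 4L)

  naive_mean <- if (include_bias) base[5:8] + dmean[5:8] else base[5:8]
  naive_cov <- (Vint + diag(ext_sd^2))[5:8, 5:8]
  structure(list(naive_mean = naive_mean, naive_cov = naive_cov,
                 adjusted_mean = bl$adjusted_mean,
                 adjusted_cov = bl$adjusted_cov,
                 resolved = bl$resolved, joint_cov = joint,
                 z_peaks = z_peaks, x = disc_sample$x,
                 ellipses = forecast_ellipses(naive_mean, naive_cov,
                                              bl$adjusted_mean,
                                              bl$adjusted_cov)),
            class = "peak_forecast")
}

# per-species (time, mag) mean + 2x2 covariance for naive and adjusted
forecast_ellipses <- function(nm_mean, nm_cov, ad_mean, ad_cov) {
  idx <- list(prey = 1:2, pred = 3:4)
  lapply(idx, function(i)
    list(naive = list(mean = nm_mean[i], cov = nm_cov[i, i]),
         adjusted = list(mean = ad_mean[i], cov = ad_cov[i, i])))
}

#' @export
print.peak_forecast <- function(x, ...) {
  cat("<peak_forecast> second-peak features (time, magnitude per species)\n")
  tab <- rbind(naive = x$naive_mean, adjusted = x$adjusted_mean,
               `naive sd` = sqrt(diag(x$naive_cov)),
               `adjusted sd` = sqrt(diag(x$adjusted_cov)))
  print(round(tab, 3))
  invisible(x)
}

#' Observe the first peak of the reality trajectory
#'
#' Extracts the first-peak features of the (smoothed) reality trajectory
#' and adds independent zero-mean Gaussian observation error with the
#' spec's peak observation sds, mimicking an imperfect peak observation
#' process.
#'
#' @param reality The reality `lv_trajectory`.
#' @param spec A [peak_uncertainty_spec()].
#' @param seed Integer seed.
#' @return Named 4-vector `(prey_time, prey_mag, pred_time, pred_mag)` of
#'   observed first-peak features.
#' @export
observe_first_peak <- function(reality, spec = peak_uncertainty_spec(),
                               seed = 303) {
  pk <- extract_peaks(reality, n_peaks = 1)
  if (!is.null(seed)) set.seed(seed)
  sds <- ifelse(is_time_feature(names(pk)), spec$time_obs_sd,
                spec$mag_obs_sd)
  pk + rnorm(4L, 0, sds)
}
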