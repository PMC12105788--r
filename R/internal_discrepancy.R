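#' Perturbation specification for internal-discrepancy experiments
#'
#' Internal discrepancy is assessed by re-running the simulator under random
#' perturbations of features normally held fixed. Two perturbation sources
#' are implemented, matching the study design:
#' \itemize{
#'   \item initial-condition jitter: initial populations drawn from
#'     `N(2000, 40^2)` (prey) and `N(800, 40^2)` (predator);
#'   \item time-varying rates: the rates are multiplied by the sinusoidal
#'     modulator `g(t) = 1 + c sin(2 pi (t - a) b / T)` with
#'     `a ~ U(4.5, 5.5)`, `b ~ U(0.6, 0.9)`, `c ~ N(0.02, 0.05^2)`,
#'     `T = 10`, drawn independently for each perturbation. By default one
#'     draw is shared by all three rates -- the uncertain judgement being a
#'     common seasonal factor on the reaction rates, mirroring the form of
#'     seasonality in the synthetic real system; with `per_rate = TRUE`
#'     each rate gets its own independent draw instead. Negative
#'     amplitudes are allowed (they flip phase).
#' }
#'
#' @param k Number of perturbations (>= 2 so variances are estimable);
#'   defaults: 200 for `"both"`, 50 for the single-source modes.
#' @param mode Which features vary: `"both"`, `"ic_only"` or `"time_only"`.
#' @param ic_mean,ic_sd Mean vector and common sd of the initial-condition
#'   jitter (counts).
#' @param c_mean,c_sd,a_range,b_range,period Parameters of the sinusoidal
#'   modulator law.
#' @param per_rate Draw an independent modulator per rate instead of one
#'   shared seasonal factor.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(k = NULL,
                              mode = c("both", "ic_only", "time_only"),
                              ic_mean = c(2000, 800), ic_sd = 40,
                              c_mean = 0.02, c_sd = 0.05,
                              a_range = c(4.5, 5.5), b_range = c(0.6, 0.9),
                              period = 10, per_rate = FALSE) {
  mode <- match.arg(mode)
  if (is.null(k)) k <- if (mode == "both") 200L else 50L
  if (k < 2) stop("k must be at least 2 for variance estimation")
  structure(list(k = as.integer(k), mode = mode, ic_mean = ic_mean,
                 ic_sd = ic_sd, c_mean = c_mean, c_sd = c_sd,
                 a_range = a_range, b_range = b_range, period = period,
                 per_rate = isTRUE(per_rate)),
            class = "perturbation_spec")
}

#' Draw a set of perturbations
#'
#' Each perturbation carries a pair of initial conditions and three
#' sinusoidal modulator parameter triples. In `ic_only` mode the modulators
#' are identities; in `time_only` mode the initial conditions stay at the
#' spec's means.
#'
#' @param spec A [perturbation_spec()].
#' @param seed Integer seed.
#' @return List of `k` perturbations, each `list(init, modulators)`.
#' @export
sample_perturbations <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "perturbation_spec"))
  set.seed(seed)
  lapply(seq_len(spec$k), function(i) {
    init <- spec$ic_mean
    if (spec$mode != "time_only")
      init <- rnorm(2L, spec$ic_mean, spec$ic_sd)
    mods <- if (spec$mode == "ic_only") {
      replicate(3L, modulator_identity(), simplify = FALSE)
    } else if (spec$per_rate) {
      lapply(1:3, function(j)
        modulator_sinusoidal(a = runif(1, spec$a_range[1], spec$a_range[2]),
                             b = runif(1, spec$b_range[1], spec$b_range[2]),
                             c = rnorm(1, spec$c_mean, spec$c_sd),
                             period = spec$period))
    } else {
      m <- modulator_sinusoidal(a = runif(1, spec$a_range[1], spec$a_range[2]),
                                b = runif(1, spec$b_range[1], spec$b_range[2]),
                                c = rnorm(1, spec$c_mean, spec$c_sd),
                                period = spec$period)
      list(m, m, m)
    }
    list(init = init, modulators = mods)
  })
}

#' Output maps for discrepancy experiments
#'
#' An output map turns a trajectory into the output vector indexed by `r`
#' over which discrepancy is summarized. `output_map_grid` reads both
#' species at a set of observation times; `output_map_peaks` extracts the
#' timing and magnitude of the first `n_peaks` population peaks of both
#' species (returning `NA`s, rather than failing, when a run has too few
#' peaks, so that failed runs can be counted and dropped downstream).
#'
#' @param times Observation times for the grid map.
#' @param n_peaks Number of peaks for the peak map.
#' @return A function mapping an `lv_trajectory` to a named numeric vector.
#' @export
output_map_grid <- function(times = seq(0, 10, by = 1)) {
  force(times)
  function(traj) {
    v <- trajectory_at(traj, times)
    setNames(c(v[, "prey"], v[, "predator"]),
             c(paste0("prey_t", times), paste0("predator_t", times)))
  }
}

#' @rdname output_map_grid
#' @export
output_map_peaks <- function(n_peaks = 2) {
  force(n_peaks)
  function(traj) {
    out <- tryCatch(extract_peaks(traj, n_peaks = n_peaks),
                    error = function(e) NULL)
    if (is.null(out))
      out <- setNames(rep(NA_real_, 4L * n_peaks), peak_names(n_peaks))
    out
  }
}

#' Run an internal-discrepancy experiment at one input point
#'
#' Evaluates the simulator once unperturbed (the base run) and once per
#' perturbation, applying the same output map to every run. The collection
#' of perturbed outputs is a sample from the internal-discrepancy
#' distribution at `x`.
#'
#' @param x Input point.
#' @param perturbations List from [sample_perturbations()].
#' @param output_map Function trajectory -> named output vector; default the
#'   observation-grid map.
#' @param base_init Unperturbed initial conditions.
#' @param times Solver output grid (dense, so peak maps stay accurate).
#' @param ... Passed to [simulate_lvpp()].
#' @return An object of class `discrepancy_sample`: `base_run` (named
#'   vector), `runs` (`k x R` matrix), `x`, `spec_mode`.
#' @export
run_discrepancy_experiment <- function(x, perturbations,
                                       output_map = output_map_grid(),
                                       base_init = c(2000, 800),
                                       times = seq(0, 10, length.out = 1001),
                                       ...) {
  if (!length(perturbations)) stop("perturbations must be non-empty")
  base <- output_map(simulate_lvpp(x, init = base_init, times = times, ...))
  runs <- matrix(NA_real_, nrow = length(perturbations), ncol = length(base),
                 dimnames = list(NULL, names(base)))
  for (j in seq_along(perturbations)) {
    p <- perturbations[[j]]
    tr <- tryCatch(
      simulate_lvpp(x, init = p$init, times = times,
                    modulators = p$modulators, ...),
      error = function(e)
        stop(sprintf("solver failure at perturbation %d: %s", j,
                     conditionMessage(e))))
    runs[j, ] <- output_map(tr)
  }
  structure(list(base_run = base, runs = runs, x = as_input_point(x),
                 k = length(perturbations)),
            class = "discrepancy_sample")
}

#' Summarize an internal-discrepancy sample
#'
#' Computes, per output `r`, the bias
#' \deqn{B_r(x) = f_r(x) - \frac1k \sum_i f_r(x, d_i),}
#' the sample variance of the perturbed runs (divisor `k - 1`), and the
#' sample correlation matrix across output pairs. Standard errors: bias
#' `sqrt(V_r / k)`; variance `V_r sqrt(2 / (k - 1))` (normal-theory
#' approximation). Outputs constant across runs get flagged `degenerate`;
#' their correlation entries are `NA` by construction rather than
#' propagated NaNs.
#'
#' @param sample A `discrepancy_sample`. Runs with any `NA` output (e.g.
#'   failed peak extraction) are dropped and counted; more than 10% dropped
#'   is an error.
#' @return An object of class `discrepancy_summary` with fields `bias`,
#'   `variance`, `sd`, `correlation`, `k`, `se_bias`, `se_variance`,
#'   `degenerate`, `n_dropped`, `base_run`, `x`.
#' @export
summarize_discrepancy <- function(sample) {
  stopifnot(inherits(sample, "discrepancy_sample"))
  runs <- sample$runs
  ok <- stats::complete.cases(runs)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.10 * nrow(runs))
    stop(sprintf("%d of %d perturbed runs unusable (> 10%%)",
                 n_dropped, nrow(runs)))
  runs <- runs[ok, , drop = FALSE]
  k <- nrow(runs)
  if (k < 2) stop("need at least 2 usable runs")
  m <- colMeans(runs)
  bias <- sample$base_run - m
  variance <- apply(runs, 2L, var)
  degenerate <- variance <= 0
  corr <- suppressWarnings(stats::cor(runs))
  corr[degenerate, ] <- NA_real_
  corr[, degenerate] <- NA_real_
  diag(corr) <- ifelse(degenerate, NA_real_, 1)
  structure(list(bias = bias, variance = variance, sd = sqrt(variance),
                 correlation = corr, k = k,
                 se_bias = sqrt(variance / k),
                 se_variance = variance * sqrt(2 / (k - 1)),
                 degenerate = degenerate, n_dropped = n_dropped,
                 base_run = sample$base_run, x = sample$x),
            class = "discrepancy_summary")
}

#' @export
print.discrepancy_summary <- function(x, ...) {
  cat(sprintf("<discrepancy_summary> k=%d runs, %d outputs (%d degenerate)\n",
              x$k, length(x$bias), sum(x$degenerate)))
  cat("  |bias| range:", signif(range(abs(x$bias)), 3),
      "  sd range:", signif(range(x$sd), 3), "\n")
  invisible(x)
}

#' Internal-discrepancy mean implied by the bias summary
#'
#' The bias is defined base-run-minus-perturbation-mean, so the mean of the
#' internal discrepancy (perturbed output minus base output) is its
#' negative. All sign bookkeeping between the bias summary and the
#' discrepancy mean used in implausibility and forecasting goes through
#' this one function.
#'
#' @param bias Bias vector `B_r(x)`.
#' @return `-bias`, the discrepancy mean `E[eps*]`.
#' @export
discrepancy_mean_from_bias <- function(bias) -bias

#' Pool-or-emulate decision across input points
#'
#' Compares discrepancy summaries across input points. If the summaries are
#' very similar (the relative spread of the discrepancy sd across points
#' stays below `threshold` for every informative output), averaging them is
#' a practical working choice ("pool"); otherwise the fields should be
#' emulated over the input space ("emulate").
#'
#' @param summaries List (length >= 2) of `discrepancy_summary` at distinct
#'   input points.
#' @param threshold Maximum allowed coefficient of variation of the sd
#'   field across points (default 0.1).
#' @return List with `decision` ("pool" or "emulate"), the per-output
#'   diagnostic `table`, and `pooled` (the averaged bias/variance) when
#'   pooling.
#' @export
pooled_or_varying <- function(summaries, threshold = 0.1) {
  if (length(summaries) < 2)
    stop("need summaries at >= 2 input points to compare")
  sds <- do.call(rbind, lapply(summaries, `[[`, "sd"))
  biases <- do.call(rbind, lapply(summaries, `[[`, "bias"))
  mean_sd <- colMeans(sds)
  spread <- apply(sds, 2L, sd)
  cv <- ifelse(mean_sd > 0, spread / mean_sd, 0)
  tab <- data.frame(output = colnames(sds), mean_sd = mean_sd,
                    sd_of_sd = spread, cv = cv, row.names = NULL)
  decision <- if (max(cv) <= threshold) "pool" else "emulate"
  pooled <- NULL
  if (decision == "pool")
    pooled <- list(bias = colMeans(biases), sd = mean_sd,
                   variance = colMeans(sds^2))
  list(decision = decision, table = tab, pooled = pooled)
}

#' Decompose internal discrepancy into its sources at one input point
#'
#' Runs the three experiments of the study design at `x`: initial
#' conditions only, time-varying rates only, and both jointly. The joint
#' experiment is the authoritative total; the single-source experiments
#' give the component decomposition, combined in quadrature when a
#' decomposed total is reported.
#'
#' @param x Input point.
#' @param n_ic,n_time,n_both Perturbation counts (defaults 50, 50, 200).
#' @param seed Base seed; the three experiments use distinct derived seeds.
#' @param output_map Output map shared by all runs.
#' @param ... Passed to [run_discrepancy_experiment()].
#' @return List of `discrepancy_summary`: `ic`, `time`, `both`, plus
#'   `samples` (the raw samples).
#' @export
discrepancy_components <- function(x, n_ic = 50, n_time = 50, n_both = 200,
                                   seed = 1, output_map = output_map_grid(),
                                   ...) {
  perts <- list(
    ic = sample_perturbations(perturbation_spec(n_ic, "ic_only"),
                              seed = seed + 1L),
    time = sample_perturbations(perturbation_spec(n_time, "time_only"),
                                seed = seed + 2L),
    both = sample_perturbations(perturbation_spec(n_both, "both"),
                                seed = seed + 3L))
  samples <- lapply(perts, function(p)
    run_discrepancy_experiment(x, p, output_map = output_map, ...))
  out <- lapply(samples, summarize_discrepancy)
  out$samples <- samples
  out
}
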