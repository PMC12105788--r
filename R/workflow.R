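# combined output map: observation-grid values plus peak features from the
# same dense trajectory, so one experiment serves matching and forecasting
output_map_combined <- function(times = seq(0, 10, by = 1), n_peaks = 2) {
  gm <- output_map_grid(times)
  pm <- output_map_peaks(n_peaks)
  function(traj) c(gm(traj), pm(traj))
}

# restrict a discrepancy sample to a subset of output columns
subset_discrepancy_sample <- function(sample, cols) {
  structure(list(base_run = sample$base_run[cols],
                 runs = sample$runs[, cols, drop = FALSE],
                 x = sample$x, k = sample$k),
            class = "discrepancy_sample")
}

# simulator outputs on the observation grid for one input point
run_on_grid <- function(x, times = seq(0, 10, by = 1), ...) {
  output_map_grid(times)(simulate_lvpp(x, times = times, ...))
}

#' Workflow configuration
#'
#' All tunable settings of the end-to-end demonstration, with every default
#' equal to the study value where one exists: 750 wave-1 runs over the
#' default ranges, pseudo-reality from a Gillespie run at `(1910, 710)`
#' with the quadratic seasonal modulator, observation error sd 50,
#' history cutoff 5, cautious 15% discrepancy, threshold 3, perturbation
#' counts 50/50/200, nominal 2% external discrepancy, and 750 wave-3
#' candidate draws.
#'
#' @param n_wave1 Wave-1 design size.
#' @param ranges Input ranges.
#' @param threshold Maximum-implausibility retention threshold.
#' @param fractional,external Cautious and nominal external fractional
#'   discrepancy sds.
#' @param sigma_e Observation-error sd (counts).
#' @param history_cutoff Present-day time.
#' @param obs_times Observation times.
#' @param n_ic,n_time,n_both Perturbation counts for the three experiment
#'   modes.
#' @param n_wave3_candidates Candidate draws for the refocusing stage.
#' @param reality_init Initial populations of the reality generator.
#' @param seed Base seed; independent named streams for each stage are
#'   derived from it so one stage can be re-run without perturbing others.
#' @return A `workflow_config` list.
#' @export
workflow_config <- function(n_wave1 = 750, ranges = lvpp_ranges(),
                            threshold = 3, fractional = 0.15,
                            external = 0.02, sigma_e = 50,
                            history_cutoff = 5,
                            obs_times = seq(0, 10, by = 1),
                            n_ic = 50, n_time = 50, n_both = 200,
                            n_wave3_candidates = 750,
                            reality_init = c(1910, 710), seed = 1) {
  structure(list(n_wave1 = n_wave1, ranges = ranges, threshold = threshold,
                 fractional = fractional, external = external,
                 sigma_e = sigma_e, history_cutoff = history_cutoff,
                 obs_times = obs_times, n_ic = n_ic, n_time = n_time,
                 n_both = n_both, n_wave3_candidates = n_wave3_candidates,
                 reality_init = reality_init, seed = seed,
                 seeds = derive_seeds(seed)),
            class = "workflow_config")
}

# independent named seed streams derived from the base seed (kept < 2^31)
derive_seeds <- function(seed) {
  base <- as.integer(seed) %% 100000L
  list(design = base * 13L + 1L, reality = base * 13L + 2L,
       noise = base * 13L + 3L, perturbations = base * 13L + 4L,
       candidates = base * 13L + 5L, peak_obs = base * 13L + 6L)
}

#' Validate a workflow configuration
#'
#' Checks ranges, positivity and estimability constraints, and lists every
#' setting that differs from its study default.
#'
#' @param config A [workflow_config()].
#' @return List with `problems` (character) and `differs_from_default`
#'   (character); both empty for the default configuration.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  ok_ranges <- tryCatch({ check_ranges(config$ranges); TRUE },
                        error = function(e) FALSE)
  if (!ok_ranges) problems <- c(problems, "invalid ranges")
  if (config$threshold <= 0)
    problems <- c(problems, "threshold must be positive")
  if (min(config$n_ic, config$n_time, config$n_both) < 2)
    problems <- c(problems,
                  "perturbation counts must be >= 2 (variance undefined)")
  if (config$sigma_e <= 0) problems <- c(problems, "sigma_e must be positive")
  if (config$n_wave1 < 2) problems <- c(problems, "n_wave1 must be >= 2")

  ref <- workflow_config(seed = config$seed)
  keys <- c("n_wave1", "threshold", "fractional", "external", "sigma_e",
            "history_cutoff", "n_ic", "n_time", "n_both",
            "n_wave3_candidates")
  differs <- keys[vapply(keys, function(k)
    !isTRUE(all.equal(config[[k]], ref[[k]])), logical(1))]
  if (!isTRUE(all.equal(config$ranges, ref$ranges)))
    differs <- c(differs, "ranges")
  if (!isTRUE(all.equal(config$reality_init, ref$reality_init)))
    differs <- c(differs, "reality_init")
  list(problems = problems, differs_from_default = differs)
}

#' Run the full structural-discrepancy demonstration
#'
#' Executes the workflow end to end: generate the pseudo-reality and noisy
#' observations; design and run wave 1; history-match with the cautious
#' fractional discrepancy; run internal-discrepancy experiments (one shared
#' perturbation set, common random numbers) at every retained wave-2 point;
#' decompose the discrepancy at the wave-2 test point; emulate the bias and
#' sd fields; refocus to a wave-3 candidate set under the structured
#' discrepancy; and produce naive and Bayes-linear-adjusted second-peak
#' forecasts at each retained point. Fully reproducible from the
#' configuration's seed streams.
#'
#' @param config A [workflow_config()].
#' @param out_dir Optional directory: when given, every intermediate
#'   artifact is written as CSV/JSON plus a JSON manifest.
#' @param verbose Print per-stage progress.
#' @return Invisible list with all stage artifacts and a `manifest`.
#' @export
run_demo <- function(config = workflow_config(), out_dir = NULL,
                     verbose = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) if (verbose) message(sprintf(...))
  stage_t <- c()
  tick <- function(nm) {
    stage_t[[nm]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }
  val <- validate_config(config)
  if (length(val$problems))
    stop("invalid config: ", paste(val$problems, collapse = "; "))
  s <- config$seeds

  say("stage 1: pseudo-reality and observations")
  reality <- make_reality(init = config$reality_init, seed = s$reality)
  obs <- make_observations(reality, obs_times = config$obs_times,
                           sigma_e = config$sigma_e, seed = s$noise,
                           history_cutoff = config$history_cutoff)
  tick("reality")

  say("stage 2: wave-1 design and runs (n = %d)", config$n_wave1)
  design1 <- maximin_lhs(config$n_wave1, config$ranges, seed = s$design)
  runs1 <- t(apply(design1, 1L, run_on_grid, times = config$obs_times))
  tick("wave1_runs")

  say("stage 3: wave-1 history match (cautious %.0f%% discrepancy)",
      100 * config$fractional)
  disc1 <- discrepancy_spec("fractional", fractional = config$fractional)
  wave1 <- classify_wave(design1, runs1, obs, disc1,
                         threshold = config$threshold)
  retained <- as.data.frame(wave1[wave1$retained, names(config$ranges)])
  say("  retained %d / %d points", nrow(retained), config$n_wave1)
  if (!nrow(retained))
    stop("refocusing aborted: wave-2 retained set is empty; ",
         "review the discrepancy specification or threshold")
  tick("wave1_match")

  # wave-2 test point: retained point with the smallest maximum
  # implausibility (a representative good match)
  test_idx <- which(wave1$retained)[which.min(wave1$i_max[wave1$retained])]
  test_point <- as.numeric(design1[test_idx, ])

  say("stage 4: discrepancy decomposition at the wave-2 test point")
  comps <- discrepancy_components(test_point, n_ic = config$n_ic,
                                  n_time = config$n_time,
                                  n_both = config$n_both,
                                  seed = s$perturbations,
                                  output_map = output_map_grid(config$obs_times))
  tick("components")

  say("stage 5: internal-discrepancy experiments at %d retained points",
      nrow(retained))
  perts <- sample_perturbations(perturbation_spec(config$n_both, "both"),
                                seed = s$perturbations)
  omap <- output_map_combined(config$obs_times)
  grid_cols <- seq_len(2L * length(config$obs_times))
  peak_cols <- 2L * length(config$obs_times) + 1:8
  samples <- lapply(seq_len(nrow(retained)), function(i)
    run_discrepancy_experiment(as.numeric(retained[i, ]), perts,
                               output_map = omap))
  summaries <- lapply(samples, function(sm)
    summarize_discrepancy(subset_discrepancy_sample(sm, grid_cols)))
  tick("experiments")

  say("stage 6: emulate bias and sd fields over the retained points")
  pool <- pooled_or_varying(summaries)
  # the emulated fields feed the refined (structured) history match, which
  # conditions on the historical outputs only, so those are the targets
  ht <- config$obs_times <= config$history_cutoff
  hist_cols <- c(paste0("prey_t", config$obs_times[ht]),
                 paste0("predator_t", config$obs_times[ht]))
  bias_resp <- do.call(rbind,
                       lapply(summaries, function(s) s$bias[hist_cols]))
  sd_resp <- do.call(rbind, lapply(summaries, function(s) s$sd[hist_cols]))
  design2 <- structure(retained, ranges = config$ranges, wave = 2L)
  bias_em <- fit_linear_emulator(design2, bias_resp, config$ranges)
  sd_em <- fit_linear_emulator(design2, sd_resp, config$ranges)
  nondeg <- !(bias_em$degenerate | sd_em$degenerate)
  r2_min <- min(bias_em$r_squared[nondeg], sd_em$r_squared[nondeg])
  say("  min R^2 over informative outputs: %.3f", r2_min)
  tick("emulation")

  say("stage 7: refocus to wave-3 candidates under structured discrepancy")
  disc2 <- discrepancy_spec("structured", external = config$external,
                            bias_em = bias_em, sd_em = sd_em)
  wave3 <- tryCatch(
    refocus(wave1, disc2, obs,
            function(p) run_on_grid(p, times = config$obs_times),
            n_target = config$n_wave3_candidates,
            threshold = config$threshold, seed = s$candidates,
            max_draws = config$n_wave3_candidates),
    error = function(e) { say("  refocus: %s", conditionMessage(e)); NULL })
  tick("refocus")

  say("stage 8: second-peak forecasts at the retained points")
  pspec <- peak_uncertainty_spec()
  z_peaks <- observe_first_peak(reality, pspec, seed = s$peak_obs)
  true_peaks <- extract_peaks(reality, n_peaks = 2)
  forecasts <- list()
  skipped <- 0L
  for (i in seq_len(nrow(retained))) {
    psample <- subset_discrepancy_sample(samples[[i]], peak_cols)
    if (any(is.na(psample$base_run))) { skipped <- skipped + 1L; next }
    fc <- tryCatch(forecast_second_peak(psample, pspec, z_peaks),
                   error = function(e) NULL)
    if (is.null(fc)) skipped <- skipped + 1L else
      forecasts[[length(forecasts) + 1L]] <- fc
  }
  fc_stats <- forecast_improvement(forecasts, true_peaks[5:8])
  tick("forecasts")

  manifest <- list(
    n_wave1 = config$n_wave1, n_retained = nrow(retained),
    test_point = test_point, pool_decision = pool$decision,
    r2_min = r2_min,
    n_degenerate_outputs = sum(!nondeg),
    n_wave3 = if (is.null(wave3)) 0L else nrow(wave3),
    n_forecasts = length(forecasts), n_forecast_skipped = skipped,
    mse_naive = fc_stats$mse_naive, mse_adjusted = fc_stats$mse_adjusted,
    seeds = s, stage_seconds = as.list(stage_t))

  result <- list(config = config, reality = reality, obs = obs,
                 design1 = design1, runs1 = runs1, wave1 = wave1,
                 retained = retained, test_point = test_point,
                 components = comps, samples = samples,
                 summaries = summaries, bias_em = bias_em, sd_em = sd_em,
                 disc2 = disc2, wave3 = wave3, z_peaks = z_peaks,
                 true_peaks = true_peaks, forecasts = forecasts,
                 manifest = manifest)
  if (!is.null(out_dir)) write_demo_artifacts(result, out_dir)
  say("done: %d retained, min R^2 %.3f, forecast MSE %.1f -> %.1f",
      nrow(retained), r2_min, fc_stats$mse_naive, fc_stats$mse_adjusted)
  invisible(result)
}

# mean squared distance (standardized per feature class) of naive and
# adjusted forecast means to the true second-peak vector
forecast_improvement <- function(forecasts, truth) {
  if (!length(forecasts))
    return(list(mse_naive = NA_real_, mse_adjusted = NA_real_))
  # times and magnitudes live on different scales; standardize by the
  # spread of the truth-relative naive errors so both contribute
  nv <- t(vapply(forecasts, `[[`, numeric(4), "naive_mean"))
  ad <- t(vapply(forecasts, `[[`, numeric(4), "adjusted_mean"))
  scale <- pmax(apply(sweep(nv, 2L, truth), 2L, function(e) sqrt(mean(e^2))),
                1e-12)
  mse <- function(m) mean(sweep(sweep(m, 2L, truth), 2L, scale, `/`)^2)
  list(mse_naive = mse(nv), mse_adjusted = mse(ad))
}

write_demo_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(nm) file.path(out_dir, nm)
  write_trajectory(result$reality, fp("reality.csv"))
  write_observations(result$obs, fp("observations.csv"))
  d1 <- as.data.frame(result$design1)
  d1$wave <- 1L
  write.csv(d1, fp("design_wave1.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$wave1), fp("wave1_results.csv"),
            row.names = FALSE)
  write.csv(result$retained, fp("design_wave2.csv"), row.names = FALSE)
  if (!is.null(result$wave3))
    write.csv(as.data.frame(result$wave3), fp("design_wave3.csv"),
              row.names = FALSE)
  long <- do.call(rbind, lapply(seq_along(result$summaries), function(i) {
    sm <- result$summaries[[i]]
    data.frame(x_id = i, output = names(sm$bias), bias = unname(sm$bias),
               sd = unname(sm$sd), se_bias = unname(sm$se_bias))
  }))
  write.csv(long, fp("discrepancy_summaries.csv"), row.names = FALSE)
  jsonlite::write_json(emulator_to_list(result$bias_em),
                       fp("bias_emulator.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(emulator_to_list(result$sd_em),
                       fp("sd_emulator.json"), auto_unbox = TRUE,
                       digits = NA)
  fc <- lapply(result$forecasts, function(f)
    list(x = f$x, naive_mean = as.list(f$naive_mean),
         adjusted_mean = as.list(f$adjusted_mean),
         naive_var = as.list(diag(f$naive_cov)),
         adjusted_var = as.list(diag(f$adjusted_cov))))
  jsonlite::write_json(fc, fp("forecasts.json"), digits = NA)
  jsonlite::write_json(result$manifest, fp("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# serializable second-order summary of a linear emulator
emulator_to_list <- function(em) {
  list(basis = rownames(em$coefficients),
       coefficients = as.data.frame(em$coefficients),
       sigma2 = as.list(em$sigma2), r_squared = as.list(em$r_squared),
       ranges = em$ranges, n = em$n)
}
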