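# shared fixtures; heavy artifacts are computed once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# the full default-configuration study, shared by the acceptance tests
demo_result <- function() {
  if (is.null(.fixtures$demo))
    .fixtures$demo <- run_demo(workflow_config(seed = 1), verbose = FALSE)
  .fixtures$demo
}

# a mid-region input point used by unit tests
mid_x <- function() c(1.0, 4e-4, 1.8)

# build a discrepancy_sample directly from a runs matrix (oracle fixtures)
fake_sample <- function(base, runs, x = mid_x()) {
  structure(list(base_run = base, runs = runs, x = x, k = nrow(runs)),
            class = "discrepancy_sample")
}

historical_names <- function(times = 0:5)
  c(paste0("prey_t", times), paste0("predator_t", times))

eval_modulator_for_test <- function(m, t) strucdisc:::eval_modulator(m, t)
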