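# Shared machinery for the simulation-based acceptance experiments.
#
# Estimator-property experiments (parameter recovery, profile-CI coverage,
# LRT calibration) run under verification-equivalent observation conditions:
# 70% marker calling but no false calls and no candidate triage
# (min_gc_markers = 1), the sampling process the likelihood models — in the
# study every candidate event was resolved by resequencing before fitting.
# The detection-sensitivity experiment uses the full default observation
# model (false calls + triage) because it tests the pipeline itself.

study_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_marker_map(seed = 101)
    cache
  }
})

small_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_marker_map(n_markers = 31179,
                                    chromosome_length = 7.466e6, seed = 103)
    }
    cache
  }
})

fit_verified_dataset <- function(map, seed, dsb_rate = 1.8e-8,
                                 grid = c(30, 30)) {
  params <- meiosis_params(seed = seed, nco_dsb_rate = dsb_rate,
                           false_call_rate = 0)
  sim <- simulate_meiosis(map, params)
  ev <- detect_events(map, sim$calls, min_gc_markers = 1)
  gcml(ev$spans, ev$conversions, grid_size = grid)
}

substream_seed_test <- function(i) 424243L + 7919L * as.integer(i)

lambda_ci_covers <- function(fit, truth) {
  ci <- suppressWarnings(confint(fit, "lambda"))
  lo <- if (is.na(ci[1, 1])) 0 else ci[1, 1]
  hi <- if (is.na(ci[1, 2])) Inf else ci[1, 2]
  lo <= truth && truth <= hi
}
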