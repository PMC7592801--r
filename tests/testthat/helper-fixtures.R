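# lazily built, memoized fixtures shared across test files

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# noise-free level-walking trial at a desk-scale rate
fix_trial <- function() {
  memo("trial", function()
    generate_trial(participant_spec(), condition_spec(0, 0),
                   n_strides = 4, noise_sd = 0, seed = 1, fs = 500))
}

# truth-known trial plus its ground-truth parameters and geometry
fix_truth <- function() {
  memo("truth", function() {
    params <- default_muscle_params()
    geometry <- default_geometry(params)
    tt <- generate_truth_trial(params, participant_spec(), seed = 3,
                               fs = 100, n_strides = 3,
                               geometry = geometry)
    list(params = params, geometry = geometry, trial = tt$trial,
         reference = tt$reference_moments)
  })
}

# muscle states simulated on the fixture trial (decimated for speed)
fix_sim <- function() {
  memo("sim", function() simulate_muscles(fix_trial(), fs_sim = 250))
}

# minimal metabolic profile around a given total series
new_profile_for_test <- function(total, grid) {
  n <- length(total)
  stridemet:::new_metabolic_profile(
    grid, total,
    sources = matrix(total, n, 1, dimnames = list(NULL, "all")),
    components = matrix(total, n, 1,
                        dimnames = list(NULL, "activation_maintenance")),
    groups = matrix(total, n, 1, dimnames = list(NULL, "all")),
    source_type = "muscle")
}

# full parameter-recovery calibration from a uniformly perturbed start;
# shared between the module tests and the acceptance suite
fix_recovery <- function() {
  memo("recovery", function() {
    tt <- fix_truth()
    start <- tt$params
    start$l_opt <- start$l_opt * 1.2
    start$l_slack <- start$l_slack * 1.2
    res <- calibrate_trial(tt$trial, params0 = start,
                           reference_moments = tt$reference,
                           geometry = tt$geometry)
    list(result = res, truth = tt$params, start = start)
  })
}
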