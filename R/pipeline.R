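# Trial-level pipelines: EMG-driven muscle simulation, the two metabolic
# estimators, and the cohort-level study runner.

model_muscles <- function() default_muscle_params()$muscle

# EMG channel feeding each model muscle; the lateral gastrocnemius is
# driven by the medial gastrocnemius recording
emg_channel_map <- function() {
  m <- model_muscles()
  stats::setNames(ifelse(m == "gastrocnemius_lateralis",
                         "gastrocnemius_medialis", m), m)
}

#' EMG-driven muscle-tendon simulation of a gait trial
#'
#' Normalizes the trial's EMG envelopes by MVC, passes them through
#' activation dynamics, prescribes the muscle-tendon lengths from the joint
#' kinematics, and integrates every modeled muscle's state over the trial.
#' The first `warmup_strides` strides serve to wash out the default
#' initial state and are excluded from `eval_idx`.
#'
#' @param trial a `gait_trial`.
#' @param params muscle-parameter table.
#' @param geometry muscle geometry.
#' @param curves Hill-curve constants.
#' @param fs_sim target sampling rate (integer divisor of the trial rate);
#'   `NULL` keeps the trial rate.
#' @param warmup_strides strides discarded from evaluation.
#' @param tau_act,tau_deact activation dynamics time constants, s.
#' @return list with `states` (per muscle), `excitations`, `activations`,
#'   `joint_angles`, `fs`, `events`, `eval_idx`, `eval_strides`.
#' @export
simulate_muscles <- function(trial, params = default_muscle_params(),
                             geometry = default_geometry(params),
                             curves = hill_curves(), fs_sim = NULL,
                             warmup_strides = 2, tau_act = 0.015,
                             tau_deact = 0.060) {
  if (!is.null(fs_sim)) trial <- decimate_trial(trial, fs_sim)
  fs <- trial$fs
  cmap <- emg_channel_map()
  missing_ch <- setdiff(unique(cmap), colnames(trial$emg))
  if (length(missing_ch) > 0)
    stop("trial EMG is missing channels: ",
         paste(missing_ch, collapse = ", "))
  excitations <- list()
  activations <- list()
  states <- list()
  for (m in params$muscle) {
    ch <- cmap[[m]]
    exc <- normalize_emg(trial$emg[, ch], trial$participant$mvc[[ch]])
    act <- activation_dynamics(exc, fs, tau_act, tau_deact)
    mt <- muscle_tendon_length(trial$joint_angles, geometry, m)
    st <- integrate_muscle_state(act, mt$l_mt,
                                 params[params$muscle == m, , drop = FALSE],
                                 fs, curves)
    excitations[[m]] <- exc
    activations[[m]] <- act
    states[[m]] <- st
  }
  ev <- trial$events
  if (is.null(ev))
    ev <- detect_strides(filter_grf(trial$grf_ipsi, fs),
                         filter_grf(trial$grf_contra, fs), fs)
  hs <- ev$ipsi_heel_strikes
  if (warmup_strides + 1 > trial$n_strides)
    stop("not enough strides for the requested warm-up")
  eval_strides <- (warmup_strides + 1):trial$n_strides
  first_eval <- hs[warmup_strides + 1]
  eval_idx <- first_eval:length(trial$time)
  list(states = states, excitations = excitations,
       activations = activations, joint_angles = trial$joint_angles,
       fs = fs, events = ev, eval_idx = eval_idx,
       eval_strides = eval_strides, trial = trial)
}

stride_bounds <- function(trial, k) {
  # sample indices [start, end] of stride k; the closing bound is the next
  # heel strike (or the periodic wrap for the final stride)
  hs <- trial$events$ipsi_heel_strikes
  s0 <- hs[k]
  s1 <- if (k + 1 <= length(hs)) hs[k + 1] else s0 + trial$samples_per_stride
  c(s0, min(s1, length(trial$time)))
}

mean_phase_bounds <- function(trial, strides) {
  ev <- trial$events
  parts <- lapply(strides, function(k)
    tryCatch(partition_phases(ev, k), error = function(e) NULL))
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0) stop("no complete stride with all gait events")
  out <- parts[[1]]
  out$start <- rowMeans(sapply(parts, `[[`, "start"))
  out$end <- rowMeans(sapply(parts, `[[`, "end"))
  out
}

normalize_over_strides <- function(series, trial, strides, n_points) {
  profs <- sapply(strides, function(k) {
    b <- stride_bounds(trial, k)
    time_normalize(series, b, n_points)
  })
  rowMeans(profs)
}

#' Musculoskeletal estimate of the metabolic-rate time profile
#'
#' Full EMG-driven pipeline: muscle simulation, muscle metabolic rate
#' (activation-maintenance heat, shortening-lengthening heat, fiber work,
#' clamped at zero per muscle), stride time-normalization, and aggregation
#' into the right-limb profile.
#'
#' @param trial a `gait_trial`.
#' @param params muscle-parameter table (calibrated, ideally).
#' @param geometry,curves,coeffs model configuration.
#' @param n_points stride-grid length.
#' @param fs_sim,warmup_strides forwarded to [simulate_muscles()].
#' @return list with `profile` (a `metabolic_profile`), `phases`
#'   (`phase_bounds`), and `stride_average` (W kg^-1).
#' @export
estimate_musculoskeletal <- function(trial,
                                     params = default_muscle_params(),
                                     geometry = default_geometry(params),
                                     curves = hill_curves(),
                                     coeffs = energetics_coefficients(),
                                     n_points = 1001, fs_sim = NULL,
                                     warmup_strides = 2) {
  sim <- simulate_muscles(trial, params, geometry, curves, fs_sim,
                          warmup_strides)
  tr <- sim$trial
  rates <- muscle_rates_from_states(sim$states, sim$excitations, params,
                                    tr$participant$body_mass,
                                    coeffs, curves)
  grid <- seq(0, 100, length.out = n_points)
  per_muscle <- lapply(rates, function(r) {
    lapply(r[c("total", "activation_maintenance", "shortening_lengthening",
               "fiber_work")],
           normalize_over_strides, trial = tr, strides = sim$eval_strides,
           n_points = n_points)
  })
  profile <- limb_profile(per_muscle, grid)
  phases <- mean_phase_bounds(tr, sim$eval_strides)
  list(profile = profile, phases = phases,
       stride_average = stride_average(profile))
}

#' Joint-space estimate of the metabolic-rate time profile
#'
#' Joint angular velocities are differentiated from the joint angles;
#' together with the joint moments they drive the joint-space metabolic
#' equations for the right side (contralateral channels masked to zero).
#' Rates are computed at the trial rate, then stride-normalized and
#' averaged over the evaluated strides.
#'
#' @param trial a `gait_trial`.
#' @param coeffs joint-space coefficient set.
#' @param n_points stride-grid length.
#' @param warmup_strides strides discarded from evaluation.
#' @return list with `profile`, `phases`, `stride_average`, and
#'   `group_shares` (moment-direction partition, percent).
#' @export
estimate_jointspace <- function(trial, coeffs = jointspace_coefficients(),
                                n_points = 1001, warmup_strides = 2) {
  fs <- trial$fs
  ang <- trial$joint_angles
  n <- nrow(ang)
  omega <- apply(ang, 2, function(a)
    c(a[2] - a[1], (a[3:n] - a[1:(n - 2)]) / 2, a[n] - a[n - 1]) * fs)
  mom <- trial$joint_moments
  colnames(mom) <- paste0(colnames(trial$joint_moments), "_right")
  colnames(omega) <- colnames(mom)
  inputs <- unilateral_mask(joint_inputs(mom, omega), "right")
  raw <- jointspace_rate(inputs, coeffs)
  eval_strides <- (warmup_strides + 1):trial$n_strides
  grid <- seq(0, 100, length.out = n_points)
  nrm <- function(x) normalize_over_strides(x, trial, eval_strides, n_points)
  profile <- new_metabolic_profile(
    grid,
    total = nrm(raw$total),
    sources = apply(raw$sources, 2, nrm),
    components = apply(raw$components, 2, nrm),
    groups = apply(raw$groups, 2, nrm),
    source_type = "joint")
  phases <- mean_phase_bounds(trial, eval_strides)
  list(profile = profile, phases = phases,
       stride_average = stride_average(profile),
       group_shares = group_shares(profile))
}

calorimetry_rate <- function(trial) {
  net_metabolic_rate(trial$gas$vo2, trial$gas$vco2,
                     trial$gas$standing_rate,
                     trial$participant$body_mass)
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Generates a cohort, optionally calibrates each participant's muscle
#' length parameters on their baseline trial, estimates the metabolic-rate
#' time profile of every trial with both methods, summarizes stride and
#' phase averages, and runs the method-comparison statistics.
#'
#' @param n_participants cohort size.
#' @param seed integer seed for the cohort.
#' @param conditions list of conditions.
#' @param noise_sd trial noise level.
#' @param n_strides strides per trial.
#' @param fs trial sampling rate, Hz.
#' @param calibrate if `TRUE`, run the pattern-search calibration per
#'   participant before estimating.
#' @param config calibration configuration.
#' @param n_points stride-grid length for the profiles.
#' @param fs_sim muscle-simulation rate (integer divisor of `fs`).
#' @return list with `summaries` (tidy data.frame), `stats` (from
#'   [compare_methods()]), `calibrated` (per-participant parameter tables,
#'   if calibrated), and `baseline_profiles` (per-method mean baseline
#'   profile and phase bounds).
#' @export
run_study <- function(n_participants = 6, seed = 1,
                      conditions = study_conditions(), noise_sd = 0.05,
                      n_strides = 5, fs = 2000, calibrate = FALSE,
                      config = calibration_config(), n_points = 501,
                      fs_sim = 200) {
  trials <- generate_cohort(n_participants, conditions, seed,
                            n_strides = n_strides, noise_sd = noise_sd,
                            fs = fs)
  pid <- vapply(trials, function(t) t$participant$id, "")
  cid <- vapply(trials, function(t) condition_id(t$condition), "")
  calibrated <- list()
  params_for <- function(p) {
    if (!is.null(calibrated[[p]])) calibrated[[p]] else
      default_muscle_params()
  }
  if (calibrate) {
    for (p in unique(pid)) {
      base_trial <- trials[[which(pid == p & cid == "baseline")[1]]]
      res <- calibrate_trial(base_trial, config = config)
      calibrated[[p]] <- res$params
    }
  }
  rows <- list()
  profs <- list(musculoskeletal = list(), jointspace = list())
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    msk <- estimate_musculoskeletal(tr, params = params_for(pid[i]),
                                    n_points = n_points, fs_sim = fs_sim)
    js <- estimate_jointspace(tr, n_points = n_points)
    cal <- calorimetry_rate(tr)
    for (est in list(list(m = "musculoskeletal", e = msk),
                     list(m = "jointspace", e = js))) {
      pa <- phase_average(est$e$profile, est$e$phases)
      rows[[length(rows) + 1]] <- data.frame(
        participant = pid[i], condition = cid[i], method = est$m,
        stride_average = est$e$stride_average,
        t(pa$phase_means), t(pa$phase_shares) |>
          `colnames<-`(paste0("share_", names(pa$phase_shares))),
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      participant = pid[i], condition = cid[i], method = "calorimetry",
      stride_average = cal, ds1 = NA, ss = NA, ds2 = NA, swing = NA,
      share_ds1 = NA, share_ss = NA, share_ds2 = NA, share_swing = NA,
      stringsAsFactors = FALSE)
    if (cid[i] == "baseline") {
      profs$musculoskeletal[[pid[i]]] <- msk
      profs$jointspace[[pid[i]]] <- js
    }
  }
  summaries <- do.call(rbind, rows)
  stats <- compare_methods(summaries)
  baseline_profiles <- lapply(profs, function(lst) {
    tot <- rowMeans(sapply(lst, function(e) e$profile$total))
    groups <- Reduce(`+`, lapply(lst, function(e) e$profile$groups)) /
      length(lst)
    phases <- lst[[1]]$phases
    phases$start <- rowMeans(sapply(lst, function(e) e$phases$start))
    phases$end <- rowMeans(sapply(lst, function(e) e$phases$end))
    grid <- lst[[1]]$profile$stride_grid
    prof <- new_metabolic_profile(grid, tot,
                                  sources = sapply(lst, function(e)
                                    e$profile$total),
                                  components = lst[[1]]$profile$components,
                                  groups = groups,
                                  source_type = lst[[1]]$profile$source_type)
    list(profile = prof, phases = phases)
  })
  list(summaries = summaries, stats = stats, calibrated = calibrated,
       baseline_profiles = baseline_profiles)
}
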