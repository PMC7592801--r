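# Per-participant calibration of tendon slack length and optimal fiber
# length by generalized pattern search against reference joint moments.

#' Calibration configuration
#'
#' Penalty weights and search controls for the muscle-parameter
#' calibration.  The three penalty weights are large (1e6) so that any
#' active penalty dominates the moment errors and the search moves quickly
#' into the penalty-free region.
#'
#' @param c1 weight of the zero-force penalty.
#' @param c2 weight of the plantarflexor-distribution penalty.
#' @param c3 weight of the physiological-range penalty.
#' @param bounds_fraction lower/upper box bounds as fractions of the
#'   starting parameter values.
#' @param improvement_tol cost-improvement termination tolerance.
#' @param max_iterations poll-iteration cap.
#' @param zero_force_eps tendon force below which a muscle counts as
#'   producing no force, N.
#' @param fs_calibration sample rate the trial is decimated to for the
#'   search, Hz (the input signals are 6 Hz band-limited).
#' @param mesh0 initial relative mesh size.
#' @param eval_budget total cost-evaluation budget of one calibration run
#'   (bounds the wall time on noisy fits where the search keeps finding
#'   marginal improvements).
#' @return a `calibration_config` list.
#' @export
calibration_config <- function(c1 = 1e6, c2 = 1e6, c3 = 1e6,
                               bounds_fraction = c(0.5, 1.5),
                               improvement_tol = 1e-6,
                               max_iterations = 300,
                               zero_force_eps = 1,
                               fs_calibration = 100,
                               mesh0 = 0.10,
                               eval_budget = 6000) {
  if (any(c(c1, c2, c3) <= 0)) stop("penalty weights must be positive")
  if (!(bounds_fraction[1] > 0 && bounds_fraction[1] < 1 &&
        bounds_fraction[2] > 1))
    stop("bounds_fraction must bracket 1")
  list(c1 = c1, c2 = c2, c3 = c3, bounds_fraction = bounds_fraction,
       improvement_tol = improvement_tol, max_iterations = max_iterations,
       zero_force_eps = zero_force_eps, fs_calibration = fs_calibration,
       mesh0 = mesh0, eval_budget = eval_budget)
}

#' Count muscles whose tendon force stays (near) zero over the stride
#'
#' @param states named list of `muscle_state_trajectory` objects covering
#'   the evaluated stride.
#' @param eps force threshold, N.
#' @return integer count.
#' @export
zero_force_penalty <- function(states, eps = 1) {
  if (any(vapply(states, nrow, 1L) == 0)) stop("empty trajectory")
  sum(vapply(states, function(s) max(s$f_tendon) <= eps, TRUE))
}

#' Plantarflexor force-distribution penalty
#'
#' 1 if the stride-mean soleus tendon force is lower than the mean of the
#' two gastrocnemius stride-mean tendon forces (strict inequality), else 0.
#'
#' @param states named list containing `soleus`,
#'   `gastrocnemius_medialis` and `gastrocnemius_lateralis`.
#' @return 0 or 1.
#' @export
plantarflexor_distribution_penalty <- function(states) {
  need <- c("soleus", "gastrocnemius_medialis", "gastrocnemius_lateralis")
  miss <- setdiff(need, names(states))
  if (length(miss) > 0)
    stop("missing plantarflexor states: ", paste(miss, collapse = ", "))
  sol <- mean(states$soleus$f_tendon)
  gas <- mean(c(mean(states$gastrocnemius_medialis$f_tendon),
                mean(states$gastrocnemius_lateralis$f_tendon)))
  as.integer(sol < gas)
}

#' Physiological fiber-length range penalty
#'
#' Counts muscles whose fiber length leaves the closed interval
#' `[l_opt (1 - width), l_opt (1 + width)]` at any sample of the stride.
#'
#' @param states named list of `muscle_state_trajectory` objects.
#' @param params muscle-parameter table matching the states.
#' @return integer count.
#' @export
physiological_range_penalty <- function(states, params) {
  validate_muscle_params(params)
  sum(vapply(names(states), function(m) {
    p <- params[params$muscle == m, ]
    lo <- p$l_opt * (1 - p$width)
    hi <- p$l_opt * (1 + p$width)
    any(states[[m]]$l_fiber < lo | states[[m]]$l_fiber > hi)
  }, TRUE))
}

#' Hip moment error restricted to the extension phase
#'
#' Mean squared error between muscle-generated and reference hip moments,
#' evaluated only at samples where the reference moment is in the
#' extension direction (negative, in the package's flexion-positive
#' convention), because the model carries no uni-articular hip flexor.
#'
#' @param muscle_moments hip moment series from the muscle simulation,
#'   N m kg^-1.
#' @param reference_moments reference hip moment series, N m kg^-1.
#' @return scalar MSE, (N m kg^-1)^2.
#' @export
hip_extension_mse <- function(muscle_moments, reference_moments) {
  if (length(muscle_moments) != length(reference_moments))
    stop("hip moment series are not aligned")
  ext <- reference_moments < 0
  if (!any(ext))
    stop("reference hip moment is never in the extension direction")
  mean((muscle_moments[ext] - reference_moments[ext])^2)
}

# decimate a trial to an integer-divisor sample rate
decimate_trial <- function(trial, fs_target) {
  if (fs_target >= trial$fs) return(trial)
  k <- trial$fs / fs_target
  if (abs(k - round(k)) > 1e-9)
    stop("fs_calibration must divide the trial sampling rate")
  k <- round(k)
  idx <- seq(1, length(trial$time), by = k)
  trial$fs <- fs_target
  trial$time <- trial$time[idx]
  trial$joint_angles <- trial$joint_angles[idx, , drop = FALSE]
  trial$joint_moments <- trial$joint_moments[idx, , drop = FALSE]
  trial$grf_ipsi <- trial$grf_ipsi[idx]
  trial$grf_contra <- trial$grf_contra[idx]
  trial$emg <- trial$emg[idx, , drop = FALSE]
  trial$samples_per_stride <- trial$samples_per_stride / k
  trial$events <- lapply(trial$events, function(e) (e - 1) %/% k + 1L)
  trial
}

apply_candidate <- function(params, candidate) {
  # candidate: named vector l_opt.<muscle>, l_slack.<muscle>
  for (m in params$muscle) {
    i <- match(m, params$muscle)
    lo <- candidate[paste0("l_opt.", m)]
    ls <- candidate[paste0("l_slack.", m)]
    if (!is.na(lo)) params$l_opt[i] <- lo
    if (!is.na(ls)) params$l_slack[i] <- ls
  }
  params
}

candidate_vector <- function(params) {
  stats::setNames(c(params$l_opt, params$l_slack),
                  c(paste0("l_opt.", params$muscle),
                    paste0("l_slack.", params$muscle)))
}

# Candidate-independent quantities for repeated cost evaluations on one
# trial: excitation/activation series, muscle-tendon lengths and moment
# arms depend only on the EMG, kinematics and geometry, not on the
# optimized length parameters, so they are computed once per calibration.
sim_prep <- function(trial, params, geometry, warmup_strides = 2,
                     tau_act = 0.015, tau_deact = 0.060) {
  fs <- trial$fs
  cmap <- emg_channel_map()
  act <- list(); lmt <- list(); arms <- list()
  for (m in params$muscle) {
    ch <- cmap[[m]]
    exc <- normalize_emg(trial$emg[, ch], trial$participant$mvc[[ch]])
    act[[m]] <- activation_dynamics(exc, fs, tau_act, tau_deact)
    mt <- muscle_tendon_length(trial$joint_angles, geometry, m)
    lmt[[m]] <- mt$l_mt
    arms[[m]] <- mt$moment_arms
  }
  hs <- trial$events$ipsi_heel_strikes
  eval_idx <- hs[warmup_strides + 1]:length(trial$time)
  list(activations = act, lmt = lmt, arms = arms, eval_idx = eval_idx,
       fs = fs, dt = 1 / fs, body_mass = trial$participant$body_mass,
       n = length(trial$time))
}

# one muscle's simulated contribution under candidate length parameters:
# joint-moment time series (N m), evaluated-stride tendon forces, and the
# fiber-length range indicator
muscle_contribution <- function(p, prep, curves) {
  m <- p$muscle
  substeps <- max(1L, as.integer(ceiling(prep$dt / muscle_dt_max(p))))
  h <- p$l_opt * sin(p$pennation_opt)
  lf0 <- sqrt(max(prep$lmt[[m]][1] - p$l_slack, 0.01 * p$l_opt)^2 + h^2)
  st <- hill_integrate_cpp(prep$activations[[m]], prep$lmt[[m]],
                           prep$dt, substeps, as.list(p[1, ]), curves,
                           FALSE, lf0)
  ft <- st[, "f_tendon"]
  lf <- st[prep$eval_idx, "lf"]
  a <- prep$arms[[m]]
  mom <- a * ft
  list(moment = mom, ft_eval = ft[prep$eval_idx],
       range_violated = as.integer(
         any(lf < p$l_opt * (1 - p$width) | lf > p$l_opt * (1 + p$width))))
}

# memoizing wrapper used by the block searches: only the polled muscle's
# simulation is recomputed, the others are served from the cache
cached_contribution <- function(prep, curves) {
  cache <- new.env(parent = emptyenv())
  function(p) {
    key <- paste(p$muscle, format(p$l_opt, digits = 17),
                 format(p$l_slack, digits = 17))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    r <- muscle_contribution(p, prep, curves)
    if (length(ls(cache)) > 64) rm(list = ls(cache), envir = cache)
    cache[[key]] <- r
    r
  }
}

# fast matrix-level cost evaluation against the prepared trial
cost_eval <- function(candidate, prep, reference_moments, config, params,
                      curves, contribution = NULL) {
  cand_params <- apply_candidate(params, candidate)
  ev <- prep$eval_idx
  mom <- matrix(0, prep$n, 3, dimnames = list(NULL, c("hip", "knee",
                                                      "ankle")))
  ft_eval <- list()
  prp <- 0L
  for (m in cand_params$muscle) {
    p <- cand_params[cand_params$muscle == m, , drop = FALSE]
    r <- if (is.null(contribution)) muscle_contribution(p, prep, curves)
         else contribution(p)
    ft_eval[[m]] <- r$ft_eval
    prp <- prp + r$range_violated
    for (j in colnames(r$moment)) mom[, j] <- mom[, j] + r$moment[, j]
  }
  mom <- mom / prep$body_mass
  zfp <- sum(vapply(ft_eval, function(f) max(f) <= config$zero_force_eps,
                    TRUE))
  sol <- mean(ft_eval$soleus)
  gas <- mean(c(mean(ft_eval$gastrocnemius_medialis),
                mean(ft_eval$gastrocnemius_lateralis)))
  pdp <- as.integer(sol < gas)
  mse_a <- mean((mom[ev, "ankle"] - reference_moments[ev, "ankle"])^2)
  mse_k <- mean((mom[ev, "knee"] - reference_moments[ev, "knee"])^2)
  mse_h <- hip_extension_mse(mom[ev, "hip"], reference_moments[ev, "hip"])
  total <- mse_a + mse_k + mse_h + config$c1 * zfp + config$c2 * pdp +
    config$c3 * prp
  structure(list(mse_ankle = mse_a, mse_knee = mse_k,
                 mse_hip_extension = mse_h, zero_force_penalty = zfp,
                 plantarflexor_distribution_penalty = pdp,
                 physiological_range_penalty = prp, total = total,
                 failed = FALSE),
            class = "cost_breakdown")
}

#' Calibration cost of a candidate parameter set
#'
#' Runs the muscle simulation under the candidate optimal fiber lengths
#' and tendon slack lengths, and evaluates the calibration cost: full
#' stride MSE of the ankle and knee muscle-generated moments against the
#' reference, hip MSE restricted to the extension phase, plus the three
#' weighted penalties.  A failed simulation yields a large finite sentinel
#' cost so the surrounding search continues.
#'
#' @param candidate named vector (`l_opt.<muscle>`, `l_slack.<muscle>`) or
#'   a muscle-parameter table.
#' @param trial a `gait_trial` (already at, or decimatable to, the
#'   calibration rate).
#' @param reference_moments n x 3 reference moments, N m kg^-1, on the
#'   trial's time base.
#' @param config a [calibration_config()].
#' @param params base muscle-parameter table (non-length parameters).
#' @param geometry,curves muscle geometry and curve constants.
#' @param warmup_strides strides discarded before evaluation.
#' @return a `cost_breakdown` list: the three MSE terms, the three penalty
#'   counts/indicators, and `total`.
#' @export
cost_function <- function(candidate, trial, reference_moments,
                          config = calibration_config(),
                          params = default_muscle_params(),
                          geometry = default_geometry(params),
                          curves = hill_curves(), warmup_strides = 2) {
  if (is.data.frame(candidate)) candidate <- candidate_vector(candidate)
  sentinel <- function(msg) {
    warning("simulation failed for a candidate (", msg,
            "); sentinel cost used", call. = FALSE)
    structure(list(mse_ankle = NA_real_, mse_knee = NA_real_,
                   mse_hip_extension = NA_real_, zero_force_penalty = NA,
                   plantarflexor_distribution_penalty = NA,
                   physiological_range_penalty = NA,
                   total = 1e12, failed = TRUE),
              class = "cost_breakdown")
  }
  tryCatch({
    tr <- decimate_trial(trial, config$fs_calibration)
    ref <- reference_moments
    if (nrow(ref) != length(tr$time)) {
      k <- round(trial$fs / config$fs_calibration)
      ref <- ref[seq(1, nrow(ref), by = k), , drop = FALSE]
    }
    prep <- sim_prep(tr, params, geometry, warmup_strides)
    cost_eval(candidate, prep, ref, config, params, curves)
  }, error = function(e) sentinel(conditionMessage(e)))
}

penalties_zero <- function(bd) {
  !isTRUE(bd$failed) &&
    bd$zero_force_penalty == 0 &&
    bd$plantarflexor_distribution_penalty == 0 &&
    bd$physiological_range_penalty == 0
}

#' Generalized pattern search over a box
#'
#' Pattern search with an expanding/contracting mesh: at each iteration
#' every poll direction (steps proportional to the box-defining parameter
#' values) is evaluated and the best improving point, if any, is accepted,
#' doubling the mesh; an unsuccessful poll halves it.  Iterates never
#' leave the box `bounds_fraction * x_box`.  The search stops when all
#' penalty terms are zero and the improvement falls below
#' `improvement_tol` (with the mesh fully contracted), or after
#' `max_iterations` poll iterations.
#'
#' @param objective function of a named parameter vector returning a
#'   `cost_breakdown` (anything with `total`; penalty fields optional).
#' @param x0 starting parameter vector (defines the box).
#' @param config a [calibration_config()].
#' @param directions optional matrix of poll directions (one per column,
#'   in units of the relative mesh times the box scale); defaults to the
#'   signed coordinate basis.
#' @param x_box parameter vector defining the 50-150 percent box and the
#'   step scaling; defaults to `x0` (so the search starts at the box
#'   center scale).
#' @param mesh_cap upper bound on the relative mesh after expansion.
#' @return list with `x_best`, `best` (its `cost_breakdown`), and `log`
#'   (per-iteration data.frame: iteration, best cost, mesh size,
#'   evaluations).
#' @export
pattern_search <- function(objective, x0, config = calibration_config(),
                           directions = NULL, x_box = x0,
                           mesh_cap = 0.5) {
  n <- length(x0)
  lo <- config$bounds_fraction[1] * x_box
  hi <- config$bounds_fraction[2] * x_box
  if (is.null(directions))
    directions <- cbind(diag(n), -diag(n))
  x <- pmin(pmax(x0, lo), hi)
  best <- objective(x)
  if (!is.finite(best$total)) stop("objective not finite at x0")
  n_fail <- 0
  mesh <- config$mesh0
  log <- list()
  for (iter in seq_len(config$max_iterations)) {
    improved <- FALSE
    evals <- 0
    prev_total <- best$total
    best_cand <- NULL
    best_bd <- best
    for (d in seq_len(ncol(directions))) {
      cand <- pmin(pmax(x + mesh * x_box * directions[, d], lo), hi)
      if (all(cand == x)) next
      bd <- objective(cand)
      evals <- evals + 1
      if (isTRUE(bd$failed)) n_fail <- n_fail + 1
      if (n_fail > 50 * n)
        stop("objective failed repeatedly; aborting pattern search")
      if (bd$total < best_bd$total) {
        best_cand <- cand
        best_bd <- bd
      }
    }
    if (!is.null(best_cand)) {
      x <- best_cand
      best <- best_bd
      improved <- TRUE
    }
    log[[iter]] <- data.frame(iteration = iter, best_cost = best$total,
                              mesh = mesh, evaluations = evals)
    if (improved) mesh <- min(mesh * 2, mesh_cap)
    else mesh <- mesh / 2
    delta <- prev_total - best$total
    pen_zero <- if (is.null(best$zero_force_penalty)) TRUE
                else penalties_zero(best)
    # "improvement below tolerance" is only meaningful once the mesh has
    # contracted past the parameter resolution of interest
    if (pen_zero && !improved && delta < config$improvement_tol &&
        mesh < config$mesh0 * 1e-3) break
  }
  list(x_best = x, best = best, log = do.call(rbind, log))
}

# compass poll directions (coordinate steps plus diagonals) for one
# muscle's (l_opt, l_slack) pair; the diagonals traverse the compensating
# valleys where a longer tendon trades off against a shorter fiber
block_directions <- function(x_names, muscles) {
  dirs <- list()
  for (m in muscles) {
    i <- match(paste0("l_opt.", m), x_names)
    j <- match(paste0("l_slack.", m), x_names)
    e <- function(k, s) { v <- numeric(length(x_names)); v[k] <- s; v }
    dirs <- c(dirs, list(e(i, 1), e(i, -1), e(j, 1), e(j, -1),
                         e(i, 1) + e(j, 1), e(i, -1) + e(j, -1),
                         e(i, 1) + e(j, -1), e(i, -1) + e(j, 1)))
  }
  do.call(cbind, dirs)
}

#' Calibrate muscle length parameters on one trial
#'
#' Optimizes tendon slack length and optimal fiber length of every muscle
#' against the trial's reference joint moments, starting from the supplied
#' initial parameters, within 50-150 percent bounds.  The search follows
#' the search-poll pattern-search paradigm, applied per muscle under the
#' full cost with all other muscles held at their current values: an
#' exploratory lattice scan over the muscle's two-parameter box locates
#' the basin (the cost surface has pocket minima along the
#' fiber-tendon compensation valley), then pattern-search polls with
#' progressively refined meshes descend within it.  Muscles are visited in
#' distal-to-proximal order and the sweep is repeated until the total cost
#' stops improving.
#'
#' @param trial a `gait_trial` (the baseline condition, by convention).
#' @param params0 starting muscle-parameter table.
#' @param reference_moments reference moments; defaults to the trial's
#'   `joint_moments`.
#' @param config a [calibration_config()].
#' @param geometry,curves forwarded to the cost function.
#' @return list with `params` (calibrated table), `breakdown` (final
#'   `cost_breakdown`), and `log` (per-block iteration logs).
#' @export
calibrate_trial <- function(trial, params0 = default_muscle_params(),
                            reference_moments = trial$joint_moments,
                            config = calibration_config(),
                            geometry = default_geometry(params0),
                            curves = hill_curves()) {
  tr <- decimate_trial(trial, config$fs_calibration)
  ref <- reference_moments
  if (nrow(ref) != length(tr$time)) {
    k <- round(trial$fs / config$fs_calibration)
    ref <- ref[seq(1, nrow(ref), by = k), , drop = FALSE]
  }
  prep <- sim_prep(tr, params0, geometry)
  contribution <- cached_contribution(prep, curves)
  n_evals <- 0L
  obj <- function(x) {
    n_evals <<- n_evals + 1L
    tryCatch(cost_eval(x, prep, ref, config, params0, curves,
                       contribution = contribution),
             error = function(e)
               structure(list(total = 1e12, failed = TRUE,
                              zero_force_penalty = NA,
                              plantarflexor_distribution_penalty = NA,
                              physiological_range_penalty = NA),
                         class = "cost_breakdown"))
  }
  x0 <- candidate_vector(params0)
  x <- x0
  logs <- list()
  best <- obj(x)
  grid_frac <- seq(config$bounds_fraction[1], config$bounds_fraction[2],
                   length.out = 13)
  # global scale search: scaling errors inherited from a common limb
  # scaling step are strongly correlated across muscles, so first scan the
  # two global factors (all optimal fiber lengths, all slack lengths)
  lopt_ix <- grep("^l_opt\\.", names(x))
  ls_ix <- grep("^l_slack\\.", names(x))
  for (ko in grid_frac) for (ks in grid_frac) {
    cand <- x0
    cand[lopt_ix] <- x0[lopt_ix] * ko
    cand[ls_ix] <- x0[ls_ix] * ks
    bd <- obj(cand)
    if (bd$total < best$total) { x <- cand; best <- bd }
  }
  # strong muscles first: they carry most of the moment signal and anchor
  # the solution before the weak muscles fit the residuals
  order_muscles <- params0$muscle[order(-params0$f_max)]
  for (sweep in 1:3) {
    sweep_start <- best$total
    for (m in order_muscles) {
      if (n_evals > config$eval_budget) break
      idx <- match(c(paste0("l_opt.", m), paste0("l_slack.", m)),
                   names(x))
      # search step: coarse lattice over this muscle's box
      for (ko in grid_frac) for (ks in grid_frac) {
        cand <- x
        cand[idx] <- x0[idx] * c(ko, ks)
        bd <- obj(cand)
        if (bd$total < best$total) { x <- cand; best <- bd }
      }
      # poll step: refined pattern search around the basin; the three
      # mesh stages together stay within the per-search iteration cap
      dirs <- block_directions(names(x), m)
      for (stage in list(c(0.10, 0.40, 0.40), c(0.02, 0.05, 0.13),
                         c(0.004, 0.01, 0.07))) {
        if (n_evals > config$eval_budget) break
        cfg_s <- config
        cfg_s$mesh0 <- stage[1]
        cfg_s$max_iterations <- max(10L,
                                    round(stage[3] * config$max_iterations))
        res <- pattern_search(obj, x, config = cfg_s, directions = dirs,
                              x_box = x0, mesh_cap = stage[2])
        x <- res$x_best
        best <- res$best
        logs[[length(logs) + 1]] <- cbind(sweep = sweep, muscle = m,
                                          res$log)
      }
    }
    # stop sweeping once a pass yields no meaningful relative improvement
    if (sweep_start - best$total <
          max(config$improvement_tol, 1e-3 * best$total)) break
  }
  list(params = apply_candidate(params0, x), breakdown = best,
       log = do.call(rbind, logs))
}
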