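# Synthetic gait-trial generator: stride-locked periodic templates shaped
# like normative level-walking data, with condition effects for treadmill
# grade and shoe inclination, and multiplicative trial noise.

emg_channels <- function() {
  c("tibialis_anterior", "soleus", "gastrocnemius_medialis",
    "vastus_medialis", "rectus_femoris", "biceps_femoris",
    "gluteus_maximus")
}

#' Participant specification
#'
#' @param id participant label.
#' @param body_mass body mass, kg.
#' @param stride_period stride duration, s.
#' @param stance_fraction stance fraction of the stride, in (0.5, 0.7).
#' @param template_scales named multiplicative factors applied to the
#'   signal templates (`angle`, `moment`, `emg`).
#' @param mvc named per-muscle EMG ceilings in raw envelope units.
#' @return a `participant_spec` list.
#' @export
participant_spec <- function(id = "P1", body_mass = 79.9,
                             stride_period = 1.10, stance_fraction = 0.62,
                             template_scales = c(angle = 1, moment = 1,
                                                 emg = 1),
                             mvc = NULL) {
  if (!is.finite(body_mass) || body_mass <= 0)
    stop("body_mass must be positive")
  if (!is.finite(stride_period) || stride_period <= 0)
    stop("stride_period must be positive")
  if (stance_fraction <= 0.5 || stance_fraction >= 0.7)
    stop("stance_fraction must lie in (0.5, 0.7)")
  if (is.null(mvc)) {
    mvc <- stats::setNames(rep(1, length(emg_channels())), emg_channels())
  }
  out <- list(id = id, body_mass = body_mass, stride_period = stride_period,
              stance_fraction = stance_fraction,
              template_scales = template_scales, mvc = mvc)
  class(out) <- "participant_spec"
  out
}

#' Walking condition specification
#'
#' The study design crosses treadmill grade (with level shoes) and shoe
#' outsole inclination (on a level treadmill): at most one of the two may
#' be nonzero.
#'
#' @param grade_deg treadmill grade in degrees, one of -6, 0, +6.
#' @param shoe_deg shoe outsole inclination in degrees, one of -7, -3, 0,
#'   +3, +7.
#' @param speed belt speed, m s^-1 (held at 1 across conditions).
#' @return a `condition_spec` list.
#' @export
condition_spec <- function(grade_deg = 0, shoe_deg = 0, speed = 1.0) {
  if (!grade_deg %in% c(-6, 0, 6))
    stop("grade_deg must be one of -6, 0, +6 (got ", grade_deg, ")")
  if (!shoe_deg %in% c(-7, -3, 0, 3, 7))
    stop("shoe_deg must be one of -7, -3, 0, +3, +7 (got ", shoe_deg, ")")
  if (grade_deg != 0 && shoe_deg != 0)
    stop("grade_deg and shoe_deg cannot both be nonzero: ",
         "the design varies one factor at a time")
  if (speed <= 0) stop("speed must be positive")
  out <- list(grade_deg = grade_deg, shoe_deg = shoe_deg, speed = speed)
  class(out) <- "condition_spec"
  out
}

#' The seven distinct walking conditions of the study design
#'
#' Three treadmill grades with level shoes and five shoe inclinations on a
#' level treadmill; the level-grade level-shoe baseline appears once.
#'
#' @return list of `condition_spec` objects, baseline first.
#' @export
study_conditions <- function() {
  c(list(condition_spec(0, 0)),
    lapply(c(-6, 6), function(g) condition_spec(g, 0)),
    lapply(c(-7, -3, 3, 7), function(s) condition_spec(0, s)))
}

condition_id <- function(condition) {
  if (condition$grade_deg != 0)
    sprintf("grade%+d", condition$grade_deg)
  else if (condition$shoe_deg != 0)
    sprintf("shoe%+d", condition$shoe_deg)
  else "baseline"
}

# evaluate and restore RNG state around seeded generation
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# periodic template from control points: linear circular interpolation on a
# dense grid, then truncation to the first `harmonics` Fourier harmonics
periodic_template <- function(phase_grid, points, harmonics = 8) {
  ph <- c(points[, 1] - 1, points[, 1], points[, 1] + 1)
  v <- rep(points[, 2], 3)
  dense <- stats::approx(ph, v, xout = phase_grid)$y
  fourier_truncate(dense, harmonics)
}

fourier_truncate <- function(y, harmonics) {
  n <- length(y)
  Y <- stats::fft(y)
  keep <- c(1, if (harmonics >= 1) 2:(min(harmonics, n %/% 2) + 1))
  keep <- c(keep, n + 2 - keep[keep > 1])
  Y[setdiff(seq_len(n), keep)] <- 0
  Re(stats::fft(Y, inverse = TRUE)) / n
}

circular_bump <- function(phase_grid, center, width, amp) {
  d <- phase_grid - center
  d <- (d + 0.5) %% 1 - 0.5
  amp * exp(-0.5 * (d / width)^2)
}

# canonical normative level-walking shapes; configuration, not hard-coded
# science (replace wholesale to emulate other gaits)
default_templates <- function() {
  deg <- pi / 180
  list(
    harmonics = 8,
    angles = list(   # control points: stride fraction, value (rad)
      hip = cbind(c(0, .1, .3, .5, .6, .7, .85, .95),
                  deg * c(20, 15, 0, -12, -10, 5, 22, 21)),
      knee = cbind(c(0, .12, .4, .55, .65, .75, .88, .97),
                   deg * c(4, 18, 6, 12, 40, 60, 25, 5)),
      ankle = cbind(c(0, .05, .15, .4, .5, .62, .75, .9),
                    deg * c(0, -6, 2, 10, 8, -18, -4, 1))
    ),
    moments = list(  # N m / kg, positive moment increases the angle
      hip = cbind(c(0, .05, .15, .3, .45, .55, .65, .8, .9),
                  c(-0.2, -0.7, -0.5, -0.1, 0.4, 0.6, 0.2, 0.0, -0.1)),
      knee = cbind(c(0, .08, .15, .25, .4, .5, .62, .75, .9),
                   c(0.1, -0.4, -0.5, -0.2, 0.1, 0.15, -0.1, 0.05, 0.15)),
      ankle = cbind(c(0, .04, .12, .25, .4, .48, .55, .62, .68, .8, .95),
                    c(0, 0.08, -0.3, -0.7, -1.2, -1.4, -0.9, -0.15, 0.02,
                      0.01, 0))
    ),
    grf_trough = 0.5,   # relative depth of the mid-stance GRF trough
    emg = list(          # circular Gaussian bursts: center, width, amplitude
      tibialis_anterior = rbind(c(0.02, 0.04, 0.35), c(0.75, 0.10, 0.25)),
      soleus = rbind(c(0.40, 0.12, 0.55)),
      gastrocnemius_medialis = rbind(c(0.42, 0.10, 0.50)),
      vastus_medialis = rbind(c(0.08, 0.06, 0.40), c(0.97, 0.04, 0.15)),
      rectus_femoris = rbind(c(0.08, 0.07, 0.25), c(0.62, 0.06, 0.20)),
      biceps_femoris = rbind(c(0.93, 0.06, 0.35), c(0.05, 0.07, 0.28)),
      gluteus_maximus = rbind(c(0.06, 0.08, 0.38))
    ),
    emg_baseline = 0.02
  )
}

# condition scaling factors, chosen once to emulate the study's reported
# direction and rough magnitude of condition effects
condition_effects <- function(condition) {
  g <- condition$grade_deg; s <- condition$shoe_deg
  list(
    moment_global = 1 + 0.02 * g,
    moment_pos_extra = 0.04 * max(g, 0),   # scales positive-power regions
    moment_neg_extra = 0.04 * max(-g, 0),  # scales negative-power regions
    ankle_moment = 1 + 0.015 * s,
    emg_pf_hipext = 1 + 0.08 * max(g, 0) - 0.03 * max(-g, 0) +
      0.02 * max(s, 0) + 0.01 * max(-s, 0),
    emg_ta_vas = (1 + 0.05 * max(-g, 0)) * (1 + 0.03 * abs(s)),
    # latent whole-body net metabolic factor (drives the emulated
    # calorimetry): quadratic fits through the study-scale condition effects
    metabolic = (1 + 0.01042 * g^2 + 0.1225 * g) *
      (1 + 0.00184 * s^2 - 0.00429 * s)
  )
}

build_stride_templates <- function(participant, condition,
                                   n_per_stride, templates = default_templates()) {
  ph <- (seq_len(n_per_stride) - 1) / n_per_stride
  eff <- condition_effects(condition)
  sc <- participant$template_scales

  ang <- sapply(c("hip", "knee", "ankle"), function(j)
    sc[["angle"]] * periodic_template(ph, templates$angles[[j]],
                                      templates$harmonics))
  mom <- sapply(c("hip", "knee", "ankle"), function(j)
    sc[["moment"]] * periodic_template(ph, templates$moments[[j]],
                                       templates$harmonics))

  # joint angular velocity of the template (rad per stride fraction);
  # used only to locate positive/negative power regions for grade scaling
  omega <- apply(ang, 2, function(a) {
    n <- length(a)
    (a[c(2:n, 1)] - a[c(n, 1:(n - 1))]) / 2
  })
  power <- mom * omega
  pw_scale <- pmax(apply(abs(power), 2, max), 1e-9)
  for (j in 1:3) {
    w_pos <- 1 / (1 + exp(-power[, j] / (0.1 * pw_scale[j])))
    mom[, j] <- mom[, j] * eff$moment_global *
      (1 + eff$moment_pos_extra * w_pos + eff$moment_neg_extra * (1 - w_pos))
  }
  mom[, "ankle"] <- mom[, "ankle"] * eff$ankle_moment

  # vertical GRF: double-bump during stance, zero in swing; normalized so
  # that ipsi + contra average exactly body weight over the stride
  sf <- participant$stance_fraction
  bw <- participant$body_mass * 9.81
  grf <- numeric(n_per_stride)
  st <- ph < sf
  s <- ph[st] / sf
  core <- 0.15 + 0.85 * pmax(sin(pi * s) *
                               (1 + templates$grf_trough * cos(2 * pi * s)), 0)
  # steep loading/unloading ramps (~0.8% of stance) so the contact edges
  # are sharp at ordinary sampling rates
  ramp <- pmin(s / 0.008, 1) * pmin((1 - s) / 0.008, 1)
  grf[st] <- core * ramp
  contra <- grf[1 + (seq_len(n_per_stride) - 1 + n_per_stride %/% 2) %%
                  n_per_stride]
  grf_scale <- bw / mean(grf + contra)
  grf <- grf * grf_scale

  emg <- sapply(emg_channels(), function(m) {
    b <- templates$emg[[m]]
    act <- templates$emg_baseline +
      Reduce(`+`, lapply(seq_len(nrow(b)), function(i)
        circular_bump(ph, b[i, 1], b[i, 2], b[i, 3])))
    f <- if (m %in% c("soleus", "gastrocnemius_medialis", "biceps_femoris",
                      "gluteus_maximus")) eff$emg_pf_hipext
         else if (m %in% c("tibialis_anterior", "vastus_medialis"))
           eff$emg_ta_vas
         else 1
    pmin(pmax(act * f * sc[["emg"]], 0), 0.95) * participant$mvc[[m]]
  })

  list(phase = ph, angles = ang, moments = mom, grf = grf, emg = emg,
       metabolic_factor = eff$metabolic)
}

#' Generate one synthetic gait trial
#'
#' Builds stride-locked periodic signal templates (truncated Fourier series
#' fitted to canonical normative gait shapes) for joint angles, joint
#' moments, bilateral vertical GRFs and EMG envelopes, applies the
#' condition effects (grade scales leg work, plantarflexor and hip-extensor
#' EMG; shoe inclination perturbs the ankle moment and tibialis /
#' plantarflexor EMG), tiles them over `n_strides`, and adds trial noise
#' (per-stride multiplicative lognormal amplitude factors plus additive
#' white noise).  Identical arguments give bitwise-identical output.
#'
#' Ground-truth contact events and a stride-average respiratory gas pair
#' emulating indirect calorimetry for the condition are attached to the
#' returned trial.
#'
#' @param participant a [participant_spec()].
#' @param condition a [condition_spec()].
#' @param n_strides number of strides (at least 2).
#' @param noise_sd relative noise magnitude (0 disables noise).
#' @param seed integer seed.
#' @param fs sampling rate, Hz.
#' @param templates template configuration, see `default_templates`.
#' @return a `gait_trial` list: `fs`, `time`, `joint_angles` (n x 3, rad),
#'   `joint_moments` (n x 3, N m kg^-1), `grf_ipsi`, `grf_contra` (N),
#'   `emg` (n x 7 raw envelopes), `condition`, `participant`, `events`
#'   (ground-truth sample indices), `gas` (stride-average vo2/vco2, ml s^-1,
#'   and the standing reference rate, W kg^-1).
#' @export
generate_trial <- function(participant, condition, n_strides = 5,
                           noise_sd = 0, seed = 1, fs = 2000,
                           templates = default_templates()) {
  stopifnot(inherits(participant, "participant_spec"),
            inherits(condition, "condition_spec"))
  if (n_strides < 2) stop("n_strides must be at least 2")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  with_seed(seed, {
    nps <- round(participant$stride_period * fs)
    tm <- build_stride_templates(participant, condition, nps, templates)
    n <- nps * n_strides
    tile <- function(x) {
      if (is.matrix(x)) x[rep(seq_len(nps), n_strides), , drop = FALSE]
      else rep(x, n_strides)
    }
    ang <- tile(tm$angles); mom <- tile(tm$moments)
    grf <- tile(tm$grf); emg <- tile(tm$emg)
    contra_shift <- function(x) {
      idx <- 1 + (seq_len(nps) - 1 + nps %/% 2) %% nps
      rep(x[idx], n_strides)
    }
    grf_contra <- contra_shift(tm$grf)

    if (noise_sd > 0) {
      stride_of <- rep(seq_len(n_strides), each = nps)
      mul <- function(ncol) {
        f <- matrix(exp(stats::rnorm(n_strides * ncol, -noise_sd^2 / 2,
                                     noise_sd)), n_strides, ncol)
        f[stride_of, , drop = FALSE]
      }
      add <- function(x) {
        sdv <- noise_sd * 0.15 * max(stats::sd(x), 1e-12)
        x + stats::rnorm(length(x), 0, sdv)
      }
      ang <- apply(ang * mul(3), 2, add)
      mom <- apply(mom * mul(3), 2, add)
      emg <- pmax(apply(emg * mul(ncol(emg)), 2, add), 0)
      gmask <- grf > 0
      grf <- pmax(add(as.vector(grf * mul(1))), 0) * gmask
      cmask <- grf_contra > 0
      grf_contra <- pmax(add(as.vector(grf_contra * mul(1))), 0) * cmask
      colnames(ang) <- colnames(mom) <- c("hip", "knee", "ankle")
      colnames(emg) <- emg_channels()
    }

    st <- round(participant$stance_fraction * nps)
    starts <- (seq_len(n_strides) - 1) * nps
    # the closing heel strike (one sample past the trial) bounds the last
    # stride for phase partitioning
    events <- list(
      ipsi_heel_strikes = c(starts + 1L, n_strides * nps + 1L),
      ipsi_toe_offs = starts + st,
      contra_heel_strikes = starts + nps %/% 2 + 1L,
      contra_toe_offs = starts + st - nps %/% 2
    )

    # emulated stride-average indirect calorimetry for this condition
    base_net <- 3.3                       # W kg^-1, level walking at 1 m/s
    standing <- 1.4                       # W kg^-1
    net <- base_net * tm$metabolic_factor *
      if (noise_sd > 0) exp(stats::rnorm(1, -(0.8 * noise_sd)^2 / 2,
                                         0.8 * noise_sd)) else 1
    gross_w <- (net + standing) * participant$body_mass
    rer <- 0.85
    vo2 <- gross_w / (16.58 + 4.51 * rer)
    gas <- list(vo2 = vo2, vco2 = rer * vo2, standing_rate = standing)

    out <- list(fs = fs, time = (seq_len(n) - 1) / fs,
                joint_angles = ang, joint_moments = mom,
                grf_ipsi = grf, grf_contra = grf_contra, emg = emg,
                condition = condition, participant = participant,
                n_strides = n_strides, samples_per_stride = nps,
                events = events, gas = gas)
    class(out) <- "gait_trial"
    out
  })
}

#' Generate a synthetic cohort over a set of walking conditions
#'
#' Participant specifications are drawn from the study population
#' (mass 79.9 +/- 13.8 kg) with participant-level variation in stride
#' period, stance fraction, MVC references and template amplitudes; each
#' participant is then run through every condition.
#'
#' @param n_participants number of participants (study subset: 6).
#' @param conditions list of [condition_spec()] objects.
#' @param seed integer seed.
#' @param n_strides,noise_sd,fs forwarded to [generate_trial()].
#' @return list of `gait_trial` objects (participants x conditions).
#' @export
generate_cohort <- function(n_participants = 6,
                            conditions = study_conditions(), seed = 1,
                            n_strides = 5, noise_sd = 0.05, fs = 2000) {
  if (n_participants < 1) stop("n_participants must be at least 1")
  if (length(conditions) == 0) stop("condition list must not be empty")
  with_seed(seed, {
    parts <- lapply(seq_len(n_participants), function(i) {
      mvc <- stats::setNames(exp(stats::rnorm(length(emg_channels()), 0,
                                              0.15)), emg_channels())
      participant_spec(
        id = sprintf("P%d", i),
        body_mass = min(max(stats::rnorm(1, 79.9, 13.8), 50), 120),
        stride_period = stats::rnorm(1, 1.10, 0.07),
        stance_fraction = min(max(stats::rnorm(1, 0.62, 0.015), 0.55),
                              0.68),
        template_scales = c(angle = exp(stats::rnorm(1, 0, 0.05)),
                            moment = exp(stats::rnorm(1, 0, 0.08)),
                            emg = exp(stats::rnorm(1, 0, 0.08))),
        mvc = mvc
      )
    })
    trial_seeds <- sample.int(.Machine$integer.max,
                              n_participants * length(conditions))
    k <- 0
    trials <- list()
    for (p in parts) for (cond in conditions) {
      k <- k + 1
      trials[[k]] <- generate_trial(p, cond, n_strides = n_strides,
                                    noise_sd = noise_sd,
                                    seed = trial_seeds[k], fs = fs)
    }
    trials
  })
}

#' Generate a truth-known trial for calibration validation
#'
#' Produces a noise-free baseline trial whose joint moments are replaced by
#' the net muscle-generated moments computed by the muscle simulation under
#' `true_params`, so that the calibration cost function has a known global
#' optimum (zero moment error at the true parameters).
#'
#' @param true_params muscle-parameter table (the ground truth).
#' @param participant a [participant_spec()].
#' @param seed integer seed.
#' @param fs sampling rate, Hz (truth trials default to the calibration
#'   grid rate).
#' @param n_strides number of strides.
#' @param geometry,curves forwarded to the muscle simulation.
#' @return list with `trial` (moments replaced) and `reference_moments`
#'   (n x 3, N m kg^-1).
#' @export
generate_truth_trial <- function(true_params, participant = participant_spec(),
                                 seed = 1, fs = 100, n_strides = 3,
                                 geometry = default_geometry(true_params),
                                 curves = hill_curves()) {
  validate_muscle_params(true_params)
  miss <- setdiff(true_params$muscle, names(geometry))
  if (length(miss) > 0)
    stop("geometry does not define muscles: ", paste(miss, collapse = ", "))
  trial <- generate_trial(participant, condition_spec(0, 0),
                          n_strides = n_strides, noise_sd = 0, seed = seed,
                          fs = fs)
  sim <- simulate_muscles(trial, params = true_params, geometry = geometry,
                          curves = curves, fs_sim = fs)
  mom <- net_joint_moments(sim$states, geometry, sim$joint_angles,
                           body_mass = participant$body_mass)
  trial$joint_moments <- mom
  list(trial = trial, reference_moments = mom)
}
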