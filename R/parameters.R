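#' Default Hill-muscle parameters for the eight modeled muscles
#'
#' Returns the packaged per-muscle parameter table used by the muscle-tendon
#' simulation and the muscle energetics: maximum isometric force `f_max` (N),
#' optimal fiber length `l_opt` (m), tendon slack length `l_slack` (m),
#' pennation angle at optimal fiber length `pennation_opt` (rad), maximum
#' contraction velocity `v_max` (optimal fiber lengths per second),
#' slow-twitch fiber ratio (fraction in \[0, 1\]), and the active
#' force-length width coefficient `width`.
#'
#' The eight muscles are the sagittal-plane set recorded (or mirrored, for
#' the lateral gastrocnemius) in the underlying gait protocol: tibialis
#' anterior, soleus, both gastrocnemii, vastus medialis, rectus femoris,
#' biceps femoris, and gluteus maximus.
#'
#' @return A data.frame with one row per muscle and the columns described
#'   above, plus the muscle name in `muscle`.
#' @export
#' @examples
#' default_muscle_params()
default_muscle_params <- function() {
  data.frame(
    muscle = c("tibialis_anterior", "soleus", "gastrocnemius_medialis",
               "gastrocnemius_lateralis", "vastus_medialis", "rectus_femoris",
               "biceps_femoris", "gluteus_maximus"),
    f_max = c(1227, 6195, 3116, 1575, 9594, 2192, 1870, 3338),
    l_opt = c(0.07, 0.04, 0.05, 0.06, 0.10, 0.08, 0.10, 0.15),
    l_slack = c(0.24, 0.28, 0.40, 0.38, 0.20, 0.45, 0.33, 0.05),
    pennation_opt = c(0.20, 0.38, 0.17, 0.21, 0.42, 0.22, 0.18, 0.35),
    v_max = rep(10, 8),
    slow_twitch_ratio = c(0.700, 0.803, 0.566, 0.507, 0.503, 0.387,
                          0.542, 0.550),
    width = c(0.49, 0.80, 0.61, 0.61, 0.76, 0.76, 0.78, 0.77),
    stringsAsFactors = FALSE
  )
}

#' Validate a muscle-parameter table
#'
#' @param params data.frame as returned by [default_muscle_params()].
#' @return `params`, invisibly, after checking invariants.
#' @keywords internal
validate_muscle_params <- function(params) {
  req <- c("muscle", "f_max", "l_opt", "l_slack", "pennation_opt",
           "v_max", "slow_twitch_ratio", "width")
  miss <- setdiff(req, names(params))
  if (length(miss) > 0)
    stop("muscle parameter table is missing columns: ",
         paste(miss, collapse = ", "))
  num <- as.matrix(params[c("f_max", "l_opt", "l_slack", "pennation_opt",
                            "v_max")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("muscle parameters must be positive and finite")
  if (any(params$slow_twitch_ratio < 0 | params$slow_twitch_ratio > 1))
    stop("slow_twitch_ratio must lie in [0, 1]")
  if (any(params$width <= 0 | params$width >= 1))
    stop("width must lie in (0, 1)")
  invisible(params)
}

#' Default muscle-tendon geometry
#'
#' Moment arms are represented as polynomials in each actuated joint angle,
#' `r_j(theta) = sum_k c_k theta^k` (meters per rad^k), in the package's
#' generalized-coordinate convention (hip flexion positive, knee flexion
#' positive, ankle dorsiflexion positive; a positive moment acts to increase
#' the angle).  The muscle-tendon length is consistent with the arms by
#' construction: `l_mt = l_ref - sum_j integral r_j dtheta_j`, so
#' `d l_mt / d theta_j = -r_j`.  Reference lengths `l_ref` are set so that,
#' in the neutral pose (all angles zero), the unloaded fiber sits slightly
#' above optimal length (`l_slack + fiber_stretch * l_opt *
#' cos(pennation_opt)` with `fiber_stretch = 1.10`): under load the tendon
#' stretch brings the fibers onto the plateau and upper ascending limb of
#' the force-length curve, with the passive element engaged at the long
#' end of the excursion.  Besides being the physiologically typical
#' operating range in walking, this makes the two calibrated length
#' parameters jointly observable from joint moments (the steep passive
#' curve pins the optimal fiber length, the tendon toe pins the slack
#' length).
#'
#' The packaged arms are constant normative sagittal-plane values; they are
#' configuration, not measured geometry, and can be replaced wholesale.
#'
#' @param params muscle-parameter table (supplies the reference lengths).
#' @param fiber_stretch neutral-pose fiber length as a multiple of optimal
#'   fiber length.
#' @return A named list, one entry per muscle, each with `l_ref` (m) and
#'   `arms`, a named list of polynomial coefficient vectors per joint.
#' @export
default_geometry <- function(params = default_muscle_params(),
                             fiber_stretch = 1.10) {
  validate_muscle_params(params)
  arms <- list(
    tibialis_anterior       = list(ankle = c(0.040)),
    soleus                  = list(ankle = c(-0.050)),
    gastrocnemius_medialis  = list(ankle = c(-0.050), knee = c(0.020)),
    gastrocnemius_lateralis = list(ankle = c(-0.045), knee = c(0.018)),
    vastus_medialis         = list(knee = c(-0.045)),
    rectus_femoris          = list(knee = c(-0.040), hip = c(0.035)),
    biceps_femoris          = list(knee = c(0.025), hip = c(-0.060)),
    gluteus_maximus         = list(hip = c(-0.060))
  )
  geom <- list()
  for (m in params$muscle) {
    i <- match(m, params$muscle)
    geom[[m]] <- list(
      l_ref = params$l_slack[i] +
        fiber_stretch * params$l_opt[i] * cos(params$pennation_opt[i]),
      arms = arms[[m]]
    )
  }
  geom
}

#' Hill-curve shape constants
#'
#' Constants of the normalized muscle curves used by the equilibrium
#' muscle-tendon model: the Gaussian active force-length curve drops to
#' `fl_floor` at one width away from optimal length; the concentric
#' force-velocity branch is a Hill hyperbola with curvature `af`; the
#' eccentric branch saturates at `ecc_max` times isometric force with slope
#' continuity at zero velocity; the passive fiber element is an exponential
#' toe reaching isometric force at strain `e0_pe`; the tendon is an
#' exponential toe reaching isometric force at strain `e0_tendon`.
#'
#' @param af Hill concentric curvature (a/F0), default 0.25.
#' @param ecc_max eccentric force plateau as a multiple of isometric force.
#' @param e0_tendon tendon strain at which tendon force equals `f_max`.
#' @param e0_pe passive fiber strain at which passive force equals `f_max`.
#' @param k_tendon,k_pe exponential shape factors of the two toe curves.
#' @param fl_floor active force-length value at `l_opt * (1 +/- width)`.
#' @param a_min activation floor used when solving the fiber-velocity
#'   equilibrium (avoids a singular solve at zero drive).
#' @param damping normalized coefficient of the damper in parallel with
#'   the contractile element (fraction of `f_max` at `v_max`); the damped
#'   equilibrium makes the fiber-velocity solve smooth and well-posed at
#'   low activation and slack tendon.
#' @return Named list of curve constants.
#' @export
hill_curves <- function(af = 0.25, ecc_max = 1.5, e0_tendon = 0.049,
                        e0_pe = 0.6, k_tendon = 3, k_pe = 4,
                        fl_floor = 0.05, a_min = 0.01, damping = 0.1) {
  stopifnot(af > 0, ecc_max > 1, e0_tendon > 0, e0_pe > 0,
            fl_floor > 0, fl_floor < 1, a_min > 0, damping > 0)
  # eccentric exponential rate fixed by slope continuity at v = 0
  k_ecc <- (1 + 1 / af) / (ecc_max - 1)
  list(af = af, ecc_max = ecc_max, k_ecc = k_ecc,
       e0_tendon = e0_tendon, k_tendon = k_tendon,
       e0_pe = e0_pe, k_pe = k_pe,
       fl_floor = fl_floor, a_min = a_min, damping = damping)
}

#' Muscle energetics coefficient set
#'
#' Packaged default coefficients of the muscle metabolic-rate equations.
#' The activation-maintenance base rate is linear in the fast-twitch
#' fraction; shortening heat coefficients are inversely proportional to the
#' fiber-type maximum shortening velocities; the lengthening coefficient is
#' a fixed multiple of the slow-twitch shortening coefficient.  Activation
#' scaling uses exponent `exp_am` for activation-maintenance heat and the
#' larger `exp_short` for shortening heat.  All rates are multiplied by the
#' aerobic scaling factor `S`.
#'
#' This is the package's versioned coefficient set (`set` names it); the
#' structural identities the estimator relies on (nonnegativity after
#' clamping, exact component decomposition, exact linearity in `S`) hold for
#' any positive coefficient values.
#'
#' @param density muscle density, kg m^-3.
#' @param specific_tension maximum isometric stress, N m^-2.
#' @param S aerobic scaling factor (dimensionless).
#' @param recruitment_model fiber recruitment model label; only
#'   `"orderly"` is packaged.
#' @return Named list of coefficients.
#' @export
energetics_coefficients <- function(density = 1059.7,
                                    specific_tension = 600000,
                                    S = 1.5,
                                    recruitment_model = "orderly") {
  stopifnot(density > 0, specific_tension > 0, S > 0)
  list(
    set = "stridemet-umberger-like-1",
    density = density,
    specific_tension = specific_tension,
    S = S,
    recruitment_model = recruitment_model,
    # activation-maintenance base heat rate, W per kg muscle:
    #   h_am = am_base + am_fast * fast_twitch_fraction
    am_base = 25, am_fast = 128,
    # activation scaling exponents
    exp_am = 0.6, exp_short = 2.0,
    # fiber-type maximum shortening velocities, l_opt/s, used only to set
    # the shortening coefficients (inverse proportionality)
    v_max_slow_frac = 0.4,           # slow-twitch v_max as fraction of v_max
    alpha_short_slow_num = 100,      # alpha_s_slow = num / v_max_slow
    alpha_short_fast_num = 153,      # alpha_s_fast = num / v_max_fast
    alpha_lengthen_mult = 0.8,       # alpha_l = mult * alpha_s_slow
    # length scaling above optimal length: h -> h * (w0 + w1 * fl)
    len_scale_w0 = 0.4, len_scale_w1 = 0.6
  )
}

#' Joint-space metabolic coefficient set
#'
#' Packaged default coefficients of the joint-space metabolic-rate
#' estimator.  Per joint and sample, with moment `M` (N m kg^-1) and angular
#' velocity `omega` (rad s^-1): the activation-maintenance term is
#' `c_am * |M|`; the shortening-lengthening term is `c_sl * |M * omega|`;
#' mechanical work costs `P / eta_pos` for positive joint power `P` and
#' `|P| / eta_neg` for negative power, with `eta_neg > eta_pos` (eccentric
#' work is metabolically cheaper).  A configurable moment dead-band
#' (default 0) zeroes near-zero moments before evaluation.
#'
#' Coefficient values are the package's versioned defaults; the estimator's
#' structural properties (additivity over joints, zero inputs give a zero
#' profile, per-sample nonnegativity) are coefficient-independent.
#'
#' @param c_am activation-maintenance coefficient, W kg^-1 per N m kg^-1.
#' @param c_sl shortening-lengthening coefficient, W kg^-1 per
#'   N m rad s^-1 kg^-1.
#' @param eta_pos positive (concentric) work efficiency.
#' @param eta_neg negative (eccentric) work efficiency magnitude.
#' @param dead_band moments with |M| below this are treated as zero.
#' @return Named list of coefficients.
#' @export
jointspace_coefficients <- function(c_am = 0.9, c_sl = 0.25,
                                    eta_pos = 0.25, eta_neg = 1.2,
                                    dead_band = 0) {
  stopifnot(eta_pos > 0, eta_neg > 0, c_am >= 0, c_sl >= 0, dead_band >= 0)
  if (eta_neg <= eta_pos)
    stop("negative-work efficiency magnitude must exceed positive-work efficiency")
  list(set = "stridemet-jointspace-1",
       c_am = c_am, c_sl = c_sl,
       eta_pos = eta_pos, eta_neg = eta_neg,
       dead_band = dead_band)
}

# muscle-group mapping used for reporting shares of the limb total
muscle_groups <- function() {
  list(
    plantarflexors = c("soleus", "gastrocnemius_medialis",
                       "gastrocnemius_lateralis"),
    knee_extensors = "vastus_medialis",
    hip_extensors  = "gluteus_maximus",
    dorsiflexors   = "tibialis_anterior",
    knee_flexors   = "biceps_femoris",
    hip_flexors    = "rectus_femoris"
  )
}
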