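#' Muscle-tendon length and moment arms from joint angles
#'
#' Evaluates the moment-arm polynomials of one muscle at the given joint
#' angles and returns the muscle-tendon length consistent with them:
#' `l_mt = l_ref - sum_j integral_0^theta_j r_j(u) du`, so that
#' `d l_mt / d theta_j = -r_j(theta_j)` holds by construction.
#'
#' @param joint_angles numeric matrix (n x joints) with column names among
#'   `"hip"`, `"knee"`, `"ankle"`, in radians, package sign convention
#'   (hip flexion +, knee flexion +, ankle dorsiflexion +).
#' @param geometry geometry list as from [default_geometry()].
#' @param muscle muscle name.
#' @return list with `l_mt` (numeric, m) and `moment_arms` (n x actuated
#'   joints matrix, m).
#' @export
muscle_tendon_length <- function(joint_angles, geometry, muscle) {
  if (!muscle %in% names(geometry))
    stop("unknown muscle '", muscle, "' in geometry")
  g <- geometry[[muscle]]
  if (is.null(dim(joint_angles)))
    joint_angles <- matrix(joint_angles, nrow = 1,
                           dimnames = list(NULL, names(joint_angles)))
  n <- nrow(joint_angles)
  joints <- names(g$arms)
  missing_j <- setdiff(joints, colnames(joint_angles))
  if (length(missing_j) > 0)
    stop("joint angles missing columns: ", paste(missing_j, collapse = ", "))
  l_mt <- rep(g$l_ref, n)
  arms <- matrix(0, n, length(joints), dimnames = list(NULL, joints))
  for (j in joints) {
    co <- g$arms[[j]]                      # r(theta) = sum co[k] theta^(k-1)
    th <- joint_angles[, j]
    r <- rep(0, n)
    P <- rep(0, n)                         # integral of r from 0 to theta
    for (k in seq_along(co)) {
      r <- r + co[k] * th^(k - 1)
      P <- P + co[k] * th^k / k
    }
    arms[, j] <- r
    l_mt <- l_mt - P
  }
  list(l_mt = l_mt, moment_arms = arms)
}

#' First-order activation dynamics
#'
#' Maps a muscle excitation series (normalized EMG, in \[0, 1\]) to an
#' activation series through a first-order ODE with asymmetric time
#' constants: the activation time constant applies while excitation exceeds
#' activation, the (slower) deactivation constant otherwise.  Integration is
#' by an exact exponential update per sample, which reproduces the
#' closed-form first-order response for piecewise-constant excitation.
#'
#' @param excitation numeric series in \[0, 1\].
#' @param fs sampling rate, Hz.
#' @param tau_act activation time constant, s.
#' @param tau_deact deactivation time constant, s.
#' @param a0 initial activation; defaults to the first excitation sample.
#' @return numeric activation series in \[0, 1\].
#' @export
activation_dynamics <- function(excitation, fs, tau_act = 0.015,
                                tau_deact = 0.060, a0 = excitation[1]) {
  if (tau_act <= 0 || tau_deact <= 0)
    stop("time constants must be positive")
  if (any(!is.finite(excitation)) || any(excitation < 0 | excitation > 1))
    stop("excitation must be finite and in [0, 1]")
  dt <- 1 / fs
  k_act <- 1 - exp(-dt / tau_act)
  k_deact <- 1 - exp(-dt / tau_deact)
  n <- length(excitation)
  a <- numeric(n)
  a[1] <- min(max(a0, 0), 1)
  for (i in seq_len(n - 1)) {
    u <- excitation[i + 1]
    k <- if (u > a[i]) k_act else k_deact
    a[i + 1] <- a[i] + (u - a[i]) * k
  }
  a
}

# stable integration step for the fiber-length ODE: the relaxation time of
# the tendon-fiber equilibrium scales with the tendon compliance, i.e.
# with the tendon slack length, so short-tendon muscles need a finer step
muscle_dt_max <- function(params) {
  min(max(0.01 * params$l_slack, 5e-4), 2.5e-3)
}

#' Integrate the equilibrium muscle-tendon state over a trial
#'
#' Forward integration of a Hill-type muscle driven by an activation series
#' and a prescribed muscle-tendon length series.  The fiber length is the
#' state; at each step the fiber velocity is found by inverting the
#' force-velocity relation so that the fiber satisfies force equilibrium
#' with the series-elastic tendon (`f_tendon = (f_ce + f_pe) cos(pennation)`
#' under the constant-thickness pennation model).  Integration uses a
#' fixed-step classical Runge-Kutta scheme with substeps chosen so the
#' effective step stays at or below `dt_max`.  The default step scales
#' with the tendon slack length (the stiffness of the tendon-fiber
#' equilibrium scales with tendon compliance): the short-tendon gluteus
#' maximus integrates at 0.5 ms, the long compliant tendons at up to
#' 2.5 ms.
#'
#' @param activation activation series in \[0, 1\].
#' @param l_mt muscle-tendon length series, m, same length.
#' @param params one-row data.frame of muscle parameters (see
#'   [default_muscle_params()]).
#' @param fs sampling rate, Hz.
#' @param curves Hill-curve constants, see [hill_curves()].
#' @param rigid_tendon if `TRUE` the tendon is inextensible and the fiber
#'   length is slaved to `l_mt` exactly.
#' @param lf0 initial fiber length, m; default is the rigid-tendon estimate
#'   at the first sample.
#' @param dt_max maximum effective integration step, s; `NULL` selects the
#'   muscle-dependent default.
#' @return a `muscle_state_trajectory`: data.frame with columns `time`,
#'   `activation`, `l_mt`, `l_fiber`, `v_fiber`, `pennation`, `f_ce`
#'   (active contractile force at the true activation), `f_pe`,
#'   `f_tendon`, and `residual` — the force-equilibrium residual, which
#'   accounts for the parallel damper and the solver's activation floor,
#'   so it stays at solver tolerance even where `f_ce` alone would not
#'   balance the tendon.
#' @export
integrate_muscle_state <- function(activation, l_mt, params, fs,
                                   curves = hill_curves(),
                                   rigid_tendon = FALSE, lf0 = NULL,
                                   dt_max = NULL) {
  if (length(activation) != length(l_mt))
    stop("activation and l_mt must share one time base")
  validate_muscle_params(params)
  if (nrow(params) != 1) stop("params must be a single muscle row")
  if (is.null(dt_max)) dt_max <- muscle_dt_max(params)
  dt <- 1 / fs
  substeps <- max(1L, as.integer(ceiling(dt / dt_max)))
  if (is.null(lf0)) {
    h <- params$l_opt * sin(params$pennation_opt)
    lf0 <- sqrt(max(l_mt[1] - params$l_slack, 0.01 * params$l_opt)^2 + h^2)
  }
  m <- hill_integrate_cpp(activation, l_mt, dt, substeps,
                          as.list(params[1, ]), curves, rigid_tendon, lf0)
  out <- data.frame(
    time = (seq_along(activation) - 1) / fs,
    activation = m[, "act"],
    l_mt = l_mt,
    l_fiber = m[, "lf"],
    v_fiber = m[, "vf"],
    pennation = acos(pmin(pmax(m[, "cos_penn"], -1), 1)),
    f_ce = m[, "f_ce"],
    f_pe = m[, "f_pe"],
    f_tendon = m[, "f_tendon"],
    residual = m[, "residual"]
  )
  attr(out, "muscle") <- params$muscle
  attr(out, "fs") <- fs
  class(out) <- c("muscle_state_trajectory", "data.frame")
  out
}

#' Net muscle-generated joint moments
#'
#' Sums, per joint, tendon force times moment arm over all muscles spanning
#' that joint.  Moments are returned in the package's generalized-coordinate
#' convention (a positive moment acts to increase the joint angle), in N m,
#' or N m per kg body mass when `body_mass` is given.
#'
#' @param states named list of `muscle_state_trajectory` objects.
#' @param geometry geometry list, see [default_geometry()].
#' @param joint_angles n x joints angle matrix used for the moment arms.
#' @param body_mass optional body mass, kg, to normalize the moments.
#' @return n x 3 matrix with columns `hip`, `knee`, `ankle`.
#' @export
net_joint_moments <- function(states, geometry, joint_angles,
                              body_mass = NULL) {
  n <- nrow(states[[1]])
  if (any(vapply(states, nrow, 1L) != n))
    stop("muscle state trajectories have mismatched time bases")
  if (nrow(joint_angles) != n)
    stop("joint angles do not share the muscle time base")
  out <- matrix(0, n, 3, dimnames = list(NULL, c("hip", "knee", "ankle")))
  for (m in names(states)) {
    mt <- muscle_tendon_length(joint_angles, geometry, m)
    for (j in colnames(mt$moment_arms)) {
      out[, j] <- out[, j] + states[[m]]$f_tendon * mt$moment_arms[, j]
    }
  }
  if (!is.null(body_mass)) {
    if (body_mass <= 0) stop("body_mass must be positive")
    out <- out / body_mass
  }
  out
}
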