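#' Muscle mass from maximum isometric force
#'
#' `mass = (f_max / specific_tension) * l_opt * density`: the physiological
#' cross-sectional area implied by the specific tension, times optimal
#' fiber length, times muscle density.
#'
#' @param params muscle-parameter table (any number of rows).
#' @param coeffs energetics coefficients, see [energetics_coefficients()].
#' @return named numeric vector of muscle masses, kg.
#' @export
#' @examples
#' muscle_mass(default_muscle_params())  # soleus ~0.438 kg
muscle_mass <- function(params, coeffs = energetics_coefficients()) {
  validate_muscle_params(params)
  stats::setNames(params$f_max / coeffs$specific_tension * params$l_opt *
                    coeffs$density, params$muscle)
}

#' Effective slow/fast fiber fractions under orderly recruitment
#'
#' Under orderly recruitment, slow-twitch fibers are recruited first: at
#' zero activation the active pool is entirely slow-twitch, and at full
#' activation the pool reflects the muscle's anatomical composition.  The
#' packaged curve is smooth and monotone between those limits.
#'
#' @param activation activation in \[0, 1\] (vectorized).
#' @param slow_twitch_ratio anatomical slow-twitch fraction.
#' @param model recruitment model label; only `"orderly"` is packaged.
#' @return list with `slow` and `fast` effective fractions (sum to 1).
#' @export
recruitment_fractions <- function(activation, slow_twitch_ratio,
                                  model = "orderly") {
  if (!identical(model, "orderly"))
    stop("unknown recruitment model '", model, "'")
  if (any(activation < 0 | activation > 1))
    stop("activation must lie in [0, 1]")
  fast <- (1 - slow_twitch_ratio) * (1 - cos(pi * activation / 2))
  list(slow = 1 - fast, fast = fast)
}

# Gaussian active force-length multiplier shared with the muscle model
active_force_length <- function(l_norm, width, curves = hill_curves()) {
  exp(log(curves$fl_floor) * ((l_norm - 1) / width)^2)
}

#' Activation-maintenance and shortening-lengthening heat rates
#'
#' Heat rates per kilogram of muscle.  The activation-maintenance rate is
#' the fiber-type-weighted base rate scaled by activation to the power
#' `exp_am`, and — above optimal fiber length — by the active force-length
#' value.  The shortening-lengthening rate is proportional to normalized
#' fiber velocity, with separate shortening coefficients per fiber type
#' (scaled by activation to the larger power `exp_short`) and a single
#' lengthening coefficient (scaled linearly by activation); above optimal
#' length it is scaled like the maintenance rate.  Both are multiplied by
#' the aerobic factor `S`.  With no drive both rates are zero (resting
#' metabolism is not modeled).
#'
#' @param activation,excitation drive series in \[0, 1\].
#' @param l_fiber fiber length series, m.
#' @param v_fiber fiber velocity series, m s^-1 (negative shortening).
#' @param params one-row muscle-parameter data.frame.
#' @param coeffs energetics coefficients.
#' @param curves Hill-curve constants (for the force-length value).
#' @return list with `activation_maintenance` and `shortening_lengthening`
#'   series, W per kg muscle.
#' @export
heat_rates <- function(activation, excitation, l_fiber, v_fiber, params,
                       coeffs = energetics_coefficients(),
                       curves = hill_curves()) {
  if (any(activation < 0 | activation > 1) ||
      any(excitation < 0 | excitation > 1))
    stop("activation and excitation must lie in [0, 1]")
  if (any(l_fiber <= 0)) stop("fiber length must be positive")
  a <- activation
  ln <- l_fiber / params$l_opt
  vn <- v_fiber / params$l_opt                       # l_opt / s
  fr <- recruitment_fractions(a, params$slow_twitch_ratio,
                              coeffs$recruitment_model)
  fl <- active_force_length(ln, params$width, curves)
  len_scale <- ifelse(ln > 1, coeffs$len_scale_w0 + coeffs$len_scale_w1 * fl,
                      1)

  h_am <- coeffs$S * (coeffs$am_base + coeffs$am_fast * fr$fast) *
    a^coeffs$exp_am * len_scale

  v_max_fast <- params$v_max
  v_max_slow <- params$v_max * coeffs$v_max_slow_frac
  a_s_slow <- coeffs$alpha_short_slow_num / v_max_slow
  a_s_fast <- coeffs$alpha_short_fast_num / v_max_fast
  a_len <- coeffs$alpha_lengthen_mult * a_s_slow

  h_sl <- ifelse(vn < 0,
                 (a_s_slow * fr$slow + a_s_fast * fr$fast) * (-vn) *
                   a^coeffs$exp_short,
                 a_len * vn * a)
  h_sl <- coeffs$S * h_sl * len_scale
  list(activation_maintenance = h_am, shortening_lengthening = h_sl)
}

#' Mechanical work rate of the muscle fibers
#'
#' Contractile-element mechanical power per kilogram of muscle, signed:
#' positive while the fiber shortens under tension, negative while it
#' lengthens (work absorption is included, not zeroed).
#'
#' @param f_ce contractile-element force, N.
#' @param v_shortening shortening velocity, m s^-1, positive while the
#'   fiber shortens (the negative of the fiber-length rate of change).
#' @param muscle_mass muscle mass, kg.
#' @return signed work rate series, W per kg muscle.
#' @export
fiber_work_rate <- function(f_ce, v_shortening, muscle_mass) {
  if (muscle_mass <= 0) stop("muscle mass must be positive")
  f_ce * v_shortening / muscle_mass
}

#' Total per-muscle metabolic rate, clamped at zero
#'
#' Sums the heat rates and the fiber work rate, converts to watts per
#' kilogram of body mass, and clamps the per-muscle total at zero from
#' below per sample (net negative fiber work cannot drive ATP synthesis).
#'
#' @param am,sl,work component series, W per kg muscle.
#' @param muscle_mass muscle mass, kg.
#' @param body_mass body mass, kg.
#' @return list with `total` (clamped, W per kg body mass), `unclamped`,
#'   and the three converted components.
#' @export
total_muscle_rate <- function(am, sl, work, muscle_mass, body_mass) {
  if (body_mass <= 0) stop("body_mass must be positive")
  k <- muscle_mass / body_mass
  comp <- list(activation_maintenance = am * k,
               shortening_lengthening = sl * k,
               fiber_work = work * k)
  unclamped <- comp$activation_maintenance + comp$shortening_lengthening +
    comp$fiber_work
  c(list(total = pmax(unclamped, 0), unclamped = unclamped), comp)
}

# full per-muscle energetics from simulated states
muscle_rates_from_states <- function(states, excitations, params, body_mass,
                                     coeffs = energetics_coefficients(),
                                     curves = hill_curves()) {
  masses <- muscle_mass(params, coeffs)
  out <- list()
  for (m in names(states)) {
    st <- states[[m]]
    p <- params[params$muscle == m, , drop = FALSE]
    hr <- heat_rates(st$activation, excitations[[m]], st$l_fiber,
                     st$v_fiber, p, coeffs, curves)
    w <- fiber_work_rate(st$f_ce, -st$v_fiber, masses[[m]])
    out[[m]] <- total_muscle_rate(hr$activation_maintenance,
                                  hr$shortening_lengthening, w,
                                  masses[[m]], body_mass)
  }
  out
}

#' Aggregate per-muscle rates into a limb metabolic profile
#'
#' Sums per-muscle total rates (already on a common stride grid) into the
#' limb profile, and emits component profiles (activation-maintenance,
#' shortening-lengthening, fiber work summed over muscles) and per-group
#' profiles (plantarflexors, knee extensors, hip extensors, dorsiflexors,
#' knee flexors, hip flexors).
#'
#' @param per_muscle named list: per muscle, a list with `total` and the
#'   three component series on the stride grid (W per kg body mass).
#' @param stride_grid percent-of-stride grid (0-100).
#' @return a `metabolic_profile` object.
#' @export
limb_profile <- function(per_muscle, stride_grid) {
  n <- length(stride_grid)
  if (any(vapply(per_muscle, function(x) length(x$total), 1L) != n))
    stop("per-muscle rates are not on the common stride grid")
  sources <- sapply(per_muscle, function(x) x$total)
  comp <- sapply(c("activation_maintenance", "shortening_lengthening",
                   "fiber_work"),
                 function(k) Reduce(`+`, lapply(per_muscle, `[[`, k)))
  groups <- muscle_groups()
  group_profiles <- sapply(names(groups), function(g) {
    ms <- intersect(groups[[g]], colnames(sources))
    if (length(ms) == 0) rep(0, n)
    else rowSums(sources[, ms, drop = FALSE])
  })
  new_metabolic_profile(stride_grid, total = rowSums(sources),
                        sources = sources, components = comp,
                        groups = group_profiles, source_type = "muscle")
}
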