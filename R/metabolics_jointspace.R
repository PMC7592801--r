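# Joint-space metabolic rate: moments and angular velocities in, limb
# metabolic profile out. Joints: hip, knee, ankle on both sides; upper-body
# joints are structurally absent.

js_joints <- function() {
  c("hip_right", "knee_right", "ankle_right",
    "hip_left", "knee_left", "ankle_left")
}

#' Assemble joint-space inputs
#'
#' @param moment n x joints matrix, N m kg^-1, columns named among
#'   `hip_right, knee_right, ankle_right, hip_left, knee_left, ankle_left`
#'   (missing columns are treated as zero).
#' @param omega matching matrix of joint angular velocities, rad s^-1.
#' @return a `joint_inputs` list with full 6-column matrices.
#' @export
joint_inputs <- function(moment, omega) {
  if (!all(dim(moment) == dim(omega)))
    stop("moment and omega must have matching dimensions")
  if (any(!is.finite(moment)) || any(!is.finite(omega)))
    stop("joint inputs must be finite")
  full <- function(x) {
    out <- matrix(0, nrow(x), 6, dimnames = list(NULL, js_joints()))
    known <- intersect(colnames(x), js_joints())
    if (length(known) == 0) stop("no recognized joint columns")
    out[, known] <- x[, known]
    out
  }
  out <- list(moment = full(moment), omega = full(omega))
  class(out) <- "joint_inputs"
  out
}

#' Zero out the contralateral side
#'
#' Reports unilateral metabolic rate by entering zeros for the moments and
#' angular velocities of all joints on the other side of the body; the
#' requested side's channels pass through unchanged.  Idempotent.
#'
#' @param inputs a `joint_inputs` object.
#' @param side `"right"` or `"left"`.
#' @return masked `joint_inputs`.
#' @export
unilateral_mask <- function(inputs, side = c("right", "left")) {
  side <- match.arg(side)
  other <- if (side == "right") "_left" else "_right"
  drop_cols <- grep(other, js_joints(), value = TRUE)
  inputs$moment[, drop_cols] <- 0
  inputs$omega[, drop_cols] <- 0
  inputs
}

#' Joint-space metabolic rate profile
#'
#' Per joint and sample, with moment `M` and angular velocity `omega`:
#' activation-maintenance term `c_am |M|`, shortening-lengthening term
#' `c_sl |M omega|`, and mechanical work at efficiency `eta_pos` for
#' positive power and `eta_neg` for negative power.  The limb profile is
#' the exact sum over joints; each joint's per-sample rate is nonnegative
#' by construction, and all-zero inputs give the identically zero profile
#' (no basal term).
#'
#' @param inputs a `joint_inputs` object (mask first for unilateral
#'   reporting).
#' @param coeffs coefficient set, see [jointspace_coefficients()].
#' @param stride_grid optional percent-stride grid when the inputs are
#'   already stride-normalized; defaults to sample index mapped to 0-100.
#' @return a `metabolic_profile` with per-joint sources, component
#'   decomposition, and moment-direction group profiles.
#' @export
jointspace_rate <- function(inputs, coeffs = jointspace_coefficients(),
                            stride_grid = NULL) {
  req <- c("c_am", "c_sl", "eta_pos", "eta_neg", "dead_band")
  miss <- setdiff(req, names(coeffs))
  if (length(miss) > 0)
    stop("coefficient set incomplete; missing: ", paste(miss, collapse = ", "))
  M <- inputs$moment
  W <- inputs$omega
  if (coeffs$dead_band > 0) M[abs(M) < coeffs$dead_band] <- 0
  n <- nrow(M)
  am <- coeffs$c_am * abs(M)
  sl <- coeffs$c_sl * abs(M * W)
  P <- M * W
  work <- pmax(P, 0) / coeffs$eta_pos + pmax(-P, 0) / coeffs$eta_neg
  sources <- am + sl + work
  comp <- cbind(activation_maintenance = rowSums(am),
                shortening_lengthening = rowSums(sl),
                mechanical_work = rowSums(work))
  # moment-direction groups: extensor direction is a negative moment in the
  # package convention (flexion/dorsiflexion positive)
  grp_def <- list(
    plantarflexors = list("ankle_right", -1), dorsiflexors = list("ankle_right", 1),
    knee_extensors = list("knee_right", -1), knee_flexors = list("knee_right", 1),
    hip_extensors = list("hip_right", -1), hip_flexors = list("hip_right", 1)
  )
  groups <- sapply(names(grp_def), function(g) {
    j <- grp_def[[g]][[1]]; sgn <- grp_def[[g]][[2]]
    sources[, j] * (sign(M[, j]) == sgn)
  })
  if (is.null(stride_grid))
    stride_grid <- 100 * (seq_len(n) - 1) / (n - 1)
  new_metabolic_profile(stride_grid, total = rowSums(sources),
                        sources = sources, components = comp,
                        groups = groups, source_type = "joint")
}

#' Attribute joint rates to muscle groups by moment direction
#'
#' Each joint's metabolic rate at each sample is attributed to the muscle
#' group acting in the direction of the joint moment at that sample
#' (plantarflexors vs dorsiflexors at the ankle, extensors vs flexors at
#' the knee and hip).  Shares are percentages of the right-limb stride
#' average and sum to 100 when the profile is nonzero.
#'
#' @param profile a joint-source `metabolic_profile` from
#'   [jointspace_rate()].
#' @param inputs the `joint_inputs` the profile was computed from.
#' @return named vector of six group shares, percent.
#' @export
partition_by_moment_direction <- function(profile, inputs) {
  if (nrow(inputs$moment) != length(profile$total))
    stop("profile and inputs are not aligned")
  group_shares(profile)
}
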