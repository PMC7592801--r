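#' EMG conditioning: high-pass, rectify, low-pass
#'
#' Standard surface-EMG envelope extraction: zero-phase high-pass filtering
#' at `hp_cutoff` (removes offset and motion artifact), full-wave
#' rectification, then zero-phase low-pass filtering at `lp_cutoff`.  Both
#' filters are 4th-order Butterworth applied forward-backward, so the
#' effective attenuation is doubled and no phase lag is introduced.  Small
#' negative excursions left by the low-pass are clamped to zero.
#'
#' @param raw raw EMG series.
#' @param fs sampling rate, Hz; must exceed twice the high-pass cutoff.
#' @param hp_cutoff high-pass cutoff, Hz.
#' @param lp_cutoff low-pass cutoff, Hz.
#' @return nonnegative envelope series.
#' @export
# zero-phase Butterworth filtering with odd-reflection end padding, so
# that edge transients decay inside the pads rather than in the data
zero_phase <- function(x, filt, fs, cutoff) {
  n <- length(x)
  np <- min(n - 1, 6L * as.integer(ceiling(fs / cutoff)))
  if (np < 1) return(signal::filtfilt(filt, x))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[(np + 1):(np + n)]
}

process_emg <- function(raw, fs, hp_cutoff = 20, lp_cutoff = 6) {
  if (fs <= 2 * max(hp_cutoff, lp_cutoff))
    stop("sampling rate too low for the requested cutoffs")
  if (any(!is.finite(raw))) stop("raw EMG must be finite")
  hp <- signal::butter(4, hp_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(4, lp_cutoff / (fs / 2), type = "low")
  x <- zero_phase(raw, hp, fs, hp_cutoff)
  x <- abs(x)
  x <- zero_phase(x, lp, fs, lp_cutoff)
  pmax(x, 0)
}

#' Normalize an EMG envelope by maximum voluntary contraction
#'
#' Divides the envelope by the MVC reference.  If the trial's maximum then
#' exceeds 1 (a stronger contraction than the MVC trial), the trial is
#' re-normalized by its own maximum so that the maximum is exactly 1.
#'
#' @param envelope nonnegative envelope series.
#' @param mvc positive MVC reference in the same units.
#' @return activation-scaled series in \[0, 1\].
#' @export
normalize_emg <- function(envelope, mvc) {
  if (!is.finite(mvc) || mvc <= 0) stop("mvc must be positive")
  x <- envelope / mvc
  mx <- max(x)
  if (mx > 1) x <- x / mx
  x
}

#' Zero-phase low-pass filtering of ground reaction forces
#'
#' @param raw force series, N.
#' @param fs sampling rate, Hz; must exceed twice the cutoff.
#' @param cutoff low-pass cutoff, Hz.
#' @return filtered series.
#' @export
filter_grf <- function(raw, fs, cutoff = 6) {
  if (fs <= 2 * cutoff) stop("sampling rate too low for the requested cutoff")
  if (any(!is.finite(raw))) stop("GRF must be finite")
  lp <- signal::butter(4, cutoff / (fs / 2), type = "low")
  zero_phase(raw, lp, fs, cutoff)
}

# run-length debouncing of a logical contact mask: fill short FALSE gaps,
# then drop short TRUE runs
debounce_mask <- function(mask, min_len) {
  r <- rle(mask)
  if (length(r$lengths) > 2) {
    inner <- 2:(length(r$lengths) - 1)
    r$values[inner][!r$values[inner] & r$lengths[inner] < min_len] <- TRUE
  }
  mask <- inverse.rle(r)
  r <- rle(mask)
  r$values[r$values & r$lengths < min_len] <- FALSE
  inverse.rle(r)
}

contact_events <- function(grf, fs, threshold, min_dur) {
  mask <- grf >= threshold
  mask <- debounce_mask(mask, max(1L, round(min_dur * fs)))
  d <- diff(c(FALSE, mask))
  list(strikes = which(d == 1), offs = which(d == -1) - 1L)
}

#' Detect heel strikes and toe-offs from vertical ground reaction forces
#'
#' A heel strike is an upward crossing of the force threshold and a toe-off
#' the following downward crossing.  Contact and flight intervals shorter
#' than `min_dur` are merged away (debouncing), so brief force dropouts
#' inside stance do not split the contact.
#'
#' @param grf_ipsi,grf_contra filtered vertical GRF series, N.
#' @param fs sampling rate, Hz.
#' @param threshold contact threshold, N.
#' @param min_dur minimum contact/flight duration, s.
#' @return a `stride_events` list with sample indices `ipsi_heel_strikes`,
#'   `ipsi_toe_offs`, `contra_heel_strikes`, `contra_toe_offs`.
#' @export
detect_strides <- function(grf_ipsi, grf_contra, fs, threshold = 20,
                           min_dur = 0.05) {
  if (threshold <= 0) stop("threshold must be positive")
  ev_i <- contact_events(grf_ipsi, fs, threshold, min_dur)
  ev_c <- contact_events(grf_contra, fs, threshold, min_dur)
  if (length(ev_i$strikes) < 2)
    stop("fewer than 2 ipsilateral heel strikes detected")
  out <- list(ipsi_heel_strikes = ev_i$strikes,
              ipsi_toe_offs = ev_i$offs,
              contra_heel_strikes = ev_c$strikes,
              contra_toe_offs = ev_c$offs)
  class(out) <- "stride_events"
  out
}

#' Partition one stride into gait-cycle phases
#'
#' The stride runs from one ipsilateral heel strike to the next.  Phases
#' are half-open intervals in stride fractions: first double support from
#' ipsilateral heel strike to contralateral toe-off; single support to the
#' contralateral heel strike; second double support to the ipsilateral
#' toe-off; swing to the next ipsilateral heel strike.  For symmetric gait
#' with 62 percent stance the boundaries fall near 12, 50 and 62 percent of
#' the stride; canonical normative boundaries are near 15, 50 and 65
#' percent.
#'
#' @param events `stride_events` object.
#' @param stride_index which stride to partition (1-based).
#' @return a `phase_bounds` data.frame with columns `phase`, `start`,
#'   `end` (fractions of stride); contiguous, non-overlapping, covering
#'   \[0, 1).
#' @export
partition_phases <- function(events, stride_index = 1) {
  hs <- events$ipsi_heel_strikes
  if (stride_index + 1 > length(hs))
    stop("stride ", stride_index, " is incomplete")
  s0 <- hs[stride_index]; s1 <- hs[stride_index + 1]
  L <- s1 - s0
  pick <- function(x, what) {
    v <- x[x > s0 & x < s1]
    if (length(v) == 0) stop("missing ", what, " within stride ",
                             stride_index)
    v[1]
  }
  cto <- pick(events$contra_toe_offs, "contralateral toe-off")
  chs <- pick(events$contra_heel_strikes, "contralateral heel strike")
  ito <- pick(events$ipsi_toe_offs, "ipsilateral toe-off")
  f <- c(cto, chs, ito)
  if (any(diff(c(s0, f, s1)) <= 0))
    stop("gait events out of order within stride ", stride_index)
  fr <- (f - s0) / L
  out <- data.frame(
    phase = c("ds1", "ss", "ds2", "swing"),
    start = c(0, fr),
    end = c(fr, 1),
    stringsAsFactors = FALSE
  )
  class(out) <- c("phase_bounds", "data.frame")
  out
}

#' Resample a series onto a uniform 0-100 percent stride grid
#'
#' Linear interpolation of one stride of data onto `n_points` equally
#' spaced points from 0 to 100 percent of the stride (inclusive).  The
#' sample at the closing heel strike (start of the next stride) provides
#' the 100 percent value.
#'
#' @param series numeric series covering at least the stride.
#' @param stride integer vector `c(start, end)`: sample indices of the
#'   opening and the next heel strike.
#' @param n_points grid length (0 to 100 percent inclusive).
#' @return numeric profile of length `n_points`.
#' @export
time_normalize <- function(series, stride, n_points = 1001) {
  if (n_points < 2) stop("n_points must be at least 2")
  s0 <- stride[1]; s1 <- stride[2]
  if (s1 <= s0) stop("empty stride interval")
  if (s1 > length(series)) stop("stride interval exceeds the series")
  idx <- s0:s1
  stats::approx(x = (idx - s0) / (s1 - s0), y = series[idx],
                xout = seq(0, 1, length.out = n_points))$y
}

#' Remove extreme outliers by the median +/- 3 IQR rule
#'
#' Drops values outside `median(x) +/- 3 * IQR(x)`, with the interquartile
#' range computed with linear-interpolation quantiles.  A degenerate IQR of
#' zero retains all values (a constant set is never discarded).
#'
#' @param values numeric vector of per-trial stride-average scalars.
#' @return list with `values` (retained subset) and `keep` (logical mask).
#' @export
remove_outliers <- function(values) {
  if (length(values) < 3) stop("need at least 3 values")
  med <- stats::median(values)
  iqr <- stats::IQR(values, type = 7)
  keep <- if (iqr == 0) rep(TRUE, length(values))
          else values >= med - 3 * iqr & values <= med + 3 * iqr
  list(values = values[keep], keep = keep)
}

#' Net metabolic rate from respiratory gas exchange
#'
#' Gross metabolic rate from a Brockway-form weighted sum of oxygen uptake
#' and carbon dioxide production, normalized by body mass, minus the
#' standing reference rate.
#'
#' @param vo2 oxygen uptake, ml s^-1 (STPD).
#' @param vco2 carbon dioxide production, ml s^-1.
#' @param standing_rate standing metabolic rate, W kg^-1.
#' @param body_mass body mass, kg.
#' @param coefficients energy equivalents, J per ml of O2 and CO2.
#' @return net metabolic rate, W kg^-1.
#' @export
net_metabolic_rate <- function(vo2, vco2, standing_rate, body_mass,
                               coefficients = c(o2 = 16.58, co2 = 4.51)) {
  if (any(vo2 < 0) || any(vco2 < 0)) stop("gas rates must be nonnegative")
  if (body_mass <= 0) stop("body_mass must be positive")
  (coefficients[["o2"]] * vo2 + coefficients[["co2"]] * vco2) / body_mass -
    standing_rate
}
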