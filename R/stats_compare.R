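# Baseline normalization, repeated-measures correlation with common slope,
# and the Bonferroni-adjusted method comparison.

#' Percent change or percent level relative to a baseline
#'
#' `type = "change"` gives `100 * (value - baseline) / baseline`;
#' `type = "level"` gives `100 * value / baseline` (the value expressed as
#' a percentage of the baseline).
#'
#' @param values numeric vector.
#' @param baseline nonzero baseline scalar.
#' @param type `"change"` or `"level"`.
#' @return numeric vector of percentages.
#' @export
percent_change <- function(values, baseline, type = c("change", "level")) {
  type <- match.arg(type)
  if (!is.finite(baseline) || baseline == 0)
    stop("baseline must be finite and nonzero")
  if (type == "change") 100 * (values - baseline) / baseline
  else 100 * values / baseline
}

#' Repeated-measures correlation
#'
#' Within-subject correlation with a common slope: the ANCOVA model with
#' subject as a factor and `x` as a covariate.  Computed by centering `x`
#' and `y` within subject; the correlation of the centered data is the
#' repeated-measures correlation, the regression of centered `y` on
#' centered `x` is the common slope, and the error degrees of freedom are
#' `n - n_subjects - 1`.  With a single subject this degenerates to the
#' Pearson correlation of that subject's data.
#'
#' @param x,y paired observations.
#' @param subject subject labels (same length).
#' @return an `rmcorr_result` list: `r`, `p`, `slope`, `df`, `n`.
#' @export
rmcorr <- function(x, y, subject) {
  n <- length(x)
  if (length(y) != n || length(subject) != n)
    stop("x, y and subject must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; subject <- as.character(subject[ok])
  n <- length(x)
  k <- length(unique(subject))
  df <- n - k - 1
  if (df < 1)
    stop("insufficient observations: need n - n_subjects - 1 >= 1")
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  ssx <- sum(xc^2); ssy <- sum(yc^2)
  if (ssx == 0 || ssy == 0) {
    r <- 0; slope <- if (ssx == 0) NA_real_ else 0
  } else {
    r <- sum(xc * yc) / sqrt(ssx * ssy)
    slope <- sum(xc * yc) / ssx
  }
  r <- min(max(r, -1), 1)
  p <- if (abs(r) >= 1) 0 else {
    f <- r^2 * df / (1 - r^2)
    stats::pf(f, 1, df, lower.tail = FALSE)
  }
  out <- list(r = r, p = p, slope = slope, df = df, n = n)
  class(out) <- "rmcorr_result"
  out
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr: r = %.3f, slope = %.3f, df = %d, p = %.4g\n",
              x$r, x$slope, x$df, x$p))
  invisible(x)
}

#' Bonferroni adjustment
#'
#' @param p_values vector of p-values.
#' @param m number of comparisons; defaults to the number of p-values.
#' @return adjusted p-values, `min(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stop("m must be at least the number of p-values")
  pmin(1, p_values * m)
}

#' Compare the two estimation methods against calorimetry and each other
#'
#' Two analyses on a tidy summary table (columns `participant`,
#' `condition`, `method`, `stride_average`, and per-phase means `ds1`,
#' `ss`, `ds2`, `swing`):
#'
#' 1. Stride-average tracking: per condition family (treadmill grades,
#'    shoe inclinations), the repeated-measures correlation of each
#'    estimator's stride average versus indirect calorimetry, both
#'    expressed as percent of the participant's baseline.  Extreme
#'    outliers (median +/- 3 IQR, per method) are removed first.  The
#'    slope is of calorimetry on the estimate, so a slope above one means
#'    the estimator underestimates the measured change.
#' 2. Time-profile agreement: per condition, the repeated-measures
#'    correlation between the two estimators' four phase averages
#'    (percent of each method's baseline stride average), with Bonferroni
#'    adjustment across conditions.
#'
#' @param summaries summary data.frame as produced by [run_study()].
#' @param alpha significance threshold.
#' @return list with `stride_tracking` (data.frame), `phase_agreement`
#'   (data.frame with adjusted p-values), `phase_agreement_mean` (mean and
#'   s.e.m. of the per-condition correlations), and `alpha`.
#' @export
compare_methods <- function(summaries, alpha = 0.05) {
  req <- c("participant", "condition", "method", "stride_average",
           "ds1", "ss", "ds2", "swing")
  miss <- setdiff(req, names(summaries))
  if (length(miss) > 0)
    stop("summaries is missing columns: ", paste(miss, collapse = ", "))
  methods <- c("musculoskeletal", "jointspace")
  if (!all(c(methods, "calorimetry") %in% summaries$method))
    stop("summaries must contain musculoskeletal, jointspace and ",
         "calorimetry rows")

  # percent-of-baseline stride averages per participant and method
  s <- summaries
  key <- function(p, m) paste(p, m, sep = "\r")
  base <- s[s$condition == "baseline", ]
  base_map <- stats::setNames(base$stride_average,
                              key(base$participant, base$method))
  missing_cells <- setdiff(key(s$participant, s$method), names(base_map))
  if (length(missing_cells) > 0)
    stop("missing baseline cells for: ",
         paste(unique(missing_cells), collapse = ", "))
  b <- base_map[key(s$participant, s$method)]
  s$pct <- mapply(function(v, bb) percent_change(v, bb, "level"),
                  s$stride_average, b)

  family_of <- function(cond) {
    ifelse(grepl("^grade", cond), "grade",
           ifelse(grepl("^shoe", cond), "shoe", "baseline"))
  }
  s$family <- family_of(s$condition)

  stride_rows <- list()
  for (fam in c("grade", "shoe")) {
    sub <- s[s$family %in% c(fam, "baseline"), ]
    for (m in methods) {
      est <- sub[sub$method == m, c("participant", "condition", "pct")]
      cal <- sub[sub$method == "calorimetry",
                 c("participant", "condition", "pct")]
      mg <- merge(est, cal, by = c("participant", "condition"),
                  suffixes = c("_est", "_cal"))
      if (nrow(mg) >= 3) {
        keep <- remove_outliers(mg$pct_est)$keep &
          remove_outliers(mg$pct_cal)$keep
        mg <- mg[keep, ]
      }
      # a family needs enough observations for the within-subject test
      if (nrow(mg) - length(unique(mg$participant)) - 1 < 1) next
      rc <- rmcorr(mg$pct_est, mg$pct_cal, mg$participant)
      stride_rows[[length(stride_rows) + 1]] <- data.frame(
        family = fam, method = m, r = rc$r, slope = rc$slope, p = rc$p,
        df = rc$df, n = rc$n, significant = rc$p <= alpha)
    }
  }
  stride_tracking <- do.call(rbind, stride_rows)

  # per-condition phase-average agreement between the two estimators
  conds <- setdiff(unique(s$condition), character(0))
  phase_rows <- list()
  for (cond in conds) {
    sub <- s[s$condition == cond & s$method %in% methods, ]
    long <- do.call(rbind, lapply(c("ds1", "ss", "ds2", "swing"),
      function(ph) data.frame(participant = sub$participant,
                              method = sub$method, phase = ph,
                              value = 100 * sub[[ph]] /
                                base_map[key(sub$participant, sub$method)])))
    w <- merge(long[long$method == "musculoskeletal",
                    c("participant", "phase", "value")],
               long[long$method == "jointspace",
                    c("participant", "phase", "value")],
               by = c("participant", "phase"),
               suffixes = c("_msk", "_js"))
    if (nrow(w) < 4) next
    rc <- rmcorr(w$value_js, w$value_msk, w$participant)
    phase_rows[[length(phase_rows) + 1]] <- data.frame(
      condition = cond, r = rc$r, slope = rc$slope, p = rc$p, df = rc$df,
      n = rc$n)
  }
  phase_agreement <- do.call(rbind, phase_rows)
  phase_agreement$p_adjusted <- bonferroni(phase_agreement$p)
  phase_agreement$significant <- phase_agreement$p_adjusted <= alpha
  rvals <- phase_agreement$r
  list(stride_tracking = stride_tracking,
       phase_agreement = phase_agreement,
       phase_agreement_mean = c(mean = mean(rvals),
                                sem = stats::sd(rvals) / sqrt(length(rvals))),
       alpha = alpha)
}
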