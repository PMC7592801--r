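test_that("percent change and percent level behave as documented", {
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(10, 5), 100)
  expect_equal(percent_change(0.83 * 4, 4), -17)
  expect_equal(percent_change(6, 4, type = "level"), 150)
  expect_error(percent_change(1, 0), "baseline")
})

test_that("phase averages integrate the profile over each phase", {
  phases <- data.frame(phase = c("ds1", "ss", "ds2", "swing"),
                       start = c(0, 0.15, 0.5, 0.65),
                       end = c(0.15, 0.5, 0.65, 1))
  grid <- seq(0, 100, length.out = 1001)
  flat <- new_profile_for_test(rep(4, 1001), grid)
  pa <- phase_average(flat, phases)
  expect_equal(unname(pa$phase_shares), c(15, 35, 15, 35))
  expect_equal(unname(pa$phase_means), rep(4, 4))
  expect_equal(sum(pa$phase_shares), 100)
  # profile nonzero only in swing
  y <- rep(0, 1001); y[652:1000] <- 2
  swing_only <- new_profile_for_test(y, grid)
  pa2 <- phase_average(swing_only, phases)
  expect_equal(unname(pa2$phase_shares["swing"]), 100)
  # linearity in the profile
  y2 <- runif(1001)
  pa_a <- phase_average(new_profile_for_test(y2, grid), phases)
  pa_b <- phase_average(new_profile_for_test(3 * y2, grid), phases)
  expect_equal(unname(pa_b$phase_means), unname(3 * pa_a$phase_means))
  expect_error(phase_average(flat, data.frame(phase = "x", start = 0.2,
                                              end = 0.2)), "degenerate")
})

test_that("rmcorr recovers perfect within-subject linearity", {
  x <- rep(1:4, 3)
  subj <- rep(c("a", "b", "c"), each = 4)
  offs <- rep(c(10, -5, 3), each = 4)
  y <- 2 * x + offs
  r <- rmcorr(x, y, subj)
  expect_equal(r$r, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$df, 12 - 3 - 1)
  expect_lt(r$p, 1e-10)
  # y constant within each subject: no within-subject relation
  r0 <- rmcorr(x, offs, subj)
  expect_equal(r0$r, 0)
})

test_that("rmcorr matches the brute-force ANCOVA oracle on small tables", {
  set.seed(31)
  for (case in 1:20) {
    ns <- sample(2:4, 1)
    nc <- sample(2:4, 1)
    subj <- rep(letters[1:ns], each = nc)
    x <- as.numeric(sample(0:9, ns * nc, replace = TRUE))
    y <- as.numeric(sample(0:9, ns * nc, replace = TRUE))
    xc <- x - stats::ave(x, subj)
    if (sum(xc^2) == 0) next
    r <- rmcorr(x, y, subj)
    # oracle: ANCOVA with subject factor and common slope
    fit <- stats::lm(y ~ factor(subj) + x)
    an <- stats::anova(fit)
    ss_x <- an["x", "Sum Sq"]
    ss_err <- an["Residuals", "Sum Sq"]
    slope <- stats::coef(fit)[["x"]]
    r_oracle <- sign(slope) * sqrt(ss_x / (ss_x + ss_err))
    p_oracle <- an["x", "Pr(>F)"]
    expect_equal(r$r, r_oracle, tolerance = 1e-10)
    expect_equal(r$slope, slope, tolerance = 1e-10)
    expect_equal(r$df, an["Residuals", "Df"])
    if (abs(r$r) < 1) expect_equal(r$p, p_oracle, tolerance = 1e-10)
  }
})

test_that("rmcorr is shift-invariant per subject and degenerates to Pearson", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(12)
  subj <- rep(c("a", "b", "c"), each = 4)
  base <- rmcorr(x, y, subj)
  shifted <- rmcorr(x + rep(c(100, -50, 7), each = 4),
                    y + rep(c(-3, 9, 40), each = 4), subj)
  expect_equal(base$r, shifted$r)
  expect_equal(base$slope, shifted$slope)
  # single subject: Pearson correlation
  one <- rmcorr(x[1:6], y[1:6], rep("s", 6))
  expect_equal(one$r, stats::cor(x[1:6], y[1:6]), tolerance = 1e-12)
  expect_error(rmcorr(x[1:3], y[1:3], c("a", "b", "c")), "insufficient")
})

test_that("Bonferroni caps at one and preserves ordering", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 8), 1)
  p <- c(0.001, 0.02, 0.04, 0.3)
  adj <- bonferroni(p)
  expect_equal(adj, pmin(1, p * 4))
  expect_equal(order(adj), order(p))
  expect_error(bonferroni(p, m = 2), "m must be")
})

test_that("method comparison is exact on self-comparison and degrades with noise", {
  mk_summaries <- function(noise_sd, seed) {
    set.seed(seed)
    conds <- c("baseline", "grade-6", "grade+6", "shoe-7", "shoe+7")
    rows <- list()
    for (p in c("P1", "P2", "P3")) {
      lat_base <- runif(1, 3, 4)
      for (cond in conds) {
        lat <- lat_base * switch(cond, baseline = 1, `grade-6` = 0.7,
                                 `grade+6` = 2, `shoe-7` = 1.1,
                                 `shoe+7` = 1.05)
        ph_lat <- lat * c(0.6, 1.6, 0.9, 0.8)
        for (m in c("musculoskeletal", "jointspace")) {
          ph <- ph_lat * exp(rnorm(4, 0, noise_sd))
          rows[[length(rows) + 1]] <- data.frame(
            participant = p, condition = cond, method = m,
            stride_average = lat * exp(rnorm(1, 0, noise_sd)),
            ds1 = ph[1], ss = ph[2], ds2 = ph[3], swing = ph[4])
        }
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, condition = cond, method = "calorimetry",
          stride_average = lat * exp(rnorm(1, 0, noise_sd)),
          ds1 = NA, ss = NA, ds2 = NA, swing = NA)
      }
    }
    do.call(rbind, rows)
  }
  # no noise: both methods and calorimetry share the latent values exactly
  st <- compare_methods(mk_summaries(0, 1))
  expect_true(all(abs(st$stride_tracking$r - 1) < 1e-10))
  expect_true(all(abs(st$phase_agreement$r - 1) < 1e-10))
  expect_equal(st$alpha, 0.05)
  expect_equal(st$phase_agreement$significant,
               st$phase_agreement$p_adjusted <= 0.05)
  # correlations decrease as independent noise grows
  mean_r <- function(noise, seed)
    mean(compare_methods(mk_summaries(noise, seed))$phase_agreement$r)
  expect_gt(mean_r(0.05, 2), mean_r(0.6, 2))
  expect_error(compare_methods(mk_summaries(0, 1)[, -4]), "missing columns")
})
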