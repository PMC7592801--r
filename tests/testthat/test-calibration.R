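fake_traj <- function(ft, lf = NULL) {
  n <- length(ft)
  data.frame(time = seq_len(n), f_tendon = ft,
             l_fiber = if (is.null(lf)) rep(0.05, n) else lf)
}

test_that("zero-force penalty counts muscles below the force epsilon", {
  active <- list(a = fake_traj(c(0, 50, 120)), b = fake_traj(c(5, 80, 10)))
  expect_equal(zero_force_penalty(active), 0)
  one_off <- c(active, list(c = fake_traj(c(0, 0, 0))))
  expect_equal(zero_force_penalty(one_off), 1)
  # a 0.5 N peak with epsilon 1 N counts as zero-force
  faint <- list(a = fake_traj(c(0, 0.5, 0.2)))
  expect_equal(zero_force_penalty(faint, eps = 1), 1)
  expect_equal(zero_force_penalty(faint, eps = 0.1), 0)
})

test_that("plantarflexor distribution penalty compares soleus to gastrocs", {
  mk <- function(sol, gm, gl)
    list(soleus = fake_traj(rep(sol, 4)),
         gastrocnemius_medialis = fake_traj(rep(gm, 4)),
         gastrocnemius_lateralis = fake_traj(rep(gl, 4)))
  expect_equal(plantarflexor_distribution_penalty(mk(100, 60, 80)), 0)
  expect_equal(plantarflexor_distribution_penalty(mk(50, 60, 80)), 1)
  # boundary: equality is not penalized (strict inequality)
  expect_equal(plantarflexor_distribution_penalty(mk(70, 60, 80)), 0)
  expect_error(plantarflexor_distribution_penalty(
    mk(1, 1, 1)[-1]), "soleus")
})

test_that("physiological range penalty enforces the closed width bounds", {
  params <- default_muscle_params()
  sol <- params[params$muscle == "soleus", ]
  within <- list(soleus = fake_traj(rep(1, 5), lf = rep(sol$l_opt, 5)))
  expect_equal(physiological_range_penalty(within, params), 0)
  dipping <- list(soleus = fake_traj(rep(1, 5),
                                     lf = c(rep(sol$l_opt, 4),
                                            0.1 * sol$l_opt)))
  expect_equal(physiological_range_penalty(dipping, params), 1)
  # exactly at the bound for one sample is inside the closed interval
  at_bound <- list(soleus = fake_traj(rep(1, 5),
                                      lf = c(rep(sol$l_opt, 4),
                                             sol$l_opt * (1 + sol$width))))
  expect_equal(physiological_range_penalty(at_bound, params), 0)
})

test_that("hip extension MSE masks to the extension direction", {
  # extension is negative in the flexion-positive convention
  ref <- c(0.5, 0.2, -0.3, -0.6, 0.1)
  sim <- c(9, 9, -0.3, -0.6, 9)
  expect_equal(hip_extension_mse(sim, ref), 0)
  # constructed offset d on the extension samples gives d^2
  d <- 0.25
  sim2 <- ref + c(0, 0, d, d, 0)
  expect_equal(hip_extension_mse(sim2, ref), d^2)
  # brute-force sample-by-sample oracle on random series
  set.seed(11)
  r <- rnorm(50); s <- rnorm(50)
  manual <- mean((s[r < 0] - r[r < 0])^2)
  expect_equal(hip_extension_mse(s, r), manual)
  expect_error(hip_extension_mse(abs(r), abs(r)), "extension")
})

test_that("the cost ledger adds up and penalties dominate", {
  tt <- fix_truth()
  bd <- cost_function(tt$params, tt$trial, tt$reference,
                      geometry = tt$geometry)
  expect_equal(bd$total,
               bd$mse_ankle + bd$mse_knee + bd$mse_hip_extension +
                 1e6 * (bd$zero_force_penalty +
                          bd$plantarflexor_distribution_penalty +
                          bd$physiological_range_penalty))
  # deterministic for fixed inputs
  bd2 <- cost_function(tt$params, tt$trial, tt$reference,
                       geometry = tt$geometry)
  expect_equal(bd$total, bd2$total)
  # a candidate that triggers any penalty costs at least 1e6
  cand <- tt$params
  cand$l_slack[cand$muscle == "soleus"] <-
    cand$l_slack[cand$muscle == "soleus"] * 1.3
  bd3 <- cost_function(cand, tt$trial, tt$reference,
                       geometry = tt$geometry)
  expect_gte(bd3$zero_force_penalty + bd3$plantarflexor_distribution_penalty +
               bd3$physiological_range_penalty, 1)
  expect_gte(bd3$total, 1e6)
  expect_equal(bd3$total,
               bd3$mse_ankle + bd3$mse_knee + bd3$mse_hip_extension +
                 1e6 * (bd3$zero_force_penalty +
                          bd3$plantarflexor_distribution_penalty +
                          bd3$physiological_range_penalty))
})

test_that("pattern search minimizes a convex quadratic inside its box", {
  center <- c(a = 1.1, b = 0.7)
  obj <- function(x) list(total = sum((x - center)^2))
  seen <- new.env(); seen$all <- list()
  obj_logged <- function(x) { seen$all[[length(seen$all) + 1]] <- x; obj(x) }
  x0 <- c(a = 1, b = 1)
  res <- pattern_search(obj_logged, x0)
  expect_lt(sum((res$x_best - center)^2), 1e-4)
  # no iterate ever leaves the 50-150% box
  for (x in seen$all) {
    expect_true(all(x >= 0.5 * x0 - 1e-12) && all(x <= 1.5 * x0 + 1e-12))
  }
  # best-so-far trace is monotone nonincreasing
  expect_true(all(diff(res$log$best_cost) <= 0))
})

test_that("calibration recovers a uniformly mis-scaled start", {
  rec <- fix_recovery()
  start_cost <- cost_function(rec$start, fix_truth()$trial,
                              fix_truth()$reference,
                              geometry = fix_truth()$geometry)$total
  expect_lt(rec$result$breakdown$total, start_cost)
  mse <- with(rec$result$breakdown,
              mse_ankle + mse_knee + mse_hip_extension)
  expect_lt(mse, 1e-3)
  expect_true(penalties_zero <- rec$result$breakdown$zero_force_penalty == 0)
})
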