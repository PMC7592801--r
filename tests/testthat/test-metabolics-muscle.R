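test_that("muscle mass follows the cross-section formula", {
  params <- default_muscle_params()
  masses <- muscle_mass(params)
  # soleus: (6195 / 600000) * 0.04 * 1059.7
  expect_equal(unname(masses["soleus"]), 6195 / 600000 * 0.04 * 1059.7,
               tolerance = 1e-12)
  expect_lt(masses["tibialis_anterior"], masses["soleus"])
  # linear in f_max
  doubled <- params
  doubled$f_max <- 2 * doubled$f_max
  expect_equal(unname(muscle_mass(doubled)), unname(2 * masses))
})

test_that("orderly recruitment moves from slow-only to the anatomical mix", {
  fr0 <- recruitment_fractions(0, 0.7)
  expect_equal(fr0$slow, 1)
  expect_equal(fr0$fast, 0)
  fr1 <- recruitment_fractions(1, 0.7)
  expect_equal(fr1$slow, 0.7)
  expect_equal(fr1$fast, 0.3)
  a <- seq(0, 1, by = 0.05)
  fr <- recruitment_fractions(a, 0.55)
  expect_true(all(diff(fr$slow) <= 0))
  expect_equal(fr$slow + fr$fast, rep(1, length(a)))
  expect_error(recruitment_fractions(0.5, 0.7, model = "random"),
               "recruitment model")
  expect_error(recruitment_fractions(1.2, 0.7), "activation")
})

test_that("heat rates vanish without drive and scale exactly with S", {
  p <- default_muscle_params()[2, ]
  n <- 6
  lf <- p$l_opt * seq(0.9, 1.15, length.out = n)
  vf <- p$l_opt * c(-2, -1, 0, 0.5, 1, 2)
  act <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  zero <- heat_rates(rep(0, n), rep(0, n), lf, vf, p)
  expect_equal(zero$activation_maintenance, rep(0, n))
  expect_equal(zero$shortening_lengthening, rep(0, n))
  # isometric fiber: no shortening-lengthening heat
  iso <- heat_rates(act, act, lf, rep(0, n), p)
  expect_equal(iso$shortening_lengthening, rep(0, n))
  expect_true(all(iso$activation_maintenance[-1] > 0))
  # the aerobic factor is an exact multiplicative identity
  h1 <- heat_rates(act, act, lf, vf, p,
                   coeffs = energetics_coefficients(S = 1))
  h15 <- heat_rates(act, act, lf, vf, p,
                    coeffs = energetics_coefficients(S = 1.5))
  expect_equal(h15$activation_maintenance, 1.5 * h1$activation_maintenance)
  expect_equal(h15$shortening_lengthening, 1.5 * h1$shortening_lengthening)
  expect_error(heat_rates(act, act, -lf, vf, p), "fiber length")
})

test_that("fiber work rate is signed mechanical power per muscle mass", {
  expect_equal(fiber_work_rate(100, 0.1, 0.5), 20)
  expect_equal(fiber_work_rate(100, -0.1, 0.5), -20)
  expect_equal(fiber_work_rate(100, 0, 0.5), 0)
  expect_error(fiber_work_rate(100, 0.1, 0), "mass")
})

test_that("per-muscle totals clamp at zero and decompose exactly", {
  am <- c(10, 5, 2)
  sl <- c(3, 1, 0)
  work <- c(5, -20, -1)
  r <- total_muscle_rate(am, sl, work, muscle_mass = 0.4, body_mass = 80)
  k <- 0.4 / 80
  expect_equal(r$unclamped,
               r$activation_maintenance + r$shortening_lengthening +
                 r$fiber_work)
  expect_equal(r$unclamped, (am + sl + work) * k)
  expect_equal(r$total, pmax((am + sl + work) * k, 0))
  expect_equal(r$total[2], 0)            # strongly negative work clamps to 0
  expect_equal(r$total[1], r$unclamped[1])
  expect_gte(sum(r$total), sum(r$unclamped))
})

test_that("the limb profile aggregates muscles and groups completely", {
  grid <- seq(0, 100, length.out = 11)
  mk <- function(tot) list(total = tot,
                           activation_maintenance = tot * 0.5,
                           shortening_lengthening = tot * 0.3,
                           fiber_work = tot * 0.2)
  one <- list(soleus = mk(rep(2, 11)))
  prof1 <- limb_profile(one, grid)
  expect_equal(prof1$total, one$soleus$total)
  per <- lapply(stats::setNames(default_muscle_params()$muscle,
                                default_muscle_params()$muscle),
                function(m) mk(runif(11, 0.5, 1.5)))
  prof <- limb_profile(per, grid)
  expect_equal(prof$total, rowSums(prof$sources))
  expect_equal(sum(group_shares(prof)), 100)
  # group mapping: plantarflexors are soleus plus both gastrocnemii
  pf <- prof$sources[, "soleus"] +
    prof$sources[, "gastrocnemius_medialis"] +
    prof$sources[, "gastrocnemius_lateralis"]
  expect_equal(prof$groups[, "plantarflexors"], pf)
  expect_equal(prof$groups[, "knee_extensors"],
               prof$sources[, "vastus_medialis"])
  expect_equal(prof$groups[, "hip_extensors"],
               prof$sources[, "gluteus_maximus"])
  expect_equal(prof$groups[, "dorsiflexors"],
               prof$sources[, "tibialis_anterior"])
  expect_equal(prof$groups[, "knee_flexors"],
               prof$sources[, "biceps_femoris"])
  expect_error(limb_profile(list(soleus = mk(rep(1, 5))), grid),
               "stride grid")
})

test_that("a zero-activation stride yields an identically zero profile", {
  tr <- fix_trial()
  tr$emg[] <- 0
  est <- estimate_musculoskeletal(tr, n_points = 101, fs_sim = 250)
  expect_equal(est$profile$total, rep(0, 101))
  expect_equal(est$stride_average, 0)
})

test_that("muscle rate scales linearly with muscle mass for fixed states", {
  sim <- fix_sim()
  params <- default_muscle_params()
  r1 <- stridemet:::muscle_rates_from_states(sim$states, sim$excitations,
                                             params, 80)
  params2 <- params
  params2$f_max <- 2 * params2$f_max
  r2 <- stridemet:::muscle_rates_from_states(sim$states, sim$excitations,
                                             params2, 80)
  # identical states, doubled f_max -> doubled mass -> doubled heat terms
  expect_equal(r2$soleus$activation_maintenance,
               2 * r1$soleus$activation_maintenance)
  expect_equal(r2$soleus$shortening_lengthening,
               2 * r1$soleus$shortening_lengthening)
})
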