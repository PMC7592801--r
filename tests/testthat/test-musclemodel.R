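test_that("muscle-tendon length is consistent with the moment arms", {
  geom <- default_geometry()
  # linear case: constant arm r over angle change dtheta gives -r dtheta
  th <- cbind(hip = c(0, 0), knee = c(0, 0), ankle = c(0, 0.3))
  mt <- muscle_tendon_length(th, geom, "soleus")
  r <- geom$soleus$arms$ankle[1]
  expect_equal(mt$l_mt[2] - mt$l_mt[1], -r * 0.3)
  # finite-difference oracle on a quadratic moment-arm polynomial
  geom2 <- geom
  geom2$soleus$arms$ankle <- c(-0.05, 0.01, 0.02)
  for (th0 in c(-0.3, 0, 0.25)) {
    h <- 1e-6
    grid <- cbind(hip = 0, knee = 0, ankle = c(th0 - h, th0 + h))
    mt2 <- muscle_tendon_length(grid, geom2, "soleus")
    dl <- (mt2$l_mt[2] - mt2$l_mt[1]) / (2 * h)
    r_at <- -0.05 + 0.01 * th0 + 0.02 * th0^2
    expect_lt(abs(dl + r_at), 1e-6)
  }
  # the gastrocnemius responds to both knee and ankle angles
  base <- muscle_tendon_length(cbind(hip = 0, knee = 0, ankle = 0), geom,
                               "gastrocnemius_medialis")$l_mt
  knee_flex <- muscle_tendon_length(cbind(hip = 0, knee = 0.4, ankle = 0),
                                    geom, "gastrocnemius_medialis")$l_mt
  dorsi <- muscle_tendon_length(cbind(hip = 0, knee = 0, ankle = 0.3),
                                geom, "gastrocnemius_medialis")$l_mt
  expect_true(knee_flex != base && dorsi != base)
  expect_error(muscle_tendon_length(cbind(hip = 0, knee = 0, ankle = 0),
                                    geom, "psoas"), "unknown muscle")
})

test_that("activation dynamics follow the first-order response", {
  fs <- 1000
  # constant excitation: activation converges to the excitation
  a <- activation_dynamics(rep(0.6, 2000), fs, a0 = 0)
  expect_lt(abs(a[2000] - 0.6), 1e-3)
  # step response reaches 1 - 1/e at t = tau_act after the step
  tau <- 0.015
  u <- c(rep(0, 101), rep(1, 200))
  a <- activation_dynamics(u, fs, tau_act = tau, a0 = 0)
  expect_equal(a[101 + tau * fs], 1 - exp(-1), tolerance = 1e-9)
  # zero in, zero out
  expect_equal(activation_dynamics(rep(0, 50), fs), rep(0, 50))
  expect_error(activation_dynamics(rep(0.5, 10), fs, tau_act = 0),
               "time constants")
  expect_error(activation_dynamics(c(0.5, 1.2), fs), "excitation")
})

test_that("isometric optimum reproduces the maximal forces", {
  p <- default_muscle_params()[2, ]   # soleus
  lmt <- rep(p$l_slack + p$l_opt * cos(p$pennation_opt), 100)
  st <- integrate_muscle_state(rep(1, 100), lmt, p, fs = 200,
                               rigid_tendon = TRUE)
  i <- 50
  expect_equal(st$l_fiber[i], p$l_opt, tolerance = 1e-10)
  expect_equal(st$f_ce[i], p$f_max, tolerance = 1e-6)
  expect_equal(st$f_tendon[i], p$f_max * cos(p$pennation_opt),
               tolerance = 1e-6)
})

test_that("active force vanishes at maximal shortening velocity", {
  p <- default_muscle_params()[1, ]   # tibialis anterior
  fs <- 2000
  n <- 100
  v <- p$v_max * p$l_opt                    # fiber shortening speed, m/s
  lf <- p$l_opt * 1.3 - (seq_len(n) - 1) / fs * v
  h <- p$l_opt * sin(p$pennation_opt)
  lmt <- p$l_slack + sqrt(pmax(lf^2 - h^2, 1e-8))
  st <- integrate_muscle_state(rep(1, n), lmt, p, fs, rigid_tendon = TRUE)
  mid <- round(n / 2)
  expect_equal(st$v_fiber[mid], -v, tolerance = 0.02 * v)
  expect_lt(st$f_ce[mid], 0.02 * p$f_max)
})

test_that("muscle states settle to a stride-periodic orbit after warm-up", {
  sim <- fix_sim()
  tr <- sim$trial
  nps <- tr$samples_per_stride
  for (m in c("soleus", "vastus_medialis", "gluteus_maximus")) {
    s3 <- sim$states[[m]]$l_fiber[(2 * nps + 1):(3 * nps)]
    s4 <- sim$states[[m]]$l_fiber[(3 * nps + 1):(4 * nps)]
    expect_lt(max(abs(s4 - s3)) / mean(s3), 0.01)
  }
})

test_that("equilibrium holds and tendons never push", {
  sim <- fix_sim()
  params <- default_muscle_params()
  for (m in names(sim$states)) {
    st <- sim$states[[m]]
    fmax <- params$f_max[params$muscle == m]
    expect_lt(max(st$residual), 1e-3 * fmax)
    expect_true(all(st$f_tendon >= 0))
    expect_true(all(st$l_fiber > 0))
  }
})

test_that("halving the integration step barely changes the trajectory", {
  tr <- fix_trial()
  p <- default_muscle_params()[2, ]
  geom <- default_geometry()
  exc <- normalize_emg(tr$emg[, "soleus"], 1)
  act <- activation_dynamics(exc, tr$fs)
  lmt <- muscle_tendon_length(tr$joint_angles, geom, "soleus")$l_mt
  a <- integrate_muscle_state(act, lmt, p, tr$fs, dt_max = 1e-3)
  b <- integrate_muscle_state(act, lmt, p, tr$fs, dt_max = 5e-4)
  expect_lt(max(abs(a$l_fiber - b$l_fiber)) / p$l_opt, 1e-3)
})

test_that("a rigid tendon slaves the fiber to the path length exactly", {
  p <- default_muscle_params()[5, ]   # vastus
  n <- 50
  lmt <- p$l_slack + p$l_opt * seq(0.8, 1.2, length.out = n)
  st <- integrate_muscle_state(rep(0.5, n), lmt, p, fs = 100,
                               rigid_tendon = TRUE)
  h <- p$l_opt * sin(p$pennation_opt)
  expect_equal(st$l_fiber, sqrt((lmt - p$l_slack)^2 + h^2),
               tolerance = 1e-12)
})

test_that("net joint moments sum force times arm with cancellation", {
  n <- 20
  geom <- list(
    m1 = list(l_ref = 0.3, arms = list(knee = c(0.04))),
    m2 = list(l_ref = 0.3, arms = list(knee = c(-0.04)))
  )
  fake_state <- function(f) {
    s <- data.frame(time = seq_len(n), f_tendon = rep(f, n))
    s
  }
  ang <- cbind(hip = rep(0, n), knee = rep(0, n), ankle = rep(0, n))
  single <- net_joint_moments(list(m1 = fake_state(100)), geom, ang)
  expect_equal(single[, "knee"], rep(100 * 0.04, n))
  expect_equal(single[, "ankle"], rep(0, n))
  both <- net_joint_moments(list(m1 = fake_state(100),
                                 m2 = fake_state(100)), geom, ang)
  expect_equal(both[, "knee"], rep(0, n))
  expect_error(net_joint_moments(list(m1 = fake_state(100)), geom,
                                 ang[1:5, ]), "time base")
})

test_that("the lateral gastrocnemius is driven by the medial EMG and spans two joints", {
  cmap <- stridemet:::emg_channel_map()
  expect_equal(unname(cmap["gastrocnemius_lateralis"]),
               "gastrocnemius_medialis")
  geom <- default_geometry()
  expect_setequal(names(geom$gastrocnemius_lateralis$arms),
                  c("ankle", "knee"))
  sim <- fix_sim()
  expect_equal(sim$excitations$gastrocnemius_lateralis,
               sim$excitations$gastrocnemius_medialis)
})
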