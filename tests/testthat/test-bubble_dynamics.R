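test_that("initial gas pressure follows the static interface balance", {
  glp <- gas_liquid_params()
  expect_equal(initial_gas_pressure(2e-6, glp), 154970, tolerance = 1e-12)
  # surface-tension-free limit
  free <- gas_liquid_params(sigma_g = 0, pv = 0)
  expect_equal(initial_gas_pressure(1e-6, free), free$p0)
  # surface contribution is linear in 1/R0
  surf <- function(R0) initial_gas_pressure(R0, glp) - glp$p0 + glp$pv
  expect_equal(surf(1e-6), 2 * surf(2e-6), tolerance = 1e-12)
  expect_error(initial_gas_pressure(-1e-6, glp), "R0 must be > 0")
  # unphysical: enormous negative vapour-pressure excess
  expect_error(initial_gas_pressure(1e-2, gas_liquid_params(pv = 2e5)),
               "unphysical")
})

test_that("polytropic gas law compresses and expands as expected", {
  pg0 <- 154970
  expect_equal(gas_pressure(2e-6, 2e-6, pg0, 1.07), pg0)
  expect_equal(gas_pressure(1e-6, 2e-6, pg0, 1.07),
               pg0 * 9.253505471242299, tolerance = 1e-12)
  expect_lt(gas_pressure(1, 2e-6, pg0, 1.07), 1e-10)
  R <- seq(1e-6, 4e-6, length.out = 50)
  expect_true(all(diff(gas_pressure(R, 2e-6, pg0, 1.07)) < 0))
  expect_error(gas_pressure(0, 2e-6, pg0), "R must be > 0")
})

test_that("natural frequency reduces to the Minnaert form and scales as
           1/R0 without surface tension", {
  free <- gas_liquid_params(sigma_g = 0, pv = 0)
  R0 <- 3e-6
  expect_equal(natural_frequency(R0, free),
               sqrt(3 * free$kappa * free$p0 / free$rho_f) / (2 * pi * R0),
               tolerance = 1e-14)
  expect_equal(natural_frequency(R0, free) / natural_frequency(2 * R0, free),
               2, tolerance = 1e-12)
  # with surface tension, agrees with the stiffness of the equations of
  # motion: finite-difference the equilibrium acceleration restoring force
  glp <- gas_liquid_params()
  cfg <- quick_scenario(dual = FALSE, Pd = 0,
                        rheology = viscosity_mode("constant"))
  R0 <- cfg$bubbles$R10
  h <- 1e-12
  dadR <- (coupled_accelerations(R0 + h, 0, 0, cfg) -
             coupled_accelerations(R0 - h, 0, 0, cfg)) / (2 * h)
  expect_equal(natural_frequency(R0, glp), sqrt(-dadR) / (2 * pi),
               tolerance = 1e-5)
  expect_equal(natural_frequency(2e-6, glp), 1624743.23, tolerance = 1e-8)
})

test_that("coupled accelerations vanish at equilibrium and decouple at
           large spacing", {
  for (kind in c("carreau_yasuda", "constant")) {
    cfg <- quick_scenario(Pd = 0, rheology = viscosity_mode(kind))
    R0 <- c(cfg$bubbles$R10, cfg$bubbles$R20)
    acc <- coupled_accelerations(R0, c(0, 0), 0, cfg)
    expect_lt(max(abs(acc)), 1e-4)   # residual is rounding of ~1e5 Pa terms
  }
  # far-apart pair behaves as two isolated bubbles (coupling decays as 1/d)
  iso <- quick_scenario(dual = FALSE)
  R <- c(2.3e-6, 1.8e-6); U <- c(1.5, -2.0); t <- 1e-7
  a1 <- coupled_accelerations(R[1], U[1], t, iso)
  err <- sapply(c(1, 1e3, 1e6), function(d) {
    far <- quick_scenario(d = d)
    abs(coupled_accelerations(R, U, t, far)[1] - a1) / abs(a1)
  })
  expect_lt(err[3], 1e-10)
  expect_true(all(diff(err) < 0))
})

test_that("coupled accelerations agree with an independent assembly of the
           two-bubble system", {
  set.seed(7)
  for (kind in c("carreau_yasuda", "constant")) {
    cfg <- quick_scenario(rheology = viscosity_mode(kind))
    for (i in 1:25) {
      R <- runif(2, 0.5e-6, 4e-6)
      U <- runif(2, -20, 20)
      t <- runif(1, 0, 1e-6)
      got <- coupled_accelerations(R, U, t, cfg)
      want <- oracle_accelerations(R, U, t, cfg)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
  # matrix (time-vectorised) evaluation matches the scalar path
  cfg <- quick_scenario()
  Rm <- matrix(runif(10, 1e-6, 3e-6), 5, 2)
  Um <- matrix(runif(10, -5, 5), 5, 2)
  tv <- seq(0, 1e-6, length.out = 5)
  accm <- coupled_accelerations(Rm, Um, tv, cfg)
  for (k in 1:5)
    expect_equal(accm[k, ],
                 coupled_accelerations(Rm[k, ], Um[k, ], tv[k], cfg),
                 tolerance = 1e-14)
})

test_that("an undriven bubble stays at its equilibrium radius", {
  for (kind in c("carreau_yasuda", "constant")) {
    cfg <- quick_scenario(dual = FALSE, Pd = 0,
                          rheology = viscosity_mode(kind),
                          t_end_cycles = 5)
    traj <- simulate_bubbles(cfg)
    expect_lt(max(abs(traj$R - cfg$bubbles$R10)), 1e-5 * cfg$bubbles$R10)
    expect_false(traj$collapsed)
  }
})

test_that("equal bubbles oscillate identically and the trajectory fields
           are mutually consistent", {
  traj <- simulate_bubbles(quick_scenario(t_end_cycles = 10))
  expect_lt(max(abs(traj$R[, 1] - traj$R[, 2])) / 2e-6, 1e-12)
  expect_true(all(traj$R > 0))
  expect_equal(traj$V, 4 / 3 * pi * traj$R^3)
  expect_equal(traj$Vdot, 4 * pi * traj$R^2 * traj$Rdot)
  # accelerations stored on the output grid match the equations of motion
  k <- c(5, 500, 1500)
  for (i in k)
    expect_equal(traj$Rddot[i, ],
                 coupled_accelerations(traj$R[i, ], traj$Rdot[i, ],
                                       traj$t[i], traj$config),
                 tolerance = 1e-12)
})

test_that("a distant pair reproduces the single-bubble trajectory
           pointwise", {
  pair <- simulate_bubbles(quick_scenario(d = 1, t_end_cycles = 20))
  solo <- simulate_bubbles(quick_scenario(dual = FALSE, t_end_cycles = 20))
  expect_lt(max(abs(pair$R[, 1] - solo$R[, 1]) / solo$R[, 1]), 1e-3)
})

test_that("small-amplitude response matches the linearised damped-driven
           oscillator", {
  # constant viscosity raised to 0.01 Pa s so the startup transient decays
  # within a few cycles and a steady state exists inside a short run
  mu <- 0.01; Pd <- 500; f <- 1e6
  cfg <- quick_scenario(dual = FALSE, Pd = Pd, f = f,
                        rheology = viscosity_mode("constant",
                                                  constant_value = mu),
                        t_end_cycles = 20, metrics_cycles = 5)
  traj <- simulate_bubbles(cfg)
  win <- traj$t >= 15 / f
  amp <- (max(traj$R[win, 1]) - min(traj$R[win, 1])) / 2
  glp <- cfg$gas
  R0 <- cfg$bubbles$R10
  m <- glp$rho_f * R0^2
  k <- 3 * glp$kappa * initial_gas_pressure(R0, glp) - 2 * glp$sigma_g / R0
  cc <- 4 * mu
  om <- 2 * pi * f
  amp_lin <- R0 * Pd / sqrt((k - m * om^2)^2 + (cc * om)^2)
  expect_equal(amp, amp_lin, tolerance = 0.05)
})

test_that("the collapse guard flags an inertial-regime exit and returns a
           partial trajectory", {
  cfg <- quick_scenario(dual = FALSE, t_end_cycles = 10)
  cfg$integration$r_min_frac <- 0.9   # tight guard: triggered by ~20% dips
  expect_warning(traj <- simulate_bubbles(cfg), "inertial-regime exit")
  expect_true(traj$collapsed)
  expect_lt(length(traj$t), 10 * 200 + 1)
})

test_that("secondary Bjerknes force is zero at rest, attractive for an
           in-phase pair, and matches an independent quadrature", {
  quiet <- simulate_bubbles(quick_scenario(Pd = 0, t_end_cycles = 5))
  fsb0 <- secondary_bjerknes(quiet, n_cycles = 3)
  expect_lt(max(abs(fsb0$F)), 1e-20)
  traj <- simulate_bubbles(quick_scenario(t_end_cycles = 15,
                                          metrics_cycles = 5))
  fsb <- secondary_bjerknes(traj, n_cycles = 10)
  expect_lt(fsb$mean, 0)
  # independent trapezoid over the stored volume-rate series
  d <- traj$config$bubbles$d; rho <- traj$config$gas$rho_f
  Fo <- -rho / (4 * pi * d^2) * traj$Vdot[, 1] * traj$Vdot[, 2]
  win <- which(traj$t >= max(traj$t) - 10 * traj$period - 1e-18)
  tt <- traj$t[win]; Fw <- Fo[win]
  integ <- sum(diff(tt) * (Fw[-1] + Fw[-length(Fw)]) / 2)
  expect_equal(fsb$mean, integ / (tt[length(tt)] - tt[1]),
               tolerance = 1e-6)
  solo <- simulate_bubbles(quick_scenario(dual = FALSE, t_end_cycles = 5))
  expect_error(secondary_bjerknes(solo), "two-bubble")
})
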