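# Shared scenario builders for the test suite. Short runs (12 cycles,
# metrics over the last 5) keep unit tests fast; the acceptance tests use
# the full 30-cycle default conditions.

quick_integration <- function(t_end_cycles = 12, samples_per_cycle = 200,
                              metrics_cycles = min(5, t_end_cycles)) {
  integration_controls(t_end_cycles = t_end_cycles,
                       samples_per_cycle = samples_per_cycle,
                       metrics_cycles = metrics_cycles)
}

quick_scenario <- function(dual = TRUE, Pd = 0.3e5, f = 1.5e6,
                           rheology = viscosity_mode("carreau_yasuda"),
                           d = 10e-6, R10 = 2e-6, R20 = 2e-6,
                           nz = 21L, ...) {
  scenario_config(
    bubbles = bubble_config(R10 = R10, R20 = if (dual) R20 else NULL,
                            d = d),
    drive = acoustic_drive(Pd = Pd, f = f),
    rheology = rheology,
    vessel = vessel_config(nz = nz),
    integration = quick_integration(...))
}

# Independent dense-solve assembly of the coupled radial accelerations,
# written against the equations directly (scalar arithmetic, base solve());
# used as the oracle for coupled_accelerations().
oracle_accelerations <- function(R, Rdot, t, cfg) {
  glp <- cfg$gas
  bc <- cfg$bubbles
  nb <- if (is.null(bc$R20)) 1L else 2L
  R0 <- c(bc$R10, bc$R20)[seq_len(nb)]
  pex <- function(i) {
    pg0 <- glp$p0 + 2 * glp$sigma_g / R0[i] - glp$pv
    pg <- pg0 * (R0[i] / R[i])^(3 * glp$kappa)
    g <- 2 * sqrt(3) * abs(Rdot[i]) / R[i]
    eta <- if (cfg$rheology$kind == "constant") cfg$rheology$constant_value
      else {
        p <- cfg$rheology$params
        p$eta_inf + (p$eta0 - p$eta_inf) *
          (1 + (p$lam * g)^p$a)^((p$n - 1) / p$a)
      }
    (pg + glp$pv - glp$p0 +
       cfg$drive$Pd * sin(2 * pi * cfg$drive$f * t + cfg$drive$phase) -
       2 * glp$sigma_g / R[i] - 4 * eta * Rdot[i] / R[i]) / glp$rho_f
  }
  if (nb == 1L) return((pex(1) - 1.5 * Rdot[1]^2) / R[1])
  d <- bc$d
  A <- matrix(c(R[1], R[2]^2 / d,
                R[1]^2 / d, R[2]), 2, 2, byrow = TRUE)
  b <- c(pex(1) - 1.5 * Rdot[1]^2 - 2 * R[2] * Rdot[2]^2 / d,
         pex(2) - 1.5 * Rdot[2]^2 - 2 * R[1] * Rdot[1]^2 / d)
  as.numeric(solve(A, b))
}
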