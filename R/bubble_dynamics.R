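#' Gas and liquid constants
#'
#' Physical constants shared by the bubble-interior gas law and the
#' surrounding liquid: polytropic exponent, vapour pressure, gas-liquid
#' surface tension, ambient static pressure and blood density. Defaults are
#' the physiological set used throughout the package (air-like gas core in
#' blood at ambient pressure).
#'
#' @param kappa Polytropic exponent (dimensionless, >= 1). 1 is isothermal,
#'   ~1.4 adiabatic; the default 1.07 is the near-isothermal value
#'   appropriate for micron-sized bubbles at MHz driving.
#' @param pv Vapour pressure inside the bubble (Pa).
#' @param sigma_g Gas-liquid surface tension (N/m).
#' @param p0 Ambient static pressure in the liquid (Pa).
#' @param rho_f Liquid (blood) density (kg/m^3).
#' @return An object of class `gas_liquid_params`.
#' @export
gas_liquid_params <- function(kappa = 1.07, pv = 2330, sigma_g = 0.056,
                              p0 = 1.013e5, rho_f = 1059) {
  v <- c(kappa = kappa, pv = pv, sigma_g = sigma_g, p0 = p0, rho_f = rho_f)
  if (!all(is.finite(v)))
    stop("gas_liquid_params: all fields must be finite")
  if (p0 <= 0 || rho_f <= 0)
    stop("gas_liquid_params: p0 and rho_f must be positive")
  if (pv < 0 || sigma_g < 0)
    stop("gas_liquid_params: pv and sigma_g must be non-negative")
  if (kappa < 1) stop("gas_liquid_params: kappa must be >= 1")
  structure(as.list(v), class = "gas_liquid_params")
}

#' Sinusoidal acoustic drive
#'
#' The far-field driving pressure is `p0 - Pd * sin(2*pi*f*t + phase)`, i.e.
#' the forcing term `+Pd*sin(...)` enters the bubble pressure balance with a
#' rarefaction-first convention at phase 0.
#'
#' @param Pd Pressure amplitude (Pa, >= 0).
#' @param f Driving frequency (Hz, > 0).
#' @param phase Phase offset (rad).
#' @return An object of class `acoustic_drive`.
#' @export
acoustic_drive <- function(Pd = 0.3e5, f = 1.5e6, phase = 0) {
  if (!is.finite(Pd) || Pd < 0) stop("acoustic_drive: Pd must be >= 0")
  if (!is.finite(f) || f <= 0) stop("acoustic_drive: f must be > 0")
  if (!is.finite(phase)) stop("acoustic_drive: phase must be finite")
  structure(list(Pd = Pd, f = f, phase = phase), class = "acoustic_drive")
}

#' Bubble geometry
#'
#' One or two shell-free microbubbles on the vessel axis. In dual mode the
#' bubbles sit at axial positions `-d/2` and `+d/2`; a single-bubble
#' configuration (`R20 = NULL`) keeps bubble 1 at `-d/2` so that the midplane
#' observation point retains the same geometry as the dual case with the
#' second bubble removed.
#'
#' @param R10 Initial radius of bubble 1 (m).
#' @param R20 Initial radius of bubble 2 (m), or `NULL` for single-bubble
#'   mode.
#' @param d Centre-to-centre spacing (m); must exceed `R10 + R20` in dual
#'   mode (non-overlapping bubbles).
#' @return An object of class `bubble_config`.
#' @export
bubble_config <- function(R10 = 2e-6, R20 = 2e-6, d = 10e-6) {
  if (!is.finite(R10) || R10 <= 0) stop("bubble_config: R10 must be > 0")
  if (!is.finite(d) || d <= 0) stop("bubble_config: d must be > 0")
  if (!is.null(R20)) {
    if (!is.finite(R20) || R20 <= 0)
      stop("bubble_config: R20 must be > 0 (or NULL for single-bubble mode)")
    if (d <= R10 + R20)
      stop("bubble_config: spacing d must exceed R10 + R20 (non-overlapping)")
  }
  structure(list(R10 = R10, R20 = R20, d = d), class = "bubble_config")
}

n_bubbles <- function(bc) if (is.null(bc$R20)) 1L else 2L

#' Axial bubble positions
#'
#' @param bc A [bubble_config()].
#' @return Numeric vector of axial positions (m): `-d/2` (and `+d/2` in dual
#'   mode).
#' @export
bubble_positions <- function(bc) {
  if (n_bubbles(bc) == 2L) c(-bc$d / 2, bc$d / 2) else -bc$d / 2
}

initial_radii <- function(bc) {
  if (n_bubbles(bc) == 2L) c(bc$R10, bc$R20) else bc$R10
}

#' Initial gas pressure of an equilibrium bubble
#'
#' Static balance across the interface at rest:
#' `pg0 = p0 + 2*sigma_g/R0 - pv`. With the physiological defaults and
#' R0 = 2 um this is 154,970 Pa.
#'
#' @param R0 Equilibrium radius (m, > 0); vectorised.
#' @param glp A [gas_liquid_params()] object.
#' @return Initial gas pressure (Pa).
#' @export
initial_gas_pressure <- function(R0, glp = gas_liquid_params()) {
  if (any(!is.finite(R0)) || any(R0 <= 0))
    stop("initial_gas_pressure: R0 must be > 0")
  pg0 <- glp$p0 + 2 * glp$sigma_g / R0 - glp$pv
  if (any(pg0 <= 0))
    stop("initial_gas_pressure: non-positive gas pressure (unphysical bubble)")
  pg0
}

#' Polytropic gas pressure
#'
#' Ideal-gas polytropic compression law `pg = pg0 * (R0/R)^(3*kappa)`,
#' strictly decreasing in the instantaneous radius.
#'
#' @param R Instantaneous radius (m, > 0); vectorised.
#' @param R0 Equilibrium radius (m).
#' @param pg0 Gas pressure at `R0` (Pa), see [initial_gas_pressure()].
#' @param kappa Polytropic exponent.
#' @return Gas pressure (Pa).
#' @export
gas_pressure <- function(R, R0, pg0, kappa = 1.07) {
  if (any(!is.finite(R)) || any(R <= 0))
    stop("gas_pressure: R must be > 0")
  pg0 * (R0 / R)^(3 * kappa)
}

#' Natural (Minnaert-type) frequency of a bubble
#'
#' Linear resonance frequency of radial oscillation about the equilibrium
#' radius, including the surface-tension correction:
#' \deqn{f_0 = \frac{1}{2\pi R_0}\sqrt{\frac{3\kappa\,p_{g0} -
#'   2\sigma_g/R_0}{\rho_f}}}
#' with `pg0` from [initial_gas_pressure()]. With `sigma_g = 0`, `pv = 0`
#' this reduces to the textbook Minnaert form
#' `(1/(2*pi*R0)) * sqrt(3*kappa*p0/rho_f)`.
#'
#' @param R0 Equilibrium radius (m); vectorised.
#' @param glp A [gas_liquid_params()] object.
#' @return Natural frequency (Hz).
#' @export
natural_frequency <- function(R0, glp = gas_liquid_params()) {
  pg0 <- glp$p0 + 2 * glp$sigma_g / R0 - glp$pv
  rad <- 3 * glp$kappa * pg0 - 2 * glp$sigma_g / R0
  if (any(rad <= 0))
    stop("natural_frequency: negative stiffness radicand (unphysical bubble)")
  sqrt(rad / glp$rho_f) / (2 * pi * R0)
}

# Liquid-side pressure excess driving the radial motion of bubble i:
#   pg + pv - p0 + Pd sin(2 pi f t + phase) - 2 sigma/R - 4 eta(g) Rdot/R
# Vectorised over time; R, Rdot conform with t.
radial_pressure_excess <- function(R, Rdot, t, R0, drive, glp, rheology) {
  pg <- gas_pressure(R, R0, initial_gas_pressure(R0, glp), glp$kappa)
  eta <- viscosity_of(rheology, interface_shear_rate(Rdot, R))
  pg + glp$pv - glp$p0 + drive$Pd * sin(2 * pi * drive$f * t + drive$phase) -
    2 * glp$sigma_g / R - 4 * eta * Rdot / R
}

#' Radial accelerations of the coupled bubble system
#'
#' Solves, exactly, the linear system in the radial accelerations defined by
#' the incompressible two-bubble Rayleigh-Plesset equations with radiation
#' coupling: for each bubble i (j the other bubble)
#' \deqn{R_i\ddot R_i + \tfrac32\dot R_i^2 +
#'   \frac1d\left(2R_j\dot R_j^2 + R_j^2\ddot R_j\right) =
#'   \frac{1}{\rho_f}\Big[p_{g,i} + p_v - p_0 + P_d\sin(2\pi f t + \phi)
#'   - \frac{2\sigma_g}{R_i} - \frac{4\eta(\dot\gamma_i)\dot R_i}{R_i}\Big]}
#' with the interface shear rate \eqn{\dot\gamma_i = 2\sqrt3|\dot R_i|/R_i}
#' and the viscosity taken from the scenario's [viscosity_mode()].
#' Single-bubble configurations drop the 1/d coupling term. The 2x2 system
#' is solved in closed form each call; its determinant
#' `R1*R2*(1 - R1*R2/d^2)` is positive whenever the bubbles do not overlap,
#' which is asserted.
#'
#' @param R Radii (m): length-`nb` vector, or an `nt x nb` matrix paired
#'   with a length-`nt` `t`.
#' @param Rdot Radial velocities (m/s), same shape as `R`.
#' @param t Time (s): scalar, or length-`nt` vector for matrix input.
#' @param cfg A [scenario_config()].
#' @return Accelerations (m/s^2) with the shape of `R`.
#' @export
coupled_accelerations <- function(R, Rdot, t, cfg) {
  bc <- cfg$bubbles
  nb <- n_bubbles(bc)
  vec_in <- !is.matrix(R)
  R <- rbind(R); Rdot <- rbind(Rdot)
  if (ncol(R) != nb)
    stop("coupled_accelerations: state width does not match bubble count")
  if (any(R <= 0)) stop("coupled_accelerations: non-positive radius")
  R0 <- initial_radii(bc)
  rho <- cfg$gas$rho_f
  pe <- vapply(seq_len(nb), function(i) {
    radial_pressure_excess(R[, i], Rdot[, i], t, R0[i],
                           cfg$drive, cfg$gas, cfg$rheology)
  }, numeric(nrow(R)))
  pe <- rbind(pe) / rho
  if (nb == 1L) {
    acc <- (pe[, 1] - 1.5 * Rdot[, 1]^2) / R[, 1]
    out <- cbind(acc)
  } else {
    d <- bc$d
    b1 <- pe[, 1] - 1.5 * Rdot[, 1]^2 - 2 * R[, 2] * Rdot[, 2]^2 / d
    b2 <- pe[, 2] - 1.5 * Rdot[, 2]^2 - 2 * R[, 1] * Rdot[, 1]^2 / d
    # [ R1      R2^2/d ] [ a1 ]   [ b1 ]
    # [ R1^2/d  R2     ] [ a2 ] = [ b2 ]
    det <- R[, 1] * R[, 2] * (1 - R[, 1] * R[, 2] / d^2)
    stopifnot(all(det > 0))
    a1 <- (b1 * R[, 2] - b2 * R[, 2]^2 / d) / det
    a2 <- (b2 * R[, 1] - b1 * R[, 1]^2 / d) / det
    out <- cbind(a1, a2)
  }
  dimnames(out) <- NULL
  if (vec_in) drop(out) else out
}

#' Simulate the radial bubble dynamics
#'
#' Integrates the coupled system of [coupled_accelerations()] from the
#' quiescent initial state `R_i(0) = R_i0`, `Rdot_i(0) = 0` with an adaptive
#' stiff solver (`deSolve::ode`, `lsodar`), and samples the solution on a
#' uniform output grid of `samples_per_cycle` points per acoustic period.
#' A root function terminates the integration if any radius falls below
#' `r_min_frac * R_i0` (default 1/50), flagging an exit from the
#' stable-cavitation regime; the partial trajectory is returned with
#' `collapsed = TRUE`.
#'
#' @param cfg A [scenario_config()].
#' @param t_end_cycles,samples_per_cycle Override the scenario integration
#'   controls (number of acoustic cycles; output samples per cycle).
#' @return An object of class `mb_trajectory`: list with the time grid `t`,
#'   `nt x nb` matrices `R`, `Rdot`, `Rddot`, `V` (= 4/3 pi R^3) and `Vdot`
#'   (= 4 pi R^2 Rdot), the bubble positions `z`, the `collapsed` flag and
#'   the generating config.
#' @export
simulate_bubbles <- function(cfg, t_end_cycles = NULL,
                             samples_per_cycle = NULL) {
  validate_scenario(cfg)
  ic <- cfg$integration
  ncyc <- if (is.null(t_end_cycles)) ic$t_end_cycles else t_end_cycles
  spc <- if (is.null(samples_per_cycle)) ic$samples_per_cycle else
    samples_per_cycle
  bc <- cfg$bubbles
  nb <- n_bubbles(bc)
  R0 <- initial_radii(bc)
  period <- 1 / cfg$drive$f
  times <- seq(0, ncyc * period, length.out = ncyc * spc + 1)
  y0 <- as.numeric(rbind(R0, 0))          # (R1, U1[, R2, U2])
  rmin <- ic$r_min_frac * R0
  idxR <- seq(1L, 2L * nb, by = 2L)
  deriv <- function(t, y, p) {
    R <- y[idxR]; U <- y[idxR + 1L]
    acc <- coupled_accelerations(R, U, t, cfg)
    dy <- numeric(2L * nb)
    dy[idxR] <- U; dy[idxR + 1L] <- acc
    list(dy)
  }
  rootf <- function(t, y, p) y[idxR] - rmin
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsodar", rtol = ic$rtol,
                      atol = rep(c(ic$atol_R, 1e-8), nb),
                      rootfunc = rootf, maxsteps = 5e5)
  collapsed <- !is.null(attr(sol, "iroot")) || nrow(sol) < length(times)
  if (collapsed)
    warning("simulate_bubbles: inertial-regime exit (radius below guard); ",
            "returning partial trajectory")
  t_out <- sol[, 1]
  R <- sol[, 1L + idxR, drop = FALSE]
  Rdot <- sol[, 2L + idxR, drop = FALSE]
  Rddot <- coupled_accelerations(R, Rdot, t_out, cfg)
  Rddot <- rbind(Rddot)
  if (nb == 1L) { R <- cbind(R); Rdot <- cbind(Rdot); Rddot <- cbind(Rddot) }
  structure(list(
    t = t_out, R = R, Rdot = Rdot, Rddot = Rddot,
    V = 4 / 3 * pi * R^3, Vdot = 4 * pi * R^2 * Rdot,
    z = bubble_positions(bc), n_bubbles = nb, period = period,
    samples_per_cycle = spc, collapsed = collapsed, config = cfg),
    class = "mb_trajectory")
}

#' @export
print.mb_trajectory <- function(x, ...) {
  cat(sprintf("Microbubble trajectory: %d bubble(s), %d samples over %.3g s\n",
              x$n_bubbles, length(x$t), max(x$t)))
  for (i in seq_len(x$n_bubbles))
    cat(sprintf("  bubble %d: R in [%.4g, %.4g] um\n", i,
                min(x$R[, i]) * 1e6, max(x$R[, i]) * 1e6))
  if (x$collapsed) cat("  flagged: inertial-regime exit (partial)\n")
  invisible(x)
}

#' Secondary Bjerknes force between the two bubbles
#'
#' Radiation interaction force
#' \deqn{F_{SB}(t) = -\frac{\rho_f}{4\pi d^2}\,\dot V_1(t)\,\dot V_2(t),}
#' negative = attraction. The time average is taken by trapezoidal
#' quadrature over the last `n_cycles` whole acoustic periods of the
#' trajectory; in-phase volume oscillations give a non-positive (attractive)
#' average.
#'
#' @param traj A dual-bubble [simulate_bubbles()] trajectory.
#' @param d Centre spacing (m); defaults to the trajectory's configuration.
#' @param rho_f Liquid density (kg/m^3); defaults likewise.
#' @param n_cycles Number of trailing whole periods to average over.
#' @return List with the force series `F` (N) on the trajectory time grid,
#'   the time average `mean` (N) and the averaging window `window` (s).
#' @export
secondary_bjerknes <- function(traj, d = traj$config$bubbles$d,
                               rho_f = traj$config$gas$rho_f,
                               n_cycles = 10) {
  if (!inherits(traj, "mb_trajectory"))
    stop("secondary_bjerknes: traj must be an mb_trajectory")
  if (traj$n_bubbles != 2L)
    stop("secondary_bjerknes: requires a two-bubble trajectory")
  F <- -rho_f / (4 * pi * d^2) * traj$Vdot[, 1] * traj$Vdot[, 2]
  win <- trailing_cycle_window(traj$t, traj$period, n_cycles)
  avg <- pracma::trapz(traj$t[win], F[win]) /
    (traj$t[win][sum(win)] - traj$t[win][1])
  list(F = F, t = traj$t, mean = avg,
       window = range(traj$t[win]))
}

# Logical index selecting the last `n_cycles` whole periods of a uniform
# time grid (fewer if the series is shorter).
trailing_cycle_window <- function(t, period, n_cycles) {
  t_end <- t[length(t)]
  n_avail <- floor((t_end - t[1]) / period + 1e-9)
  if (n_avail < 1)
    stop("time series shorter than one acoustic period")
  n_use <- min(n_cycles, n_avail)
  t >= t_end - n_use * period - 1e-12 * period
}

#' Write a trajectory to CSV
#'
#' Columnar text output with header
#' `t_s, R1_m, R1dot_m_s, R2_m, R2dot_m_s, V1_m3, V2_m3, FSB_N`.
#' Single-bubble trajectories fill the bubble-2 and force columns with `NA`.
#'
#' @param traj An `mb_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  nt <- length(traj$t)
  if (traj$n_bubbles == 2L) {
    fsb <- secondary_bjerknes(traj)$F
    df <- data.frame(t_s = traj$t,
                     R1_m = traj$R[, 1], R1dot_m_s = traj$Rdot[, 1],
                     R2_m = traj$R[, 2], R2dot_m_s = traj$Rdot[, 2],
                     V1_m3 = traj$V[, 1], V2_m3 = traj$V[, 2],
                     FSB_N = fsb)
  } else {
    df <- data.frame(t_s = traj$t,
                     R1_m = traj$R[, 1], R1dot_m_s = traj$Rdot[, 1],
                     R2_m = NA_real_, R2dot_m_s = NA_real_,
                     V1_m3 = traj$V[, 1], V2_m3 = NA_real_,
                     FSB_N = NA_real_)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
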