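#' Vessel wall configuration
#'
#' Geometry and lumped mechanical properties of the microvessel segment.
#' Each axial wall point is modelled as an independent spring-mass-damper
#' element with hoop stiffness `k_w = E*h/RV^2` (optionally the plane-strain
#' stiffness `E/(1-nu^2)*h/RV^2`), mass per area `rho_s*h`, and damping
#' `c = 2*zeta*sqrt(k_w*rho_s*h)`.
#'
#' @param RV Inner radius (m).
#' @param L Segment length (m); wall fields are evaluated on `nz` uniform
#'   axial points over `[-L/2, L/2]`.
#' @param rho_s Wall density (kg/m^3).
#' @param E Young's modulus (Pa).
#' @param nu Poisson ratio, in (0, 0.5).
#' @param h Wall thickness (m).
#' @param zeta Damping ratio of the lumped wall element, in (0, 1).
#' @param plane_strain If `TRUE`, stiffen by `1/(1-nu^2)`.
#' @param nz Number of axial grid points.
#' @return An object of class `vessel_config`.
#' @export
vessel_config <- function(RV = 5e-6, L = 40e-6, rho_s = 1049, E = 4e6,
                          nu = 0.49, h = 1e-6, zeta = 0.1,
                          plane_strain = FALSE, nz = 81L) {
  v <- c(RV = RV, L = L, rho_s = rho_s, E = E, h = h, zeta = zeta)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("vessel_config: RV, L, rho_s, E, h, zeta must be positive")
  if (!is.finite(nu) || nu <= 0 || nu >= 0.5)
    stop("vessel_config: nu must lie in (0, 0.5)")
  if (zeta >= 1)
    stop("vessel_config: zeta must be < 1 (underdamped wall element)")
  if (nz < 3) stop("vessel_config: nz must be at least 3")
  structure(list(RV = RV, L = L, rho_s = rho_s, E = E, nu = nu, h = h,
                 zeta = zeta, plane_strain = isTRUE(plane_strain),
                 nz = as.integer(nz)),
            class = "vessel_config")
}

#' Hoop stiffness of the lumped wall element
#'
#' @param vcfg A [vessel_config()].
#' @return Stiffness per unit wall area (Pa/m).
#' @export
wall_stiffness <- function(vcfg) {
  k <- vcfg$E * vcfg$h / vcfg$RV^2
  if (vcfg$plane_strain) k <- k / (1 - vcfg$nu^2)
  k
}

#' Axial grid of wall observation points
#'
#' @param vcfg A [vessel_config()].
#' @return `nz` uniform axial positions (m) over `[-L/2, L/2]`.
#' @export
wall_grid <- function(vcfg) {
  seq(-vcfg$L / 2, vcfg$L / 2, length.out = vcfg$nz)
}

#' Liquid velocity induced by pulsating bubbles
#'
#' Free-space superposition of pulsating point sources: each bubble of
#' radius `R_i` and wall velocity `Rdot_i` at axial position `z_i`
#' contributes \eqn{u(x) = R_i^2\dot R_i\,(x - x_i)/|x - x_i|^3}. This is
#' the gradient of the velocity potential \eqn{\phi = -\sum_i
#' R_i^2\dot R_i/|x - x_i|} and satisfies the kinematic interface condition
#' exactly on each (isolated) bubble surface.
#'
#' @param r,z Observation point: radial distance from the axis and axial
#'   position (m). Must lie outside every bubble.
#' @param R,Rdot Bubble radii (m) and wall velocities (m/s), length nb.
#' @param zb Axial bubble positions (m), length nb.
#' @return Named numeric vector `c(ur =, uz =)` (m/s).
#' @export
induced_velocity <- function(r, z, R, Rdot, zb) {
  s <- sqrt(r^2 + (z - zb)^2)
  if (any(s <= R))
    stop("induced_velocity: observation point inside a bubble")
  q <- R^2 * Rdot
  c(ur = sum(q * r / s^3), uz = sum(q * (z - zb) / s^3))
}

# Geometry helper: distances from each bubble position to each wall grid
# point (r = RV); returns a list of nb vectors of length nz.
wall_distances <- function(zb, z, RV) {
  lapply(zb, function(zi) sqrt(RV^2 + (z - zi)^2))
}

#' Microstreaming wall shear stress
#'
#' Evaluates the analytic radial derivative of the axial source-flow
#' velocity at the wall, `du_z/dr = -3 q r (z - z_i)/s^5` summed over
#' bubbles (with `q = R^2 Rdot`, `s` the bubble-to-point distance), takes
#' the wall shear rate as its magnitude, and returns the signed stress
#' `tau_ex = eta(gamma_wall) * du_z/dr`.
#'
#' @param traj An [simulate_bubbles()] trajectory.
#' @param vcfg A [vessel_config()].
#' @param mode A [viscosity_mode()]; defaults to the trajectory scenario's.
#' @param z Axial evaluation points (m); defaults to [wall_grid()].
#' @return `nt x nz` matrix of wall shear stress (Pa).
#' @export
wall_shear_stress <- function(traj, vcfg, mode = traj$config$rheology,
                              z = wall_grid(vcfg)) {
  s <- wall_distances(traj$z, z, vcfg$RV)
  dudr <- matrix(0, nrow = length(traj$t), ncol = length(z))
  for (i in seq_len(traj$n_bubbles)) {
    q <- traj$R[, i]^2 * traj$Rdot[, i]
    geo <- -3 * vcfg$RV * (z - traj$z[i]) / s[[i]]^5
    dudr <- dudr + outer(q, geo)
  }
  eta <- viscosity_of(mode, abs(as.vector(dudr)))
  matrix(eta * as.vector(dudr), nrow = nrow(dudr))
}

#' Acoustic (normal) wall stress
#'
#' Unsteady-Bernoulli pressure estimate of the source superposition at the
#' wall:
#' \deqn{\sigma_n(z,t) = \rho_f \sum_i \frac{2R_i\dot R_i^2 +
#'   R_i^2\ddot R_i}{s_i} - \frac{\rho_f}{2}|u|^2,}
#' where `s_i` is the distance from bubble i to the wall point and `u` the
#' induced velocity there. Positive values push the wall outward
#' (distention), negative values pull it inward (invagination/suction).
#'
#' @inheritParams wall_shear_stress
#' @param rho_f Liquid density (kg/m^3).
#' @return `nt x nz` matrix of wall normal stress (Pa).
#' @export
wall_normal_stress <- function(traj, vcfg, rho_f = traj$config$gas$rho_f,
                               z = wall_grid(vcfg)) {
  s <- wall_distances(traj$z, z, vcfg$RV)
  nt <- length(traj$t); nz <- length(z)
  sn <- matrix(0, nt, nz); ur <- matrix(0, nt, nz); uz <- matrix(0, nt, nz)
  for (i in seq_len(traj$n_bubbles)) {
    q <- traj$R[, i]^2 * traj$Rdot[, i]
    qdot <- 2 * traj$R[, i] * traj$Rdot[, i]^2 +
      traj$R[, i]^2 * traj$Rddot[, i]
    sn <- sn + rho_f * outer(qdot, 1 / s[[i]])
    ur <- ur + outer(q, vcfg$RV / s[[i]]^3)
    uz <- uz + outer(q, (z - traj$z[i]) / s[[i]]^3)
  }
  sn - rho_f / 2 * (ur^2 + uz^2)
}

#' Elastic wall response to a normal-stress history
#'
#' Integrates, per axial point, the lumped wall element
#' \deqn{\rho_s h\,\ddot w + c\,\dot w + k_w\,w = \sigma_n(z,t)}
#' from quiescent initial conditions, with `k_w` from [wall_stiffness()]
#' and `c = 2*zeta*sqrt(k_w*rho_s*h)`. The load is treated as piecewise
#' linear between samples and the update is the exact solution of the
#' linear oscillator on each step (the interpolation of the forcing is the
#' only discretisation), so the scheme is unconditionally stable and
#' second-order in the sampling interval.
#'
#' @param sigma_n `nt x nz` matrix of wall normal stress (Pa) on a uniform
#'   time grid.
#' @param t Time grid (s), uniform spacing.
#' @param vcfg A [vessel_config()].
#' @return List with `w_d` (radial displacement, m) and `eps` (hoop strain
#'   `w_d/RV`), both `nt x nz`.
#' @export
wall_response <- function(sigma_n, t, vcfg) {
  if (!is.matrix(sigma_n)) sigma_n <- cbind(sigma_n)
  if (any(!is.finite(sigma_n))) stop("wall_response: non-finite load")
  nt <- nrow(sigma_n)
  if (length(t) != nt) stop("wall_response: time grid mismatch")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("wall_response: time grid must be uniform")
  dt <- dt[1]
  m <- vcfg$rho_s * vcfg$h
  kw <- wall_stiffness(vcfg)
  if (kw <= 0) stop("wall_response: non-positive wall stiffness")
  zt <- vcfg$zeta
  om <- sqrt(kw / m)
  omd <- om * sqrt(1 - zt^2)
  e <- exp(-zt * om * dt)
  cd <- cos(omd * dt); sd <- sin(omd * dt)
  u <- sigma_n / m                         # acceleration-scaled load
  w <- matrix(0, nt, ncol(sigma_n))
  v <- rep(0, ncol(sigma_n))
  x <- rep(0, ncol(sigma_n))
  for (k in seq_len(nt - 1L)) {
    y <- u[k, ]; dy <- u[k + 1L, ] - y
    # particular (piecewise-linear load) + homogeneous response, exact
    c1 <- x - y / om^2 + 2 * zt * dy / (om^3 * dt)
    c2 <- (v + zt * om * c1 - dy / (dt * om^2)) / omd
    x <- e * (c1 * cd + c2 * sd) + (y + dy) / om^2 -
      2 * zt * dy / (om^3 * dt)
    v <- e * ((-zt * om * c1 + omd * c2) * cd -
                (zt * om * c2 + omd * c1) * sd) + dy / (dt * om^2)
    w[k + 1L, ] <- x
  }
  list(w_d = w, eps = w / vcfg$RV)
}

#' Wall-line stress and response time series
#'
#' Runs the full one-way-coupled wall chain for a trajectory: microstreaming
#' shear stress, acoustic normal stress, and the lumped elastic response, on
#' the axial wall grid. The wall fields are pure post-processing of the
#' trajectory (no feedback on the bubble dynamics).
#'
#' @param traj An [simulate_bubbles()] trajectory.
#' @param vcfg A [vessel_config()]; defaults to the trajectory scenario's.
#' @param mode A [viscosity_mode()]; defaults likewise.
#' @return An object of class `wall_series`: list with `t`, axial grid `z`,
#'   and `nt x nz` matrices `tau_ex`, `sigma_n`, `w_d`, `eps`.
#' @export
wall_series <- function(traj, vcfg = traj$config$vessel,
                        mode = traj$config$rheology) {
  z <- wall_grid(vcfg)
  tau <- wall_shear_stress(traj, vcfg, mode, z)
  sn <- wall_normal_stress(traj, vcfg, traj$config$gas$rho_f, z)
  resp <- wall_response(sn, traj$t, vcfg)
  structure(list(t = traj$t, z = z, tau_ex = tau, sigma_n = sn,
                 w_d = resp$w_d, eps = resp$eps,
                 period = traj$period, vessel = vcfg),
            class = "wall_series")
}

#' @export
print.wall_series <- function(x, ...) {
  cat(sprintf("Wall series: %d axial points x %d samples\n",
              length(x$z), length(x$t)))
  cat(sprintf("  max |tau_ex| = %.4g Pa, sigma_n in [%.4g, %.4g] Pa\n",
              max(abs(x$tau_ex)), min(x$sigma_n), max(x$sigma_n)))
  cat(sprintf("  max |hoop strain| = %.4g\n", max(abs(x$eps))))
  invisible(x)
}

# Index of the wall grid point nearest an axial position.
wall_index <- function(ws, z_obs) which.min(abs(ws$z - z_obs))

#' Write a wall series to long-format CSV
#'
#' Columns `t_s, z_m, tau_ex_Pa, sigma_n_Pa, w_d_m, eps`, one row per
#' (time, axial point) pair.
#'
#' @param ws A [wall_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wall_series <- function(ws, path) {
  df <- data.frame(
    t_s = rep(ws$t, times = length(ws$z)),
    z_m = rep(ws$z, each = length(ws$t)),
    tau_ex_Pa = as.vector(ws$tau_ex),
    sigma_n_Pa = as.vector(ws$sigma_n),
    w_d_m = as.vector(ws$w_d),
    eps = as.vector(ws$eps))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
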