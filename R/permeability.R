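#' Endothelium parameters
#'
#' Constants of the stress-to-permeability chain: the endothelial cell
#' radius and leaky-junction half-width set the (configurable) permeability
#' prefactor `4e8/(3*pi*Rcell) * w_half^3`; the Young's modulus enters the
#' effective-stress correction; `clamp_negative_tau` controls whether
#' negative effective stress is clamped to zero before the shape-index
#' regression (which is an empirical fit on non-negative shear stress).
#'
#' All ratio metrics built on the chain (enhancement ratio, pulse count)
#' are independent of `Rcell`, `w_half` and `prefactor`.
#'
#' @param Rcell Endothelial cell radius (m).
#' @param w_half Half-width of the leaky junction (m).
#' @param E Young's modulus used in the effective-stress correction (Pa).
#' @param clamp_negative_tau Clamp negative effective stress to 0 before
#'   the shape-index evaluation (default `TRUE`).
#' @param prefactor Override for the permeability prefactor (model units);
#'   `NULL` computes it from `Rcell` and `w_half`.
#' @return An object of class `endothelium_params`.
#' @export
endothelium_params <- function(Rcell = 15e-6, w_half = 20e-9, E = 4e6,
                               clamp_negative_tau = TRUE, prefactor = NULL) {
  if (!is.finite(Rcell) || Rcell <= 0)
    stop("endothelium_params: Rcell must be > 0")
  if (!is.finite(w_half) || w_half <= 0)
    stop("endothelium_params: w_half must be > 0")
  if (!is.finite(E) || E <= 0) stop("endothelium_params: E must be > 0")
  if (is.null(prefactor))
    prefactor <- 4e8 / (3 * pi * Rcell) * w_half^3
  if (!is.finite(prefactor) || prefactor <= 0)
    stop("endothelium_params: prefactor must be > 0")
  structure(list(Rcell = Rcell, w_half = w_half, E = E,
                 clamp_negative_tau = isTRUE(clamp_negative_tau),
                 prefactor = prefactor),
            class = "endothelium_params")
}

#' Effective wall stress felt by the endothelium
#'
#' Combines the microstreaming shear stress with the cell-mechanical
#' contribution of the wall strain: `tau = tau_ex - E * eps`. The raw
#' (possibly negative) value is returned; clamping for the downstream
#' shape-index evaluation is applied by the pipeline according to
#' `clamp_negative_tau`.
#'
#' @param tau_ex Microstreaming wall shear stress (Pa); vector or matrix.
#' @param eps Hoop strain (dimensionless), conformable with `tau_ex`.
#' @param E Young's modulus (Pa).
#' @return Effective stress (Pa), same shape as `tau_ex`.
#' @export
effective_stress <- function(tau_ex, eps, E = 4e6) {
  if (any(!is.finite(tau_ex)) || any(!is.finite(eps)))
    stop("effective_stress: inputs must be finite")
  tau_ex - E * eps
}

#' Endothelial shape index
#'
#' Empirical regression of endothelial cell elongation on wall shear
#' stress: `SI = 0.38*exp(-0.79*tau) + 0.225*exp(-0.043*tau)` with `tau` in
#' Pa. Strictly decreasing; `SI(0) = 0.605` and `SI -> 0` as
#' `tau -> Inf`. Negative stresses (possible only with clamping disabled)
#' are evaluated as written, with a warning, since the regression is only
#' supported on non-negative stress.
#'
#' @param tau Effective stress (Pa); vector or matrix.
#' @return Shape index (dimensionless), same shape as `tau`.
#' @export
shape_index <- function(tau) {
  if (any(!is.finite(tau))) stop("shape_index: tau must be finite")
  if (any(tau < 0))
    warning("shape_index: negative stress outside the regression's support; ",
            "evaluated as written")
  0.38 * exp(-0.79 * tau) + 0.225 * exp(-0.043 * tau)
}

#' Junction permeability from the shape index
#'
#' `K = prefactor * (0.479 + 0.00593*exp(-14.75*SI))` with the prefactor
#' `4e8/(3*pi*Rcell) * w_half^3` (model units). Strictly decreasing in the
#' shape index, so the full stress -> SI -> K chain is monotone increasing
#' in stress; `K` scales as `w_half^3` and `1/Rcell`.
#'
#' @param SI Shape index (dimensionless, >= 0); vector or matrix.
#' @param ep An [endothelium_params()] object.
#' @return Permeability (model units), same shape as `SI`.
#' @export
permeability_K <- function(SI, ep = endothelium_params()) {
  if (any(!is.finite(SI)) || any(SI < 0))
    stop("permeability_K: SI must be finite and non-negative")
  ep$prefactor * (0.479 + 0.00593 * exp(-14.75 * SI))
}

#' Zero-stress baseline permeability
#'
#' @param ep An [endothelium_params()] object.
#' @return `permeability_K(shape_index(0), ep)`.
#' @export
baseline_permeability <- function(ep = endothelium_params()) {
  permeability_K(shape_index(0), ep)
}

#' Excess permeability over the zero-stress baseline
#'
#' `dK(t) = K(t) - K_baseline`, with the time integral taken by trapezoidal
#' quadrature over the last `n_cycles` whole acoustic periods (startup
#' transients are discarded by construction of the window).
#'
#' @param K Permeability series (model units) on the time grid `t`.
#' @param t Time grid (s).
#' @param period Acoustic period (s).
#' @param baseline Baseline permeability ([baseline_permeability()]).
#' @param n_cycles Number of trailing whole periods to integrate over.
#' @return List with the full series `dK`, the window index `window`
#'   (logical), and the window `integral` (model units * s).
#' @export
excess_permeability <- function(K, t, period, baseline, n_cycles = 10) {
  if (length(K) != length(t))
    stop("excess_permeability: K and t length mismatch")
  win <- trailing_cycle_window(t, period, n_cycles)
  dK <- K - baseline
  list(dK = dK, window = win,
       integral = pracma::trapz(t[win], dK[win]))
}

#' Permeability pulse count
#'
#' Number of upward crossings of the threshold
#' `K_baseline + threshold_frac * max(dK)` per second, over the last
#' `n_cycles` whole acoustic periods. A flat series has zero pulses; peak
#' excesses below 1e-9 of the baseline are treated as flat (numerical noise
#' floor of an unstressed scenario). The count is non-increasing in
#' `threshold_frac` and independent of the permeability prefactor.
#'
#' @inheritParams excess_permeability
#' @param threshold_frac Fraction of the window's peak excess used as the
#'   crossing threshold.
#' @return Pulses per second (1/s).
#' @export
pulse_count <- function(K, t, period, baseline, threshold_frac = 0.1,
                        n_cycles = 10) {
  win <- trailing_cycle_window(t, period, n_cycles)
  x <- K[win] - baseline
  span <- t[win][sum(win)] - t[win][1]
  peak <- max(x)
  if (peak <= 1e-9 * abs(baseline)) return(0)
  thr <- threshold_frac * peak
  up <- sum(x[-1] > thr & x[-length(x)] <= thr)
  up / span
}

#' Permeability series and summary metrics for a wall series
#'
#' Maps the wall stress/strain history through the effective-stress,
#' shape-index and permeability laws on the full axial grid, and computes
#' the scenario's summary metrics (pulse count, integrated excess
#' permeability) at the wall observation point (default: the midplane,
#' z = 0).
#'
#' @param ws A [wall_series()].
#' @param ep An [endothelium_params()] object.
#' @param z_obs Axial observation position (m); snapped to the nearest grid
#'   point.
#' @param n_cycles Steady-state window (trailing whole acoustic periods)
#'   for the metrics.
#' @param threshold_frac Pulse-count threshold fraction.
#' @return An object of class `perm_series`: list with `t`, `z`, matrices
#'   `tau` (effective stress, raw), `SI`, `K`, the observation index
#'   `i_obs`, the `baseline`, and `metrics` (list with
#'   `pulse_count_per_s`, `integrated_excess`, `max_K`, `window_s`).
#' @export
permeability_series <- function(ws, ep = endothelium_params(), z_obs = 0,
                                n_cycles = 10, threshold_frac = 0.1) {
  if (!inherits(ws, "wall_series"))
    stop("permeability_series: ws must be a wall_series")
  tau <- effective_stress(ws$tau_ex, ws$eps, ep$E)
  tau_si <- if (ep$clamp_negative_tau) pmax(tau, 0) else tau
  SI <- shape_index(tau_si)
  K <- permeability_K(SI, ep)
  i_obs <- wall_index(ws, z_obs)
  base <- baseline_permeability(ep)
  exc <- excess_permeability(K[, i_obs], ws$t, ws$period, base, n_cycles)
  pc <- pulse_count(K[, i_obs], ws$t, ws$period, base, threshold_frac,
                    n_cycles)
  structure(list(
    t = ws$t, z = ws$z, tau = tau, SI = SI, K = K, i_obs = i_obs,
    baseline = base, period = ws$period,
    metrics = list(pulse_count_per_s = pc,
                   integrated_excess = exc$integral,
                   max_K = max(K[, i_obs]),
                   window_s = diff(range(ws$t[exc$window])))),
    class = "perm_series")
}

#' @export
print.perm_series <- function(x, ...) {
  cat(sprintf("Permeability series: %d axial points x %d samples\n",
              length(x$z), length(x$t)))
  cat(sprintf("  observation point z = %.3g um\n", x$z[x$i_obs] * 1e6))
  cat(sprintf("  pulse count = %.4g /s, integrated excess = %.4g\n",
              x$metrics$pulse_count_per_s, x$metrics$integrated_excess))
  invisible(x)
}

#' Dual/single permeability enhancement ratio
#'
#' Ratio of the time-integrated excess permeability of a dual-bubble
#' scenario to that of a single-bubble scenario, computed at the same wall
#' observation point over steady-state windows of equal length. The ratio
#' is independent of the permeability prefactor (cell radius and junction
#' width cancel).
#'
#' @param dual,single [permeability_series()] objects (or numeric
#'   integrated-excess values).
#' @return Dimensionless ratio; `NaN` with a warning when the single-bubble
#'   integral is zero (undefined ratio).
#' @export
enhancement_ratio <- function(dual, single) {
  gi <- function(x) {
    if (inherits(x, "perm_series")) x$metrics$integrated_excess
    else as.numeric(x)
  }
  num <- gi(dual); den <- gi(single)
  if (den == 0) {
    warning("enhancement_ratio: single-bubble excess integral is zero; ",
            "ratio undefined")
    return(NaN)
  }
  num / den
}

#' Write a permeability series to CSV
#'
#' Long-format columns `t_s, z_m, tau_Pa, SI, K`, one row per (time, axial
#' point) pair.
#'
#' @param ps A [permeability_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_permeability_series <- function(ps, path) {
  df <- data.frame(
    t_s = rep(ps$t, times = length(ps$z)),
    z_m = rep(ps$z, each = length(ps$t)),
    tau_Pa = as.vector(ps$tau),
    SI = as.vector(ps$SI),
    K = as.vector(ps$K))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
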