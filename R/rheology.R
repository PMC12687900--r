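#' Carreau-Yasuda blood rheology parameters
#'
#' Container for the five constants of the Carreau-Yasuda shear-thinning law
#' \deqn{\eta(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty)
#'   \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a}.}
#' The defaults are a standard whole-blood fit (zero-shear viscosity
#' 0.0519 Pa s, infinite-shear viscosity 0.00476 Pa s, relaxation time
#' 0.438 s, power index 0.191, transition parameter 0.409). In parts of the
#' rheology literature the limiting viscosities are written \eqn{\mu_0} /
#' \eqn{\mu_\infty}; they are the same quantities as `eta0` / `eta_inf`.
#'
#' @param eta0 Zero-shear viscosity (Pa s).
#' @param eta_inf Infinite-shear viscosity (Pa s); must satisfy
#'   `eta0 > eta_inf > 0`.
#' @param lam Relaxation time \eqn{\lambda} (s), positive.
#' @param n Power index (dimensionless); `0 < n < 1` is the shear-thinning
#'   regime this package targets.
#' @param a Yasuda transition parameter (dimensionless), positive.
#' @return An object of class `cy_params`.
#' @seealso [apparent_viscosity()], [viscosity_mode()]
#' @examples
#' blood <- carreau_yasuda_params()
#' apparent_viscosity(c(0, 100, 1e6), blood)
#' @export
carreau_yasuda_params <- function(eta0 = 0.0519, eta_inf = 0.00476,
                                  lam = 0.438, n = 0.191, a = 0.409) {
  stopifnot(is.numeric(eta0), is.numeric(eta_inf), is.numeric(lam),
            is.numeric(n), is.numeric(a))
  if (!all(is.finite(c(eta0, eta_inf, lam, n, a))))
    stop("carreau_yasuda_params: all parameters must be finite")
  if (!(eta0 > eta_inf && eta_inf > 0))
    stop("carreau_yasuda_params: need eta0 > eta_inf > 0")
  if (lam <= 0) stop("carreau_yasuda_params: lam must be positive")
  if (a <= 0) stop("carreau_yasuda_params: a must be positive")
  if (n <= 0 || n >= 1)
    stop("carreau_yasuda_params: n must lie in (0, 1) (shear-thinning)")
  structure(list(eta0 = eta0, eta_inf = eta_inf, lam = lam, n = n, a = a),
            class = "cy_params")
}

#' @export
print.cy_params <- function(x, ...) {
  cat("Carreau-Yasuda parameters:\n")
  cat(sprintf("  eta0 = %g Pa s, eta_inf = %g Pa s\n", x$eta0, x$eta_inf))
  cat(sprintf("  lambda = %g s, n = %g, a = %g\n", x$lam, x$n, x$a))
  invisible(x)
}

#' Apparent viscosity of a Carreau-Yasuda fluid
#'
#' Evaluates the shear-rate-dependent apparent viscosity. The function is
#' vectorised over `gamma_dot`; the returned value is always in
#' `(eta_inf, eta0]` and is strictly decreasing in the shear rate for
#' shear-thinning parameter sets (`n < 1`).
#'
#' For shear rates above 1e8 1/s the factor `(lam * gamma_dot)^a` is
#' evaluated in log space; this avoids overflow at extreme rates and agrees
#' with the direct evaluation to better than 1e-12 relative.
#'
#' @param gamma_dot Scalar shear rate(s) (1/s), non-negative and finite.
#' @param params A [carreau_yasuda_params()] object.
#' @return Apparent viscosity (Pa s), same length as `gamma_dot`.
#' @export
apparent_viscosity <- function(gamma_dot, params = carreau_yasuda_params()) {
  if (!inherits(params, "cy_params"))
    stop("apparent_viscosity: params must be a cy_params object")
  if (!is.numeric(gamma_dot) || any(!is.finite(gamma_dot)))
    stop("apparent_viscosity: gamma_dot must be finite numeric")
  if (any(gamma_dot < 0))
    stop("apparent_viscosity: gamma_dot must be non-negative")
  ex <- (params$n - 1) / params$a
  lg <- params$lam * gamma_dot
  fac <- numeric(length(lg))
  hi <- gamma_dot > 1e8
  if (any(!hi)) fac[!hi] <- exp(ex * log1p(lg[!hi]^params$a))
  if (any(hi)) {
    # log1p((lam g)^a) = a log(lam g) + log1p((lam g)^-a), exact split
    la <- params$a * log(lg[hi])
    fac[hi] <- exp(ex * (la + log1p(exp(-la))))
  }
  params$eta_inf + (params$eta0 - params$eta_inf) * fac
}

#' Scalar shear-rate invariant of a rate-of-deformation tensor
#'
#' Computes \eqn{\dot\gamma = \sqrt{2\, D : D}} from a 3x3 symmetric
#' rate-of-deformation tensor \eqn{D = (\nabla u + \nabla u^T)/2}, the
#' standard generalised shear rate for incompressible flow. For simple shear
#' with velocity gradient g the invariant equals g; for a purely radial
#' (bubble-wall) flow with surface velocity `Rdot` at radius `R` it equals
#' \eqn{2\sqrt{3}\,|\dot R|/R}.
#'
#' @param D 3x3 numeric matrix, symmetric to within `tol` (relative to its
#'   largest entry) and finite.
#' @param tol Relative symmetry tolerance.
#' @return Non-negative scalar shear rate (1/s).
#' @export
shear_rate_invariant <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || !all(dim(D) == c(3L, 3L)) || !is.numeric(D))
    stop("shear_rate_invariant: D must be a numeric 3x3 matrix")
  if (any(!is.finite(D)))
    stop("shear_rate_invariant: D must be finite")
  scale <- max(abs(D))
  if (scale > 0 && max(abs(D - t(D))) > tol * scale)
    stop("shear_rate_invariant: D is not symmetric within tolerance")
  Ds <- (D + t(D)) / 2
  sqrt(2 * sum(Ds * Ds))
}

#' Viscosity mode for a scenario
#'
#' Selects between the full Carreau-Yasuda law and a constant (Newtonian)
#' viscosity. The constant default, 0.0035 Pa s, is a conventional
#' hemodynamic blood viscosity.
#'
#' @param kind `"carreau_yasuda"` or `"constant"`.
#' @param constant_value Viscosity (Pa s) used when `kind = "constant"`.
#' @param params [carreau_yasuda_params()] used when
#'   `kind = "carreau_yasuda"`.
#' @return An object of class `viscosity_mode`.
#' @export
viscosity_mode <- function(kind = c("carreau_yasuda", "constant"),
                           constant_value = 0.0035,
                           params = carreau_yasuda_params()) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (!is.numeric(constant_value) || !is.finite(constant_value) ||
        constant_value <= 0)
      stop("viscosity_mode: constant_value must be a positive viscosity")
  } else if (!inherits(params, "cy_params")) {
    stop("viscosity_mode: params must be a cy_params object")
  }
  structure(list(kind = kind, constant_value = constant_value,
                 params = params),
            class = "viscosity_mode")
}

#' @export
print.viscosity_mode <- function(x, ...) {
  if (x$kind == "constant")
    cat(sprintf("Viscosity mode: constant, %g Pa s\n", x$constant_value))
  else {
    cat("Viscosity mode: Carreau-Yasuda\n")
    print(x$params)
  }
  invisible(x)
}

#' Evaluate the active viscosity law
#'
#' Dispatches on a [viscosity_mode()]: either the constant viscosity
#' (independent of shear rate) or [apparent_viscosity()] at the given rate.
#'
#' @param mode A [viscosity_mode()] object.
#' @param gamma_dot Shear rate(s), 1/s.
#' @return Viscosity (Pa s), recycled to the length of `gamma_dot`.
#' @export
viscosity_of <- function(mode, gamma_dot) {
  if (!inherits(mode, "viscosity_mode"))
    stop("viscosity_of: mode must be a viscosity_mode object")
  if (mode$kind == "constant")
    rep_len(mode$constant_value, length(gamma_dot))
  else
    apparent_viscosity(gamma_dot, mode$params)
}

# Characteristic scalar shear rate of the purely radial flow at a bubble
# interface: the invariant of D for the source field at r = R.
interface_shear_rate <- function(Rdot, R) 2 * sqrt(3) * abs(Rdot) / R
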