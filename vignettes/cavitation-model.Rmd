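---
title: "A reduced-order model of microbubble cavitation in a compliant microvessel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of microbubble cavitation in a compliant microvessel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonovessel)
```

## What the package models

Ultrasound-driven microbubbles oscillating inside a microvessel exert
oscillatory stresses on the endothelium; in the stable-cavitation regime
(tens of kPa, MHz) these stresses transiently widen paracellular junctions
and raise vascular permeability, which is the working principle of
ultrasound-mediated drug delivery across tight endothelial barriers.
`sonovessel` implements a desk-scale model chain for one or two shell-free
bubbles on the axis of a straight vessel segment:

1. **Radial bubble dynamics.** Each bubble obeys an incompressible
   Rayleigh–Plesset equation; a pair is coupled through the standard
   radiation-interaction term, giving for bubble $i$ (with $j \neq i$ and
   centre spacing $d$)
   $$R_i\ddot R_i + \tfrac32\dot R_i^2
     + \frac1d\!\left(2R_j\dot R_j^2 + R_j^2\ddot R_j\right)
     = \frac{1}{\rho_f}\!\left[p_{g,i} + p_v - p_0 + P_d\sin(2\pi f t)
     - \frac{2\sigma_g}{R_i} - \frac{4\eta(\dot\gamma_i)\dot R_i}{R_i}\right],$$
   with the polytropic gas law $p_{g,i} = p_{g0,i}(R_{i0}/R_i)^{3\kappa}$
   and the equilibrium pressure $p_{g0,i} = p_0 + 2\sigma_g/R_{i0} - p_v$.
   The two accelerations appear on both sides; the $2\times2$ linear
   system is solved exactly at every evaluation (its determinant
   $R_1R_2(1 - R_1R_2/d^2)$ is positive whenever the bubbles do not
   overlap), which keeps the integration stable at small spacings.
2. **Blood rheology.** The viscosity entering the interface damping term
   is either a constant (0.0035 Pa s) or the Carreau–Yasuda shear-thinning
   law
   $\eta(\dot\gamma) = \eta_\infty + (\eta_0-\eta_\infty)
   [1+(\lambda\dot\gamma)^a]^{(n-1)/a}$
   evaluated at the scalar invariant of the purely radial flow at the
   interface, $\dot\gamma_i = 2\sqrt3\,|\dot R_i|/R_i$. The exponent is
   the standard Carreau–Yasuda form $(n-1)/a$.
3. **Wall stresses.** The liquid velocity is approximated by the
   free-space superposition of pulsating point sources,
   $u(x) = \sum_i R_i^2\dot R_i (x-x_i)/|x-x_i|^3$. At each wall point
   $(r = R_V, z)$ the microstreaming shear stress is
   $\tau_{ex} = \eta(|\partial u_z/\partial r|)\,\partial u_z/\partial r$
   with the radial derivative taken analytically, and the normal stress is
   the unsteady-Bernoulli estimate
   $\sigma_n = \rho_f\sum_i (2R_i\dot R_i^2 + R_i^2\ddot R_i)/s_i
   - \tfrac{\rho_f}{2}|u|^2$ ($s_i$ the bubble-to-point distance;
   positive = outward push).
4. **Wall response.** Each axial wall point is an independent lumped
   element $\rho_s h\,\ddot w + c\,\dot w + k_w w = \sigma_n(z,t)$ with
   thin-shell hoop stiffness $k_w = Eh/R_V^2$ (optionally
   $E/(1-\nu^2)\cdot h/R_V^2$) and damping
   $c = 2\zeta\sqrt{k_w\rho_s h}$; the hoop strain is
   $\varepsilon = w/R_V$.
5. **Permeability.** The effective stress felt by the endothelium is
   $\tau = \tau_{ex} - E\varepsilon$; the cell shape index is the
   empirical regression $SI = 0.38e^{-0.79\tau} + 0.225e^{-0.043\tau}$
   ($\tau$ in Pa), and the junction permeability is
   $K = \frac{4\times10^8}{3\pi R_{cell}}w^3(0.479 + 0.00593e^{-14.75\,SI})$.
   Summary metrics are the pulse count (threshold crossings of the excess
   permeability per second) and the time-integrated excess permeability
   over the steady-state window; the dual/single ratio of the latter is
   the enhancement ratio. All ratio metrics are independent of the
   prefactor constants $R_{cell}$ and $w$.

The wall is one-way coupled: the trajectory drives the wall fields, and
nothing feeds back. This is the central reduction relative to a fully
coupled fluid–structure (FEM/ALE) treatment and is discussed under
*Limitations*.

## Reference conditions and tunable parameters

The default scenario — `default_scenario()` — is the package's reference
condition set:

| parameter | symbol | default | notes |
|---|---|---|---|
| bubble radii | $R_{10}, R_{20}$ | 2 μm | equal pair; `R20 = NULL` for a single bubble |
| spacing | $d$ | 10 μm | bubbles at $z = \mp d/2$ |
| drive | $P_d$, $f$ | 30 kPa, 1.5 MHz | stable cavitation regime |
| gas | $\kappa$, $p_v$, $\sigma_g$ | 1.07, 2330 Pa, 0.056 N/m | near-isothermal micron bubble |
| liquid | $p_0$, $\rho_f$ | 101.3 kPa, 1059 kg/m³ | blood |
| rheology | $\eta_0,\eta_\infty,\lambda,n,a$ | 0.0519 Pa s, 0.00476 Pa s, 0.438 s, 0.191, 0.409 | whole-blood Carreau–Yasuda fit |
| vessel | $R_V$, $L$, $\rho_s$, $E$, $\nu$ | 5 μm, 40 μm, 1049 kg/m³, 4 MPa, 0.49 | capillary-scale segment |
| wall element | $h$, $\zeta$ | 1 μm, 0.1 | not fixed by the physiology above; repository defaults, configurable and echoed in every output |
| endothelium | $R_{cell}$, $w$ | 15 μm, 20 nm | permeability prefactor only; configurable |
| integration | — | 30 cycles, 200 samples/cycle | metrics over the final 10 cycles |

A single-bubble scenario keeps the bubble at $z = -d/2$, i.e. it is the
dual geometry with bubble 2 removed, so single-versus-dual comparisons
observe the same wall point (the midplane, $z = 0$, 7.07 μm from the
bubble) under identical drive. For a symmetric pair the midplane shear
cancels exactly by antisymmetry, which is why sweep-level stress maxima
are reduced over the whole 81-point axial grid while the permeability
point metrics stay at the midplane observation point.

With the defaults, the free natural frequency of a 2 μm bubble is

```{r}
natural_frequency(2e-6, gas_liquid_params()) / 1e6   # MHz
```

so the 1.5 MHz drive sits just below resonance, and the in-phase pair
mode (added-mass factor $1 + R_0/d$) sits almost exactly on it. This
near-resonant operating point shapes several of the behaviours discussed
below.

## Numerical choices

* **Integrator.** `deSolve::ode` with `lsodar`, relative tolerance
  $10^{-8}$, absolute tolerance $10^{-14}$ on radii; output on a uniform
  grid of 200 samples per period, enough to resolve the rebound spikes in
  the stress series. A root function stops the integration if any radius
  falls below $R_0/50$ (an exit from the stable regime); the partial
  trajectory is returned flagged.
* **Wall element.** The forcing is interpolated linearly between samples
  and each step uses the exact solution of the linear oscillator, so the
  update is unconditionally stable; the only error is the interpolation
  of the load (second order in the sampling interval, verified against
  the closed-form forced response to $10^{-6}$).
* **Rheology guard.** $(\lambda\dot\gamma)^a$ is evaluated in log space
  above $10^8$ 1/s; the two branches agree to better than $10^{-9}$ at
  the switch point.
* **Clamping.** $E\varepsilon$ can exceed $\tau_{ex}$, making the
  effective stress negative; because the shape-index regression is only
  supported on non-negative stress, negative values are clamped to zero
  before it (configurable via `clamp_negative_tau`).
* **Noise floor.** A peak excess permeability below $10^{-9}$ of the
  baseline is treated as flat, so an undriven scenario reports zero
  pulses instead of counting floating-point noise crossings.
* **Steady-state windows.** All metrics discard startup transients by
  averaging/integrating over the trailing 10 whole periods of the
  30-cycle run; trapezoidal quadrature is used for integrals and the
  secondary Bjerknes average.
* **Determinism.** No randomness anywhere: identical configurations give
  byte-identical metric files.

## Design decisions at genuinely open points

* **Forcing convention.** The drive enters the liquid pressure as
  $+P_d\sin(2\pi ft)$ (far-field pressure $p_0 - P_d\sin$), phase 0 at
  $t=0$; the choice only shifts the steady-state phase.
* **Vapour pressure** adds to the internal pressure ($p_g + p_v$),
  consistent with its subtraction in the equilibrium balance.
* **Interface shear rate.** The scalar rate used in the viscous damping
  term is the invariant of the radial source flow at the interface,
  $2\sqrt3|\dot R|/R$ — the natural closure when no full velocity
  gradient field is available.
* **Wall thickness and damping** ($h$, $\zeta$) are not determined by the
  other constants; 1 μm and 0.1 are typical capillary-wall values, kept
  configurable and echoed in output metadata.
* **Observation point.** Point metrics default to the midplane wall point
  $(r = R_V, z = 0)$, equidistant from both bubbles.
* **Spacing sweep grid** {10, 16, 26, 36} μm: the outer two values probe
  the decoupling trend, the inner two the strongly coupled regime.

## What the scenario generator emulates — and what it does not

Scenario configurations (YAML/JSON) and the sweep drivers reproduce the
reference study conditions: the default dual scenario above and the four
standard parameter studies (pressure {50, 100, 150} kPa, frequency
{0.25–2} MHz, asymmetric bubble size {1, 2, 3, 4} μm against a 2 μm
partner, spacing {10, 16, 26, 36} μm). These are idealised conditions:
fixed bubble positions on the axis, a quiescent liquid, a perfectly
straight segment, no translation, coalescence, shell, or thermal damping.
Passing the property suite therefore demonstrates internal consistency of
the model chain and the robustness of its parameter orderings — not
agreement with any particular in vivo configuration.

## Behaviour at the reference conditions, and limitations

The suite and the acceptance script compute, among others, the following
facts about this model at the defaults; they are worth stating plainly
because some differ from what fully coupled confined simulations show.

* **Orderings that hold.** Wall stresses grow monotonically with drive
  pressure; the amplitude–frequency response peaks at the sweep frequency
  nearest the natural frequency; wall shear grows with the size of an
  asymmetric partner bubble; wall normal stress decays monotonically with
  spacing; the pair loads the wall harder than a single bubble; normal
  stress dominates shear at the near wall point; equal in-phase bubbles
  attract (negative mean secondary Bjerknes force).
* **Absolute stress levels are over-predicted.** The free-space source
  superposition ignores the confinement of the 5 μm vessel, which in a
  fully coupled treatment suppresses both the oscillation amplitude and
  the transmitted stresses by an order of magnitude or more. The
  single-bubble midplane shear maximum computed here is a few hundred Pa,
  whereas confined fluid–structure simulations of the same conditions
  report tens of Pa.
* **Resonance coincidence reverses the amplitude ordering.** Because the
  in-phase pair mode falls almost exactly on the 1.5 MHz drive, the pair
  oscillates slightly *more* than the isolated bubble here, not less as
  confined simulations (whose effective resonances are shifted well below
  the free-field value) find.
* **The permeability chain saturates.** With kPa-scale wall loads, the
  hoop strains reach the percent level and $E\varepsilon$ is of order
  $10^4$–$10^5$ Pa — far beyond the ~0.1–100 Pa band in which the
  shape-index regression responds. $K(t)$ then alternates between its
  baseline and its saturated maximum for single and dual scenarios alike,
  so the integrated-excess enhancement ratio computed at these stress
  levels is close to 1 and the pulse counts tie at one per cycle. In the
  stress regime the regression was fitted for, the same chain is strongly
  super-linear (a doubling of stress multiplies the excess several-fold),
  which is the regime in which a dual-bubble synergy factor above 2 would
  be expressed.

These gaps are properties of the deliberate one-way-coupled, unconfined
reduction, not of its implementation; the implementation-level invariants
(exact acceleration assembly, oscillator closed forms, quadrature
consistency, frame indifference, prefactor invariance) are all verified
independently in the test suite.

## Problem sizes

The reference runs integrate 30 acoustic cycles (20 μs at 1.5 MHz) at 200
output samples per cycle, with wall fields on 81 axial points; a dual
scenario completes in a few seconds on one core, and the full test suite
plus acceptance script in about a minute.
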