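#' Integration controls
#'
#' @param t_end_cycles Simulated acoustic cycles (default 30).
#' @param samples_per_cycle Output samples per acoustic period (default
#'   200).
#' @param rtol Relative tolerance of the stiff integrator.
#' @param atol_R Absolute tolerance on the radius states (m).
#' @param metrics_cycles Trailing whole cycles used for steady-state
#'   metrics (default 10).
#' @param r_min_frac Collapse guard: integration stops if any radius falls
#'   below this fraction of its initial value.
#' @return An object of class `integration_controls`.
#' @export
integration_controls <- function(t_end_cycles = 30, samples_per_cycle = 200,
                                 rtol = 1e-8, atol_R = 1e-14,
                                 metrics_cycles = 10, r_min_frac = 0.02) {
  stopifnot(t_end_cycles >= 1, samples_per_cycle >= 16,
            rtol > 0, atol_R > 0,
            metrics_cycles >= 1, metrics_cycles <= t_end_cycles,
            r_min_frac > 0, r_min_frac < 1)
  structure(list(t_end_cycles = t_end_cycles,
                 samples_per_cycle = samples_per_cycle,
                 rtol = rtol, atol_R = atol_R,
                 metrics_cycles = metrics_cycles,
                 r_min_frac = r_min_frac),
            class = "integration_controls")
}

#' Scenario configuration
#'
#' Aggregates every ingredient of one simulation: bubble geometry, acoustic
#' drive, gas/liquid constants, rheology mode, vessel wall, endothelium and
#' integration controls.
#'
#' @param bubbles A [bubble_config()].
#' @param drive An [acoustic_drive()].
#' @param gas A [gas_liquid_params()] (includes the liquid constants `p0`,
#'   `rho_f`).
#' @param rheology A [viscosity_mode()].
#' @param vessel A [vessel_config()].
#' @param endothelium An [endothelium_params()].
#' @param integration An [integration_controls()].
#' @param z_obs Wall observation position (m) for point metrics.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(bubbles = bubble_config(),
                            drive = acoustic_drive(),
                            gas = gas_liquid_params(),
                            rheology = viscosity_mode("carreau_yasuda"),
                            vessel = vessel_config(),
                            endothelium = endothelium_params(),
                            integration = integration_controls(),
                            z_obs = 0) {
  cfg <- structure(list(bubbles = bubbles, drive = drive, gas = gas,
                        rheology = rheology, vessel = vessel,
                        endothelium = endothelium,
                        integration = integration, z_obs = z_obs),
                   class = "scenario_config")
  validate_scenario(cfg)
  cfg
}

#' Validate a scenario configuration
#'
#' Checks the class and nested invariants of every component; additionally
#' requires the bubbles to fit inside the vessel.
#'
#' @param cfg A [scenario_config()].
#' @return `cfg`, invisibly; errors on violation.
#' @export
validate_scenario <- function(cfg) {
  if (!inherits(cfg, "scenario_config"))
    stop("validate_scenario: not a scenario_config")
  want <- c(bubbles = "bubble_config", drive = "acoustic_drive",
            gas = "gas_liquid_params", rheology = "viscosity_mode",
            vessel = "vessel_config", endothelium = "endothelium_params",
            integration = "integration_controls")
  for (f in names(want))
    if (!inherits(cfg[[f]], want[[f]]))
      stop(sprintf("validate_scenario: field '%s' must be a %s", f,
                   want[[f]]))
  rmax <- max(initial_radii(cfg$bubbles))
  if (rmax >= cfg$vessel$RV)
    stop("validate_scenario: bubble radius must be below the vessel radius")
  if (!is.finite(cfg$z_obs) || abs(cfg$z_obs) > cfg$vessel$L / 2)
    stop("validate_scenario: z_obs must lie within the vessel segment")
  invisible(cfg)
}

#' Default dual-bubble scenario
#'
#' The package's reference conditions: two 2-um bubbles 10 um apart on the
#' axis of a 5-um-radius, 40-um-long vessel, driven at 30 kPa / 1.5 MHz,
#' with Carreau-Yasuda blood rheology and default wall/endothelium
#' constants.
#'
#' @return A [scenario_config()].
#' @export
default_scenario <- function() scenario_config()

#' Single-bubble reduction of a scenario
#'
#' Drops bubble 2 while keeping everything else (including bubble 1's axial
#' position at `-d/2`) identical, for single-versus-dual comparisons under
#' the same drive and geometry.
#'
#' @param cfg A dual-bubble [scenario_config()].
#' @return The single-bubble `scenario_config`.
#' @export
drop_second_bubble <- function(cfg) {
  validate_scenario(cfg)
  if (n_bubbles(cfg$bubbles) != 2L)
    stop("drop_second_bubble: scenario is already single-bubble")
  cfg$bubbles <- bubble_config(R10 = cfg$bubbles$R10, R20 = NULL,
                               d = cfg$bubbles$d)
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  bc <- x$bubbles
  if (n_bubbles(bc) == 2L)
    cat(sprintf("Scenario: dual bubbles R10 = %g um, R20 = %g um, d = %g um\n",
                bc$R10 * 1e6, bc$R20 * 1e6, bc$d * 1e6))
  else
    cat(sprintf("Scenario: single bubble R10 = %g um (at z = %g um)\n",
                bc$R10 * 1e6, -bc$d / 2 * 1e6))
  cat(sprintf("  drive: %g kPa at %g MHz; rheology: %s\n",
              x$drive$Pd / 1e3, x$drive$f / 1e6, x$rheology$kind))
  cat(sprintf("  vessel: RV = %g um, L = %g um; %d cycles x %d samples\n",
              x$vessel$RV * 1e6, x$vessel$L * 1e6,
              x$integration$t_end_cycles,
              x$integration$samples_per_cycle))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------
# Configuration files use human-scale units in their key names (um, kPa,
# MHz, nm); internal objects are SI throughout.

scenario_to_list <- function(cfg) {
  bc <- cfg$bubbles
  out <- list(
    bubbles = c(list(R10_um = bc$R10 * 1e6),
                if (!is.null(bc$R20)) list(R20_um = bc$R20 * 1e6),
                list(d_um = bc$d * 1e6)),
    drive = list(Pd_kPa = cfg$drive$Pd / 1e3, f_MHz = cfg$drive$f / 1e6,
                 phase_rad = cfg$drive$phase),
    gas = list(kappa = cfg$gas$kappa, pv_Pa = cfg$gas$pv,
               sigma_N_per_m = cfg$gas$sigma_g),
    liquid = list(p0_Pa = cfg$gas$p0, rho_kg_m3 = cfg$gas$rho_f),
    rheology = list(kind = cfg$rheology$kind,
                    constant_Pa_s = cfg$rheology$constant_value,
                    eta0_Pa_s = cfg$rheology$params$eta0,
                    eta_inf_Pa_s = cfg$rheology$params$eta_inf,
                    lambda_s = cfg$rheology$params$lam,
                    n = cfg$rheology$params$n,
                    a = cfg$rheology$params$a),
    vessel = list(RV_um = cfg$vessel$RV * 1e6, L_um = cfg$vessel$L * 1e6,
                  rho_kg_m3 = cfg$vessel$rho_s, E_Pa = cfg$vessel$E,
                  nu = cfg$vessel$nu, h_um = cfg$vessel$h * 1e6,
                  zeta = cfg$vessel$zeta,
                  plane_strain = cfg$vessel$plane_strain,
                  nz = cfg$vessel$nz),
    endothelium = list(Rcell_um = cfg$endothelium$Rcell * 1e6,
                       w_half_nm = cfg$endothelium$w_half * 1e9,
                       E_Pa = cfg$endothelium$E,
                       clamp_negative_tau =
                         cfg$endothelium$clamp_negative_tau,
                       prefactor = cfg$endothelium$prefactor),
    integration = unclass(cfg$integration),
    observation = list(z_um = cfg$z_obs * 1e6))
  out
}

scenario_from_list <- function(x) {
  gl <- function(node, key, default = NULL) {
    if (!is.null(node[[key]])) node[[key]] else default
  }
  b <- x$bubbles
  bubbles <- bubble_config(
    R10 = gl(b, "R10_um", 2) * 1e-6,
    R20 = if (is.null(b$R20_um)) NULL else b$R20_um * 1e-6,
    d = gl(b, "d_um", 10) * 1e-6)
  drive <- acoustic_drive(Pd = gl(x$drive, "Pd_kPa", 30) * 1e3,
                          f = gl(x$drive, "f_MHz", 1.5) * 1e6,
                          phase = gl(x$drive, "phase_rad", 0))
  gas <- gas_liquid_params(kappa = gl(x$gas, "kappa", 1.07),
                           pv = gl(x$gas, "pv_Pa", 2330),
                           sigma_g = gl(x$gas, "sigma_N_per_m", 0.056),
                           p0 = gl(x$liquid, "p0_Pa", 1.013e5),
                           rho_f = gl(x$liquid, "rho_kg_m3", 1059))
  r <- x$rheology
  rheology <- viscosity_mode(
    kind = gl(r, "kind", "carreau_yasuda"),
    constant_value = gl(r, "constant_Pa_s", 0.0035),
    params = carreau_yasuda_params(
      eta0 = gl(r, "eta0_Pa_s", 0.0519),
      eta_inf = gl(r, "eta_inf_Pa_s", 0.00476),
      lam = gl(r, "lambda_s", 0.438),
      n = gl(r, "n", 0.191), a = gl(r, "a", 0.409)))
  v <- x$vessel
  vessel <- vessel_config(RV = gl(v, "RV_um", 5) * 1e-6,
                          L = gl(v, "L_um", 40) * 1e-6,
                          rho_s = gl(v, "rho_kg_m3", 1049),
                          E = gl(v, "E_Pa", 4e6), nu = gl(v, "nu", 0.49),
                          h = gl(v, "h_um", 1) * 1e-6,
                          zeta = gl(v, "zeta", 0.1),
                          plane_strain = gl(v, "plane_strain", FALSE),
                          nz = gl(v, "nz", 81L))
  e <- x$endothelium
  endo <- endothelium_params(
    Rcell = gl(e, "Rcell_um", 15) * 1e-6,
    w_half = gl(e, "w_half_nm", 20) * 1e-9,
    E = gl(e, "E_Pa", 4e6),
    clamp_negative_tau = gl(e, "clamp_negative_tau", TRUE),
    prefactor = e$prefactor)
  ic <- x$integration
  integ <- integration_controls(
    t_end_cycles = gl(ic, "t_end_cycles", 30),
    samples_per_cycle = gl(ic, "samples_per_cycle", 200),
    rtol = gl(ic, "rtol", 1e-8), atol_R = gl(ic, "atol_R", 1e-14),
    metrics_cycles = gl(ic, "metrics_cycles", 10),
    r_min_frac = gl(ic, "r_min_frac", 0.02))
  scenario_config(bubbles = bubbles, drive = drive, gas = gas,
                  rheology = rheology, vessel = vessel,
                  endothelium = endo, integration = integ,
                  z_obs = gl(x$observation, "z_um", 0) * 1e-6)
}

#' Write a scenario configuration file
#'
#' YAML (default) or JSON, chosen by `format` or the file extension.
#'
#' @param cfg A [scenario_config()].
#' @param path Output file path.
#' @param format `"auto"` (by extension), `"yaml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(cfg, path, format = c("auto", "yaml", "json")) {
  format <- match.arg(format)
  validate_scenario(cfg)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
      else "yaml"
  x <- scenario_to_list(cfg)
  if (format == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else
    writeLines(yaml::as.yaml(x, precision = 15), path)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' Accepts YAML or JSON (auto-detected: files whose first non-blank
#' character is `{` are parsed as JSON). Missing keys fall back to the
#' package defaults.
#'
#' @param path Configuration file path.
#' @return A [scenario_config()].
#' @export
read_scenario <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  first <- substr(trimws(txt), 1, 1)
  x <- if (identical(first, "{")) jsonlite::fromJSON(txt,
                                                     simplifyVector = TRUE)
    else yaml::yaml.load(txt)
  scenario_from_list(x)
}

# ---- running ----------------------------------------------------------------

# Peak-to-peak radius excursion of each bubble over the steady-state window.
steady_amplitude <- function(traj, n_cycles) {
  win <- trailing_cycle_window(traj$t, traj$period, n_cycles)
  apply(traj$R[win, , drop = FALSE], 2, function(r) max(r) - min(r))
}

#' Run one scenario end to end
#'
#' Simulates the bubble dynamics, evaluates the wall stress fields and
#' elastic response on the axial grid, maps them to permeability, and
#' gathers summary metrics. Everything is deterministic: identical
#' configurations give identical outputs. If `out_dir` is given, writes
#' `trajectory.csv`, `wall_series.csv`, `permeability.csv` and
#' `metrics.json` (metrics plus a complete configuration echo, so a run is
#' reproducible from its metadata alone).
#'
#' Stress maxima in the metrics are taken over the whole axial grid and the
#' steady-state window; point metrics (pulse count, integrated excess,
#' normal-stress extremes) are taken at the scenario's observation point.
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return An object of class `scenario_result`: list with `trajectory`,
#'   `wall`, `permeability`, `metrics` and `metadata`.
#' @export
run_scenario <- function(cfg, out_dir = NULL) {
  validate_scenario(cfg)
  traj <- simulate_bubbles(cfg)
  ws <- wall_series(traj)
  ps <- permeability_series(ws, cfg$endothelium, z_obs = cfg$z_obs,
                            n_cycles = cfg$integration$metrics_cycles)
  ncyc <- cfg$integration$metrics_cycles
  win <- trailing_cycle_window(traj$t, traj$period, ncyc)
  amp <- steady_amplitude(traj, ncyc)
  i_obs <- ps$i_obs
  metrics <- list(
    amplitude_m = as.numeric(amp),
    max_abs_tau_Pa = max(abs(ws$tau_ex[win, ])),
    max_abs_sigma_n_Pa = max(abs(ws$sigma_n[win, ])),
    max_abs_tau_obs_Pa = max(abs(ws$tau_ex[win, i_obs])),
    max_abs_sigma_n_obs_Pa = max(abs(ws$sigma_n[win, i_obs])),
    min_sigma_n_obs_Pa = min(ws$sigma_n[win, i_obs]),
    max_sigma_n_obs_Pa = max(ws$sigma_n[win, i_obs]),
    pulse_count_per_s = ps$metrics$pulse_count_per_s,
    integrated_excess = ps$metrics$integrated_excess,
    mean_FSB_N = if (traj$n_bubbles == 2L)
      secondary_bjerknes(traj, n_cycles = ncyc)$mean else NA_real_,
    collapsed = traj$collapsed)
  metadata <- list(config = scenario_to_list(cfg),
                   package_version =
                     as.character(utils::packageVersion("sonovessel")),
                   n_time_samples = length(traj$t),
                   n_axial_points = length(ws$z))
  res <- structure(list(trajectory = traj, wall = ws, permeability = ps,
                        metrics = metrics, metadata = metadata),
                   class = "scenario_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(traj, file.path(out_dir, "trajectory.csv"))
    write_wall_series(ws, file.path(out_dir, "wall_series.csv"))
    write_permeability_series(ps, file.path(out_dir, "permeability.csv"))
    jsonlite::write_json(list(metrics = metrics, metadata = metadata),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$trajectory)
  cat(sprintf("  max |tau_ex| = %.4g Pa (grid), |sigma_n| = %.4g Pa\n",
              x$metrics$max_abs_tau_Pa, x$metrics$max_abs_sigma_n_Pa))
  cat(sprintf("  pulses = %.4g /s, integrated excess = %.4g\n",
              x$metrics$pulse_count_per_s, x$metrics$integrated_excess))
  invisible(x)
}

#' Parameter sweep
#'
#' Runs the base scenario once per value of the sweep axis and collects a
#' tidy table of metrics, ordered by the axis value. Axes: acoustic
#' pressure amplitude `Pd` (Pa), drive frequency `f` (Hz), bubble-1 radius
#' `R10` (m), or spacing `d` (m) — all in SI units. A failed member run is
#' recorded with `failed = TRUE` and the sweep continues.
#'
#' @param base A [scenario_config()] used as the template.
#' @param axis One of `"Pd"`, `"f"`, `"R10"`, `"d"`.
#' @param values Numeric sweep values (SI units), non-empty.
#' @param out_dir Optional directory; each member run writes its outputs to
#'   a subdirectory, and the sweep table is written as `sweep.csv`.
#' @return `data.frame` with one row per value: axis, value, per-bubble
#'   steady amplitudes, grid maxima of |tau_ex| and |sigma_n|, pulse count,
#'   integrated excess, collapse and failure flags.
#' @export
run_sweep <- function(base, axis = c("Pd", "f", "R10", "d"), values,
                      out_dir = NULL) {
  axis <- match.arg(axis)
  validate_scenario(base)
  if (length(values) == 0) stop("run_sweep: values must be non-empty")
  values <- sort(as.numeric(values))
  rows <- lapply(values, function(v) {
    cfg <- base
    cfg <- switch(axis,
      Pd = { cfg$drive <- acoustic_drive(v, cfg$drive$f, cfg$drive$phase)
             cfg },
      f = { cfg$drive <- acoustic_drive(cfg$drive$Pd, v, cfg$drive$phase)
            cfg },
      R10 = { cfg$bubbles <- bubble_config(v, cfg$bubbles$R20,
                                           cfg$bubbles$d); cfg },
      d = { cfg$bubbles <- bubble_config(cfg$bubbles$R10, cfg$bubbles$R20,
                                         v); cfg })
    res <- tryCatch({
      sub <- if (is.null(out_dir)) NULL else
        file.path(out_dir, sprintf("%s_%g", axis, v))
      run_scenario(cfg, sub)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(axis = axis, value = v, amplitude1_m = NA_real_,
                 amplitude2_m = NA_real_, max_abs_tau_Pa = NA_real_,
                 max_abs_sigma_n_Pa = NA_real_,
                 pulse_count_per_s = NA_real_,
                 integrated_excess = NA_real_,
                 collapsed = NA, failed = TRUE)
    } else {
      m <- res$metrics
      data.frame(axis = axis, value = v, amplitude1_m = m$amplitude_m[1],
                 amplitude2_m = if (length(m$amplitude_m) > 1)
                   m$amplitude_m[2] else NA_real_,
                 max_abs_tau_Pa = m$max_abs_tau_Pa,
                 max_abs_sigma_n_Pa = m$max_abs_sigma_n_Pa,
                 pulse_count_per_s = m$pulse_count_per_s,
                 integrated_excess = m$integrated_excess,
                 collapsed = m$collapsed, failed = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
  }
  tab
}

#' Compare single- and dual-bubble systems
#'
#' Runs a dual-bubble scenario and its single-bubble reduction (bubble 2
#' dropped, identical drive and geometry) and reports the synergy metrics:
#' the per-bubble amplitude ratio, the grid stress ratios, the pulse-count
#' ratio and the integrated-excess permeability enhancement ratio.
#'
#' @param base A dual-bubble [scenario_config()].
#' @param out_dir Optional directory; the two runs write to `dual/` and
#'   `single/`, and the summary to `comparison.json`.
#' @return An object of class `tmfss_comparison`: list with `dual` and
#'   `single` results and a `summary` list of ratios.
#' @export
compare_smfss_tmfss <- function(base, out_dir = NULL) {
  validate_scenario(base)
  if (n_bubbles(base$bubbles) != 2L)
    stop("compare_smfss_tmfss: base scenario must be dual-bubble")
  dual <- run_scenario(base,
                       if (is.null(out_dir)) NULL
                       else file.path(out_dir, "dual"))
  single <- run_scenario(drop_second_bubble(base),
                         if (is.null(out_dir)) NULL
                         else file.path(out_dir, "single"))
  md <- dual$metrics; ms <- single$metrics
  summary <- list(
    amplitude_ratio = md$amplitude_m[1] / ms$amplitude_m[1],
    tau_ratio = md$max_abs_tau_Pa / ms$max_abs_tau_Pa,
    sigma_n_ratio = md$max_abs_sigma_n_Pa / ms$max_abs_sigma_n_Pa,
    pulse_count_ratio = if (ms$pulse_count_per_s > 0)
      md$pulse_count_per_s / ms$pulse_count_per_s else NA_real_,
    enhancement_ratio = enhancement_ratio(dual$permeability,
                                          single$permeability))
  res <- structure(list(dual = dual, single = single, summary = summary),
                   class = "tmfss_comparison")
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.tmfss_comparison <- function(x, ...) {
  s <- x$summary
  cat("Dual vs single microbubble comparison:\n")
  cat(sprintf("  per-bubble amplitude ratio: %.4g\n", s$amplitude_ratio))
  cat(sprintf("  max |tau_ex| ratio: %.4g, max |sigma_n| ratio: %.4g\n",
              s$tau_ratio, s$sigma_n_ratio))
  cat(sprintf("  pulse-count ratio: %.4g, enhancement ratio: %.4g\n",
              s$pulse_count_ratio, s$enhancement_ratio))
  invisible(x)
}

# ---- fixtures --------------------------------------------------------------

#' Write the reference scenario and sweep fixtures
#'
#' Emits the default dual-bubble configuration plus the four standard sweep
#' specifications: pressure {50, 100, 150} kPa, frequency
#' {0.25, 0.5, 0.75, 1.0} MHz, bubble-1 radius {1, 2, 3, 4} um, and
#' spacing {10, 16, 26, 36} um. Each sweep file carries the full base
#' configuration plus a `sweep` block with the axis and the values in the
#' file's units.
#'
#' @param dir Output directory (created if missing).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_fixture_configs <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- default_scenario()
  paths <- character(0)
  p <- file.path(dir, "default.yaml")
  write_scenario(base, p); paths <- c(paths, p)
  sweeps <- list(
    pressure = list(axis = "Pd", key = "values_kPa",
                    values = c(50, 100, 150)),
    frequency = list(axis = "f", key = "values_MHz",
                     values = c(0.25, 0.5, 0.75, 1.0)),
    radius = list(axis = "R10", key = "values_um", values = c(1, 2, 3, 4)),
    spacing = list(axis = "d", key = "values_um",
                   values = c(10, 16, 26, 36)))
  for (nm in names(sweeps)) {
    sp <- sweeps[[nm]]
    x <- scenario_to_list(base)
    x$sweep <- c(list(axis = sp$axis),
                 stats::setNames(list(sp$values), sp$key))
    p <- file.path(dir, sprintf("sweep_%s.yaml", nm))
    writeLines(yaml::as.yaml(x, precision = 15), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# Convert sweep values given in config-file units to SI for run_sweep().
sweep_values_to_si <- function(axis, key, values) {
  fac <- switch(paste(axis, key),
    "Pd values_kPa" = 1e3, "f values_MHz" = 1e6,
    "R10 values_um" = 1e-6, "d values_um" = 1e-6,
    stop("unknown sweep axis/unit combination: ", axis, " ", key))
  values * fac
}

#' Read a sweep specification file
#'
#' A sweep file is a scenario configuration with an extra `sweep` block
#' (`axis` plus a unit-suffixed `values_*` vector, as written by
#' [write_fixture_configs()]).
#'
#' @param path Sweep file path.
#' @return List with `base` (a [scenario_config()]), `axis` and SI
#'   `values`.
#' @export
read_sweep_spec <- function(path) {
  x <- yaml::yaml.load(paste(readLines(path, warn = FALSE),
                             collapse = "\n"))
  if (is.null(x$sweep))
    stop("read_sweep_spec: file has no 'sweep' block")
  sw <- x$sweep
  key <- setdiff(names(sw), "axis")
  if (length(key) != 1)
    stop("read_sweep_spec: sweep block needs exactly one values_* entry")
  vals <- sweep_values_to_si(sw$axis, key, as.numeric(sw[[key]]))
  x$sweep <- NULL
  list(base = scenario_from_list(x), axis = sw$axis, values = vals)
}
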