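test_that("the default scenario is valid, carries the reference
           conditions, and yields the documented equilibrium gas
           pressure", {
  cfg <- default_scenario()
  expect_s3_class(cfg, "scenario_config")
  expect_invisible(validate_scenario(cfg))
  expect_equal(cfg$bubbles$R10, 2e-6)
  expect_equal(cfg$bubbles$d, 10e-6)
  expect_equal(cfg$drive$Pd, 0.3e5)
  expect_equal(cfg$drive$f, 1.5e6)
  expect_equal(cfg$vessel$RV, 5e-6)
  expect_equal(cfg$rheology$kind, "carreau_yasuda")
  expect_equal(initial_gas_pressure(cfg$bubbles$R10, cfg$gas), 154970,
               tolerance = 1e-12)
  expect_error(scenario_config(bubbles = bubble_config(R10 = 6e-6,
                                                       R20 = NULL,
                                                       d = 20e-6)),
               "below the vessel radius")
})

test_that("scenario configurations round-trip through YAML and JSON", {
  cfg <- quick_scenario(R10 = 1.7e-6, Pd = 42e3,
                        rheology = viscosity_mode("constant",
                                                  constant_value = 0.004))
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("cfg.", ext))
    write_scenario(cfg, path)
    back <- read_scenario(path)
    expect_equal(back$bubbles, cfg$bubbles, tolerance = 1e-12)
    expect_equal(back$drive, cfg$drive, tolerance = 1e-12)
    expect_equal(back$gas, cfg$gas, tolerance = 1e-12)
    expect_equal(back$rheology, cfg$rheology, tolerance = 1e-12)
    expect_equal(back$vessel, cfg$vessel, tolerance = 1e-12)
    expect_equal(back$endothelium, cfg$endothelium, tolerance = 1e-12)
    expect_equal(back$integration, cfg$integration, tolerance = 1e-12)
  }
  # single-bubble mode survives the round trip (R20 stays absent)
  solo <- quick_scenario(dual = FALSE)
  path <- file.path(tempdir(), "solo.yaml")
  write_scenario(solo, path)
  expect_null(read_scenario(path)$bubbles$R20)
})

test_that("an undriven run reports zero stress and permeability metrics", {
  res <- run_scenario(quick_scenario(Pd = 0, t_end_cycles = 6,
                                     metrics_cycles = 3))
  expect_lt(res$metrics$max_abs_tau_Pa, 1e-12)
  expect_lt(res$metrics$max_abs_sigma_n_Pa, 1e-8)
  expect_identical(res$metrics$pulse_count_per_s, 0)
  expect_lt(abs(res$metrics$integrated_excess), 1e-25)
})

test_that("identical configurations produce byte-identical outputs", {
  cfg <- quick_scenario(t_end_cycles = 8, metrics_cycles = 3)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  r1 <- run_scenario(cfg, out_dir = d1)
  r2 <- run_scenario(cfg, out_dir = d2)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(readLines(file.path(d1, "metrics.json")),
                   readLines(file.path(d2, "metrics.json")))
  # metadata echoes every filled-in default needed to reproduce the run
  echo <- r1$metadata$config
  expect_equal(echo$vessel$h_um, 1)
  expect_equal(echo$vessel$zeta, 0.1)
  expect_equal(echo$endothelium$Rcell_um, 15)
  expect_equal(echo$endothelium$w_half_nm, 20)
  expect_true(is.numeric(echo$endothelium$prefactor))
})

test_that("run_scenario writes the documented output files", {
  out <- file.path(tempdir(), "runout")
  res <- run_scenario(quick_scenario(t_end_cycles = 6, metrics_cycles = 3,
                                     nz = 11L), out_dir = out)
  tr <- utils::read.csv(file.path(out, "trajectory.csv"))
  expect_named(tr, c("t_s", "R1_m", "R1dot_m_s", "R2_m", "R2dot_m_s",
                     "V1_m3", "V2_m3", "FSB_N"))
  expect_equal(nrow(tr), length(res$trajectory$t))
  ws <- utils::read.csv(file.path(out, "wall_series.csv"))
  expect_named(ws, c("t_s", "z_m", "tau_ex_Pa", "sigma_n_Pa", "w_d_m",
                     "eps"))
  ps <- utils::read.csv(file.path(out, "permeability.csv"))
  expect_named(ps, c("t_s", "z_m", "tau_Pa", "SI", "K"))
  expect_equal(nrow(ps), length(res$trajectory$t) * 11L)
})

test_that("sweeps return ordered tidy tables and survive member
           failures", {
  base <- quick_scenario(t_end_cycles = 6, metrics_cycles = 3, nz = 11L)
  tab <- run_sweep(base, "Pd", c(30e3, 10e3))
  expect_equal(tab$value, c(10e3, 30e3))   # ordered by axis value
  expect_false(any(tab$failed))
  expect_true(all(tab$max_abs_sigma_n_Pa > 0))
  # a bubble larger than the vessel is rejected but the sweep continues
  tab2 <- run_sweep(base, "R10", c(2e-6, 6e-6))
  expect_identical(tab2$failed, c(FALSE, TRUE))
  expect_true(is.na(tab2$max_abs_tau_Pa[2]))
})

test_that("the dual-versus-single comparison reports ratios consistent
           with its own member runs, and its CSV outputs reproduce the
           enhancement ratio", {
  base <- quick_scenario(t_end_cycles = 10, metrics_cycles = 4, nz = 11L)
  out <- file.path(tempdir(), "cmp")
  cmp <- compare_smfss_tmfss(base, out_dir = out)
  expect_equal(cmp$summary$sigma_n_ratio,
               cmp$dual$metrics$max_abs_sigma_n_Pa /
                 cmp$single$metrics$max_abs_sigma_n_Pa)
  expect_error(compare_smfss_tmfss(drop_second_bubble(base)),
               "dual-bubble")
  # recompute the integrated-excess ratio from the written K series
  reread <- function(dir, res) {
    df <- utils::read.csv(file.path(out, dir, "permeability.csv"))
    zs <- sort(unique(df$z_m))
    zo <- zs[which.min(abs(zs - 0))]
    sub <- df[df$z_m == zo, ]
    base_K <- baseline_permeability(base$endothelium)
    win <- sonovessel:::trailing_cycle_window(sub$t_s, 1 / base$drive$f, 4)
    pracma::trapz(sub$t_s[win], sub$K[win] - base_K)
  }
  ratio_files <- reread("dual", cmp$dual) / reread("single", cmp$single)
  expect_equal(cmp$summary$enhancement_ratio, ratio_files,
               tolerance = 1e-6)
})

test_that("fixture configs are written and parse back into runnable sweep
           specifications", {
  dir <- file.path(tempdir(), "fixtures")
  paths <- write_fixture_configs(dir)
  expect_length(paths, 5)
  expect_true(all(file.exists(paths)))
  def <- read_scenario(file.path(dir, "default.yaml"))
  expect_equal(def$bubbles$d, 10e-6)
  sp <- read_sweep_spec(file.path(dir, "sweep_pressure.yaml"))
  expect_equal(sp$axis, "Pd")
  expect_equal(sp$values, c(50e3, 100e3, 150e3))
  sp <- read_sweep_spec(file.path(dir, "sweep_spacing.yaml"))
  expect_equal(sp$values, c(10, 16, 26, 36) * 1e-6)
  sp <- read_sweep_spec(file.path(dir, "sweep_frequency.yaml"))
  expect_equal(sp$values, c(0.25, 0.5, 0.75, 1.0) * 1e6)
  expect_error(read_sweep_spec(file.path(dir, "default.yaml")),
               "no 'sweep' block")
})

test_that("the command-line driver is shipped and syntactically valid", {
  cli <- system.file("cli", "sonovessel.R", package = "sonovessel")
  expect_true(nzchar(cli) && file.exists(cli))
  expect_silent(parse(file = cli))
})
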