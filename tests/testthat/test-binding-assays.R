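test_that("noiseless Boltzmann melt curves are recovered to high precision", {
  sim <- simulate_melt_curve(synth_spec(51, "melt_curve", tm = 52, cv = 0))
  f <- fit_boltzmann(sim$data$temperature, sim$data$signal)
  expect_true(f$converged)
  expect_equal(f$tm, 52, tolerance = 1e-3)
  expect_equal(f$slope, 1.0, tolerance = 1e-3)
  expect_equal(f$f_pre, 10, tolerance = 1e-3)
  expect_equal(f$f_post, 100, tolerance = 1e-3)
})

test_that("Tm sits at the half-transition of the fitted curve", {
  sim <- simulate_melt_curve(synth_spec(52, "melt_curve", tm = 47.3, cv = 0.01))
  f <- fit_boltzmann(sim$data$temperature, sim$data$signal)
  half <- (f$f_pre + f$f_post) / 2
  value_at_tm <- f$f_pre + (f$f_post - f$f_pre) / (1 + exp((f$tm - f$tm) / f$slope))
  expect_equal(value_at_tm, half, tolerance = 1e-9)
})

test_that("a temperature-mirrored curve is flagged as a negative-slope transition", {
  sim <- simulate_melt_curve(synth_spec(53, "melt_curve", cv = 0))
  mirrored <- rev(sim$data$signal)
  f <- fit_boltzmann(sim$data$temperature, mirrored)
  expect_false(f$converged)
  expect_true("negative_slope_transition" %in% f$flags)
})

test_that("flat signal is flagged, not fitted", {
  f <- fit_boltzmann(seq(30, 70, 0.5), rep(42, 81))
  expect_false(f$converged)
})

test_that("Tm standard deviation over 100 noisy curves stays below 0.3 C", {
  tms <- vapply(1:100, function(seed) {
    sim <- simulate_melt_curve(synth_spec(40000 + seed, "melt_curve", cv = 0.02))
    fit_boltzmann(sim$data$temperature, sim$data$signal)$tm
  }, numeric(1))
  expect_lt(stats::sd(tms), 0.3)
  expect_equal(mean(tms), 52, tolerance = 0.01)
})

test_that("thermal shift calls binding per the printed threshold rules", {
  apo <- simulate_melt_curve(synth_spec(61, "melt_curve", tm = 52, cv = 0))$data
  holo <- simulate_melt_curve(synth_spec(62, "melt_curve", tm = 54, cv = 0))$data
  nc <- simulate_melt_curve(synth_spec(63, "melt_curve", tm = 51.6, cv = 0))$data
  ts_strict <- thermal_shift(apo, holo, threshold = 2, mode = ">")
  expect_equal(ts_strict$delta_tm, 2, tolerance = 1e-6)
  expect_false(ts_strict$significant_binding)  # strictly-greater DSF rule
  ts_naltsa <- thermal_shift(apo, holo, threshold = 2, mode = ">=")
  expect_true(ts_naltsa$significant_binding)   # cell-engagement convention
  ts_nc <- thermal_shift(apo, nc, threshold = 2, mode = ">=")
  expect_equal(ts_nc$delta_tm, -0.4, tolerance = 1e-6)
  expect_false(ts_nc$significant_binding)
  ts_id <- thermal_shift(apo, apo)
  expect_equal(ts_id$delta_tm, 0, tolerance = 1e-9)
})

test_that("noiseless SPR traces return the generating rates to machine precision", {
  sim <- simulate_spr_traces(synth_spec(71, "spr_traces", noise_sd = 0))
  f <- fit_spr_kinetic(sim$data)
  expect_true(f$converged)
  expect_equal(f$kon, 1.2e6, tolerance = 1e-4)
  expect_equal(f$koff, 0.1, tolerance = 1e-4)
  expect_equal(f$rmax, 30, tolerance = 1e-4)
  expect_equal(f$kd, 0.1 / 1.2e6, tolerance = 1e-4)
})

test_that("the dissociation segment alone yields the same koff as the global fit", {
  sim <- simulate_spr_traces(synth_spec(72, "spr_traces", noise_sd = 0))
  top <- sim$data[sim$data$concentration == max(sim$data$concentration) &
                    sim$data$time > 60, ]
  koff_ll <- spr_dissociation_koff(top$time, top$response)
  f <- fit_spr_kinetic(sim$data)
  expect_equal(koff_ll, f$koff, tolerance = 1e-3)
})

test_that("kinetic recovery holds within 1% over 20 seeded rate draws", {
  set.seed(77)
  for (i in 1:20) {
    kon <- 10^stats::runif(1, 4, 7)
    koff <- 10^stats::runif(1, -3, 0)
    kd <- koff / kon
    t_eq <- 2 / koff
    sim <- simulate_spr_traces(synth_spec(50000 + i, "spr_traces",
                                          noise_sd = 0, kon = kon, koff = koff,
                                          concentrations = kd * c(0.5, 1, 2, 4, 8),
                                          t_on = t_eq, t_off = t_eq,
                                          dt = t_eq / 120))
    f <- fit_spr_kinetic(sim$data, t_on_end = t_eq)
    expect_lt(abs(f$kon - kon) / kon, 0.01)
    expect_lt(abs(f$koff - koff) / koff, 0.01)
  }
})

test_that("steady-state affinity fits recover Kd and agree with kinetics", {
  kd <- 87e-9; rmax <- 30
  conc <- kd * c(0.125, 0.25, 0.5, 1, 2, 4, 8)
  req <- rmax * conc / (kd + conc)
  f <- fit_spr_steady_state(conc, req)
  expect_equal(f$kd, kd, tolerance = 1e-6)
  expect_equal(f$rmax, rmax, tolerance = 1e-6)
  # half-saturation identity
  expect_equal(rmax * kd / (kd + kd), rmax / 2)
  expect_error(fit_spr_steady_state(kd, rmax / 2), "distinct")
  # plateau responses of the kinetic model reproduce the kinetic Kd within 2%
  sim <- simulate_spr_traces(synth_spec(73, "spr_traces", noise_sd = 0,
                                        t_on = 300,
                                        concentrations = 8.33e-8 *
                                          c(0.25, 0.5, 1, 2, 4, 8)))
  plateau <- do.call(rbind, lapply(split(sim$data, sim$data$concentration),
                                   function(d) {
    ass <- d[d$time <= 300, ]
    data.frame(conc = d$concentration[1], req = max(ass$response))
  }))
  fs <- fit_spr_steady_state(plateau$conc, plateau$req)
  expect_equal(fs$kd, 0.1 / 1.2e6, tolerance = 0.02)
})

test_that("an uncurved concentration range triggers the ill-conditioning warning", {
  kd <- 1e-7; rmax <- 30
  conc <- kd * c(1e3, 2e3, 4e3, 8e3)   # all far above Kd: no curvature
  req <- rmax * conc / (kd + conc)
  expect_warning(fit_spr_steady_state(conc, req), "ill-conditioned|curvature")
})
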