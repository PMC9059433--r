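test_that("all-closed circuit at atmospheric source is a fixed point", {
  sc <- vent_scenario(
    source_pressure = 101.325, # kPa absolute = atmospheric, zero gauge drive
    insp_area = 0, n_cycles = 1, washout = 0, dt_out = 0.02
  )
  sim <- simulate_vcv(sc)
  expect_lt(max(abs(sim$waveform$p_tube_cmH2O)), 1e-9)
  expect_lt(max(abs(sim$waveform$p_lung_cmH2O)), 1e-9)
  expect_lt(max(abs(sim$waveform$v_lung_mL - 2000)), 1e-6)
})

test_that("rigid-chamber constant-flow fill matches the linear closed form", {
  sc <- vent_scenario(
    tidal_volume = 240, inspiratory_time = 0.6, plateau_time = 0,
    exhaust_time = 0.2, cycle_period = 0.8, insp_area = 0,
    source_pressure = 400, n_cycles = 1, washout = 0, dt_out = 0.005
  )
  sim <- simulate_vcv(sc)
  wf <- sim$waveform[sim$waveform$phase == "INSPIRATION", ]
  q <- target_flow(sc$vcv)
  rho <- reference_density(sc$gas)
  slope_pa <- sc$gas$R * sc$gas$theta * rho * q / sc$tube$volume
  expected <- convert_pressure(slope_pa * wf$time_s, "Pa", "cmH2O")
  expect_false(sim$flow_limited)
  expect_lt(max(abs(wf$p_tube_cmH2O - expected)) / max(expected), 1e-3)
})

test_that("the default breath delivers the set tidal volume within 1%", {
  sim <- simulate_vcv(fast_scenario())
  bm <- breath_metrics(sim)
  expect_true(all(abs(bm$delivered_mL - 500) / 500 < 0.01))
  # the set inspiratory flow is reached and not exceeded
  expect_equal(
    max(sim$waveform$flow_insp_L_min),
    convert_flow(target_flow(sim$scenario$vcv), "m3/s", "L/min"),
    tolerance = 1e-6
  )
})

test_that("mass is conserved across scenario families", {
  scs <- list(
    default = fast_scenario(),
    small_breath = fast_scenario(tidal_volume = 300),
    stiff_lung = fast_scenario(compliance = 0.02),
    rig_5_3 = make_preset("PB1", n_cycles = 1, washout = 0, dt_out = 0.02)
  )
  for (nm in names(scs)) {
    sim <- simulate_vcv(scs[[nm]])
    expect_lt(sim$mass$residual_pct, 0.5)
  }
})

test_that("quasi-static filling equilibrates the lung at the source pressure", {
  # wide-open inspiratory path, no exhaust: the lung must end at the
  # regulated source pressure, having taken up C * (p_source - p_atm)
  sc <- vent_scenario(
    tidal_volume = 1e6, inspiratory_time = 25, plateau_time = 0,
    exhaust_time = 0.5, cycle_period = 25.5, source_pressure = 120,
    supply_area = 30, insp_area = 60, exhaust_area = 0,
    n_cycles = 1, washout = 0, dt_out = 0.05
  )
  sim <- simulate_vcv(sc)
  insp <- sim$waveform[sim$waveform$phase == "INSPIRATION", ]
  p_src_gauge <- convert_pressure(120e3 - sc$gas$p_atm, "Pa", "cmH2O")
  expect_equal(insp$p_lung_cmH2O[nrow(insp)], p_src_gauge, tolerance = 0.01)
  dv_expected <- sc$lung$compliance * (120e3 - sc$gas$p_atm) # m^3
  dv_sim <- (insp$v_lung_mL[nrow(insp)] - 2000) * 1e-6
  expect_equal(dv_sim, dv_expected, tolerance = 0.01)
})

test_that("static compliance is recovered from plateau minus PEEP", {
  for (cl in c(0.07, 0.10)) {
    sim <- simulate_vcv(recovery_scenario(cl, 400))
    m <- steady_state_metrics(sim)
    expect_true(m$plateau_detected)
    c_est <- m$delivered_mL / (m$plateau_cmH2O - m$peep_cmH2O) / 1000
    expect_equal(c_est, cl, tolerance = 0.05)
  }
})

test_that("expiratory flow is set by tube pressure, not the source", {
  # tidal-volume cutoff makes the pre-expiration state independent of the
  # source; with the tube blown down from ~5 atm the exhaust starts choked,
  # so peak expiratory flow must be identical when the source is doubled
  base <- list(
    tidal_volume = 2000, inspiratory_time = 1.2, plateau_time = 0.3,
    exhaust_time = 1.6, cycle_period = 4, insp_area = 0,
    n_cycles = 1, washout = 0, dt_out = 0.005
  )
  sim1 <- simulate_vcv(do.call(vent_scenario, c(base, source_pressure = 700)))
  sim2 <- simulate_vcv(do.call(vent_scenario, c(base, source_pressure = 1400)))
  # choked at expiration onset: tube absolute pressure ~5x atmospheric
  p_start <- max(sim1$waveform$p_tube_cmH2O)
  ratio <- 101325 / (101325 + convert_pressure(p_start, "cmH2O", "Pa"))
  expect_lt(ratio, critical_pressure_ratio(sim1$scenario$gas))
  m1 <- steady_state_metrics(sim1, washout = 0)
  m2 <- steady_state_metrics(sim2, washout = 0)
  expect_equal(m1$peak_exp_flow_L_min, m2$peak_exp_flow_L_min, tolerance = 1e-6)
})

test_that("halving integrator tolerances leaves peak pressure unchanged", {
  m1 <- steady_state_metrics(simulate_vcv(fast_scenario()))
  m2 <- steady_state_metrics(simulate_vcv(fast_scenario(rtol = 5e-9, atol = 5e-11)))
  expect_lt(abs(m1$peak_cmH2O - m2$peak_cmH2O) / m2$peak_cmH2O, 1e-3)
})

test_that("identical configurations give bit-identical waveform CSVs", {
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_waveform_csv(simulate_vcv(fast_scenario()), f1)
  write_waveform_csv(simulate_vcv(fast_scenario()), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  # header is the documented fixed column set
  expect_identical(
    readLines(f1, n = 1),
    "time_s,phase,p_tube_cmH2O,p_lung_cmH2O,flow_insp_L_min,flow_exh_L_min,v_lung_mL"
  )
})

test_that("invalid scenario settings are rejected at construction", {
  expect_error(vent_scenario(tidal_volume = -1))
  expect_error(vent_scenario(exhaust_time = 0))
  expect_error(vent_scenario(plateau_time = 2, inspiratory_time = 1.2))
  expect_error(vent_scenario(n_cycles = 2, washout = 2))
  expect_error(vent_scenario(family = "rig"), "timer_delay")
})

test_that("plateau detector finds flat segments and rejects ramps", {
  tt <- seq(0, 2, by = 0.01)
  flat <- ifelse(tt < 0.5, 20 * tt, 10) # ramp then exactly constant
  det <- detect_plateau(tt, flat, eps = 0.5, tau = 0.2)
  expect_equal(nrow(det), 1)
  expect_equal(det$pressure, 10)
  expect_gte(det$start, 0.49)

  ramp <- 2 * tt # slope 2 > eps
  expect_equal(nrow(detect_plateau(tt, ramp, eps = 0.5, tau = 0.2)), 0)

  # constant segment exactly 2*tau long is detected with its value
  seg <- c(seq(0, 1, by = 0.01), seq(1.01, 1.4, by = 0.01) * 0 + 5)
  ttt <- seq_along(seg) * 0.01
  det2 <- detect_plateau(ttt, seg, eps = 0.5, tau = 0.2)
  expect_equal(nrow(det2), 1)
  expect_equal(det2$pressure, 5)
})

test_that("plateau presence is monotone in exhaust time, appearing at long T_e", {
  # no end-inspiratory pause, so the only flat region is the settled
  # end-expiratory pressure; the transition T_e sits beyond the clinical
  # 1-1.8 s grid for the desk-scale mechanics
  base <- vent_scenario(
    plateau_time = 0, inspiratory_time = 1.2,
    cycle_period = 12, n_cycles = 2, washout = 1, dt_out = 0.01
  )
  sw <- run_sweep(base, "exhaust_time", c(1.0, 2.0, 4.0, 6.0, 8.0))
  expect_true(all(sw$ok))
  det <- sw$plateau_detected
  expect_true(all(diff(as.integer(det)) >= 0))
  expect_false(det[1]) # short exhaust: no platform
  expect_true(det[length(det)]) # long exhaust: platform present
})

test_that("breath metrics handle synthetic waveforms and incomplete cycles", {
  # constant-pressure synthetic waveform: peak = plateau = PEEP
  tt <- seq(0, 4, by = 0.01)
  s <- vcv_settings(500e-6, 1.2, 0.3, 1.6, 4)
  wf <- tibble::tibble(
    time_s = tt, cycle = 1L, phase = phase_at(pmin(tt, 4 - 1e-9), s),
    p_tube_cmH2O = 7, p_lung_cmH2O = 7,
    flow_insp_L_min = 0, flow_exh_L_min = 0, v_lung_mL = 2000
  )
  bm <- breath_metrics(wf)
  expect_equal(bm$peak_cmH2O, 7)
  expect_equal(bm$plateau_cmH2O, 7)
  expect_equal(bm$peep_cmH2O, 7)

  # triangular inspiratory flow filling the 0.9 s delivery window
  tri <- pmax(0, 1 - abs(tt - 0.45) / 0.45) * 30
  tri[phase_at(pmin(tt, 4 - 1e-9), s) != "INSPIRATION"] <- 0
  wf$flow_insp_L_min <- tri
  bm2 <- breath_metrics(wf)
  # area = 0.5 * base(0.9 s) * height(30 L/min) = 225 mL
  expect_equal(bm2$delivered_mL, 225, tolerance = 1e-3)

  # no expiration simulated at all: no complete breath
  wf_insp <- wf[wf$phase %in% c("INSPIRATION", "PLATEAU"), ]
  expect_error(breath_metrics(wf_insp), "no complete breath")
})
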