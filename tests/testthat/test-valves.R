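gas_air <- gas_properties()

test_that("critical pressure ratio matches the closed form", {
  expect_equal(round(critical_pressure_ratio(gas_air), 3), 0.528)
  expect_equal(
    critical_pressure_ratio(gas_properties(heat_capacity_ratio = 2)),
    4 / 9
  )
  # k -> 1+ limit tends to exp(-1/2); frozen from high-precision evaluation
  b_near1 <- critical_pressure_ratio(gas_properties(heat_capacity_ratio = 1 + 1e-6))
  expect_equal(b_near1, 0.6065304322637292, tolerance = 1e-9)
  expect_equal(b_near1, exp(-0.5), tolerance = 1e-6)
  expect_error(
    critical_pressure_ratio(list(k = 0.9)),
    "k must exceed 1"
  )
})

test_that("orifice flow reproduces frozen high-precision reference values", {
  # choked: A = 6 mm^2, 200 kPa over atmosphere (ratio 0.507 < 0.528)
  expect_equal(
    orifice_mass_flow(6e-6, 200e3, 101325, gas_air),
    2.832551409698204e-3,
    tolerance = 1e-12
  )
  # subsonic branch at ratio 0.8, same area and upstream pressure
  expect_equal(
    orifice_mass_flow(6e-6, 200e3, 0.8 * 200e3, gas_air),
    2.319305102000823e-3,
    tolerance = 1e-12
  )
})

test_that("orifice flow degenerate cases and input validation", {
  expect_equal(orifice_mass_flow(6e-6, 1.5e5, 1.5e5, gas_air), 0)
  expect_equal(orifice_mass_flow(0, 2e5, 1e5, gas_air), 0)
  # choked flow ignores downstream pressure
  f1 <- orifice_mass_flow(6e-6, 2e5, 0.3 * 2e5, gas_air)
  f2 <- orifice_mass_flow(6e-6, 2e5, 0.5 * 2e5, gas_air)
  expect_identical(f1, f2)
  expect_error(orifice_mass_flow(1e-6, -1, 1e5, gas_air), "positive")
  expect_error(orifice_mass_flow(1e-6, 1e5, 0, gas_air), "positive")
  expect_error(orifice_mass_flow(-1e-6, 1e5, 1e5, gas_air))
})

test_that("orifice flow properties hold over randomized gases and pressures", {
  set.seed(42)
  for (i in 1:40) {
    k <- stats::runif(1, 1.05, 2)
    gas <- gas_properties(heat_capacity_ratio = k)
    b <- critical_pressure_ratio(gas)
    p_up <- stats::runif(1, 1.2e5, 6e5)
    a <- stats::runif(1, 1e-6, 2e-5)

    # continuity at the critical ratio
    f_choked <- orifice_mass_flow(a, p_up, p_up * b, gas)
    f_sub <- orifice_mass_flow(a, p_up, p_up * (b + 1e-13), gas)
    expect_lt(abs(f_sub - f_choked) / f_choked, 1e-9)

    # strict monotone decrease of the subsonic branch toward equalization
    r <- sort(stats::runif(8, b + 1e-3, 1 - 1e-6))
    f <- orifice_mass_flow(a, p_up, p_up * r, gas)
    expect_true(all(diff(f) < 0))

    # linearity in area
    expect_equal(
      orifice_mass_flow(2 * a, p_up, p_up * r[1], gas),
      2 * orifice_mass_flow(a, p_up, p_up * r[1], gas)
    )

    # choked plateau: zero sensitivity to downstream pressure below b
    r0 <- stats::runif(1, 0.05, b - 0.05)
    h <- 1e-3
    df <- orifice_mass_flow(a, p_up, p_up * (r0 + h), gas) -
      orifice_mass_flow(a, p_up, p_up * (r0 - h), gas)
    expect_identical(df, 0)
  }
})

test_that("valve connectivity truth table matches the circuit narratives", {
  # hand-written oracle from the 5/2 / 5/3 / 3/2 descriptions:
  # 5/2 home exhausts the patient line, actuated supplies it;
  # 5/3 rests supplying (spring-return, energize to exhaust), mid closed;
  # 3/2 rests exhausting, energize to supply.
  oracle <- list(
    list("5/2", "HOME", c(supply = 0, exhaust = 1)),
    list("5/2", "ACTUATED", c(supply = 1, exhaust = 0)),
    list("5/3", "HOME", c(supply = 1, exhaust = 0)),
    list("5/3", "ACTUATED", c(supply = 0, exhaust = 1)),
    list("5/3", "MID", c(supply = 0, exhaust = 0)),
    list("3/2", "HOME", c(supply = 0, exhaust = 1)),
    list("3/2", "ACTUATED", c(supply = 1, exhaust = 0))
  )
  for (row in oracle) {
    expect_identical(valve_connectivity(row[[1]], row[[2]]), row[[3]])
  }
  expect_error(valve_connectivity("5/2", "MID"), "not valid")
  expect_error(valve_connectivity("4/2", "HOME"), "unknown valve archetype")
  # PA/PB/PC aliases resolve
  expect_identical(
    valve_connectivity("PB", "MID"),
    valve_connectivity("5/3", "MID")
  )
})

test_that("5/2 bistable memory: sole coil drives, both/neither retain", {
  spec <- valve_spec("5/2")
  st <- valve_state(spec, "HOME")
  # both coils energized act with the same force: position retained
  expect_identical(valve_state_update(spec, st, TRUE, TRUE)$position, "HOME")
  expect_identical(valve_state_update(spec, st, FALSE, FALSE)$position, "HOME")
  st2 <- valve_state_update(spec, st, TRUE, FALSE)
  expect_identical(st2$position, "ACTUATED")
  # memory: de-energizing does not spring back
  expect_identical(valve_state_update(spec, st2, FALSE, FALSE)$position, "ACTUATED")
  expect_identical(valve_state_update(spec, st2, FALSE, TRUE)$position, "HOME")
})

test_that("spring-return archetypes follow the coil, exhaustively", {
  for (arch in c("5/3", "3/2")) {
    spec <- valve_spec(arch)
    for (pos in c("HOME", "ACTUATED")) {
      st <- valve_state(spec, pos)
      expect_identical(valve_state_update(spec, st, TRUE)$position, "ACTUATED")
      expect_identical(valve_state_update(spec, st, FALSE)$position, "HOME")
    }
  }
  # connectivity is recomputed on update
  spec <- valve_spec("3/2")
  st <- valve_state_update(spec, valve_state(spec, "HOME"), FALSE)
  expect_identical(st$connectivity, c(supply = 0, exhaust = 1))
})

test_that("switching delay defers the position change", {
  spec <- valve_spec("5/3", switching_delay = 0.5)
  st <- valve_state(spec, "HOME")
  st <- valve_state_update(spec, st, TRUE, now = 0) # schedules the switch
  expect_identical(st$position, "HOME")
  st <- valve_state_update(spec, st, TRUE, now = 0.4)
  expect_identical(st$position, "HOME")
  st <- valve_state_update(spec, st, TRUE, now = 0.5)
  expect_identical(st$position, "ACTUATED")
})

test_that("on-delay timer asserts after a sustained input and resets on fall", {
  tm <- on_delay_timer(10)
  tm <- on_delay_timer_update(tm, TRUE, 0)
  expect_false(tm$output)
  tm <- on_delay_timer_update(tm, TRUE, 9.99)
  expect_false(tm$output)
  tm <- on_delay_timer_update(tm, TRUE, 10)
  expect_true(tm$output)

  tm <- on_delay_timer(10)
  for (t in seq(0, 20, by = 1)) tm <- on_delay_timer_update(tm, FALSE, t)
  expect_false(tm$output)

  tm <- on_delay_timer(10)
  tm <- on_delay_timer_update(tm, TRUE, 0)
  tm <- on_delay_timer_update(tm, TRUE, 4)
  tm <- on_delay_timer_update(tm, FALSE, 4.5) # falling edge resets
  tm <- on_delay_timer_update(tm, TRUE, 5)
  tm <- on_delay_timer_update(tm, TRUE, 14.9)
  expect_false(tm$output)
  tm <- on_delay_timer_update(tm, TRUE, 15)
  expect_true(tm$output)

  expect_error(on_delay_timer_update(tm, TRUE, 1), "backwards")
})
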