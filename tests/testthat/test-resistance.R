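test_that("transpiration rate is mass loss over area and time", {
  expect_equal(transpiration_rate(40, 200, 2), 0.1)
  expect_equal(transpiration_rate(0, 200, 2), 0)
  expect_equal(transpiration_rate(31.0, 199.18, 2), 0.0778, tolerance = 1e-3)
  expect_warning(transpiration_rate(-5, 200, 2), "mass gain")
  expect_error(transpiration_rate(40, 0, 2), "surface area")
  expect_error(transpiration_rate(40, 200, 0), "time interval")
})

test_that("total resistance carries the unit factor and inverts algebraically", {
  # unit-factor check: E = 3.6 with unit driving force gives 1 s/cm
  expect_equal(total_resistance(3.6, 9.7, 8.7), 1)
  expect_identical(FLUX_UNIT_FACTOR, 3.6)
  expect_equal(total_resistance(0.0778, 17.26, 8.70), 396.09, tolerance = 1e-3)

  # algebraic round trip for random resistances and driving forces
  set.seed(11)
  for (i in 1:50) {
    r <- runif(1, 0.5, 2000)
    dx <- runif(1, 0.1, 15)
    x_a <- runif(1, 0, 10)
    E <- FLUX_UNIT_FACTOR * dx / r
    expect_equal(total_resistance(E, x_a + dx, x_a), r, tolerance = 1e-12)
  }
  expect_error(total_resistance(0, 17, 8), "no transpiration")
  expect_error(total_resistance(0.1, 8, 8.5), "condensation")
})

test_that("resistance partitioning by subtraction rejects negative components", {
  expect_equal(tissue_resistance(396, 4.0), 392)
  expect_identical(tissue_resistance(396, 0), 396)
  expect_error(tissue_resistance(3.0, 4.0), "exceeds total")

  expect_equal(boundary_layer_by_difference(396, 392), 4.0)
  expect_identical(boundary_layer_by_difference(392, 392), 0)
  expect_error(boundary_layer_by_difference(392, 396), "inconsistency")

  expect_equal(bulk_boundary_layer(413, 363), 50)
  expect_identical(bulk_boundary_layer(363, 363), 0)
  expect_error(bulk_boundary_layer(360, 363), "inconsistency")
})

test_that("surface conditions interpolate between ambient and intercellular air", {
  amb <- air_state(20, 50, 101325)
  # no boundary layer: the surface sits at ambient conditions
  s0 <- surface_conditions(0.0778, 0, amb$x_vol, 20)
  expect_identical(s0$x_pS, amb$x_vol)
  expect_equal(s0$rh_surface_pct, 50, tolerance = 1e-6)

  # measured apple boundary layer of 4.8 s/cm lifts the surface humidity
  s <- surface_conditions(0.0778, 4.8, 8.70, 20, 101325)
  expect_equal(s$x_pS, 8.70 + 0.0778 * 4.8 / 3.6, tolerance = 1e-12)
  expect_equal(s$rh_surface_pct, 50.60, tolerance = 1e-3)

  # series limit: all resistance in the boundary layer puts the surface at
  # the intercellular state (saturated air for aw = 1)
  x_p <- intercellular_water_content(20, 1.0)
  r_tot <- 400
  E <- FLUX_UNIT_FACTOR * (x_p - amb$x_vol) / r_tot
  s1 <- surface_conditions(E, r_tot, amb$x_vol, 20)
  expect_equal(s1$x_pS, x_p, tolerance = 1e-12)
  expect_equal(s1$rh_surface_pct, 100, tolerance = 1e-6)

  expect_error(surface_conditions(5, 100, 15, 20), "supersaturated")
  expect_error(surface_conditions(-1, 4, 8, 20), "non-negative")
})

test_that("flux continuity holds for any partition of the total resistance", {
  set.seed(23)
  for (i in 1:200) {
    t_air <- runif(1, 0, 30)
    rh <- runif(1, 20, 90)
    aw <- runif(1, 0.95, 1)
    x_a <- air_state(t_air, rh)$x_vol
    x_p <- intercellular_water_content(t_air, aw)
    r_tot <- runif(1, 5, 1500)
    f <- runif(1, 0.01, 0.99)   # arbitrary split into tissue + boundary layer
    r_B <- f * r_tot
    r_T <- r_tot - r_B
    E <- FLUX_UNIT_FACTOR * (x_p - x_a) / r_tot
    x_pS <- surface_conditions(E, r_B, x_a, t_air)$x_pS
    expect_true(x_a <= x_pS && x_pS <= x_p)
    expect_equal((x_p - x_pS) / r_T, E / FLUX_UNIT_FACTOR, tolerance = 1e-9)
    expect_equal((x_pS - x_a) / r_B, E / FLUX_UNIT_FACTOR, tolerance = 1e-9)
  }
})

test_that("Arrhenius adjustment reproduces its anchors and estimates Ea", {
  expect_identical(arrhenius_adjust(391, 20, 20, 25000), 391)
  # two-point activation energy from apple tissue resistance at 20 and 1 degC
  Ea <- estimate_activation_energy(c(391, 750), c(20, 1))
  expect_equal(Ea, 22906.54, tolerance = 1e-4)
  expect_equal(arrhenius_adjust(391, 20, 1, Ea), 750, tolerance = 1e-9)
  expect_equal(arrhenius_adjust(750, 1, 20, Ea), 391, tolerance = 1e-9)
  # resistance increases as temperature falls
  expect_gt(arrhenius_adjust(391, 20, 5, 23000), 391)

  # collinear synthetic points recover the generating Ea exactly
  Ea_true <- 30000
  temps <- c(0, 10, 25)
  r <- arrhenius_adjust(100, 20, temps, Ea_true)
  expect_equal(estimate_activation_energy(r, temps), Ea_true,
               tolerance = 1e-9)
  # identical resistances at two temperatures imply zero activation energy
  expect_equal(estimate_activation_energy(c(55, 55), c(5, 25)), 0,
               tolerance = 1e-9)
  expect_error(estimate_activation_energy(391, 20), "two distinct")
  expect_error(estimate_activation_energy(c(391, 400), c(20, 20)),
               "two distinct")
})

test_that("run_protocol partitions according to the selected protocol", {
  apple <- make_apple()
  spec <- simulation_spec(apple, r_T_s_cm = 391, r_B_s_cm = 4.8,
                          balance_resolution_mg = 0)
  sim <- forward_simulate(spec)

  free <- suppressMessages(run_protocol(
    sim$weighing, sim$climate, apple,
    protocol_config("free", rb_default_s_cm = 4.8)))
  expect_equal(free$r_T, 391, tolerance = 1e-9)
  expect_equal(free$r_tot, free$r_T + free$r_B, tolerance = 1e-12)
  expect_equal(free$E * free$r_tot, FLUX_UNIT_FACTOR * free$delta_x,
               tolerance = 1e-12)
  expect_true(free$x_a <= free$x_pS && free$x_pS <= free$x_p)

  # apples fall back to the 4.0 s/cm free-convection default with a message
  expect_message(
    d <- run_protocol(sim$weighing, sim$climate, apple,
                      protocol_config("free")),
    "4.0 s/cm")
  expect_equal(d$r_B, 4.0)

  # non-apples have no default boundary layer
  straw <- produce_item("s1", "strawberry", 15)
  expect_error(
    suppressMessages(run_protocol(sim$weighing, sim$climate, straw,
                                  protocol_config("free"))),
    "no free-convection boundary-layer default")

  # forced and wetted protocols assign the whole total to the tissue
  spec0 <- simulation_spec(apple, r_T_s_cm = 391, r_B_s_cm = 0,
                           balance_resolution_mg = 0)
  sim0 <- forward_simulate(spec0)
  forced <- suppressMessages(run_protocol(sim0$weighing, sim0$climate, apple,
                                          protocol_config("forced")))
  expect_equal(forced$r_T, 391, tolerance = 1e-9)
  expect_identical(forced$r_B, 0)

  # bulk needs the individually measured tissue resistance
  bspec <- simulation_spec(apple, r_T_s_cm = 363, r_B_s_cm = 50.4,
                           duration_h = 48, balance_resolution_mg = 0)
  bsim <- forward_simulate(bspec)
  expect_error(
    suppressMessages(run_protocol(bsim$weighing, bsim$climate, apple,
                                  protocol_config("bulk"))),
    "tissue resistance")
  bulk <- suppressMessages(run_protocol(
    bsim$weighing, bsim$climate, apple,
    protocol_config("bulk", r_tissue_s_cm = 363)))
  expect_equal(bulk$r_B, 50.4, tolerance = 1e-9)
})

test_that("degenerate weighing series are diagnosed, not silently analysed", {
  apple <- make_apple()
  clim <- make_constant_climate()
  ts <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + c(0, 12, 24) * 3600
  flat <- weighing_series("a", ts, c(131, 131, 131))
  expect_error(
    suppressMessages(run_protocol(flat, clim, apple,
                                  protocol_config("free", rb_default_s_cm = 4))),
    "no transpiration")
  gaining <- weighing_series("a", ts, c(131, 131.2, 131.4))
  expect_warning(
    try(suppressMessages(run_protocol(
      gaining, clim, apple, protocol_config("free", rb_default_s_cm = 4))),
      silent = TRUE),
    "mass gain")
  # too-short series triggers a duration warning
  short <- weighing_series("a", ts[1:2] , c(131, 130.9))
  expect_warning(
    suppressMessages(run_protocol(
      short, clim, apple, protocol_config("free", rb_default_s_cm = 4))),
    "below the recommended minimum")
})
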