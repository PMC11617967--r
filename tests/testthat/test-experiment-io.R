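test_that("weighing series enforce ordering, count and positive net mass", {
  ts <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC") + c(0, 3600, 7200)
  s <- weighing_series("a", ts, c(131, 130.99, 130.98))
  expect_s3_class(s, "weighing_series")
  expect_equal(nrow(s$records), 3)
  expect_error(weighing_series("a", ts[c(1, 3, 2)], c(131, 130.99, 130.98)),
               "strictly increasing")
  expect_error(weighing_series("a", ts[1], 131), "at least two")
  expect_error(weighing_series("a", ts, c(131, NA, 130.98)), "missing")
  # bulk tare is subtracted and must leave a positive net mass
  b <- weighing_series("box", ts, c(20500, 20490, 20480), is_bulk = TRUE,
                       container_tare_g = 500)
  expect_equal(b$records$mass_g, c(20000, 19990, 19980))
  expect_error(weighing_series("box", ts, c(400, 390, 380),
                               container_tare_g = 500), "non-positive mass")
})

test_that("weighing CSVs round-trip bit-identically, including quantized masses", {
  apple <- make_apple()
  spec <- simulation_spec(apple, r_T_s_cm = 391, r_B_s_cm = 4.8, seed = 7,
                          drift_sd_temp_c = 0.3, drift_sd_rh_pct = 1.5)
  sim <- forward_simulate(spec)
  wpath <- tempfile(fileext = ".csv")
  write_weighing_csv(sim$weighing, wpath)
  back <- read_weighing_csv(wpath)
  expect_named(back, "apple-1")
  expect_identical(back[[1]]$records$mass_g, sim$weighing$records$mass_g)
  expect_identical(as.numeric(back[[1]]$records$timestamp),
                   as.numeric(sim$weighing$records$timestamp))

  cpath <- tempfile(fileext = ".csv")
  write_climate_csv(sim$climate, cpath)
  cback <- read_climate_csv(cpath)
  expect_identical(cback$records$temperature_c, sim$climate$records$temperature_c)
  expect_identical(cback$records$relative_humidity_pct,
                   sim$climate$records$relative_humidity_pct)
  expect_identical(cback$records$pressure_pa, sim$climate$records$pressure_pa)
})

test_that("malformed weighing and climate files are rejected with diagnostics", {
  p <- tempfile(fileext = ".csv")

  writeLines(c("item_id,when,mass_g", "a,2024-03-01T00:00:00,131"), p)
  expect_error(read_weighing_csv(p), "missing required column")

  writeLines(c("item_id,timestamp,mass_g",
               "a,2024-03-01T02:00:00,130.9",
               "a,2024-03-01T00:00:00,131"), p)
  expect_error(read_weighing_csv(p), "strictly increasing")

  writeLines(c("item_id,timestamp,mass_g",
               "a,2024-03-01T00:00:00,131",
               "a,2024-03-01T00:00:00,131"), p)
  expect_error(read_weighing_csv(p), "duplicate")

  writeLines(c("item_id,timestamp,mass_g",
               "a,2024-03-01T00:00:00,131",
               "a,not-a-time,130.9"), p)
  expect_error(read_weighing_csv(p), "unparseable timestamp")

  writeLines(c("item_id,timestamp,mass_g",
               "a,2024-03-01T00:00:00,131",
               "a,2024-03-01T02:00:00,-1"), p)
  expect_error(read_weighing_csv(p), "mass")

  writeLines(c("timestamp,temp_c,rh_pct",
               "2024-03-01T00:00:00,20,50",
               "2024-03-01T01:00:00,20,140"), p)
  expect_error(read_climate_csv(p), "\\[0, 100\\]")

  expect_error(read_weighing_csv("no/such/file.csv"), "not found")

  # a minimal two-row file parses into a series of length two
  writeLines(c("item_id,timestamp,mass_g",
               "a,2024-03-01T00:00:00,131",
               "a,2024-03-02T00:00:00,130.6"), p)
  s <- read_weighing_csv(p)
  expect_equal(nrow(s$a$records), 2)
})

test_that("mean climate is a time-weighted mean of the logged signal", {
  start <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  const <- make_constant_climate(20, 50, hours = 24)
  m <- mean_climate(const, start, start + 24 * 3600)
  expect_equal(m$temperature_c, 20)
  expect_equal(m$relative_humidity_pct, 50)
  expect_equal(m$pressure_pa, 101325)

  # two equal-duration halves at 19 and 21 degC average to 20
  ts <- start + c(0, 6, 6.0001, 12) * 3600
  halves <- climate_log(ts, c(19, 19, 21, 21), rep(50, 4))
  m2 <- mean_climate(halves, start, start + 12 * 3600)
  expect_equal(m2$temperature_c, 20, tolerance = 1e-4)
  expect_true(is.na(m2$pressure_pa))

  # irregular sampling against a brute-force dense time integration
  set.seed(5)
  t_irr <- start + sort(c(0, runif(40, 0, 24), 24)) * 3600
  temp <- 20 + cumsum(rnorm(length(t_irr), 0, 0.2))
  irr <- climate_log(t_irr, temp, rep(60, length(t_irr)), 101000)
  a <- start + 3 * 3600; b <- start + 21 * 3600
  knots <- as.numeric(t_irr)
  dense <- sort(unique(c(seq(as.numeric(a), as.numeric(b), length.out = 20001),
                         knots[knots > as.numeric(a) & knots < as.numeric(b)])))
  yy <- approx(knots, temp, xout = dense)$y
  oracle <- sum(diff(dense) * (head(yy, -1) + tail(yy, -1)) / 2) /
    (as.numeric(b) - as.numeric(a))
  expect_equal(mean_climate(irr, a, b)$temperature_c, oracle,
               tolerance = 1e-9)

  # windows outside the log raise a coverage error
  expect_error(mean_climate(const, start - 3600, start + 3600),
               "does not cover")
  expect_error(mean_climate(const, start + 3600, start), "precede")
})
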