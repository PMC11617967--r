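# Independent oracle for the psychrometric chain: literal re-evaluation of
# the printed relations, deliberately not routed through package functions.
oracle_x_vol <- function(temp_c, rh_pct, pbar = 101325) {
  psa <- exp((6.4142801 + 0.0996709 * temp_c) / (1 + 0.004197225 * temp_c))
  pda <- psa * rh_pct / 100
  xa <- (287.058 / 461.52) * pda / (pbar - pda)
  rho <- (1 + xa) * pbar / ((287.058 + 461.52 * xa) * (273.15 + temp_c))
  xa * rho * 1000
}

make_apple <- function(mass_g = 131, ...) {
  produce_item("apple-1", "apple", mass_g = mass_g, ...)
}

make_constant_climate <- function(temp_c = 20, rh_pct = 50, pbar = 101325,
                                  hours = 24, step_min = 60,
                                  start = as.POSIXct("2024-03-01 00:00:00",
                                                     tz = "UTC")) {
  ts <- start + seq(0, hours * 3600, by = step_min * 60)
  climate_log(ts, rep(temp_c, length(ts)), rep(rh_pct, length(ts)), pbar)
}
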