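#' Specification of a forward transpiration simulation
#'
#' Defines the produce item, the true tissue and boundary-layer resistances,
#' the nominal climate with optional slow first-order autoregressive drift,
#' the weighing schedule and the balance resolution for one synthetic
#' experiment.
#'
#' @param item A [produce_item()].
#' @param r_T_s_cm,r_B_s_cm True tissue and boundary-layer resistances in
#'   s cm^-1 (non-negative, positive sum).
#' @param temp_c,rh_pct,pressure_pa Nominal climate.
#' @param duration_h Experiment duration in h.
#' @param weighing_interval_h Interval between weighings in h; must be a
#'   whole number of minutes and shorter than the duration.
#' @param balance_resolution_mg Balance quantisation step in mg (default
#'   0.1, the resolution of a precision balance; 0 disables quantisation).
#' @param drift_sd_temp_c,drift_sd_rh_pct Stationary standard deviations of
#'   the AR(1) climate drift (default 0: drift off).
#' @param drift_ar1 AR(1) coefficient of the minute-scale drift, in [0, 1).
#' @param climate_interval_min Cadence of the emitted climate log in
#'   minutes.
#' @param seed Random seed for the climate drift; `NULL` leaves the RNG
#'   untouched.
#' @param start_time POSIXct start of the experiment.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(item, r_T_s_cm, r_B_s_cm,
                            temp_c = 20, rh_pct = 50,
                            pressure_pa = .DEFAULT_PRESSURE_PA,
                            duration_h = 24, weighing_interval_h = 2,
                            balance_resolution_mg = 0.1,
                            drift_sd_temp_c = 0, drift_sd_rh_pct = 0,
                            drift_ar1 = 0.98, climate_interval_min = 1,
                            seed = NULL,
                            start_time = as.POSIXct("2024-03-01 00:00:00",
                                                    tz = "UTC")) {
  stopifnot(inherits(item, "produce_item"))
  if (r_T_s_cm < 0 || r_B_s_cm < 0) {
    stop("resistances must be non-negative", call. = FALSE)
  }
  if (r_T_s_cm + r_B_s_cm <= 0) {
    stop("total resistance must be positive", call. = FALSE)
  }
  if (rh_pct < 0 || rh_pct > 100) {
    stop("nominal relative humidity must lie in [0, 100] % (supersaturated otherwise)",
         call. = FALSE)
  }
  if (weighing_interval_h >= duration_h) {
    stop("weighing interval must be shorter than the duration", call. = FALSE)
  }
  if (abs(weighing_interval_h * 60 - round(weighing_interval_h * 60)) > 1e-9) {
    stop("weighing interval must be a whole number of minutes", call. = FALSE)
  }
  if (drift_ar1 < 0 || drift_ar1 >= 1) {
    stop("AR(1) coefficient must lie in [0, 1)", call. = FALSE)
  }
  if (balance_resolution_mg < 0) {
    stop("balance resolution must be non-negative", call. = FALSE)
  }
  structure(
    list(item = item, r_T_s_cm = r_T_s_cm, r_B_s_cm = r_B_s_cm,
         temp_c = temp_c, rh_pct = rh_pct, pressure_pa = pressure_pa,
         duration_h = duration_h, weighing_interval_h = weighing_interval_h,
         balance_resolution_mg = balance_resolution_mg,
         drift_sd_temp_c = drift_sd_temp_c, drift_sd_rh_pct = drift_sd_rh_pct,
         drift_ar1 = drift_ar1, climate_interval_min = climate_interval_min,
         seed = seed, start_time = start_time),
    class = "simulation_spec"
  )
}

# stationary AR(1) noise of length n with stationary sd `sd`
.ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  z <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in seq_len(n - 1)) e[i + 1] <- phi * e[i] + z[i]
  e
}

#' Forward-simulate a weighing experiment
#'
#' Integrates the diffusion model forward in time: at each one-minute
#' internal step the ambient vapour concentration follows from the (possibly
#' drifting) climate, the transpiration rate is
#' `E = FLUX_UNIT_FACTOR * (x_p - x_a) / (r_T + r_B)` and the mass decreases
#' by `E * A * dt`. The dynamics are quasi-static, so fixed-step explicit
#' stepping at one-minute resolution is adequate; the surface area is held
#' at its initial value (protocol losses are well under 1 % of mass). The
#' mass trajectory is sampled at the weighing interval and quantised to the
#' balance resolution; the climate log is emitted at its own cadence.
#'
#' The produce temperature is the item's measured value when present,
#' otherwise the nominal air temperature (held fixed under drift, standing
#' in for the produce's thermal inertia).
#'
#' @param spec A [simulation_spec()].
#' @return A list with `weighing` (a [weighing_series()]), `climate` (a
#'   [climate_log()]) and `truth` (the injected resistances and the exact
#'   unquantised final mass).
#' @export
forward_simulate <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n_min <- round(spec$duration_h * 60)
  t_min <- 0:n_min

  T_t <- spec$temp_c +
    .ar1_noise(n_min + 1, spec$drift_sd_temp_c, spec$drift_ar1)
  rh_t <- pmin(pmax(
    spec$rh_pct + .ar1_noise(n_min + 1, spec$drift_sd_rh_pct, spec$drift_ar1),
    0), 100)

  Tp <- spec$item$produce_temperature_c
  if (is.null(Tp)) Tp <- spec$temp_c
  x_p <- intercellular_water_content(Tp, spec$item$water_activity,
                                     spec$pressure_pa)
  x_a_t <- .x_vol_chain(T_t, rh_t, spec$pressure_pa)
  E_t <- FLUX_UNIT_FACTOR * (x_p - x_a_t) / (spec$r_T_s_cm + spec$r_B_s_cm)

  A <- spec$item$area_cm2
  # left-endpoint explicit step, one minute: dm [g] = E [mg/cm2/h] * A / 60 / 1000
  dm_g <- E_t[seq_len(n_min)] * A / 60 / 1000
  mass_g <- spec$item$mass_g - c(0, cumsum(dm_g))

  w_step <- round(spec$weighing_interval_h * 60)
  w_idx <- seq(1, n_min + 1, by = w_step)
  if (w_idx[length(w_idx)] != n_min + 1) w_idx <- c(w_idx, n_min + 1)
  w_mass <- mass_g[w_idx]
  if (spec$balance_resolution_mg > 0) {
    q_g <- spec$balance_resolution_mg / 1000
    w_mass <- round(w_mass / q_g) * q_g
  }

  ts <- spec$start_time + t_min * 60
  c_idx <- seq(1, n_min + 1, by = max(1, round(spec$climate_interval_min)))
  if (c_idx[length(c_idx)] != n_min + 1) c_idx <- c(c_idx, n_min + 1)

  list(
    weighing = weighing_series(spec$item$item_id, ts[w_idx], w_mass),
    climate = climate_log(ts[c_idx], T_t[c_idx], rh_t[c_idx],
                          spec$pressure_pa),
    truth = list(r_T_s_cm = spec$r_T_s_cm, r_B_s_cm = spec$r_B_s_cm,
                 final_mass_g = mass_g[n_min + 1])
  )
}

#' Simulate-then-estimate parameter-recovery experiment
#'
#' Runs the forward simulator and feeds its outputs through the estimation
#' chain for the chosen protocol, reporting the injected against the
#' recovered resistances:
#'
#' * `free`: a single free-convection run, analysed with the true
#'   boundary-layer resistance supplied as the protocol default (the
#'   boundary layer is assumed, the tissue resistance estimated);
#' * `forced`, `wetted`: a paired experiment on the same fruit -- one run
#'   with the authentic boundary layer and one with it stripped
#'   (`r_B = 0`); the tissue resistance comes from the stripped run and the
#'   boundary layer from the difference of the two totals;
#' * `bulk`: a single packaged run analysed with the true tissue resistance
#'   (known from the individual protocol), estimating the bulk boundary
#'   layer.
#'
#' @param spec A [simulation_spec()] carrying the true resistances.
#' @param protocol Protocol to exercise.
#' @param estimator Transpiration-rate estimator passed to the analysis.
#' @return A data.frame with one row per parameter: `protocol`,
#'   `parameter`, `true`, `estimated`, `rel_error` and `basis`
#'   (`"estimated"` or `"assumed"`).
#' @export
recovery_experiment <- function(spec,
                                protocol = c("free", "forced", "wetted", "bulk"),
                                estimator = c("endpoint", "slope")) {
  stopifnot(inherits(spec, "simulation_spec"))
  protocol <- match.arg(protocol)
  estimator <- match.arg(estimator)
  min_h <- spec$duration_h  # the simulated duration defines the protocol window

  if (protocol == "free") {
    sim <- forward_simulate(spec)
    cfg <- protocol_config("free", rb_default_s_cm = spec$r_B_s_cm,
                           estimator = estimator, min_duration_h = min_h)
    res <- run_protocol(sim$weighing, sim$climate, spec$item, cfg)
    est <- data.frame(
      parameter = c("r_T", "r_B"),
      true = c(spec$r_T_s_cm, spec$r_B_s_cm),
      estimated = c(res$r_T, res$r_B),
      basis = c("estimated", "assumed")
    )
  } else if (protocol %in% c("forced", "wetted")) {
    sim_free <- forward_simulate(spec)
    spec0 <- spec
    spec0$r_B_s_cm <- 0
    sim0 <- forward_simulate(spec0)
    cfg0 <- protocol_config(protocol, estimator = estimator,
                            min_duration_h = min_h)
    res0 <- run_protocol(sim0$weighing, sim0$climate, spec$item, cfg0)
    cfg_free <- protocol_config("free", rb_default_s_cm = 0,
                                estimator = estimator, min_duration_h = min_h)
    res_free <- run_protocol(sim_free$weighing, sim_free$climate, spec$item,
                             cfg_free)
    est <- data.frame(
      parameter = c("r_T", "r_B"),
      true = c(spec$r_T_s_cm, spec$r_B_s_cm),
      estimated = c(res0$r_T,
                    boundary_layer_by_difference(res_free$r_tot, res0$r_tot)),
      basis = c("estimated", "estimated")
    )
  } else { # bulk
    sim <- forward_simulate(spec)
    cfg <- protocol_config("bulk", r_tissue_s_cm = spec$r_T_s_cm,
                           estimator = estimator, min_duration_h = min_h)
    res <- run_protocol(sim$weighing, sim$climate, spec$item, cfg)
    est <- data.frame(
      parameter = c("r_T", "r_B"),
      true = c(spec$r_T_s_cm, spec$r_B_s_cm),
      estimated = c(res$r_T, res$r_B),
      basis = c("assumed", "estimated")
    )
  }
  est$rel_error <- ifelse(est$true == 0, abs(est$estimated - est$true),
                          abs(est$estimated - est$true) / est$true)
  cbind(protocol = protocol, est)
}
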