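#' Weighing series for one fruit or one bulk container
#'
#' @param item_id Label for the weighed item.
#' @param timestamp POSIXct timestamps, strictly increasing, at least two.
#' @param mass_g Masses in g at balance resolution (0.1 mg for a precision
#'   balance); gross mass for bulk containers, tare subtracted internally.
#' @param is_bulk Whether the series weighs a packed container.
#' @param container_tare_g Container tare in g (bulk only).
#' @return An object of class `weighing_series` with a `records` data.frame
#'   of net masses.
#' @export
weighing_series <- function(item_id, timestamp, mass_g, is_bulk = FALSE,
                            container_tare_g = 0) {
  if (!inherits(timestamp, "POSIXct")) {
    stop("'timestamp' must be POSIXct", call. = FALSE)
  }
  if (length(timestamp) != length(mass_g)) {
    stop("timestamps and masses must have equal length", call. = FALSE)
  }
  if (length(timestamp) < 2) {
    stop("a weighing series needs at least two records", call. = FALSE)
  }
  if (anyNA(timestamp) || anyNA(mass_g)) {
    stop("missing timestamps or masses are not allowed", call. = FALSE)
  }
  if (any(diff(as.numeric(timestamp)) <= 0)) {
    stop(sprintf("timestamps must be strictly increasing (item '%s')", item_id),
         call. = FALSE)
  }
  net <- mass_g - container_tare_g
  if (any(net <= 0)) {
    stop(sprintf("non-positive mass after tare subtraction (item '%s')", item_id),
         call. = FALSE)
  }
  structure(
    list(item_id = item_id,
         records = data.frame(timestamp = timestamp, mass_g = net),
         is_bulk = is_bulk, container_tare_g = container_tare_g),
    class = "weighing_series"
  )
}

#' @export
print.weighing_series <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("Weighing series '%s'%s: %d records, %s to %s, %.4f -> %.4f g\n",
              x$item_id, if (x$is_bulk) " (bulk)" else "", n,
              format(x$records$timestamp[1]), format(x$records$timestamp[n]),
              x$records$mass_g[1], x$records$mass_g[n]))
  invisible(x)
}

#' Climate log of temperature, humidity and barometric pressure
#'
#' @param timestamp POSIXct timestamps, strictly increasing.
#' @param temperature_c Air temperatures in degC.
#' @param relative_humidity_pct Relative humidities in percent, 0 to 100.
#' @param pressure_pa Barometric pressures in Pa, or `NA` when not logged.
#' @return An object of class `climate_log` with a `records` data.frame.
#' @export
climate_log <- function(timestamp, temperature_c, relative_humidity_pct,
                        pressure_pa = NA_real_) {
  if (!inherits(timestamp, "POSIXct")) {
    stop("'timestamp' must be POSIXct", call. = FALSE)
  }
  n <- length(timestamp)
  if (length(temperature_c) != n || length(relative_humidity_pct) != n) {
    stop("climate columns must have equal length", call. = FALSE)
  }
  temperature_c <- as.numeric(temperature_c)
  relative_humidity_pct <- as.numeric(relative_humidity_pct)
  pressure_pa <- rep_len(as.numeric(pressure_pa), n)
  if (anyNA(timestamp) || anyNA(temperature_c) || anyNA(relative_humidity_pct)) {
    stop("missing timestamps, temperatures or humidities are not allowed",
         call. = FALSE)
  }
  if (any(diff(as.numeric(timestamp)) <= 0)) {
    stop("climate timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(relative_humidity_pct < 0 | relative_humidity_pct > 100)) {
    stop("relative humidity must lie in [0, 100] %", call. = FALSE)
  }
  structure(
    list(records = data.frame(timestamp = timestamp,
                              temperature_c = temperature_c,
                              relative_humidity_pct = relative_humidity_pct,
                              pressure_pa = pressure_pa)),
    class = "climate_log"
  )
}

#' @export
print.climate_log <- function(x, ...) {
  r <- x$records
  cat(sprintf("Climate log: %d records, %s to %s, %.1f-%.1f degC, %.1f-%.1f %% rH\n",
              nrow(r), format(r$timestamp[1]), format(r$timestamp[nrow(r)]),
              min(r$temperature_c), max(r$temperature_c),
              min(r$relative_humidity_pct), max(r$relative_humidity_pct)))
  invisible(x)
}

#' Measurement-protocol configuration
#'
#' @param protocol One of `"free"`, `"forced"`, `"wetted"`, `"bulk"`.
#' @param rb_default_s_cm Assumed free-convection boundary-layer resistance
#'   in s cm^-1; if `NULL`, the apple default of 4.0 s cm^-1 is applied to
#'   apples only and other species raise an error.
#' @param aw Fallback water activity when the produce item carries none.
#' @param estimator `"endpoint"` (first/last weighing difference, default)
#'   or `"slope"` (least-squares slope of mass against time, for noisy
#'   series).
#' @param min_duration_h Minimum recommended series duration in h; defaults
#'   to 24 for individual-fruit protocols and 48 for bulk.
#' @param r_tissue_s_cm Tissue resistance from the individual-fruit
#'   protocol, required by the bulk protocol.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(protocol = c("free", "forced", "wetted", "bulk"),
                            rb_default_s_cm = NULL,
                            aw = .DEFAULT_WATER_ACTIVITY,
                            estimator = c("endpoint", "slope"),
                            min_duration_h = NULL,
                            r_tissue_s_cm = NULL) {
  protocol <- match.arg(protocol)
  estimator <- match.arg(estimator)
  if (!is.null(rb_default_s_cm) && rb_default_s_cm < 0) {
    stop("default boundary-layer resistance must be non-negative", call. = FALSE)
  }
  if (aw <= 0 || aw > 1) stop("water activity must lie in (0, 1]", call. = FALSE)
  if (is.null(min_duration_h)) {
    min_duration_h <- if (protocol == "bulk") 48 else 24
  }
  if (!is.null(r_tissue_s_cm) && r_tissue_s_cm < 0) {
    stop("tissue resistance must be non-negative", call. = FALSE)
  }
  structure(
    list(protocol = protocol, rb_default_s_cm = rb_default_s_cm, aw = aw,
         estimator = estimator, min_duration_h = min_duration_h,
         r_tissue_s_cm = r_tissue_s_cm),
    class = "protocol_config"
  )
}

.parse_timestamps <- function(x, what, path) {
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")
  ts <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in fmts) {
    need <- is.na(ts)
    if (!any(need)) break
    ts[need] <- as.POSIXct(strptime(x[need], fmt, tz = "UTC"))
  }
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    stop(sprintf("%s '%s': unparseable timestamp at data row(s) %s (expect ISO-8601)",
                 what, path, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  ts
}

.check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s '%s': missing required column(s): %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read weighing series from a CSV file
#'
#' Expects a comma-separated UTF-8 file with a header and columns
#' `item_id`, `timestamp` (ISO-8601), `mass_g`, and optionally `is_bulk`
#' and `container_tare_g`. Returns one validated series per `item_id`;
#' duplicate (item, timestamp) pairs and non-monotone timestamps are
#' rejected.
#'
#' @param path Path to the CSV file.
#' @return A named list of [weighing_series()] objects.
#' @export
read_weighing_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("item_id", "timestamp", "mass_g"), "weighing file", path)
  if (nrow(df) == 0) stop(sprintf("weighing file '%s' has no data rows", path),
                          call. = FALSE)
  if (!is.numeric(df$mass_g) || anyNA(df$mass_g)) {
    stop(sprintf("weighing file '%s': non-numeric or missing mass_g", path),
         call. = FALSE)
  }
  df$timestamp <- .parse_timestamps(df$timestamp, "weighing file", path)
  key <- paste(df$item_id, format(df$timestamp, "%Y-%m-%dT%H:%M:%OS6"))
  if (anyDuplicated(key)) {
    stop(sprintf("weighing file '%s': duplicate (item_id, timestamp) at data row(s) %s",
                 path, paste(which(duplicated(key)), collapse = ", ")),
         call. = FALSE)
  }
  out <- lapply(split(df, df$item_id), function(d) {
    weighing_series(
      item_id = d$item_id[1], timestamp = d$timestamp, mass_g = d$mass_g,
      is_bulk = if ("is_bulk" %in% names(d)) isTRUE(as.logical(d$is_bulk[1])) else FALSE,
      container_tare_g = if ("container_tare_g" %in% names(d)) d$container_tare_g[1] else 0
    )
  })
  out[unique(df$item_id)]
}

#' Write weighing series to a CSV file
#'
#' Inverse of [read_weighing_csv()]; numeric columns are written at full
#' precision so that a read-back reproduces them bit-identically.
#'
#' @param series A [weighing_series()] or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weighing_csv <- function(series, path) {
  if (inherits(series, "weighing_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(
      item_id = s$item_id,
      timestamp = format(s$records$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      mass_g = formatC(s$records$mass_g + s$container_tare_g,
                       digits = 17, format = "g"),
      is_bulk = s$is_bulk,
      container_tare_g = formatC(s$container_tare_g, digits = 17, format = "g")
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a climate log from a CSV file
#'
#' Expects columns `timestamp` (ISO-8601), `temp_c`, `rh_pct` and
#' optionally `pbar_pa`.
#'
#' @param path Path to the CSV file.
#' @return A [climate_log()].
#' @export
read_climate_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' not found", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(df, c("timestamp", "temp_c", "rh_pct"), "climate file", path)
  if (nrow(df) == 0) stop(sprintf("climate file '%s' has no data rows", path),
                          call. = FALSE)
  df$timestamp <- .parse_timestamps(df$timestamp, "climate file", path)
  climate_log(
    timestamp = df$timestamp, temperature_c = df$temp_c,
    relative_humidity_pct = df$rh_pct,
    pressure_pa = if ("pbar_pa" %in% names(df)) df$pbar_pa else NA_real_
  )
}

#' Write a climate log to a CSV file
#'
#' @param log A [climate_log()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(log, path) {
  stopifnot(inherits(log, "climate_log"))
  r <- log$records
  out <- data.frame(
    timestamp = format(r$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temp_c = formatC(r$temperature_c, digits = 17, format = "g"),
    rh_pct = formatC(r$relative_humidity_pct, digits = 17, format = "g"),
    pbar_pa = ifelse(is.na(r$pressure_pa), "",
                     formatC(r$pressure_pa, digits = 17, format = "g"))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# exact time-weighted mean of a piecewise-linear signal over [a, b]
.tw_mean <- function(t_s, y, a_s, b_s) {
  if (b_s == a_s) return(stats::approx(t_s, y, xout = a_s)$y)
  knots <- sort(unique(c(a_s, b_s, t_s[t_s > a_s & t_s < b_s])))
  yy <- stats::approx(t_s, y, xout = knots)$y
  sum(diff(knots) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2) / (b_s - a_s)
}

#' Time-weighted mean climate over a window
#'
#' Treats the logged climate as piecewise linear between samples and returns
#' the exact time-weighted mean of temperature, relative humidity and
#' pressure over `[t_start, t_end]`. The log must cover the window;
#' pressure is `NA` if any pressure sample in the window is missing.
#'
#' @param log A [climate_log()].
#' @param t_start,t_end POSIXct window bounds, `t_start <= t_end`.
#' @return A list with `temperature_c`, `relative_humidity_pct`,
#'   `pressure_pa`.
#' @export
mean_climate <- function(log, t_start, t_end) {
  stopifnot(inherits(log, "climate_log"))
  r <- log$records
  t_s <- as.numeric(r$timestamp)
  a <- as.numeric(t_start)
  b <- as.numeric(t_end)
  if (b < a) stop("t_end must not precede t_start", call. = FALSE)
  if (a < t_s[1] - 1e-6 || b > t_s[length(t_s)] + 1e-6) {
    stop(sprintf(
      "climate log (%s to %s) does not cover the requested window (%s to %s)",
      format(r$timestamp[1]), format(r$timestamp[nrow(r)]),
      format(t_start), format(t_end)), call. = FALSE)
  }
  a <- max(a, t_s[1]); b <- min(b, t_s[length(t_s)])
  list(
    temperature_c = .tw_mean(t_s, r$temperature_c, a, b),
    relative_humidity_pct = .tw_mean(t_s, r$relative_humidity_pct, a, b),
    pressure_pa = if (anyNA(r$pressure_pa)) NA_real_
                  else .tw_mean(t_s, r$pressure_pa, a, b)
  )
}
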