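#' Read a monitoring-station log
#'
#' CSV dialect: header `timestamp,temperature_c,rh_pct,co2_ppm,light`,
#' ISO-8601 timestamps (parsed as UTC). Validates the record invariants:
#' strictly increasing timestamps, relative humidity in `[0, 100]`,
#' non-negative CO2.
#'
#' @param path CSV file path.
#' @return Data frame with `timestamp` (`POSIXct`) and the four variables.
#' @export
read_station_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "temperature_c", "rh_pct", "co2_ppm", "light")
  if (!all(need %in% names(df)))
    stop("station log must have columns: ", paste(need, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                             tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  validate_station_log(df)
  df
}

validate_station_log <- function(df) {
  if (anyNA(df$timestamp)) stop("unparseable timestamps in station log")
  if (is.unsorted(df$timestamp, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  if (any(df$rh_pct < 0 | df$rh_pct > 100)) stop("rh_pct outside [0, 100]")
  if (any(df$co2_ppm < 0)) stop("co2_ppm must be >= 0")
  invisible(df)
}

#' Summarize a station log: means and diurnal extrema
#'
#' For each monitored variable (temperature, relative humidity, CO2, light)
#' reports the overall mean and the clock hours of the diurnal maximum and
#' minimum. Extrema are read off the hourly-binned mean profile (24 bins by
#' clock hour, ties toward the earlier hour), not off raw samples, matching
#' how diurnal cycles are reported (e.g. maximum around 15:00, minimum
#' around 03:00). A flat profile (range < 1e-9) yields `NA` extrema and a
#' `flat` flag.
#'
#' @param records Data frame as from [read_station_log()]. Records are
#'   sorted by timestamp first, so input order does not matter.
#' @return A `station_summary`: named list per variable with `mean`,
#'   `max_hour`, `min_hour`, `flat`, plus `n_records` and `span_hours`.
#' @export
summarize_log <- function(records) {
  records <- records[order(records$timestamp), , drop = FALSE]
  validate_station_log(records)
  span_h <- as.numeric(difftime(max(records$timestamp), min(records$timestamp),
                                units = "hours"))
  if (span_h < 24)
    stop(sprintf("insufficient data: log spans %.1f h, need >= 24 h", span_h))
  hour <- as.POSIXlt(records$timestamp)$hour
  vars <- c("temperature_c", "rh_pct", "co2_ppm", "light")
  out <- list()
  for (v in vars) {
    x <- records[[v]]
    prof <- tapply(x, factor(hour, levels = 0:23), mean)
    prof <- prof[!is.na(prof)]
    flat <- diff(range(prof)) < 1e-9
    hours <- as.integer(names(prof))
    out[[v]] <- list(mean = mean(x),
                     max_hour = if (flat) NA_integer_ else hours[which.max(prof)],
                     min_hour = if (flat) NA_integer_ else hours[which.min(prof)],
                     flat = flat)
  }
  structure(c(out, list(n_records = nrow(records), span_hours = span_h)),
            class = "station_summary")
}

#' @export
print.station_summary <- function(x, ...) {
  cat(sprintf("<station_summary: %d records over %.1f h>\n",
              x$n_records, x$span_hours))
  for (v in c("temperature_c", "rh_pct", "co2_ppm", "light")) {
    s <- x[[v]]
    cat(sprintf("  %-13s mean %8.2f  diurnal max %s:00, min %s:00%s\n", v,
                s$mean, format(s$max_hour), format(s$min_hour),
                if (s$flat) " (flat)" else ""))
  }
  invisible(x)
}

#' Volumetric aerial spore concentration
#'
#' Spores per cubic metre of air drawn past the sampling slide:
#' `count / (flow_lpm * duration_min / 1000)`. At the survey defaults
#' (10 L/min for 15 min) the sampled volume is 0.15 m^3, so a count of 150
#' gives exactly 1000 spores/m^3. No trap-efficiency correction is applied
#' by default (`correction = 1`).
#'
#' @param count Spores counted (>= 0).
#' @param flow_lpm Pump flow in litres per minute (> 0; default 10).
#' @param duration_min Sampling duration in minutes (> 0; default 15).
#' @param correction Multiplicative correction hook (default 1).
#' @return Concentration in spores per m^3.
#' @export
spore_concentration <- function(count, flow_lpm = 10, duration_min = 15,
                                correction = 1) {
  if (any(count < 0)) stop("spore count must be >= 0")
  if (any(flow_lpm <= 0)) stop("flow_lpm must be > 0")
  if (any(duration_min <= 0)) stop("duration_min must be > 0")
  count / (flow_lpm * duration_min / 1000) * correction
}
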