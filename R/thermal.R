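# Thermal time: growing degree days and the sensing-window context that
# feeds the INSEY denominator.

#' Daily growing degree days
#'
#' `max(0, (tmax + tmin)/2 - base_temp)`. The default base temperature of
#' 10 degrees C is the maize convention.
#'
#' @param tmax,tmin Daily maximum and minimum air temperature, degrees C.
#' @param base_temp Crop base temperature, degrees C.
#' @return Degree-days (degrees C day), floored at zero. Vectorized.
#' @examples
#' daily_gdd(30, 20)      # 15
#' daily_gdd(12, 4)       # 0
#' @export
daily_gdd <- function(tmax, tmin, base_temp = 10) {
  if (!is.numeric(tmax) || !is.numeric(tmin) || anyNA(tmax) || anyNA(tmin)) {
    stop_domain("temperatures must be non-missing numbers")
  }
  if (any(tmax < tmin)) stop_domain("`tmax` must be >= `tmin` on every day")
  pmax(0, (tmax + tmin) / 2 - base_temp)
}

#' Thermal context between sowing and sensing
#'
#' Accumulates growing degree days over the window `(sowing, sensing]`
#' and counts the days with positive daily GDD — the denominator of the
#' in-season estimated yield. The weather table must cover every day of
#' the window; gaps are reported.
#'
#' @param weather Data frame with columns `date` (Date or ISO string),
#'   `tmax_c`, `tmin_c`.
#' @param sowing,sensing Sowing and sensing dates (Date or ISO string);
#'   `sensing > sowing`.
#' @param base_temp Base temperature, degrees C.
#' @return An object of class `thermal_context` with fields
#'   `sowing_date`, `sensing_date`, `base_temp`, `positive_gdd_days`
#'   (count of window days with positive GDD) and `cumulative_gdd`.
#' @export
thermal_context <- function(weather, sowing, sensing, base_temp = 10) {
  if (!all(c("date", "tmax_c", "tmin_c") %in% names(weather))) {
    stop_input("`weather` needs columns date, tmax_c, tmin_c")
  }
  sowing <- as.Date(sowing)
  sensing <- as.Date(sensing)
  if (is.na(sowing) || is.na(sensing)) stop_input("unparseable sowing/sensing date")
  if (sensing <= sowing) stop_domain("`sensing` must be after `sowing`")
  dates <- as.Date(weather$date)
  if (anyNA(dates)) stop_input("unparseable date in weather table")
  window <- seq(sowing + 1, sensing, by = "day")
  missing <- window[!window %in% dates]
  if (length(missing) > 0) {
    stop_input(sprintf(
      "weather table is missing %d day(s) in the sowing-sensing window: %s",
      length(missing), paste(format(utils::head(missing, 5)), collapse = ", ")
    ))
  }
  sel <- match(window, dates)
  gdd <- daily_gdd(weather$tmax_c[sel], weather$tmin_c[sel], base_temp)
  structure(
    list(
      sowing_date = sowing, sensing_date = sensing, base_temp = base_temp,
      positive_gdd_days = sum(gdd > 0), cumulative_gdd = sum(gdd)
    ),
    class = "thermal_context"
  )
}

#' @export
print.thermal_context <- function(x, ...) {
  cat(sprintf(
    "<thermal_context> %s -> %s: %d positive-GDD days, %.1f degree-days (base %g C)\n",
    format(x$sowing_date), format(x$sensing_date),
    x$positive_gdd_days, x$cumulative_gdd, x$base_temp
  ))
  invisible(x)
}
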