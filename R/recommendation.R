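# In-season N prescription: INSEY, response index, power-law yield
# potential, and the fertilizer-N dose equation.

#' In-season estimated yield (INSEY)
#'
#' The greenness index (DGCI, or NDVI in sensor mode) divided by thermal
#' time since sowing. The default denominator is the count of days with
#' positive growing degree days, the usual convention in the
#' sensor-based N literature; `denominator = "gdd"` instead divides by
#' cumulative degree-days.
#'
#' @param index Greenness index value (DGCI or NDVI), > 0.
#' @param ctx A [thermal_context()].
#' @param denominator `"days"` (count of positive-GDD days, default) or
#'   `"gdd"` (cumulative GDD).
#' @return INSEY, per day (or per degree-day).
#' @export
insey <- function(index, ctx, denominator = c("days", "gdd")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(ctx, "thermal_context"))
  check_number(index, "index", 0, Inf, strict_min = TRUE)
  den <- switch(denominator,
    days = ctx$positive_gdd_days,
    gdd = ctx$cumulative_gdd
  )
  if (den <= 0) {
    stop_domain("no positive thermal accumulation before sensing; INSEY undefined")
  }
  index / den
}

#' Response index from a nitrogen-rich reference strip
#'
#' Ratio of the greenness of an N-enriched strip (maintained at a
#' non-limiting N supply, 240 kg N/ha in the calibration trials) to the
#' test plot. Values below 1 — the test plot out-greening the strip —
#' are plausible field noise and are kept (with a message); an optional
#' cap bounds the ratio from above.
#'
#' @param index_test Greenness index of the test plot, > 0.
#' @param index_enrich Greenness index of the enriched strip, > 0.
#' @param cap Optional upper bound applied to the ratio.
#' @return Dimensionless response index.
#' @examples
#' response_index(0.55, 0.66) # 1.2
#' @export
response_index <- function(index_test, index_enrich, cap = NULL) {
  check_number(index_test, "index_test", 0, Inf, strict_min = TRUE)
  check_number(index_enrich, "index_enrich", 0, Inf, strict_min = TRUE)
  ri <- index_enrich / index_test
  if (any(ri < 1)) {
    message("response index below 1: test plot reads greener than the enriched strip")
  }
  if (!is.null(cap)) ri <- pmin(ri, cap)
  ri
}

#' Fit the power-law yield-potential calibration
#'
#' Fits `yield = a * insey^b` by ordinary least squares on the log-log
#' scale, `ln(yield) = ln(a) + b * ln(insey)`, the standard way such
#' yield-potential functions are calibrated from multi-rate N trials.
#' Each fitted model belongs to one sensing stage (days after sowing).
#'
#' @param insey_values INSEY values, all > 0, length >= 3.
#' @param grain_yield Grain yields (t/ha at standard moisture), all > 0.
#' @param stage_das Sensing stage the calibration belongs to (days
#'   after sowing), e.g. 35 or 45.
#' @return An object of class `calibration_model` with fields `a`, `b`,
#'   `stage_das`, `n` and `sigma_log` (residual standard deviation on
#'   the log scale).
#' @examples
#' x <- c(0.005, 0.01, 0.02)
#' fit_power_function(x, 2 * x^0.8, stage_das = 35)
#' @export
fit_power_function <- function(insey_values, grain_yield, stage_das = NA_real_) {
  if (length(insey_values) != length(grain_yield)) {
    stop_input("`insey_values` and `grain_yield` must have equal length")
  }
  if (length(insey_values) < 3) {
    stop_domain("need at least 3 calibration pairs to fit the power function")
  }
  check_number(insey_values, "insey_values", 0, Inf, strict_min = TRUE)
  check_number(grain_yield, "grain_yield", 0, Inf, strict_min = TRUE)
  lx <- log(insey_values)
  if (stats::var(lx) == 0) {
    stop_domain("all INSEY values are equal; the power-law fit is singular")
  }
  fit <- stats::lm(log(grain_yield) ~ lx)
  co <- stats::coef(fit)
  structure(
    list(
      a = unname(exp(co[1])), b = unname(co[2]), stage_das = stage_das,
      n = length(insey_values), sigma_log = stats::sigma(fit)
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Yield-potential calibration (stage %s DAS): yield = %.4g * INSEY^%.4g  [n = %d, residual log-sd %.3g]\n",
    format(x$stage_das), x$a, x$b, x$n, x$sigma_log
  ))
  invisible(x)
}

#' Write / read a calibration model file
#'
#' Plain structured text (YAML) holding `a`, `b`, the sensing stage and
#' the fit diagnostics.
#'
#' @param model A `calibration_model`.
#' @param path File path.
#' @return `path` / the re-read `calibration_model`.
#' @export
write_calibration_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  yaml::write_yaml(unclass(model), path)
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such model file: %s", path))
  m <- yaml::read_yaml(path)
  need <- c("a", "b", "stage_das", "n", "sigma_log")
  if (!all(need %in% names(m))) {
    stop_input(sprintf(
      "model file %s lacks field(s): %s", path,
      paste(setdiff(need, names(m)), collapse = ", ")
    ))
  }
  if (!is.numeric(m$a) || m$a <= 0) stop_domain("model `a` must be > 0")
  structure(m[need], class = "calibration_model")
}

#' Potential yield without additional nitrogen
#'
#' `YP0 = a * INSEY^b`, the calibrated power law evaluated at the
#' observed INSEY.
#'
#' @param insey_value INSEY, > 0.
#' @param model A [fit_power_function()] calibration.
#' @param stage_das Optional sensing stage; when given it must match
#'   the model's stage.
#' @return Potential yield, t/ha.
#' @export
potential_yield <- function(insey_value, model, stage_das = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  check_number(insey_value, "insey_value", 0, Inf, strict_min = TRUE)
  if (!is.null(stage_das) && !is.na(model$stage_das) &&
      stage_das != model$stage_das) {
    stop_domain(sprintf(
      "sensing stage %g DAS does not match the calibration's stage %g DAS",
      stage_das, model$stage_das
    ))
  }
  model$a * insey_value^model$b
}

#' Achievable yield with added nitrogen
#'
#' `YPN = YP0 * RI`: the potential yield scaled by the response index.
#'
#' @param yp0 Potential yield without added N, t/ha, >= 0.
#' @param ri Response index, > 0.
#' @return Achievable yield, t/ha.
#' @export
achievable_yield <- function(yp0, ri) {
  check_number(yp0, "yp0", 0, Inf)
  check_number(ri, "ri", 0, Inf, strict_min = TRUE)
  yp0 * ri
}

#' Fertilizer nitrogen dose
#'
#' `dose = 10 * grain_n_pct * (YPN - YP0) / efficiency`, floored at zero
#' and reported to 0.1 kg/ha. The factor 10 converts t/ha times percent
#' N into kg N/ha; 1.43 is the mean maize grain N concentration (%) and
#' 0.5 the achievable N-use efficiency factor for South Asia. With the
#' defaults the dose is `28.6 kg/ha` per t/ha of predicted yield
#' response. A negative predicted response (YPN < YP0) is floored at
#' zero with a warning rather than treated as an error.
#'
#' @param ypn,yp0 Achievable and potential yield, t/ha.
#' @param grain_n_pct Grain N concentration, percent.
#' @param efficiency Achievable efficiency factor, > 0.
#' @return Dose, kg N/ha, rounded to 0.1.
#' @examples
#' n_dose(6, 4) # 57.2
#' @export
n_dose <- function(ypn, yp0, grain_n_pct = 1.43, efficiency = 0.5) {
  check_number(efficiency, "efficiency", 0, Inf, strict_min = TRUE)
  check_number(grain_n_pct, "grain_n_pct", 0, 100)
  if (any(ypn < yp0)) {
    warning("achievable yield below potential yield; dose floored at 0")
  }
  round(pmax(0, 10 * grain_n_pct * (ypn - yp0) / efficiency), 1)
}

#' Bundle one sensing event
#'
#' Pairs the test-plot and enriched-strip greenness readings with their
#' thermal context. `index_kind = "ndvi"` runs the identical pipeline on
#' NDVI readings (sensor mode): the greenness values are simply
#' substituted, nothing else changes.
#'
#' @param index_test,index_enrich Greenness readings (> 0) of the test
#'   plot and the N-enriched strip.
#' @param thermal A [thermal_context()].
#' @param stage_das Sensing stage, days after sowing.
#' @param index_kind `"dgci"` or `"ndvi"`.
#' @return An object of class `sensing_session`.
#' @export
sensing_session <- function(index_test, index_enrich, thermal,
                            stage_das = NA_real_,
                            index_kind = c("dgci", "ndvi")) {
  index_kind <- match.arg(index_kind)
  check_number(index_test, "index_test", 0, Inf, strict_min = TRUE)
  check_number(index_enrich, "index_enrich", 0, Inf, strict_min = TRUE)
  stopifnot(inherits(thermal, "thermal_context"))
  structure(
    list(
      index_test = index_test, index_enrich = index_enrich,
      thermal = thermal, stage_das = stage_das, index_kind = index_kind
    ),
    class = "sensing_session"
  )
}

#' Recommend an in-season fertilizer N dose
#'
#' Composes the full prescription chain for one sensing event: INSEY
#' from the test-plot reading and thermal time, potential yield from the
#' calibrated power law, response index from the enriched strip,
#' achievable yield, and the dose equation.
#'
#' @param session A [sensing_session()].
#' @param model A [fit_power_function()] calibration for the same stage.
#' @param grain_n_pct,efficiency Dose-equation constants, see
#'   [n_dose()].
#' @param ri_cap Optional upper bound on the response index.
#' @param denominator INSEY denominator convention, see [insey()].
#' @return An object of class `n_recommendation`: `insey`, `ri`, `yp0`,
#'   `ypn`, `n_dose` (kg/ha), plus the inputs used.
#' @export
recommend <- function(session, model, grain_n_pct = 1.43, efficiency = 0.5,
                      ri_cap = NULL, denominator = c("days", "gdd")) {
  stopifnot(inherits(session, "sensing_session"),
            inherits(model, "calibration_model"))
  denominator <- match.arg(denominator)
  if (!is.na(session$stage_das) && !is.na(model$stage_das) &&
      session$stage_das != model$stage_das) {
    stop_domain(sprintf(
      "session stage %g DAS does not match the calibration's stage %g DAS",
      session$stage_das, model$stage_das
    ))
  }
  step <- function(tag, expr) {
    tryCatch(expr, maizeNrec_domain_error = function(e) {
      stop_domain(sprintf("[%s] %s", tag, conditionMessage(e)))
    })
  }
  ins <- step("insey", insey(session$index_test, session$thermal, denominator))
  yp0 <- step("potential_yield", potential_yield(ins, model))
  ri <- step("response_index",
             response_index(session$index_test, session$index_enrich, ri_cap))
  ypn <- step("achievable_yield", achievable_yield(yp0, ri))
  dose <- step("n_dose", n_dose(ypn, yp0, grain_n_pct, efficiency))
  structure(
    list(
      insey = ins, ri = ri, yp0 = yp0, ypn = ypn, n_dose = dose,
      index_kind = session$index_kind, stage_das = session$stage_das,
      grain_n_pct = grain_n_pct, efficiency_factor = efficiency
    ),
    class = "n_recommendation"
  )
}

#' @export
print.n_recommendation <- function(x, ...) {
  cat(sprintf(
    paste0(
      "In-season N recommendation (%s, stage %s DAS)\n",
      "  INSEY           %.5g\n",
      "  response index  %.3f\n",
      "  yield potential %.2f t/ha (without N) -> %.2f t/ha (with N)\n",
      "  N dose          %.1f kg/ha\n"
    ),
    toupper(x$index_kind), format(x$stage_das),
    x$insey, x$ri, x$yp0, x$ypn, x$n_dose
  ))
  invisible(x)
}
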