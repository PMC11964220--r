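# Typed CSV readers/writers for the three table kinds the tool consumes.

read_typed_csv <- function(path, columns, label) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(columns), names(df))
  if (length(miss) > 0) {
    stop_input(sprintf("%s %s lacks column(s): %s", label, path,
                       paste(miss, collapse = ", ")))
  }
  for (col in names(columns)) {
    kind <- columns[[col]]
    raw <- df[[col]]
    if (kind == "date") {
      parsed <- as.Date(as.character(raw), format = "%Y-%m-%d")
      bad <- which(is.na(parsed) & !is.na(raw) & nzchar(as.character(raw)))
      if (length(bad) > 0) {
        stop_input(sprintf("%s %s: unparseable value in row %d, column `%s`",
                           label, path, bad[1], col))
      }
      df[[col]] <- parsed
    } else if (kind == "numeric") {
      parsed <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(parsed) & !is.na(raw) & nzchar(trimws(as.character(raw))))
      if (length(bad) > 0) {
        stop_input(sprintf("%s %s: unparseable value in row %d, column `%s`",
                           label, path, bad[1], col))
      }
      df[[col]] <- parsed
    } else {
      df[[col]] <- as.character(raw)
    }
  }
  df
}

#' Read a daily weather table
#'
#' Columns `date` (ISO), `tmax_c`, `tmin_c`.
#'
#' @param path CSV path.
#' @return Typed data frame.
#' @export
read_weather_csv <- function(path) {
  df <- read_typed_csv(
    path, c(date = "date", tmax_c = "numeric", tmin_c = "numeric"),
    "weather table"
  )
  if (any(df$tmax_c < df$tmin_c, na.rm = TRUE)) {
    stop_domain("weather table has days with tmax < tmin")
  }
  df
}

#' Read a calibration-trial table
#'
#' Columns `plot_id`, `stage_das`, `insey`, `grain_yield_t_ha`.
#'
#' @param path CSV path.
#' @return Typed data frame.
#' @export
read_calibration_csv <- function(path) {
  read_typed_csv(
    path,
    c(plot_id = "character", stage_das = "numeric",
      insey = "numeric", grain_yield_t_ha = "numeric"),
    "calibration table"
  )
}

#' Read a validation plot table
#'
#' One row per plot/treatment with the yield, N-concentration, cost,
#' energy and emission columns consumed by [compute_metrics()]. Missing
#' numeric cells are kept as `NA`.
#'
#' @param path CSV path.
#' @return Typed data frame.
#' @export
read_plot_csv <- function(path) {
  read_typed_csv(
    path,
    c(treatment = "character", fertilizer_n_kg_ha = "numeric",
      grain_yield_t_ha = "numeric", cob_yield_t_ha = "numeric",
      stover_yield_t_ha = "numeric", biological_yield_t_ha = "numeric",
      grain_n_pct = "numeric", stover_n_pct = "numeric",
      cost_usd_ha = "numeric", gross_return_usd_ha = "numeric",
      energy_input_mj_ha = "numeric", ghg_kg_co2eq_ha = "numeric",
      n2o_kg_co2eq_ha = "numeric"),
    "plot table"
  )
}

#' Write a table to CSV
#'
#' Plain CSV, `NA` cells written empty; the round trip through the
#' matching reader is lossless.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
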