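# Run configuration: defaults matching the published constants, YAML
# loading with strict key checking.

#' Default run configuration
#'
#' All tunables in one place. Defaults follow the published constants
#' where the method states them: grain N concentration 1.43%,
#' achievable efficiency factor 0.5, grain moisture target 14.5%; the
#' maize base temperature of 10 degrees C is the crop convention.
#'
#' @return Named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    base_temp = 10,
    grain_n_pct = 1.43,
    efficiency_factor = 0.5,
    ri_cap = NULL,
    insey_denominator = "days",
    hue_band = NULL,
    min_brightness = 0.05,
    max_brightness = 1,
    moisture_target_pct = 14.5,
    control = "N0PK",
    reference = "RDF",
    seed = 1
  )
}

config_ranges <- list(
  base_temp = c(-20, 35),
  grain_n_pct = c(0, 100),
  efficiency_factor = c(1e-6, 1),
  ri_cap = c(1, 10),
  min_brightness = c(0, 1),
  max_brightness = c(0, 1),
  moisture_target_pct = c(0, 99.9),
  seed = c(-.Machine$integer.max, .Machine$integer.max)
)

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected by name; omitted keys fall back to
#' [default_run_config()]; numeric values are range-checked. An empty
#' file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return Named list, as [default_run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("no such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop_input("config file must be a YAML mapping")
  defaults <- default_run_config()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    stop_input(sprintf("unknown config key(s): %s",
                       paste(unknown, collapse = ", ")))
  }
  out <- utils::modifyList(defaults, cfg)
  for (key in names(config_ranges)) {
    val <- out[[key]]
    if (is.null(val)) next
    rng <- config_ranges[[key]]
    if (!is.numeric(val) || length(val) != 1 || is.na(val)) {
      stop_input(sprintf("config key `%s` must be a single number", key))
    }
    if (val < rng[1] || val > rng[2]) {
      stop_input(sprintf("config key `%s` = %g out of range [%g, %g]",
                         key, val, rng[1], rng[2]))
    }
  }
  if (!out$insey_denominator %in% c("days", "gdd")) {
    stop_input("config key `insey_denominator` must be \"days\" or \"gdd\"")
  }
  if (!is.null(out$hue_band) &&
      (!is.numeric(out$hue_band) || length(out$hue_band) != 2)) {
    stop_input("config key `hue_band` must be two numbers (degrees)")
  }
  out
}
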