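# Synthetic-data generators: leaf images with controllable DGCI, daily
# weather series, power-law calibration trials, and an internally
# consistent six-treatment validation plot table.
#
# All generators are pure functions of their arguments (seed included):
# identical calls give identical output, and the caller's RNG state is
# left untouched.

#' Generate a synthetic leaf image with a target mean DGCI
#'
#' Draws an elliptical "leaf" on a non-green background. Leaf colours
#' are sampled directly in HSB space — where DGCI is linear in hue,
#' saturation and brightness, so zero-mean jitter leaves the expected
#' index at the target — and converted to RGB. At zero noise the leaf
#' is uniform with saturation and brightness 1, so a target of 1/3
#' produces exact pure green.
#'
#' @param width,height Image size in pixels.
#' @param target_mean_dgci Target mask-mean DGCI. Reachable range:
#'   `[0, 2/3]` at zero noise, `[0.1, 0.76]` with noise (the leaf hue
#'   must stay in the green-yellow band 60-180 degrees).
#' @param background `"white"`, `"soil"` or `"grey"`.
#' @param noise_sd Per-channel jitter sd in `[0, 1]` (hue jitter is
#'   scaled by 60 degrees per channel unit).
#' @param seed Integer seed; same spec, same image.
#' @return A [leaf_image()] whose `mask` is the true leaf mask.
#' @export
make_leaf_image <- function(width = 120, height = 120,
                            target_mean_dgci = 1 / 3,
                            background = c("white", "soil", "grey"),
                            noise_sd = 0, seed = 1) {
  background <- match.arg(background)
  check_number(noise_sd, "noise_sd", 0, 0.2)
  if (noise_sd == 0) {
    s0 <- 1; b0 <- 1
  } else {
    s0 <- 0.85; b0 <- 0.85
  }
  # DGCI = (h/60 - 1 + (1 - s) + (1 - b)) / 3  =>  solve for the mean hue
  h0 <- 60 * (3 * target_mean_dgci + 1 - (1 - s0) - (1 - b0))
  if (h0 < 60 || h0 > 180) {
    lo <- (60 / 60 - 1 + (1 - s0) + (1 - b0)) / 3
    hi <- (180 / 60 - 1 + (1 - s0) + (1 - b0)) / 3
    stop_domain(sprintf(
      "target mean DGCI %.3f unreachable at noise_sd %g; reachable range [%.3f, %.3f]",
      target_mean_dgci, noise_sd, lo, hi
    ))
  }
  bg <- switch(background,
    white = c(1, 1, 1), soil = c(0.45, 0.32, 0.20), grey = c(0.8, 0.8, 0.8)
  )
  with_seed(seed, {
    xx <- matrix(rep(seq_len(width), each = height), height, width)
    yy <- matrix(rep(seq_len(height), times = width), height, width)
    cx <- (width + 1) / 2; cy <- (height + 1) / 2
    mask <- ((xx - cx) / (0.40 * width))^2 + ((yy - cy) / (0.45 * height))^2 <= 1
    n_leaf <- sum(mask)
    h <- h0 + stats::rnorm(n_leaf, 0, 60 * noise_sd)
    s <- pmin(1, pmax(0.01, s0 + stats::rnorm(n_leaf, 0, noise_sd)))
    b <- pmin(1, pmax(0.01, b0 + stats::rnorm(n_leaf, 0, noise_sd)))
    h <- pmin(180, pmax(60, h))
    rgb_leaf <- hsb_to_rgb(h, s, b)
    px <- array(0, dim = c(height, width, 3))
    for (k in 1:3) {
      ch <- matrix(bg[k], height, width)
      if (noise_sd > 0) {
        ch <- ch + matrix(stats::rnorm(height * width, 0, noise_sd),
                          height, width)
      }
      ch[mask] <- rgb_leaf[[k]]
      px[, , k] <- pmin(1, pmax(0, ch))
    }
    leaf_image(px, mask = mask, source = NA_character_,
               meta = list(target_mean_dgci = target_mean_dgci, seed = seed))
  })
}

#' Generate a daily weather series
#'
#' Simple seasonal presets for a subtropical site. The `"kharif"`
#' (monsoon season) preset keeps every day's mean temperature well
#' above a 10 degree C maize base, so the count of positive-GDD days
#' equals the series length; the `"winter"` preset produces some days
#' below base.
#'
#' @param n_days Number of days, >= 1.
#' @param preset `"kharif"` or `"winter"`.
#' @param start_date First day of the series (typically the day after
#'   sowing).
#' @param seed Integer seed.
#' @return Data frame with columns `date`, `tmax_c`, `tmin_c`
#'   (`tmax_c >= tmin_c` on every day).
#' @export
make_weather <- function(n_days, preset = c("kharif", "winter"),
                         start_date = NULL, seed = 1) {
  preset <- match.arg(preset)
  if (n_days < 1) stop_domain("`n_days` must be >= 1")
  if (is.null(start_date)) {
    start_date <- switch(preset, kharif = "2023-07-05", winter = "2023-12-01")
  }
  with_seed(seed, {
    tmin <- switch(preset,
      kharif = stats::rnorm(n_days, 26, 1.5),
      winter = stats::rnorm(n_days, 5, 3)
    )
    tmax <- tmin + stats::runif(n_days, 6, 10)
    if (preset == "kharif") tmin <- pmax(tmin, 15) # monsoon nights stay warm
    data.frame(
      date = seq(as.Date(start_date), by = "day", length.out = n_days),
      tmax_c = round(tmax, 1),
      tmin_c = round(tmin, 1)
    )
  })
}

#' Generate a power-law calibration trial
#'
#' Emulates a multi-rate N trial: INSEY values spread over a range, and
#' grain yields on the power law `a_true * insey^b_true` with
#' multiplicative lognormal noise. At zero noise the points lie exactly
#' on the law.
#'
#' @param a_true,b_true True power-law parameters (`a_true > 0`).
#' @param n_plots Number of plots, >= 3.
#' @param noise_sd_log Sd of the lognormal yield noise (log scale).
#' @param insey_range Length-2 positive increasing range of INSEY.
#' @param stage_das Sensing stage label for the rows.
#' @param seed Integer seed.
#' @return Data frame with columns `plot_id`, `stage_das`, `insey`,
#'   `grain_yield_t_ha`.
#' @export
make_trial <- function(a_true = 300, b_true = 0.9, n_plots = 35,
                       noise_sd_log = 0.1, insey_range = c(0.004, 0.02),
                       stage_das = 35, seed = 1) {
  check_number(a_true, "a_true", 0, Inf, strict_min = TRUE)
  if (n_plots < 3) stop_domain("`n_plots` must be >= 3")
  if (length(insey_range) != 2 || insey_range[1] <= 0 ||
      insey_range[2] <= insey_range[1]) {
    stop_domain("`insey_range` must be positive and increasing")
  }
  with_seed(seed, {
    x <- sort(stats::runif(n_plots, insey_range[1], insey_range[2]))
    y <- a_true * x^b_true
    if (noise_sd_log > 0) {
      y <- y * exp(stats::rnorm(n_plots, 0, noise_sd_log))
    }
    data.frame(
      plot_id = sprintf("P%02d", seq_len(n_plots)),
      stage_das = stage_das, insey = x, grain_yield_t_ha = y
    )
  })
}

#' Default validation-experiment target indices
#'
#' The six treatments of the validation design — an unfertilized
#' control, 50 or 75 kg/ha basal N with two image-based (App) or
#' optical-sensor (GS) guided splits, and the blanket recommended dose
#' (RDF) — with the target index values the generator reproduces.
#' Fertilizer N totals are basal plus the two reported splits. Index
#' targets use published field-scale values where available; the
#' remaining entries are fixed plausible values at the same scale (see
#' the methods vignette for the reconciliation).
#'
#' @return Data frame with one row per treatment: `treatment`,
#'   `fertilizer_n_kg_ha`, `pnb`, `iue`, `vnf`, `hi_pct`,
#'   `shelling_pct`, `ghgi`, `eco_energy`, `eco_ghg`, `cost_usd_ha`.
#' @export
default_validation_targets <- function() {
  data.frame(
    treatment = c("N0PK", "N50PK+App", "N50PK+GS", "N75PK+App",
                  "N75PK+GS", "RDF"),
    fertilizer_n_kg_ha = c(0, 50 + 41.9 + 30, 50 + 39.4 + 36.4,
                           75 + 58.6 + 41.2, 75 + 35.6 + 33.7, 150),
    pnb = c(NA, 1.19, 1.12, 0.87, 1.05, 1.18),
    iue = c(45, 44, 43, 40, 41.5, 42),
    vnf = c(NA, 0.45, 0.63, 0.82, 0.67, 0.38),
    hi_pct = c(27.6, 35.13, 34.5, 33.3, 34.2, 34.8),
    shelling_pct = c(67.75, 76.88, 75, 74, 74.5, 75.5),
    ghgi = c(45, 52.875, 59.3, 86.925, 66.9, 75),
    eco_energy = c(0.094, 0.116, 0.110, 0.098, 0.105, 0.104),
    eco_ghg = c(0.55, 0.85, 0.78, 0.72, 0.76, 0.75),
    cost_usd_ha = c(925, 996, 1035, 1010, 1045, 1000)
  )
}

build_validation_rows <- function(targets, soil_n_supply, grain_price_usd_t) {
  t <- targets
  if (any(t$hi_pct <= 0 | t$hi_pct >= 100, na.rm = TRUE)) {
    stop_domain("inconsistent targets: harvest index must lie in (0, 100)")
  }
  if (any(t$shelling_pct <= 0 | t$shelling_pct > 100, na.rm = TRUE)) {
    stop_domain("inconsistent targets: shelling percent must lie in (0, 100]")
  }
  if (any(t$hi_pct >= t$shelling_pct, na.rm = TRUE)) {
    stop_domain("inconsistent targets: harvest index must be below shelling percent (stover would be non-positive)")
  }
  fert <- t$fertilizer_n_kg_ha > 0
  uptake <- ifelse(fert, t$pnb * t$fertilizer_n_kg_ha, soil_n_supply)
  grain_kg <- t$iue * uptake
  grain_t <- grain_kg / 1000
  biological_t <- grain_t * 100 / t$hi_pct
  cob_t <- grain_t * 100 / t$shelling_pct
  stover_t <- biological_t - cob_t
  loss <- (t$fertilizer_n_kg_ha + soil_n_supply) - uptake
  grain_nup <- ifelse(fert, loss / t$vnf, 0.75 * uptake)
  if (any(grain_nup <= 0 | grain_nup > uptake)) {
    stop_domain("inconsistent targets: implied grain N uptake falls outside (0, total uptake]")
  }
  grain_n_pct <- 100 * grain_nup / grain_kg
  stover_n_pct <- 100 * (uptake - grain_nup) / (stover_t * 1000)
  gross <- grain_price_usd_t * grain_t
  data.frame(
    treatment = t$treatment,
    fertilizer_n_kg_ha = t$fertilizer_n_kg_ha,
    grain_yield_t_ha = grain_t,
    cob_yield_t_ha = cob_t,
    stover_yield_t_ha = stover_t,
    biological_yield_t_ha = biological_t,
    grain_n_pct = grain_n_pct,
    stover_n_pct = stover_n_pct,
    cost_usd_ha = t$cost_usd_ha,
    gross_return_usd_ha = gross,
    energy_input_mj_ha = gross / t$eco_energy,
    ghg_kg_co2eq_ha = gross / t$eco_ghg,
    n2o_kg_co2eq_ha = t$ghgi * grain_t
  )
}

#' Generate a validation plot table from target index values
#'
#' Works backwards from target indices to raw plot quantities: total
#' uptake from the partial N balance, grain yield from internal
#' utilization efficiency, biological and cob yields from harvest index
#' and shelling percent, grain N concentration from the virtual N
#' factor, emissions from GHG intensity, and energy/GHG totals from the
#' eco-efficiency targets. Re-running [compute_metrics()] on the
#' zero-noise table therefore reproduces the target index vector
#' exactly. With `replicates > 1` and `noise_sd > 0`, each replicate
#' jitters the targets multiplicatively (lognormal), so replicate means
#' scatter around the targets.
#'
#' @param targets Target table as [default_validation_targets()].
#' @param soil_n_supply Soil N supply, taken as the control plot's
#'   total uptake, kg/ha.
#' @param grain_price_usd_t Grain price used for gross returns,
#'   currency per tonne.
#' @param replicates Number of replicate rows per treatment.
#' @param noise_sd Lognormal sd of the per-replicate target jitter.
#' @param seed Integer seed.
#' @return Plot table in [read_plot_csv()] layout (plus a `replicate`
#'   column when `replicates > 1`).
#' @export
make_validation_table <- function(targets = default_validation_targets(),
                                  soil_n_supply = 60,
                                  grain_price_usd_t = 185,
                                  replicates = 1, noise_sd = 0, seed = 13) {
  if (replicates < 1) stop_domain("`replicates` must be >= 1")
  check_number(noise_sd, "noise_sd", 0, 0.2)
  if (replicates == 1 || noise_sd == 0) {
    out <- do.call(rbind, replicate(
      replicates,
      build_validation_rows(targets, soil_n_supply, grain_price_usd_t),
      simplify = FALSE
    ))
    if (replicates > 1) {
      out <- cbind(out, replicate = rep(seq_len(replicates),
                                        each = nrow(targets)))
    }
    rownames(out) <- NULL
    return(out)
  }
  with_seed(seed, {
    jitter_cols <- c("pnb", "iue", "vnf", "hi_pct", "shelling_pct",
                     "ghgi", "eco_energy", "eco_ghg")
    reps <- lapply(seq_len(replicates), function(r) {
      t <- targets
      for (col in jitter_cols) {
        t[[col]] <- t[[col]] * exp(stats::rnorm(nrow(t), 0, noise_sd))
      }
      rows <- build_validation_rows(t, soil_n_supply, grain_price_usd_t)
      rows$replicate <- r
      rows
    })
    out <- do.call(rbind, reps)
    rownames(out) <- NULL
    out
  })
}
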