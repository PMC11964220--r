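# Treatment-level metrics report over a validation plot table.

#' Compute all evaluation metrics for a plot table
#'
#' Takes one row per plot (or per treatment mean) and computes every
#' index: grain/stover/total N uptake, shelling percentage, harvest
#' index, physiological efficiency, partial N balance, internal
#' utilization efficiency, virtual N factor and N loss, GHG intensity
#' of N2O, both eco-efficiency indices, and cost saving over the
#' reference. Two-plot contrasts (physiological efficiency, soil N
#' supply for the virtual N factor) use the designated unfertilized
#' control; relative-difference columns compare each treatment against
#' the designated reference (conventionally the blanket RDF schedule).
#' Indices that are undefined for a row (e.g. partial N balance on the
#' control) come back as `NA`.
#'
#' When the table carries a `replicate` column, rows are first averaged
#' by treatment.
#'
#' @param plots Data frame with columns `treatment`,
#'   `fertilizer_n_kg_ha`, `grain_yield_t_ha`, `cob_yield_t_ha`,
#'   `stover_yield_t_ha`, `biological_yield_t_ha`, `grain_n_pct`,
#'   `stover_n_pct`, `cost_usd_ha`, `gross_return_usd_ha`,
#'   `energy_input_mj_ha`, `ghg_kg_co2eq_ha`, `n2o_kg_co2eq_ha`.
#'   Missing numeric cells are allowed and propagate as `NA`.
#' @param control Treatment label of the unfertilized control.
#' @param reference Optional treatment label of the reference schedule
#'   for cost-saving and relative-difference columns.
#' @return Data frame, one row per treatment, with the index columns
#'   and (when `reference` is given) `rel_*_pct` columns.
#' @export
compute_metrics <- function(plots, control, reference = NULL) {
  need <- c("treatment", "fertilizer_n_kg_ha", "grain_yield_t_ha",
            "cob_yield_t_ha", "stover_yield_t_ha", "biological_yield_t_ha",
            "grain_n_pct", "stover_n_pct", "cost_usd_ha",
            "gross_return_usd_ha", "energy_input_mj_ha",
            "ghg_kg_co2eq_ha", "n2o_kg_co2eq_ha")
  miss <- setdiff(need, names(plots))
  if (length(miss) > 0) {
    stop_input(sprintf("plot table lacks column(s): %s",
                       paste(miss, collapse = ", ")))
  }
  if ("replicate" %in% names(plots)) {
    num <- setdiff(need, "treatment")
    plots <- stats::aggregate(
      plots[num], by = list(treatment = plots$treatment),
      FUN = mean, na.rm = TRUE
    )
  }
  if (!control %in% plots$treatment) {
    stop_input(sprintf("control treatment `%s` not found in the table", control))
  }
  p <- plots
  grain_kg <- p$grain_yield_t_ha * 1000
  stover_kg <- p$stover_yield_t_ha * 1000
  p$grain_n_uptake_kg_ha <- n_uptake(p$grain_n_pct, grain_kg)
  p$stover_n_uptake_kg_ha <- n_uptake(p$stover_n_pct, stover_kg)
  p$total_n_uptake_kg_ha <- p$grain_n_uptake_kg_ha + p$stover_n_uptake_kg_ha
  p$shelling_pct <- 100 * p$grain_yield_t_ha / p$cob_yield_t_ha
  p$harvest_index_pct <- 100 * p$grain_yield_t_ha / p$biological_yield_t_ha

  ci <- match(control, p$treatment)
  uptake_c <- p$total_n_uptake_kg_ha[ci]
  grain_c_kg <- grain_kg[ci]
  fertilized <- p$fertilizer_n_kg_ha > 0

  du <- p$total_n_uptake_kg_ha - uptake_c
  p$pe_n <- ifelse(fertilized & du != 0, (grain_kg - grain_c_kg) / du, NA_real_)
  p$pnb_n <- partial_n_balance(p$total_n_uptake_kg_ha, p$fertilizer_n_kg_ha)
  p$iue_n <- internal_utilization_efficiency(grain_kg, p$total_n_uptake_kg_ha)
  loss <- (p$fertilizer_n_kg_ha + uptake_c) - p$total_n_uptake_kg_ha
  p$n_loss_kg_ha <- ifelse(fertilized, loss, NA_real_)
  p$vnf <- ifelse(fertilized, loss / p$grain_n_uptake_kg_ha, NA_real_)
  p$ghgi_n2o_kg_co2eq_t <- ghgi_n2o(p$n2o_kg_co2eq_ha, p$grain_yield_t_ha)
  p$eco_eff_energy <- eco_efficiency(p$gross_return_usd_ha,
                                     p$energy_input_mj_ha, "energy")
  p$eco_eff_ghg <- eco_efficiency(p$gross_return_usd_ha,
                                  p$ghg_kg_co2eq_ha, "ghg")

  if (!is.null(reference)) {
    if (!reference %in% p$treatment) {
      stop_input(sprintf("reference treatment `%s` not found in the table",
                         reference))
    }
    ri <- match(reference, p$treatment)
    p$cost_saving_usd_ha <- cost_saving_over_reference(
      p$cost_usd_ha, p$cost_usd_ha[ri]
    )
    for (col in c("grain_yield_t_ha", "harvest_index_pct",
                  "ghgi_n2o_kg_co2eq_t", "eco_eff_energy", "eco_eff_ghg")) {
      ref_val <- p[[col]][ri]
      p[[paste0("rel_", col, "_pct")]] <-
        if (!is.na(ref_val) && ref_val != 0) {
          relative_difference_pct(p[[col]], ref_val)
        } else NA_real_
    }
  }
  p
}
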