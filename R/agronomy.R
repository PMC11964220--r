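# Agronomic evaluation metrics: growth indices, yield ratios, N uptake,
# nitrogen-use-efficiency indices, GHG intensity, cost and
# eco-efficiency accounting.
#
# Indices that are undefined for a given plot (e.g. partial N balance on
# an unfertilized control) return NA, never 0: a control row legitimately
# lacks them.

#' Leaf area index
#'
#' Leaf area per plant divided by the land area per plant (planting
#' geometry), both in cm^2.
#'
#' @param leaf_area_cm2 Leaf area per plant, cm^2, > 0.
#' @param geometry_cm2 Planting geometry (land area per plant), cm^2,
#'   > 0; 60 cm x 20 cm spacing gives 1200.
#' @return Dimensionless LAI.
#' @examples
#' leaf_area_index(1440, 1200) # 1.2
#' @export
leaf_area_index <- function(leaf_area_cm2, geometry_cm2) {
  check_number(geometry_cm2, "geometry_cm2", 0, Inf, strict_min = TRUE)
  check_number(leaf_area_cm2, "leaf_area_cm2", 0, Inf, strict_min = TRUE)
  leaf_area_cm2 / geometry_cm2
}

#' Crop growth rate
#'
#' `CGR = (W2 - W1) / (T2 - T1) * 1/A`: dry-matter gain per unit land
#' area and time.
#'
#' @param w1,w2 Plant dry weight (g) at the start and end of the
#'   interval, > 0.
#' @param t1,t2 Interval bounds, days after sowing, `t2 > t1`.
#' @param area Land area occupied per plant, m^2, > 0.
#' @return g/m^2/day.
#' @export
crop_growth_rate <- function(w1, w2, t1, t2, area) {
  check_number(w1, "w1", 0, Inf, strict_min = TRUE)
  check_number(w2, "w2", 0, Inf, strict_min = TRUE)
  check_number(area, "area", 0, Inf, strict_min = TRUE)
  if (any(t2 <= t1)) stop_domain("`t2` must be after `t1`")
  (w2 - w1) / (t2 - t1) / area
}

#' Relative growth rate
#'
#' `RGR = (ln W2 - ln W1) / (T2 - T1)`: dry-matter gain per unit of
#' existing dry matter. Scale-invariant in the weights.
#'
#' @inheritParams crop_growth_rate
#' @return g/g/day.
#' @export
relative_growth_rate <- function(w1, w2, t1, t2) {
  check_number(w1, "w1", 0, Inf, strict_min = TRUE)
  check_number(w2, "w2", 0, Inf, strict_min = TRUE)
  if (any(t2 <= t1)) stop_domain("`t2` must be after `t1`")
  (log(w2) - log(w1)) / (t2 - t1)
}

#' Shelling percentage
#'
#' Grain yield as a percentage of cob yield.
#'
#' @param grain_t_ha Grain yield, t/ha, `<= cob_t_ha`.
#' @param cob_t_ha Cob yield, t/ha, > 0.
#' @return Percent.
#' @export
shelling_percent <- function(grain_t_ha, cob_t_ha) {
  check_number(cob_t_ha, "cob_t_ha", 0, Inf, strict_min = TRUE)
  if (any(grain_t_ha > cob_t_ha)) {
    stop_domain("grain yield cannot exceed cob yield")
  }
  100 * grain_t_ha / cob_t_ha
}

#' Harvest index
#'
#' Grain yield as a percentage of total above-ground biological yield.
#'
#' @param grain_t_ha Grain yield, t/ha, > 0.
#' @param biological_t_ha Biological (cob + stover) yield, t/ha,
#'   `>= grain_t_ha`.
#' @return Percent.
#' @export
harvest_index <- function(grain_t_ha, biological_t_ha) {
  check_number(grain_t_ha, "grain_t_ha", 0, Inf, strict_min = TRUE)
  if (any(biological_t_ha < grain_t_ha)) {
    stop_domain("biological yield must be >= grain yield")
  }
  100 * grain_t_ha / biological_t_ha
}

#' Standardize grain weight to a target moisture content
#'
#' Dry-matter conservation: the field weight is scaled by
#' `(100 - field_moisture) / (100 - target_moisture)`. Grain yields are
#' conventionally reported at 14.5% moisture.
#'
#' @param field_weight Weight as harvested (any mass unit).
#' @param field_moisture_pct Moisture at weighing, percent, in
#'   `[0, 100)`.
#' @param target_pct Reporting moisture, percent, in `[0, 100)`.
#' @return Standardized weight in the input unit.
#' @export
standardize_grain_moisture <- function(field_weight, field_moisture_pct,
                                       target_pct = 14.5) {
  check_number(field_moisture_pct, "field_moisture_pct", 0, 100,
               strict_max = TRUE)
  check_number(target_pct, "target_pct", 0, 100, strict_max = TRUE)
  field_weight * (100 - field_moisture_pct) / (100 - target_pct)
}

#' Nitrogen uptake
#'
#' N concentration (percent) times dry yield (kg/ha). Total plant uptake
#' is the sum of the grain and stover components.
#'
#' @param n_pct N concentration, percent, in `[0, 100]`.
#' @param yield_kg_ha Yield of the component, kg/ha.
#' @return kg N/ha.
#' @examples
#' n_uptake(1.73, 5000) # 86.5
#' @export
n_uptake <- function(n_pct, yield_kg_ha) {
  check_number(n_pct, "n_pct", 0, 100)
  n_pct / 100 * yield_kg_ha
}

#' Total plant N uptake (grain + stover)
#'
#' @param grain_n_pct,stover_n_pct N concentrations, percent.
#' @param grain_kg_ha,stover_kg_ha Dry yields, kg/ha.
#' @return kg N/ha.
#' @export
total_n_uptake <- function(grain_n_pct, grain_kg_ha,
                           stover_n_pct, stover_kg_ha) {
  n_uptake(grain_n_pct, grain_kg_ha) + n_uptake(stover_n_pct, stover_kg_ha)
}

#' Physiological efficiency of nitrogen
#'
#' Extra grain per extra unit of plant N uptake, relative to an
#' unfertilized control:
#' `(grain_yield_N - grain_yield_C) / (uptake_N - uptake_C)`, yields in
#' kg/ha.
#'
#' @param grain_yield_n_kg_ha,grain_yield_c_kg_ha Grain yield of the
#'   fertilized plot and the control, kg/ha.
#' @param uptake_n_kg_ha,uptake_c_kg_ha Total N uptake of the fertilized
#'   plot and the control, kg/ha.
#' @return kg grain per kg N uptake; `NA` when the uptake difference is
#'   zero (the index is undefined).
#' @export
physiological_efficiency <- function(grain_yield_n_kg_ha, grain_yield_c_kg_ha,
                                     uptake_n_kg_ha, uptake_c_kg_ha) {
  du <- uptake_n_kg_ha - uptake_c_kg_ha
  out <- ifelse(du == 0, NA_real_,
                (grain_yield_n_kg_ha - grain_yield_c_kg_ha) / du)
  if (anyNA(out)) warning("zero uptake difference: physiological efficiency undefined")
  out
}

#' Partial nitrogen balance
#'
#' Total plant N uptake divided by fertilizer N applied. Values above 1
#' suggest soil N drawdown ("soil mining").
#'
#' @param total_uptake_n_kg_ha Total N uptake, kg/ha.
#' @param f_n_kg_ha Fertilizer N applied, kg/ha.
#' @return Dimensionless; `NA` for unfertilized plots.
#' @export
partial_n_balance <- function(total_uptake_n_kg_ha, f_n_kg_ha) {
  ifelse(f_n_kg_ha > 0, total_uptake_n_kg_ha / f_n_kg_ha, NA_real_)
}

#' Internal utilization efficiency of nitrogen
#'
#' Grain yield per unit total plant N uptake.
#'
#' @param grain_yield_kg_ha Grain yield, kg/ha.
#' @param total_uptake_n_kg_ha Total N uptake, kg/ha.
#' @return kg grain per kg N; `NA` at zero uptake.
#' @export
internal_utilization_efficiency <- function(grain_yield_kg_ha,
                                            total_uptake_n_kg_ha) {
  ifelse(total_uptake_n_kg_ha > 0,
         grain_yield_kg_ha / total_uptake_n_kg_ha, NA_real_)
}

#' Virtual nitrogen factor and environmental N loss
#'
#' N loss to the environment is the difference between N input
#' (fertilizer plus soil N supply) and N output (total plant uptake);
#' the virtual N factor divides that loss by grain N uptake. The total N
#' uptake of the unfertilized control plot is taken as the soil N
#' supply. A negative loss (apparent net soil mining) is returned as is,
#' with a warning, rather than clamped.
#'
#' @param f_n_kg_ha Fertilizer N applied, kg/ha.
#' @param soil_n_supply_kg_ha Soil N supply (control plot's total
#'   uptake), kg/ha.
#' @param total_uptake_n_kg_ha Total plant N uptake, kg/ha.
#' @param grain_n_uptake_kg_ha Grain N uptake, kg/ha, > 0.
#' @return List with `n_loss` (kg/ha) and `vnf` (dimensionless).
#' @export
virtual_n_factor <- function(f_n_kg_ha, soil_n_supply_kg_ha,
                             total_uptake_n_kg_ha, grain_n_uptake_kg_ha) {
  check_number(grain_n_uptake_kg_ha, "grain_n_uptake_kg_ha", 0, Inf,
               strict_min = TRUE)
  n_loss <- (f_n_kg_ha + soil_n_supply_kg_ha) - total_uptake_n_kg_ha
  if (any(n_loss < 0)) {
    warning("negative N loss: uptake exceeds fertilizer + soil supply (apparent soil mining)")
  }
  list(n_loss = n_loss, vnf = n_loss / grain_n_uptake_kg_ha)
}

#' Greenhouse-gas intensity of N2O
#'
#' Yield-scaled N2O emission: kg CO2-equivalents per tonne of grain.
#'
#' @param n2o_kg_co2eq_ha N2O emission, kg CO2-eq/ha.
#' @param grain_yield_t_ha Grain yield, t/ha.
#' @return kg CO2-eq/t; `NA` at zero yield.
#' @export
ghgi_n2o <- function(n2o_kg_co2eq_ha, grain_yield_t_ha) {
  ifelse(grain_yield_t_ha > 0, n2o_kg_co2eq_ha / grain_yield_t_ha, NA_real_)
}

#' Eco-efficiency index
#'
#' Gross economic return per unit of environmental pressure: per MJ of
#' total energy input (`kind = "energy"`) or per kg CO2-eq of GHG
#' emission (`kind = "ghg"`).
#'
#' @param gross_return Gross return, currency/ha.
#' @param denominator Total energy input (MJ/ha) or GHG emission
#'   (kg CO2-eq/ha), depending on `kind`.
#' @param kind `"energy"` or `"ghg"` (labelling only; the arithmetic is
#'   the same ratio).
#' @return Currency per MJ or per kg CO2-eq; `NA` at zero denominator.
#' @export
eco_efficiency <- function(gross_return, denominator,
                           kind = c("energy", "ghg")) {
  match.arg(kind)
  ifelse(denominator > 0, gross_return / denominator, NA_real_)
}

#' Cost saving over a reference treatment
#'
#' Difference in cost of cultivation, reference minus treatment;
#' positive values are savings.
#'
#' @param cost_treatment,cost_reference Costs, currency/ha.
#' @return Currency/ha.
#' @export
cost_saving_over_reference <- function(cost_treatment, cost_reference) {
  cost_reference - cost_treatment
}

#' Tier-1-style N2O emission stand-in
#'
#' A clearly labelled simple estimator — emission factor times applied
#' N, converted N2O-N -> N2O by 44/28 and to CO2-equivalents by a global
#' warming potential — for users who have no process-based emission
#' model output at hand. It is plumbing, not a reproduction of any
#' full farm emission model, and its defaults (EF 0.01, GWP 273) follow
#' common Tier-1 practice.
#'
#' @param f_n_kg_ha Fertilizer N applied, kg/ha.
#' @param ef Fraction of applied N emitted as N2O-N.
#' @param gwp Global warming potential of N2O (CO2-eq per kg N2O).
#' @return kg CO2-eq/ha.
#' @export
estimate_n2o_tier1 <- function(f_n_kg_ha, ef = 0.01, gwp = 273) {
  check_number(ef, "ef", 0, 1)
  f_n_kg_ha * ef * 44 / 28 * gwp
}
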