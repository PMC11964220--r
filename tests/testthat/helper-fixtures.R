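# Shared fixtures, built in code at test time.

# A monsoon-season thermal context with exactly `n_days` positive-GDD days.
fixture_context <- function(n_days = 35, seed = 1) {
  w <- make_weather(n_days, "kharif", seed = seed)
  thermal_context(w, as.Date(w$date[1]) - 1, w$date[n_days])
}

# A noiseless calibration with known constants.
fixture_model <- function(a = 300, b = 0.9, stage = 35) {
  tr <- make_trial(a_true = a, b_true = b, noise_sd_log = 0, stage_das = stage,
                   seed = 2)
  fit_power_function(tr$insey, tr$grain_yield_t_ha, stage_das = stage)
}

# Independent hand composition of the five-step prescription chain,
# written against the formulas, not the package path.
manual_dose <- function(dgci_test, dgci_enrich, n_pos_days, a, b,
                        grain_n_pct = 1.43, efficiency = 0.5) {
  ins <- dgci_test / n_pos_days
  yp0 <- a * ins^b
  ri <- dgci_enrich / dgci_test
  ypn <- yp0 * ri
  round(max(0, 10 * grain_n_pct * (ypn - yp0) / efficiency), 1)
}
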