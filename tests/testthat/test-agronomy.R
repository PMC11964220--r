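# Growth indices, yield ratios, N uptake, NUE indices, GHG intensity,
# energy and eco-efficiency accounting.

test_that("growth indices match hand arithmetic and basic properties", {
  expect_equal(leaf_area_index(1440, 1200), 1.2)
  expect_equal(leaf_area_index(5040, 1200), 4.2)
  expect_error(leaf_area_index(1000, 0), class = "maizeNrec_domain_error")

  expect_equal(crop_growth_rate(20, 80, 0, 30, 0.12), 60 / 30 / 0.12)
  expect_equal(crop_growth_rate(20, 20, 0, 30, 0.12), 0)
  expect_equal(crop_growth_rate(20, 80, 0, 30, 0.06),
               2 * crop_growth_rate(20, 80, 0, 30, 0.12))
  expect_error(crop_growth_rate(20, 80, 30, 30, 0.12),
               class = "maizeNrec_domain_error")

  expect_equal(relative_growth_rate(20, 80, 0, 30), log(4) / 30)
  expect_equal(relative_growth_rate(20, 20, 0, 30), 0)
  expect_equal(relative_growth_rate(20, 80, 0, 30),
               relative_growth_rate(200, 800, 0, 30)) # scale invariance
  expect_error(relative_growth_rate(0, 80, 0, 30),
               class = "maizeNrec_domain_error")
})

test_that("shelling percent and harvest index are bounded ratios", {
  expect_equal(shelling_percent(5, 6.5), 100 * 5 / 6.5)
  expect_equal(shelling_percent(5, 6.5), 76.92, tolerance = 1e-3)
  expect_equal(shelling_percent(6, 6), 100)
  expect_equal(shelling_percent(0, 5), 0)
  expect_error(shelling_percent(7, 6.5), class = "maizeNrec_domain_error")

  expect_equal(harvest_index(3.5, 10), 35)
  expect_equal(harvest_index(5, 14.25), 35.09, tolerance = 1e-3)
  expect_equal(harvest_index(10, 10), 100)
  expect_error(harvest_index(11, 10), class = "maizeNrec_domain_error")

  # bounded on random valid inputs
  set.seed(1)
  g <- runif(50, 1, 8)
  biol <- g + runif(50, 0, 15)
  cob <- g + runif(50, 0, 3)
  expect_true(all(harvest_index(g, biol) <= 100))
  expect_true(all(shelling_percent(g, cob) <= 100))
})

test_that("moisture standardization conserves dry matter", {
  expect_equal(standardize_grain_moisture(1000, 20), 1000 * 80 / 85.5)
  expect_equal(standardize_grain_moisture(1000, 20), 935.67, tolerance = 1e-2)
  expect_equal(standardize_grain_moisture(1234, 14.5), 1234)
  expect_equal(standardize_grain_moisture(855, 0), 855 * 100 / 85.5)
  expect_error(standardize_grain_moisture(1000, 20, target_pct = 100),
               class = "maizeNrec_domain_error")
})

test_that("N uptake is concentration times yield and additive over components", {
  expect_equal(n_uptake(1.73, 5000), 86.5)
  expect_equal(n_uptake(0, 5000), 0)
  expect_equal(total_n_uptake(1.73, 5000, 0.46, 8000),
               n_uptake(1.73, 5000) + n_uptake(0.46, 8000))
})

test_that("NUE indices follow their defining ratios", {
  expect_equal(physiological_efficiency(6000, 3000, 135, 60), 40)
  expect_equal(physiological_efficiency(3000, 3000, 135, 60), 0)
  expect_warning(out <- physiological_efficiency(6000, 3000, 60, 60))
  expect_true(is.na(out))

  expect_equal(partial_n_balance(120, 100), 1.2)
  expect_equal(partial_n_balance(100, 100), 1)
  expect_equal(partial_n_balance(145.1, 121.9), 1.19, tolerance = 1e-2)
  expect_true(is.na(partial_n_balance(120, 0)))

  expect_equal(internal_utilization_efficiency(6000, 150), 40)
  expect_equal(internal_utilization_efficiency(5500, 120), 45.83,
               tolerance = 1e-3)
  expect_equal(internal_utilization_efficiency(6000, 150),
               internal_utilization_efficiency(12000, 300)) # scale invariant
  expect_true(is.na(internal_utilization_efficiency(6000, 0)))
})

test_that("virtual N factor divides the input-output N gap by grain uptake", {
  out <- virtual_n_factor(100, 50, 120, 100)
  expect_equal(out$n_loss, 30)
  expect_equal(out$vnf, 0.3)
  z <- virtual_n_factor(70, 50, 120, 100)
  expect_equal(z$vnf, 0)
  # doubling the loss at fixed grain uptake doubles VNF
  d <- virtual_n_factor(130, 50, 120, 100)
  expect_equal(d$vnf, 2 * out$vnf)
  # negative loss returned with a warning, not clamped
  expect_warning(neg <- virtual_n_factor(40, 50, 120, 100), "mining")
  expect_equal(neg$n_loss, -30)
})

test_that("GHGI and eco-efficiency are simple intensity ratios", {
  expect_equal(ghgi_n2o(300, 5), 60)
  expect_equal(ghgi_n2o(0, 5), 0)
  expect_equal(ghgi_n2o(300, 2.5), 2 * ghgi_n2o(300, 5))
  expect_true(is.na(ghgi_n2o(300, 0)))
  # GHGI times yield reconstructs the emission input
  set.seed(2)
  em <- runif(20, 100, 600); y <- runif(20, 2, 8)
  expect_equal(ghgi_n2o(em, y) * y, em, tolerance = 1e-12)

  expect_equal(eco_efficiency(1160, 10000, "energy"), 0.116)
  expect_equal(eco_efficiency(850, 1000, "ghg"), 0.85)
  expect_equal(eco_efficiency(2 * 850, 1000, "ghg"), 2 * 0.85)
  expect_true(is.na(eco_efficiency(850, 0, "ghg")))
})

test_that("cost saving and relative difference behave as signed comparisons", {
  expect_equal(cost_saving_over_reference(996, 1000), 4)
  expect_equal(cost_saving_over_reference(1000, 1000), 0)
  expect_equal(cost_saving_over_reference(1000, 996),
               -cost_saving_over_reference(996, 1000))

  expect_equal(relative_difference_pct(1.40, 1.18), 18.6)
  expect_equal(relative_difference_pct(0.85, 0.75), 13.3)
  expect_equal(relative_difference_pct(3, 3), 0)
  expect_error(relative_difference_pct(1, 0), class = "maizeNrec_domain_error")
})

test_that("energy accounting partitions direct/indirect and renewable/non-renewable", {
  coefs <- demo_energy_coefficients()
  single <- energy_input(data.frame(item = "fertilizer_n", quantity = 100),
                         coefs)
  expect_equal(single$total_mj,
               100 * coefs$mj_per_unit[coefs$item == "fertilizer_n"])

  inv <- data.frame(
    item = c("human_labour", "diesel", "maize_seed", "fertilizer_n",
             "machinery"),
    quantity = c(400, 60, 20, 150, 15)
  )
  e <- energy_input(inv, coefs)
  expect_equal(e$direct_mj + e$indirect_mj, e$total_mj, tolerance = 1e-9)
  expect_equal(e$renewable_mj + e$nonrenewable_mj, e$total_mj,
               tolerance = 1e-9)
  expect_equal(e$renewable_mj, 400 * 1.96 + 20 * 14.7)

  empty <- energy_input(data.frame(item = character(), quantity = numeric()),
                        coefs)
  expect_equal(empty$total_mj, 0)
  expect_error(
    energy_input(data.frame(item = "unobtainium", quantity = 1), coefs),
    "unobtainium", class = "maizeNrec_input_error"
  )
})

test_that("indices are unchanged by consistent unit conversion", {
  # PNB, IUE, HI, shelling only see ratios: t/ha vs kg/ha with matched
  # units must agree
  g_t <- 6.2; up <- 140; f <- 120
  expect_equal(internal_utilization_efficiency(g_t * 1000, up),
               1000 * internal_utilization_efficiency(g_t, up))
  expect_equal(harvest_index(g_t, 17.5), harvest_index(g_t * 1000, 17500))
  expect_equal(shelling_percent(g_t, 8), shelling_percent(g_t * 1000, 8000))
  expect_equal(partial_n_balance(up, f), partial_n_balance(up * 1, f * 1))
})

test_that("the Tier-1 N2O stand-in scales linearly with applied N", {
  expect_equal(estimate_n2o_tier1(0), 0)
  expect_equal(estimate_n2o_tier1(100), 100 * 0.01 * 44 / 28 * 273)
  expect_equal(estimate_n2o_tier1(200), 2 * estimate_n2o_tier1(100))
})
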