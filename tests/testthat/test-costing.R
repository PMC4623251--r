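test_that("bundle unit costs are quantity-weighted sums of ingredient prices", {
  empty <- cost_bundle("empty", NULL)
  expect_equal(unit_cost_from_bundle(empty), 0)
  one <- cost_bundle("one", data.frame(label = "x", quantity = 3,
                                       unit_price = 10))
  expect_equal(unit_cost_from_bundle(one), 30)
  expect_error(cost_bundle("bad", data.frame(label = "x", quantity = -1,
                                             unit_price = 10)), ">= 0")
})

test_that("bundled ingredient fixtures sum to the published aggregate unit costs", {
  bundles <- load_cost_bundles()
  expect_equal(unit_cost_from_bundle(bundles$wound_management), 79)
  expect_equal(unit_cost_from_bundle(bundles$debridement), 1022)
  expect_equal(unit_cost_from_bundle(bundles$minor_amputation), 5153)
  expect_equal(unit_cost_from_bundle(bundles$major_amputation), 7360)
  # prevention bundles match the rounded display costs
  expect_equal(unit_cost_from_bundle(bundles$prevention_sub_optimal), 65)
  expect_equal(unit_cost_from_bundle(bundles$prevention_standard), 185)
  expect_equal(unit_cost_from_bundle(bundles$prevention_standard_plus_temp),
               406, tolerance = 1e-9)
})

test_that("prevention cost reproduces the published strategy totals", {
  expect_equal(round_half_up(prevention_cost(peru, "sub_optimal")), 13350763)
  expect_equal(round_half_up(prevention_cost(peru, "standard")), 38129966)
  expect_equal(round_half_up(prevention_cost(peru, "standard_plus_temp")),
               83849832)
  expect_equal(prevention_cost(simple_ps(total_diabetes_population = 0),
                               "standard"), 0)
})

test_that("treatment costs price each endpoint at its admission cost", {
  fl <- compute_flows(peru, "sub_optimal")
  by_ep <- treatment_cost(fl, peru)
  # published line: debridement 5,416 persons at US$1,022 -> US$5,535,166
  expect_equal(unname(by_ep["debridement"]), 5535166, tolerance = 1e-3)
  # deaths are costed at the amputation undergone
  expect_equal(unname(by_ep["death_major"]),
               fl$n_death_major_amputation * peru$cost_major_amputation)
  expect_equal(unname(by_ep["death_minor"]),
               fl$n_death_minor_amputation * peru$cost_minor_amputation)
  tmp <- total_direct_cost(peru, "standard_plus_temp")
  expect_equal(tmp$treatment_total, 12950435, tolerance = 1e-3)
  zero <- treatment_cost(compute_flows(simple_ps(baseline_ulcer_prevalence = 0),
                                       "sub_optimal"), simple_ps())
  expect_true(all(zero == 0))
})

test_that("human-capital indirect cost follows the annuity-due convention", {
  # base case: PEN 750/month at 2.64, 3 %, 2 years -> US$6,719
  expect_equal(indirect_cost_per_death(peru$economic),
               (750 / 2.64) * 12 * (1 + 1 / 1.03), tolerance = 1e-12)
  expect_equal(round_half_up(indirect_cost_per_death(peru$economic)), 6719)
  # zero discount: plain wage bill over the lost years
  econ0 <- simple_econ(discount_rate = 0, retirement_age = 65,
                       mean_age_at_death = 63)
  expect_equal(indirect_cost_per_death(econ0), 24 * 1000 / 2)
  # one lost year is never discounted
  econ1 <- simple_econ(retirement_age = 64, mean_age_at_death = 63,
                       discount_rate = 0.10)
  expect_equal(indirect_cost_per_death(econ1), 12 * 1000 / 2)
})

test_that("discounted indirect cost converges to the undiscounted bill as r -> 0", {
  undiscounted <- indirect_cost_per_death(simple_econ(discount_rate = 0))
  near_zero <- indirect_cost_per_death(simple_econ(discount_rate = 1e-10))
  expect_equal(near_zero, undiscounted, tolerance = 1e-8)
})

test_that("indirect cost is invariant to a joint currency rescaling", {
  base <- indirect_cost_per_death(simple_econ())
  scaled <- indirect_cost_per_death(
    simple_econ(minimum_wage_local = 1000 * 7.3, exchange_rate = 2 * 7.3))
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("total direct cost reproduces the published cost of illness", {
  sub <- total_direct_cost(peru, "sub_optimal")
  std <- total_direct_cost(peru, "standard")
  tmp <- total_direct_cost(peru, "standard_plus_temp")
  expect_equal(round_half_up(sub$direct_total / 1e6, 1), 74.5)
  expect_equal(round_half_up(std$direct_total / 1e6, 1), 71.8)
  expect_equal(round_half_up(tmp$direct_total / 1e6, 1), 96.8)
  # structural identities
  for (cb in list(sub, std, tmp)) {
    expect_equal(cb$treatment_total, sum(cb$treatment_by_endpoint),
                 tolerance = 1e-12)
    expect_equal(cb$direct_total, cb$prevention_total + cb$treatment_total,
                 tolerance = 1e-12)
    expect_equal(cb$indirect_total,
                 summarize_outcomes(cb$flows)$deaths *
                   indirect_cost_per_death(peru$economic),
                 tolerance = 1e-12)
  }
})

test_that("degenerate scenario with no ulcers and free prevention costs nothing", {
  ps <- simple_ps(baseline_ulcer_prevalence = 0,
                  prevention_cost_per_person = c(sub_optimal = 0, standard = 0,
                                                 standard_plus_temp = 0))
  cb <- total_direct_cost(ps, "sub_optimal")
  expect_equal(cb$direct_total, 0)
  expect_equal(cb$indirect_total, 0)
})

test_that("treatment total is linear in unit costs and monotone in prevalence", {
  set.seed(11)
  for (i in 1:20) {
    ps <- generate_parameter_set(scenario_spec(seed = i))
    cb <- total_direct_cost(ps, "sub_optimal")
    # doubling the major-amputation cost raises the total by the major spend
    ps2 <- perturb_parameter(ps, "cost_major_amputation",
                             2 * ps$cost_major_amputation)
    cb2 <- total_direct_cost(ps2, "sub_optimal")
    expect_equal(cb2$treatment_total - cb$treatment_total,
                 cb$treatment_by_endpoint[["heal_major"]] +
                   cb$treatment_by_endpoint[["death_major"]],
                 tolerance = 1e-9)
    # higher prevalence -> strictly more treatment cost (when anything is ulcerated)
    hi <- min(1, ps$baseline_ulcer_prevalence * 1.2 + 1e-6)
    cb3 <- total_direct_cost(
      perturb_parameter(ps, "baseline_ulcer_prevalence", hi), "sub_optimal")
    expect_gt(cb3$treatment_total, cb$treatment_total)
  }
})
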