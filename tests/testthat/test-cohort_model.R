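table3_counts <- list(
  # node -> published person counts (sub-optimal, standard, standard+temp)
  n_ulcerated = c(45761, 25168, 9696),
  n_outpatient_heal = c(32032, 17618, 6787),
  n_hospital = c(13728, 7551, 2909),
  n_debridement_heal = c(5416, 2979, 1148),
  n_heal_major_amputation = c(3658, 2012, 775),
  n_heal_minor_amputation = c(2897, 1594, 614),
  n_death_major_amputation = c(981, 539, 208),
  n_death_minor_amputation = c(777, 427, 165)
)

test_that("cohort flows reproduce the published person counts for all strategies", {
  for (i in seq_along(strategies())) {
    fl <- compute_flows(peru, strategies()[i])
    for (node in names(table3_counts)) {
      expect_equal(round_half_up(fl[[node]]), table3_counts[[node]][i],
                   label = paste(strategies()[i], node))
    }
  }
})

test_that("flows conserve persons at every internal node", {
  fl <- compute_flows(peru, "sub_optimal")
  expect_equal(fl$n_ulcerated + fl$n_no_ulcer, fl$population_high_risk,
               tolerance = 1e-9)
  expect_equal(fl$n_outpatient_heal + fl$n_hospital, fl$n_ulcerated,
               tolerance = 1e-9)
  expect_equal(fl$n_debridement_heal + fl$n_heal_major_amputation +
                 fl$n_heal_minor_amputation + fl$n_death_major_amputation +
                 fl$n_death_minor_amputation,
               fl$n_hospital, tolerance = 1e-9)
})

test_that("zero prevalence sends the whole cohort to the no-ulcer node", {
  ps <- simple_ps(baseline_ulcer_prevalence = 0)
  fl <- compute_flows(ps, "sub_optimal")
  expect_equal(fl$n_no_ulcer, fl$population_high_risk)
  for (node in names(table3_counts)) expect_equal(fl[[node]], 0)
  out <- summarize_outcomes(fl)
  expect_equal(out$deaths, 0)
  expect_equal(out$major_amputations, 0)
})

test_that("outcome summary reproduces published deaths and counts major amputees", {
  expect_equal(
    round_half_up(summarize_outcomes(compute_flows(peru, "sub_optimal"))$deaths),
    1757)
  out_tmp <- summarize_outcomes(compute_flows(peru, "standard_plus_temp"))
  # hand-check: 206298 x 0.047 x 0.3 x 0.128 deaths; majors include deceased
  expect_equal(round_half_up(out_tmp$deaths), 372)
  expect_equal(out_tmp$deaths, 206298 * 0.047 * 0.3 * 0.128, tolerance = 1e-9)
  expect_equal(round_half_up(out_tmp$major_amputations), 983)
  fl <- compute_flows(peru, "standard")
  out <- summarize_outcomes(fl)
  expect_equal(out$deaths,
               fl$n_death_major_amputation + fl$n_death_minor_amputation)
  expect_gte(out$major_amputations, fl$n_heal_major_amputation)
})

test_that("path enumeration is a faithful oracle for the flow computation", {
  for (s in strategies()) {
    paths <- enumerate_tree_paths(peru, s)
    fl <- compute_flows(peru, s)
    expect_equal(sum(paths$probability), 1, tolerance = 1e-12)
    persons_on <- function(pattern) {
      sum(paths$persons[grepl(pattern, paths$path)])
    }
    expect_equal(persons_on("^ulcer/hospital/death/major$"),
                 fl$n_death_major_amputation, tolerance = 1e-9)
    expect_equal(persons_on("^ulcer/hospital/amputation_heal/minor$"),
                 fl$n_heal_minor_amputation, tolerance = 1e-9)
    expect_equal(persons_on("^no_ulcer$"), fl$n_no_ulcer, tolerance = 1e-9)
    expect_equal(sum(paths$persons), fl$population_high_risk, tolerance = 1e-6)
  }
})

test_that("a degenerate tree with 0/1 probabilities has one unit-probability path", {
  ps <- simple_ps(baseline_ulcer_prevalence = 1,
                  p_hospital = 1, p_outpatient = 0,
                  p_amputation_heal = 0, p_debridement_heal = 0, p_death = 1,
                  p_major_given_amputation = 1, p_minor_given_amputation = 0)
  paths <- enumerate_tree_paths(ps, "sub_optimal")
  live <- paths[paths$probability > 0, ]
  expect_identical(nrow(live), 1L)
  expect_equal(live$probability, 1)
  expect_identical(live$path, "ulcer/hospital/death/major")
})

test_that("flows are monotone in prevalence/effectiveness and linear in population", {
  base <- compute_flows(peru, "sub_optimal")
  # higher baseline prevalence -> more ulcers, deaths, major amputations
  up <- compute_flows(perturb_parameter(peru, "baseline_ulcer_prevalence", 0.28),
                      "sub_optimal")
  expect_gt(up$n_ulcerated, base$n_ulcerated)
  expect_gt(summarize_outcomes(up)$deaths, summarize_outcomes(base)$deaths)
  # higher effectiveness -> fewer, for the treated strategy
  std <- compute_flows(peru, "standard")
  more_eff <- compute_flows(perturb_parameter(peru, "effectiveness_standard", 0.6),
                            "standard")
  expect_lt(more_eff$n_ulcerated, std$n_ulcerated)
  expect_lt(summarize_outcomes(more_eff)$major_amputations,
            summarize_outcomes(std)$major_amputations)
  # doubling the population doubles every terminal count
  doubled <- compute_flows(
    perturb_parameter(peru, "total_diabetes_population", 2 * 942000),
    "sub_optimal")
  for (node in names(table3_counts)) {
    expect_equal(doubled[[node]], 2 * base[[node]], tolerance = 1e-9,
                 label = node)
  }
})

test_that("unknown strategies are rejected", {
  expect_error(compute_flows(peru, "usual_care"), "unknown strategy")
  expect_error(enumerate_tree_paths(peru, "standard2"), "unknown strategy")
})

test_that("flows_table tabulates every strategy and node at full precision", {
  tab <- flows_table(peru)
  expect_setequal(unique(tab$strategy), strategies())
  sub <- tab[tab$strategy == "sub_optimal" & tab$node == "n_ulcerated", ]
  expect_equal(sub$persons, 206298 * 0.122 / 0.55, tolerance = 1e-9)
})
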