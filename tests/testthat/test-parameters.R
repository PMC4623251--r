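test_that("bundled Peru config loads with the published point estimates", {
  ps <- peru
  expect_s3_class(ps, "parameter_set")
  expect_identical(ps$total_diabetes_population, 942000L)
  expect_equal(ps$high_risk_fraction, 0.219)
  expect_equal(ps$baseline_ulcer_prevalence, 0.122 / 0.55, tolerance = 1e-12)
  expect_equal(unname(ps$effectiveness["standard"]), 0.45)
  expect_equal(unname(ps$effectiveness["standard_plus_temp"]),
               1 - 0.047 / (0.122 / 0.55), tolerance = 1e-12)
  expect_equal(ps$p_death, 0.128)
  # per-person prevention costs are the published totals / cohort size
  expect_equal(unname(ps$prevention_cost_per_person),
               c(13350763, 38129966, 83849832) / 206298, tolerance = 1e-12)
  expect_equal(unname(ps$prevention_cost_display), c(65, 185, 406))
  expect_length(validate_parameters(ps), 0)
})

test_that("omitted complements are filled in at construction", {
  ps <- simple_ps(p_hospital = 0.3, p_outpatient = NULL)
  expect_equal(ps$p_outpatient, 0.7)
  ps2 <- simple_ps(p_major_given_amputation = 0.55,
                   p_minor_given_amputation = NULL)
  expect_equal(ps2$p_minor_given_amputation, 0.45)
})

test_that("validation reports every violation in one pass, not just the first", {
  broken <- unclass(simple_ps())
  broken$p_death <- 1.2                      # out of [0,1] AND breaks the simplex
  broken$cost_debridement <- -5              # negative cost
  broken$high_risk_fraction <- 2             # out of [0,1]
  broken <- structure(broken, class = "parameter_set")
  problems <- validate_parameters(broken)
  expect_true(any(grepl("p_death", problems)))
  expect_true(any(grepl("cost_debridement", problems)))
  expect_true(any(grepl("high_risk_fraction", problems)))
  expect_true(any(grepl("sum to 1", problems)))
  expect_gte(length(problems), 4)
})

test_that("each sum-to-one triplet is enforced at construction", {
  expect_error(simple_ps(p_outpatient = 0.5), "p_outpatient")
  expect_error(simple_ps(p_debridement_heal = 0.5), "sum to 1")
  expect_error(simple_ps(p_minor_given_amputation = 0.9), "sum to 1")
})

test_that("missing config fields raise errors naming the field", {
  cfg <- yaml::read_yaml(system.file("extdata", "peru_2012.yaml",
                                     package = "footcea"))
  cfg$epidemiology$p_death <- NULL
  expect_error(load_parameters(cfg), "p_death")
  cfg2 <- yaml::read_yaml(system.file("extdata", "peru_2012.yaml",
                                      package = "footcea"))
  cfg2$economics <- NULL
  expect_error(load_parameters(cfg2), "economics")
})

test_that("an out-of-range probability in the config is a validation error", {
  cfg <- yaml::read_yaml(system.file("extdata", "peru_2012.yaml",
                                     package = "footcea"))
  cfg$epidemiology$p_death <- 1.2
  expect_error(load_parameters(cfg), "p_death")
})

test_that("ranges must bracket their point estimates", {
  expect_error(
    simple_ps(ranges = list(baseline_ulcer_prevalence = c(0.3, 0.5))),
    "bracket")
  expect_error(simple_ps(ranges = list(no_such_parameter = c(0, 1))),
               "unknown parameter")
})

test_that("serializing and re-loading a parameter set is the identity", {
  cfg <- as_config(peru)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp, precision = 15)
  ps2 <- load_parameters(tmp)
  for (f in setdiff(names(peru), c("economic", "total_diabetes_population"))) {
    expect_equal(peru[[f]], ps2[[f]], tolerance = 1e-12, label = f)
  }
  # YAML round-trips the integer population as numeric; value is unchanged
  expect_equal(as.numeric(peru$total_diabetes_population),
               as.numeric(ps2$total_diabetes_population))
  expect_equal(unclass(peru$economic), unclass(ps2$economic))
})

test_that("baseline prevalence back-calculation matches its closed form and inverts", {
  expect_equal(derive_baseline_prevalence(0.122, 0.45), 0.122 / 0.55,
               tolerance = 1e-15)
  expect_equal(round_half_up(100 * derive_baseline_prevalence(0.122, 0.45), 2),
               22.18)
  expect_equal(derive_baseline_prevalence(0.3, 0), 0.3)
  expect_error(derive_baseline_prevalence(0.1, 1), "division by zero")
  # round-trip: strategy_prevalence o derive_baseline_prevalence = identity
  set.seed(7)
  for (i in 1:50) {
    e <- runif(1, 0, 0.999)
    p <- runif(1, 0, 1 - e)  # keep the derived baseline a valid proportion
    expect_equal(strategy_prevalence(derive_baseline_prevalence(p, e), e), p,
                 tolerance = 1e-12)
  }
})

test_that("strategy_prevalence scales the baseline and stays in range", {
  expect_equal(strategy_prevalence(0.122 / 0.55, 0.45), 0.122, tolerance = 1e-12)
  expect_equal(strategy_prevalence(0.122 / 0.55, 1 - 0.047 / (0.122 / 0.55)),
               0.047, tolerance = 1e-12)
  expect_equal(strategy_prevalence(0.3, 1), 0)
  expect_error(strategy_prevalence(1.2, 0.5), "proportions")
})

test_that("high-risk cohort size is population times fraction, full precision", {
  expect_equal(high_risk_population(peru), 206298)
  expect_equal(high_risk_population(simple_ps(total_diabetes_population = 0)), 0)
  expect_equal(high_risk_population(
    simple_ps(total_diabetes_population = 1e6, high_risk_fraction = 0.219)),
    219000)
})

test_that("economic assumptions are validated", {
  expect_error(simple_econ(exchange_rate = 0), "exchange_rate")
  expect_error(simple_econ(discount_rate = 1), "discount_rate")
  expect_error(simple_econ(mean_age_at_death = 70), "retirement_age")
})
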