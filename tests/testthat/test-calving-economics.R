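# Hand-computed expected calf values under the renormalized sex split;
# these closed forms are the independent oracle for the tree EMVs.
sex_renorm <- c(male = 0.485, female = 0.516) / 1.001
E_DAIRY <- sex_renorm["male"] * 50 + sex_renorm["female"] * 100
E_CROSS <- sex_renorm["male"] * 142 + sex_renorm["female"] * 219
E_PRIMI <- unname(0.85 * 100 + 0.15 * E_DAIRY)       # sorted semen -> female
E_PLURI <- unname(0.85 * E_DAIRY + 0.15 * E_CROSS)

test_that("parameter validation names offending fields and renormalizes", {
  expect_error(economic_parameters(sensor_sensitivity = 1.2),
               "sensor_sensitivity")
  expect_error(economic_parameters(value_male_dairy = -5),
               "value_male_dairy")
  expect_error(economic_parameters(p_male_unsorted = 0.2,
                                   p_female_unsorted = 0.2),
               "must sum to 1")
  p <- economic_parameters()
  expect_equal(p$p_male_unsorted + p$p_female_unsorted, 1,
               tolerance = 1e-12)
})

test_that("parameter files round-trip through YAML and JSON", {
  defaults <- economic_parameters()
  yaml_path <- system.file("extdata", "table1-parameters.yaml",
                           package = "calvesense")
  expect_equal(read_economic_parameters(yaml_path), defaults,
               tolerance = 1e-12)

  json_path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(sensor_cost_per_calving = 12), json_path,
                       auto_unbox = TRUE)
  p <- read_economic_parameters(json_path)
  expect_equal(p$sensor_cost_per_calving, 12)
  expect_equal(p$sensor_sensitivity, defaults$sensor_sensitivity)

  bad <- tempfile(fileext = ".yaml")
  writeLines("not_a_parameter: 1", bad)
  expect_error(read_economic_parameters(bad), "unknown parameter")
})

test_that("mortality-free arms equal the expected calf value (oracle)", {
  p0 <- economic_parameters(sensor_cost_per_calving = 0,
                            mort_primi_sensor = 0, mort_pluri_sensor = 0,
                            mort_primi_nosensor = 0,
                            mort_pluri_nosensor = 0)
  primi <- build_calving_tree("primiparous", p0, with_sensor = TRUE)
  expect_equal(rollback(primi)$root_emv, E_PRIMI, tolerance = 1e-9)
  expect_equal(policy_value(primi), E_PRIMI, tolerance = 1e-9)
  expect_equal(E_PRIMI, 96.37, tolerance = 0.005)

  pluri <- build_calving_tree("pluriparous", p0, with_sensor = TRUE)
  expect_equal(rollback(pluri)$root_emv, E_PLURI, tolerance = 1e-9)
  expect_equal(policy_value(pluri), E_PLURI, tolerance = 1e-9)
})

test_that("baseline scenario matches closed-form expectations (oracle)", {
  sc <- calving_scenario(economic_parameters())
  primi <- sc[sc$parity == "primiparous", ]
  pluri <- sc[sc$parity == "pluriparous", ]

  # without sensor: survival x expected calf value
  expect_equal(primi$emv_without_sensor, 0.89 * E_PRIMI, tolerance = 1e-9)
  expect_equal(pluri$emv_without_sensor, 0.873 * E_PLURI, tolerance = 1e-9)
  # with sensor: alarm branch uses monitored mortality, missed alarms
  # inherit the unmonitored mortality; cost paid on the whole arm
  expect_equal(primi$emv_with_sensor,
               (0.863 * 1 + 0.137 * 0.89) * E_PRIMI - 10, tolerance = 1e-9)
  expect_equal(pluri$emv_with_sensor,
               (0.863 * 0.983 + 0.137 * 0.873) * E_PLURI - 10,
               tolerance = 1e-9)
  expect_equal(sc$incremental_emv,
               sc$emv_with_sensor - sc$emv_without_sensor)
  expect_identical(sc$structure_id, rep("mortality_marginal", 2))

  # EMVs bounded by payoffs
  expect_true(all(sc$emv_with_sensor >= -10 & sc$emv_with_sensor <= 219))
})

test_that("symmetric arms with zero cost give exactly zero incremental EMV", {
  p_sym <- economic_parameters(sensor_cost_per_calving = 0,
                               mort_primi_sensor = 0.11,
                               mort_pluri_sensor = 0.127)
  sc <- calving_scenario(p_sym)
  expect_equal(sc$incremental_emv, c(0, 0), tolerance = 1e-12)
})

test_that("perfect sensor at zero cost recovers the closed-form benefit", {
  p1 <- economic_parameters(sensor_sensitivity = 1,
                            sensor_cost_per_calving = 0,
                            mort_primi_sensor = 0, mort_pluri_sensor = 0)
  sc <- calving_scenario(p1)
  expect_equal(sc$incremental_emv[sc$parity == "primiparous"],
               0.11 * E_PRIMI, tolerance = 1e-9)
  expect_equal(sc$incremental_emv[sc$parity == "pluriparous"],
               0.127 * E_PLURI, tolerance = 1e-9)
  # ~10.60 EUR for primiparous dams under default parameters
  expect_equal(0.11 * E_PRIMI, 10.60, tolerance = 0.005)
})

test_that("zeroed calf values make 'no sensor' optimal (cost-only tree)", {
  p0 <- economic_parameters(value_male_dairy = 0, value_female_dairy = 0,
                            value_male_cross = 0, value_female_cross = 0)
  sc <- calving_scenario(p0)
  expect_true(all(sc$emv_with_sensor <= 0))
  expect_true(all(sc$emv_without_sensor <= 0))
  expect_identical(sc$optimal_decision, rep("no sensor", 2))
})

test_that("incremental EMV is monotone in sensitivity and cost", {
  base <- economic_parameters()
  inc <- function(p, parity) {
    sc <- calving_scenario(p)
    sc$incremental_emv[sc$parity == parity]
  }
  for (parity in c("primiparous", "pluriparous")) {
    sens <- vapply(seq(0.4315, 1, length.out = 7), function(s) {
      inc(economic_parameters(sensor_sensitivity = s), parity)
    }, numeric(1))
    expect_true(all(diff(sens) >= -1e-12))
    costs <- vapply(c(0, 5, 10, 20), function(cst) {
      inc(economic_parameters(sensor_cost_per_calving = cst), parity)
    }, numeric(1))
    expect_true(all(diff(costs) <= 1e-12))
  }
})

test_that("sensitivity report sweeps the documented grids", {
  sweeps <- sensitivity_report(steps = 5)
  expect_length(sweeps, 6L)
  sens <- sweeps[["sensor_sensitivity.primiparous"]]
  expect_equal(range(sens$grid), 0.863 * c(0.5, 1.5))
  expect_true(all(diff(sens$emv_series) >= -1e-12))   # monotone
  expect_true(any(sens$clamped))                      # 1.2945 clamps to 1

  # dystocia does not sit on the payoff path of this structure: flat sweep
  dys <- sweeps[["p_dystocia_dairy.primiparous"]]
  expect_equal(range(dys$grid), 0.0375 * c(0.75, 1.25))
  expect_true(all(abs(dys$emv_series - dys$baseline_emv) < 1e-12))

  # endpoints cross-checked against the enumeration oracle
  p_hi <- economic_parameters(sensor_sensitivity = 1)
  arm <- build_calving_tree("primiparous", p_hi, TRUE)
  expect_equal(rollback(arm)$root_emv, policy_value(arm), tolerance = 1e-9)
})

test_that("the nested-mortality structure variant responds to dystocia", {
  sc1 <- calving_scenario(structure = "mortality_marginal")
  sc2 <- calving_scenario(structure = "mortality_within_dystocia")
  expect_identical(sc2$structure_id, rep("mortality_within_dystocia", 2))
  # conditioning mortality on dystocia lowers overall losses
  expect_true(all(sc2$emv_without_sensor > sc1$emv_without_sensor))
  # and makes the incremental EMV depend on the dystocia probability
  sw <- sensitivity_report(steps = 3,
                           structure = "mortality_within_dystocia")
  dys <- sw[["p_dystocia_dairy.primiparous"]]
  expect_gt(diff(range(dys$emv_series)), 0)
})
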