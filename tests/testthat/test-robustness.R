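test_that("the identity scenario reproduces the baseline bit for bit", {
  sim <- simulate_panel(sim_config(n_units = 14, seed = 61))
  spec <- study_spec()
  ctl <- fast_ctl()
  base <- synth_control(sim$panel, spec, control = ctl)
  scn <- scenario("identity")
  fit <- run_scenario(sim$panel, spec, scn, control = ctl)
  expect_identical(fit$weights, base$weights)
  expect_identical(fit$gap_path, base$gap_path)
  cmp <- compare_scenarios(list(base, fit))
  expect_equal(nrow(cmp), 2)
  expect_equal(cmp$delta_vs_baseline, c(0, 0))
  # rerun is pure
  fit2 <- run_scenario(sim$panel, spec, scn, control = ctl)
  expect_identical(fit2$gap_path, fit$gap_path)
})

test_that("scenarios subset, truncate and can use group lookups", {
  sim <- simulate_panel(sim_config(n_units = 20, seed = 62))
  spec <- study_spec()
  lookup <- data.frame(unit = sim$panel$units,
                       group = rep(c("east", "west"), 10))
  lookup$group[lookup$unit == sim$panel$treated_unit] <- "treated_home"
  scn <- scenario("drop-west", drop_groups = "west", lookup = lookup,
                  end_year = 2019)
  fit <- run_scenario(sim$panel, spec, scn, control = fast_ctl())
  expect_equal(length(fit$donors), 9)
  expect_equal(max(fit$years), 2019)
  expect_equal(fit$scenario$name, "drop-west")

  # refusing to drop the treated unit or the whole pool
  expect_error(scenario("bad", drop_groups = "west"), "lookup")
  scn_all <- scenario("too-small",
                      drop_units = setdiff(sim$panel$units,
                                           sim$panel$treated_unit)[-1])
  expect_error(run_scenario(sim$panel, spec, scn_all, control = fast_ctl()),
               "fewer than 2 donors")
})

test_that("dropping irrelevant noise donors barely moves the estimate", {
  sim <- simulate_panel(sim_config(n_units = 60, seed = 63))
  spec <- study_spec()
  ctl <- fast_ctl()
  base <- synth_control(sim$panel, spec, control = ctl)
  noise_donors <- setdiff(sim$panel$units,
                          c(sim$panel$treated_unit, sim$truth$hull_donors))
  scn <- scenario("drop-noise", drop_units = utils::head(noise_donors, 30))
  fit <- run_scenario(sim$panel, spec, scn, control = ctl)
  expect_lt(abs(fit$mean_post_effect - base$mean_post_effect), 0.02)
  expect_lt(abs(fit$mean_post_effect - sim$truth$mean_effect), 0.02)
})

test_that("mechanism scenarios recover the injected mediator directions", {
  sim <- simulate_panel(sim_config(n_units = 20, mode = "mechanism",
                                   seed = 64))
  spec_med <- predictor_spec(covariates = character(0))  # mediator lags only
  ctl <- fast_ctl()
  up <- run_scenario(sim$panel, spec_med,
                     scenario("expenditure",
                              outcome_variable = "gov_health_expenditure",
                              expected_sign = "positive"), control = ctl)
  down <- run_scenario(sim$panel, spec_med,
                       scenario("enrollees",
                                outcome_variable = "insured_persons",
                                expected_sign = "negative"), control = ctl)
  expect_equal(up$outcome, "gov_health_expenditure")
  chk_up <- direction_check(up, "positive")
  chk_dn <- direction_check(down, "negative")
  expect_true(chk_up$pass)
  expect_true(chk_dn$pass)
  expect_gt(chk_up$fraction_matching, 0.5)
  expect_gt(chk_dn$fraction_matching, 0.5)

  # the enrollee series had pre-2011 gaps: they must be imputed, not fatal
  expect_true(anyNA(sim$panel$values$insured_persons))
  expect_false(anyNA(down$treated_path))
})

test_that("direction_check evaluates signs as stated", {
  sim <- simulate_panel(sim_config(n_units = 12, noise_sd = 0, seed = 65))
  fit <- synth_control(sim$panel, study_spec(), v_method = "uniform")
  # true effect path is negative throughout
  neg <- direction_check(fit, "negative")
  expect_true(neg$pass)
  expect_equal(neg$fraction_matching, 1)
  pos <- direction_check(fit, "positive")
  expect_false(pos$pass)
})
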