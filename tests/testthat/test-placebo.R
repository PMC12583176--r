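test_that("in-space ensemble covers every donor and filters monotonically", {
  sim <- simulate_panel(sim_config(n_units = 14, seed = 21))
  spec <- study_spec()
  ctl <- fast_ctl()
  fit <- synth_control(sim$panel, spec, control = ctl)
  pl <- placebo_space(sim$panel, spec, cutoff_multiplier = Inf,
                      control = ctl, treated_fit = fit)
  expect_equal(nrow(pl$units), 13)
  expect_true(all(pl$units$included))
  expect_false(sim$panel$treated_unit %in% pl$units$unit)
  expect_equal(dim(pl$gaps), c(16, 13))

  # tightening the multiplier never adds units
  counts <- vapply(c(1, 5, 700, Inf), function(cm)
    sum(placebo_space(sim$panel, spec, cutoff_multiplier = cm,
                      control = ctl, treated_fit = fit)$n_included),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(placebo_space(sim$panel, spec, cutoff_multiplier = -1,
                             treated_fit = fit), "positive")
})

test_that("an injected treated-only shift drives the pseudo p to its floor", {
  # large post-period shift only for the treated unit: its ratio exceeds
  # every placebo ratio, so no included placebo reaches it
  sim <- simulate_panel(sim_config(n_units = 21, treated_draw = "iid",
                                   effect_path = rep(-3, 11),
                                   noise_sd = 0.02, seed = 31))
  spec <- study_spec()
  ctl <- fast_ctl()
  pl <- placebo_space(sim$panel, spec, cutoff_multiplier = Inf,
                      control = ctl)
  expect_equal(pl$n_included, 20)
  expect_true(all(pl$units$rmspe_ratio < pl$treated_ratio))
  expect_equal(pl$pseudo_p, 0)
  expect_equal(pl$pseudo_p_rank, 1 / 21)
})

test_that("a placebo unit with an exact twin fits perfectly and stays included", {
  fx <- factor_panel(n = 8, m = 3, noise_sd = 0.05)
  p <- fx$panel
  # make donors u03 and u04 identical: each other's perfect synthetic twin
  for (v in names(p$values)) p$values[[v]]["u04", ] <- p$values[[v]]["u03", ]
  pl <- placebo_space(p, predictor_spec(covariates = c("c1", "c2")),
                      cutoff_multiplier = Inf, v_method = "uniform")
  twins <- pl$units$unit %in% c("u03", "u04")
  expect_true(all(pl$units$pre_rmspe[twins] < 1e-8))
  # the ratio convention stays well-defined at a (near-)zero pre-RMSPE:
  # infinite at an exact zero, never NaN, and the unit remains included
  expect_true(all(!is.na(pl$units$rmspe_ratio[twins])))
  expect_true(all(pl$units$included[twins]))
})

test_that("on a null panel the ensemble mean gap is indistinguishable from 0", {
  sim <- simulate_panel(sim_config(n_units = 20, mode = "null",
                                   treated_draw = "iid", seed = 77))
  pl <- placebo_space(sim$panel, study_spec(), cutoff_multiplier = Inf,
                      control = fast_ctl())
  unit_means <- colMeans(pl$gaps)
  se <- sd(unit_means) / sqrt(length(unit_means))
  expect_lt(abs(mean(unit_means)), 2 * se)
})

test_that("in-time placebo truncates the sample and drops late lags", {
  sim <- simulate_panel(sim_config(n_units = 14, seed = 41))
  spec <- study_spec()
  expect_message(
    tf <- placebo_time(sim$panel, spec, fake_treatment_year = 2010,
                       control = fast_ctl()),
    "dropping lag predictor")
  # only data before the true treatment year are used
  expect_equal(max(tf$years), 2011)
  expect_equal(tf$treatment_year, 2010)
  # lag predictors at/after 2010 were dropped: 5 covariates + lags 2007-2009
  expect_equal(length(tf$weights$V), 5 + 3)

  expect_error(placebo_time(sim$panel, spec, fake_treatment_year = 2008),
               "allow_short_pre")
  tf8 <- suppressMessages(
    placebo_time(sim$panel, spec, fake_treatment_year = 2008,
                 allow_short_pre = TRUE))
  expect_equal(tf8$treatment_year, 2008)
  expect_equal(tf8$v_method, "uniform")   # nested needs 2+ pre-years
  expect_error(placebo_time(sim$panel, spec, fake_treatment_year = 2013),
               "precede")
})

test_that("a backdated reform year shows no effect on a null hull panel", {
  sim <- simulate_panel(sim_config(n_units = 16, mode = "null",
                                   noise_sd = 0, seed = 51))
  tf <- suppressMessages(
    placebo_time(sim$panel, study_spec(), fake_treatment_year = 2010,
                 control = fast_ctl()))
  expect_lt(max(abs(tf$gap_path)), 1e-7)
})
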