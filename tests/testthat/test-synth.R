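test_that("predictor matrices follow the spec order and scaling", {
  sim <- simulate_panel(sim_config(n_units = 15, seed = 8))
  X <- build_predictors(sim$panel, study_spec())
  expect_equal(nrow(X$X0), 9)          # 5 covariates + 4 lags
  expect_equal(X$names[1:5], study_spec()$covariates)
  expect_equal(X$names[6:9], sprintf("misallocation(%d)", 2007:2010))
  expect_equal(ncol(X$X0), 14)
  # rows standardized over treated + donors
  all_rows <- cbind(X$X1, X$X0)
  expect_equal(unname(rowMeans(all_rows)), rep(0, 9), tolerance = 1e-12)
  expect_equal(unname(apply(all_rows, 1, sd)), rep(1, 9), tolerance = 1e-12)
  # raw values preserved for reporting
  expect_equal(unname(X$X1_raw), unname(X$X1 * X$scale + X$center))

  # zero-variance predictor is a named error
  p2 <- sim$panel
  p2$values$gdp[] <- 5e6
  expect_error(build_predictors(p2, study_spec()), "gdp")

  # a single donor is refused
  p3 <- subset_panel(sim$panel,
                     drop_units = setdiff(sim$panel$units,
                                          sim$panel$treated_unit)[-1])
  expect_error(build_predictors(p3, study_spec()), "at least 2 donor")
})

test_that("an exact donor twin of the treated unit yields a zero gap path", {
  fx <- factor_panel(n = 8, m = 3, noise_sd = 0.05)
  p <- fx$panel
  # duplicate the treated row as a donor
  for (v in names(p$values)) {
    m <- p$values[[v]]
    m <- rbind(m, twin = m[p$treated_unit, ])
    rownames(m)[nrow(m)] <- "twin"
    p$values[[v]] <- m
  }
  p$units <- c(p$units, "twin")
  fit <- synth_control(p, predictor_spec(covariates = c("c1", "c2")),
                       v_method = "uniform")
  expect_lt(max(abs(fit$gap_path)), 1e-6)
  expect_lt(fit$pre_rmspe, 1e-6)
  expect_gt(fit$weights$W[["twin"]], 0.49)
})

test_that("fit identities: gaps, RMSPEs, mean effect, balance arithmetic", {
  sim <- simulate_panel(sim_config(n_units = 18, seed = 12))
  fit <- synth_control(sim$panel, study_spec(), control = fast_ctl())
  expect_equal(fit$gap_path, fit$treated_path - fit$synthetic_path)
  post <- fit$years >= fit$treatment_year
  expect_equal(fit$mean_post_effect, mean(fit$gap_path[post]))
  expect_equal(fit$pre_rmspe, sqrt(mean(fit$gap_path[!post]^2)))
  expect_equal(fit$post_rmspe, sqrt(mean(fit$gap_path[post]^2)))
  b <- fit$balance
  expect_equal(b$bias_pct,
               (b$synthetic - b$treated) / b$treated * 100)
  # synthetic predictor values are the W-combination of raw donor rows
  X <- build_predictors(sim$panel, study_spec())
  expect_equal(b$synthetic,
               as.numeric(X$X0_raw %*% fit$weights$W))

  # S3 surface
  expect_equal(residuals(fit), fit$gap_path)
  expect_equal(fitted(fit), fit$synthetic_path)
  expect_equal(coef(fit), fit$weights$W)
  expect_equal(coef(fit, "V"), fit$weights$V)
  expect_equal(weights(fit), fit$weights$W)
  expect_equal(unname(predict(fit, 2015)),
               unname(fit$synthetic_path["2015"]))
  expect_output(print(fit), "Mean post-treatment effect")
  expect_output(summary(fit), "Predictor balance")
  et <- effects_table(fit)
  expect_equal(et$effect, unname(fit$gap_path[post]))
  expect_equal(attr(et, "means")[["effect"]], fit$mean_post_effect)
})

test_that("zero treated value flags the bias as undefined", {
  expect_identical(bias_pct(c(2, 0), c(1, 1)), c(-50, NA))
})

test_that("hull-member treated unit is recovered exactly at zero noise", {
  sim <- simulate_panel(sim_config(n_units = 20, noise_sd = 0, seed = 3))
  fit <- synth_control(sim$panel, study_spec(), control = fast_ctl(2, 80))
  pre <- fit$years < fit$treatment_year
  expect_lt(max(abs(fit$gap_path[pre])), 1e-7)
  expect_equal(unname(fit$gap_path[!pre]),
               unname(sim$truth$effect_path), tolerance = 1e-6)
  expect_equal(fit$mean_post_effect, sim$truth$mean_effect,
               tolerance = 1e-6)
})

test_that("exact convex-hull weights are reproduced on a small donor pool", {
  # treated = exact combination of donors 1..3; with more latent factors
  # than donors the representation is unique, so W must equal the truth
  fx <- factor_panel(n = 6, m = 3, noise_sd = 0, n_factors = 6)
  spec <- predictor_spec(covariates = c("c1", "c2"),
                         lag_years = 2007:2011)
  fit <- synth_control(fx$panel, spec, v_method = "uniform")
  W <- fit$weights$W
  expect_equal(unname(W[1:3]), fx$w_true, tolerance = 1e-4)
  expect_lt(sum(W[-(1:3)]), 1e-4)
})
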