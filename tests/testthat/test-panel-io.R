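test_that("panel construction, writing and re-reading reproduce all cells", {
  p <- tiny_panel()
  expect_s3_class(p, "scm_panel")
  expect_equal(dim(p$values$y), c(2, 3))
  expect_equal(sum(!is.na(p$values$y)), 6)

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, tmp)
  schema <- list(treated_unit = "a", treatment_year = 2012,
                 roles = list(y = "outcome"))
  p2 <- read_panel(tmp, schema)
  expect_identical(p2$values$y, p$values$y)
  expect_identical(p2$units, p$units)
  expect_identical(p2$treatment_year, p$treatment_year)

  # schema from YAML on disk works the same way
  sfile <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(schema, sfile)
  p3 <- read_panel(tmp, sfile)
  expect_identical(p3$values$y, p$values$y)
})

test_that("structural defects are hard errors naming the culprit", {
  df <- tiny_panel_df()
  expect_error(
    panel_data(df[-2, ], "a", 2012, c(y = "outcome")),
    "(a, 2011)", fixed = TRUE)
  expect_error(
    panel_data(rbind(df, df[1, ]), "a", 2012, c(y = "outcome")),
    "duplicate.*'a', year 2010")
  bad <- df; bad$y <- as.character(bad$y); bad$y[3] <- "oops"
  expect_error(panel_data(bad, "a", 2012, c(y = "outcome")),
               "non-numeric.*row 3")
  expect_error(panel_data(df, "zzz", 2012, c(y = "outcome")),
               "treated unit")
  expect_error(panel_data(df, "a", 2010, c(y = "outcome")),
               "treatment_year")
  gap <- df; gap$year[gap$year == 2011] <- 2013
  expect_error(panel_data(gap, "a", 2012, c(y = "outcome")), "contiguous")
})

test_that("linear imputation fills interior, leading and trailing gaps", {
  yrs <- 2007:2013
  df <- expand.grid(unit = c("t", "d1", "d2"), year = yrs)
  df$y <- 1
  df$m <- 10 + 2 * (df$year - 2011)
  df$m[df$unit == "t" & df$year == 2012] <- NA       # interior
  df$m[df$unit == "d1" & df$year <= 2010] <- NA      # leading run
  df$m[df$unit == "d2" & df$year >= 2012] <- NA      # trailing run
  p <- panel_data(df, "t", 2012, c(y = "outcome", m = "mediator"))
  q <- impute_linear(p, "m")

  # interior midpoint between 2011 (10) and 2013 (14)
  expect_equal(q$values$m["t", "2012"], 12)
  # leading gaps: extend the line through the first two observed points;
  # cross-checked against an independent least-squares line
  fitln <- lm(y ~ x, data.frame(x = c(2011, 2012), y = c(10, 12)))
  expect_equal(unname(q$values$m["d1", c("2007", "2008", "2009", "2010")]),
               unname(predict(fitln, data.frame(x = 2007:2010))))
  expect_equal(unname(q$values$m["d1", "2007"]), 2)
  # trailing gaps analogous
  expect_equal(unname(q$values$m["d2", "2013"]), 14)

  # idempotence and purity
  expect_identical(impute_linear(q, "m")$values$m, q$values$m)
  expect_true(anyNA(p$values$m))   # input untouched
  # fully observed series returned unchanged
  expect_identical(impute_linear(p, "y")$values$y, p$values$y)
})

test_that("imputation guards: too few observations, negative clipping", {
  yrs <- 2007:2010
  df <- expand.grid(unit = c("t", "d"), year = yrs)
  df$y <- 1
  df$m <- NA_real_
  # unit t observed (2007, 2008) = (5, 1): slope -4, so the trailing
  # extrapolation goes negative and gets clipped for the count-like
  # mediator role
  df$m[df$unit == "t" & df$year == 2007] <- 5
  df$m[df$unit == "t" & df$year == 2008] <- 1
  df$m[df$unit == "d"] <- 7
  p <- panel_data(df, "t", 2009, c(y = "outcome", m = "mediator"))
  expect_warning(q <- impute_linear(p, "m"), "clipped")
  expect_equal(unname(q$values$m["t", c("2009", "2010")]), c(0, 0))
  # without clipping the raw line continues below zero
  q2 <- suppressWarnings(impute_linear(p, "m", clip_zero = FALSE))
  expect_equal(unname(q2$values$m["t", "2009"]), -3)

  df$m[df$unit == "t" & df$year == 2008] <- NA
  p2 <- panel_data(df, "t", 2009, c(y = "outcome", m = "mediator"))
  expect_error(impute_linear(p2, "m"), "fewer than 2")
})

test_that("subsetting drops donors, truncates years, preserves balance", {
  sim <- simulate_panel(sim_config(n_units = 24, seed = 5))
  p <- sim$panel
  drop <- setdiff(p$units, p$treated_unit)[1:11]
  q <- subset_panel(p, drop_units = drop)
  expect_equal(length(q$units), 13)
  expect_false(any(drop %in% q$units))

  r <- subset_panel(p, end_year = 2019)
  expect_equal(range(r$years), c(2007, 2019))
  expect_equal(dim(r$values$misallocation), c(24, 13))

  # identity subset
  s <- subset_panel(p)
  expect_identical(s$values, p$values)

  expect_error(subset_panel(p, drop_units = p$treated_unit),
               "cannot drop the treated unit")
  expect_error(subset_panel(p, end_year = 2011), "precedes")
  # a subset panel revalidates cleanly
  expect_s3_class(panel_data(as.data.frame(q), q$treated_unit,
                             q$treatment_year, q$roles), "scm_panel")
})
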