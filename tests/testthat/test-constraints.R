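test_that("risk inversion matches the analytic logit form and bisection", {
  f <- manual_fit(c(`(Intercept)` = -8, dose = 0.1))
  d <- invert_dose_for_risk(f, risk = 0.05)
  expect_equal(as.numeric(d), (qlogis(0.05) + 8) / 0.1, tolerance = 1e-9)
  expect_equal(as.numeric(d), 50.556, tolerance = 1e-3)
  d_bis <- invert_dose_for_risk(f, risk = 0.05, method = "bisection")
  expect_equal(as.numeric(d), as.numeric(d_bis), tolerance = 1e-6)
  # round trip on random fits, both methods
  withr::with_seed(51, {
    for (i in 1:20) {
      b <- c(`(Intercept)` = runif(1, -10, -2), dose = runif(1, 0.02, 0.3),
             age = runif(1, 0, 0.08))
      ff <- manual_fit(b, covariates = "age")
      risk <- runif(1, 0.01, 0.6)
      prof <- c(age = runif(1, 40, 80))
      dd <- suppressWarnings(invert_dose_for_risk(ff, prof, risk))
      expect_equal(ntcp_probability(ff, as.numeric(dd), prof), risk,
                   tolerance = 1e-6)
      db <- suppressWarnings(
        invert_dose_for_risk(ff, prof, risk, method = "bisection"))
      expect_equal(as.numeric(dd), as.numeric(db), tolerance = 1e-6)
    }
  })
})

test_that("baseline risk above target is flagged below floor", {
  f <- manual_fit(c(`(Intercept)` = qlogis(0.10), dose = 0.1))
  expect_warning(d <- invert_dose_for_risk(f, risk = 0.05),
                 class = "radntcp_below_floor")
  expect_true(attr(d, "below_floor"))
  expect_lt(as.numeric(d), 0)
  neg <- manual_fit(c(`(Intercept)` = 1, dose = -0.02))
  expect_error(invert_dose_for_risk(neg, risk = 0.05),
               class = "radntcp_nonmonotone")
})

test_that("constraint doses tighten with age at exactly -beta_age/beta_D per year", {
  b <- c(`(Intercept)` = -7, dose = 0.08, age = 0.05)
  f <- manual_fit(b, covariates = "age")
  tab <- constraint_table(list(MGM = f), risk = 0.05)
  expect_equal(nrow(tab), 4L)
  expect_true(all(diff(tab$dose_gy) < 0)) # non-increasing across strata
  # closed-form analytic oracle per cell
  expected <- (qlogis(0.05) + 7 - 0.05 * c(45, 55, 65, 75)) / 0.08
  expect_equal(tab$dose_gy, expected, tolerance = 1e-9)
  # age gradient is exactly -beta_age/beta_D Gy per year
  grad <- diff(tab$dose_gy) / diff(tab$age)
  expect_equal(grad, rep(-0.05 / 0.08, 3), tolerance = 1e-9)
  # zero age effect: all strata identical
  f0 <- manual_fit(c(`(Intercept)` = -7, dose = 0.08, age = 0),
                   covariates = "age")
  tab0 <- constraint_table(list(MGM = f0), risk = 0.05)
  expect_equal(length(unique(round(tab0$dose_gy, 9))), 1L)
})

test_that("raising the risk target raises every constraint dose", {
  f <- manual_fit(c(`(Intercept)` = -7, dose = 0.08, age = 0.05),
                  covariates = "age")
  t05 <- constraint_table(list(MGM = f), risk = 0.05)
  t10 <- constraint_table(list(MGM = f), risk = 0.10)
  expect_true(all(t10$dose_gy > t05$dose_gy))
})

test_that("constraint display follows the integer-Gy and <10 floor conventions", {
  f <- manual_fit(c(`(Intercept)` = -4, dose = 0.08, age = 0.06),
                  covariates = "age")
  tab <- constraint_table(list(MGM = f), risk = 0.05, floor = 10)
  low <- tab$dose_gy < 10
  expect_true(all(tab$dose_display[low] == "<10"))
  expect_true(all(tab$dose_display[!low] ==
                    as.character(round(tab$dose_gy[!low]))))
  expect_true(all(tab$below_floor[low]))
})

test_that("curves are ordered by age, cross the risk target at the inverted dose", {
  co <- simulate_cohort(simulation_config(n = 2000, seed = 52))
  f <- fit_ntcp(co, "MGM", "age")
  grid <- seq(0, 80, by = 0.25)
  cs <- suppressWarnings(ntcp_curves(f, NULL, dose_grid = grid))
  expect_s3_class(cs, "ntcp_curveset")
  # >=70 curve above <=49 curve everywhere (positive age coefficient)
  young <- cs$ntcp[cs$age_stratum == "<=49"]
  old <- cs$ntcp[cs$age_stratum == ">=70"]
  expect_gt(coef(f)[["age"]], 0)
  expect_true(all(old > young))
  # reading the crossing dose off the curve reproduces the inversion
  d_inv <- as.numeric(invert_dose_for_risk(f, c(age = 65), 0.05))
  stratum <- cs[cs$age_stratum == "60-69", ]
  crossing <- stratum$dose[which.max(stratum$ntcp >= 0.05)]
  expect_lt(abs(crossing - d_inv), 0.25 + 1e-9) # within grid resolution
})

test_that("bootstrap bands behave: degenerate ensembles give zero width", {
  co <- simulate_cohort(simulation_config(n = 500, seed = 53))
  f <- fit_ntcp(co, "MGM", "age")
  ens <- bootstrap_ntcp(co, "MGM", "age", B = 30, seed = 5)
  # degenerate ensemble: every replicate replaced by the point fit
  ens$coefficients <- matrix(rep(coef(f), each = 10), nrow = 10,
                             dimnames = list(NULL, names(coef(f))))
  cs <- ntcp_curves(f, ens, dose_grid = seq(0, 80, 10))
  expect_equal(cs$lower, cs$ntcp, tolerance = 1e-12)
  expect_equal(cs$upper, cs$ntcp, tolerance = 1e-12)
  # a real ensemble's band contains the central curve at every grid point
  ens2 <- bootstrap_ntcp(co, "MGM", "age", B = 100, seed = 6)
  cs2 <- ntcp_curves(f, ens2, dose_grid = seq(10, 70, 10))
  expect_true(all(cs2$lower <= cs2$ntcp + 1e-9))
  expect_true(all(cs2$upper >= cs2$ntcp - 1e-9))
  # empty ensemble warns and returns central curve only
  expect_warning(cs3 <- ntcp_curves(f, NULL, dose_grid = seq(0, 80, 10)))
  expect_true(all(is.na(cs3$lower)))
})

test_that("autoplot methods return ggplot objects", {
  f <- manual_fit(c(`(Intercept)` = -7, dose = 0.08, age = 0.05),
                  covariates = "age")
  tab <- constraint_table(list(MGM = f))
  expect_s3_class(autoplot(tab), "ggplot")
  cs <- suppressWarnings(ntcp_curves(f, NULL, dose_grid = seq(0, 80, 20)))
  expect_s3_class(autoplot(cs), "ggplot")
})
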