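test_that("negative log-likelihood matches Bernoulli closed forms", {
  co <- tibble::tibble(outcome = rep(c(0, 1), 150), dose = rep(50, 300))
  # all p = 0.5 at beta = 0
  expect_equal(negative_log_likelihood(c(0, 0), co, roi = "dose"),
               300 * log(2), tolerance = 1e-12)
  # null model at the event fraction 34/300
  co2 <- tibble::tibble(outcome = c(rep(1, 34), rep(0, 266)))
  nll <- negative_log_likelihood(qlogis(34 / 300), co2)
  expect_equal(nll, -(34 * log(34 / 300) + 266 * log(266 / 300)),
               tolerance = 1e-12)
  expect_equal(nll, 106.03, tolerance = 1e-2)
  # perfect prediction drives the clipped likelihood towards zero
  co3 <- tibble::tibble(outcome = c(0, 1), dose = c(-1, 1))
  expect_lt(negative_log_likelihood(c(0, 40), co3, roi = "dose"), 1e-10)
})

test_that("intercept-only MLE is the logit of the event fraction", {
  co <- tibble::tibble(outcome = c(rep(1, 34), rep(0, 266)), age = 60)
  f <- fit_ntcp(co, roi = NULL, covariates = character())
  expect_equal(unname(coef(f)), qlogis(34 / 300), tolerance = 1e-8)
  expect_equal(f$bic, log(300) - 2 * f$log_likelihood)
})

test_that("MLE matches a brute-force grid search on the toy cohort", {
  co <- toy_cohort()
  f <- fit_ntcp(co, roi = "dose", covariates = character())
  # independent oracle: exhaustive search over a (beta0, beta_D) grid
  b0_grid <- seq(-9, 1, by = 0.05)
  bd_grid <- seq(0, 0.25, by = 0.001)
  nll_mat <- outer(b0_grid, bd_grid, Vectorize(function(b0, bd) {
    negative_log_likelihood(c(b0, bd), co, roi = "dose")
  }))
  best <- arrayInd(which.min(nll_mat), dim(nll_mat))
  expect_lt(abs(coef(f)[["dose"]] - bd_grid[best[2]]), 0.001)
  # the intercept rides a correlated likelihood ridge: a 0.001 step in the
  # dose slope moves the conditional optimum ~0.05 in the intercept, so the
  # grid argmin is resolved to ~2 intercept steps
  expect_lt(abs(coef(f)[["(Intercept)"]] - b0_grid[best[1]]), 0.1)
  # and the MLE beats every grid point on the likelihood itself
  expect_lte(negative_log_likelihood(coef(f), co, roi = "dose"),
             min(nll_mat) + 1e-9)
})

test_that("MLE agrees with glm and leaves a near-zero gradient", {
  co <- simulate_cohort(simulation_config(n = 1500, seed = 8))
  f <- fit_ntcp(co, "MGM", c("age", "sex"))
  g <- stats::glm(outcome ~ MGM + age + sex, binomial, data = co)
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(f$vcov))),
               unname(sqrt(diag(stats::vcov(g)))), tolerance = 1e-4)
  expect_lt(f$gradient_max, 1e-6)
  # nesting: adding covariates can only improve the deviance
  f0 <- fit_ntcp(co, "MGM", character())
  expect_gte(f$log_likelihood, f0$log_likelihood)
})

test_that("degenerate and separated cohorts fail with classed errors", {
  one_class <- tibble::tibble(outcome = rep(0, 30), dose = runif(30, 20, 70),
                              age = 60)
  expect_error(fit_ntcp(one_class, "dose", character()),
               class = "radntcp_degenerate")
  sep <- tibble::tibble(dose = c(seq(20, 58, 2), seq(62, 80, 2)))
  sep$outcome <- as.integer(sep$dose > 60)
  expect_error(fit_ntcp(sep, "dose", character()),
               class = "radntcp_separation")
})

test_that("ntcp_probability evaluates the logistic model", {
  f <- manual_fit(c(`(Intercept)` = -5, dose = 0.08, age = 0.04),
                  covariates = "age")
  expect_equal(ntcp_probability(f, 50, c(age = 70)), plogis(1.8))
  expect_equal(ntcp_probability(f, 50, c(age = 70)), 0.8581, tolerance = 1e-4)
  # strictly increasing in dose when beta_D > 0
  p <- ntcp_probability(f, seq(0, 80, 5), c(age = 60))
  expect_true(all(diff(p) > 0))
  expect_error(ntcp_probability(f, 50), class = "radntcp_missing_covariate")
})

test_that("D50/gamma50 re-parameterization is self-consistent", {
  f <- manual_fit(c(`(Intercept)` = -6, dose = 0.1))
  dg <- derive_d50_gamma(f)
  expect_equal(dg$d50, 60)
  expect_equal(dg$gamma50, 1.5)
  expect_equal(ntcp_probability(f, dg$d50), 0.5, tolerance = 1e-9)
  # slope of the NTCP curve at D50 equals beta_D / 4 (finite differences)
  h <- 1e-4
  slope <- (ntcp_probability(f, dg$d50 + h) -
              ntcp_probability(f, dg$d50 - h)) / (2 * h)
  expect_equal(slope, 0.1 / 4, tolerance = 1e-6)
  # and on a fitted model with covariates
  co <- simulate_cohort(simulation_config(n = 2000, seed = 9))
  ff <- fit_ntcp(co, "MGM", "age")
  dg2 <- derive_d50_gamma(ff, c(age = 65))
  expect_equal(ntcp_probability(ff, dg2$d50, c(age = 65)), 0.5,
               tolerance = 1e-9)
  neg <- manual_fit(c(`(Intercept)` = 2, dose = -0.05))
  expect_error(derive_d50_gamma(neg), class = "radntcp_nonmonotone")
})

test_that("probability is increasing in age when the age coefficient is positive", {
  co <- simulate_cohort(simulation_config(n = 3000, seed = 10))
  f <- fit_ntcp(co, "MGM", "age")
  expect_gt(coef(f)[["age"]], 0)
  p <- vapply(c(45, 55, 65, 75),
              function(a) ntcp_probability(f, 55, c(age = a)), numeric(1))
  expect_true(all(diff(p) > 0))
})
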