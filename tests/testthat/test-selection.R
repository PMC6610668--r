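test_that("BIC score follows k*ln(n) - 2*lnL", {
  expect_equal(bic_score(0, 1, exp(1)), 1)
  # null model on 300 patients with 34 events
  ll0 <- 34 * log(34 / 300) + 266 * log(266 / 300)
  expect_equal(bic_score(ll0, 1, 300), 217.77, tolerance = 1e-2)
  # adding a zero-gain coefficient costs exactly ln(n)
  expect_equal(bic_score(ll0, 2, 300) - bic_score(ll0, 1, 300), log(300))
})

test_that("Benjamini-Hochberg adjustment matches the step-up oracle", {
  expect_equal(benjamini_hochberg(0.03), 0.03) # m = 1 identity
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)))
  withr::with_seed(41, {
    for (i in 1:20) {
      p <- runif(sample(3:12, 1))
      adj <- benjamini_hochberg(p)
      # brute-force step-up: adj_i = min over ranks >= rank_i of p_(j)*m/j
      m <- length(p)
      o <- order(p)
      brute <- numeric(m)
      brute[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
      brute <- pmin(brute, 1)
      expect_equal(adj, brute, tolerance = 1e-12)
      expect_true(all(adj >= p - 1e-12))
      # permutation equivariance
      perm <- sample(m)
      expect_equal(benjamini_hochberg(p[perm]), adj[perm])
    }
  })
})

test_that("roc_auc implements the Mann-Whitney pair count with ties at 1/2", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "radntcp_degenerate")
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(6:30, 1)
      s <- sample(seq(0, 1, 0.1), n, replace = TRUE) # ties likely
      y <- rbinom(n, 1, 0.4)
      if (length(unique(y)) < 2) next
      # brute force over all positive-negative pairs
      pos <- s[y == 1]; neg <- s[y == 0]
      brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
      expect_equal(roc_auc(s, y), brute, tolerance = 1e-12)
      # complement and monotone-transform invariance (tie-free case)
      s2 <- s + seq_along(s) * 1e-9
      expect_equal(roc_auc(s2, y) + roc_auc(-s2, y), 1)
      expect_equal(roc_auc(exp(3 * s2), y), roc_auc(s2, y))
    }
  })
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    s <- rnorm(80)
    y <- rbinom(80, 1, plogis(s))
    expect_equal(roc_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-10)
  })
})

test_that("forward stepwise selects the one true covariate and is deterministic", {
  cands <- c("age", "sex", "t_category", "smoking")
  hits <- 0L
  for (s in 1:20) {
    cfg <- simulation_config(
      n = 3000, seed = 300 + s,
      true_coefficients = c(intercept = -7.5, dose = 0.05, age = 0.08))
    co <- simulate_cohort(cfg)
    sel <- forward_stepwise(co, "MGM", cands)
    if (length(sel$selected) >= 1 && sel$selected[1] == "age") hits <- hits + 1L
  }
  expect_gte(hits, 18L)
  # determinism given cohort and candidate order
  co <- simulate_cohort(simulation_config(n = 1000, seed = 77))
  s1 <- forward_stepwise(co, "MGM", cands)
  s2 <- forward_stepwise(co, "MGM", cands)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$bic_trace, s2$bic_trace)
  # BIC trace strictly decreasing after the base model
  expect_true(all(diff(s1$bic_trace) < 0))
})

test_that("stepwise rejects pure-noise candidates most of the time", {
  empties <- 0L
  for (s in 1:20) {
    co <- simulate_cohort(simulation_config(
      n = 1000, seed = 600 + s,
      true_coefficients = c(intercept = -4.5, dose = 0.05, age = 0)))
    co$noise1 <- rnorm(nrow(co))
    co$noise2 <- rnorm(nrow(co))
    sel <- forward_stepwise(co, "MGM", c("noise1", "noise2", "smoking"))
    if (length(sel$selected) == 0) empties <- empties + 1L
  }
  expect_gte(empties, 15L)
})

test_that("duplicated candidates tie-break by list order", {
  co <- simulate_cohort(simulation_config(n = 2000, seed = 88))
  co$age_copy <- co$age
  sel <- forward_stepwise(co, "MGM", c("age", "age_copy"))
  expect_equal(sel$selected[1], "age")
})

test_that("diagnostics table adjusts dose and age families separately", {
  fits <- withr::with_seed(45, {
    lapply(1:8, function(i) {
      beta_d <- if (i == 1) 0.15 else 0.01 # one ROI with a strong dose effect
      co <- tibble::tibble(
        dose = runif(400, 20, 75), age = runif(400, 40, 80))
      co$outcome <- rbinom(400, 1, plogis(-6 + beta_d * co$dose + 0.03 * co$age))
      if (length(unique(co$outcome)) < 2) co$outcome[1:2] <- c(0, 1)
      fit_ntcp(co, "dose", "age")
    })
  })
  names(fits) <- paste0("ROI", 1:8)
  tab <- diagnostics_table(fits)
  expect_equal(nrow(tab), 8L)
  expect_equal(which.min(tab$dose_fdr_p), 1L)
  expect_true(all(tab$dose_fdr_p >= tab$dose_p - 1e-12))
  expect_true(all(tab$age_fdr_p >= tab$age_p - 1e-12))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  # identical fits give identical rows
  same <- diagnostics_table(list(A = fits[[2]], B = fits[[2]]))
  expect_equal(same$dose_fdr_p[1], same$dose_fdr_p[2])
  expect_equal(same$bic[1], same$bic[2])
  # a fit without an age term is refused
  co <- toy_cohort()
  expect_error(
    diagnostics_table(list(X = fit_ntcp(co, "dose", character()))))
})
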