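# Shared toy fixtures, all built in code.

# 20-patient toy cohort with a visible dose effect; used where a brute-force
# oracle over (beta0, beta_D) is feasible.
toy_cohort <- function() {
  tibble::tibble(
    patient_id = sprintf("T%02d", 1:20),
    age = rep(60, 20),
    dose = c(20, 25, 30, 32, 35, 38, 40, 42, 45, 48,
             50, 52, 55, 58, 60, 62, 65, 68, 70, 72),
    outcome = c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0,
                0, 1, 0, 1, 0, 1, 1, 0, 1, 1))
}

# hand-built fit object for closed-form checks
manual_fit <- function(beta, covariates = character(), roi = "dose") {
  structure(list(coefficients = beta,
                 vcov = diag(length(beta)) * NA_real_,
                 log_likelihood = NA_real_, bic = NA_real_,
                 wald_p = setNames(rep(NA_real_, length(beta)), names(beta)),
                 auc = NA_real_, n = 0L, n_events = 0L, roi = roi,
                 covariate_names = covariates),
            class = "ntcp_fit")
}

random_differential_dvh <- function(n_bins = 8) {
  doses <- sort(runif(n_bins, 1, 75))
  v <- runif(n_bins)
  dvh(doses, v / sum(v), kind = "differential")
}
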