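#' Proportional-odds (ordinal logistic) NTCP fit
#'
#' Fits a cumulative-logit proportional-odds model of an ordinal toxicity
#' grade on summary dose and covariates,
#' \eqn{P(G \ge g) = \mathrm{logit}^{-1}(\eta - \zeta_g)} with a shared
#' linear predictor \eqn{\eta = \beta_D D + \sum_x \beta_x x} and strictly
#' increasing thresholds \eqn{\zeta_g}. With exactly two grade levels the
#' model is the binary logistic fit, and is fitted as such (the single
#' threshold equals minus the binary intercept). Three or more levels are
#' fitted with [MASS::polr()].
#'
#' @inheritParams fit_ntcp
#' @param grade Name of the ordinal grade column (integer >= 0); default
#'   `"ordinal_grade"`.
#' @return An object of class `ntcp_ordinal`: `coefficients` (dose and
#'   covariate slopes, positive = higher grades more likely), `thresholds`
#'   (strictly increasing), `log_likelihood`, `bic`, `n`, `n_levels`.
#' @examples
#' co <- simulate_cohort(simulation_config(n = 500, seed = 11))
#' ordinal_fit(co, "MGM", "age")
#' @export
ordinal_fit <- function(cohort, roi, covariates = "age",
                        grade = "ordinal_grade") {
  if (!grade %in% names(cohort)) {
    abort(sprintf("Cohort lacks ordinal grade column `%s`.", grade))
  }
  g <- cohort[[grade]]
  levs <- sort(unique(g[!is.na(g)]))
  if (length(levs) < 2L) {
    abort("Ordinal fit needs >= 2 distinct grade levels.",
          class = "radntcp_degenerate")
  }
  if (length(levs) == 2L) {
    bin <- cohort
    bin$outcome <- as.integer(g == levs[2])
    f <- fit_ntcp(bin, roi, covariates)
    b <- f$coefficients
    return(structure(list(
      coefficients = b[-1],
      std_errors = sqrt(diag(f$vcov))[-1],
      thresholds = setNames(-b[["(Intercept)"]],
                            paste(levs[1], levs[2], sep = "|")),
      log_likelihood = f$log_likelihood, bic = f$bic, n = f$n,
      n_levels = 2L, roi = roi, covariate_names = f$covariate_names,
      backend = "binary"), class = "ntcp_ordinal"))
  }
  dat <- dplyr::select(cohort, dplyr::all_of(c(roi, covariates)))
  names(dat)[1] <- "dose"
  dat$.grade <- factor(g, levels = levs, ordered = TRUE)
  dat <- dat[complete.cases(dat), , drop = FALSE]
  fml <- stats::as.formula(paste(".grade ~ dose",
                                 if (length(covariates))
                                   paste("+", paste(covariates, collapse = " + "))
                                 else ""))
  m <- MASS::polr(fml, data = dat, Hess = TRUE)
  ll <- as.numeric(logLik(m))
  k <- length(m$coefficients) + length(m$zeta)
  se <- sqrt(diag(stats::vcov(m)))[seq_along(m$coefficients)]
  structure(list(
    coefficients = m$coefficients,
    std_errors = se,
    thresholds = m$zeta,
    log_likelihood = ll,
    bic = bic_score(ll, k, nrow(dat)),
    n = nrow(dat), n_levels = length(levs), roi = roi,
    covariate_names = covariates, backend = "polr"),
    class = "ntcp_ordinal")
}

#' @export
print.ntcp_ordinal <- function(x, ...) {
  cat(sprintf("Proportional-odds NTCP fit for %s (%d grade levels, n = %d)\n",
              x$roi, x$n_levels, x$n))
  cat("slopes:\n"); print(round(x$coefficients, 5))
  cat("thresholds:\n"); print(round(x$thresholds, 5))
  cat(sprintf("logLik = %.3f, BIC = %.2f\n", x$log_likelihood, x$bic))
  invisible(x)
}
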