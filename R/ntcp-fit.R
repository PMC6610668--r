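#' Bernoulli negative log-likelihood of a logistic NTCP model
#'
#' Evaluates \eqn{-\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)]} with
#' \eqn{p_i = \mathrm{logit}^{-1}(\beta_0 + \beta_D D_i + \sum_x \beta_x x_i)}
#' and probabilities clipped to `[1e-12, 1 - 1e-12]` before taking logs.
#'
#' @param beta Coefficient vector ordered (intercept, dose if `roi` given,
#'   covariates in `covariates` order).
#' @param cohort Cohort tibble; needs `outcome` plus the referenced columns.
#' @param roi Name of the summary-dose column, or `NULL` for a model with no
#'   dose term.
#' @param covariates Character vector of covariate column names.
#' @return Scalar negative log-likelihood.
#' @examples
#' co <- tibble::tibble(outcome = c(0, 1), MGM = c(40, 60), age = c(50, 70))
#' negative_log_likelihood(c(0, 0, 0), co, "MGM", "age")  # 2*log(2)
#' @export
negative_log_likelihood <- function(beta, cohort, roi = NULL,
                                    covariates = character()) {
  X <- build_design(cohort, roi, covariates)
  y <- cohort$outcome
  p <- plogis(drop(X %*% beta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

build_design <- function(cohort, roi, covariates) {
  if (nrow(cohort) == 0L) abort("Cohort is empty.")
  cols <- c(if (!is.null(roi)) roi, covariates)
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    abort(sprintf("Cohort lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(cohort)),
             if (!is.null(roi)) as.matrix(cohort[roi]),
             if (length(covariates)) as.matrix(cohort[covariates]))
  if (!is.null(roi)) colnames(X)[2] <- "dose"
  storage.mode(X) <- "double"
  X
}

#' Fit a logistic NTCP model by maximum likelihood
#'
#' Fits \eqn{P(\mathrm{RAD}) = \mathrm{logit}^{-1}(\beta_0 + \beta_D D +
#' \sum_x \beta_x x)} by Newton-Raphson on the Bernoulli log-likelihood
#' (convergence when the gradient max-norm drops below `1e-8`), with a
#' Nelder-Mead restart if a Newton step fails. The optimisation runs on
#' internally standardized predictors; quasi-complete separation is reported
#' as an error when any standardized coefficient exceeds 50 in magnitude
#' while the deviance is still falling. The covariance estimate is the
#' inverse observed information; Wald p-values are two-sided normal; the ROC
#' AUC of the fitted linear predictor is attached.
#'
#' @inheritParams negative_log_likelihood
#' @param cohort Cohort tibble with an `outcome` column in `{0, 1}` plus a
#'   summary-dose column per ROI and any covariate columns.
#' @return An object of class `ntcp_fit` with elements `coefficients`,
#'   `vcov`, `log_likelihood`, `bic`, `wald_p`, `auc`, `n`, `roi`,
#'   `covariate_names`. Supports [tidy()], [glance()], `coef()`, `logLik()`.
#' @examples
#' co <- simulate_cohort(simulation_config(n = 400, seed = 7))
#' fit_ntcp(co, roi = "MGM", covariates = "age")
#' @export
fit_ntcp <- function(cohort, roi = NULL, covariates = "age") {
  if (is.null(covariates)) covariates <- character()
  X <- build_design(cohort, roi, covariates)
  keep <- complete.cases(X) & !is.na(cohort$outcome)
  X <- X[keep, , drop = FALSE]
  y <- cohort$outcome[keep]
  n <- length(y)
  if (!all(y %in% c(0, 1))) abort("`outcome` must be coded 0/1.")
  if (all(y == y[1])) {
    abort("Cohort has a single outcome class; need >= 1 event and >= 1 non-event.",
          class = "radntcp_degenerate")
  }
  # standardize non-intercept columns so the separation cap is scale-free
  ctr <- c(0, colMeans(X[, -1, drop = FALSE]))
  scl <- c(1, apply(X[, -1, drop = FALSE], 2, function(v) {
    s <- stats::sd(v); if (s < 1e-12) 1 else s
  }))
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Z[, 1] <- 1

  b <- rep(0, ncol(Z))
  nll <- function(bb) {
    p <- plogis(drop(Z %*% bb))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  grad_max <- Inf
  for (it in seq_len(200)) {
    eta <- drop(Z %*% b)
    p <- plogis(eta)
    g <- drop(crossprod(Z, y - p))
    grad_max <- max(abs(g))
    if (grad_max < 1e-8) break
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Z * w, Z)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      opt <- stats::optim(b, nll, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12))
      b <- opt$par
      next
    }
    # step-halve if the full Newton step overshoots
    f0 <- nll(b)
    lambda <- 1
    repeat {
      bn <- b + lambda * step
      if (nll(bn) <= f0 + 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    b <- bn
    if (length(b) > 1L && max(abs(b[-1])) > 50) {
      abort(paste("Quasi-complete separation: a standardized coefficient",
                  "exceeded 50 while the deviance was still decreasing."),
            class = "radntcp_separation")
    }
  }
  if (grad_max >= 1e-6) {
    opt <- stats::optim(b, nll, method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-14))
    b <- opt$par
    p <- plogis(drop(Z %*% b))
    grad_max <- max(abs(drop(crossprod(Z, y - p))))
    if (grad_max >= 1e-4) {
      abort("Logistic MLE did not converge.", class = "radntcp_no_convergence")
    }
  }
  # perfect prediction = complete separation: the likelihood is unbounded
  # and only the probability clipping stopped the coefficients growing
  p_conv <- plogis(drop(Z %*% b))
  if (max(abs(y - p_conv)) < 1e-6) {
    abort("Complete separation: the model predicts every outcome perfectly.",
          class = "radntcp_separation")
  }
  # back-transform: beta_orig_j = b_j / s_j; intercept absorbs the centers
  beta <- b / scl
  beta[1] <- b[1] - sum((ctr / scl * b)[-1])
  names(beta) <- colnames(X)
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  info <- crossprod(X * w, X)
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(names(beta), names(beta))
  se <- sqrt(diag(vc))
  zstat <- beta / se
  ll <- -negative_ll_from_eta(eta, y)
  k <- length(beta)
  fit <- structure(list(
    coefficients = beta,
    vcov = vc,
    log_likelihood = ll,
    bic = bic_score(ll, k, n),
    wald_p = 2 * pnorm(-abs(zstat)),
    auc = if (!is.null(roi) || length(covariates)) roc_auc(eta, y) else NA_real_,
    n = n,
    n_events = sum(y),
    roi = roi,
    covariate_names = covariates,
    gradient_max = grad_max
  ), class = "ntcp_fit")
  fit
}

negative_ll_from_eta <- function(eta, y) {
  p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

#' @export
print.ntcp_fit <- function(x, ...) {
  cat(sprintf("Logistic NTCP fit%s (n = %d, events = %d)\n",
              if (is.null(x$roi)) "" else paste0(" for ", x$roi),
              x$n, x$n_events))
  print(round(x$coefficients, 5))
  cat(sprintf("logLik = %.3f, BIC = %.2f, AUC = %s\n", x$log_likelihood,
              x$bic, if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' @export
coef.ntcp_fit <- function(object, ...) object$coefficients

#' @export
vcov.ntcp_fit <- function(object, ...) object$vcov

#' @export
logLik.ntcp_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

resolve_profile <- function(fit, profile) {
  covs <- fit$covariate_names
  if (length(covs) == 0L) return(numeric(0))
  profile <- unlist(profile)
  missing <- setdiff(covs, names(profile))
  if (length(missing)) {
    abort(sprintf("Covariate profile lacks: %s.",
                  paste(missing, collapse = ", ")),
          class = "radntcp_missing_covariate")
  }
  profile[covs]
}

#' Predicted complication probability from a fitted NTCP model
#'
#' @param fit An `ntcp_fit`.
#' @param dose Dose(s) in Gy (EQD2 summary dose).
#' @param profile Named vector or list supplying every covariate in the fit
#'   (e.g. `c(age = 65)`).
#' @return Probabilities in `(0, 1)`, one per dose.
#' @examples
#' co <- simulate_cohort(simulation_config(n = 400, seed = 7))
#' f <- fit_ntcp(co, "MGM", "age")
#' ntcp_probability(f, c(40, 60), profile = c(age = 70))
#' @export
ntcp_probability <- function(fit, dose, profile = NULL) {
  stopifnot(inherits(fit, "ntcp_fit"))
  x <- resolve_profile(fit, profile)
  b <- fit$coefficients
  lp <- b[["(Intercept)"]] +
    (if (!is.null(fit$roi)) b[["dose"]] * dose else 0) +
    (if (length(x)) sum(b[fit$covariate_names] * x) else 0)
  unname(plogis(lp))
}

#' D50 / gamma50 dose-response parameters of a fitted model
#'
#' Re-parameterizes the logistic fit, at a fixed covariate profile, into the
#' dose giving 50% complication probability, \eqn{D_{50} = -(\beta_0 +
#' \sum_x \beta_x x)/\beta_D}, and the normalized slope at that dose,
#' \eqn{\gamma_{50} = \beta_D D_{50} / 4}.
#'
#' @inheritParams ntcp_probability
#' @return A tibble with columns `d50` (Gy) and `gamma50`.
#' @export
derive_d50_gamma <- function(fit, profile = NULL) {
  stopifnot(inherits(fit, "ntcp_fit"))
  if (is.null(fit$roi)) abort("Fit has no dose term.")
  b <- fit$coefficients
  if (b[["dose"]] <= 0) {
    abort("Dose coefficient is not positive; dose-response is non-monotone increasing.",
          class = "radntcp_nonmonotone")
  }
  x <- resolve_profile(fit, profile)
  offset <- b[["(Intercept)"]] +
    (if (length(x)) sum(b[fit$covariate_names] * x) else 0)
  d50 <- -offset / b[["dose"]]
  tibble::tibble(d50 = d50, gamma50 = b[["dose"]] * d50 / 4)
}
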