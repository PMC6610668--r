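#' Bootstrap an NTCP fit by case resampling
#'
#' Draws `B` resamples of the cohort rows (with replacement, size `n`),
#' refits the model on each, and keeps the coefficient vectors of the
#' replicates that converge. Separated or non-converged replicates are
#' flagged and excluded from percentile bands. Identical `seed` and cohort
#' give an identical ensemble.
#'
#' @inheritParams fit_ntcp
#' @param B Number of bootstrap replicates (default 2000).
#' @param seed Integer seed controlling the resampling.
#' @return An object of class `ntcp_boot`: `seed`, `B`, `coefficients`
#'   (matrix, one row per converged replicate), `converged` (logical, length
#'   `B`), `fit` (the full-data fit), `roi`, `covariate_names`.
#' @examples
#' co <- simulate_cohort(simulation_config(n = 300, seed = 3))
#' bootstrap_ntcp(co, "MGM", "age", B = 25, seed = 1)
#' @export
bootstrap_ntcp <- function(cohort, roi, covariates = "age", B = 2000,
                           seed = 1) {
  check_number(B, "B", lower = 1)
  fit <- fit_ntcp(cohort, roi, covariates)
  n <- nrow(cohort)
  k <- length(fit$coefficients)
  coefs <- matrix(NA_real_, nrow = B, ncol = k,
                  dimnames = list(NULL, names(fit$coefficients)))
  converged <- logical(B)
  local_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      rep_fit <- tryCatch(fit_ntcp(cohort[idx, , drop = FALSE], roi, covariates),
                          error = function(e) NULL)
      if (!is.null(rep_fit)) {
        coefs[b, ] <- rep_fit$coefficients
        converged[b] <- TRUE
      }
    }
  })
  if (mean(converged) < 0.5) {
    abort(sprintf(
      "Only %d/%d bootstrap replicates converged; the model is too unstable for percentile bands.",
      sum(converged), B), class = "radntcp_boot_unstable")
  }
  structure(list(seed = seed, B = B,
                 coefficients = coefs[converged, , drop = FALSE],
                 converged = converged, fit = fit, roi = roi,
                 covariate_names = fit$covariate_names),
            class = "ntcp_boot")
}

#' @export
print.ntcp_boot <- function(x, ...) {
  cat(sprintf("NTCP bootstrap ensemble: %d/%d converged replicates (seed %d)\n",
              sum(x$converged), x$B, x$seed))
  print(boot_ci(x))
  invisible(x)
}

#' Percentile confidence intervals from a bootstrap ensemble
#'
#' @param ensemble An `ntcp_boot` object.
#' @param level Confidence level (default 0.95).
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `lower`, `upper`.
#' @export
boot_ci <- function(ensemble, level = 0.95) {
  stopifnot(inherits(ensemble, "ntcp_boot"))
  alpha <- (1 - level) / 2
  qs <- apply(ensemble$coefficients, 2, quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  tibble::tibble(term = colnames(ensemble$coefficients),
                 estimate = unname(ensemble$fit$coefficients),
                 lower = qs[1, ], upper = qs[2, ])
}
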