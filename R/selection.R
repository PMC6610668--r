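#' Bayesian information criterion
#'
#' \eqn{\mathrm{BIC} = k \ln n - 2 \ln L}; lower is more parsimonious.
#'
#' @param log_likelihood Maximized log-likelihood.
#' @param k Number of fitted coefficients (>= 1).
#' @param n Number of observations (>= 1).
#' @return Scalar BIC.
#' @examples
#' bic_score(0, 1, exp(1))  # 1
#' @export
bic_score <- function(log_likelihood, k, n) {
  check_number(log_likelihood, "log_likelihood")
  check_number(k, "k", lower = 1)
  check_number(n, "n", lower = 1)
  k * log(n) - 2 * log_likelihood
}

#' Forward-stepwise covariate selection by BIC
#'
#' Starting from the dose-only base model, greedily adds the candidate
#' covariate whose inclusion lowers BIC the most, and stops when no
#' remaining candidate lowers it. Candidates whose fit fails (e.g.
#' separation) are excluded with a warning. Deterministic: ties are broken
#' by lowest BIC, then candidate-list order.
#'
#' @inheritParams fit_ntcp
#' @param candidates Character vector of candidate covariate columns.
#' @return An object of class `ntcp_selection`: `roi`, `candidates`,
#'   `selected` (in selection order), `bic_trace` (base model first, then
#'   one BIC per accepted covariate), `final_fit`.
#' @examples
#' co <- simulate_cohort(simulation_config(n = 600, seed = 5))
#' forward_stepwise(co, "MGM", c("age", "sex", "smoking"))
#' @export
forward_stepwise <- function(cohort, roi, candidates) {
  if (length(candidates) == 0L) abort("Need at least one candidate covariate.")
  selected <- character()
  base <- fit_ntcp(cohort, roi, selected)
  trace <- base$bic
  best_fit <- base
  remaining <- candidates
  while (length(remaining)) {
    bics <- vapply(remaining, function(cand) {
      tryCatch(fit_ntcp(cohort, roi, c(selected, cand))$bic,
               error = function(e) {
                 warn(sprintf("Candidate `%s` excluded at this step: %s",
                              cand, conditionMessage(e)))
                 Inf
               })
    }, numeric(1))
    if (min(bics) >= trace[length(trace)] - 1e-12) break
    pick <- remaining[which.min(bics)] # which.min keeps first on ties
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    trace <- c(trace, min(bics))
    best_fit <- fit_ntcp(cohort, roi, selected)
  }
  structure(list(roi = roi, candidates = candidates, selected = selected,
                 bic_trace = trace, final_fit = best_fit),
            class = "ntcp_selection")
}

#' @export
print.ntcp_selection <- function(x, ...) {
  cat(sprintf("Forward-stepwise BIC selection for %s\n", x$roi))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat("BIC trace:", paste(sprintf("%.2f", x$bic_trace), collapse = " -> "), "\n")
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; the output keeps
#' the input order. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.04))  # 0.03 0.03 0.04
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    abort("All p-values must be numbers in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' ROC AUC by the Mann-Whitney formulation
#'
#' Fraction of (positive, negative) score pairs correctly ordered, with tied
#' pairs counted 1/2 — computed from midranks, so it matches the area under
#' the empirical ROC curve with linear tie interpolation.
#'
#' @param scores Numeric risk scores (higher = more likely positive).
#' @param outcomes Binary outcomes in `{0, 1}`, same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) {
    abort("`scores` and `outcomes` must have equal length.")
  }
  if (!all(outcomes %in% c(0, 1))) abort("`outcomes` must be coded 0/1.")
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) {
    abort("Need at least one positive and one negative outcome.",
          class = "radntcp_degenerate")
  }
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-ROI model diagnostics table
#'
#' Collects the Wald p-values for the dose and age coefficients across a set
#' of per-ROI fits, adjusts each column as its own Benjamini-Hochberg
#' family (all ROIs' dose p-values together, all age p-values together), and
#' attaches each model's BIC and ROC AUC.
#'
#' @param fits Named list of `ntcp_fit` objects (names are the ROI/muscle
#'   labels); every fit must contain dose and age coefficients.
#' @return A tibble with columns `muscle`, `dose_p`, `age_p`, `dose_fdr_p`,
#'   `age_fdr_p`, `bic`, `auc`.
#' @export
diagnostics_table <- function(fits) {
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, function(f) f$roi %||% "ROI", character(1))
  }
  rows <- purrr::imap(fits, function(f, nm) {
    if (!"dose" %in% names(f$wald_p) || !"age" %in% names(f$wald_p)) {
      abort(sprintf("Fit `%s` lacks a dose or age coefficient.", nm))
    }
    tibble::tibble(muscle = nm, dose_p = f$wald_p[["dose"]],
                   age_p = f$wald_p[["age"]], bic = f$bic, auc = f$auc)
  })
  out <- dplyr::bind_rows(rows)
  out$dose_fdr_p <- benjamini_hochberg(out$dose_p)
  out$age_fdr_p <- benjamini_hochberg(out$age_p)
  dplyr::select(out, "muscle", "dose_p", "age_p", "dose_fdr_p", "age_fdr_p",
                "bic", "auc")
}
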