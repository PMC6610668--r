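#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a fitted NTCP model
#'
#' @param x An `ntcp_fit`.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @export
tidy.ntcp_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(se),
                 statistic = unname(x$coefficients / se),
                 p.value = unname(x$wald_p))
}

#' One-row model summary of a fitted NTCP model
#'
#' @param x An `ntcp_fit`.
#' @param ... Unused.
#' @return A tibble with `logLik`, `bic`, `auc`, `nobs`, `n_events`, `df`.
#' @export
glance.ntcp_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, bic = x$bic, auc = x$auc,
                 nobs = x$n, n_events = x$n_events,
                 df = length(x$coefficients))
}

#' Tidy a bootstrap ensemble
#'
#' @param x An `ntcp_boot`.
#' @param ... Passed to [boot_ci()] (e.g. `level`).
#' @return Per-coefficient point estimate and percentile interval.
#' @export
tidy.ntcp_boot <- function(x, ...) boot_ci(x, ...)

#' Tidy a stepwise-selection result
#'
#' @param x An `ntcp_selection`.
#' @param ... Unused.
#' @return One row per selection step: `step`, `added`, `bic`.
#' @export
tidy.ntcp_selection <- function(x, ...) {
  tibble::tibble(step = seq_along(x$bic_trace) - 1L,
                 added = c("(base)", x$selected),
                 bic = x$bic_trace)
}
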