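#' Age-stratified NTCP curves with bootstrap bands
#'
#' Evaluates the fitted dose-response at every grid dose for each age
#' stratum's representative age. The central curve comes from the point fit;
#' the 2.5/97.5 percentile band at each grid dose comes from re-evaluating
#' every converged bootstrap replicate there. With a positive age
#' coefficient the per-stratum curves are ordered by age at every dose.
#'
#' @inheritParams constraint_table
#' @param fit An `ntcp_fit` containing dose and age coefficients.
#' @param ensemble Optional `ntcp_boot` for the same model; `NULL` gives the
#'   central curve only, with a warning.
#' @param dose_grid Strictly increasing dose grid in Gy.
#' @param level Band coverage (default 0.95).
#' @return A tibble of class `ntcp_curveset` with columns `roi`,
#'   `age_stratum`, `age`, `dose`, `ntcp`, `lower`, `upper`.
#' @examples
#' co <- simulate_cohort(simulation_config(n = 300, seed = 3))
#' f <- fit_ntcp(co, "MGM", "age")
#' bs <- bootstrap_ntcp(co, "MGM", "age", B = 25, seed = 1)
#' ntcp_curves(f, bs, dose_grid = seq(0, 80, 5))
#' @export
ntcp_curves <- function(fit, ensemble = NULL, dose_grid = seq(0, 80, by = 1),
                        age_strata = default_age_strata(), level = 0.95,
                        profile = NULL) {
  stopifnot(inherits(fit, "ntcp_fit"))
  if (any(diff(dose_grid) <= 0)) {
    abort("`dose_grid` must be strictly increasing.")
  }
  if (!"age" %in% fit$covariate_names) abort("Fit has no age coefficient.")
  if (is.null(ensemble)) {
    warn("No bootstrap ensemble supplied; returning central curves without bands.")
  } else {
    stopifnot(inherits(ensemble, "ntcp_boot"))
  }
  alpha <- (1 - level) / 2
  extra <- unlist(profile)
  strata_rows <- purrr::map2(age_strata$age_stratum, age_strata$age,
                             function(lab, a) {
    prof <- c(age = a, extra)
    central <- ntcp_probability(fit, dose_grid, prof)
    if (!is.null(ensemble) && nrow(ensemble$coefficients) > 0) {
      cf <- ensemble$coefficients
      x <- resolve_profile(fit, prof)
      offs <- cf[, "(Intercept)"] +
        (if (length(x)) drop(cf[, fit$covariate_names, drop = FALSE] %*% x)
         else 0)
      # replicates x grid matrix of predicted probabilities
      pm <- plogis(outer(offs, rep(1, length(dose_grid))) +
                     outer(cf[, "dose"], dose_grid))
      lo <- apply(pm, 2, quantile, probs = alpha, names = FALSE)
      hi <- apply(pm, 2, quantile, probs = 1 - alpha, names = FALSE)
    } else {
      lo <- hi <- rep(NA_real_, length(dose_grid))
    }
    tibble::tibble(roi = fit$roi, age_stratum = lab, age = a,
                   dose = dose_grid, ntcp = central, lower = lo, upper = hi)
  })
  out <- dplyr::bind_rows(strata_rows)
  class(out) <- c("ntcp_curveset", class(out))
  out
}

#' Plot age-stratified NTCP curves
#'
#' @param object An `ntcp_curveset` from [ntcp_curves()].
#' @param ... Unused.
#' @return A ggplot object: one dose-response curve per age stratum with its
#'   percentile ribbon where bands are available.
#' @export
autoplot.ntcp_curveset <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$dose, y = .data$ntcp,
                                    colour = .data$age_stratum,
                                    fill = .data$age_stratum))
  if (!all(is.na(object$lower))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      alpha = 0.15, colour = NA)
  }
  p + ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Mean dose to ROI (EQD2 Gy)",
                  y = "Predicted probability of chronic RAD",
                  colour = "Age", fill = "Age",
                  title = unique(object$roi)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot an age-stratified constraint table
#'
#' @param object An `ntcp_constraints` tibble from [constraint_table()].
#' @param ... Unused.
#' @return A ggplot dot plot of constraint dose by muscle and age stratum.
#' @export
autoplot.ntcp_constraints <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = pmax(.data$dose_gy, 0),
                               y = .data$muscle,
                               colour = .data$age_stratum)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = sprintf("Mean dose (Gy) at %.0f%% predicted risk",
                  100 * (attr(object, "risk_target") %||% 0.05)),
      y = NULL, colour = "Age") +
    ggplot2::theme_minimal()
}
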