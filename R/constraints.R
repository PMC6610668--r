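#' Dose achieving a target complication risk
#'
#' Inverts a fitted logistic NTCP model at a fixed covariate profile:
#' \eqn{D = (\mathrm{logit}(r) - \beta_0 - \sum_x \beta_x x)/\beta_D}. The
#' closed form can be cross-checked against a bisection solve of
#' `ntcp_probability(fit, D, profile) = risk` via `method = "bisection"`;
#' both agree to well under `1e-6` Gy.
#'
#' If the model's baseline risk at 0 Gy already exceeds the target, the
#' closed-form dose is negative: a classed warning (`radntcp_below_floor`)
#' is emitted and the value is returned with attribute `below_floor = TRUE`
#' so downstream tables can flag the cell.
#'
#' @inheritParams ntcp_probability
#' @param risk Target complication probability in `(0, 1)` (default 0.05).
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return Dose in Gy (possibly negative when below floor), with a logical
#'   `below_floor` attribute.
#' @examples
#' co <- simulate_cohort(simulation_config(n = 400, seed = 7))
#' f <- fit_ntcp(co, "MGM", "age")
#' invert_dose_for_risk(f, profile = c(age = 65), risk = 0.05)
#' @export
invert_dose_for_risk <- function(fit, profile = NULL, risk = 0.05,
                                 method = c("closed_form", "bisection")) {
  stopifnot(inherits(fit, "ntcp_fit"))
  method <- match.arg(method)
  check_number(risk, "risk", lower = 1e-12, upper = 1 - 1e-12)
  if (is.null(fit$roi)) abort("Fit has no dose term.")
  b <- fit$coefficients
  if (b[["dose"]] <= 0) {
    abort("Dose coefficient is not positive; cannot invert an increasing dose-response.",
          class = "radntcp_nonmonotone")
  }
  x <- resolve_profile(fit, profile)
  offset <- b[["(Intercept)"]] +
    (if (length(x)) sum(b[fit$covariate_names] * x) else 0)
  d_closed <- (qlogis(risk) - offset) / b[["dose"]]
  d <- if (method == "closed_form") {
    d_closed
  } else {
    lo <- min(0, d_closed) - 1
    hi <- max(1, d_closed) + 1
    uniroot(function(dd) plogis(offset + b[["dose"]] * dd) - risk,
            lower = lo, upper = hi, tol = 1e-10)$root
  }
  below <- plogis(offset) > risk # baseline risk at 0 Gy above target
  if (below) {
    warn(sprintf("Baseline NTCP at 0 Gy (%.3f) already exceeds the %.1f%% target.",
                 plogis(offset), 100 * risk),
         class = "radntcp_below_floor")
  }
  structure(unname(d), below_floor = below)
}

#' Default decade-of-age strata
#'
#' Decade strata with the representative age at which the continuous-age
#' model is evaluated for each stratum.
#'
#' @return A tibble with columns `age_stratum` and `age` (45, 55, 65, 75).
#' @export
default_age_strata <- function() {
  tibble::tibble(age_stratum = c("<=49", "50-59", "60-69", ">=70"),
                 age = c(45, 55, 65, 75))
}

#' Age-stratified mean-dose constraint table
#'
#' For each fitted ROI model and each age stratum, the mean (EQD2 gEUD)
#' dose at which the predicted complication risk equals `risk`. Doses are
#' reported rounded to the nearest integer Gy; any cell under the floor
#' (default 10 Gy, including baseline-risk-above-target cells) is displayed
#' as `"<10"`. With a positive age coefficient the constraint tightens
#' (decreases) with age at exactly \eqn{-\beta_{age}/\beta_D} Gy per year.
#'
#' @param fits Named list of `ntcp_fit` objects containing dose and age
#'   coefficients (names = muscle labels).
#' @param age_strata Tibble with `age_stratum` and representative `age`
#'   columns; defaults to [default_age_strata()].
#' @param risk Target risk (default 0.05).
#' @param floor Display floor in Gy (default 10).
#' @param profile Named values for any additional covariates in the fits.
#' @return A tibble of class `ntcp_constraints` with columns `muscle`,
#'   `age_stratum`, `age`, `dose_gy` (full precision), `dose_display`
#'   (integer Gy as character, or `"<10"`), `below_floor`.
#' @export
constraint_table <- function(fits, age_strata = default_age_strata(),
                             risk = 0.05, floor = 10, profile = NULL) {
  if (is.null(names(fits)) || any(!nzchar(names(fits)))) {
    names(fits) <- vapply(fits, function(f) f$roi %||% "ROI", character(1))
  }
  rows <- purrr::imap(fits, function(f, nm) {
    if (!"age" %in% f$covariate_names) {
      abort(sprintf("Fit `%s` has no age coefficient.", nm))
    }
    cells <- purrr::map2(age_strata$age_stratum, age_strata$age,
                         function(lab, a) {
      prof <- c(age = a, unlist(profile))
      d <- withCallingHandlers(
        tryCatch(invert_dose_for_risk(f, prof, risk),
                 radntcp_nonmonotone = function(e) {
                   structure(NA_real_, below_floor = NA)
                 }),
        radntcp_below_floor = function(w) invokeRestart("muffleWarning"))
      tibble::tibble(muscle = nm, age_stratum = lab, age = a,
                     dose_gy = as.numeric(d),
                     below_floor = isTRUE(attr(d, "below_floor")) |
                       (!is.na(d) && d < floor))
    })
    dplyr::bind_rows(cells)
  })
  out <- dplyr::bind_rows(rows)
  out$dose_display <- dplyr::case_when(
    is.na(out$dose_gy) ~ NA_character_,
    out$dose_gy < floor ~ paste0("<", floor),
    TRUE ~ as.character(round(out$dose_gy)))
  out <- dplyr::select(out, "muscle", "age_stratum", "age", "dose_gy",
                       "dose_display", "below_floor")
  attr(out, "risk_target") <- risk
  attr(out, "floor") <- floor
  class(out) <- c("ntcp_constraints", class(out))
  out
}
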