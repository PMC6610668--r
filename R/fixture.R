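#' Published contingency counts for chronic radiation-associated dysphagia
#'
#' The printed decade-of-age contingency structure of the 300-patient
#' chemo-IMRT oropharyngeal cohort the package's defaults emulate: stratum
#' denominators 58/148/68/26, chronic-RAD events 4/14/11/5 (34 overall),
#' and the component event counts (videofluoroscopy-detected aspiration 21
#' and stricture 10, gastrostomy tube at 12 months 18, at 24 months 10, at
#' last disease-free follow-up 12; each out of 300).
#'
#' @return An object of class `rad_counts`: a list with tibbles `strata`
#'   (`stratum`, `n`, `events`) and `components` (`component`, `events`,
#'   `n`).
#' @examples
#' prevalence_by_stratum(rad_counts_fixture())
#' component_rates(rad_counts_fixture())
#' @export
rad_counts_fixture <- function() {
  strata <- tibble::tibble(
    stratum = c("<=49", "50-59", "60-69", ">=70"),
    n = c(58L, 148L, 68L, 26L),
    events = c(4L, 14L, 11L, 5L))
  components <- tibble::tibble(
    component = c("aspiration", "stricture", "gtube_12mo", "gtube_24mo",
                  "gtube_last_fu"),
    events = c(21L, 10L, 18L, 10L, 12L),
    n = 300L)
  stopifnot(sum(strata$events) == 34L, sum(strata$n) == 300L)
  structure(list(strata = strata, components = components),
            class = "rad_counts")
}

#' @export
print.rad_counts <- function(x, ...) {
  cat("Chronic-RAD contingency counts (n = 300)\n")
  print(x$strata)
  print(x$components)
  invisible(x)
}

#' Component event rates from a counts fixture
#'
#' @param fixture A `rad_counts` object.
#' @return A tibble `component`, `events`, `n`, `percent` (rounded to the
#'   nearest integer).
#' @export
component_rates <- function(fixture = rad_counts_fixture()) {
  stopifnot(inherits(fixture, "rad_counts"))
  dplyr::mutate(fixture$components,
                percent = round(100 * .data$events / .data$n))
}
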