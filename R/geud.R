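#' Fractionation scheme
#'
#' @param total_dose Prescribed total dose in Gy (> 0).
#' @param n_fractions Number of fractions (integer >= 1).
#' @return A `fractionation_scheme` list.
#' @examples
#' fractionation_scheme(70, 33)
#' @export
fractionation_scheme <- function(total_dose, n_fractions) {
  check_number(total_dose, "total_dose", lower = 1e-9)
  check_number(n_fractions, "n_fractions", lower = 1)
  if (n_fractions != round(n_fractions)) {
    abort("`n_fractions` must be an integer.")
  }
  structure(list(total_dose = total_dose, n_fractions = as.integer(n_fractions)),
            class = "fractionation_scheme")
}

#' Convert a differential DVH to 2-Gy equivalents (EQD2)
#'
#' Applies the linear-quadratic fractionation correction bin by bin. With a
#' per-bin dose per fraction \eqn{d_i = D_i / n}, each bin dose becomes
#' \deqn{D_i \cdot \frac{d_i + \alpha/\beta}{2 + \alpha/\beta},}
#' the isoeffective dose delivered in 2-Gy fractions. Bins at exactly
#' 2 Gy/fraction are unchanged; bins above 2 Gy/fraction move up, bins below
#' move down. Volumes are untouched.
#'
#' @param x A differential `dvh`.
#' @param scheme A [fractionation_scheme()] (only `n_fractions` is used: the
#'   whole DVH is assumed delivered in the same number of fractions).
#' @param alpha_beta Linear-quadratic alpha/beta ratio in Gy; default 3 Gy,
#'   typical of late-responding muscle.
#' @return A differential `dvh` on the EQD2 dose scale.
#' @examples
#' d <- dvh(60, 1, kind = "differential")
#' eqd2_transform(d, fractionation_scheme(60, 20), alpha_beta = 3)  # 72 Gy
#' @export
eqd2_transform <- function(x, scheme, alpha_beta = 3) {
  if (dvh_kind(x) != "differential") {
    abort("EQD2 transform expects a differential DVH.",
          class = "radntcp_dvh_invalid")
  }
  check_number(alpha_beta, "alpha_beta", lower = 1e-9)
  if (!inherits(scheme, "fractionation_scheme")) {
    scheme <- do.call(fractionation_scheme, as.list(scheme))
  }
  d_per_fx <- x$dose / scheme$n_fractions
  new_dose <- x$dose * (d_per_fx + alpha_beta) / (2 + alpha_beta)
  out <- x
  out$dose <- new_dose
  out
}

#' Generalized mean (gEUD) of a differential DVH
#'
#' The power-mean reduction \eqn{(\sum_i v_i D_i^a)^{1/a}} used to collapse
#' an ROI's heterogeneous dose distribution to a single summary dose.
#' `a = 1` gives the arithmetic mean dose; large `a` approaches the maximum
#' dose; the result is non-decreasing in `a` (power-mean inequality) and
#' always lies between the minimum and maximum bin dose.
#'
#' @param x A differential `dvh`.
#' @param a Power-mean exponent; must be non-zero. Default 1 (mean dose),
#'   matching constraint reporting in mean-dose units.
#' @return Summary dose in Gy.
#' @examples
#' d <- dvh(c(40, 60), c(0.5, 0.5), kind = "differential")
#' generalized_mean_dose(d, a = 1)  # 50
#' generalized_mean_dose(d, a = 2)  # 50.99
#' @export
generalized_mean_dose <- function(x, a = 1) {
  if (dvh_kind(x) != "differential") {
    abort("gEUD expects a differential DVH; convert cumulative input first.",
          class = "radntcp_dvh_invalid")
  }
  check_number(a, "a")
  if (a == 0) {
    abort("Exponent `a` must be non-zero (geometric-mean variant not supported).")
  }
  # structural checks only: masses need not sum to exactly 1 (a cumulative
  # source ending above zero volume leaves a deficit); weights renormalise
  if (nrow(x) == 0L || anyNA(x$dose) || anyNA(x$volume) ||
      any(x$dose < 0) || any(x$volume < -1e-12) ||
      (nrow(x) > 1L && any(diff(x$dose) <= 0))) {
    abort("Invalid differential DVH.", class = "radntcp_dvh_invalid")
  }
  w <- x$volume / sum(x$volume)
  # log-space accumulation keeps large |a| stable
  pos <- x$dose > 0
  if (!any(pos)) return(0)
  if (a > 0) {
    m <- max(x$dose[pos])
    s <- sum(w[pos] * exp(a * (log(x$dose[pos]) - log(m))))
    m * exp(log(s) / a)
  } else {
    if (!all(pos)) return(0) # zero-dose bin dominates for a < 0
    m <- min(x$dose)
    s <- sum(w * exp(a * (log(x$dose) - log(m))))
    m * exp(log(s) / a)
  }
}

#' Reduce a DVH to a fractionation-corrected summary dose
#'
#' Convenience chain: cumulative input is converted to differential form,
#' transformed to EQD2, and collapsed with [generalized_mean_dose()].
#'
#' @inheritParams eqd2_transform
#' @param x A `dvh` (cumulative or differential).
#' @param a gEUD exponent (default 1, mean dose).
#' @return Summary EQD2 gEUD in Gy.
#' @export
reduce_dvh <- function(x, scheme, a = 1, alpha_beta = 3) {
  if (dvh_kind(x) == "cumulative") x <- cumulative_to_differential(x)
  generalized_mean_dose(eqd2_transform(x, scheme, alpha_beta), a = a)
}

#' Reduce a directory of per-patient, per-ROI DVH files
#'
#' Expects files named `<patient_id>_<roi>.<ext>` (e.g. `P001_MGM.csv`).
#' Every patient must have a file for every requested ROI.
#'
#' @param dir Directory of DVH text files.
#' @param rois Character vector of ROI names to collect.
#' @param scheme A [fractionation_scheme()], or a data frame with columns
#'   `patient_id`, `total_dose`, `n_fractions` for per-patient schemes.
#' @param a gEUD exponent, recycled across ROIs or a named vector per ROI.
#' @param alpha_beta Alpha/beta ratio in Gy.
#' @param kind DVH kind of the stored files.
#' @return A tibble with `patient_id` and one summary-dose column per ROI.
#' @export
reduce_dvh_dir <- function(dir, rois, scheme, a = 1, alpha_beta = 3,
                           kind = "cumulative") {
  files <- list.files(dir, full.names = TRUE)
  stems <- sub("\\.[^.]*$", "", basename(files))
  ids <- unique(sub("_[^_]+$", "", stems))
  if (length(ids) == 0L) abort(sprintf("No DVH files found in %s.", dir))
  exps <- if (is.null(names(a))) setNames(rep_len(a, length(rois)), rois) else a
  per_patient <- function(id) {
    sch <- if (is.data.frame(scheme)) {
      row <- scheme[scheme$patient_id == id, , drop = FALSE]
      if (nrow(row) != 1L) {
        abort(sprintf("No fractionation scheme for patient %s.", id))
      }
      fractionation_scheme(row$total_dose, row$n_fractions)
    } else scheme
    vals <- vapply(rois, function(roi) {
      f <- files[stems == paste(id, roi, sep = "_")]
      if (length(f) != 1L) {
        abort(sprintf("Missing DVH file for patient %s, ROI %s.", id, roi),
              class = "radntcp_missing_dvh")
      }
      reduce_dvh(parse_dvh(f, kind = kind, roi = roi), sch,
                 a = exps[[roi]], alpha_beta = alpha_beta)
    }, numeric(1))
    tibble::tibble(patient_id = id, !!!as.list(vals))
  }
  dplyr::bind_rows(lapply(ids, per_patient))
}
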