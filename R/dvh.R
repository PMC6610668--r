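#' Construct a dose-volume histogram
#'
#' A DVH is stored as a tibble with columns `dose` (Gy) and `volume`
#' (fraction of the ROI volume), plus attributes `kind` (`"cumulative"` or
#' `"differential"`) and `roi`. Cumulative volumes are the fraction of the
#' ROI receiving at least each dose; differential volumes are the fraction
#' inside each dose bin.
#'
#' @param dose Numeric vector of strictly increasing doses in Gy (>= 0).
#' @param volume Numeric vector of volume fractions in `[0, 1]`.
#' @param kind `"cumulative"` or `"differential"`.
#' @param roi Optional ROI label.
#' @return A `dvh` tibble.
#' @examples
#' dvh(c(0, 20, 40), c(1, 0.5, 0), kind = "cumulative", roi = "MGM")
#' @export
dvh <- function(dose, volume, kind = c("cumulative", "differential"),
                roi = "ROI") {
  kind <- match.arg(kind)
  out <- tibble::tibble(dose = as.numeric(dose), volume = as.numeric(volume))
  attr(out, "kind") <- kind
  attr(out, "roi") <- roi
  class(out) <- c("dvh", class(out))
  validate_dvh(out)
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh: %s, %s, %d bins>\n", attr(x, "roi"), attr(x, "kind"),
              nrow(x)))
  NextMethod()
}

dvh_kind <- function(x) attr(x, "kind") %||% "cumulative"
dvh_roi <- function(x) attr(x, "roi") %||% "ROI"

#' Validate a DVH
#'
#' Checks the structural invariants: strictly increasing non-negative doses;
#' for cumulative DVHs, non-increasing volumes starting at <= 1; for
#' differential DVHs, non-negative volumes summing to 1 within `1e-6`.
#'
#' @param x A `dvh` object.
#' @return `x`, invisibly usable, or an error describing the violation.
#' @export
validate_dvh <- function(x) {
  if (nrow(x) == 0L) abort("DVH has no bins.", class = "radntcp_dvh_invalid")
  if (anyNA(x$dose) || anyNA(x$volume)) {
    abort("DVH contains missing values.", class = "radntcp_dvh_invalid")
  }
  if (any(x$dose < 0)) {
    abort("DVH doses must be non-negative.", class = "radntcp_dvh_invalid")
  }
  if (nrow(x) > 1L && any(diff(x$dose) <= 0)) {
    abort("DVH doses must be strictly increasing.",
          class = "radntcp_dvh_invalid")
  }
  if (any(x$volume < -1e-12)) {
    abort("DVH volumes must be non-negative.", class = "radntcp_dvh_invalid")
  }
  if (dvh_kind(x) == "cumulative") {
    if (x$volume[1] > 1 + 1e-9) {
      abort("Cumulative DVH must start at volume <= 1.",
            class = "radntcp_dvh_invalid")
    }
    if (nrow(x) > 1L && any(diff(x$volume) > 1e-9)) {
      abort("Cumulative DVH volumes must be non-increasing.",
            class = "radntcp_dvh_invalid")
    }
  } else {
    if (abs(sum(x$volume) - 1) > 1e-6) {
      abort("Differential DVH volumes must sum to 1 (within 1e-6).",
            class = "radntcp_dvh_invalid")
    }
  }
  x
}

#' Parse a DVH from delimited text
#'
#' Reads a two-column (dose, volume) table from a file or literal text, with
#' an optional single header line. Volumes recorded in percent are detected
#' (any value > 1.5) and rescaled to fractions; the returned DVH always
#' carries fractional volumes.
#'
#' @param file Path to a delimited text file, or a character vector of lines.
#' @param kind DVH kind declared by the source: `"cumulative"` or
#'   `"differential"`.
#' @param volume_unit `"auto"` (detect percent by values > 1.5),
#'   `"percent"`, or `"fraction"`.
#' @param delimiter Field delimiter; `NULL` auto-detects comma vs tab vs
#'   whitespace.
#' @param roi ROI label attached to the result; defaults to the file name.
#' @return A validated `dvh` tibble with fractional volumes.
#' @examples
#' txt <- c("dose,volume", "0,100", "20,50", "40,0")
#' parse_dvh(txt, kind = "cumulative")
#' @export
parse_dvh <- function(file, kind = c("cumulative", "differential"),
                      volume_unit = c("auto", "percent", "fraction"),
                      delimiter = NULL, roi = NULL) {
  kind <- match.arg(kind)
  volume_unit <- match.arg(volume_unit)
  if (length(file) == 1L && file.exists(file)) {
    lines <- readr::read_lines(file)
    roi <- roi %||% sub("\\.[^.]*$", "", basename(file))
  } else {
    lines <- as.character(file)
    roi <- roi %||% "ROI"
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("Empty DVH table.", class = "radntcp_dvh_parse")
  }
  delimiter <- delimiter %||%
    (if (grepl(",", lines[[1]])) "," else if (grepl("\t", lines[[1]])) "\t"
     else " ")
  split_row <- function(l) {
    parts <- strsplit(trimws(l), if (delimiter == " ") "\\s+" else delimiter,
                      fixed = delimiter != " ")[[1]]
    parts[nzchar(parts)]
  }
  first <- suppressWarnings(as.numeric(split_row(lines[[1]])))
  if (anyNA(first)) lines <- lines[-1] # header line
  if (length(lines) == 0L) {
    abort("Empty DVH table.", class = "radntcp_dvh_parse")
  }
  cells <- lapply(lines, split_row)
  if (any(lengths(cells) < 2L)) {
    abort("Each DVH row needs a dose and a volume column.",
          class = "radntcp_dvh_parse")
  }
  num <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(cells, `[`, 1:2))), ncol = 2,
           byrow = TRUE))
  if (anyNA(num)) {
    abort("Non-numeric values in DVH table body.", class = "radntcp_dvh_parse")
  }
  dose <- num[, 1]
  volume <- num[, 2]
  if (any(diff(dose) <= 0)) {
    abort("DVH dose column must be strictly increasing.",
          class = "radntcp_dvh_parse")
  }
  is_percent <- switch(volume_unit,
                       percent = TRUE,
                       fraction = FALSE,
                       auto = any(volume > 1.5))
  if (is_percent) volume <- volume / 100
  dvh(dose, volume, kind = kind, roi = roi)
}

#' Write a DVH to delimited text
#'
#' @param x A `dvh` object.
#' @param file Output path.
#' @param delimiter Field delimiter (default comma).
#' @return `file`, invisibly. Volumes are always written as fractions.
#' @export
write_dvh <- function(x, file, delimiter = ",") {
  validate_dvh(x)
  readr::write_delim(tibble::tibble(dose = x$dose, volume = x$volume),
                     file, delim = delimiter)
  invisible(file)
}

#' Convert a cumulative DVH to differential form
#'
#' Each interval between consecutive cumulative bins becomes one
#' differential bin: its mass is the drop in cumulative volume across the
#' interval and its representative dose is the interval midpoint.
#'
#' @param x A cumulative `dvh` with at least two bins.
#' @return A differential `dvh`. Masses sum to the first minus the last
#'   cumulative volume; the result is renormalised to sum to 1 only if that
#'   total is 1 (i.e. the histogram starts at 1 and ends at 0); otherwise it
#'   keeps the raw masses and skips the sum-to-1 check.
#' @examples
#' cumulative_to_differential(dvh(c(0, 10, 20), c(1, 0.6, 0)))
#' @export
cumulative_to_differential <- function(x) {
  if (dvh_kind(x) != "cumulative") {
    abort("Input must be a cumulative DVH.", class = "radntcp_dvh_invalid")
  }
  validate_dvh(x)
  if (nrow(x) < 2L) {
    abort("Need >= 2 cumulative bins to form intervals.",
          class = "radntcp_dvh_invalid")
  }
  mid <- (x$dose[-nrow(x)] + x$dose[-1]) / 2
  mass <- -diff(x$volume)
  mass[mass < 0 & mass > -1e-12] <- 0
  out <- tibble::tibble(dose = mid, volume = mass)
  attr(out, "kind") <- "differential"
  attr(out, "roi") <- dvh_roi(x)
  class(out) <- c("dvh", class(tibble::tibble()))
  if (abs(sum(mass) - 1) <= 1e-6) validate_dvh(out)
  out
}

#' Convert a differential DVH to cumulative form
#'
#' Bin edges are reconstructed as the midpoints between consecutive
#' representative doses (extrapolated half a spacing at either end); the
#' cumulative volume at each edge is the mass at or beyond it.
#'
#' @param x A differential `dvh`.
#' @return A cumulative `dvh`. Round-tripping through
#'   [cumulative_to_differential()] preserves the bin masses exactly.
#' @export
differential_to_cumulative <- function(x) {
  if (dvh_kind(x) != "differential") {
    abort("Input must be a differential DVH.", class = "radntcp_dvh_invalid")
  }
  n <- nrow(x)
  if (n == 1L) {
    edges <- c(max(x$dose[1] - 0.5, 0), x$dose[1] + 0.5)
  } else {
    inner <- (x$dose[-n] + x$dose[-1]) / 2
    edges <- c(max(2 * x$dose[1] - inner[1], 0), inner,
               2 * x$dose[n] - inner[n - 1])
  }
  cumvol <- rev(cumsum(rev(c(x$volume, 0))))
  out <- tibble::tibble(dose = edges, volume = cumvol)
  attr(out, "kind") <- "cumulative"
  attr(out, "roi") <- dvh_roi(x)
  class(out) <- c("dvh", class(tibble::tibble()))
  validate_dvh(out)
}
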