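#' Read a cohort table from delimited text
#'
#' One row per patient; requires `patient_id`, `age`, `outcome` and, for
#' fitting, one summary-dose column per ROI plus any covariate columns.
#'
#' @param file CSV or TSV path.
#' @return A cohort tibble.
#' @export
read_cohort <- function(file) {
  co <- if (grepl("\\.tsv$", file)) {
    readr::read_tsv(file, show_col_types = FALSE)
  } else {
    readr::read_csv(file, show_col_types = FALSE)
  }
  need <- c("patient_id", "age", "outcome")
  missing <- setdiff(need, names(co))
  if (length(missing)) {
    abort(sprintf("Cohort file lacks column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (any(co$age <= 0, na.rm = TRUE)) abort("Ages must be positive.")
  co
}

#' Configuration for a full analysis run
#'
#' @param cohort_file Optional path to a cohort table; `NULL` simulates one
#'   from `simulation` instead.
#' @param dvh_dir Optional directory of per-patient, per-ROI DVH files
#'   (named `<patient_id>_<roi>.<ext>`); when given, summary doses are
#'   computed by [reduce_dvh_dir()] and joined onto the cohort, otherwise
#'   the cohort must already carry one dose column per ROI.
#' @param rois ROIs to model.
#' @param candidates Candidate covariates for stepwise selection.
#' @param selection_roi ROI whose dose is used during covariate selection.
#' @param geud_a gEUD exponent(s), scalar or named per ROI.
#' @param alpha_beta Alpha/beta ratio (Gy) for the EQD2 transform.
#' @param fractionation [fractionation_scheme()] applied to DVH reduction.
#' @param bootstrap_B Bootstrap replicates per ROI.
#' @param risk_target Constraint risk level.
#' @param age_strata Tibble of strata and representative ages.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param simulation A [simulation_config()] used when no cohort file is
#'   given (its own seed is overridden by the derived stage seed).
#' @param output_dir Directory for the serialized report and tables.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort_file = NULL, dvh_dir = NULL,
                       rois = default_roi_doses()$roi,
                       candidates = c("age", "sex", "t_category",
                                      "n_category", "smoking", "chemo_agent"),
                       selection_roi = "MGM",
                       geud_a = 1, alpha_beta = 3,
                       fractionation = fractionation_scheme(70, 35),
                       bootstrap_B = 200, risk_target = 0.05,
                       age_strata = default_age_strata(), seed = 1,
                       simulation = simulation_config(),
                       output_dir = tempfile("radntcp_run_")) {
  check_number(risk_target, "risk_target", lower = 1e-12, upper = 1 - 1e-12)
  check_number(seed, "seed")
  if (!is.null(cohort_file) && !file.exists(cohort_file)) {
    abort(sprintf("Cohort file not found: %s.", cohort_file))
  }
  if (!is.null(dvh_dir) && !dir.exists(dvh_dir)) {
    abort(sprintf("DVH directory not found: %s.", dvh_dir))
  }
  structure(list(cohort_file = cohort_file, dvh_dir = dvh_dir, rois = rois,
                 candidates = candidates, selection_roi = selection_roi,
                 geud_a = geud_a, alpha_beta = alpha_beta,
                 fractionation = fractionation, bootstrap_B = bootstrap_B,
                 risk_target = risk_target, age_strata = age_strata,
                 seed = as.integer(seed), simulation = simulation,
                 output_dir = output_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; `fractionation`
#' is given as `{total_dose, n_fractions}` and `age_strata` as parallel
#' lists `age_stratum` / `age`.
#'
#' @param file YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(file) {
  y <- yaml::read_yaml(file)
  args <- y[intersect(names(y), c("cohort_file", "dvh_dir", "rois",
                                  "candidates", "selection_roi", "geud_a",
                                  "alpha_beta", "bootstrap_B", "risk_target",
                                  "seed", "output_dir"))]
  args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
  if (!is.null(y$fractionation)) {
    args$fractionation <- fractionation_scheme(y$fractionation$total_dose,
                                               y$fractionation$n_fractions)
  }
  if (!is.null(y$age_strata)) {
    args$age_strata <- tibble::tibble(
      age_stratum = unlist(y$age_strata$age_stratum),
      age = unlist(y$age_strata$age))
  }
  do.call(run_config, args)
}

# master seed -> reproducible per-stage seeds, kept within 32-bit range
stage_seed <- function(seed, stage) {
  (abs(seed) * 97L + match(stage, c("simulate", "bootstrap")) * 1009L) %%
    .Machine$integer.max
}

#' Run the full dosimetric analysis pipeline
#'
#' Executes the end-to-end chain: cohort intake (file or simulation), DVH
#' reduction to EQD2 gEUD summary doses, per-ROI logistic NTCP fits of
#' dose + age, forward-stepwise BIC covariate selection, the per-ROI
#' diagnostics table (FDR-adjusted dose/age p-values, BIC, AUC), bootstrap
#' ensembles, age-stratified curves, and the mean-dose constraint table at
#' the configured risk target. A versioned JSON report plus delimited
#' tables are written to `config$output_dir`; reruns with an identical
#' config produce byte-identical reports. Any stage failure aborts with a
#' stage-labelled error and removes partial outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with `cohort`, `fits`, `selection`,
#'   `diagnostics`, `ensembles`, `curves`, `constraints`, `report_path`.
#' @export
run_full_analysis <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      abort(sprintf("Stage [%s] failed: %s", name, conditionMessage(e)),
            class = "radntcp_stage_error", parent = e)
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_file)) {
      say("stage cohort: reading %s", config$cohort_file)
      read_cohort(config$cohort_file)
    } else {
      sim <- config$simulation
      sim$seed <- stage_seed(config$seed, "simulate")
      say("stage cohort: simulating n = %d (seed %d)", sim$n, sim$seed)
      simulate_cohort(sim)
    }
  })

  cohort <- stage("dvh_reduction", {
    if (!is.null(config$dvh_dir)) {
      say("stage dvh_reduction: gEUD a = %s, alpha/beta = %g Gy",
          paste(config$geud_a, collapse = "/"), config$alpha_beta)
      doses <- reduce_dvh_dir(config$dvh_dir, config$rois,
                              config$fractionation, a = config$geud_a,
                              alpha_beta = config$alpha_beta)
      missing_pt <- setdiff(cohort$patient_id, doses$patient_id)
      if (length(missing_pt)) {
        abort(sprintf("Missing DVHs for patient(s): %s.",
                      paste(missing_pt, collapse = ", ")),
              class = "radntcp_missing_dvh")
      }
      dplyr::inner_join(
        dplyr::select(cohort, -dplyr::any_of(config$rois)),
        doses, by = "patient_id")
    } else {
      missing <- setdiff(config$rois, names(cohort))
      if (length(missing)) {
        abort(sprintf("Cohort lacks summary-dose column(s): %s.",
                      paste(missing, collapse = ", ")))
      }
      cohort
    }
  })

  selection <- stage("selection", {
    say("stage selection: forward-stepwise BIC on %s", config$selection_roi)
    forward_stepwise(cohort, config$selection_roi, config$candidates)
  })

  fits <- stage("fit", {
    say("stage fit: dose + age logistic NTCP per ROI")
    setNames(lapply(config$rois, function(r) fit_ntcp(cohort, r, "age")),
             config$rois)
  })

  diagnostics <- stage("diagnostics", diagnostics_table(fits))

  ensembles <- stage("bootstrap", {
    bseed <- stage_seed(config$seed, "bootstrap")
    say("stage bootstrap: B = %d per ROI (seed %d)", config$bootstrap_B, bseed)
    setNames(lapply(config$rois, function(r) {
      bootstrap_ntcp(cohort, r, "age", B = config$bootstrap_B, seed = bseed)
    }), config$rois)
  })

  curves <- stage("curves", {
    dplyr::bind_rows(lapply(config$rois, function(r) {
      ntcp_curves(fits[[r]], ensembles[[r]], dose_grid = seq(0, 80, by = 2),
                  age_strata = config$age_strata)
    }))
  })

  constraints <- stage("constraints", {
    say("stage constraints: inverting at %.0f%% risk", 100 * config$risk_target)
    constraint_table(fits, age_strata = config$age_strata,
                     risk = config$risk_target)
  })

  report_path <- stage("report", {
    prev <- prevalence_by_stratum(cohort)
    report <- list(
      schema = "radntcp-report/1",
      parameters = list(seed = config$seed, geud_a = config$geud_a,
                        alpha_beta = config$alpha_beta,
                        risk_target = config$risk_target,
                        bootstrap_B = config$bootstrap_B,
                        rois = config$rois),
      prevalence = prev,
      selection = list(selected = selection$selected,
                       bic_trace = selection$bic_trace),
      fits = lapply(fits, function(f) {
        list(coefficients = as.list(f$coefficients),
             covariance = unname(apply(f$vcov, 1, as.list)),
             bic = f$bic, auc = f$auc, log_likelihood = f$log_likelihood,
             wald_p = as.list(f$wald_p), n = f$n)
      }),
      diagnostics = diagnostics,
      constraints = tibble::as_tibble(constraints))
    rp <- file.path(config$output_dir, "report.json")
    jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    written <<- c(written, rp)
    dp <- file.path(config$output_dir, "diagnostics.csv")
    readr::write_csv(diagnostics, dp)
    cp <- file.path(config$output_dir, "constraints.csv")
    readr::write_csv(tibble::as_tibble(constraints), cp)
    cu <- file.path(config$output_dir, "curves.csv")
    readr::write_csv(curves, cu)
    written <<- c(written, dp, cp, cu)
    rp
  })
  say("report written to %s", report_path)

  invisible(list(cohort = cohort, fits = fits, selection = selection,
                 diagnostics = diagnostics, ensembles = ensembles,
                 curves = curves, constraints = constraints,
                 report_path = report_path))
}

#' Read back a serialized analysis report
#'
#' @param path Path to a `report.json` written by [run_full_analysis()].
#' @return The report as a list; errors if the schema tag is missing or
#'   unsupported.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(rep$schema, "radntcp-report/1")) {
    abort("Unrecognised report schema.")
  }
  rep
}
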