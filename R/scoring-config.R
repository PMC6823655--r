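# Tunable scoring parameters and diagnosis code lists.

read_code_list <- function(path) {
  if (!file.exists(path)) stop("code list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

default_code_list_path <- function(name) {
  system.file("extdata", "code_lists", paste0(name, "_synthetic.txt"),
              package = "bpscore", mustWork = TRUE)
}

#' Scoring configuration
#'
#' All thresholds and cut points used by the nine domain scorers, with the
#' operational defaults: encounters under a week apart collapse into one
#' visit; more than ten no-shows with booked appointments (NSBA) elevate
#' service density; blood pressure above 140/90 and BMI above 25/30/35 add
#' 0.5 and 0.25/0.5/0.75 respectively to medical complexity; more than five
#' recorded diagnoses add 1; PHQ-9 totals above 9 trigger risk of harm; and
#' the hospitalization complexity score is binned at 15, 25 and 50.
#'
#' Diagnosis categorisation (substance-use/mental-health, complex-care,
#' neurodegenerative) is driven by plain-text code lists, one code per line.
#' The lists shipped with the package are small synthetic placeholders meant
#' for testing and simulation; deployments substitute their own lists (e.g.
#' the GPSC complex-care list in force locally).
#'
#' @param nsba_threshold NSBA count above which service density is elevated.
#' @param encounter_collapse_days Encounters closer than this collapse into one.
#' @param sumh_codes,complex_care_codes,neurodegenerative_codes Character
#'   vectors of diagnosis codes, or paths to one-code-per-line files.
#' @param bp_systolic,bp_diastolic Blood-pressure thresholds (mmHg); exceeding
#'   either elevates medical complexity by 0.5.
#' @param bmi_cutoffs,bmi_increments Ascending BMI cut points (kg/m2) and the
#'   increment applied at the highest exceeded cut point.
#' @param dx_elevation_threshold Diagnosis count above which medical
#'   complexity gains 1.
#' @param phq9_threshold PHQ-9 total above which risk of harm is maximal.
#' @param hcs_bins Ascending cut points binning the hospitalization
#'   complexity score into domain scores 0..4.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(nsba_threshold = 10L,
                           encounter_collapse_days = 7L,
                           sumh_codes = default_code_list_path("sumh_codes"),
                           complex_care_codes = default_code_list_path("complex_care_codes"),
                           neurodegenerative_codes = default_code_list_path("neurodegenerative_codes"),
                           bp_systolic = 140,
                           bp_diastolic = 90,
                           bmi_cutoffs = c(25, 30, 35),
                           bmi_increments = c(0.25, 0.5, 0.75),
                           dx_elevation_threshold = 5L,
                           phq9_threshold = 9L,
                           hcs_bins = c(0, 15, 25, 50)) {
  as_codes <- function(x) {
    if (length(x) == 1 && is.character(x) && file.exists(x)) read_code_list(x) else as.character(x)
  }
  stopifnot(
    length(bmi_cutoffs) == length(bmi_increments),
    all(diff(bmi_cutoffs) > 0), all(bmi_increments >= 0),
    all(diff(hcs_bins) > 0),
    nsba_threshold >= 0, encounter_collapse_days >= 1
  )
  structure(
    list(
      nsba_threshold = as.integer(nsba_threshold),
      encounter_collapse_days = as.integer(encounter_collapse_days),
      sumh_codes = as_codes(sumh_codes),
      complex_care_codes = as_codes(complex_care_codes),
      neurodegenerative_codes = as_codes(neurodegenerative_codes),
      bp_systolic = bp_systolic,
      bp_diastolic = bp_diastolic,
      bmi_cutoffs = bmi_cutoffs,
      bmi_increments = bmi_increments,
      dx_elevation_threshold = as.integer(dx_elevation_threshold),
      phq9_threshold = as.integer(phq9_threshold),
      hcs_bins = hcs_bins
    ),
    class = "scoring_config"
  )
}

#' Read / write a scoring configuration as YAML
#'
#' @param path A YAML file. Fields mirror the arguments of [scoring_config()];
#'   absent fields take the defaults.
#' @return For `read_scoring_config`, a `scoring_config`; for
#'   `write_scoring_config`, `path` invisibly.
#' @export
read_scoring_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(scoring_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown scoring config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(scoring_config, raw)
}

#' @rdname read_scoring_config
#' @param config A `scoring_config`.
#' @export
write_scoring_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Categorise problem-list entries against the configured code lists
#'
#' Sets the `is_sumh`, `is_complex_care` and `is_neurodegenerative` booleans
#' from exact membership of `code` in the configured lists, overriding any
#' values already present. Categories are derived from codes, never from the
#' free-text label.
#'
#' @param problems A problems table (as in a `record_bundle`).
#' @param config A [scoring_config()].
#' @return The problems table with category booleans filled in.
#' @export
classify_problems <- function(problems, config = scoring_config()) {
  problems$is_sumh <- problems$code %in% config$sumh_codes
  problems$is_complex_care <- problems$code %in% config$complex_care_codes
  problems$is_neurodegenerative <- problems$code %in% config$neurodegenerative_codes
  problems
}
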