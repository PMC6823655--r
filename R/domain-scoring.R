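# The nine domain (Q-score) scorers. Each maps a windowed virtual patient
# record onto a 0-4 partial complexity score:
#   Q1 attachment, Q2 service density, Q3 social/environmental,
#   Q4 psychosocial, Q5 relationships, Q6 activities of daily living,
#   Q7 medical complexity, Q8 acute (hospital) utilization,
#   Q9 risk of harm to self or others.
#
# Conventions shared by the scorers:
#  * HoNOS rules listing several items take the maximum over those items:
#    the only reading that yields a single 0-4 value per domain.
#  * Presence triggers (PWD forms, SHX codes, InterRAI-MDS / mobility
#    assessments, violence alerts, Extended Leave, PHQ-9 above threshold)
#    set the domain to 4 outright.
#  * Missing assessment data contributes 0 and clears the domain's
#    completeness flag; it is never an error, because marginalized clients
#    often lack assessments and must still be scorable.
#  * All scores are clamped to [0, 4] after elevations.

DOMAIN_NAMES <- c(
  q1 = "attachment", q2 = "service_density", q3 = "social_environmental",
  q4 = "psychosocial", q5 = "relationships", q6 = "adl",
  q7 = "medical_complexity", q8 = "acute_utilization", q9 = "risk_of_harm"
)

clamp04 <- function(x) min(max(x, 0), 4)

windowed <- function(x, window) window_filter(x, window)

has_flag <- function(x, kinds) any(x$flags$flag_kind %in% kinds)

honos_item_max <- function(assessment, items) {
  if (is.null(assessment)) return(0)
  max(as.numeric(assessment[paste0("item", items)]))
}

#' Collapse closely spaced encounter dates
#'
#' Encounters less than `collapse_days` apart count as a single visit:
#' walking the sorted dates, a date is dropped when it falls fewer than
#' `collapse_days` days after the last retained date. This operationalises
#' "equally dispersed" visits for the attachment score.
#'
#' @param dates A vector of dates.
#' @param collapse_days Minimum spacing, in days, for two encounters to count
#'   separately (default 7).
#' @return The retained dates, sorted ascending.
#' @export
collapse_encounters <- function(dates, collapse_days = 7L) {
  dates <- sort(as.Date(dates))
  if (length(dates) <= 1) return(dates)
  keep <- dates[1]
  last <- dates[1]
  for (d in as.list(dates[-1])) {
    if (as.numeric(d - last) >= collapse_days) {
      keep <- c(keep, d)
      last <- d
    }
  }
  keep
}

#' @rdname score_all
#' @export
score_attachment <- function(x, window, config = scoring_config()) {
  x <- windowed(x, window)
  visits <- x$encounters$date[x$encounters$attended]
  n <- length(collapse_encounters(visits, config$encounter_collapse_days))
  if (n >= 4) 0 else 4 - n
}

#' @rdname score_all
#' @export
score_service_density <- function(x, window, config = scoring_config()) {
  x <- windowed(x, window)
  enc <- x$encounters
  programs <- unique(enc$program[enc$attended & !is.na(enc$program)])
  p <- length(programs)
  base <- if (p <= 1) 0 else min(p - 1, 4)
  nsba <- sum(enc$booked & !enc$attended)
  clamp04(base + as.integer(nsba > config$nsba_threshold))
}

#' @rdname score_all
#' @export
score_social_environmental <- function(x, window, config = scoring_config()) {
  x <- windowed(x, window)
  if (has_flag(x, c("PWD_FORM", "SHX_CODE"))) return(4)
  honos_item_max(latest_honos(x), c(11, 12))
}

#' @rdname score_all
#' @export
score_psychosocial <- function(x, window, config = scoring_config()) {
  x <- windowed(x, window)
  honos_item_max(latest_honos(x), c(1, 4, 5, 8))
}

#' @rdname score_all
#' @export
score_relationships <- function(x, window, config = scoring_config()) {
  x <- windowed(x, window)
  if (has_flag(x, "SHX_CODE")) return(4)
  honos_item_max(latest_honos(x), c(9, 11, 12))
}

#' @rdname score_all
#' @export
score_adl <- function(x, window, config = scoring_config()) {
  x <- windowed(x, window)
  if (has_flag(x, c("INTERRAI_MDS", "MOBILITY_ASSESSMENT"))) return(4)
  honos_item_max(latest_honos(x), c(5, 10, 11, 12))
}

# Latest observation carrying a given vitals measurement; BP and BMI may be
# recorded on different rows, so each is resolved independently.
latest_vital <- function(x, cols) {
  vit <- x$vitals
  present <- rowSums(!is.na(as.data.frame(vit[, cols, drop = FALSE]))) == length(cols)
  vit <- vit[present, , drop = FALSE]
  if (nrow(vit) == 0) return(NULL)
  vit[order(vit$date, decreasing = TRUE)[1], , drop = FALSE]
}

#' @rdname score_all
#' @export
score_medical_complexity <- function(x, window, config = scoring_config()) {
  x <- windowed(x, window)
  prb <- x$problems
  ndx <- nrow(prb)
  has_sumh <- any(prb$is_sumh %in% TRUE)
  has_cc <- any(prb$is_complex_care %in% TRUE)
  has_neuro <- any(prb$is_neurodegenerative %in% TRUE)
  extended_leave <- has_flag(x, "EXTENDED_LEAVE")
  hon <- latest_honos(x)
  honos_any4 <- !is.null(hon) &&
    max(as.numeric(hon[HONOS_ITEM_COLS])) == 4

  # Highest matching tier wins.
  base <-
    if (has_cc || ndx >= 6 || (has_sumh && extended_leave) || has_neuro || honos_any4) 4
    else if (ndx >= 2 && has_sumh) 3
    else if (has_sumh && !extended_leave) 2
    else if (ndx >= 4) 1
    else 0

  elevation <- 0
  if (ndx > config$dx_elevation_threshold) elevation <- elevation + 1
  bp <- latest_vital(x, c("systolic_bp", "diastolic_bp"))
  if (!is.null(bp) &&
      (bp$systolic_bp > config$bp_systolic || bp$diastolic_bp > config$bp_diastolic)) {
    elevation <- elevation + 0.5
  }
  bmi <- latest_vital(x, "bmi")
  if (!is.null(bmi)) {
    exceeded <- which(bmi$bmi > config$bmi_cutoffs)
    if (length(exceeded) > 0) {
      # increments are mutually exclusive: highest applicable cut point only
      elevation <- elevation + config$bmi_increments[max(exceeded)]
    }
  }
  clamp04(base + elevation)
}

#' Hospitalization complexity score
#'
#' A raw acute-utilization burden combining emergency and inpatient use over
#' the window: each ED visit contributes its inverse CTAS weight
#' `6 - ctas_level` (so a resuscitation-level visit counts 5, a non-urgent
#' one counts 1), and each acute admission contributes its length of stay in
#' days. Open admissions accrue days up to the as-of date.
#'
#' @inheritParams score_all
#' @return A non-negative number, binned into Q8 by [score_acute_utilization()].
#' @export
hospitalization_complexity_score <- function(x, window, config = scoring_config()) {
  x <- windowed(x, window)
  ed <- sum(6 - x$ed_visits$ctas_level)
  adm <- x$admissions
  los <- 0
  if (nrow(adm) > 0) {
    discharge <- adm$discharge_date
    discharge[is.na(discharge)] <- window$as_of_date
    # as of the reference date, days beyond it have not been observed
    discharge <- pmin(discharge, window$as_of_date)
    los <- sum(as.numeric(discharge - adm$admit_date))
  }
  ed + los
}

#' @rdname score_all
#' @export
score_acute_utilization <- function(x, window, config = scoring_config()) {
  hcs <- hospitalization_complexity_score(x, window, config)
  bins <- config$hcs_bins # c(0, 15, 25, 50)
  if (hcs <= bins[1]) 0
  else if (hcs > bins[4]) 4
  else if (hcs >= bins[3]) 3
  else if (hcs >= bins[2]) 2
  else 1
}

#' @rdname score_all
#' @export
score_risk_of_harm <- function(x, window, config = scoring_config()) {
  x <- windowed(x, window)
  if (has_flag(x, c("VIOLENCE_ALERT", "EXTENDED_LEAVE"))) return(4)
  phq <- latest_phq9(x)
  if (!is.null(phq) && phq$total > config$phq9_threshold) return(4)
  honos_item_max(latest_honos(x), c(1, 2))
}

domain_completeness <- function(x) {
  has_honos <- nrow(x$honos) > 0
  c(
    # attachment is computable from the absence of visits itself
    q1 = TRUE,
    q2 = nrow(x$encounters) > 0,
    q3 = has_honos || has_flag(x, c("PWD_FORM", "SHX_CODE")),
    q4 = has_honos,
    q5 = has_honos || has_flag(x, "SHX_CODE"),
    q6 = has_honos || has_flag(x, c("INTERRAI_MDS", "MOBILITY_ASSESSMENT")),
    q7 = nrow(x$problems) > 0 || nrow(x$vitals) > 0 || has_honos ||
      has_flag(x, "EXTENDED_LEAVE"),
    q8 = nrow(x$ed_visits) > 0 || nrow(x$admissions) > 0,
    q9 = has_honos || nrow(x$phq9) > 0 ||
      has_flag(x, c("VIOLENCE_ALERT", "EXTENDED_LEAVE"))
  )
}

#' Score all nine complexity domains for one client
#'
#' Applies the analysis window once, then runs the nine domain scorers on the
#' windowed virtual patient record. Each Q-score lies in \[0, 4\]; Q7 may be
#' fractional after the blood-pressure/BMI modifiers, the others are
#' integers. A domain's completeness flag records whether at least one
#' contributing data element was present; an incomplete domain scores 0,
#' except attachment (Q1), where having no visits is itself the maximal
#' signal and the domain is always considered computable.
#'
#' @param x A `vpr` (windowed or not; filtering is idempotent).
#' @param window An [analysis_window()].
#' @param config A [scoring_config()].
#' @return A `domain_scores` object: list with `client_id`, `as_of_date`,
#'   numeric `q` (named q1..q9) and logical `completeness` (named q1..q9).
#' @export
score_all <- function(x, window, config = scoring_config()) {
  x <- windowed(x, window)
  q <- c(
    q1 = score_attachment(x, window, config),
    q2 = score_service_density(x, window, config),
    q3 = score_social_environmental(x, window, config),
    q4 = score_psychosocial(x, window, config),
    q5 = score_relationships(x, window, config),
    q6 = score_adl(x, window, config),
    q7 = score_medical_complexity(x, window, config),
    q8 = score_acute_utilization(x, window, config),
    q9 = score_risk_of_harm(x, window, config)
  )
  structure(
    list(
      client_id = x$client_id,
      as_of_date = window$as_of_date,
      q = q,
      completeness = domain_completeness(x)
    ),
    class = "domain_scores"
  )
}

#' @export
print.domain_scores <- function(x, ...) {
  cat("<domain_scores>", x$client_id, "as of", format(x$as_of_date), "\n")
  print(round(x$q, 2))
  invisible(x)
}

#' Score every client in a bundle
#'
#' Links the bundle into virtual patient records and scores each client.
#'
#' @param bundle A `record_bundle`.
#' @param window An [analysis_window()].
#' @param config A [scoring_config()].
#' @return A tibble with one row per client: `client_id`, `as_of_date`,
#'   `q1`..`q9` and completeness flags `complete_q1`..`complete_q9`.
#' @export
score_cohort <- function(bundle, window, config = scoring_config()) {
  vprs <- link_records(bundle)
  rows <- lapply(vprs, function(v) {
    s <- score_all(v, window, config)
    tibble::as_tibble(c(
      list(client_id = s$client_id, as_of_date = s$as_of_date),
      as.list(s$q),
      setNames(as.list(s$completeness), paste0("complete_", names(s$completeness)))
    ))
  })
  if (length(rows) == 0) {
    return(tibble::tibble(
      client_id = character(0), as_of_date = as.Date(character(0)),
      !!!setNames(rep(list(numeric(0)), 9), paste0("q", 1:9)),
      !!!setNames(rep(list(logical(0)), 9), paste0("complete_q", 1:9))
    ))
  }
  do.call(rbind, rows)
}
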