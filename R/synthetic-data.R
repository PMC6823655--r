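# Synthetic multi-source cohort generator. No client-level data accompany
# the scoring method, so testing relies on archetype-driven simulation:
# each archetype is a bag of per-source generating distributions chosen to
# caricature a recognisable CHC subpopulation, and a cohort is a seeded
# mixture of archetypes emitted in the standard bundle format.

#' Define a client archetype for cohort simulation
#'
#' An archetype bundles the per-source generating distributions for one
#' subpopulation: encounter and no-show rates (per month over the analysis
#' window), how many programs a client touches, HoNOS item severity,
#' problem-list size and category probabilities, vitals, emergency and
#' inpatient utilization, administrative flag prevalences and PHQ-9 results.
#'
#' @param name Archetype label.
#' @param encounter_rate Expected attended encounters per month.
#' @param nsba_rate Expected booked-but-missed appointments per month.
#' @param program_pool Programs this subpopulation can touch.
#' @param n_programs_probs Probability vector over using 1, 2, ... programs.
#' @param honos_prob Probability at least one HoNOS assessment exists.
#' @param honos_item_probs Length-5 probabilities over item scores 0..4.
#' @param honos_item_overrides Named list (`item5` etc.) of per-item
#'   probability vectors overriding the common one.
#' @param problem_lambda Poisson mean of problem-list size.
#' @param sumh_prob,complex_care_prob,neuro_prob Probability that a client's
#'   problem list includes a substance-use/mental-health, complex-care, or
#'   neurodegenerative code (given a non-empty list).
#' @param vitals_prob Probability a vitals observation exists.
#' @param sbp_mean,sbp_sd,dbp_mean,dbp_sd,bmi_mean,bmi_sd Normal parameters
#'   for systolic/diastolic blood pressure (mmHg) and BMI (kg/m2).
#' @param ed_rate Expected ED visits per month.
#' @param ctas_probs Length-5 probabilities over CTAS levels 1..5.
#' @param admission_rate Expected acute admissions per month.
#' @param los_mean Poisson mean length of stay (days).
#' @param flag_probs Named per-kind prevalences over [FLAG_KINDS].
#' @param phq9_prob Probability a PHQ-9 result exists.
#' @param phq9_mean,phq9_sd Normal parameters for the PHQ-9 total (rounded
#'   and clipped to 0..27).
#' @return An `archetype` list.
#' @export
archetype <- function(name,
                      encounter_rate = 0.3,
                      nsba_rate = 0.05,
                      program_pool = c("primary_care", "mhsu"),
                      n_programs_probs = c(0.7, 0.3),
                      honos_prob = 0.3,
                      honos_item_probs = c(0.7, 0.2, 0.1, 0, 0),
                      honos_item_overrides = list(),
                      problem_lambda = 1,
                      sumh_prob = 0.1,
                      complex_care_prob = 0.05,
                      neuro_prob = 0.01,
                      vitals_prob = 0.7,
                      sbp_mean = 120, sbp_sd = 14,
                      dbp_mean = 76, dbp_sd = 9,
                      bmi_mean = 24, bmi_sd = 4,
                      ed_rate = 0.03,
                      ctas_probs = c(0.02, 0.08, 0.25, 0.4, 0.25),
                      admission_rate = 0.005,
                      los_mean = 3,
                      flag_probs = c(PWD_FORM = 0, SHX_CODE = 0,
                                     INTERRAI_MDS = 0, MOBILITY_ASSESSMENT = 0,
                                     VIOLENCE_ALERT = 0, EXTENDED_LEAVE = 0),
                      phq9_prob = 0.2,
                      phq9_mean = 5, phq9_sd = 4) {
  stopifnot(
    encounter_rate >= 0, nsba_rate >= 0, ed_rate >= 0, admission_rate >= 0,
    length(honos_item_probs) == 5, length(ctas_probs) == 5,
    all(unlist(flag_probs) >= 0), all(unlist(flag_probs) <= 1),
    length(n_programs_probs) <= length(program_pool)
  )
  fp <- setNames(rep(0, length(FLAG_KINDS)), FLAG_KINDS)
  fp[names(flag_probs)] <- unlist(flag_probs)
  structure(
    list(
      name = name,
      encounter_rate = encounter_rate, nsba_rate = nsba_rate,
      program_pool = program_pool, n_programs_probs = n_programs_probs,
      honos_prob = honos_prob, honos_item_probs = honos_item_probs,
      honos_item_overrides = honos_item_overrides,
      problem_lambda = problem_lambda, sumh_prob = sumh_prob,
      complex_care_prob = complex_care_prob, neuro_prob = neuro_prob,
      vitals_prob = vitals_prob,
      sbp_mean = sbp_mean, sbp_sd = sbp_sd,
      dbp_mean = dbp_mean, dbp_sd = dbp_sd,
      bmi_mean = bmi_mean, bmi_sd = bmi_sd,
      ed_rate = ed_rate, ctas_probs = ctas_probs,
      admission_rate = admission_rate, los_mean = los_mean,
      flag_probs = fp,
      phq9_prob = phq9_prob, phq9_mean = phq9_mean, phq9_sd = phq9_sd
    ),
    class = "archetype"
  )
}

#' Built-in archetypes
#'
#' Three caricatured CHC subpopulations: `low` (youth-clinic-style users of
#' one or two programs with little assessed severity), `high` (the
#' multi-program, housing-unstable, substance-use/mental-health population a
#' complex-care mandate targets), and `frail_senior` (ADL-limited clients
#' with home-health assessments and long admissions).
#'
#' @return Named list of [archetype()] objects.
#' @export
default_archetypes <- function() {
  list(
    low = archetype(
      "low",
      encounter_rate = 0.15, nsba_rate = 0.02,
      program_pool = c("primary_care", "youth_clinic", "trans_care", "hep_c"),
      n_programs_probs = c(0.7, 0.3),
      honos_prob = 0.2, honos_item_probs = c(0.8, 0.15, 0.05, 0, 0),
      problem_lambda = 0.8, sumh_prob = 0.08, complex_care_prob = 0.02,
      neuro_prob = 0,
      vitals_prob = 0.7, sbp_mean = 118, sbp_sd = 12, dbp_mean = 74,
      dbp_sd = 8, bmi_mean = 23, bmi_sd = 3,
      ed_rate = 0.02, ctas_probs = c(0.01, 0.05, 0.2, 0.44, 0.3),
      admission_rate = 0.002, los_mean = 2,
      flag_probs = c(SHX_CODE = 0.02),
      phq9_prob = 0.15, phq9_mean = 4, phq9_sd = 3
    ),
    high = archetype(
      "high",
      encounter_rate = 0.8, nsba_rate = 0.7,
      program_pool = c("primary_care", "mhsu", "outreach", "oat",
                       "housing_support", "wound_care", "social_work"),
      n_programs_probs = c(0.05, 0.15, 0.25, 0.25, 0.2, 0.1),
      honos_prob = 0.9, honos_item_probs = c(0.15, 0.2, 0.25, 0.25, 0.15),
      honos_item_overrides = list(
        item11 = c(0.1, 0.15, 0.2, 0.3, 0.25), # housing instability
        item12 = c(0.1, 0.2, 0.25, 0.25, 0.2)
      ),
      problem_lambda = 5, sumh_prob = 0.85, complex_care_prob = 0.3,
      neuro_prob = 0.05,
      vitals_prob = 0.8, sbp_mean = 134, sbp_sd = 18, dbp_mean = 84,
      dbp_sd = 12, bmi_mean = 27, bmi_sd = 6,
      ed_rate = 0.4, ctas_probs = c(0.05, 0.25, 0.4, 0.2, 0.1),
      admission_rate = 0.08, los_mean = 6,
      flag_probs = c(PWD_FORM = 0.35, SHX_CODE = 0.5, VIOLENCE_ALERT = 0.15,
                     EXTENDED_LEAVE = 0.1, INTERRAI_MDS = 0.05,
                     MOBILITY_ASSESSMENT = 0.05),
      phq9_prob = 0.5, phq9_mean = 13, phq9_sd = 6
    ),
    frail_senior = archetype(
      "frail_senior",
      encounter_rate = 0.5, nsba_rate = 0.05,
      program_pool = c("primary_care", "home_health", "ot_pt", "geriatrics"),
      n_programs_probs = c(0.2, 0.4, 0.3, 0.1),
      honos_prob = 0.7, honos_item_probs = c(0.4, 0.3, 0.2, 0.08, 0.02),
      honos_item_overrides = list(
        item5 = c(0.1, 0.2, 0.3, 0.25, 0.15),  # physical illness/disability
        item10 = c(0.1, 0.2, 0.3, 0.25, 0.15)  # ADLs
      ),
      problem_lambda = 6, sumh_prob = 0.15, complex_care_prob = 0.6,
      neuro_prob = 0.35,
      vitals_prob = 0.9, sbp_mean = 144, sbp_sd = 20, dbp_mean = 82,
      dbp_sd = 10, bmi_mean = 26, bmi_sd = 5,
      ed_rate = 0.15, ctas_probs = c(0.05, 0.3, 0.4, 0.2, 0.05),
      admission_rate = 0.15, los_mean = 12,
      flag_probs = c(INTERRAI_MDS = 0.6, MOBILITY_ASSESSMENT = 0.5,
                     PWD_FORM = 0.2),
      phq9_prob = 0.3, phq9_mean = 8, phq9_sd = 4
    )
  )
}

#' Specify a synthetic cohort
#'
#' @param n Number of clients (> 0).
#' @param mixture Named proportions over archetype names; must sum to 1.
#' @param seed Integer seed; cohorts are fully reproducible, and each client
#'   draws from a stream derived from `(seed, client index)`, so client `i`
#'   is stable under changes of `n`.
#' @param as_of_date Reference date the lookback window ends at.
#' @param lookback_months Window length in calendar months.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n, mixture = c(low = 0.5, high = 0.5), seed = 1L,
                        as_of_date = "2019-01-01", lookback_months = 18L) {
  n <- as.integer(n)
  if (is.na(n) || n <= 0) stop("n must be a positive integer", call. = FALSE)
  if (is.null(names(mixture)) || any(!nzchar(names(mixture)))) {
    stop("mixture proportions must be named by archetype", call. = FALSE)
  }
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    stop("mixture proportions must be non-negative and sum to 1", call. = FALSE)
  }
  structure(
    list(
      n = n, mixture = mixture, seed = as.integer(seed),
      as_of_date = as.Date(as_of_date),
      lookback_months = as.integer(lookback_months)
    ),
    class = "cohort_spec"
  )
}

#' Read a cohort specification from YAML
#'
#' @param path YAML file with fields `n`, `mixture` (name: proportion map),
#'   `seed`, `as_of_date`, `lookback_months`.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort_spec(
    n = raw$n,
    mixture = unlist(raw$mixture),
    seed = raw$seed %||% 1L,
    as_of_date = raw$as_of_date %||% "2019-01-01",
    lookback_months = raw$lookback_months %||% 18L
  )
}

client_stream_seed <- function(seed, i) {
  ((as.numeric(seed) %% 100000) * 1000003 + i) %% 2147483646 + 1
}

sample_probs <- function(values, n, probs) {
  if (n == 0) return(values[0])
  values[sample.int(length(values), n, replace = TRUE, prob = probs)]
}

random_dates <- function(n, window) {
  days <- as.numeric(window$as_of_date - window$start)
  window$as_of_date - sample.int(days, n, replace = TRUE) + 1
}

generate_client <- function(id, arch, window, config) {
  months <- window$lookback_months
  tabs <- list()

  n_prog <- sample_probs(seq_along(arch$n_programs_probs), 1, arch$n_programs_probs)
  programs <- sample(arch$program_pool, n_prog)
  n_att <- rpois(1, arch$encounter_rate * months)
  n_nsba <- rpois(1, arch$nsba_rate * months)
  if (n_att + n_nsba > 0) {
    tabs$encounters <- tibble::tibble(
      client_id = id,
      source_system = sample(c("primary_care_emr", "cmh_emr"), n_att + n_nsba,
                             replace = TRUE),
      date = random_dates(n_att + n_nsba, window),
      program = c(
        # every used program gets at least one attended encounter
        if (n_att > 0) c(programs, sample(programs, max(0, n_att - n_prog),
                                          replace = TRUE))[seq_len(n_att)],
        sample(programs, n_nsba, replace = TRUE)
      ),
      booked = TRUE,
      attended = rep(c(TRUE, FALSE), c(n_att, n_nsba))
    )
  }

  if (runif(1) < arch$honos_prob) {
    item_p <- lapply(HONOS_ITEM_COLS, function(col) {
      arch$honos_item_overrides[[col]] %||% arch$honos_item_probs
    })
    items <- lapply(item_p, function(p) sample_probs(0:4, 1, p))
    tabs$honos <- tibble::as_tibble(c(
      list(client_id = id, date = random_dates(1, window)),
      setNames(items, HONOS_ITEM_COLS)
    ))
  }

  n_dx <- rpois(1, arch$problem_lambda)
  if (n_dx > 0) {
    codes <- paste0("Z", sprintf("%02d", sample.int(99, n_dx, replace = TRUE)))
    if (runif(1) < arch$sumh_prob) codes[1] <- sample(config$sumh_codes, 1)
    if (n_dx > 1 && runif(1) < arch$complex_care_prob) {
      codes[2] <- sample(config$complex_care_codes, 1)
    }
    if (n_dx > 2 && runif(1) < arch$neuro_prob) {
      codes[3] <- sample(config$neurodegenerative_codes, 1)
    }
    tabs$problems <- classify_problems(tibble::tibble(
      client_id = id, code = codes, label = paste("dx", codes),
      is_sumh = FALSE, is_complex_care = FALSE, is_neurodegenerative = FALSE
    ), config)
  }

  if (runif(1) < arch$vitals_prob) {
    tabs$vitals <- tibble::tibble(
      client_id = id, date = random_dates(1, window),
      systolic_bp = max(80, round(rnorm(1, arch$sbp_mean, arch$sbp_sd))),
      diastolic_bp = max(50, round(rnorm(1, arch$dbp_mean, arch$dbp_sd))),
      bmi = max(14, round(rnorm(1, arch$bmi_mean, arch$bmi_sd), 1))
    )
  }

  n_ed <- rpois(1, arch$ed_rate * months)
  if (n_ed > 0) {
    tabs$ed_visits <- tibble::tibble(
      client_id = id, date = random_dates(n_ed, window),
      ctas_level = sample_probs(1:5, n_ed, arch$ctas_probs)
    )
  }

  n_adm <- rpois(1, arch$admission_rate * months)
  if (n_adm > 0) {
    admit <- random_dates(n_adm, window)
    los <- rpois(n_adm, arch$los_mean)
    tabs$admissions <- tibble::tibble(
      client_id = id, admit_date = admit, discharge_date = admit + los
    )
  }

  kinds <- FLAG_KINDS[runif(length(FLAG_KINDS)) < arch$flag_probs]
  if (length(kinds) > 0) {
    tabs$flags <- tibble::tibble(
      client_id = id, flag_kind = kinds,
      date = random_dates(length(kinds), window)
    )
  }

  if (runif(1) < arch$phq9_prob) {
    tabs$phq9 <- tibble::tibble(
      client_id = id, date = random_dates(1, window),
      total = min(27L, max(0L, as.integer(round(rnorm(1, arch$phq9_mean, arch$phq9_sd)))))
    )
  }

  if (length(tabs) == 0) {
    # every sampled client exists somewhere: a registration-era encounter
    # predating the window keeps them linkable without affecting any score
    tabs$encounters <- tibble::tibble(
      client_id = id, source_system = "primary_care_emr",
      date = window$start - sample.int(365, 1),
      program = arch$program_pool[1], booked = TRUE, attended = TRUE
    )
  }

  tabs
}

#' Generate a synthetic multi-source cohort
#'
#' Draws exactly `spec$n` clients, each assigned an archetype from the
#' mixture and simulated from that archetype's distributions inside the
#' analysis window. Output is a validated [record_bundle()], so everything
#' downstream (linkage, scoring, reporting) runs on it unchanged.
#'
#' @param spec A [cohort_spec()].
#' @param archetypes Named list of [archetype()]s covering the mixture names.
#' @param config A [scoring_config()] (used to categorise simulated problem
#'   codes).
#' @return A `record_bundle` with `spec$n` distinct clients.
#' @export
generate_cohort <- function(spec, archetypes = default_archetypes(),
                            config = scoring_config()) {
  stopifnot(inherits(spec, "cohort_spec"))
  unknown <- setdiff(names(spec$mixture), names(archetypes))
  if (length(unknown) > 0) {
    stop("mixture names not in archetypes: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  window <- analysis_window(spec$as_of_date, spec$lookback_months)
  per_client <- vector("list", spec$n)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (i in seq_len(spec$n)) {
    set.seed(client_stream_seed(spec$seed, i))
    arch_name <- sample_probs(names(spec$mixture), 1, spec$mixture)
    id <- sprintf("%s-%05d", toupper(substr(arch_name, 1, 1)), i)
    per_client[[i]] <- generate_client(id, archetypes[[arch_name]], window, config)
  }
  tables <- lapply(BUNDLE_TABLES, function(tb) {
    parts <- Filter(Negate(is.null), lapply(per_client, `[[`, tb))
    if (length(parts) == 0) NULL else do.call(rbind, parts)
  })
  names(tables) <- BUNDLE_TABLES
  do.call(record_bundle, c(tables, list(validate = TRUE)))
}

#' Deterministic worked-example clients
#'
#' A small hand-constructed bundle containing one client per canonical
#' scoring situation: `no_visits` (nothing inside the window, attachment 4),
#' `five_dispersed_visits` (five visits a month apart, attachment 0),
#' `five_programs` (attended in five distinct programs, service density 4),
#' `empty_problem_list` (no recorded diagnoses, medical complexity 0),
#' `phq9_ten` (latest PHQ-9 of 10 with an all-zero HoNOS, risk of harm 4),
#' and `max_triggers` (every presence trigger and elevation fires at once).
#'
#' @param as_of_date Date the fixtures are anchored to.
#' @return A validated `record_bundle`.
#' @export
make_worked_fixtures <- function(as_of_date = "2019-01-01") {
  as_of <- as.Date(as_of_date)
  enc <- function(id, dates, program = "primary_care", attended = TRUE) {
    tibble::tibble(
      client_id = id, source_system = "primary_care_emr",
      date = as.Date(dates), program = program, booked = TRUE,
      attended = attended
    )
  }
  honos_row <- function(id, date, items) {
    tibble::as_tibble(c(
      list(client_id = id, date = as.Date(date)),
      setNames(as.list(as.integer(items)), HONOS_ITEM_COLS)
    ))
  }

  encounters <- rbind(
    # exists in the source system, but nothing inside an 18-month window
    enc("no_visits", as_of - 730),
    enc("five_dispersed_visits", as_of - c(30, 60, 90, 120, 150)),
    enc("five_programs", as_of - c(10, 40, 70, 100, 130),
        program = c("primary_care", "mhsu", "outreach", "oat", "housing_support")),
    enc("empty_problem_list", as_of - 20),
    enc("phq9_ten", as_of - 15),
    enc("max_triggers", as_of - c(10, 40, 70, 100, 130),
        program = c("primary_care", "mhsu", "outreach", "oat", "housing_support")),
    enc("max_triggers", as_of - seq(5, 115, by = 10), program = "mhsu",
        attended = FALSE) # 12 NSBA
  )
  honos <- rbind(
    honos_row("phq9_ten", as_of - 10, rep(0L, 12)),
    honos_row("max_triggers", as_of - 10, rep(4L, 12))
  )
  problems <- tibble::tibble(
    client_id = "max_triggers",
    code = c("F20", "E11", "Z01", "Z02", "Z03", "Z04"),
    label = c("schizophrenia", "type 2 diabetes", paste("dx", 1:4)),
    is_sumh = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    is_complex_care = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_neurodegenerative = FALSE
  )
  vitals <- tibble::tibble(
    client_id = "max_triggers", date = as_of - 5,
    systolic_bp = 160, diastolic_bp = 100, bmi = 36
  )
  ed_visits <- tibble::tibble(
    client_id = "max_triggers", date = as_of - c(20, 50), ctas_level = c(1L, 2L)
  )
  admissions <- tibble::tibble(
    client_id = "max_triggers", admit_date = as_of - 90,
    discharge_date = as_of - 30
  )
  flags <- tibble::tibble(
    client_id = "max_triggers",
    flag_kind = c("PWD_FORM", "SHX_CODE", "INTERRAI_MDS", "VIOLENCE_ALERT",
                  "EXTENDED_LEAVE"),
    date = as_of - 100
  )
  phq9 <- tibble::tibble(
    client_id = c("phq9_ten", "max_triggers"), date = as_of - c(12, 12),
    total = c(10L, 27L)
  )
  record_bundle(
    encounters = encounters, honos = honos, problems = problems,
    vitals = vitals, ed_visits = ed_visits, admissions = admissions,
    flags = flags, phq9 = phq9
  )
}
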