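# Independent brute-force re-implementation of the nine domain rules, written
# as naive condition-by-condition lookups over the published rule table. It
# shares no code with the package scorers and is deliberately slow and
# literal; property tests compare the two on randomized records.

oracle_collapse <- function(dates, gap = 7) {
  dates <- sort(as.Date(dates))
  retained <- as.Date(character(0))
  for (i in seq_along(dates)) {
    if (length(retained) == 0) {
      retained <- dates[i]
    } else if (as.numeric(dates[i] - retained[length(retained)]) >= gap) {
      retained <- c(retained, dates[i])
    }
  }
  retained
}

oracle_window_dates <- function(dates, window) {
  dates[!is.na(dates) & dates > window$start & dates <= window$as_of_date]
}

oracle_latest_honos_items <- function(v, window) {
  hon <- v$honos[oracle_in(v$honos$date, window), , drop = FALSE]
  if (nrow(hon) == 0) return(NULL)
  sums <- apply(as.matrix(hon[paste0("item", 1:12)]), 1, sum)
  best <- which(hon$date == max(hon$date))
  best <- best[which.max(sums[best])]
  as.numeric(hon[best, paste0("item", 1:12)])
}

oracle_in <- function(dates, window) {
  !is.na(dates) & dates > window$start & dates <= window$as_of_date
}

oracle_has <- function(v, kind) any(v$flags$flag_kind %in% kind)

oracle_scores <- function(v, window, config = scoring_config()) {
  q <- numeric(9)

  # Q1: lookup over collapsed attended-visit counts
  visits <- oracle_window_dates(v$encounters$date[v$encounters$attended], window)
  n <- length(oracle_collapse(visits, config$encounter_collapse_days))
  lookup_q1 <- c("0" = 4, "1" = 3, "2" = 2, "3" = 1)
  q[1] <- if (as.character(n) %in% names(lookup_q1)) lookup_q1[[as.character(n)]] else 0

  # Q2: programs seen (attended, in window), then NSBA elevation
  enc <- v$encounters[oracle_in(v$encounters$date, window), , drop = FALSE]
  p <- length(unique(enc$program[enc$attended & !is.na(enc$program)]))
  q2 <- if (p <= 1) 0 else if (p == 2) 1 else if (p == 3) 2 else if (p == 4) 3 else 4
  nsba <- nrow(enc[enc$booked & !enc$attended, ])
  if (nsba > config$nsba_threshold) q2 <- q2 + 1
  q[2] <- min(q2, 4)

  items <- oracle_latest_honos_items(v, window)
  it <- function(i) if (is.null(items)) 0 else items[i]

  # Q3
  q[3] <- if (oracle_has(v, "PWD_FORM") || oracle_has(v, "SHX_CODE")) 4 else
    max(it(11), it(12))
  # Q4
  q[4] <- max(it(1), it(4), it(5), it(8))
  # Q5
  q[5] <- if (oracle_has(v, "SHX_CODE")) 4 else max(it(9), it(11), it(12))
  # Q6
  q[6] <- if (oracle_has(v, "INTERRAI_MDS") || oracle_has(v, "MOBILITY_ASSESSMENT")) 4 else
    max(it(5), it(10), it(11), it(12))

  # Q7: tiers evaluated as an explicit condition table, highest match wins
  prb <- v$problems
  ndx <- nrow(prb)
  sumh <- isTRUE(any(prb$is_sumh))
  cc <- isTRUE(any(prb$is_complex_care))
  neuro <- isTRUE(any(prb$is_neurodegenerative))
  el <- oracle_has(v, "EXTENDED_LEAVE")
  any4 <- !is.null(items) && any(items == 4)
  tier_table <- list(
    list(score = 4, hit = cc || ndx >= 6 || (sumh && el) || neuro || any4),
    list(score = 3, hit = ndx >= 2 && sumh),
    list(score = 2, hit = sumh && !el),
    list(score = 1, hit = ndx >= 4),
    list(score = 0, hit = TRUE)
  )
  base <- 0
  for (tier in tier_table) if (tier$hit) { base <- tier$score; break }
  extra <- 0
  if (ndx > config$dx_elevation_threshold) extra <- extra + 1
  vit <- v$vitals
  bp_rows <- vit[!is.na(vit$systolic_bp) & !is.na(vit$diastolic_bp), , drop = FALSE]
  if (nrow(bp_rows) > 0) {
    bp <- bp_rows[which(bp_rows$date == max(bp_rows$date))[1], ]
    if (bp$systolic_bp > config$bp_systolic || bp$diastolic_bp > config$bp_diastolic) {
      extra <- extra + 0.5
    }
  }
  bmi_rows <- vit[!is.na(vit$bmi), , drop = FALSE]
  if (nrow(bmi_rows) > 0) {
    b <- bmi_rows[which(bmi_rows$date == max(bmi_rows$date))[1], ]$bmi
    if (b > 35) extra <- extra + 0.75
    else if (b > 30) extra <- extra + 0.5
    else if (b > 25) extra <- extra + 0.25
  }
  q[7] <- max(0, min(4, base + extra))

  # Q8: inverse-CTAS + LOS burden, binned
  ed <- v$ed_visits[oracle_in(v$ed_visits$date, window), , drop = FALSE]
  hcs <- sum(6 - ed$ctas_level)
  adm <- v$admissions
  if (nrow(adm) > 0) {
    for (i in seq_len(nrow(adm))) {
      dis <- adm$discharge_date[i]
      if (is.na(dis)) dis <- window$as_of_date
      if (adm$admit_date[i] <= window$as_of_date && dis > window$start) {
        hcs <- hcs + as.numeric(min(dis, window$as_of_date) - adm$admit_date[i])
      }
    }
  }
  q[8] <- if (hcs == 0) 0 else if (hcs > 50) 4 else if (hcs >= 25) 3 else
    if (hcs >= 15) 2 else 1

  # Q9
  phq <- v$phq9[oracle_in(v$phq9$date, window), , drop = FALSE]
  phq_high <- FALSE
  if (nrow(phq) > 0) {
    best <- which(phq$date == max(phq$date))
    best <- best[which.max(phq$total[best])]
    phq_high <- phq$total[best] > config$phq9_threshold
  }
  q[9] <- if (oracle_has(v, "VIOLENCE_ALERT") || oracle_has(v, "EXTENDED_LEAVE") ||
              phq_high) 4 else max(it(1), it(2))

  setNames(q, paste0("q", 1:9))
}

# Randomized single-client record touching every rule branch; dates span
# both sides of the window boundary. Caller controls the RNG state.
random_vpr <- function(as_of = AS_OF) {
  rdate <- function(n) as_of - sample.int(730, n, replace = TRUE) + 1
  n_enc <- sample(0:8, 1)
  n_hon <- sample(0:2, 1)
  n_prb <- sample(0:7, 1)
  n_ed <- sample(0:3, 1)
  n_adm <- sample(0:2, 1)
  n_phq <- sample(0:2, 1)
  kinds <- FLAG_KINDS[runif(6) < 0.15]
  vpr(
    client_id = "rnd",
    encounters = if (n_enc) tibble::tibble(
      client_id = "rnd", source_system = "s", date = rdate(n_enc),
      program = sample(c("a", "b", "c", "d", "e", "f"), n_enc, replace = TRUE),
      booked = TRUE, attended = runif(n_enc) < 0.7
    ),
    honos = if (n_hon) do.call(rbind, lapply(seq_len(n_hon), function(i) {
      tibble::as_tibble(c(
        list(client_id = "rnd", date = rdate(1)),
        setNames(as.list(sample(0:4, 12, replace = TRUE)), paste0("item", 1:12))
      ))
    })),
    problems = if (n_prb) tibble::tibble(
      client_id = "rnd", code = paste0("P", seq_len(n_prb)), label = "dx",
      is_sumh = runif(n_prb) < 0.3,
      is_complex_care = runif(n_prb) < 0.15,
      is_neurodegenerative = runif(n_prb) < 0.1
    ),
    vitals = if (runif(1) < 0.6) tibble::tibble(
      client_id = "rnd", date = rdate(1),
      systolic_bp = if (runif(1) < 0.8) sample(100:180, 1) else NA_real_,
      diastolic_bp = if (runif(1) < 0.8) sample(60:110, 1) else NA_real_,
      bmi = if (runif(1) < 0.8) runif(1, 16, 45) else NA_real_
    ),
    ed_visits = if (n_ed) tibble::tibble(
      client_id = "rnd", date = rdate(n_ed),
      ctas_level = sample(1:5, n_ed, replace = TRUE)
    ),
    admissions = if (n_adm) {
      admit <- rdate(n_adm)
      tibble::tibble(
        client_id = "rnd", admit_date = admit,
        discharge_date = {
          d <- admit + sample(0:40, n_adm, replace = TRUE)
          d[runif(n_adm) < 0.2] <- NA
          d
        }
      )
    },
    flags = if (length(kinds)) tibble::tibble(
      client_id = "rnd", flag_kind = kinds, date = rdate(length(kinds))
    ),
    phq9 = if (n_phq) tibble::tibble(
      client_id = "rnd", date = rdate(n_phq),
      total = sample(0:27, n_phq, replace = TRUE)
    )
  )
}
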