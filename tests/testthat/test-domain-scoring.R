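test_that("encounter collapse merges visits under a week apart", {
  d <- AS_OF - 100
  expect_equal(collapse_encounters(d + 0:5), d)
  expect_equal(collapse_encounters(d + c(0, 30, 60)), d + c(0, 30, 60))
  expect_equal(collapse_encounters(d + c(0, 6, 7, 13)), d + c(0, 7))
  expect_length(collapse_encounters(as.Date(character(0))), 0)
  # spacing parameter is honoured
  expect_equal(collapse_encounters(d + c(0, 10), collapse_days = 14), d)
})

test_that("attachment (Q1) maps collapsed visit counts 4+/3/2/1/0 to 0..4", {
  visits <- function(dates) vpr(encounters = enc_tbl(dates))
  expect_equal(score_attachment(visits(AS_OF - c(30, 60, 90, 120, 150)), WIN), 0)
  expect_equal(score_attachment(visits(AS_OF - c(30, 60, 90)), WIN), 1)
  expect_equal(score_attachment(visits(AS_OF - c(30, 60)), WIN), 2)
  expect_equal(score_attachment(visits(AS_OF - 30), WIN), 3)
  expect_equal(score_attachment(vpr(), WIN), 4)
  # six visits inside one week collapse to a single visit
  expect_equal(score_attachment(visits(AS_OF - c(30:35)), WIN), 3)
  # no-shows are not visits
  v <- vpr(encounters = enc_tbl(AS_OF - c(30, 60), attended = FALSE))
  expect_equal(score_attachment(v, WIN), 4)
})

test_that("service density (Q2) counts programs seen, elevated by >10 no-shows", {
  progs <- function(k) vpr(encounters = enc_tbl(
    AS_OF - seq(10, by = 20, length.out = k), program = paste0("p", seq_len(k))
  ))
  expect_equal(score_service_density(progs(1), WIN), 0)
  expect_equal(score_service_density(progs(2), WIN), 1)
  expect_equal(score_service_density(progs(5), WIN), 4)
  expect_equal(score_service_density(vpr(), WIN), 0)

  with_nsba <- function(k, n_miss) vpr(encounters = rbind(
    enc_tbl(AS_OF - seq(10, by = 20, length.out = k), program = paste0("p", seq_len(k))),
    enc_tbl(AS_OF - seq(5, by = 9, length.out = n_miss), attended = FALSE)
  ))
  expect_equal(score_service_density(with_nsba(3, 11), WIN), 3) # base 2 + 1
  expect_equal(score_service_density(with_nsba(3, 10), WIN), 2) # at threshold: no lift
  expect_equal(score_service_density(with_nsba(5, 11), WIN), 4) # clamped at 4
})

test_that("HoNOS-driven domains take the maximum over their listed items", {
  h <- function(...) vpr(honos = honos_tbl(AS_OF - 10, honos_items(...)))
  # Q3: items 11, 12
  expect_equal(score_social_environmental(h(item11 = 2, item12 = 1), WIN), 2)
  # Q4: items 1, 4, 5, 8
  expect_equal(score_psychosocial(h(item4 = 3, item5 = 1, item8 = 2), WIN), 3)
  expect_equal(score_psychosocial(h(item5 = 4), WIN), 4)
  expect_equal(score_psychosocial(h(), WIN), 0)
  # Q5: items 9, 11, 12
  expect_equal(score_relationships(h(item9 = 1), WIN), 1)
  # Q6: items 5, 10, 11, 12
  expect_equal(score_adl(h(item10 = 2), WIN), 2)
  # Q9: items 1, 2
  expect_equal(score_risk_of_harm(h(item1 = 2, item2 = 1), WIN), 2)
  # items outside a domain's list do not leak in
  expect_equal(score_social_environmental(h(item1 = 4), WIN), 0)
})

test_that("presence triggers force a domain to 4 regardless of HoNOS", {
  low_honos <- honos_tbl(AS_OF - 10, honos_items(item11 = 1))
  expect_equal(
    score_social_environmental(vpr(honos = low_honos,
                                   flags = flags_tbl("PWD_FORM")), WIN), 4)
  expect_equal(
    score_relationships(vpr(honos = low_honos,
                            flags = flags_tbl("SHX_CODE")), WIN), 4)
  expect_equal(
    score_adl(vpr(flags = flags_tbl("INTERRAI_MDS")), WIN), 4)
  expect_equal(
    score_adl(vpr(flags = flags_tbl("MOBILITY_ASSESSMENT")), WIN), 4)
  expect_equal(
    score_risk_of_harm(vpr(flags = flags_tbl("VIOLENCE_ALERT")), WIN), 4)
  expect_equal(
    score_risk_of_harm(vpr(flags = flags_tbl("EXTENDED_LEAVE")), WIN), 4)
  expect_equal(score_risk_of_harm(vpr(phq9 = phq9_tbl(10)), WIN), 4)
  expect_equal(score_risk_of_harm(vpr(phq9 = phq9_tbl(9)), WIN), 0)
})

test_that("medical complexity (Q7) tiers resolve with highest match winning", {
  q7 <- function(...) score_medical_complexity(vpr(...), WIN)
  expect_equal(q7(), 0)
  expect_equal(q7(problems = problems_tbl(1, sumh = TRUE)), 2)
  expect_equal(q7(problems = problems_tbl(3, sumh = TRUE)), 3)
  expect_equal(q7(problems = problems_tbl(4)), 1)
  expect_equal(q7(problems = problems_tbl(3)), 0) # 1-3 plain dx: no tier
  expect_equal(q7(problems = problems_tbl(1, complex_care = TRUE)), 4)
  expect_equal(q7(problems = problems_tbl(1, neuro = TRUE)), 4)
  expect_equal(q7(problems = problems_tbl(6)), 4)
  expect_equal(q7(problems = problems_tbl(1, sumh = TRUE),
                  flags = flags_tbl("EXTENDED_LEAVE")), 4)
  expect_equal(q7(honos = honos_tbl(AS_OF - 10, honos_items(item7 = 4))), 4)
})

test_that("Q7 modifiers add on top of the tier and clamp at 4", {
  vit <- function(sbp = NA, dbp = NA, bmi = NA) tibble::tibble(
    client_id = "x", date = AS_OF - 5,
    systolic_bp = sbp, diastolic_bp = dbp, bmi = bmi
  )
  q7 <- function(...) score_medical_complexity(vpr(...), WIN)

  # BP > 140/90 means systolic above 140 OR diastolic above 90
  expect_equal(q7(problems = problems_tbl(1, sumh = TRUE),
                  vitals = vit(150, 80)), 2.5)
  expect_equal(q7(problems = problems_tbl(1, sumh = TRUE),
                  vitals = vit(130, 95)), 2.5)
  expect_equal(q7(problems = problems_tbl(1, sumh = TRUE),
                  vitals = vit(140, 90)), 2)
  # BMI increments are mutually exclusive, highest applicable
  expect_equal(q7(problems = problems_tbl(1, sumh = TRUE),
                  vitals = vit(bmi = 26)), 2.25)
  expect_equal(q7(problems = problems_tbl(1, sumh = TRUE),
                  vitals = vit(bmi = 31)), 2.5)
  expect_equal(q7(problems = problems_tbl(1, sumh = TRUE),
                  vitals = vit(bmi = 36)), 2.75)
  # >5 diagnoses adds 1, then everything clamps at 4
  expect_equal(q7(problems = problems_tbl(6), vitals = vit(150, 80, 32)), 4)
  # vitals alone never score without a tier basis above 0
  expect_equal(q7(vitals = vit(150, 95, 36)), 1.25)
})

test_that("hospitalization complexity combines inverse CTAS and length of stay", {
  expect_equal(hospitalization_complexity_score(vpr(), WIN), 0)
  one_ed <- vpr(ed_visits = tibble::tibble(client_id = "x", date = AS_OF - 10,
                                           ctas_level = 2L))
  expect_equal(hospitalization_complexity_score(one_ed, WIN), 4)
  mixed <- vpr(
    ed_visits = tibble::tibble(client_id = "x", date = AS_OF - c(10, 20),
                               ctas_level = c(5L, 5L)),
    admissions = tibble::tibble(client_id = "x", admit_date = AS_OF - 40,
                                discharge_date = AS_OF - 30)
  )
  expect_equal(hospitalization_complexity_score(mixed, WIN), 12)
  # open admission accrues to the as-of date
  open_adm <- vpr(admissions = tibble::tibble(
    client_id = "x", admit_date = AS_OF - 30, discharge_date = as.Date(NA)
  ))
  expect_equal(hospitalization_complexity_score(open_adm, WIN), 30)
})

test_that("acute utilization (Q8) bins the burden at 15/25/50", {
  hcs_vpr <- function(los) vpr(admissions = tibble::tibble(
    client_id = "x", admit_date = AS_OF - los, discharge_date = AS_OF
  ))
  expect_equal(score_acute_utilization(vpr(), WIN), 0)
  expect_equal(score_acute_utilization(hcs_vpr(1), WIN), 1)
  expect_equal(score_acute_utilization(hcs_vpr(14), WIN), 1)
  expect_equal(score_acute_utilization(hcs_vpr(15), WIN), 2)
  expect_equal(score_acute_utilization(hcs_vpr(20), WIN), 2)
  expect_equal(score_acute_utilization(hcs_vpr(25), WIN), 3)
  expect_equal(score_acute_utilization(hcs_vpr(50), WIN), 3)
  expect_equal(score_acute_utilization(hcs_vpr(51), WIN), 4)
})

test_that("score_all composes the individual scorers and sets completeness", {
  empty <- score_all(vpr(), WIN)
  expect_equal(unname(empty$q), c(4, rep(0, 8)))
  expect_true(empty$completeness[["q1"]])
  expect_false(any(empty$completeness[paste0("q", 2:9)]))

  fx <- link_records(make_worked_fixtures(AS_OF))
  maxed <- score_all(fx$max_triggers, WIN)
  expect_equal(unname(maxed$q[2:9]), rep(4, 8))
  expect_equal(maxed$q[["q1"]], 0) # five dispersed visits: maximally attached
  expect_true(all(maxed$completeness))

  # composition equals calling each scorer individually
  v <- fx$phq9_ten
  s <- score_all(v, WIN)
  expect_equal(s$q[["q1"]], score_attachment(v, WIN))
  expect_equal(s$q[["q7"]], score_medical_complexity(v, WIN))
  expect_equal(s$q[["q9"]], score_risk_of_harm(v, WIN))
})

test_that("incomplete domains (other than attachment) score zero", {
  set.seed(101)
  cfg <- scoring_config()
  for (i in 1:200) {
    v <- random_vpr()
    s <- score_all(v, WIN, cfg)
    expect_true(all(s$q >= 0 & s$q <= 4))
    inc <- !s$completeness[paste0("q", 2:9)]
    expect_true(all(s$q[paste0("q", 2:9)][inc] == 0))
  }
})

test_that("scorers agree with the independent rule-table oracle on random records", {
  set.seed(2024)
  cfg <- scoring_config()
  for (i in 1:400) {
    v <- random_vpr()
    expect_equal(score_all(v, WIN, cfg)$q, oracle_scores(v, WIN, cfg),
                 info = paste("case", i))
  }
})

test_that("scores move monotonically with their inputs", {
  # q1 non-increasing in dispersed visit count
  q1s <- vapply(0:6, function(k) {
    v <- if (k == 0) vpr() else
      vpr(encounters = enc_tbl(AS_OF - seq(10, by = 20, length.out = k)))
    score_attachment(v, WIN)
  }, numeric(1))
  expect_true(all(diff(q1s) <= 0))

  # q2 non-decreasing in program count
  q2s <- vapply(1:6, function(k) {
    score_service_density(vpr(encounters = enc_tbl(
      AS_OF - seq(10, by = 20, length.out = k), program = paste0("p", 1:k)
    )), WIN)
  }, numeric(1))
  expect_true(all(diff(q2s) >= 0))

  # HoNOS domains non-decreasing in each contributing item
  for (lvl in 0:3) {
    lo <- vpr(honos = honos_tbl(AS_OF - 10, honos_items(item11 = lvl)))
    hi <- vpr(honos = honos_tbl(AS_OF - 10, honos_items(item11 = lvl + 1)))
    expect_lte(score_social_environmental(lo, WIN),
               score_social_environmental(hi, WIN))
    expect_lte(score_adl(lo, WIN), score_adl(hi, WIN))
  }

  # q8 non-decreasing in hcs (increasing LOS)
  q8s <- vapply(c(0, 5, 14, 15, 24, 25, 50, 51, 80), function(los) {
    v <- if (los == 0) vpr() else vpr(admissions = tibble::tibble(
      client_id = "x", admit_date = AS_OF - los, discharge_date = AS_OF
    ))
    score_acute_utilization(v, WIN)
  }, numeric(1))
  expect_true(all(diff(q8s) >= 0))
})
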