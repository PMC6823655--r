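test_that("bundle round-trips through JSON and CSV with identical field values", {
  bundle <- make_worked_fixtures(AS_OF)

  json_path <- file.path(withr::local_tempdir(), "bundle.json")
  write_bundle(bundle, json_path, "json")
  back <- read_bundle(json_path)
  for (tb in names(bundle)) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(bundle[[tb]]),
                 info = tb)
  }

  csv_dir <- file.path(withr::local_tempdir(), "bundle_csv")
  write_bundle(bundle, csv_dir, "csv")
  back_csv <- read_bundle(csv_dir)
  for (tb in names(bundle)) {
    expect_equal(as.data.frame(back_csv[[tb]]), as.data.frame(bundle[[tb]]),
                 info = tb)
  }
})

test_that("invariant violations are rejected with table/row/field diagnostics", {
  bad_honos <- honos_tbl(AS_OF - 5, honos_items(item3 = 4))
  bad_honos$item3 <- 5L
  err <- expect_error(record_bundle(honos = bad_honos), "honos")
  expect_match(conditionMessage(err), "item3")
  expect_match(conditionMessage(err), "row 1")

  issues <- validate_bundle(record_bundle(
    ed_visits = tibble::tibble(client_id = "a", date = AS_OF, ctas_level = 9L),
    validate = FALSE
  ))
  expect_equal(issues$table, "ed_visits")
  expect_equal(issues$field, "ctas_level")

  expect_error(
    record_bundle(flags = tibble::tibble(client_id = "a", flag_kind = "NOT_A_KIND",
                                         date = AS_OF)),
    "flag_kind"
  )
  expect_error(
    record_bundle(admissions = tibble::tibble(
      client_id = "a", admit_date = AS_OF, discharge_date = AS_OF - 1
    )),
    "discharge_date"
  )
})

test_that("a CSV directory with partial tables loads the typed records it holds", {
  dir <- withr::local_tempdir()
  write.csv(
    data.frame(client_id = c("A", "A", "B"), source_system = "s",
               date = "2018-06-01", program = "p", booked = TRUE,
               attended = TRUE),
    file.path(dir, "encounters.csv"), row.names = FALSE
  )
  hon <- data.frame(client_id = "B", date = "2018-07-01")
  for (i in 1:12) hon[[paste0("item", i)]] <- 1L
  write.csv(hon, file.path(dir, "honos.csv"), row.names = FALSE)

  bundle <- read_bundle(dir)
  expect_equal(nrow(bundle$encounters), 3)
  expect_equal(nrow(bundle$honos), 1)
  expect_s3_class(bundle$encounters$date, "Date")
  expect_type(bundle$encounters$attended, "logical")
  expect_equal(sum(vapply(bundle, nrow, integer(1))), 4)
})

test_that("linkage groups records by client and conserves every row", {
  bundle <- record_bundle(
    encounters = rbind(enc_tbl(AS_OF - 1), enc_tbl(AS_OF - 2)),
    phq9 = phq9_tbl(5)
  )
  bundle$encounters$client_id <- c("A", "B")
  bundle$phq9$client_id <- "A"
  vprs <- link_records(bundle)
  expect_named(vprs, c("A", "B"))
  expect_equal(nrow(vprs$A$encounters), 1)
  expect_equal(nrow(vprs$A$phq9), 1)
  expect_equal(nrow(vprs$B$encounters), 1)

  expect_length(link_records(record_bundle()), 0)

  cohort <- generate_cohort(cohort_spec(100, c(low = 0.4, high = 0.6), seed = 3))
  vprs <- link_records(cohort)
  expect_length(vprs, 100)
  for (tb in names(cohort)) {
    expect_equal(
      sum(vapply(vprs, function(v) nrow(v[[tb]]), integer(1))),
      nrow(cohort[[tb]]),
      info = tb
    )
  }
})

test_that("the analysis window is half-open at the start and inclusive of as-of", {
  v <- vpr(encounters = enc_tbl(c(
    AS_OF,                       # on as-of: in
    AS_OF - 1,                   # in
    as.Date("2017-07-01"),       # exactly 18 calendar months before: out
    as.Date("2017-07-02"),       # first day inside
    as.Date("2017-06-01")        # 19 months before: out
  )))
  f <- window_filter(v, WIN)
  expect_setequal(
    as.character(f$encounters$date),
    c("2019-01-01", "2018-12-31", "2017-07-02")
  )
})

test_that("window filtering is idempotent and leaves current-state tables alone", {
  v <- vpr(
    encounters = enc_tbl(c(AS_OF - 10, AS_OF - 900)),
    problems = problems_tbl(3),
    flags = flags_tbl("PWD_FORM"),
    honos = honos_tbl(AS_OF - 700, honos_items(item1 = 2)),
    admissions = tibble::tibble(client_id = "x", admit_date = AS_OF - 900,
                                discharge_date = AS_OF - 880)
  )
  once <- window_filter(v, WIN)
  expect_identical(window_filter(once, WIN), once)
  expect_equal(nrow(once$encounters), 1)
  expect_equal(nrow(once$honos), 0)
  expect_equal(nrow(once$admissions), 0)
  expect_equal(nrow(once$problems), 3)   # current-state: retained
  expect_equal(nrow(once$flags), 1)      # current-state: retained

  undated <- vpr(problems = problems_tbl(2), flags = flags_tbl("SHX_CODE"))
  filtered <- window_filter(undated, WIN)
  expect_equal(nrow(filtered$problems), 2)
  expect_equal(nrow(filtered$flags), 1)
})

test_that("calendar-month lookback clips day-of-month correctly", {
  w <- analysis_window("2019-03-31", 1L)
  expect_equal(w$start, as.Date("2019-02-28"))
  w2 <- analysis_window("2020-03-31", 1L)
  expect_equal(w2$start, as.Date("2020-02-29"))
  expect_error(analysis_window("2019-01-01", 0), "positive")
})

test_that("latest HoNOS picks max date, breaking ties by item sum", {
  v <- vpr(honos = rbind(
    honos_tbl(AS_OF - 300, honos_items(item1 = 4)),
    honos_tbl(AS_OF - 60, honos_items(item2 = 1))
  ))
  expect_equal(latest_honos(v, WIN)$item2, 1)

  tie <- vpr(honos = rbind(
    honos_tbl(AS_OF - 60, honos_items(item1 = 1)),
    honos_tbl(AS_OF - 60, honos_items(item1 = 3, item2 = 2))
  ))
  expect_equal(latest_honos(tie, WIN)$item1, 3)

  expect_null(latest_honos(vpr(), WIN))
})
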