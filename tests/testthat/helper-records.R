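# Shared builders for hand-constructed records.

AS_OF <- as.Date("2019-01-01")
WIN <- analysis_window(AS_OF, 18L)

enc_tbl <- function(dates, program = "primary_care", booked = TRUE,
                    attended = TRUE, source = "primary_care_emr") {
  tibble::tibble(
    client_id = "x", source_system = source, date = as.Date(dates),
    program = program, booked = booked, attended = attended
  )
}

honos_tbl <- function(date, items = rep(0L, 12)) {
  stopifnot(length(items) == 12)
  tibble::as_tibble(c(
    list(client_id = "x", date = as.Date(date)),
    setNames(as.list(as.integer(items)), paste0("item", 1:12))
  ))
}

honos_items <- function(...) {
  # honos_items(item11 = 2, item12 = 1): all other items zero
  spec <- list(...)
  items <- setNames(rep(0L, 12), paste0("item", 1:12))
  items[names(spec)] <- as.integer(unlist(spec))
  unname(items)
}

problems_tbl <- function(n = 1, sumh = FALSE, complex_care = FALSE,
                         neuro = FALSE) {
  if (n == 0) return(NULL)
  tibble::tibble(
    client_id = "x", code = paste0("D", seq_len(n)), label = "dx",
    is_sumh = c(sumh, rep(FALSE, n - 1)),
    is_complex_care = c(complex_care, rep(FALSE, n - 1)),
    is_neurodegenerative = c(neuro, rep(FALSE, n - 1))
  )
}

flags_tbl <- function(kinds) {
  tibble::tibble(client_id = "x", flag_kind = kinds, date = AS_OF - 30)
}

phq9_tbl <- function(total, date = AS_OF - 10) {
  tibble::tibble(client_id = "x", date = as.Date(date), total = as.integer(total))
}
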