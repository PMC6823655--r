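# Population-level aggregation: interval histograms of composite scores,
# per-domain score distributions, and the weighted-vs-unweighted delta table.

CCS_BANDS <- c("0-1", "1-2", "2+")

# Maximum attainable weighted composite with the default three-tier factors;
# slightly above 3 by construction, so band validation allows it.
max_weighted_ccs <- function(w = default_weights()) sqrt(sum(as.numeric(w)^2))

#' Composite-score interval histogram
#'
#' Counts composite scores into the reporting bands 0-1, 1-2 and 2+,
#' implemented as the partition \[0,1), \[1,2), \[2, max\]. Counts always sum
#' to the number of scores.
#'
#' @param scores Numeric composite scores (unweighted in \[0,3\]; weighted
#'   scores may exceed 3 by at most the weighting overshoot).
#' @return A named integer vector with elements `0-1`, `1-2`, `2+`.
#' @export
interval_histogram <- function(scores) {
  scores <- as.numeric(scores)
  upper <- max_weighted_ccs() + 1e-6
  if (any(is.na(scores)) || any(scores < 0) || any(scores > upper)) {
    stop("composite scores must lie in [0, 3] (weighted: up to the weighting maximum)",
         call. = FALSE)
  }
  setNames(c(
    sum(scores < 1),
    sum(scores >= 1 & scores < 2),
    sum(scores >= 2)
  ), CCS_BANDS)
}

#' Per-domain score distributions
#'
#' Tabulates, for each of the nine domains, how many clients sit at each
#' observed score level -- both the raw Q-score and the weighted domain score
#' `w * q`. Level counts sum to the number of clients for every domain.
#'
#' @param scores A per-client score table from [score_cohort()].
#' @param w A [weight_config()].
#' @return A tibble with columns `domain`, `kind` (`"unweighted"` /
#'   `"weighted"`), `score`, `n`.
#' @export
domain_breakdown <- function(scores, w = default_weights()) {
  w <- weight_config(w)
  rows <- list()
  for (d in paste0("q", 1:9)) {
    raw <- scores[[d]]
    for (kind in c("unweighted", "weighted")) {
      vals <- if (kind == "weighted") as.numeric(w[d]) * raw else raw
      if (length(vals) == 0) {
        tab <- integer(0)
        lev <- numeric(0)
      } else {
        tab <- table(vals)
        lev <- as.numeric(names(tab))
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        domain = d, kind = kind, score = lev, n = as.integer(tab)
      )
    }
  }
  do.call(rbind, rows)
}

#' Weighted-vs-unweighted delta report
#'
#' @param composites A data frame with columns `client_id`, `ccs_weighted`,
#'   `ccs_unweighted` (e.g. from [composite_cohort()]).
#' @return A list with `per_client` (tibble of client_id, ccs_unweighted,
#'   ccs_weighted, delta) and `summary` (mean, min, max of delta).
#' @export
delta_report <- function(composites) {
  per_client <- tibble::tibble(
    client_id = composites$client_id,
    ccs_unweighted = composites$ccs_unweighted,
    ccs_weighted = composites$ccs_weighted,
    delta = composites$ccs_weighted - composites$ccs_unweighted
  )
  n <- nrow(per_client)
  list(
    per_client = per_client,
    summary = c(
      mean = if (n) mean(per_client$delta) else NA_real_,
      min = if (n) min(per_client$delta) else NA_real_,
      max = if (n) max(per_client$delta) else NA_real_
    )
  )
}

#' Assemble the population-level report
#'
#' Scores and composites for every client in a bundle, aggregated into the
#' tabular data behind the standard population charts: composite interval
#' counts (weighted and unweighted), per-domain score distributions, and the
#' per-client delta table.
#'
#' @param bundle A `record_bundle`.
#' @param window An [analysis_window()].
#' @param config A [scoring_config()].
#' @param w A [weight_config()].
#' @return A `population_report`: list with `n_clients`, `as_of_date`,
#'   `scores` (per-client table with composites), `interval_counts` (tibble:
#'   kind, band, n), `domain_distribution`, and `delta`.
#' @export
population_report <- function(bundle, window, config = scoring_config(),
                              w = default_weights()) {
  scores <- composite_cohort(score_cohort(bundle, window, config), w)
  interval_counts <- rbind(
    tibble::tibble(
      kind = "unweighted", band = CCS_BANDS,
      n = as.integer(interval_histogram(scores$ccs_unweighted))
    ),
    tibble::tibble(
      kind = "weighted", band = CCS_BANDS,
      n = as.integer(interval_histogram(scores$ccs_weighted))
    )
  )
  structure(
    list(
      n_clients = nrow(scores),
      as_of_date = window$as_of_date,
      scores = scores,
      interval_counts = interval_counts,
      domain_distribution = domain_breakdown(scores, w),
      delta = delta_report(scores)
    ),
    class = "population_report"
  )
}

#' @export
print.population_report <- function(x, ...) {
  cat("<population_report>", x$n_clients, "clients as of",
      format(x$as_of_date), "\n")
  print(x$interval_counts)
  invisible(x)
}

#' Export a population report to disk
#'
#' Writes the per-client score table, interval band counts, per-domain
#' distribution and delta table with a deterministic column order.
#'
#' @param report A [population_report()].
#' @param path Output directory (created if needed) for `format = "csv"`;
#'   a single `.json` file for `format = "json"`.
#' @param format `"csv"` or `"json"`.
#' @return The written path(s), invisibly.
#' @export
export_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  scores <- as.data.frame(report$scores)
  scores$as_of_date <- date_to_chr(scores$as_of_date)
  tables <- list(
    scores = scores,
    interval_counts = as.data.frame(report$interval_counts),
    domain_distribution = as.data.frame(report$domain_distribution),
    delta = as.data.frame(report$delta$per_client)
  )
  if (format == "csv") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- character(0)
    for (nm in names(tables)) {
      f <- file.path(path, paste0(nm, ".csv"))
      write.csv(tables[[nm]], f, row.names = FALSE, na = "")
      files <- c(files, f)
    }
    return(invisible(files))
  }
  payload <- c(
    list(
      n_clients = report$n_clients,
      as_of_date = date_to_chr(report$as_of_date),
      delta_summary = as.list(report$delta$summary)
    ),
    tables
  )
  jsonlite::write_json(payload, path,
    dataframe = "rows", na = "null", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
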