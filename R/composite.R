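# Composite Complexity Score (CCS): each domain Q-score is divided by 4 to
# an adjusted value p in [0, 1]; the composite is the root sum squared of the
# nine p values, giving a range of 0 to 3. Weighted composites multiply each
# p by a per-domain factor inside the root sum square -- the only placement
# for which the +20% / -25% three-tier factors keep the maximum near 3.

#' Per-domain weight configuration
#'
#' Multiplicative factors applied to the adjusted domain values inside the
#' weighted composite. The defaults are the three staff-survey-derived tiers:
#' social/environmental (Q3), psychosocial (Q4) and medical complexity (Q7)
#' over-weighted at 1.20; attachment (Q1), ADLs (Q6) and risk of harm (Q9)
#' at 1.00; service density (Q2), relationships (Q5) and hospital utilization
#' (Q8) under-weighted at 0.75.
#'
#' @param w Named numeric vector of nine positive factors (`q1`..`q9`).
#' @param provenance Free-text note recording where the factors came from.
#' @return A `weight_config`: the named factor vector with a provenance
#'   attribute.
#' @export
weight_config <- function(w = default_weights(), provenance = NULL) {
  if (is.list(w)) w <- unlist(w)
  nm <- paste0("q", 1:9)
  if (length(w) != 9) stop("weights must be nine factors named q1..q9", call. = FALSE)
  if (is.null(names(w))) names(w) <- nm
  if (!setequal(names(w), nm)) {
    stop("weights must be nine factors named q1..q9", call. = FALSE)
  }
  w <- w[nm]
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("all weighting factors must be positive", call. = FALSE)
  }
  structure(w, provenance = provenance %||% attr(w, "provenance") %||% "unspecified",
            class = "weight_config")
}

#' @rdname weight_config
#' @export
default_weights <- function() {
  structure(
    c(q1 = 1.00, q2 = 0.75, q3 = 1.20, q4 = 1.20, q5 = 0.75,
      q6 = 1.00, q7 = 1.20, q8 = 0.75, q9 = 1.00),
    provenance = "default three-tier staff-survey weighting (1.20 / 1.00 / 0.75)",
    class = "weight_config"
  )
}

#' @export
print.weight_config <- function(x, ...) {
  cat("<weight_config>", attr(x, "provenance"), "\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Read / write a weight configuration as YAML
#'
#' @param path A YAML file with fields `q1`..`q9` (and optional `provenance`).
#' @return For `read_weight_config` a `weight_config`; for
#'   `write_weight_config`, `path` invisibly.
#' @export
read_weight_config <- function(path) {
  raw <- yaml::read_yaml(path)
  prov <- raw$provenance
  raw$provenance <- NULL
  weight_config(unlist(raw), provenance = prov)
}

#' @rdname read_weight_config
#' @param w A `weight_config`.
#' @export
write_weight_config <- function(w, path) {
  payload <- c(as.list(setNames(as.numeric(w), names(w))),
               list(provenance = attr(w, "provenance")))
  yaml::write_yaml(payload, path)
  invisible(path)
}

as_q_vector <- function(q) {
  if (inherits(q, "domain_scores")) q <- q$q
  q <- as.numeric(q)
  if (length(q) != 9) stop("expected nine domain scores", call. = FALSE)
  if (any(is.na(q)) || any(q < 0 - 1e-12) || any(q > 4 + 1e-12)) {
    stop("domain scores must lie in [0, 4]", call. = FALSE)
  }
  setNames(q, paste0("q", 1:9))
}

new_composite_result <- function(client_id, p, unweighted, weighted) {
  structure(
    list(
      client_id = client_id,
      p = p,
      ccs_unweighted = unweighted,
      ccs_weighted = weighted,
      delta = if (is.na(weighted)) NA_real_ else weighted - unweighted
    ),
    class = "composite_result"
  )
}

#' Composite complexity scores
#'
#' `composite_unweighted()` computes the unweighted CCS:
#' `sqrt(sum((q/4)^2))`, ranging 0 (all domains 0) to 3 (all domains 4).
#' `composite_weighted()` additionally computes the weighted CCS
#' `sqrt(sum((w * q/4)^2))` and the delta between the two; outputs always
#' carry both forms, since the weighting reflects one site's values at one
#' time.
#'
#' @param q Nine domain scores in \[0, 4\]: a numeric vector or a
#'   `domain_scores` object from [score_all()].
#' @param w A [weight_config()].
#' @return A `composite_result`: adjusted values `p` (q/4), `ccs_unweighted`,
#'   `ccs_weighted` (`NA` for the unweighted-only form) and `delta`.
#' @export
composite_unweighted <- function(q) {
  client_id <- if (inherits(q, "domain_scores")) q$client_id else NA_character_
  qv <- as_q_vector(q)
  p <- qv / 4
  new_composite_result(client_id, p, sqrt(sum(p^2)), NA_real_)
}

#' @rdname composite_unweighted
#' @export
composite_weighted <- function(q, w = default_weights()) {
  client_id <- if (inherits(q, "domain_scores")) q$client_id else NA_character_
  w <- weight_config(w)
  qv <- as_q_vector(q)
  p <- qv / 4
  new_composite_result(
    client_id, p,
    sqrt(sum(p^2)),
    sqrt(sum((as.numeric(w) * p)^2))
  )
}

#' @export
print.composite_result <- function(x, ...) {
  cat(sprintf(
    "<composite_result> %s  unweighted %.3f  weighted %s  delta %s\n",
    x$client_id %||% "?",
    x$ccs_unweighted,
    if (is.na(x$ccs_weighted)) "-" else sprintf("%.3f", x$ccs_weighted),
    if (is.na(x$delta)) "-" else sprintf("%+.3f", x$delta)
  ))
  invisible(x)
}

#' Composite scores for a scored cohort
#'
#' @param scores A per-client score table from [score_cohort()].
#' @param w A [weight_config()].
#' @return `scores` with columns `ccs_unweighted`, `ccs_weighted`, `delta`
#'   appended.
#' @export
composite_cohort <- function(scores, w = default_weights()) {
  w <- weight_config(w)
  qm <- as.matrix(scores[paste0("q", 1:9)]) / 4
  scores$ccs_unweighted <- sqrt(rowSums(qm^2))
  scores$ccs_weighted <- sqrt(rowSums(sweep(qm, 2, as.numeric(w), `*`)^2))
  scores$delta <- scores$ccs_weighted - scores$ccs_unweighted
  scores
}

#' Derive domain weights from a staff importance survey
#'
#' Staff rate each domain's importance for determining client complexity on
#' a five-point scale (Not / Slightly / Moderately / Important / Very
#' Important). Per domain, the fraction of respondents answering Important or
#' Very Important classifies the domain into a weighting tier: at or above
#' `high` receives the over-weight factor, below `low` the under-weight
#' factor, and anything between the neutral factor. Setting `low = high`
#' yields a two-tier scheme.
#'
#' @param survey A data frame with columns `domain` (q1..q9) and rating
#'   counts `not_important`, `slightly_important`, `moderately_important`,
#'   `important`, `very_important`.
#' @param high,low Fraction thresholds in \[0, 1\], `low <= high`.
#' @param factors Length-3 numeric: over-weight, neutral, under-weight
#'   factors (defaults 1.20 / 1.00 / 0.75).
#' @return A [weight_config()] whose provenance note records the thresholds.
#' @export
derive_weights_from_survey <- function(survey, high = 0.8, low = 0.5,
                                       factors = c(1.20, 1.00, 0.75)) {
  rating_cols <- c("not_important", "slightly_important",
                   "moderately_important", "important", "very_important")
  missing <- setdiff(c("domain", rating_cols), names(survey))
  if (length(missing) > 0) {
    stop("survey summary lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!(low <= high && low >= 0 && high <= 1)) {
    stop("thresholds must satisfy 0 <= low <= high <= 1", call. = FALSE)
  }
  nm <- paste0("q", 1:9)
  if (!setequal(survey$domain, nm)) {
    stop("survey must cover exactly the domains q1..q9", call. = FALSE)
  }
  survey <- survey[match(nm, survey$domain), ]
  counts <- as.matrix(survey[rating_cols])
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("zero respondents for domain(s): ",
         paste(survey$domain[totals == 0], collapse = ", "), call. = FALSE)
  }
  frac_high <- (counts[, "important"] + counts[, "very_important"]) / totals
  w <- ifelse(frac_high >= high, factors[1],
              ifelse(frac_high < low, factors[3], factors[2]))
  weight_config(
    setNames(w, nm),
    provenance = sprintf(
      "derived from staff survey (n = %d max respondents/domain); tiers %s/%s/%s at fractions >= %s / < %s rating Important or Very Important",
      max(totals), factors[1], factors[2], factors[3], high, low
    )
  )
}
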