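#' SOC report-rate distribution
#'
#' Report numbers and rates per System Organ Class, for one drug or pooled
#' over all drugs in the table. The denominator is the drug's report total
#' (or the pooled total); rates are carried unrounded, with a 2-decimal
#' half-up rendering in `rate_display` matching the published tables.
#'
#' @param counts An [adr_counts()] with a `soc` section.
#' @param drug A drug name, or NULL for the pooled distribution.
#' @return Tibble `drug, soc, count, denominator, rate_percent, rate_display`,
#'   one row per SOC, sorted by count descending (ties by SOC name).
#' @export
#' @examples
#' fx <- load_paper_fixture()
#' head(soc_distribution(fx$counts), 3)          # pooled
#' head(soc_distribution(fx$counts, "liraglutide"), 3)
soc_distribution <- function(counts, drug = NULL) {
  stopifnot(inherits(counts, "adr_counts"))
  if (is.null(counts$soc) || nrow(counts$soc) == 0) abort("no SOC section in table")
  if (is.null(drug)) {
    tbl <- dplyr::summarise(dplyr::group_by(counts$soc, .data$soc),
                            count = sum(.data$count), .groups = "drop")
    tbl$drug <- "pooled"
    denom <- sum(counts$totals$n_reports)
  } else {
    if (!drug %in% counts$totals$drug) abort(paste0("unknown drug: ", drug))
    tbl <- counts$soc[counts$soc$drug == drug, c("soc", "count")]
    tbl$drug <- drug
    denom <- counts$totals$n_reports[counts$totals$drug == drug]
  }
  tbl$denominator <- denom
  tbl$rate_percent <- 100 * tbl$count / denom
  tbl$rate_display <- sprintf("%.2f", round_half_up(tbl$rate_percent, 2))
  dplyr::arrange(tbl[, c("drug", "soc", "count", "denominator",
                         "rate_percent", "rate_display")],
                 dplyr::desc(.data$count), .data$soc)
}

#' Top-N most reported preferred terms for one drug
#'
#' PT report counts ranked descending, ties broken lexicographically by PT
#' name; rates use the drug's report total as denominator. The output is a
#' prefix of the full ranking: increasing `n` never reorders earlier entries.
#'
#' @param counts An [adr_counts()] with a `pt` section.
#' @param drug Drug name (must be present).
#' @param n Maximum number of PTs to return (>= 1); fewer are returned when
#'   the drug's PT vocabulary is smaller, with no padding.
#' @return Tibble `drug, pt, count, denominator, rate_percent, rate_display`.
#' @export
top_adrs <- function(counts, drug, n = 20) {
  stopifnot(inherits(counts, "adr_counts"), n >= 1)
  if (is.null(counts$pt) || nrow(counts$pt) == 0) {
    abort("no PT section in table (aggregate-only input carries SOC counts)")
  }
  if (!drug %in% counts$totals$drug) abort(paste0("unknown drug: ", drug))
  tbl <- counts$pt[counts$pt$drug == drug, ]
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$count), .data$pt)
  tbl <- head(tbl, n)
  denom <- counts$totals$n_reports[counts$totals$drug == drug]
  tbl$denominator <- denom
  tbl$rate_percent <- 100 * tbl$count / denom
  tbl$rate_display <- sprintf("%.2f", round_half_up(tbl$rate_percent, 2))
  tbl[, c("drug", "pt", "count", "denominator", "rate_percent", "rate_display")]
}

#' Demographic summary over a set of drugs
#'
#' Sums the demographic strata of the selected drugs per axis and level,
#' computes rates against the summed report total, and the female:male
#' ratio from the summed sex counts. `"unknown"` levels are reported, never
#' dropped. With zero female and male counts the ratio is `NaN`.
#'
#' @param counts An [adr_counts()] with a `demographics` section.
#' @param drugs Character vector of drugs to include (default: all).
#' @param collapse_before Optional integer year: numeric year levels earlier
#'   than this collapse into one `"Before <year>"` band, matching the shape
#'   of published report-year tables.
#' @return A list of class `demographic_summary`: `summary` (tibble `axis,
#'   level, count, rate_percent`), `female_male_ratio`, `n_reports`, `drugs`.
#' @export
#' @examples
#' fx <- load_paper_fixture()
#' demographic_summary(fx$counts)$female_male_ratio  # 1.62
demographic_summary <- function(counts, drugs = NULL, collapse_before = NULL) {
  stopifnot(inherits(counts, "adr_counts"))
  if (is.null(counts$demographics) || nrow(counts$demographics) == 0) {
    abort("no demographics section in table")
  }
  drugs <- drugs %||% counts$totals$drug
  if (length(drugs) == 0) abort("drug set must be non-empty")
  missing <- setdiff(drugs, counts$totals$drug)
  if (length(missing)) abort(paste0("unknown drug(s): ", paste(missing, collapse = ", ")))

  d <- counts$demographics[counts$demographics$drug %in% drugs, ]
  if (!is.null(collapse_before)) {
    yr <- d$axis == "year" & !is.na(suppressWarnings(as.integer(d$level))) &
      suppressWarnings(as.integer(d$level)) < collapse_before
    d$level[yr] <- paste("Before", collapse_before)
  }
  smry <- dplyr::summarise(dplyr::group_by(d, .data$axis, .data$level),
                           count = sum(.data$count), .groups = "drop")
  n_total <- sum(counts$totals$n_reports[counts$totals$drug %in% drugs])
  smry$rate_percent <- 100 * smry$count / n_total

  fem <- sum(smry$count[smry$axis == "sex" & smry$level == "female"])
  mal <- sum(smry$count[smry$axis == "sex" & smry$level == "male"])
  structure(list(summary = smry,
                 female_male_ratio = fem / mal,
                 n_reports = n_total, drugs = drugs),
            class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat("<demographic_summary> ", x$n_reports, " reports over ",
      length(x$drugs), " drug(s); female:male = ",
      sprintf("%.2f", x$female_male_ratio), ":1\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Serious-outcome proportions per drug
#'
#' Regulatory seriousness summary from report-level data: per drug, the
#' percentage of reports carrying at least one outcome in each category —
#' `death`, `hospitalization`, `major_events` (life-threatening, disability
#' or congenital anomaly) and `any_serious` (any outcome at all). Categories
#' are not exclusive: a report flagged both death and hospitalization counts
#' once in each, and once in `any_serious`.
#'
#' @param reports An [adr_reports()] tibble.
#' @return Tibble `drug, n_reports, category, count, rate_percent` (empty for
#'   empty input).
#' @export
serious_outcome_summary <- function(reports) {
  stopifnot(inherits(reports, "adr_reports"))
  categories <- c("death", "hospitalization", "major_events", "any_serious")
  if (nrow(reports) == 0) {
    return(tibble::tibble(drug = character(), n_reports = integer(),
                          category = character(), count = integer(),
                          rate_percent = numeric()))
  }
  major <- c("life_threatening", "disability", "congenital_anomaly")
  flags <- tibble::tibble(
    drug = reports$drug,
    death = vapply(reports$outcomes, function(o) "death" %in% o, logical(1)),
    hospitalization = vapply(reports$outcomes, function(o) "hospitalization" %in% o, logical(1)),
    major_events = vapply(reports$outcomes, function(o) any(major %in% o), logical(1)),
    any_serious = lengths(reports$outcomes) > 0)
  long <- tidyr::pivot_longer(flags, dplyr::all_of(categories),
                              names_to = "category", values_to = "flag")
  out <- dplyr::summarise(dplyr::group_by(long, .data$drug, .data$category),
                          n_reports = dplyr::n(), count = sum(.data$flag),
                          .groups = "drop")
  out$rate_percent <- 100 * out$count / out$n_reports
  out$category <- factor(out$category, levels = categories)
  out <- dplyr::arrange(out, .data$drug, .data$category)
  out$category <- as.character(out$category)
  out[, c("drug", "n_reports", "category", "count", "rate_percent")]
}
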