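#' Aggregated ADR count tables
#'
#' The working currency of the descriptive and disproportionality analyses:
#' per-drug report totals plus per-(drug, SOC) and per-(drug, PT) occurrence
#' counts, demographic strata and outcome counts. Occurrence counting follows
#' one convention throughout: a report contributes at most 1 to each PT it
#' lists, and its SOC contribution is the number of distinct listed PTs
#' mapping to that SOC, so per drug the SOC counts and PT counts sum to the
#' same total ADR occurrence count.
#'
#' Sections other than `totals` are optional (aggregate-only published tables
#' typically carry no PT section). `soc_reports` holds distinct-report counts
#' per (drug, SOC), needed for report-unit contingency tables at SOC level.
#'
#' @param totals Tibble `drug, n_reports` (n_reports >= 1, drugs unique).
#' @param soc Tibble `drug, soc, count` of occurrence counts, or NULL.
#' @param pt Tibble `drug, pt, count` of report counts per PT, or NULL.
#' @param soc_reports Tibble `drug, soc, n_reports_soc` (distinct reports
#'   listing at least one PT of that SOC), or NULL.
#' @param demographics Tibble `drug, axis, level, count` with axis in
#'   `adr_levels()$axes`, or NULL.
#' @param outcomes Tibble `drug, outcome, count`, or NULL.
#' @param validate Run invariant checks (default TRUE).
#' @return An object of class `adr_counts` (a named list of tibbles).
#' @export
adr_counts <- function(totals, soc = NULL, pt = NULL, soc_reports = NULL,
                       demographics = NULL, outcomes = NULL, validate = TRUE) {
  as_tbl <- function(x) if (is.null(x)) NULL else tibble::as_tibble(x)
  x <- structure(list(totals = as_tbl(totals), soc = as_tbl(soc), pt = as_tbl(pt),
                      soc_reports = as_tbl(soc_reports),
                      demographics = as_tbl(demographics), outcomes = as_tbl(outcomes)),
                 class = "adr_counts")
  if (validate) validate_adr_counts(x)
  x
}

#' @export
print.adr_counts <- function(x, ...) {
  cat("<adr_counts> ", nrow(x$totals), " drug(s), ",
      sum(x$totals$n_reports), " reports\n", sep = "")
  for (s in c("soc", "pt", "soc_reports", "demographics", "outcomes")) {
    if (!is.null(x[[s]])) cat("  ", s, ": ", nrow(x[[s]]), " rows\n", sep = "")
  }
  invisible(x)
}

#' Drugs present in a count table
#' @param x An `adr_counts` object.
#' @return Character vector in table order.
#' @export
count_table_drugs <- function(x) {
  stopifnot(inherits(x, "adr_counts"))
  x$totals$drug
}

check_counts_col <- function(tbl, col, what) {
  v <- tbl[[col]]
  if (anyNA(v) || any(v < 0) || any(v != floor(v))) {
    abort(paste0(what, ": counts must be non-negative integers"))
  }
}

validate_adr_counts <- function(x) {
  tt <- x$totals
  if (is.null(tt) || !all(c("drug", "n_reports") %in% names(tt))) {
    abort("totals section must have columns drug, n_reports")
  }
  if (anyDuplicated(tt$drug)) abort("duplicate drug in totals")
  if (nrow(tt) > 0 && (anyNA(tt$n_reports) || any(tt$n_reports < 1))) {
    abort("n_reports must be >= 1 for every drug present")
  }
  drugs <- tt$drug
  for (s in c("soc", "pt", "soc_reports", "demographics", "outcomes")) {
    tbl <- x[[s]]
    if (is.null(tbl) || nrow(tbl) == 0) next
    unknown <- setdiff(unique(tbl$drug), drugs)
    if (length(unknown)) {
      abort(paste0(s, " section references drug(s) absent from totals: ",
                   paste(unknown, collapse = ", ")))
    }
    cnt_col <- if (s == "soc_reports") "n_reports_soc" else "count"
    check_counts_col(tbl, cnt_col, s)
  }
  # conservation of occurrences: when both levels are present they must agree
  if (!is.null(x$soc) && nrow(x$soc) > 0 && !is.null(x$pt) && nrow(x$pt) > 0) {
    s_tot <- tapply(x$soc$count, x$soc$drug, sum)
    p_tot <- tapply(x$pt$count, x$pt$drug, sum)
    shared <- intersect(names(s_tot), names(p_tot))
    if (!isTRUE(all.equal(as.numeric(s_tot[shared]), as.numeric(p_tot[shared])))) {
      abort("per-drug SOC occurrence totals must equal PT occurrence totals")
    }
  }
  if (!is.null(x$demographics) && nrow(x$demographics) > 0) {
    d <- x$demographics
    bad_axis <- setdiff(unique(d$axis), DEMOGRAPHIC_AXES)
    if (length(bad_axis)) {
      abort(paste0("unknown demographic axis: ", paste(bad_axis, collapse = ", ")))
    }
    sums <- dplyr::summarise(dplyr::group_by(d, .data$drug, .data$axis),
                             total = sum(.data$count), .groups = "drop")
    sums <- dplyr::left_join(sums, tt, by = "drug")
    # sex/age/region strata partition the reports; year tables may omit bands
    # (the published tables stop at the last full calendar year)
    strict <- sums$axis %in% c("sex", "age_group", "region")
    if (any(sums$total[strict] != sums$n_reports[strict])) {
      abort("sex/age_group/region strata must sum to n_reports per drug")
    }
    if (any(sums$total > sums$n_reports)) {
      abort("demographic strata may not exceed n_reports")
    }
  }
  invisible(x)
}

#' Aggregate report-level data into count tables
#'
#' Builds the full [adr_counts()] structure from individual case safety
#' reports: per-drug report totals, PT report counts, SOC occurrence counts
#' (each report contributes one occurrence per distinct listed PT),
#' distinct-report SOC counts, demographic strata (with `"unknown"` levels
#' kept) and outcome counts (five regulatory categories plus `any_serious`).
#'
#' @param reports An [adr_reports()] tibble.
#' @param dict A [meddra_dictionary()] resolving every PT in `reports`;
#'   an unresolvable PT is an error naming the PT and the report id.
#' @return An [adr_counts()] object.
#' @export
#' @examples
#' d <- meddra_dictionary(c("Nausea", "Headache"),
#'                        c("Gastrointestinal disorders", "Nervous system disorders"))
#' r <- adr_reports(c("r1", "r2"), "X", list("Nausea", c("Nausea", "Headache")))
#' aggregate_reports(r, d)
aggregate_reports <- function(reports, dict) {
  stopifnot(inherits(reports, "adr_reports"), inherits(dict, "meddra_dict"))
  if (nrow(reports) == 0) {
    empty <- tibble::tibble(drug = character(), n_reports = integer())
    return(adr_counts(empty,
                      soc = tibble::tibble(drug = character(), soc = character(), count = integer()),
                      pt = tibble::tibble(drug = character(), pt = character(), count = integer())))
  }
  long <- tidyr::unnest(
    tibble::tibble(report_id = reports$report_id, drug = reports$drug,
                   pt = reports$reactions),
    "pt")
  unknown <- !(long$pt %in% dict$pt)
  if (any(unknown)) {
    first <- which(unknown)[1]
    abort(paste0("PT not in dictionary: '", long$pt[first],
                 "' (report ", long$report_id[first], ")"))
  }
  long$soc <- soc_of(dict, long$pt)

  totals <- dplyr::count(tibble::tibble(drug = reports$drug), .data$drug,
                         name = "n_reports")
  pt_counts <- dplyr::count(long, .data$drug, .data$pt, name = "count")
  soc_counts <- dplyr::count(long, .data$drug, .data$soc, name = "count")
  soc_reports <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(long, .data$report_id, .data$drug, .data$soc),
                    .data$drug, .data$soc),
    n_reports_soc = dplyr::n(), .groups = "drop")

  base <- tibble::tibble(drug = reports$drug, sex = reports$sex,
                         age_group = reports$age_group, region = reports$region,
                         year = ifelse(is.na(reports$year), "unknown",
                                       as.character(reports$year)))
  demo <- dplyr::bind_rows(lapply(c("sex", "age_group", "region", "year"), function(ax) {
    d <- dplyr::count(base, .data$drug, level = .data[[ax]], name = "count")
    d$axis <- ax
    d[, c("drug", "axis", "level", "count")]
  }))

  out_long <- tidyr::unnest(
    tibble::tibble(drug = reports$drug, outcome = reports$outcomes), "outcome")
  out_counts <- dplyr::count(out_long, .data$drug, .data$outcome, name = "count")
  any_serious <- dplyr::count(
    dplyr::filter(tibble::tibble(drug = reports$drug, k = lengths(reports$outcomes)),
                  .data$k > 0),
    .data$drug, name = "count")
  if (nrow(any_serious) > 0) any_serious$outcome <- "any_serious"
  outcomes <- dplyr::bind_rows(out_counts, any_serious)

  adr_counts(totals, soc = soc_counts, pt = pt_counts, soc_reports = soc_reports,
             demographics = demo, outcomes = outcomes)
}

aggregate_files <- c(totals = "totals.csv", soc = "soc.csv", pt = "pt.csv",
                     soc_reports = "soc_reports.csv",
                     demographics = "demographics.csv", outcomes = "outcomes.csv")

#' Write / read an aggregate count table as a directory of CSV files
#'
#' One CSV per section (`totals.csv`, `soc.csv`, `pt.csv`, `soc_reports.csv`,
#' `demographics.csv`, `outcomes.csv`); absent sections are skipped. The pair
#' round-trips exactly: `read_aggregate(write_aggregate(x, dir))` equals `x`.
#'
#' @param x An [adr_counts()] object.
#' @param dir Directory path (created if needed).
#' @return `write_aggregate()` returns `dir` invisibly; `read_aggregate()`
#'   returns an [adr_counts()] object.
#' @export
write_aggregate <- function(x, dir) {
  stopifnot(inherits(x, "adr_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in names(aggregate_files)) {
    if (!is.null(x[[s]])) readr::write_csv(x[[s]], file.path(dir, aggregate_files[[s]]),
                                           progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_aggregate
#' @export
read_aggregate <- function(dir) {
  if (!file.exists(file.path(dir, "totals.csv"))) {
    abort(paste0("no totals.csv in ", dir))
  }
  rd <- function(s) {
    p <- file.path(dir, aggregate_files[[s]])
    if (!file.exists(p)) return(NULL)
    df <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
    num_col <- intersect(c("n_reports", "count", "n_reports_soc"), names(df))
    for (cc in num_col) df[[cc]] <- as.integer(df[[cc]])
    for (cc in setdiff(names(df), num_col)) df[[cc]] <- as.character(df[[cc]])
    strip_readr_attrs(df)
  }
  adr_counts(rd("totals"), soc = rd("soc"), pt = rd("pt"),
             soc_reports = rd("soc_reports"), demographics = rd("demographics"),
             outcomes = rd("outcomes"))
}
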