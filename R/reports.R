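#' Individual case safety reports
#'
#' Container for report-level spontaneous-reporting data: one row per report,
#' with the coded reactions and seriousness outcomes held as list-columns.
#' Reactions are sets (deduplicated, non-empty); demographics come from the
#' closed level sets in [adr_levels()], with `"unknown"` as the explicit
#' missing level. `year` is an integer or `NA` (unknown).
#'
#' @param report_id Character vector of opaque report identifiers.
#' @param drug Character vector of drug names.
#' @param reactions List of character vectors of PT names (each non-empty).
#' @param sex,age_group,region Character vectors from the closed level sets.
#' @param year Integer vector (NA = unknown).
#' @param outcomes List of character vectors, each a subset of
#'   `adr_levels()$outcomes` (possibly empty = non-serious report).
#' @return A tibble of class `adr_reports`.
#' @export
#' @examples
#' adr_reports("r1", "drugA", list(c("Nausea", "Headache")), sex = "female")
adr_reports <- function(report_id, drug, reactions,
                        sex = "unknown", age_group = "unknown",
                        region = "unknown", year = NA_integer_,
                        outcomes = list(character())) {
  n <- length(report_id)
  x <- tibble::tibble(
    report_id = as.character(report_id),
    drug = as.character(drug),
    reactions = as.list(reactions),
    sex = rep_len(as.character(sex), n),
    age_group = rep_len(as.character(age_group), n),
    region = rep_len(as.character(region), n),
    year = rep_len(as.integer(year), n),
    outcomes = rep_len(as.list(outcomes), n))
  x$reactions <- lapply(x$reactions, function(r) unique(as.character(r)))
  x$outcomes <- lapply(x$outcomes, as.character)
  validate_adr_reports(x)
}

validate_adr_reports <- function(x) {
  bad <- which(lengths(x$reactions) == 0 | vapply(x$reactions, anyNA, logical(1)))
  if (length(bad)) {
    abort(paste0("report(s) without valid reactions at row(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  check_levels <- function(col, levels, name) {
    bad <- setdiff(unique(col), levels)
    if (length(bad)) {
      abort(paste0("invalid ", name, " level(s): ", paste(bad, collapse = ", ")))
    }
  }
  check_levels(x$sex, SEX_LEVELS, "sex")
  check_levels(x$age_group, AGE_LEVELS, "age_group")
  check_levels(x$region, REGION_LEVELS, "region")
  check_levels(unlist(x$outcomes), OUTCOME_LEVELS, "outcome")
  class(x) <- unique(c("adr_reports", class(x)))
  x
}

split_cell <- function(cell, sep) {
  parts <- strsplit(ifelse(is.na(cell), "", cell), sep, fixed = TRUE)
  lapply(parts, function(p) unique(trimws(p)[trimws(p) != ""]))
}

#' Read individual case safety reports from CSV
#'
#' Expects columns `report_id, drug, reactions, sex, age_group, region, year,
#' outcomes`; `reactions` and `outcomes` cells are `sep`-delimited lists of
#' terms. Blank or missing demographic cells map to the explicit `"unknown"`
#' level; duplicated PTs within one report are deduplicated (set semantics).
#' An empty `reactions` cell is a record-level error reported with its row
#' number.
#'
#' @param path CSV file path.
#' @param sep In-cell delimiter for `reactions` / `outcomes` (default `"|"`).
#' @return An [adr_reports()] tibble (zero rows for a header-only file).
#' @export
read_reports <- function(path, sep = "|") {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("report_id", "drug", "reactions", "sex", "age_group",
                "region", "year", "outcomes")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(paste0("report file lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    return(adr_reports(character(), character(), list())[0, ])
  }
  reactions <- split_cell(df$reactions, sep)
  empty <- which(lengths(reactions) == 0)
  if (length(empty)) {
    abort(paste0("empty reactions cell at data row(s): ",
                 paste(head(empty, 5), collapse = ", ")))
  }
  to_unknown <- function(col) {
    col <- trimws(ifelse(is.na(col), "", col))
    ifelse(col == "", "unknown", col)
  }
  yr <- trimws(ifelse(is.na(df$year), "", df$year))
  yr <- suppressWarnings(as.integer(ifelse(yr %in% c("", "unknown"), NA, yr)))
  adr_reports(df$report_id, df$drug, reactions,
              sex = to_unknown(df$sex), age_group = to_unknown(df$age_group),
              region = to_unknown(df$region), year = yr,
              outcomes = split_cell(df$outcomes, sep))
}

#' Write individual case safety reports to CSV
#'
#' Inverse of [read_reports()]: `read_reports(write_reports(x, path))` is the
#' identity on valid report sets.
#'
#' @param reports An [adr_reports()] tibble.
#' @inheritParams read_reports
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, sep = "|") {
  stopifnot(inherits(reports, "adr_reports"))
  out <- tibble::tibble(
    report_id = reports$report_id,
    drug = reports$drug,
    reactions = vapply(reports$reactions, paste, character(1), collapse = sep),
    sex = reports$sex,
    age_group = reports$age_group,
    region = reports$region,
    year = ifelse(is.na(reports$year), "", as.character(reports$year)),
    outcomes = vapply(reports$outcomes, paste, character(1), collapse = sep))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
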