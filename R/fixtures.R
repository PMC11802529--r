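#' Published VigiAccess count tables for five hepatic anti-fibrotic agents
#'
#' Loads the packaged aggregate tables for empagliflozin, liraglutide,
#' candesartan, obeticholic acid and resmetirom as retrieved from the public
#' WHO-VigiAccess front-end (November 2024 snapshot): per-drug report totals,
#' the 27-SOC occurrence counts, demographic strata (sex, age band, reporting
#' year band, continent), the printed top-20 PT report rates, and the printed
#' per-drug serious-ADR percentages. Values byte-match the published tables;
#' the fixture is read-only reference data.
#'
#' The demographic year axis is incomplete in the published table (it stops
#' at the last full calendar year), so year strata sum to less than
#' `n_reports`; sex, age and region strata partition the reports exactly.
#'
#' @return A list of class `paper_fixture` with elements:
#'   \describe{
#'     \item{counts}{[adr_counts()] with `totals`, `soc` and `demographics`
#'       sections (no PT counts are published, only top-20 rates).}
#'     \item{table4_rates}{Tibble `drug, pt, rate_percent` of printed top-20
#'       PT report rates.}
#'     \item{serious_rates}{Tibble `drug, serious_percent` of printed
#'       serious-ADR proportions.}
#'   }
#' @export
#' @examples
#' fx <- load_paper_fixture()
#' sum(fx$counts$totals$n_reports)  # 130567
load_paper_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "pvsignal", mustWork = TRUE)
  rd <- function(f, ints = character()) {
    df <- readr::read_csv(ext(f), show_col_types = FALSE, progress = FALSE)
    for (cc in ints) df[[cc]] <- as.integer(df[[cc]])
    strip_readr_attrs(df)
  }
  counts <- adr_counts(
    totals = rd("vigiaccess_totals.csv", "n_reports"),
    soc = rd("vigiaccess_soc_counts.csv", "count"),
    demographics = rd("vigiaccess_demographics.csv", "count"))
  structure(list(counts = counts,
                 table4_rates = rd("vigiaccess_top20_pt_rates.csv"),
                 serious_rates = rd("vigiaccess_serious_rates.csv")),
            class = "paper_fixture")
}

#' @export
print.paper_fixture <- function(x, ...) {
  cat("<paper_fixture> VigiAccess snapshot, ",
      nrow(x$counts$totals), " drugs, ", sum(x$counts$totals$n_reports),
      " reports\n", sep = "")
  invisible(x)
}
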