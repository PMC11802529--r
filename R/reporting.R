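#' Run the full descriptive + disproportionality analysis and write outputs
#'
#' Thin workflow wrapper tying the library together: accepts an
#' [adr_counts()] object, a directory of aggregate CSVs, or a report-level
#' CSV (with a dictionary), then writes descriptive summaries, the signal
#' table and forest exports into `output_dir`. Every output is produced by
#' the corresponding exported function, so programmatic and file-based use
#' agree exactly.
#'
#' @param input An `adr_counts`, a directory path of aggregate CSVs, or a
#'   report-level CSV path.
#' @param output_dir Output directory (created if needed).
#' @param level `"soc"` or `"pt"` for the disproportionality screen.
#' @param mode `"occurrence"` or `"report"` counting unit.
#' @param metrics Subset of `c("ror", "prr")`.
#' @param top_n Top-N PT listing size (used when PT counts are available).
#' @param dictionary A [meddra_dictionary()] or its CSV path; required when
#'   `input` is a report-level CSV.
#' @return Invisibly, a list with `counts`, `signals`, `soc_rates`,
#'   `demographics` and the written `files`.
#' @export
run_analysis <- function(input, output_dir, level = c("soc", "pt"),
                         mode = c("occurrence", "report"),
                         metrics = c("ror", "prr"), top_n = 20,
                         dictionary = NULL) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  counts <- resolve_input(input, dictionary)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    p <- file.path(output_dir, name)
    readr::write_csv(tibble::as_tibble(df), p, progress = FALSE)
    files[[name]] <<- p
  }

  soc_rates <- dplyr::bind_rows(
    c(lapply(counts$totals$drug, function(g) soc_distribution(counts, g)),
      list(soc_distribution(counts))))
  put(soc_rates, "soc_distribution.csv")

  demo <- demographic_summary(counts)
  put(demo$summary, "demographics.csv")

  if (!is.null(counts$pt) && nrow(counts$pt) > 0) {
    top <- dplyr::bind_rows(lapply(counts$totals$drug, function(g)
      top_adrs(counts, g, n = top_n)))
    put(top, "top_adrs.csv")
  }

  signals <- screen_signals(counts, level = level, metrics = metrics, mode = mode)
  put(signals, "signal_table.csv")
  inform(paste0("analyzed ", sum(counts$totals$n_reports), " reports over ",
                nrow(counts$totals), " drugs; ", nrow(signals),
                " signal rows (", sum(signals$correction_applied),
                " with zero-cell correction)"))

  for (m in intersect(c("ROR", "PRR"), unique(signals$metric))) {
    fd <- forest_data(signals[signals$metric == m, ])
    p <- file.path(output_dir, paste0("forest_", tolower(m), ".tsv"))
    write_forest_tsv(fd, p)
    files[[basename(p)]] <- p
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      png_path <- file.path(output_dir, paste0("forest_", tolower(m), ".png"))
      grDevices::png(png_path, width = 1400, height = 120 + 28 * nrow(fd), res = 150)
      print(plot_forest(fd))
      grDevices::dev.off()
      files[[basename(png_path)]] <- png_path
    }
  }
  invisible(list(counts = counts, signals = signals, soc_rates = soc_rates,
                 demographics = demo, files = files))
}

resolve_input <- function(input, dictionary = NULL) {
  if (inherits(input, "adr_counts")) return(input)
  if (is.character(input) && dir.exists(input)) return(read_aggregate(input))
  if (is.character(input) && file.exists(input)) {
    if (is.null(dictionary)) {
      abort("report-level input requires a PT-to-SOC dictionary")
    }
    if (is.character(dictionary)) dictionary <- read_meddra_dictionary(dictionary)
    return(aggregate_reports(read_reports(input), dictionary))
  }
  abort("input must be an adr_counts object, an aggregate directory, or a report CSV")
}

#' Simulate a dataset and write it (with its truth table) to disk
#'
#' @param config An [srs_config()] or a YAML config path.
#' @param output_dir Output directory (created if needed); receives
#'   `reports.csv`, `truth.csv` and `dictionary.csv`.
#' @return Invisibly, a list with the `reports`, the `truth` table and
#'   written `files`.
#' @export
run_simulation <- function(config, output_dir) {
  if (is.character(config)) config <- read_srs_config(config)
  stopifnot(inherits(config, "srs_config"))
  reports <- simulate_srs(config)
  truth <- truth_table(config)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  files <- c(reports = file.path(output_dir, "reports.csv"),
             truth = file.path(output_dir, "truth.csv"),
             dictionary = file.path(output_dir, "dictionary.csv"))
  write_reports(reports, files[["reports"]])
  readr::write_csv(truth, files[["truth"]], progress = FALSE)
  write_meddra_dictionary(srs_dictionary(config), files[["dictionary"]])
  per_drug <- table(reports$drug)
  inform(paste0("simulated ", nrow(reports), " reports: ",
                paste(names(per_drug), as.integer(per_drug),
                      sep = "=", collapse = ", ")))
  invisible(list(reports = reports, truth = truth, files = files))
}

# Printed headline values of the published analysis, used only as the
# comparison column of the reproduction report.
printed_reference <- function() {
  tibble::tribble(
    ~quantity, ~printed,
    "total reports", 130567,
    "female reports", 74554,
    "male reports", 46030,
    "sex unknown reports", 9983,
    "female:male ratio", 1.62,
    "pooled GI rate (%)", 29.44,
    "pooled general disorders rate (%)", 24.12,
    "pooled nervous system rate (%)", 14.42,
    "pooled investigations rate (%)", 15.93,
    "Americas share (%)", 53.58,
    "liraglutide GI rate (%)", 47.67,
    "empagliflozin infections rate (%)", 22.85,
    "liraglutide GI ROR", 4.629,
    "liraglutide GI ROR ci_low", 4.517,
    "liraglutide GI ROR ci_high", 4.744,
    "liraglutide GI PRR", 3.566,
    "liraglutide GI PRR ci_low", 3.492,
    "liraglutide GI PRR ci_high", 3.642)
}

#' Recompute the published headline results from the packaged tables
#'
#' Runs the packaged VigiAccess snapshot through the pipeline and compares
#' each computed quantity with its printed counterpart: pooled totals and
#' demographic ratios, pooled and per-drug SOC rates, and the five-drug
#' gastrointestinal ROR/PRR screen (occurrence unit, drug totals taken as
#' the sums over the 27 SOC rows). Declared reproduction tolerance, printed
#' in the report: percentages exact after 2-decimal rounding; ROR/PRR within
#' 1% relative, since the published analysis' internal denominators are not
#' recoverable from the printed tables.
#'
#' @param output_dir Optional directory; when given, writes
#'   `reproduction.csv` and a plain-text rendering `reproduction.txt`.
#' @return Tibble `quantity, computed, printed, abs_dev, rel_dev` (invisible
#'   when `output_dir` is given).
#' @export
#' @examples
#' rep <- reproduce_paper()
#' rep[rep$quantity == "liraglutide GI ROR", ]
reproduce_paper <- function(output_dir = NULL) {
  fx <- load_paper_fixture()
  counts <- fx$counts
  gi <- "Gastrointestinal disorders"

  demo <- demographic_summary(counts)
  sx <- function(lv) demo$summary$count[demo$summary$axis == "sex" &
                                          demo$summary$level == lv]
  pooled <- soc_distribution(counts)
  pooled_rate <- function(s) pooled$rate_percent[pooled$soc == s]
  drug_rate <- function(g, s) {
    d <- soc_distribution(counts, g)
    d$rate_percent[d$soc == s]
  }
  americas <- demo$summary$rate_percent[demo$summary$axis == "region" &
                                          demo$summary$level == "Americas"]
  ct <- build_contingency(counts, "liraglutide", gi, level = "soc",
                          mode = "occurrence")
  r <- ror(ct); p <- prr(ct)

  computed <- c(
    sum(counts$totals$n_reports), sx("female"), sx("male"), sx("unknown"),
    round_half_up(demo$female_male_ratio, 2),
    pooled_rate(gi),
    pooled_rate("General disorders and administration site conditions"),
    pooled_rate("Nervous system disorders"),
    pooled_rate("Investigations"),
    americas,
    drug_rate("liraglutide", gi),
    drug_rate("empagliflozin", "Infections and infestations"),
    r$estimate, r$ci_low, r$ci_high,
    p$estimate, p$ci_low, p$ci_high)

  out <- printed_reference()
  out$computed <- computed
  out$abs_dev <- abs(out$computed - out$printed)
  out$rel_dev <- out$abs_dev / abs(out$printed)
  out <- out[, c("quantity", "computed", "printed", "abs_dev", "rel_dev")]

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    readr::write_csv(out, file.path(output_dir, "reproduction.csv"),
                     progress = FALSE)
    txt <- c("Reproduction of the published headline results from the packaged tables",
             "Tolerance: percentages exact after 2-dp rounding; ROR/PRR within 1% relative",
             "",
             sprintf("%-38s %12s %12s %10s", "quantity", "computed", "printed", "rel_dev"),
             sprintf("%-38s %12.4f %12.4f %9.3f%%", out$quantity, out$computed,
                     out$printed, 100 * out$rel_dev))
    writeLines(txt, file.path(output_dir, "reproduction.txt"))
    return(invisible(out))
  }
  out
}
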