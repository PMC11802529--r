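#' Plot-ready forest rows from signal estimates
#'
#' Arranges a single-metric set of signal estimates for a forest plot:
#' one labelled row per estimate, sorted by point estimate descending, with
#' the no-association reference line at 1 encoded in the export.
#'
#' @param signals A `signal_estimate` tibble; all rows must share one metric.
#' @return Tibble `label, metric, estimate, ci_low, ci_high, n_cases,
#'   significant, reference`.
#' @export
#' @examples
#' fx <- load_paper_fixture()
#' sig <- screen_signals(fx$counts, level = "soc", metrics = "ror")
#' forest_data(sig[sig$term == "Gastrointestinal disorders", ])
forest_data <- function(signals) {
  signals <- tibble::as_tibble(signals)
  if (nrow(signals) == 0) {
    return(tibble::tibble(label = character(), metric = character(),
                          estimate = numeric(), ci_low = numeric(),
                          ci_high = numeric(), n_cases = integer(),
                          significant = logical(), reference = numeric()))
  }
  if (length(unique(signals$metric)) > 1) {
    abort("forest rows must share a single metric (got a mix of ROR/PRR)")
  }
  out <- tibble::tibble(
    label = ifelse(is.na(signals$drug), as.character(seq_len(nrow(signals))),
                   paste(signals$drug, signals$term, sep = " | ")),
    metric = signals$metric,
    estimate = signals$estimate,
    ci_low = signals$ci_low,
    ci_high = signals$ci_high,
    n_cases = signals$n_cases,
    significant = signals$significant,
    reference = 1)
  dplyr::arrange(out, dplyr::desc(.data$estimate))
}

#' Write / read forest rows as TSV
#'
#' The pair round-trips exactly.
#'
#' @param fd A [forest_data()] tibble.
#' @param path Output TSV path.
#' @return `write_forest_tsv()` returns `path` invisibly; `read_forest_tsv()`
#'   the tibble.
#' @export
write_forest_tsv <- function(fd, path) {
  readr::write_tsv(fd, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_forest_tsv
#' @export
read_forest_tsv <- function(path) {
  strip_readr_attrs(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    label = readr::col_character(),
                    metric = readr::col_character(),
                    estimate = readr::col_double(),
                    ci_low = readr::col_double(),
                    ci_high = readr::col_double(),
                    n_cases = readr::col_integer(),
                    significant = readr::col_logical(),
                    reference = readr::col_double())))
}

#' Render a forest plot (requires ggplot2)
#'
#' Point estimates with 95% CI whiskers on a log axis, dashed reference line
#' at 1, significant signals filled.
#'
#' @param fd A [forest_data()] tibble.
#' @return A ggplot object.
#' @export
plot_forest <- function(fd) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_forest() requires the ggplot2 package")
  }
  fd$label <- factor(fd$label, levels = rev(fd$label))
  ggplot2::ggplot(fd, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 22, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white"),
                               guide = "none") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0(unique(fd$metric), " (95% CI, log scale)"), y = NULL) +
    ggplot2::theme_minimal()
}
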