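#' 2x2 contingency table for one (drug, term) pair
#'
#' Cells follow the standard pharmacovigilance layout: `a` target drug with
#' the target ADR, `b` target drug with other ADRs, `c` other drugs with the
#' target ADR, `d` other drugs with other ADRs.
#'
#' @param a,b,c,d Non-negative cell counts.
#' @param drug,term,level,mode Optional provenance labels.
#' @return An object of class `contingency_table`.
#' @export
#' @examples
#' contingency_table(3, 97, 30, 970)
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              term = NA_character_, level = NA_character_,
                              mode = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0)) abort("cells must be non-negative counts")
  structure(list(a = a, b = b, c = c, d = d, drug = drug, term = term,
                 level = level, mode = mode),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>", if (!is.na(x$drug)) paste0(x$drug, " x ", x$term), "\n")
  print(matrix(c(x$a, x$c, x$b, x$d), 2, 2,
               dimnames = list(c("target drug", "other drugs"),
                               c("target ADR", "other ADRs"))))
  invisible(x)
}

#' Build the 2x2 table for a (drug, term) pair against all other drugs
#'
#' In `occurrence` mode the counting unit is ADR occurrences: `a` is the
#' (drug, term) occurrence count and `a + b` is the drug's total occurrences
#' at the requested level, with `c`, `d` analogous over the remaining drugs
#' pooled. In `report` mode the unit is reports: `a + b` equals the drug's
#' report total; at SOC level this requires the distinct-report
#' `soc_reports` section (available when the table was aggregated from
#' report-level data).
#'
#' @param counts An [adr_counts()] with at least two drugs.
#' @param drug Target drug.
#' @param term SOC or PT name, per `level`.
#' @param level `"soc"` or `"pt"`.
#' @param mode `"occurrence"` (default) or `"report"`.
#' @return A [contingency_table()].
#' @export
#' @examples
#' fx <- load_paper_fixture()
#' build_contingency(fx$counts, "liraglutide", "Gastrointestinal disorders")
build_contingency <- function(counts, drug, term, level = c("soc", "pt"),
                              mode = c("occurrence", "report")) {
  stopifnot(inherits(counts, "adr_counts"))
  level <- match.arg(level)
  mode <- match.arg(mode)
  if (nrow(counts$totals) < 2) {
    abort("comparator undefined: the table must contain at least two drugs")
  }
  if (!drug %in% counts$totals$drug) abort(paste0("unknown drug: ", drug))

  if (mode == "occurrence") {
    section <- counts[[level]]
    if (is.null(section) || nrow(section) == 0) {
      abort(paste0("no ", toupper(level), " section in table"))
    }
    term_col <- section[[level]]
    if (!term %in% term_col) abort(paste0("unknown ", level, " term: ", term))
    target <- section$drug == drug
    hit <- term_col == term
    a <- sum(section$count[target & hit])
    b <- sum(section$count[target]) - a
    c_ <- sum(section$count[!target & hit])
    d <- sum(section$count[!target]) - c_
  } else {
    if (level == "pt") {
      section <- counts$pt
      if (is.null(section) || nrow(section) == 0) abort("no PT section in table")
      if (!term %in% section$pt) abort(paste0("unknown pt term: ", term))
      hit <- section$pt == term & section$drug == drug
      a <- sum(section$count[hit])
      c_ <- sum(section$count[section$pt == term & section$drug != drug])
    } else {
      section <- counts$soc_reports
      if (is.null(section) || nrow(section) == 0) {
        abort("report-level data required: no soc_reports section in table")
      }
      if (!term %in% section$soc) abort(paste0("unknown soc term: ", term))
      a <- sum(section$n_reports_soc[section$soc == term & section$drug == drug])
      c_ <- sum(section$n_reports_soc[section$soc == term & section$drug != drug])
    }
    n_target <- counts$totals$n_reports[counts$totals$drug == drug]
    n_other <- sum(counts$totals$n_reports[counts$totals$drug != drug])
    b <- n_target - a
    d <- n_other - c_
  }
  contingency_table(a, b, c_, d, drug = drug, term = term, level = level,
                    mode = mode)
}

# Shared Wald machinery for both disproportionality metrics. With any zero
# cell the Haldane-Anscombe +0.5 correction is applied to all four cells and
# flagged; evaluability always refers to the uncorrected case count a.
wald_signal <- function(ct, metric) {
  # doubles: cell products overflow 32-bit integers on large datasets
  a <- as.numeric(ct$a); b <- as.numeric(ct$b)
  c <- as.numeric(ct$c); d <- as.numeric(ct$d)
  correction <- any(c(a, b, c, d) == 0)
  if (correction) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  if (metric == "ror") {
    est <- (a * d) / (b * c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  } else {
    est <- (a / (a + b)) / (c / (c + d))
    se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  }
  ci_low <- exp(log(est) - 1.96 * se)
  ci_high <- exp(log(est) + 1.96 * se)
  evaluable <- ct$a >= 3
  significant <- if (metric == "ror") {
    evaluable && est > 2 && ci_low > 1
  } else {
    evaluable && est > 2
  }
  tibble::tibble(drug = ct$drug, term = ct$term, level = ct$level, mode = ct$mode,
                 metric = toupper(metric), a = ct$a, b = ct$b, c = ct$c, d = ct$d,
                 estimate = est, ci_low = ci_low, ci_high = ci_high,
                 n_cases = ct$a, evaluable = evaluable, significant = significant,
                 correction_applied = correction)
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = (a d)/(b c)` with the log-scale Wald interval
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. The signal is flagged
#' significant when ROR > 2, the CI lower bound exceeds 1 and the pair has at
#' least three cases (`a >= 3`). A table with any zero cell gets the
#' Haldane-Anscombe +0.5 correction on all four cells, flagged in
#' `correction_applied`; evaluability still refers to the uncorrected `a`.
#'
#' @param ct A [contingency_table()].
#' @return A one-row tibble of class `signal_estimate` with columns `drug,
#'   term, level, mode, metric, a, b, c, d, estimate, ci_low, ci_high,
#'   n_cases, evaluable, significant, correction_applied`.
#' @export
#' @examples
#' ror(contingency_table(10, 10, 10, 10))$estimate  # 1
ror <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  out <- wald_signal(ct, "ror")
  class(out) <- c("signal_estimate", class(out))
  out
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `PRR = (a/(a+b)) / (c/(c+d))` with the log-scale Wald interval
#' `exp(ln PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`; flagged
#' significant when PRR > 2 with at least three cases. Zero-cell handling as
#' in [ror()].
#'
#' @inheritParams ror
#' @return A one-row `signal_estimate` tibble (see [ror()]).
#' @export
prr <- function(ct) {
  stopifnot(inherits(ct, "contingency_table"))
  out <- wald_signal(ct, "prr")
  class(out) <- c("signal_estimate", class(out))
  out
}

#' Screen every (drug, term) pair for disproportionate reporting
#'
#' Builds the 2x2 table and requested metrics for every pair with at least
#' one case (`a >= 1`); pairs with fewer than three cases are returned with
#' `evaluable = FALSE` and are never flagged. Output is ordered by drug
#' (table order) then term.
#'
#' @param counts An [adr_counts()] with at least two drugs.
#' @param level `"soc"` or `"pt"`.
#' @param metrics Subset of `c("ror", "prr")`.
#' @param mode `"occurrence"` or `"report"`.
#' @return A `signal_estimate` tibble, one row per pair per metric.
#' @export
#' @examples
#' fx <- load_paper_fixture()
#' sig <- screen_signals(fx$counts, level = "soc", metrics = "ror")
#' sig[sig$significant, c("drug", "term", "estimate")]
screen_signals <- function(counts, level = c("soc", "pt"),
                           metrics = c("ror", "prr"),
                           mode = c("occurrence", "report")) {
  stopifnot(inherits(counts, "adr_counts"))
  level <- match.arg(level)
  mode <- match.arg(mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  section <- if (mode == "report" && level == "soc") counts$soc_reports else counts[[level]]
  if (is.null(section) || nrow(section) == 0) {
    abort(paste0("no ", level, " data available for mode '", mode, "'"))
  }
  term_col <- if ("soc" %in% names(section)) "soc" else "pt"
  cnt_col <- if ("n_reports_soc" %in% names(section)) "n_reports_soc" else "count"
  pairs <- section[section[[cnt_col]] >= 1, c("drug", term_col)]
  names(pairs) <- c("drug", "term")
  pairs <- dplyr::arrange(pairs,
                          match(.data$drug, counts$totals$drug), .data$term)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    ct <- build_contingency(counts, pairs$drug[i], pairs$term[i],
                            level = level, mode = mode)
    dplyr::bind_rows(lapply(metrics, function(m) wald_signal(ct, m)))
  }))
  class(out) <- c("signal_estimate", class(out))
  out
}

#' Export a signal table to CSV
#'
#' @param signals A `signal_estimate` tibble (from [screen_signals()] or
#'   bound [ror()]/[prr()] rows).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(signals, path) {
  readr::write_csv(tibble::as_tibble(signals), path, progress = FALSE)
  invisible(path)
}
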