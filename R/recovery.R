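#' Parameter-recovery study for the disproportionality estimators
#'
#' Repeatedly generates datasets from a configuration, runs them through the
#' full pipeline (aggregation, report-unit 2x2 construction at PT level,
#' ROR and PRR with Wald CIs) and compares the estimates with the
#' configuration's asymptotic truth: mean estimate, relative bias of the
#' mean, and the fraction of replicates whose 95% CI covers the true value.
#' Replicate r uses seed `config$seed + r - 1`.
#'
#' @param config An [srs_config()].
#' @param replicates Number of replicate datasets (>= 1).
#' @param pairs Tibble `drug, pt` of pairs to track; defaults to the
#'   configured signal pairs, or to every (drug, PT) pair for a null
#'   configuration.
#' @return Tibble `drug, pt, metric, true_or, mean_estimate, rel_bias,
#'   coverage, replicates`. With a single replicate, coverage is 0 or 1.
#' @export
#' @examples
#' cfg <- srs_config(
#'   drugs = c(A = 1, B = 1),
#'   vocabulary = data.frame(pt = c("Nausea", "Fatigue"),
#'                           soc = c("Gastrointestinal disorders",
#'                                   "General disorders"),
#'                           baseline_prob = c(0.1, 0.6)),
#'   signals = data.frame(drug = "A", pt = "Nausea", multiplier = 4),
#'   n_reports = 2000, seed = 7)
#' recovery_study(cfg, replicates = 3)
recovery_study <- function(config, replicates, pairs = NULL) {
  stopifnot(inherits(config, "srs_config"), replicates >= 1)
  if (is.null(pairs)) {
    pairs <- if (nrow(config$signals) > 0) {
      config$signals[, c("drug", "pt")]
    } else {
      truth_table(config)[, c("drug", "pt")]
    }
  }
  pairs <- tibble::as_tibble(pairs)
  dict <- srs_dictionary(config)
  truth <- vapply(seq_len(nrow(pairs)),
                  function(i) true_ror(config, pairs$drug[i], pairs$pt[i]),
                  numeric(1))

  one_rep <- function(r) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    counts <- aggregate_reports(simulate_srs(cfg), dict)
    dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
      est <- tryCatch({
        ct <- build_contingency(counts, pairs$drug[i], pairs$pt[i],
                                level = "pt", mode = "report")
        dplyr::bind_rows(ror(ct), prr(ct))
      }, error = function(e) NULL)
      if (is.null(est)) return(NULL)
      tibble::tibble(pair = i, metric = est$metric, estimate = est$estimate,
                     covered = est$ci_low <= truth[i] & truth[i] <= est$ci_high)
    }))
  }
  reps <- dplyr::bind_rows(lapply(seq_len(replicates), one_rep))
  out <- dplyr::summarise(
    dplyr::group_by(reps, .data$pair, .data$metric),
    mean_estimate = mean(.data$estimate),
    coverage = mean(.data$covered),
    replicates = dplyr::n(), .groups = "drop")
  out$drug <- pairs$drug[out$pair]
  out$pt <- pairs$pt[out$pair]
  out$true_or <- truth[out$pair]
  out$rel_bias <- out$mean_estimate / out$true_or - 1
  out[, c("drug", "pt", "metric", "true_or", "mean_estimate", "rel_bias",
          "coverage", "replicates")]
}
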