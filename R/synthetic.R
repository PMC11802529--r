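# Pooled demographic shares of the packaged VigiAccess snapshot; used as the
# generator's default categorical distributions so synthetic cohorts resemble
# the study population. Year mass before 2019 is spread over 2014-2018 and
# the residual (unknown / partial current year) assigned to 2024.
default_demographics <- function() {
  norm <- function(x) x / sum(x)
  list(
    sex = norm(c(female = 74554, male = 46030, unknown = 9983)),
    age_group = norm(c(`<18` = 654, `18-44` = 12856, `45-64` = 36897,
                       `65-74` = 20558, `>75` = 12399, unknown = 47203)),
    region = norm(c(Africa = 1167, Americas = 69964, Asia = 16448,
                    Europe = 40539, Oceania = 2449)),
    year = norm(c(`2014` = 10520, `2015` = 10520, `2016` = 10520,
                  `2017` = 10519, `2018` = 10519, `2019` = 13157,
                  `2020` = 9594, `2021` = 10091, `2022` = 12677,
                  `2023` = 17406, `2024` = 15044)))
}

# Per-category seriousness probabilities; the implied pooled any-serious rate
# (~2%) matches the magnitude of the published per-drug serious proportions.
default_seriousness <- function() {
  c(death = 0.004, life_threatening = 0.003, hospitalization = 0.012,
    disability = 0.002, congenital_anomaly = 0.0005)
}

#' Configuration of the synthetic spontaneous-reporting generator
#'
#' Defines a complete data-generating process for individual case safety
#' reports: a categorical drug assignment, per-PT Bernoulli reaction
#' inclusion whose odds are multiplied by injectable per-(drug, PT) signal
#' strengths, categorical demographics, and independent per-category
#' Bernoulli seriousness outcomes. Reports drawing zero reactions are
#' redrawn (spontaneous reports always carry at least one reaction).
#'
#' @param drugs Named numeric vector of positive marginal drug weights, or a
#'   data frame with columns `name, weight`.
#' @param vocabulary Data frame `pt, soc, baseline_prob` with baseline
#'   inclusion probabilities in the open interval (0, 1).
#' @param signals Data frame `drug, pt, multiplier` of odds multipliers
#'   (> 0); omitted pairs default to multiplier 1 (no signal). NULL = null
#'   configuration.
#' @param demographics Named list of named probability vectors for `sex`,
#'   `age_group`, `region` and `year`; defaults to the pooled shares of the
#'   packaged VigiAccess snapshot.
#' @param seriousness Named probability vector over the five regulatory
#'   outcome categories.
#' @param n_reports Number of reports to generate (>= 1).
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @return An object of class `srs_config`.
#' @export
#' @examples
#' cfg <- srs_config(
#'   drugs = c(drugA = 1, drugB = 1),
#'   vocabulary = data.frame(pt = c("Nausea", "Fatigue"),
#'                           soc = c("Gastrointestinal disorders",
#'                                   "General disorders"),
#'                           baseline_prob = c(0.2, 0.6)),
#'   signals = data.frame(drug = "drugA", pt = "Nausea", multiplier = 4),
#'   n_reports = 100, seed = 1)
srs_config <- function(drugs, vocabulary, signals = NULL, demographics = NULL,
                       seriousness = NULL, n_reports, seed) {
  if (is.data.frame(drugs)) drugs <- setNames(drugs$weight, drugs$name)
  if (is.null(names(drugs)) || any(names(drugs) == "")) abort("drugs must be named")
  if (any(!is.finite(drugs)) || any(drugs <= 0)) {
    abort("drug weights must be positive and finite")
  }
  vocabulary <- tibble::as_tibble(vocabulary)
  if (!all(c("pt", "soc", "baseline_prob") %in% names(vocabulary))) {
    abort("vocabulary needs columns pt, soc, baseline_prob")
  }
  if (anyDuplicated(vocabulary$pt)) abort("duplicate PT in vocabulary")
  p <- vocabulary$baseline_prob
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("baseline probabilities must lie in the open interval (0, 1)")
  }
  if (is.null(signals)) {
    signals <- tibble::tibble(drug = character(), pt = character(),
                              multiplier = numeric())
  }
  signals <- tibble::as_tibble(signals)
  if (nrow(signals) > 0) {
    bad_drug <- setdiff(signals$drug, names(drugs))
    bad_pt <- setdiff(signals$pt, vocabulary$pt)
    if (length(bad_drug) || length(bad_pt)) {
      abort(paste0("signal keys reference undefined drug/PT: ",
                   paste(c(bad_drug, bad_pt), collapse = ", ")))
    }
    if (any(signals$multiplier <= 0)) abort("signal multipliers must be > 0")
  }
  demographics <- demographics %||% default_demographics()
  for (ax in c("sex", "age_group", "region")) {
    lv <- names(demographics[[ax]])
    bad <- setdiff(lv, adr_levels()[[ax]])
    if (length(bad)) abort(paste0("invalid ", ax, " level(s): ",
                                  paste(bad, collapse = ", ")))
  }
  seriousness <- seriousness %||% default_seriousness()
  if (!all(names(seriousness) %in% OUTCOME_LEVELS) ||
      any(seriousness < 0) || any(seriousness > 1)) {
    abort("seriousness must be probabilities named by outcome category")
  }
  if (length(n_reports) != 1 || n_reports < 1) abort("n_reports must be >= 1")
  structure(list(drugs = drugs, vocabulary = vocabulary, signals = signals,
                 demographics = demographics, seriousness = seriousness,
                 n_reports = as.integer(n_reports), seed = as.integer(seed)),
            class = "srs_config")
}

#' A ready-made study-shaped configuration
#'
#' Five drugs weighted like the packaged snapshot's report totals, a
#' 15-term toy vocabulary over 8 SOCs with baseline frequencies typical of
#' common spontaneous-report reactions, default demographics and
#' seriousness, and no injected signals (null configuration).
#'
#' @inheritParams srs_config
#' @param signals Optional signal data frame, as in [srs_config()].
#' @return An `srs_config`.
#' @export
default_srs_config <- function(n_reports = 10000, seed = 1, signals = NULL) {
  gi <- "Gastrointestinal disorders"
  vocab <- tibble::tribble(
    ~pt, ~soc, ~baseline_prob,
    "Nausea", gi, 0.12,
    "Vomiting", gi, 0.06,
    "Diarrhoea", gi, 0.06,
    "Abdominal pain", gi, 0.03,
    "Headache", "Nervous system disorders", 0.06,
    "Dizziness", "Nervous system disorders", 0.05,
    "Fatigue", "General disorders and administration site conditions", 0.10,
    "Malaise", "General disorders and administration site conditions", 0.04,
    "Pruritus", "Skin and subcutaneous tissue disorders", 0.05,
    "Rash", "Skin and subcutaneous tissue disorders", 0.04,
    "Urinary tract infection", "Infections and infestations", 0.03,
    "Blood glucose increased", "Investigations", 0.04,
    "Weight decreased", "Investigations", 0.03,
    "Arthralgia", "Musculoskeletal and connective tissue disorders", 0.03,
    "Insomnia", "Psychiatric disorders", 0.02)
  srs_config(
    drugs = c(empagliflozin = 43095, liraglutide = 59268, candesartan = 22033,
              `obeticholic acid` = 6047, resmetirom = 124),
    vocabulary = vocab, signals = signals,
    n_reports = n_reports, seed = seed)
}

#' The PT-to-SOC dictionary implied by a generator configuration
#' @param config An `srs_config`.
#' @return A [meddra_dictionary()].
#' @export
srs_dictionary <- function(config) {
  stopifnot(inherits(config, "srs_config"))
  meddra_dictionary(config$vocabulary$pt, config$vocabulary$soc)
}

# per-drug x per-PT inclusion probability matrix implied by the config
inclusion_matrix <- function(config) {
  drugs <- names(config$drugs)
  vocab <- config$vocabulary
  P <- matrix(rep(vocab$baseline_prob, each = length(drugs)),
              nrow = length(drugs), ncol = nrow(vocab),
              dimnames = list(drugs, vocab$pt))
  if (nrow(config$signals) > 0) {
    for (i in seq_len(nrow(config$signals))) {
      g <- config$signals$drug[i]; t <- config$signals$pt[i]
      P[g, t] <- plogis(qlogis(P[g, t]) + log(config$signals$multiplier[i]))
    }
  }
  P
}

#' Generate synthetic individual case safety reports
#'
#' Draws `n_reports` reports from the configured process. The random stream
#' is consumed in a fixed, documented order — drug assignment, the reaction
#' inclusion matrix in vocabulary order, zero-reaction redraws, forced picks,
#' then sex, age group, region, year, and the five outcome categories — so
#' the same configuration always yields the identical dataset. Reports that
#' draw zero reactions are redrawn (up to 100 rounds); any still empty get
#' one PT forced by sampling proportional to their inclusion probabilities,
#' with the count recorded in the `forced_reports` attribute.
#'
#' @param config An [srs_config()].
#' @return An [adr_reports()] tibble of `config$n_reports` rows.
#' @export
#' @examples
#' cfg <- default_srs_config(n_reports = 50, seed = 42)
#' simulate_srs(cfg)
simulate_srs <- function(config) {
  stopifnot(inherits(config, "srs_config"))
  set.seed(config$seed)
  n <- config$n_reports
  drugs <- names(config$drugs)
  vocab <- config$vocabulary
  V <- nrow(vocab)

  drug_idx <- sample.int(length(drugs), n, replace = TRUE,
                         prob = config$drugs / sum(config$drugs))
  P <- inclusion_matrix(config)
  probs <- P[drug_idx, , drop = FALSE]
  X <- matrix(rbinom(n * V, 1L, probs), nrow = n, ncol = V)

  empty <- which(rowSums(X) == 0)
  tries <- 0L
  while (length(empty) > 0 && tries < 100L) {
    sub <- probs[empty, , drop = FALSE]
    X[empty, ] <- rbinom(length(sub), 1L, sub)
    empty <- empty[rowSums(X[empty, , drop = FALSE]) == 0]
    tries <- tries + 1L
  }
  forced <- length(empty)
  if (forced > 0) {
    if (max(rowSums(probs[empty, , drop = FALSE])) == 0) {
      abort("generation failed: zero inclusion probability everywhere")
    }
    for (i in empty) {
      X[i, sample.int(V, 1, prob = probs[i, ])] <- 1L
    }
  }
  w <- which(X == 1L, arr.ind = TRUE)
  reactions <- unname(split(vocab$pt[w[, "col"]],
                            factor(w[, "row"], levels = seq_len(n))))

  dm <- config$demographics
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  sex <- draw(dm$sex)
  age <- draw(dm$age_group)
  region <- draw(dm$region)
  year <- as.integer(draw(dm$year))

  ser <- config$seriousness
  O <- vapply(names(ser), function(o) rbinom(n, 1L, ser[[o]]), integer(n))
  if (n == 1) O <- matrix(O, nrow = 1, dimnames = list(NULL, names(ser)))
  outcomes <- apply(O, 1, function(row) names(ser)[row == 1L], simplify = FALSE)

  out <- adr_reports(sprintf("R%07d", seq_len(n)), drugs[drug_idx], reactions,
                     sex = sex, age_group = age, region = region, year = year,
                     outcomes = outcomes)
  attr(out, "forced_reports") <- forced
  out
}

#' Asymptotic report-level odds ratio implied by a configuration
#'
#' Closed form for the true reporting odds ratio of `pt` for `drug` against
#' the weight-pooled mixture of the comparator drugs: the drug's inclusion
#' odds divided by the odds of the comparators' weighted mean inclusion
#' probability. Equals the injected multiplier whenever all comparators
#' carry multiplier 1 (they then share the baseline). The zero-reaction
#' redraw slightly perturbs finite-sample marginals but not this asymptotic
#' target's role as the recovery benchmark (see the methods vignette).
#'
#' @param config An [srs_config()].
#' @param drug,pt The pair of interest (must be defined in the config).
#' @return The asymptotic odds ratio (a positive scalar).
#' @export
true_ror <- function(config, drug, pt) {
  stopifnot(inherits(config, "srs_config"))
  if (!drug %in% names(config$drugs)) abort(paste0("unknown drug: ", drug))
  if (!pt %in% config$vocabulary$pt) abort(paste0("unknown pt: ", pt))
  P <- inclusion_matrix(config)
  p_target <- P[drug, pt]
  others <- setdiff(names(config$drugs), drug)
  w <- config$drugs[others] / sum(config$drugs[others])
  p_mix <- sum(w * P[others, pt])
  (p_target / (1 - p_target)) / (p_mix / (1 - p_mix))
}

#' Truth table of asymptotic odds ratios for every (drug, PT) pair
#' @param config An [srs_config()].
#' @return Tibble `drug, pt, true_or`.
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "srs_config"))
  grid <- expand.grid(drug = names(config$drugs), pt = config$vocabulary$pt,
                      stringsAsFactors = FALSE)
  grid$true_or <- vapply(seq_len(nrow(grid)),
                         function(i) true_ror(config, grid$drug[i], grid$pt[i]),
                         numeric(1))
  tibble::as_tibble(grid[order(match(grid$drug, names(config$drugs)), grid$pt), ])
}

#' Read a generator configuration from YAML
#'
#' Expected top-level keys: `drugs` (name: weight mapping), `vocabulary`
#' (list of `{pt, soc, baseline_prob}`), optional `signals` (list of
#' `{drug, pt, multiplier}`), optional `demographics` and `seriousness`
#' mappings, `n_reports`, `seed`.
#'
#' @param path YAML file path.
#' @return An [srs_config()].
#' @export
read_srs_config <- function(path) {
  y <- yaml::read_yaml(path)
  required <- c("drugs", "vocabulary", "n_reports", "seed")
  missing <- setdiff(required, names(y))
  if (length(missing)) {
    abort(paste0("generator config lacks required key(s): ",
                 paste(missing, collapse = ", ")))
  }
  to_tbl <- function(lst) dplyr::bind_rows(lapply(lst, tibble::as_tibble))
  dem <- if (!is.null(y$demographics)) lapply(y$demographics, unlist) else NULL
  srs_config(drugs = unlist(y$drugs), vocabulary = to_tbl(y$vocabulary),
             signals = if (!is.null(y$signals)) to_tbl(y$signals) else NULL,
             demographics = dem,
             seriousness = if (!is.null(y$seriousness)) unlist(y$seriousness) else NULL,
             n_reports = y$n_reports, seed = y$seed)
}
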