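gi <- "Gastrointestinal disorders"

test_that("configuration validation rejects incoherent inputs", {
  vocab <- data.frame(pt = "Nausea", soc = gi, baseline_prob = 0.1)
  expect_error(srs_config(c(A = -1), vocab, n_reports = 10, seed = 1),
               "positive")
  expect_error(srs_config(c(A = 1),
                          data.frame(pt = "Nausea", soc = gi, baseline_prob = 1),
                          n_reports = 10, seed = 1),
               "open interval")
  expect_error(srs_config(c(A = 1), vocab,
                          signals = data.frame(drug = "B", pt = "Nausea",
                                               multiplier = 2),
                          n_reports = 10, seed = 1),
               "undefined drug/PT")
})

test_that("generation is deterministic given the configuration", {
  cfg <- default_srs_config(n_reports = 300, seed = 77)
  expect_identical(simulate_srs(cfg), simulate_srs(cfg))
  cfg2 <- default_srs_config(n_reports = 300, seed = 78)
  expect_false(identical(simulate_srs(cfg), simulate_srs(cfg2)))
})

test_that("near-certain baselines include their PT in every report", {
  cfg <- srs_config(c(drugA = 1),
                    data.frame(pt = "Nausea", soc = gi, baseline_prob = 0.999),
                    n_reports = 5, seed = 4)
  rep <- simulate_srs(cfg)
  expect_equal(nrow(rep), 5)
  expect_true(all(vapply(rep$reactions, function(r) "Nausea" %in% r, logical(1))))
})

test_that("every report carries at least one reaction even at tiny baselines", {
  cfg <- srs_config(c(drugA = 1),
                    data.frame(pt = c("Nausea", "Fatigue"), soc = c(gi, gi),
                               baseline_prob = c(0.001, 0.001)),
                    n_reports = 200, seed = 12)
  rep <- simulate_srs(cfg)
  expect_true(all(lengths(rep$reactions) >= 1))
  expect_gte(attr(rep, "forced_reports"), 0)
})

test_that("the truth table collapses to the injected multipliers", {
  null_cfg <- default_srs_config(n_reports = 10, seed = 1)
  tt <- truth_table(null_cfg)
  expect_equal(tt$true_or, rep(1, nrow(tt)))

  cfg <- signal_config(multiplier = 4)
  expect_equal(true_ror(cfg, "drugA", "Nausea"), 4)
  expect_equal(true_ror(cfg, "drugA", "Fatigue"), 1)
  expect_error(true_ror(cfg, "drugC", "Nausea"), "unknown drug")
  expect_error(true_ror(cfg, "drugA", "Vertigo"), "unknown pt")
})

test_that("mixed-multiplier comparator closed form matches a large simulation", {
  # target A at baseline odds; comparators B (m = 1) and C (m = 2) pooled
  cfg <- srs_config(
    drugs = c(A = 1, B = 1, C = 1),
    vocabulary = data.frame(
      pt = c("Nausea", "Fatigue", "Headache"),
      soc = c(gi, "General disorders and administration site conditions",
              "Nervous system disorders"),
      baseline_prob = c(0.05, 0.9, 0.6)),
    signals = data.frame(drug = "C", pt = "Nausea", multiplier = 2),
    n_reports = 400000, seed = 2024)
  p_b <- 0.05
  p_c <- plogis(qlogis(0.05) + log(2))
  p_mix <- (p_b + p_c) / 2
  closed <- (0.05 / 0.95) / (p_mix / (1 - p_mix))
  expect_equal(true_ror(cfg, "A", "Nausea"), closed)

  counts <- aggregate_reports(simulate_srs(cfg), srs_dictionary(cfg))
  ct <- build_contingency(counts, "A", "Nausea", level = "pt", mode = "report")
  est <- ror(ct)$estimate
  # +/- 3 Monte-Carlo SEs on the log odds ratio plus the small (<2%)
  # conditioning bias of the zero-reaction redraw
  expect_lt(abs(log(est) - log(closed)), 0.08)
})

test_that("marginal calibration tightens as baselines grow", {
  freq_dev <- function(p) {
    cfg <- srs_config(c(A = 1),
                      data.frame(pt = c("t1", "t2", "t3"), soc = gi,
                                 baseline_prob = rep(p, 3)),
                      n_reports = 20000, seed = 55)
    rep <- simulate_srs(cfg)
    f <- mean(vapply(rep$reactions, function(r) "t1" %in% r, logical(1)))
    abs(f - p) / p
  }
  dev_low <- freq_dev(0.05)   # frequent zero-reaction redraws inflate marginals
  dev_high <- freq_dev(0.5)
  expect_lt(dev_high, dev_low)
  # conditioning on >=1 reaction inflates the marginal by at most
  # 1/(1 - z) where z = (1 - p)^3 is the zero-reaction probability
  z <- (1 - 0.5)^3
  expect_lt(dev_high, (1 / (1 - z) - 1) + 0.03)
})

test_that("occurrence and report units share the a-cell for deduplicated reactions", {
  cfg <- signal_config(multiplier = 3, n_reports = 3000, seed = 9)
  counts <- aggregate_reports(simulate_srs(cfg), srs_dictionary(cfg))
  occ <- build_contingency(counts, "drugA", "Nausea", level = "pt",
                           mode = "occurrence")
  rep <- build_contingency(counts, "drugA", "Nausea", level = "pt",
                           mode = "report")
  expect_equal(occ$a, rep$a)
  expect_equal(rep$a + rep$b,
               counts$totals$n_reports[counts$totals$drug == "drugA"])
})

test_that("recovery study recovers an injected signal with small bias", {
  cfg <- signal_config(multiplier = 4, n_reports = 10000, seed = 400)
  res <- recovery_study(cfg, replicates = 100)
  r <- res[res$metric == "ROR", ]
  expect_equal(r$true_or, 4)
  expect_lt(abs(r$rel_bias), 0.05)
  expect_equal(r$replicates, 100L)
})

test_that("a single-replicate study degenerates to 0/1 coverage", {
  cfg <- signal_config(multiplier = 1, n_reports = 2000, seed = 33)
  res <- recovery_study(cfg, replicates = 1,
                        pairs = data.frame(drug = "drugA", pt = "Nausea"))
  expect_true(all(res$coverage %in% c(0, 1)))
})

test_that("YAML configs round into srs_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "drugs: {A: 1.0, B: 3.0}",
    "vocabulary:",
    "  - {pt: Nausea, soc: Gastrointestinal disorders, baseline_prob: 0.1}",
    "  - {pt: Fatigue, soc: General disorders and administration site conditions, baseline_prob: 0.6}",
    "signals:",
    "  - {drug: A, pt: Nausea, multiplier: 4}",
    "n_reports: 50",
    "seed: 3"), path)
  cfg <- read_srs_config(path)
  expect_s3_class(cfg, "srs_config")
  expect_equal(true_ror(cfg, "A", "Nausea"), 4)
  expect_equal(nrow(simulate_srs(cfg)), 50)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("drugs: {A: 1.0}", bad)
  expect_error(read_srs_config(bad), "vocabulary")
})
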