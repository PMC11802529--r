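# Shared builders for toy dictionaries, reports and generator configs.

toy_dict <- function() {
  meddra_dictionary(
    c("Nausea", "Vomiting", "Headache", "Fatigue", "Rash"),
    c("Gastrointestinal disorders", "Gastrointestinal disorders",
      "Nervous system disorders",
      "General disorders and administration site conditions",
      "Skin and subcutaneous tissue disorders"))
}

# two-drug, two-PT config with one injectable signal; the high-baseline
# filler keeps zero-reaction redraws (and their conditioning bias) rare
signal_config <- function(multiplier = 4, n_reports = 5000, seed = 1,
                          baseline = 0.05) {
  srs_config(
    drugs = c(drugA = 1, drugB = 1),
    vocabulary = data.frame(
      pt = c("Nausea", "Fatigue"),
      soc = c("Gastrointestinal disorders",
              "General disorders and administration site conditions"),
      baseline_prob = c(baseline, 0.9)),
    signals = if (multiplier != 1)
      data.frame(drug = "drugA", pt = "Nausea", multiplier = multiplier),
    n_reports = n_reports, seed = seed)
}

# independent random 2x2 tables with all cells >= 1
random_tables <- function(n, seed, max_cell = 500) {
  set.seed(seed)
  matrix(sample.int(max_cell, 4 * n, replace = TRUE), ncol = 4)
}

write_report_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("report_id,drug,reactions,sex,age_group,region,year,outcomes",
               lines), path)
  path
}
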