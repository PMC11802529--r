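fx <- load_paper_fixture()
gi <- "Gastrointestinal disorders"

test_that("occurrence-mode 2x2 reconstruction from the SOC table is exact", {
  ct <- build_contingency(fx$counts, "liraglutide", gi, level = "soc")
  # frozen from hand summation of the 27-SOC columns
  expect_equal(ct$a, 28252L)
  expect_equal(ct$b, 68299L)
  expect_equal(ct$c, 10191L)
  expect_equal(ct$d, 113926L)
  expect_equal(ct$a + ct$b + ct$c + ct$d, sum(fx$counts$soc$count))
})

test_that("two-drug toy cells land in their quadrants directly", {
  toy <- adr_counts(
    data.frame(drug = c("X", "Y"), n_reports = c(10, 100)),
    pt = data.frame(drug = c("X", "X", "Y", "Y"),
                    pt = c("t", "u", "t", "u"),
                    count = c(3, 7, 30, 70)))
  ct <- build_contingency(toy, "X", "t", level = "pt")
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(3, 7, 30, 70))
})

test_that("degenerate builds fail loudly", {
  one_drug <- adr_counts(data.frame(drug = "X", n_reports = 5),
                         soc = data.frame(drug = "X", soc = gi, count = 5))
  expect_error(build_contingency(one_drug, "X", gi), "at least two drugs")
  expect_error(build_contingency(fx$counts, "liraglutide", "Not a SOC"),
               "unknown soc term")
  # report unit at SOC level needs distinct-report counts
  expect_error(build_contingency(fx$counts, "liraglutide", gi, mode = "report"),
               "report-level data required")
})

test_that("ROR and PRR match hand-computed toy tables", {
  null_ct <- contingency_table(10, 10, 10, 10)
  r <- ror(null_ct)
  expect_equal(r$estimate, 1)
  expect_equal(r$ci_low * r$ci_high, 1)  # symmetric about 1 on the log scale

  expect_equal(ror(contingency_table(3, 97, 30, 970))$estimate, 1)
  expect_equal(prr(contingency_table(10, 100 - 10, 100, 1000 - 100))$estimate, 1)
  expect_equal(prr(contingency_table(10, 90, 10, 190))$estimate, 2)
})

test_that("liraglutide GI estimates agree with the published analysis", {
  ct <- build_contingency(fx$counts, "liraglutide", gi)
  r <- ror(ct)
  p <- prr(ct)
  # frozen values from the closed-form reconstruction
  expect_equal(r$estimate, 4.624246, tolerance = 1e-6)
  expect_equal(p$estimate, 3.563747, tolerance = 1e-6)
  expect_true(r$significant)
  expect_true(p$significant)
  expect_lt(abs(r$estimate - 4.629) / 4.629, 0.01)
  expect_lt(abs(p$estimate - 3.566) / 3.566, 0.01)
})

test_that("zero cells trigger a flagged Haldane-Anscombe correction", {
  ct <- contingency_table(5, 95, 0, 100)
  r <- ror(ct)
  expect_true(r$correction_applied)
  expect_equal(r$estimate, (5.5 * 100.5) / (95.5 * 0.5))
  expect_true(is.finite(r$ci_low) && is.finite(r$ci_high))
  expect_equal(r$n_cases, 5)

  # uncorrected case count governs evaluability
  r0 <- ror(contingency_table(0, 100, 50, 100))
  expect_true(r0$correction_applied)
  expect_false(r0$evaluable)
  expect_false(r0$significant)
})

test_that("estimator identities hold across random tables", {
  tabs <- random_tables(300, seed = 42)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs[i, 1]; b <- tabs[i, 2]; c <- tabs[i, 3]; d <- tabs[i, 4]
    r <- ror(contingency_table(a, b, c, d))
    p <- prr(contingency_table(a, b, c, d))
    # swapping target and comparator inverts the ROR and its CI exactly
    r_swap <- ror(contingency_table(c, d, a, b))
    expect_equal(r_swap$estimate, 1 / r$estimate, tolerance = 1e-12)
    expect_equal(r_swap$ci_low, 1 / r$ci_high, tolerance = 1e-12)
    expect_equal(r_swap$ci_high, 1 / r$ci_low, tolerance = 1e-12)
    # scaling all cells leaves points fixed and narrows the CI
    r2 <- ror(contingency_table(2 * a, 2 * b, 2 * c, 2 * d))
    expect_equal(r2$estimate, r$estimate, tolerance = 1e-12)
    expect_lt(r2$ci_high / r2$ci_low, r$ci_high / r$ci_low + 1e-12)
    # ROR always sits at least as far from 1 as PRR, on the same side
    expect_gte(log(r$estimate) * log(p$estimate), 0)
    expect_gte(abs(log(r$estimate)), abs(log(p$estimate)) - 1e-12)
    # independent log-space recomputation (compared on the ratio scale)
    expect_equal(r$estimate, exp(log(a) + log(d) - log(b) - log(c)),
                 tolerance = 1e-12)
  }
})

test_that("screening equals independent per-pair recomputation", {
  cfg <- default_srs_config(n_reports = 800, seed = 21)
  ag <- aggregate_reports(simulate_srs(cfg), srs_dictionary(cfg))
  scr <- screen_signals(ag, level = "pt", metrics = c("ror", "prr"))
  expect_true(all(scr$a >= 1))
  for (i in sample.int(nrow(scr), 25)) {
    row <- scr[i, ]
    ct <- build_contingency(ag, row$drug, row$term, level = "pt")
    ref <- if (row$metric == "ROR") ror(ct) else prr(ct)
    expect_equal(row$estimate, ref$estimate)
    expect_equal(row$ci_low, ref$ci_low)
    expect_equal(row$significant, ref$significant)
  }
  # ordered by drug (table order) then term
  ord <- order(match(scr$drug, ag$totals$drug), scr$term)
  expect_equal(scr$drug, scr$drug[ord])
  expect_equal(scr$term, scr$term[ord])
})

test_that("SOC-level screen of the snapshot flags the liraglutide GI signal", {
  scr <- screen_signals(fx$counts, level = "soc")
  lira_gi <- scr[scr$drug == "liraglutide" & scr$term == gi, ]
  expect_equal(nrow(lira_gi), 2)
  expect_true(all(lira_gi$significant))
  # every pair printed with a nonzero count shows up once per metric
  expect_equal(nrow(scr), 2 * sum(fx$counts$soc$count >= 1))
})

test_that("pairs with fewer than three cases are never evaluable", {
  toy <- adr_counts(
    data.frame(drug = c("X", "Y"), n_reports = c(100, 100)),
    pt = data.frame(drug = c("X", "X", "Y", "Y"),
                    pt = c("t", "u", "t", "u"),
                    count = c(2, 98, 1, 99)))
  scr <- screen_signals(toy, level = "pt", metrics = "ror")
  xt <- scr[scr$drug == "X" & scr$term == "t", ]
  expect_false(xt$evaluable)
  expect_false(xt$significant)
})

test_that("forest rows sort by estimate with the reference encoded", {
  scr <- screen_signals(fx$counts, level = "soc", metrics = "ror")
  fd <- forest_data(scr[scr$term == gi, ])
  expect_equal(nrow(fd), 5)
  expect_match(fd$label[1], "liraglutide")
  expect_equal(fd$estimate, sort(fd$estimate, decreasing = TRUE))
  expect_true(all(fd$reference == 1))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_forest_tsv(fd, path)
  expect_equal(read_forest_tsv(path), fd)

  empty <- forest_data(scr[0, ])
  expect_equal(nrow(empty), 0)
  write_forest_tsv(empty, path)
  expect_true(file.exists(path))

  mixed <- screen_signals(fx$counts, level = "soc")
  expect_error(forest_data(mixed), "single metric")
})
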