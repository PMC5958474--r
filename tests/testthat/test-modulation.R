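test_that("comparison tables validate their rows", {
  expect_error(comparison_table(data.frame(gene = "ATM", fold_change = -1),
                                "d"), "positive")
  expect_error(comparison_table(data.frame(gene = c("ATM", "ATM"),
                                           fold_change = c(2, 3)), "d"),
               "one row per gene")
  expect_error(comparison_table(data.frame(gene = "ATM", fold_change = 2,
                                           p_value = 1.5), "d"), "p-values")
  empty <- comparison_table(data.frame(gene = character(0),
                                       fold_change = numeric(0)), "d")
  expect_s3_class(empty, "comparison_table")
})

test_that("fold-change thresholds call up/down inclusively, ties to the call", {
  tab <- comparison_table(
    data.frame(gene = c("PARP1", "MRE11A", "ATM", "ATR", "CHEK1"),
               fold_change = c(2.03, 0.46, 1.0, 2.0, 0.5)),
    disease = "organelle stress")
  calls <- call_modulation(tab, the_panel)
  expect_identical(unname(calls$labels[c("PARP1", "MRE11A", "ATM",
                                         "ATR", "CHEK1")]),
                   c("up", "down", "unchanged", "up", "down"))
  # everything not in the table stays unchanged, denominator intact
  expect_length(calls$labels, 68)
  expect_identical(sum(calls$labels == "unchanged"), 64L)
})

test_that("p-values gate the call when present, and only then", {
  tab <- comparison_table(
    data.frame(gene = c("ATM", "ATR", "CHEK1"),
               fold_change = c(3, 3, 3),
               p_value = c(0.2, 0.01, NA)),
    disease = "d")
  calls <- call_modulation(tab, the_panel)
  expect_identical(unname(calls$labels[c("ATM", "ATR", "CHEK1")]),
                   c("unchanged", "up", "up"))
  bh <- call_modulation(tab, the_panel, p_adjust = "BH")
  expect_s3_class(bh, "modulation_calls")
})

test_that("non-panel tokens are reported and ignored; aliases are mapped", {
  tab <- comparison_table(
    data.frame(gene = c("Ku70", "GAPDH"), fold_change = c(2.5, 9)), "d")
  expect_message(calls <- call_modulation(tab, the_panel), "GAPDH")
  expect_identical(unname(calls$labels["XRCC6"]), "up")
})

test_that("count_modulated equals a gene-by-gene threshold scan", {
  set.seed(12)
  genes <- panel_genes(the_panel)
  for (rep in 1:25) {
    n <- sample(10:68, 1)
    pick <- sample(genes, n)
    fc <- exp(rnorm(n, 0, 1))
    p <- ifelse(runif(n) < 0.3, NA, runif(n))
    tab <- comparison_table(data.frame(gene = pick, fold_change = fc,
                                       p_value = p), "rand")
    calls <- call_modulation(tab, the_panel)
    ok_p <- is.na(p) | p <= 0.05
    expect_identical(unname(count_modulated(calls)),
                     c(sum(fc >= 2 & ok_p), sum(fc <= 0.5 & ok_p)))
    cat_of <- stats::setNames(the_panel$genes$category, genes)
    expect_identical(
      unname(count_modulated(calls, "DDCF")),
      c(sum(fc >= 2 & ok_p & cat_of[pick] == "DDCF"),
        sum(fc <= 0.5 & ok_p & cat_of[pick] == "DDCF")))
  }
})

test_that("risk percentages display with ties away from zero", {
  expect_identical(risk_percent(18)$display, 26L)   # 26.47
  expect_identical(risk_percent(16)$display, 24L)   # 23.53
  expect_identical(risk_percent(12)$display, 18L)   # 17.65
  expect_identical(risk_percent(1)$display, 1L)     # 1.47
  expect_identical(risk_percent(0)$display, 0L)
  expect_identical(risk_percent(68)$display, 100L)
  expect_error(risk_percent(69), "panel_size")
})

test_that("risk groups split at 10 and 5 on the unrounded percentage", {
  expect_identical(classify_risk(100 * 18 / 68), "high")    # 26.47
  expect_identical(classify_risk(100 * 7 / 68), "high")     # 10.29
  expect_identical(classify_risk(100 * 6 / 68), "medium")   # 8.82
  expect_identical(classify_risk(c(10, 5, 4.999, 0)),
                   c("high", "medium", "low", "low"))
  expect_error(classify_risk(-1), "\\[0, 100\\]")
})

test_that("adding a modulated gene never lowers the risk", {
  ranks <- c(low = 1, medium = 2, high = 3)
  prev <- risk_percent(0)
  for (n in 1:68) {
    cur <- risk_percent(n)
    expect_true(cur$raw > prev$raw)
    expect_gte(ranks[classify_risk(cur$raw)], ranks[classify_risk(prev$raw)])
    prev <- cur
  }
})

test_that("direction summaries pool and round to one decimal", {
  calls <- list(make_calls(ddcf_up = 15, ddcf_down = 5),
                make_calls(ddcf_up = 15, ddcf_down = 5),
                make_calls(ddcf_up = 14, ddcf_down = 4))
  ds <- direction_summary(calls, "DDCF")
  expect_identical(ds$total_up, 44L)
  expect_identical(ds$total_changes, 58L)
  expect_equal(ds$percent_up, 75.9)
  none <- direction_summary(list(make_calls()), "DDRF")
  expect_true(is.na(none$percent_up))
  zero_up <- direction_summary(list(make_calls(ddrf_down = 10)), "DDRF")
  expect_equal(zero_up$percent_up, 0.0)
})

test_that("cohort summaries partition the cohort", {
  one <- risk_report(list(make_calls(disease = "quiet",
                                     disease_class = "inflammation")))
  cs <- cohort_summary(one)
  expect_equal(cs$percent[cs$group == "low"], 100.0)
  expect_identical(sum(cs$count), 1L)
})

test_that("comparison metadata survives a write/read round trip", {
  tab <- comparison_table(
    data.frame(gene = c("ATM", "BRCA1"), fold_change = c(2.5, 0.4),
               p_value = c(0.01, NA)),
    disease = "ulcerative colitis", disease_class = "digestive",
    tissue = "colon", geo_id = "GSE00000")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_comparison(tab, tf)
  back <- read_comparison(tf)
  expect_identical(attr(back, "disease"), "ulcerative colitis")
  expect_identical(attr(back, "geo_id"), "GSE00000")
  expect_equal(back$fold_change, tab$fold_change)
  expect_equal(back$p_value, tab$p_value)
})
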