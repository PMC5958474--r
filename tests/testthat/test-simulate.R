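test_that("a fixed seed reproduces every artifact bit for bit", {
  cfg <- sim_config(123)
  a <- gen_est_table(cfg, the_panel)
  b <- gen_est_table(cfg, the_panel)
  expect_identical(a$est$counts, b$est$counts)
  expect_identical(a$truth, b$truth)

  ca <- gen_comparison(cfg, the_panel)
  cb <- gen_comparison(cfg, the_panel)
  expect_identical(ca$table$fold_change, cb$table$fold_change)
  expect_identical(ca$table$p_value, cb$table$p_value)

  ma <- gen_methylation_panel(cfg, the_panel)
  mb <- gen_methylation_panel(cfg, the_panel)
  expect_identical(ma$expression, mb$expression)
  expect_identical(ma$methylation$sam, mb$methylation$sam)

  # artifacts draw from separate streams: another seed changes everything
  expect_false(identical(gen_est_table(sim_config(124), the_panel)$est$counts,
                         a$est$counts))
})

test_that("zero planted expression yields an all-absent table", {
  cfg <- sim_config(2, tpm_high = 0, tpm_low = 0)
  sim <- gen_est_table(cfg, the_panel)
  expect_true(all(sim$est$counts == 0))
  expect_true(all(sim$truth == "absent"))
})

test_that("classification recovers at least 95% of planted EST labels", {
  sim <- gen_est_table(sim_config(1), the_panel)
  cm <- classify_expression(sim$est)
  # the auto threshold separates the planted levels
  expect_gt(cm$threshold_used, sim_config(1)$tpm_low)
  expect_lt(cm$threshold_used, sim_config(1)$tpm_high)
  expect_gte(mean(cm$calls == sim$truth), 0.95)
})

test_that("an overwhelming planted effect is always called up", {
  cfg <- sim_config(4, planted_log2fc = 3, noise_sd = 0.1)
  sim <- gen_comparison(cfg, the_panel,
                        planted_log2fc = c(BRCA1 = 3))
  calls <- call_modulation(sim$table, the_panel)
  expect_identical(unname(calls$labels["BRCA1"]), "up")
})

test_that("modulation calling recovers at least 90% of planted genes", {
  genes <- panel_genes(the_panel)
  lfc <- c(stats::setNames(rep(1.5, 10), genes[1:10]),
           stats::setNames(rep(-1.5, 10), genes[31:40]))
  sim <- gen_comparison(sim_config(7), the_panel, planted_log2fc = lfc)
  calls <- call_modulation(sim$table, the_panel)
  planted <- names(lfc)
  expect_gte(mean(calls$labels[planted] == sim$truth[planted]), 0.90)
})

test_that("with no planted effects the modulated fraction tracks the test size", {
  # noise high enough that the p <= alpha criterion, not the fold-change
  # gate, is binding (see the methods vignette)
  cfg <- sim_config(11, noise_sd = 1.5)
  called <- unlist(lapply(1:15, function(k) {
    sim <- gen_comparison(cfg, the_panel,
                          disease_meta = list(disease = paste0("null", k)))
    call_modulation(sim$table, the_panel)$labels != "unchanged"
  }))
  expect_length(called, 1020)
  frac <- mean(called)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("a noiseless planted hypo gene correlates perfectly with SAH", {
  sim <- gen_methylation_panel(sim_config(9), the_panel, noise_sd_expr = 0)
  hypo <- names(sim$truth)[sim$truth == "hypo"][1]
  res <- correlate(sim$expression[hypo, ], sim$methylation$sah,
                   index_name = "SAH", gene = hypo)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
})

test_that("planted non-regulated genes are significant at about the alpha rate", {
  set.seed(36)
  sah <- runif(6, 3, 5)
  hits <- replicate(1000, correlate(rnorm(6, 10, 1), sah)$significant)
  expect_gt(mean(hits), 0.03)
  expect_lt(mean(hits), 0.08)
})

test_that("methylation classification recovers at least 80% of planted labels", {
  sim <- gen_methylation_panel(sim_config(3), the_panel)
  cls <- classify_methylation_panel(sim$expression, sim$methylation)
  expect_gte(mean(cls$class == sim$truth[cls$gene]), 0.80)
  expect_identical(as.vector(table(sim$truth)[c("hypo", "hyper", "non")]),
                   c(5L, 15L, 48L))
})

test_that("a written study round-trips through the package readers", {
  dir <- withr::local_tempdir()
  study <- simulate_study(21, out_dir = dir)

  est <- read_est_counts(file.path(dir, "est_counts.tsv"),
                         file.path(dir, "library_totals.tsv"))
  expect_equal(unname(est$tpm), unname(study$est$tpm))

  files <- list.files(file.path(dir, "comparisons"), full.names = TRUE)
  expect_length(files, 39)
  one <- read_comparison(grep("Gastric_cancer", files, value = TRUE))
  expect_identical(attr(one, "disease"), "Gastric cancer")
  expect_equal(one$fold_change,
               study$comparisons[["Gastric cancer"]]$fold_change,
               tolerance = 1e-9)

  meth <- read_methylation(file.path(dir, "methylation.tsv"))
  expect_equal(meth$ratio, study$methylation$ratio, tolerance = 1e-9)

  manifest <- jsonlite::read_json(file.path(dir, "truth.json"),
                                  simplifyVector = TRUE)
  expect_identical(nrow(manifest$diseases), 39L)
  expect_identical(manifest$seed, 21L)
})

test_that("the published-study preset plants the published study structure", {
  study <- simulate_study(77)
  m <- study$manifest$diseases
  counts <- disease_risk_counts()
  expect_identical(m$n_total, counts$n_modulated)
  expect_identical(m$percent, counts$reported_percent)
  expect_identical(m$group, counts$reported_group)
  # cancers' planted direction totals match the published class summaries
  cancer <- study$comparison_truth[m$disease[m$disease_class == "cancer"]]
  cat_of <- stats::setNames(the_panel$genes$category,
                            the_panel$genes$symbol)
  tot <- function(lab, cat) {
    sum(vapply(cancer, function(tr)
      sum(tr == lab & cat_of[names(tr)] == cat), numeric(1)))
  }
  expect_identical(tot("up", "DDCF"), 44)
  expect_identical(tot("down", "DDCF"), 14)
  expect_identical(tot("up", "DDRF"), 32)
  expect_identical(tot("down", "DDRF"), 13)
  # the ten housekeeping factors are never planted absent
  ubi <- c("PARP1", "XRCC6", "XRCC5", "PRKDC",
           "APEX1", "XPC", "ERCC3", "ERCC5", "HMGB1", "MLH1")
  expect_true(all(study$est_truth[ubi, ] != "absent"))
})
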