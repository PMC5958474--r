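#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. One master seed
#' fixes all outputs bit-for-bit; each generated artifact draws from its own
#' stream derived from (seed, artifact name), so adding a generator never
#' perturbs existing fixtures.
#'
#' Defaults emulate the study conditions the pipeline assumes: EST libraries
#' of 1e5-1e6 tags with planted highly expressed genes at 200 TPM and low
#' ones at 20 TPM; microarray-style contrasts with 5 replicates per arm,
#' log-normal noise of 0.3 on the log2 scale and planted effects of
#' |log2 fold change| = 1.5; six-tissue methylation panels with a planted
#' signal-to-noise ratio of 5.
#'
#' @param seed integer master seed.
#' @param n_tissues number of tissues for EST tables (default 21).
#' @param library_total_range integer range of per-tissue library totals.
#' @param tpm_high,tpm_low planted expression levels (TPM) for high/low
#'   cells; must satisfy `tpm_high > tpm_low > 0`.
#' @param high_prob probability a gene-tissue cell is planted high.
#' @param n_replicates replicates per arm in contrasts (>= 2).
#' @param planted_log2fc default |log2 fold change| of planted modulated
#'   genes (>= 1 so planted genes are truly modulated).
#' @param noise_sd log2-scale standard deviation of replicate noise.
#' @param snr planted slope signal-to-noise ratio for methylation-regulated
#'   genes.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed, n_tissues = 21,
                       library_total_range = c(1e5, 1e6),
                       tpm_high = 200, tpm_low = 20, high_prob = 0.25,
                       n_replicates = 5, planted_log2fc = 1.5,
                       noise_sd = 0.3, snr = 5) {
  assert_that(length(seed) == 1 && is.finite(seed), "seed must be an integer")
  if (tpm_high == 0) {
    assert_that(tpm_low == 0, "tpm_low must be 0 when tpm_high is 0")
  } else {
    assert_that(tpm_high > tpm_low && tpm_low > 0,
                "need tpm_high > tpm_low > 0")
  }
  assert_that(n_replicates >= 2, "need at least 2 replicates per arm")
  assert_that(n_tissues >= 3, "need at least 3 tissues")
  assert_that(noise_sd > 0 && snr > 0, "noise_sd and snr must be positive")
  structure(list(seed = as.integer(seed), n_tissues = n_tissues,
                 library_total_range = library_total_range,
                 tpm_high = tpm_high, tpm_low = tpm_low,
                 high_prob = high_prob, n_replicates = n_replicates,
                 planted_log2fc = planted_log2fc, noise_sd = noise_sd,
                 snr = snr),
            class = "sim_config")
}

#' Generate a synthetic EST table with planted expression classes
#'
#' Each gene-tissue cell is planted `high` (at `tpm_high`) or `low` (at
#' `tpm_low`); cells listed in `planted_absent` are forced to zero. Counts
#' are Poisson: `counts[g,t] ~ Pois(tpm * library_total[t] / 1e6)`. The
#' returned ground-truth label of a cell is its planted class, except that
#' a cell whose sampled count is zero is truly `absent` -- under EST
#' semantics an unobserved tag is an unexpressed gene.
#'
#' @param config a [sim_config()].
#' @param panel a [load_panel()] panel (rows of the table).
#' @param tissues optional tissue names (default `tissue_1..n`).
#' @param planted_absent optional data.frame with columns `gene`, `tissue`
#'   naming cells forced to zero.
#' @param planted_present optional character vector of genes planted
#'   ubiquitously expressed: a sampled zero count is bumped to one observed
#'   tag, so these genes are never absent.
#' @return list with `est` (an `est_table`) and `truth` (gene x tissue
#'   character matrix of planted labels).
#' @export
gen_est_table <- function(config, panel, tissues = NULL,
                          planted_absent = NULL, planted_present = NULL) {
  genes <- panel_genes(panel)
  if (is.null(tissues)) tissues <- paste0("tissue_", seq_len(config$n_tissues))
  with_stream(config$seed, "est", {
    totals <- stats::setNames(
      floor(stats::runif(length(tissues), config$library_total_range[1],
                         config$library_total_range[2] + 1)), tissues)
    class_mat <- matrix(
      ifelse(stats::runif(length(genes) * length(tissues)) < config$high_prob,
             "high", "low"),
      nrow = length(genes), dimnames = list(genes, tissues))
    tpm_mat <- matrix(ifelse(class_mat == "high", config$tpm_high,
                             config$tpm_low),
                      nrow = length(genes), dimnames = dimnames(class_mat))
    if (!is.null(planted_absent)) {
      for (i in seq_len(nrow(planted_absent))) {
        tpm_mat[planted_absent$gene[i], planted_absent$tissue[i]] <- 0
        class_mat[planted_absent$gene[i], planted_absent$tissue[i]] <- "absent"
      }
    }
    lambda <- sweep(tpm_mat, 2, totals, "*") / 1e6
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     nrow = nrow(lambda), dimnames = dimnames(lambda))
    if (!is.null(planted_present)) {
      pp <- counts[planted_present, , drop = FALSE]
      pp[pp == 0] <- 1L
      counts[planted_present, ] <- pp
    }
    truth <- class_mat
    truth[counts == 0] <- "absent"
    list(est = normalize_est(counts, totals), truth = truth)
  })
}

#' Generate a synthetic disease-vs-control contrast
#'
#' Per gene, case and control replicate intensities are drawn log-normal
#' around a gene-specific baseline, the case arm offset by the planted
#' log2 fold change. The reported fold change is the ratio of arithmetic
#' arm means; the p-value comes from a two-sample (Welch) t-test on the
#' log2 values. Planted truth labels are `up` for log2fc >= 1, `down` for
#' <= -1, `unchanged` otherwise.
#'
#' @param config a [sim_config()].
#' @param panel a [load_panel()] panel.
#' @param disease_meta list with `disease`, `disease_class`, `tissue`,
#'   `geo_id` (all optional).
#' @param planted_log2fc named numeric vector (gene -> log2 fold change);
#'   unnamed genes get 0. Default: none planted.
#' @return list with `table` (a [comparison_table()] over all panel genes)
#'   and `truth` (named label vector).
#' @export
gen_comparison <- function(config, panel, disease_meta = list(),
                           planted_log2fc = numeric(0)) {
  genes <- panel_genes(panel)
  lfc <- stats::setNames(rep(0, length(genes)), genes)
  if (length(planted_log2fc) > 0) {
    assert_that(all(names(planted_log2fc) %in% genes),
                "planted genes must belong to the panel")
    lfc[names(planted_log2fc)] <- planted_log2fc
  }
  nm <- disease_meta$disease %||% "synthetic_disease"
  with_stream(config$seed, paste0("comparison:", nm), {
    n <- config$n_replicates
    baseline <- stats::runif(length(genes), 3, 8)
    fc <- numeric(length(genes))
    p <- numeric(length(genes))
    for (i in seq_along(genes)) {
      ctrl <- baseline[i] + stats::rnorm(n, 0, config$noise_sd)
      case <- baseline[i] + lfc[i] + stats::rnorm(n, 0, config$noise_sd)
      fc[i] <- mean(2^case) / mean(2^ctrl)
      p[i] <- stats::t.test(case, ctrl)$p.value
    }
    truth <- ifelse(lfc >= 1, "up", ifelse(lfc <= -1, "down", "unchanged"))
    table <- comparison_table(
      data.frame(gene = genes, fold_change = fc, p_value = p,
                 stringsAsFactors = FALSE),
      disease = nm,
      disease_class = disease_meta$disease_class %||% "inflammation",
      tissue = disease_meta$tissue %||% "",
      geo_id = disease_meta$geo_id %||% paste0("SYN-", nm))
    list(table = table, truth = stats::setNames(truth, genes))
  })
}

#' Generate a synthetic methylation panel with planted regulation classes
#'
#' Draws positive per-tissue SAM and SAH concentrations, then per-gene
#' expression vectors: planted `hypo` genes are linear in SAH, planted
#' `hyper` genes linear in SAM or in SAM/SAH (alternating), all with
#' Gaussian noise at the configured signal-to-noise ratio; `non` genes are
#' independent noise.
#'
#' @param config a [sim_config()].
#' @param panel a [load_panel()] panel.
#' @param tissues tissue names (default the six-tissue set heart, liver,
#'   lung, kidney, spleen, brain).
#' @param n_hypo,n_hyper numbers of planted hypo-/hyper-regulated genes
#'   (defaults 5 and 15, the reported group sizes).
#' @param noise_sd_expr standard deviation of the Gaussian expression noise
#'   (default 1; the planted slope is `snr * 1 / sd(index)`, so 0 gives
#'   exactly linear planted genes).
#' @return list with `methylation` (a [methylation_table()]), `expression`
#'   (gene x tissue matrix) and `truth` (named class vector).
#' @export
gen_methylation_panel <- function(config, panel,
                                  tissues = c("heart", "liver", "lung",
                                              "kidney", "spleen", "brain"),
                                  n_hypo = 5, n_hyper = 15,
                                  noise_sd_expr = 1) {
  genes <- panel_genes(panel)
  assert_that(length(tissues) >= 3, "at least 3 tissues required")
  assert_that(n_hypo + n_hyper <= length(genes),
              "too many planted genes for the panel")
  with_stream(config$seed, "methylation", {
    nt <- length(tissues)
    # Identifiability by design: the hypomethylation index (SAH) must not be
    # confounded with the hypermethylation indices (SAM, SAM/SAH) in the
    # realized tissue vectors, or planted classes cannot be told apart at
    # small n. SAH is drawn orthogonal to SAM by construction (residualized
    # draws, rescaled to a narrow positive range), and SAM spans a much
    # wider relative range so the ratio is SAM-driven.
    sam <- stats::runif(nt, 20, 80)
    e <- stats::residuals(stats::lm(stats::runif(nt) ~ sam))
    meth <- methylation_table(tissues, sam = sam,
                              sah = 4 + 0.5 * e / stats::sd(e))
    planted <- sample(genes, n_hypo + n_hyper)
    truth <- stats::setNames(rep("non", length(genes)), genes)
    truth[planted[seq_len(n_hypo)]] <- "hypo"
    truth[planted[n_hypo + seq_len(n_hyper)]] <- "hyper"

    hyper_ix <- 0
    expr <- matrix(NA_real_, length(genes), nt,
                   dimnames = list(genes, tissues))
    for (g in genes) {
      if (truth[g] == "hypo") {
        index <- meth$sah
      } else if (truth[g] == "hyper") {
        hyper_ix <- hyper_ix + 1
        index <- if (hyper_ix %% 2 == 1) meth$ratio else meth$sam
      } else {
        expr[g, ] <- stats::rnorm(nt, 10, max(noise_sd_expr, 1e-9))
        next
      }
      slope <- sample(c(-1, 1), 1) * config$snr / stats::sd(index)
      expr[g, ] <- 10 + slope * index +
        stats::rnorm(nt, 0, noise_sd_expr)
    }
    list(methylation = meth, expression = expr, truth = truth)
  })
}

# 21 human tissue names for the published-study EST table
.preset_tissues <- c("adipose tissue", "adrenal gland", "blood",
                     "bone marrow", "brain", "embryonic tissue", "eye",
                     "heart", "intestine", "kidney", "liver", "lung",
                     "lymph node", "muscle", "ovary", "pancreas", "skin",
                     "spleen", "testis", "thymus", "vascular")

# the ten genes reported ubiquitously expressed across human tissues
.preset_ubiquitous <- c("PARP1", "XRCC6", "XRCC5", "PRKDC",
                        "APEX1", "XPC", "ERCC3", "ERCC5", "HMGB1", "MLH1")

#' Simulate a full study ("published-study" preset)
#'
#' Generates every input of the pipeline in one call, with planted ground
#' truth: a 21-tissue x 68-gene EST table in which the ten classic
#' housekeeping factors are never planted absent while every other gene is
#' absent somewhere; 39 disease contrasts (27 inflammatory disorders + 12
#' cancers) whose planted modulated-gene counts equal the published
#' per-disease numbers, with the cancers' planted category/direction splits
#' apportioned so DDCF changes total 44 up / 14 down and DDRF changes 32 up
#' / 13 down; and a six-tissue methylation panel with 5 hypo- and 15
#' hyper-regulated genes planted. Planted contrast effects are strong
#' (|log2fc| = 2, noise 0.25) so that calling recovers the planted counts
#' exactly and the regenerated risk report matches the manifest.
#'
#' @param seed integer master seed.
#' @param panel a [load_panel()] panel (default the table2 variant).
#' @param out_dir optional directory; when given, all inputs are written as
#'   TSVs plus a `truth.json` manifest.
#' @return list with `est`, `est_truth`, `comparisons` (named list of
#'   comparison tables), `comparison_truth`, `methylation`,
#'   `methylation_expression`, `methylation_truth`, and `manifest` (the
#'   planted per-disease counts, percentages and groups).
#' @export
simulate_study <- function(seed, panel = load_panel(), out_dir = NULL) {
  config_est <- sim_config(seed)
  genes <- panel_genes(panel)

  # EST table: non-ubiquitous genes planted absent in 1-4 random tissues
  absent <- with_stream(seed, "absent_plan", {
    others <- setdiff(genes, .preset_ubiquitous)
    do.call(rbind, lapply(others, function(g) {
      k <- sample(1:4, 1)
      data.frame(gene = g, tissue = sample(.preset_tissues, k),
                 stringsAsFactors = FALSE)
    }))
  })
  est_sim <- gen_est_table(config_est, panel, tissues = .preset_tissues,
                           planted_absent = absent,
                           planted_present = .preset_ubiquitous)

  # disease contrasts with published per-disease modulated counts
  counts <- disease_risk_counts()
  plan <- .allocate_modulation(counts)
  config_cmp <- sim_config(seed, planted_log2fc = 2, noise_sd = 0.25)
  ddcf <- panel_genes(panel, "DDCF")
  ddrf <- panel_genes(panel, "DDRF")
  comparisons <- list()
  truths <- list()
  for (i in seq_len(nrow(plan))) {
    picks <- with_stream(seed, paste0("plant:", plan$disease[i]), {
      cc <- sample(ddcf, plan$ddcf_up[i] + plan$ddcf_down[i])
      rr <- sample(ddrf, plan$ddrf_up[i] + plan$ddrf_down[i])
      list(cu = cc[seq_len(plan$ddcf_up[i])],
           cd = cc[plan$ddcf_up[i] + seq_len(plan$ddcf_down[i])],
           ru = rr[seq_len(plan$ddrf_up[i])],
           rd = rr[plan$ddrf_up[i] + seq_len(plan$ddrf_down[i])])
    })
    lfc <- c(stats::setNames(rep(2, length(picks$cu)), picks$cu),
             stats::setNames(rep(-2, length(picks$cd)), picks$cd),
             stats::setNames(rep(2, length(picks$ru)), picks$ru),
             stats::setNames(rep(-2, length(picks$rd)), picks$rd))
    sim <- gen_comparison(config_cmp, panel,
                          disease_meta = list(
                            disease = plan$disease[i],
                            disease_class = plan$disease_class[i]),
                          planted_log2fc = lfc)
    comparisons[[plan$disease[i]]] <- sim$table
    truths[[plan$disease[i]]] <- sim$truth
  }

  meth_sim <- gen_methylation_panel(sim_config(seed), panel)

  planted_total <- plan$ddcf_up + plan$ddcf_down + plan$ddrf_up +
    plan$ddrf_down
  pct <- risk_percent(planted_total, length(genes))
  manifest <- list(
    seed = seed,
    diseases = data.frame(
      disease = plan$disease, disease_class = plan$disease_class,
      n_up = plan$ddcf_up + plan$ddrf_up,
      n_down = plan$ddcf_down + plan$ddrf_down,
      n_total = planted_total, percent = pct$display,
      group = classify_risk(pct$raw), stringsAsFactors = FALSE),
    methylation_classes = as.list(table(meth_sim$truth)),
    n_est_absent_cells = sum(est_sim$truth == "absent"))

  out <- list(est = est_sim$est, est_truth = est_sim$truth,
              comparisons = comparisons, comparison_truth = truths,
              methylation = meth_sim$methylation,
              methylation_expression = meth_sim$expression,
              methylation_truth = meth_sim$truth, manifest = manifest)
  if (!is.null(out_dir)) .write_study(out, out_dir)
  out
}

# split each disease's modulated count into DDCF/DDRF x up/down; cancers are
# constrained so class-level totals match the published direction summaries
.allocate_modulation <- function(counts) {
  plan <- counts[, c("disease", "disease_class", "n_modulated")]
  plan$ddcf_up <- 0L; plan$ddcf_down <- 0L
  plan$ddrf_up <- 0L; plan$ddrf_down <- 0L

  ca <- which(plan$disease_class == "cancer")
  ddcf_n <- apportion(58, plan$n_modulated[ca])
  ddcf_up <- apportion(44, ddcf_n)
  ddrf_n <- plan$n_modulated[ca] - ddcf_n
  ddrf_up <- apportion(32, ddrf_n)
  plan$ddcf_up[ca] <- ddcf_up
  plan$ddcf_down[ca] <- ddcf_n - ddcf_up
  plan$ddrf_up[ca] <- ddrf_up
  plan$ddrf_down[ca] <- ddrf_n - ddrf_up

  inf <- which(plan$disease_class != "cancer")
  for (i in inf) {
    n <- plan$n_modulated[i]
    nddcf <- as.integer(round_half_away(n * 26 / 68))
    nup_c <- as.integer(round_half_away(nddcf * 0.75))
    nup_r <- as.integer(round_half_away((n - nddcf) * 0.75))
    plan$ddcf_up[i] <- nup_c
    plan$ddcf_down[i] <- nddcf - nup_c
    plan$ddrf_up[i] <- nup_r
    plan$ddrf_down[i] <- n - nddcf - nup_r
  }
  plan
}

.slug <- function(x) {
  gsub("(^_+|_+$)", "", gsub("[^A-Za-z0-9]+", "_", x))
}

.write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  est <- study$est
  utils::write.table(
    data.frame(gene = est$genes, est$counts, check.names = FALSE),
    file.path(out_dir, "est_counts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(tissue = est$tissues, total_ests = est$library_totals),
    file.path(out_dir, "library_totals.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cmp_dir <- file.path(out_dir, "comparisons")
  dir.create(cmp_dir, showWarnings = FALSE)
  for (nm in names(study$comparisons)) {
    write_comparison(study$comparisons[[nm]],
                     file.path(cmp_dir, paste0(.slug(nm), ".tsv")))
  }
  utils::write.table(study$methylation[, c("tissue", "sam", "sah")],
                     file.path(out_dir, "methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = rownames(study$methylation_expression),
               study$methylation_expression, check.names = FALSE),
    file.path(out_dir, "methylation_expression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$manifest$seed, diseases = study$manifest$diseases,
         methylation_classes = study$manifest$methylation_classes,
         n_est_absent_cells = study$manifest$n_est_absent_cells),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}
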