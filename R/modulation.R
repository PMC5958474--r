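#' Construct a disease-vs-control comparison table
#'
#' One GEO2R-style contrast: per-gene expression fold change (disease over
#' control, a positive ratio) with an optional p-value, plus metadata naming
#' the disease, its class, the tissue and the accession (or synthetic tag).
#'
#' @param rows data.frame with columns `gene`, `fold_change` and optionally
#'   `p_value` (`NA` allowed).
#' @param disease disease name.
#' @param disease_class one of `"vascular"`, `"autoimmune"`, `"digestive"`,
#'   `"metabolic"`, `"aging"`, `"cancer"`, `"inflammation"`,
#'   `"cytokine_stimulus"`, `"oxidative_ko"`, `"organelle_stress"`.
#' @param tissue tissue or cell type string.
#' @param geo_id accession string or synthetic tag.
#' @return a `comparison_table` (data.frame with metadata attributes).
#' @export
comparison_table <- function(rows, disease, disease_class = "inflammation",
                             tissue = "", geo_id = "") {
  assert_that(all(c("gene", "fold_change") %in% names(rows)),
              "rows need columns gene, fold_change")
  if (!"p_value" %in% names(rows)) rows$p_value <- rep(NA_real_, nrow(rows))
  assert_that(all(is.finite(rows$fold_change) & rows$fold_change > 0),
              "fold changes must be positive ratios")
  pv <- rows$p_value[!is.na(rows$p_value)]
  assert_that(all(pv >= 0 & pv <= 1), "p-values must lie in [0, 1]")
  assert_that(!anyDuplicated(rows$gene), "at most one row per gene")
  out <- rows[, c("gene", "fold_change", "p_value")]
  rownames(out) <- NULL
  structure(out, class = c("comparison_table", "data.frame"),
            disease = disease, disease_class = disease_class,
            tissue = tissue, geo_id = geo_id)
}

#' Read a comparison TSV with `#key=value` header metadata
#'
#' Lines beginning `#disease=`, `#class=`, `#tissue=`, `#geo_id=` before the
#' header row carry metadata; the body has columns
#' `gene<TAB>fold_change<TAB>p_value` (`p_value` may be `NA`).
#'
#' @param path file path.
#' @return a [comparison_table()].
#' @export
read_comparison <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#[A-Za-z_]+=", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#", "", ln)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  body <- lines[!startsWith(lines, "#")]
  rows <- utils::read.delim(text = paste(body, collapse = "\n"),
                            stringsAsFactors = FALSE)
  comparison_table(rows,
                   disease = meta$disease %||% basename(path),
                   disease_class = meta$class %||% "inflammation",
                   tissue = meta$tissue %||% "",
                   geo_id = meta$geo_id %||% "")
}

#' Write a comparison table (round-trips through [read_comparison()])
#'
#' @param table a `comparison_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(table, path) {
  hdr <- c(paste0("#disease=", attr(table, "disease")),
           paste0("#class=", attr(table, "disease_class")),
           paste0("#tissue=", attr(table, "tissue")),
           paste0("#geo_id=", attr(table, "geo_id")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Call up/down modulation of panel genes in one contrast
#'
#' A panel gene is called `up` when its fold change is at least `up_fc`,
#' `down` when at most `down_fc` -- in both cases requiring `p <= alpha`
#' when a p-value is present (a missing p-value leaves the fold-change
#' criterion alone deciding). Genes absent from the table, and genes failing
#' both criteria, are `unchanged`. Tokens are normalized against the panel
#' (aliases, mouse case); tokens not in the panel are reported via a message
#' and ignored.
#'
#' @param table a [comparison_table()].
#' @param panel a [load_panel()] panel.
#' @param up_fc up-regulation fold-change cut (default 2).
#' @param down_fc down-regulation cut (default 0.5); requires
#'   `up_fc > 1 > down_fc > 0`.
#' @param alpha significance level applied when p-values are present
#'   (default 0.05).
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()] over the table's p-values before thresholding;
#'   default `"none"` (`"BH"` available).
#' @return a `modulation_calls` object: named label vector over all panel
#'   genes plus thresholds and contrast metadata.
#' @export
#' @examples
#' panel <- load_panel()
#' tab <- comparison_table(
#'   data.frame(gene = c("PARP1", "MRE11A", "ATM"),
#'              fold_change = c(2.03, 0.46, 1.0)),
#'   disease = "mitochondrial stress", geo_id = "GSE40207")
#' calls <- call_modulation(tab, panel)
#' count_modulated(calls, "DDCF")
call_modulation <- function(table, panel, up_fc = 2.0, down_fc = 0.5,
                            alpha = 0.05, p_adjust = "none") {
  assert_that(up_fc > 1 && down_fc < 1 && down_fc > 0,
              "need up_fc > 1 > down_fc > 0")
  genes <- panel_genes(panel)
  labels <- stats::setNames(rep("unchanged", length(genes)), genes)

  sym <- normalize_symbol(as.character(table$gene), panel)
  unknown <- table$gene[is.na(sym)]
  if (length(unknown) > 0) {
    message("ignoring ", length(unknown), " non-panel gene(s): ",
            paste(unknown, collapse = ", "))
  }
  keep <- !is.na(sym)
  fc <- table$fold_change[keep]
  p <- table$p_value[keep]
  if (!identical(p_adjust, "none")) p <- stats::p.adjust(p, method = p_adjust)
  sig <- is.na(p) | p <= alpha
  lab <- ifelse(fc >= up_fc & sig, "up",
                ifelse(fc <= down_fc & sig, "down", "unchanged"))
  labels[sym[keep]] <- lab

  structure(
    list(labels = labels,
         category = stats::setNames(panel$genes$category, genes),
         thresholds = list(up_fc = up_fc, down_fc = down_fc, alpha = alpha),
         disease = attr(table, "disease"),
         disease_class = attr(table, "disease_class"),
         tissue = attr(table, "tissue"), geo_id = attr(table, "geo_id")),
    class = "modulation_calls"
  )
}

#' @export
print.modulation_calls <- function(x, ...) {
  n <- count_modulated(x)
  cat(sprintf("<modulation_calls> %s [%s]: %d up, %d down of %d panel genes\n",
              x$disease %||% "?", x$geo_id %||% "", n[["n_up"]], n[["n_down"]],
              length(x$labels)))
  invisible(x)
}

#' Count up/down calls, optionally within one panel category
#'
#' @param calls a `modulation_calls` object.
#' @param category `"both"` (default), `"DDCF"` or `"DDRF"`.
#' @return named integer vector `c(n_up =, n_down =)`.
#' @export
count_modulated <- function(calls, category = c("both", "DDCF", "DDRF")) {
  category <- match.arg(category)
  lab <- calls$labels
  if (category != "both") lab <- lab[calls$category == category]
  c(n_up = sum(lab == "up"), n_down = sum(lab == "down"))
}

#' Genomic-risk percentage of a disease
#'
#' The genomic-risk index is the share of the 68-gene panel modulated in a
#' disease contrast: `100 * (n_up + n_down) / panel_size`. The display value
#' is rounded to the nearest integer, ties away from zero (18/68 = 26.47
#' prints as 26%; 16/68 = 23.53 as 24%).
#'
#' @param n_total number of up- plus down-regulated panel genes.
#' @param panel_size denominator (default 68).
#' @return list with `raw` (exact percentage) and `display` (integer).
#' @export
risk_percent <- function(n_total, panel_size = 68) {
  assert_that(all(n_total >= 0 & n_total <= panel_size),
              "n_total must lie in [0, panel_size]")
  raw <- 100 * n_total / panel_size
  list(raw = raw, display = as.integer(round_half_away(raw)))
}

#' Classify a disease into a genomic-risk group
#'
#' Applied to the unrounded percentage: `high` when at least 10% of the
#' panel is modulated, `medium` in \[5, 10), `low` below 5. A 7-gene disease
#' (10.29%) is high; a 6-gene disease (8.82%) is medium.
#'
#' @param raw_percent numeric vector of raw percentages in \[0, 100\].
#' @return character vector in `{"high", "medium", "low"}`.
#' @export
classify_risk <- function(raw_percent) {
  assert_that(all(raw_percent >= 0 & raw_percent <= 100),
              "percentage must lie in [0, 100]")
  ifelse(raw_percent >= 10, "high",
         ifelse(raw_percent >= 5, "medium", "low"))
}

#' Assess genomic risk for one called contrast
#'
#' @param calls a [call_modulation()] result.
#' @param panel_size risk denominator (default 68).
#' @return one-row data.frame `disease, disease_class, n_up, n_down,
#'   n_total, percent_raw, percent, group`.
#' @export
assess_risk <- function(calls, panel_size = 68) {
  n <- count_modulated(calls)
  n_total <- unname(n[["n_up"]] + n[["n_down"]])
  pct <- risk_percent(n_total, panel_size)
  data.frame(disease = calls$disease %||% "",
             disease_class = calls$disease_class %||% "",
             n_up = unname(n[["n_up"]]), n_down = unname(n[["n_down"]]),
             n_total = n_total, percent_raw = pct$raw, percent = pct$display,
             group = classify_risk(pct$raw), stringsAsFactors = FALSE)
}

#' Genomic-risk report over many contrasts
#'
#' @param calls_list list of `modulation_calls`.
#' @param panel_size risk denominator (default 68).
#' @param path optional TSV output path.
#' @return data.frame, one row per contrast (see [assess_risk()]).
#' @export
risk_report <- function(calls_list, panel_size = 68, path = NULL) {
  report <- do.call(rbind, lapply(calls_list, assess_risk,
                                  panel_size = panel_size))
  rownames(report) <- NULL
  if (!is.null(path)) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  report
}

#' Direction tendency of modulation across a disease class
#'
#' Pools the up and down calls of one panel category across several
#' contrasts and reports which direction dominates, e.g. "44 out of 58 DDCF
#' changes in cancers are up, 75.9%". Percent is rounded half away from
#' zero to one decimal; it is `NA` when there are no changes at all.
#'
#' @param calls_list list of `modulation_calls` (typically one disease
#'   class).
#' @param category `"DDCF"`, `"DDRF"` or `"both"`.
#' @return list `total_up`, `total_down`, `total_changes`, `percent_up`.
#' @export
direction_summary <- function(calls_list, category = c("DDCF", "DDRF", "both")) {
  category <- match.arg(category)
  assert_that(length(calls_list) > 0, "need at least one contrast")
  counts <- vapply(calls_list, count_modulated, integer(2),
                   category = category)
  up <- sum(counts["n_up", ])
  down <- sum(counts["n_down", ])
  changes <- up + down
  list(total_up = up, total_down = down, total_changes = changes,
       percent_up = if (changes == 0) NA_real_ else
         round_half_away(100 * up / changes, 1))
}

#' Risk-group composition of a disease cohort
#'
#' For each risk group, the number and percentage of cohort members placed
#' in it (one-decimal, half away from zero); counts always sum to the
#' cohort size.
#'
#' @param assessments a [risk_report()] data.frame.
#' @param disease_class optional filter on the `disease_class` column.
#' @return data.frame `group, count, percent` over `high, medium, low`.
#' @export
cohort_summary <- function(assessments, disease_class = NULL) {
  if (!is.null(disease_class)) {
    assessments <- assessments[assessments$disease_class %in% disease_class, ,
                               drop = FALSE]
  }
  assert_that(nrow(assessments) > 0, "empty cohort")
  counts <- vapply(c("high", "medium", "low"),
                   function(g) sum(assessments$group == g), numeric(1))
  data.frame(group = names(counts), count = as.integer(counts),
             percent = round_half_away(100 * counts / nrow(assessments), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Published per-disease modulated-gene counts
#'
#' The curated table of 27 inflammatory disorders and 12 cancers with the
#' number of panel genes reported modulated in each (from public GEO2R
#' contrasts), together with the percentage and risk group as originally
#' reported. Feeding `n_modulated` through [risk_percent()] and
#' [classify_risk()] reproduces the reported columns.
#'
#' @return data.frame `disease, disease_class, n_modulated,
#'   reported_percent, reported_group`.
#' @export
disease_risk_counts <- function() {
  utils::read.delim(system.file("extdata", "disease_modulation_counts.tsv",
                                package = "genorisk"),
                    stringsAsFactors = FALSE)
}

#' Published organelle-stress fold-change contrasts
#'
#' Ten knockout-versus-wild-type contrasts probing endoplasmic reticulum,
#' Golgi, lysosome, endosome, mitochondrial and autophagy stress (e.g.
#' ClpP-/- testis for mitochondrial stress, GSE40207). Only genes whose
#' reported fold change passed the >= 2 / <= 0.5 screen carry a value; all
#' other panel genes are unchanged. p-values are not part of the published
#' summary, so the fold-change criterion alone decides.
#'
#' @return named list of [comparison_table()] objects, one per accession.
#' @export
organelle_stress_contrasts <- function() {
  meta <- utils::read.delim(system.file("extdata",
                                        "organelle_stress_contrasts.tsv",
                                        package = "genorisk"),
                            stringsAsFactors = FALSE)
  fc <- utils::read.delim(system.file("extdata",
                                      "organelle_stress_foldchanges.tsv",
                                      package = "genorisk"),
                          stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    rows <- fc[fc$geo_id == meta$geo_id[i], c("gene", "fold_change")]
    comparison_table(rows, disease = meta$comparison[i],
                     disease_class = "organelle_stress",
                     tissue = meta$tissue[i], geo_id = meta$geo_id[i])
  })
  stats::setNames(out, meta$geo_id)
}
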