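#' Normalize EST counts to transcripts per million
#'
#' Expressed-sequence-tag (EST) counts proxy gene expression: the number of
#' tags observed for a gene in a tissue cDNA library, out of
#' `library_totals[t]` tags sequenced for that tissue. Normalization is
#' per-million: `tpm[g, t] = counts[g, t] / library_totals[t] * 1e6`.
#'
#' @param counts gene x tissue matrix of nonnegative integer EST counts
#'   (rownames = gene symbols, colnames = tissue names).
#' @param library_totals positive integer vector of total ESTs per tissue,
#'   named by tissue or in column order.
#' @return an `est_table`: list with `counts`, `library_totals`, `tpm`,
#'   `genes`, `tissues`.
#' @export
#' @examples
#' m <- matrix(c(2, 0, 30, 5), 2, 2,
#'             dimnames = list(c("PARP1", "ATM"), c("heart", "liver")))
#' est <- normalize_est(m, c(heart = 1e6, liver = 2e5))
#' est$tpm
normalize_est <- function(counts, library_totals) {
  counts <- as.matrix(counts)
  assert_that(all(counts >= 0) && all(counts == floor(counts)),
              "counts must be nonnegative integers")
  assert_that(length(library_totals) == ncol(counts),
              "one library total per tissue required")
  if (!is.null(names(library_totals)) && !is.null(colnames(counts))) {
    assert_that(setequal(names(library_totals), colnames(counts)),
                "library_totals names must match tissue columns")
    library_totals <- library_totals[colnames(counts)]
  }
  assert_that(all(library_totals > 0), "library totals must be positive")
  assert_that(all(colSums(counts) <= library_totals),
              "per-tissue counts exceed the library total")
  tpm <- sweep(counts, 2, library_totals, "/") * 1e6
  structure(
    list(genes = rownames(counts), tissues = colnames(counts),
         counts = counts, library_totals = library_totals, tpm = tpm),
    class = "est_table"
  )
}

#' @export
print.est_table <- function(x, ...) {
  cat(sprintf("<est_table> %d genes x %d tissues; library totals %s-%s\n",
              length(x$genes), length(x$tissues),
              format(min(x$library_totals), big.mark = ","),
              format(max(x$library_totals), big.mark = ",")))
  invisible(x)
}

#' Read an EST count table and its library totals
#'
#' @param counts_path TSV with first column `gene` and one column per tissue.
#' @param totals_path TSV with columns `tissue` and `total_ests`.
#' @return an [normalize_est()] `est_table`.
#' @export
read_est_counts <- function(counts_path, totals_path) {
  raw <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  assert_that(names(raw)[1] == "gene", "first column must be 'gene'")
  counts <- as.matrix(raw[, -1, drop = FALSE])
  rownames(counts) <- raw$gene
  tot <- utils::read.delim(totals_path, stringsAsFactors = FALSE)
  assert_that(all(c("tissue", "total_ests") %in% names(tot)),
              "totals file needs columns tissue, total_ests")
  normalize_est(counts, stats::setNames(tot$total_ests, tot$tissue))
}

#' Default expression threshold
#'
#' The high/low cut used when `classify_expression(threshold = "auto")`:
#' the mean TPM over all gene x tissue cells with nonzero expression. A
#' single global threshold, in TPM units.
#'
#' @param table an `est_table`.
#' @return positive scalar TPM threshold.
#' @export
auto_threshold <- function(table) {
  nz <- table$tpm[table$tpm > 0]
  assert_that(length(nz) > 0, "cannot derive a threshold: all counts zero")
  mean(nz)
}

#' Classify gene-tissue expression into high / low / absent
#'
#' A gene is `absent` (-) in a tissue where no tag was observed (TPM exactly
#' 0), `high` (++) where its TPM is strictly greater than the threshold, and
#' `low` (+) otherwise. Ties at the threshold are `low`: the rule is
#' "higher than the threshold", so equality is not high.
#'
#' @param table an `est_table` from [normalize_est()].
#' @param threshold positive TPM value, or `"auto"` (default) for
#'   [auto_threshold()].
#' @return a `call_matrix`: list with a character matrix `calls` in
#'   `{"high","low","absent"}` and `threshold_used`.
#' @export
classify_expression <- function(table, threshold = "auto") {
  if (identical(threshold, "auto")) {
    threshold <- auto_threshold(table)
  } else {
    assert_that(is.numeric(threshold) && length(threshold) == 1 &&
                threshold > 0, "threshold must be a positive TPM value")
  }
  calls <- ifelse(table$tpm == 0, "absent",
                  ifelse(table$tpm > threshold, "high", "low"))
  structure(
    list(genes = table$genes, tissues = table$tissues, calls = calls,
         threshold_used = threshold),
    class = "call_matrix"
  )
}

#' @export
print.call_matrix <- function(x, ...) {
  tab <- table(factor(x$calls, c("high", "low", "absent")))
  cat(sprintf(
    "<call_matrix> %d genes x %d tissues (threshold %.3g TPM): %d ++ / %d + / %d -\n",
    length(x$genes), length(x$tissues), x$threshold_used,
    tab["high"], tab["low"], tab["absent"]))
  invisible(x)
}

#' Fraction of a panel subset called highly expressed, per tissue
#'
#' `H%` for tissue t is `100 * #{g in subset : call[g, t] == high} /
#' |subset|` -- the basis of the tissue "variety" pyramid tiers.
#'
#' @param calls a `call_matrix`.
#' @param panel_subset character vector of gene symbols (must all be rows of
#'   `calls`).
#' @return named numeric vector of percentages in \[0, 100\], one per tissue.
#' @export
h_fraction <- function(calls, panel_subset) {
  assert_that(length(panel_subset) > 0, "panel subset must be nonempty")
  assert_that(all(panel_subset %in% calls$genes),
              "subset genes missing from the call matrix: ",
              paste(setdiff(panel_subset, calls$genes), collapse = ", "))
  sub <- calls$calls[match(panel_subset, calls$genes), , drop = FALSE]
  100 * colSums(sub == "high") / length(panel_subset)
}

#' Tissue variety tier from its H%
#'
#' Tissues are tiered by how many panel genes they express highly:
#' `high_variety` when H% > 19, `moderate_variety` when 5 <= H% <= 19
#' (both bounds inclusive), `low_variety` when H% < 5.
#'
#' @param h_percent numeric vector of percentages in \[0, 100\].
#' @return character vector of tiers.
#' @export
#' @examples
#' tier_tissue(c(73.1, 19, 19.01, 4.99))
tier_tissue <- function(h_percent) {
  assert_that(all(h_percent >= 0 & h_percent <= 100),
              "H% must lie in [0, 100]")
  ifelse(h_percent > 19, "high_variety",
         ifelse(h_percent >= 5, "moderate_variety", "low_variety"))
}

#' Genes expressed in every tissue
#'
#' A panel gene is ubiquitously expressed when its call is high or low --
#' i.e. not absent -- in every tissue examined. Order follows
#' `panel_subset`.
#'
#' @inheritParams h_fraction
#' @return character vector of ubiquitously expressed genes.
#' @export
find_ubiquitous <- function(calls, panel_subset) {
  assert_that(length(panel_subset) > 0, "panel subset must be nonempty")
  assert_that(all(panel_subset %in% calls$genes),
              "subset genes missing from the call matrix")
  sub <- calls$calls[match(panel_subset, calls$genes), , drop = FALSE]
  panel_subset[rowSums(sub == "absent") == 0]
}

#' Write a call matrix as TSV plus a JSON sidecar
#'
#' The TSV uses the field notation `++` / `+` / `-`; the sidecar records the
#' threshold and each tissue's H% and variety tier for the given panel
#' subset.
#'
#' @param calls a `call_matrix`.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @param panel_subset genes for the sidecar H% (default: all rows).
#' @return `path`, invisibly.
#' @export
write_call_matrix <- function(calls, path, panel_subset = calls$genes) {
  sym <- matrix(c(high = "++", low = "+", absent = "-")[calls$calls],
                nrow = length(calls$genes),
                dimnames = list(calls$genes, calls$tissues))
  df <- data.frame(gene = rownames(sym), sym, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  h <- h_fraction(calls, panel_subset)
  sidecar <- list(threshold_used = calls$threshold_used,
                  h_percent = as.list(h),
                  tier = as.list(tier_tissue(h)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
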