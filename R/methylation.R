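#' Tissue methylation-index table
#'
#' Per-tissue concentrations of S-adenosylmethionine (SAM, the universal
#' methyl donor -- a hypermethylation index) and S-adenosylhomocysteine
#' (SAH, a methyltransferase inhibitor -- a hypomethylation index), with
#' their ratio SAM/SAH (a second hypermethylation index). The classic
#' measurement covers six tissues: heart, liver, lung, kidney, spleen,
#' brain; at least three are required for any correlation.
#'
#' @param tissues character vector of tissue names (unique).
#' @param sam positive numeric vector of SAM concentrations.
#' @param sah positive numeric vector of SAH concentrations.
#' @return a `methylation_table` data.frame `tissue, sam, sah, ratio`.
#' @export
methylation_table <- function(tissues, sam, sah) {
  assert_that(length(tissues) >= 3, "at least 3 tissues required")
  assert_that(!anyDuplicated(tissues), "tissue names must be unique")
  assert_that(length(sam) == length(tissues) &&
              length(sah) == length(tissues),
              "sam/sah must have one value per tissue")
  assert_that(all(sam > 0) && all(sah > 0),
              "SAM and SAH concentrations must be positive")
  structure(
    data.frame(tissue = tissues, sam = sam, sah = sah, ratio = sam / sah,
               stringsAsFactors = FALSE),
    class = c("methylation_table", "data.frame"))
}

#' Read a methylation TSV (`tissue<TAB>sam<TAB>sah`)
#'
#' @param path file path.
#' @return a [methylation_table()].
#' @export
read_methylation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(all(c("tissue", "sam", "sah") %in% names(df)),
              "methylation file needs columns tissue, sam, sah")
  methylation_table(df$tissue, df$sam, df$sah)
}

#' Pearson correlation of expression with a methylation index
#'
#' Correlates one gene's per-tissue expression with a per-tissue index
#' (SAH, SAM, SAM/SAH, or a regulator gene's expression). Reports Pearson
#' r, r-squared, the two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom, a
#' significance flag at `alpha`, and -- when significant -- a correlation
#' tier: `high` for r^2 > 0.7, `low` otherwise.
#'
#' @param expression numeric per-tissue expression values for one gene.
#' @param index numeric per-tissue index values, same tissues, same order.
#' @param alpha significance level (default 0.05).
#' @param index_name label stored in the result (e.g. `"SAH"`).
#' @param gene gene symbol stored in the result.
#' @return a `correlation_result` list: `gene, index, n, r, r_squared, p,
#'   significant, tier` (`tier` is `NA` when not significant).
#' @export
#' @examples
#' sah <- c(2.1, 0.8, 1.4, 3.0, 2.2, 0.5)
#' correlate(2 * sah, sah, index_name = "SAH")$r_squared
correlate <- function(expression, index, alpha = 0.05, index_name = "",
                      gene = "") {
  assert_that(length(expression) == length(index),
              "expression and index must be paired")
  n <- length(expression)
  assert_that(n >= 3, "at least 3 tissues required")
  if (stats::sd(expression) == 0 || stats::sd(index) == 0) {
    stop(structure(
      class = c("genorisk_degenerate_input_error", "error", "condition"),
      list(message = "zero variance: correlation undefined", call = NULL)))
  }
  ct <- stats::cor.test(expression, index, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate)
  significant <- ct$p.value < alpha
  structure(
    list(gene = gene, index = index_name, n = n, r = r, r_squared = r^2,
         p = ct$p.value, significant = significant,
         tier = if (significant) (if (r^2 > 0.7) "high" else "low")
                else NA_character_),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> %s vs %s: r2 = %.4f, p = %.4g (n = %d)%s\n",
              x$gene, x$index, x$r_squared, x$p, x$n,
              if (isTRUE(x$significant)) paste0(" *", x$tier) else ""))
  invisible(x)
}

#' Classify a gene's methylation regulation mode
#'
#' Given the gene's correlation results against the three methylation
#' indices, the gene is `hypo`(methylation-regulated) when its expression
#' tracks SAH; `hyper` when it tracks SAM or SAM/SAH while not tracking
#' SAH; `non` otherwise. SAH takes precedence when both would apply, so
#' every gene receives exactly one label.
#'
#' @param sah_result,sam_result,ratio_result [correlate()] results for the
#'   SAH, SAM and SAM/SAH indices of the same gene.
#' @return one of `"hypo"`, `"hyper"`, `"non"`.
#' @export
classify_methylation_regulation <- function(sah_result, sam_result,
                                            ratio_result) {
  for (res in list(sah_result, sam_result, ratio_result)) {
    assert_that(inherits(res, "correlation_result"),
                "all three index results are required")
  }
  if (isTRUE(sah_result$significant)) return("hypo")
  if (isTRUE(sam_result$significant) || isTRUE(ratio_result$significant)) {
    return("hyper")
  }
  "non"
}

#' Classify every panel gene from a tissue expression matrix
#'
#' Convenience wrapper: correlates each gene's per-tissue expression with
#' SAH, SAM and SAM/SAH and applies
#' [classify_methylation_regulation()]. Genes with zero expression variance
#' across tissues cannot be correlated and are classified `non`.
#'
#' @param expression gene x tissue numeric matrix (columns must match
#'   `methylation$tissue`).
#' @param methylation a [methylation_table()].
#' @param alpha significance level (default 0.05).
#' @return data.frame `gene, class, r2_sah, r2_sam, r2_ratio`.
#' @export
classify_methylation_panel <- function(expression, methylation,
                                       alpha = 0.05) {
  assert_that(setequal(colnames(expression), methylation$tissue),
              "expression columns must match methylation tissues")
  expression <- expression[, methylation$tissue, drop = FALSE]
  res <- lapply(rownames(expression), function(g) {
    ex <- expression[g, ]
    if (stats::sd(ex) == 0) {
      return(data.frame(gene = g, class = "non", r2_sah = NA_real_,
                        r2_sam = NA_real_, r2_ratio = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sah <- correlate(ex, methylation$sah, alpha, "SAH", g)
    sam <- correlate(ex, methylation$sam, alpha, "SAM", g)
    rat <- correlate(ex, methylation$ratio, alpha, "SAM/SAH", g)
    data.frame(gene = g,
               class = classify_methylation_regulation(sah, sam, rat),
               r2_sah = sah$r_squared, r2_sam = sam$r_squared,
               r2_ratio = rat$r_squared, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-tissue DNA damage response potential
#'
#' A scalar summary of how strongly a tissue expresses the panel, used as
#' the response variable when correlating against candidate regulator
#' genes. Default: the tissue's H% over the combined 68-gene panel;
#' alternative: the tissue's mean TPM over the panel.
#'
#' @param table an `est_table` over the panel genes.
#' @param method `"h_percent"` (default) or `"mean_tpm"`.
#' @param threshold passed to [classify_expression()] for `"h_percent"`.
#' @return named numeric vector, one value per tissue.
#' @export
tissue_potential <- function(table, method = c("h_percent", "mean_tpm"),
                             threshold = "auto") {
  method <- match.arg(method)
  if (method == "h_percent") {
    h_fraction(classify_expression(table, threshold), table$genes)
  } else {
    colMeans(table$tpm)
  }
}

#' Correlate tissue DNA damage response potential with a regulator gene
#'
#' Same statistic and tiering as [correlate()]; the response is a
#' per-tissue summary of panel expression (see [tissue_potential()]) and
#' the predictor a candidate regulator's per-tissue expression (oxygen
#' sensors, VEGF pathway genes, stem cell master regulators, ...).
#'
#' @param potential per-tissue DNA damage response potential.
#' @param regulator_expression per-tissue expression of the regulator.
#' @param alpha significance level (default 0.05).
#' @param regulator regulator gene symbol for the report.
#' @return a `correlation_result` with `index = "regulator:<name>"`.
#' @export
regulator_correlation <- function(potential, regulator_expression,
                                  alpha = 0.05, regulator = "") {
  correlate(potential, regulator_expression, alpha,
            index_name = paste0("regulator:", regulator))
}
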