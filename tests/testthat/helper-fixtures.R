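# shared fixtures, built in code

the_panel <- load_panel()

# an est_table with exact TPM values (library totals of 1e6 make counts = tpm)
make_est <- function(tpm, tissues = colnames(tpm)) {
  normalize_est(tpm, stats::setNames(rep(1e6, ncol(tpm)), tissues))
}

# a modulation_calls object with prescribed per-category up/down counts,
# bypassing the calling machinery (for summary arithmetic tests)
make_calls <- function(ddcf_up = 0, ddcf_down = 0, ddrf_up = 0,
                       ddrf_down = 0, disease = "synthetic",
                       disease_class = "cancer") {
  ddcf <- panel_genes(the_panel, "DDCF")
  ddrf <- panel_genes(the_panel, "DDRF")
  labels <- stats::setNames(rep("unchanged", 68), c(ddcf, ddrf))
  labels[ddcf[seq_len(ddcf_up)]] <- "up"
  labels[ddcf[ddcf_up + seq_len(ddcf_down)]] <- "down"
  labels[ddrf[seq_len(ddrf_up)]] <- "up"
  labels[ddrf[ddrf_up + seq_len(ddrf_down)]] <- "down"
  structure(
    list(labels = labels,
         category = stats::setNames(the_panel$genes$category,
                                    the_panel$genes$symbol),
         thresholds = list(up_fc = 2, down_fc = 0.5, alpha = 0.05),
         disease = disease, disease_class = disease_class,
         tissue = "", geo_id = ""),
    class = "modulation_calls")
}

# direct-formula Pearson oracle: covariance ratio and the t transform
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# brute-force exclusive-region oracle: set algebra over every signature
venn_oracle <- function(collection) {
  nm <- names(collection)
  subsets <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  counts <- vapply(subsets, function(inside) {
    outside <- setdiff(nm, inside)
    region <- Reduce(intersect, collection[inside])
    for (s in outside) region <- setdiff(region, collection[[s]])
    length(region)
  }, integer(1))
  stats::setNames(counts,
                  vapply(subsets, paste, character(1), collapse = "&"))
}
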