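#' Collect per-disease modulated gene sets
#'
#' Builds the named sets fed to the overlap analysis from a list of
#' modulation calls, keeping one direction ("up", "down") or their union
#' ("both"). Up- and down-regulated sets are usually analyzed separately,
#' mirroring how modulated factors cluster by disease.
#'
#' @param calls_list list of `modulation_calls` (names become set names;
#'   unnamed lists fall back to each contrast's disease).
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return a named list of character vectors (class `gene_set_collection`).
#' @export
gene_sets <- function(calls_list, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  want <- if (direction == "both") c("up", "down") else direction
  sets <- lapply(calls_list, function(cl) {
    names(cl$labels)[cl$labels %in% want]
  })
  nm <- names(calls_list) %||% vapply(calls_list, function(cl)
    cl$disease %||% "", character(1))
  if (is.null(names(sets))) names(sets) <- nm
  assert_that(!anyDuplicated(names(sets)), "set names must be unique")
  structure(sets, direction = direction, class = "gene_set_collection")
}

#' Exclusive Venn regions of a gene-set collection
#'
#' Every gene in the union is assigned to exactly one exclusive region: the
#' signature of all sets that contain it (e.g. `"A&C"` holds the genes in A
#' and C but no other set). Region cardinalities therefore sum to the size
#' of the union. With more than 6 sets a full region table becomes
#' unreadable; only pairwise intersections are reported.
#'
#' @param collection named list of character vectors (gene symbols).
#' @return data.frame `signature, n_sets, count, genes` (genes
#'   comma-separated), covering every nonempty subset of the set names; or,
#'   beyond 6 sets, a pairwise intersection table `set1, set2, count`.
#' @export
#' @examples
#' venn_regions(list(A = c("ATM", "ATR"), B = c("ATR", "BRCA1")))
venn_regions <- function(collection) {
  assert_that(length(collection) >= 1, "empty collection")
  nm <- names(collection)
  assert_that(!is.null(nm) && all(nzchar(nm)) && !anyDuplicated(nm),
              "sets must be uniquely named")
  collection <- lapply(collection, unique)

  if (length(collection) > 6) {
    pairs <- utils::combn(nm, 2)
    return(data.frame(
      set1 = pairs[1, ], set2 = pairs[2, ],
      count = apply(pairs, 2, function(p)
        length(intersect(collection[[p[1]]], collection[[p[2]]]))),
      stringsAsFactors = FALSE))
  }

  union_all <- unique(unlist(collection, use.names = FALSE))
  membership <- vapply(collection, function(s) union_all %in% s,
                       logical(length(union_all)))
  membership <- matrix(membership, nrow = length(union_all),
                       dimnames = list(union_all, nm))
  sig_of_gene <- apply(membership, 1, function(m) paste(nm[m], collapse = "&"))

  # all nonempty subsets, in size order then set order
  subsets <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, paste, collapse = "&", simplify = FALSE)))
  counts <- vapply(subsets, function(s) sum(sig_of_gene == s), numeric(1))
  genes <- vapply(subsets, function(s)
    paste(union_all[sig_of_gene == s], collapse = ","), character(1))
  data.frame(signature = subsets,
             n_sets = lengths(strsplit(subsets, "&", fixed = TRUE)),
             count = as.integer(counts), genes = genes,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Disease-specific genes of a collection
#'
#' Genes belonging to exactly one set, keyed by that set, plus a flag for
#' whether the collection is "mostly specific": a strict majority (> 50%)
#' of the union lies in singleton regions.
#'
#' @inheritParams venn_regions
#' @return list with `specific` (named list of character vectors, one per
#'   set), `n_specific`, `n_union`, and logical `mostly_specific`.
#' @export
specific_genes <- function(collection) {
  assert_that(length(collection) >= 1, "empty collection")
  regions <- venn_regions(collection)
  singles <- regions[regions$n_sets == 1, , drop = FALSE]
  specific <- stats::setNames(
    lapply(singles$genes, function(g)
      if (nzchar(g)) strsplit(g, ",", fixed = TRUE)[[1]] else character(0)),
    singles$signature)
  n_specific <- sum(singles$count)
  n_union <- sum(regions$count)
  list(specific = specific, n_specific = n_specific, n_union = n_union,
       mostly_specific = n_union > 0 && n_specific > n_union / 2)
}

#' Draw a 2- or 3-set Venn diagram of region counts
#'
#' Base-graphics circles annotated with the exclusive region cardinalities
#' from [venn_regions()]. Intended as a quick look, not publication art.
#'
#' @inheritParams venn_regions
#' @param main plot title.
#' @return the region data.frame, invisibly.
#' @export
plot_venn <- function(collection, main = "") {
  k <- length(collection)
  assert_that(k %in% c(2, 3), "plot_venn draws 2 or 3 sets")
  regions <- venn_regions(collection)
  lookup <- stats::setNames(regions$count, regions$signature)
  nm <- names(collection)

  centers <- if (k == 2) {
    cbind(x = c(-0.5, 0.5), y = c(0, 0))
  } else {
    cbind(x = c(-0.5, 0.5, 0), y = c(0.3, 0.3, -0.55))
  }
  graphics::plot.new()
  graphics::plot.window(xlim = c(-2, 2), ylim = c(-2, 2), asp = 1)
  graphics::title(main = main)
  theta <- seq(0, 2 * pi, length.out = 200)
  for (i in seq_len(k)) {
    graphics::polygon(centers[i, "x"] + 1.1 * cos(theta),
                      centers[i, "y"] + 1.1 * sin(theta), border = i)
    graphics::text(centers[i, "x"] * 2.2, centers[i, "y"] * 2.2 +
                     ifelse(k == 2, 1.2, 0), nm[i], col = i)
  }
  label_at <- function(sig, x, y) {
    graphics::text(x, y, lookup[[sig]] %||% 0)
  }
  if (k == 2) {
    label_at(nm[1], -1, 0); label_at(nm[2], 1, 0)
    label_at(paste(nm, collapse = "&"), 0, 0)
  } else {
    label_at(nm[1], -1, 0.7); label_at(nm[2], 1, 0.7); label_at(nm[3], 0, -1.2)
    label_at(paste(nm[1:2], collapse = "&"), 0, 0.7)
    label_at(paste(nm[c(1, 3)], collapse = "&"), -0.65, -0.35)
    label_at(paste(nm[c(2, 3)], collapse = "&"), 0.65, -0.35)
    label_at(paste(nm, collapse = "&"), 0, 0.1)
  }
  invisible(regions)
}
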