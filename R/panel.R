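#' The 68-gene DNA damage checkpoint/repair panel
#'
#' The package profiles a curated panel of 26 DNA damage checkpoint factors
#' (DDCFs: sensors, mediators, transducers, and in one variant effectors) and
#' 42 DNA damage repair factors (DDRFs: direct reversal, base and nucleotide
#' excision repair, the three double-strand-break repair pathways, mismatch
#' repair, plus HMGB1 shared across pathways). Two published DDCF membership
#' variants exist and both are shipped:
#'
#' * `"table2"` (default): the membership used by every quantitative table
#'   downstream (risk index, organelle stress). Includes IL1A and the split
#'   replication protein A subunits RPA1/RPA2/RPA3.
#' * `"figure2"`: the pathway-diagram membership. Includes the effectors
#'   CDC25A/CDC25C and the clamp loader RFC1, a single RPA (RPA1), no IL1A.
#'
#' Either way `|DDCF| = 26`, `|DDRF| = 42`, and the genomic-risk denominator
#' is 68.
#'
#' @name gene_panel
NULL

.ddcf_subgroups <- c("sensor", "mediator", "transducer", "effector")
.ddrf_subgroups <- c("DR", "NER", "BER", "DSBR-HR", "DSBR-NHEJ", "DSBR-MMEJ",
                     "MMR", "shared")

# DDCF rows present only in one membership variant
.variant_only <- list(
  table2  = c("IL1A", "RPA2", "RPA3"),
  figure2 = c("RFC1", "CDC25A", "CDC25C")
)

#' Load a gene-panel definition file
#'
#' Reads a tab-separated panel definition (columns `symbol`, `category`,
#' `subgroup`, `aliases`, `mouse_symbol`; aliases `|`-separated) and returns a
#' validated `gene_panel`. The bundled default file carries the union of both
#' DDCF membership variants; `variant` selects which 26-gene DDCF list is
#' active (see [gene_panel]).
#'
#' @param path path to a panel TSV; default the bundled panel.
#' @param variant `"table2"` (default) or `"figure2"`.
#' @return an object of class `gene_panel`: a list with `name`, `variant`,
#'   and a data.frame `genes` (one row per panel member, DDCFs first).
#' @export
#' @examples
#' panel <- load_panel()
#' table(panel$genes$category)
load_panel <- function(path = NULL, variant = c("table2", "figure2")) {
  variant <- match.arg(variant)
  if (is.null(path)) {
    path <- system.file("extdata", "ddr_panel.tsv", package = "genorisk")
  }
  assert_that(file.exists(path), "panel file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("symbol", "category", "subgroup", "aliases", "mouse_symbol")
  assert_that(all(needed %in% names(raw)),
              "panel file must have columns ", paste(needed, collapse = ", "))

  bad <- which(raw$symbol == "" | !raw$category %in% c("DDCF", "DDRF"))
  if (length(bad) > 0) {
    stop_validation("malformed panel row at line ", bad[1] + 1L,
                    " (counting the header)")
  }

  drop <- unlist(.variant_only[setdiff(names(.variant_only), variant)])
  genes <- raw[!(raw$symbol %in% drop), , drop = FALSE]
  genes <- genes[order(match(genes$category, c("DDCF", "DDRF"))), ,
                 drop = FALSE]
  rownames(genes) <- NULL

  panel <- structure(
    list(name = sub("\\.tsv$", "", basename(path)), variant = variant,
         genes = genes),
    class = "gene_panel"
  )
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  genes <- panel$genes
  n_ddcf <- sum(genes$category == "DDCF")
  n_ddrf <- sum(genes$category == "DDRF")
  if (n_ddcf != 26L || n_ddrf != 42L) {
    stop(structure(
      class = c("genorisk_panel_integrity_error", "error", "condition"),
      list(message = sprintf(
        "panel integrity: expected 26 DDCFs and 42 DDRFs, found %d and %d",
        n_ddcf, n_ddrf), call = NULL)
    ))
  }
  assert_that(!anyDuplicated(genes$symbol), "duplicated panel symbol")
  ok_sub <- ifelse(genes$category == "DDCF",
                   genes$subgroup %in% .ddcf_subgroups,
                   genes$subgroup %in% .ddrf_subgroups)
  assert_that(all(ok_sub), "invalid category/subgroup combination: ",
              paste(genes$symbol[!ok_sub], collapse = ", "))
  aliases <- toupper(unlist(strsplit(genes$aliases[genes$aliases != ""], "|",
                                     fixed = TRUE)))
  assert_that(!any(aliases %in% toupper(genes$symbol)),
              "alias collides with an official symbol")
  assert_that(!anyDuplicated(aliases), "alias shared by two panel records")
  invisible(panel)
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel '%s'> variant=%s: %d DDCFs + %d DDRFs = %d genes\n",
              x$name, x$variant,
              sum(x$genes$category == "DDCF"),
              sum(x$genes$category == "DDRF"), nrow(x$genes)))
  invisible(x)
}

#' Panel member symbols
#'
#' @param panel a [gene_panel].
#' @param category `"both"` (default), `"DDCF"` or `"DDRF"`.
#' @return character vector of official symbols in panel order.
#' @export
panel_genes <- function(panel, category = c("both", "DDCF", "DDRF")) {
  category <- match.arg(category)
  g <- panel$genes
  if (category != "both") g <- g[g$category == category, , drop = FALSE]
  g$symbol
}

# lookup table: token (uppercased) -> official symbol, with provenance
.alias_map <- function(panel) {
  g <- panel$genes
  rows <- lapply(seq_len(nrow(g)), function(i) {
    al <- strsplit(g$aliases[i], "|", fixed = TRUE)[[1]]
    al <- al[al != ""]
    data.frame(token = toupper(c(g$symbol[i], g$mouse_symbol[i], al)),
               symbol = g$symbol[i], stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  unique(map)
}

#' Normalize a gene token to its official panel symbol
#'
#' Case-insensitive lookup of a raw token against panel symbols, mouse
#' homolog symbols and legacy aliases (e.g. `Ku70` is XRCC6, `XPB` is ERCC3).
#' Mouse homology follows symbol case convention, so `Parp1` resolves to
#' PARP1 for either species.
#'
#' @param token character vector of raw gene tokens.
#' @param panel a [gene_panel].
#' @param species `"human"` or `"mouse"`; both use the same token space, the
#'   argument documents the provenance of the input.
#' @return character vector of official symbols; `NA` where the token is not
#'   a panel member.
#' @export
#' @examples
#' panel <- load_panel()
#' normalize_symbol(c("Ku70", "XPB", "Parp1", "GAPDH"), panel)
normalize_symbol <- function(token, panel, species = c("human", "mouse")) {
  match.arg(species)
  assert_that(is.character(token) && all(nzchar(token)),
              "tokens must be nonempty strings")
  map <- .alias_map(panel)
  up <- toupper(token)
  vapply(up, function(tk) {
    hit <- unique(map$symbol[map$token == tk])
    if (length(hit) > 1) {
      stop_validation("ambiguous gene token '", tk, "' matches: ",
                      paste(hit, collapse = ", "))
    }
    if (length(hit) == 0) NA_character_ else hit
  }, character(1), USE.NAMES = FALSE)
}
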