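# Queries and normalisation over the per-cell-line omics layers.

#' Median-center an expression matrix by gene
#'
#' Subtracts from every value the median expression of its gene across the
#' panel of cell lines, the dialect used for panel-style (DepMap-like)
#' expression data.  Missing cells are ignored when computing the median and
#' stay missing; a gene row that is entirely missing is left as-is with a
#' warning.
#'
#' @param mat Numeric matrix, genes in rows, cell lines in columns.
#' @return Matrix of the same shape; every row with data has median 0.
#' @export
median_center_expression <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  meds <- apply(mat, 1L, stats::median, na.rm = TRUE)
  all_missing <- !is.finite(meds)
  if (any(all_missing)) {
    warning(sum(all_missing), " gene row(s) entirely missing; left missing")
    meds[all_missing] <- 0
  }
  sweep(mat, 1L, meds, "-")
}

#' Filter mutation records by COSMIC recurrence
#'
#' In the default mode a mutation is retained only when its COSMIC
#' occurrence count is strictly greater than `min_occurrences` (default 5).
#' In hotspot mode (used for panel-style lines) only records flagged as
#' COSMIC hotspot mutations are retained, regardless of count.
#'
#' @param records Data frame with at least `cosmic_occurrences` and, in
#'   hotspot mode, `hotspot`.
#' @param min_occurrences Strict lower bound on the count.  Default 5.
#' @param hotspot_mode Retain only hotspot mutations.  Default FALSE.
#' @return The retained subset, original order.
#' @export
filter_mutations <- function(records, min_occurrences = 5,
                             hotspot_mode = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) return(records)
  if (any(records$cosmic_occurrences < 0, na.rm = TRUE)) {
    stop("negative cosmic_occurrences")
  }
  keep <- if (hotspot_mode) {
    records$hotspot %in% TRUE
  } else {
    !is.na(records$cosmic_occurrences) &
      records$cosmic_occurrences > min_occurrences
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call gene amplifications from log2 copy-number ratios
#'
#' @param cna Named numeric vector (gene -> log2 ratio) or data frame with
#'   `gene` and `dna_amp`.
#' @param threshold Log2 ratio at or above which a gene is called amplified
#'   (inclusive).  Default 0.8.
#' @return Character vector of amplified gene symbols.
#' @export
call_amplifications <- function(cna, threshold = 0.8) {
  if (is.data.frame(cna)) {
    gene <- cna$gene
    val <- cna$dna_amp
  } else {
    gene <- names(cna)
    val <- as.numeric(cna)
  }
  keep <- is.finite(val) & val >= threshold
  unique(gene[keep])
}

.store_lookup <- function(df, cell_line, gene, col) {
  if (is.null(df)) return(NA_real_)
  hit <- df$cell_line == cell_line & df$gene == gene
  if (!any(hit)) return(NA_real_)
  df[[col]][which(hit)[1]]
}

#' Query one gene across every cell line in a store
#'
#' Returns, for each cell line the store knows, the gene's screen rank and
#' hit status, expression value and copy-number ratio; absent layers and
#' unmeasured cells are reported as missing.  Rows are sorted by screen rank
#' ascending (missing ranks last).
#'
#' @param gene Gene symbol (case-sensitive).
#' @param store An [omics_store()].
#' @return Data frame `cell_line`, `rank`, `is_hit`, `expression_lfc`,
#'   `dna_amp`, one row per cell line.
#' @export
gene_query <- function(gene, store) {
  stopifnot(inherits(store, "omics_store"))
  known <- c(
    if (!is.null(store$cna)) store$cna$gene,
    if (!is.null(store$expr)) store$expr$gene,
    if (!is.null(store$mutations)) store$mutations$gene,
    if (!is.null(store$hits)) unlist(lapply(store$hits, `[[`, "gene"),
                                     use.names = FALSE)
  )
  if (!gene %in% known) stop("gene '", gene, "' not found in any layer")
  lines <- store_cell_lines(store)
  rows <- lapply(lines, function(cl) {
    rank <- NA_integer_
    is_hit <- NA
    h <- store$hits[[cl]]
    if (!is.null(h)) {
      i <- match(gene, h$gene)
      if (!is.na(i)) {
        rank <- h$rank[i]
        is_hit <- h$is_hit[i]
      }
    }
    data.frame(
      cell_line = cl, rank = rank, is_hit = is_hit,
      expression_lfc = .store_lookup(store$expr, cl, gene, "expression_lfc"),
      dna_amp = .store_lookup(store$cna, cl, gene, "dna_amp"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$rank), out$rank, out$cell_line), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Query one protein across the RPPA layer
#'
#' Returns the normalized linear expression value of a protein or
#' phospho-protein for every cell line, rank-ordered by value descending;
#' ties are broken alphabetically by cell-line name.
#'
#' @param name Protein or phospho-protein name as measured on the array.
#' @param proteins RPPA data frame (`cell_line`, `protein`, `value`) or an
#'   [omics_store()] with an `rppa` layer.
#' @return Data frame `cell_line`, `protein`, `value`, descending value.
#' @export
protein_query <- function(name, proteins) {
  if (inherits(proteins, "omics_store")) proteins <- proteins$rppa
  if (is.null(proteins)) stop("no RPPA layer in store")
  rows <- proteins[proteins$protein == name, , drop = FALSE]
  if (nrow(rows) == 0) stop("protein '", name, "' not measured")
  rows <- rows[order(-rows$value, rows$cell_line), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
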