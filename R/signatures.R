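# Oncogene and druggable signatures: orthogonal set logic over the omics
# store.  "Genomically altered" means amplified (log2 copy ratio at or above
# the amplification cut) or carrying at least one mutation that survives the
# COSMIC recurrence filter; deletions and expression outliers do not count.

.retained_mutations <- function(store, cell_line, cosmic_min, hotspot_mode) {
  if (is.null(store$mutations)) {
    return(store$mutations)
  }
  mut <- store$mutations[store$mutations$cell_line == cell_line, ,
                         drop = FALSE]
  filter_mutations(mut, min_occurrences = cosmic_min,
                   hotspot_mode = hotspot_mode)
}

#' Genomically altered genes of a cell line
#'
#' @param store An [omics_store()].
#' @param cell_line Cell-line name.
#' @param amp_threshold Inclusive log2 amplification cut.  Default 0.8.
#' @param cosmic_min Strict COSMIC recurrence cut for mutations.  Default 5.
#' @param hotspot_mode Use the hotspot mutation rule instead of the
#'   recurrence count.  Default FALSE.
#' @return Character vector of altered gene symbols.
#' @export
altered_genes <- function(store, cell_line, amp_threshold = 0.8,
                          cosmic_min = 5, hotspot_mode = FALSE) {
  stopifnot(inherits(store, "omics_store"))
  amped <- character(0)
  if (!is.null(store$cna)) {
    cna <- store$cna[store$cna$cell_line == cell_line, , drop = FALSE]
    amped <- call_amplifications(cna, threshold = amp_threshold)
  }
  mutated <- character(0)
  mut <- .retained_mutations(store, cell_line, cosmic_min, hotspot_mode)
  if (!is.null(mut)) mutated <- unique(mut$gene)
  sort(unique(c(amped, mutated)))
}

.hit_table <- function(store, cell_line) {
  if (is.null(store$hits) || is.null(store$hits[[cell_line]])) {
    stop("no screen hit calls for cell line '", cell_line, "'")
  }
  store$hits[[cell_line]]
}

.gene_drugs <- function(store, gene) {
  if (is.null(store$drugs)) return(NA_character_)
  d <- store$drugs$drug[store$drugs$gene == gene]
  if (length(d) == 0) NA_character_ else paste(d, collapse = ", ")
}

# One signature row per gene: every field is looked up from its store layer,
# never recomputed here.  A gene both amplified and mutated appears once
# carrying both annotations.
.signature_rows <- function(store, cell_line, genes, cosmic_min,
                            hotspot_mode) {
  h <- if (!is.null(store$hits)) store$hits[[cell_line]] else NULL
  mut <- .retained_mutations(store, cell_line, cosmic_min, hotspot_mode)
  rows <- lapply(genes, function(g) {
    i <- if (is.null(h)) NA_integer_ else match(g, h$gene)
    m <- if (is.null(mut)) mut else mut[mut$gene == g, , drop = FALSE]
    data.frame(
      gene = g,
      quant_log = if (!is.na(i)) h$quant_log[i] else NA_real_,
      rank = if (!is.na(i)) h$rank[i] else NA_integer_,
      is_hit = if (!is.na(i)) h$is_hit[i] else NA,
      expression_lfc = .store_lookup(store$expr, cell_line, g,
                                     "expression_lfc"),
      dna_amp = .store_lookup(store$cna, cell_line, g, "dna_amp"),
      mutation = if (!is.null(m) && nrow(m) > 0) {
        paste(m$protein_change, collapse = ", ")
      } else NA_character_,
      cosmic_occurrences = if (!is.null(m) && nrow(m) > 0) {
        max(m$cosmic_occurrences)
      } else NA_integer_,
      drugs = .gene_drugs(store, g),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows) == 0) {
    data.frame(gene = character(0), quant_log = numeric(0),
               rank = integer(0), is_hit = logical(0),
               expression_lfc = numeric(0), dna_amp = numeric(0),
               mutation = character(0), cosmic_occurrences = integer(0),
               drugs = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  # Published signature tables run from the most over-expressed gene down.
  out <- out[order(is.na(out$expression_lfc), -xtfrm(out$expression_lfc),
                   out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate oncogene signature
#'
#' Genes that are genomically altered in the cell line and annotated as bona
#' fide oncogenes, regardless of their screen hit status; each row carries
#' the gene's screen score, expression, copy number, retained mutations and
#' mapped drugs.  Rows are sorted by expression value descending.
#'
#' @param cell_line Cell-line name.
#' @param store An [omics_store()] with CNA and/or mutation layers and
#'   oncogene annotations.
#' @param amp_threshold,cosmic_min,hotspot_mode Alteration-call parameters;
#'   see [altered_genes()].
#' @return Signature data frame (`gene`, `quant_log`, `rank`, `is_hit`,
#'   `expression_lfc`, `dna_amp`, `mutation`, `cosmic_occurrences`, `drugs`).
#' @export
candidate_signature <- function(cell_line, store, amp_threshold = 0.8,
                                cosmic_min = 5, hotspot_mode = FALSE) {
  stopifnot(inherits(store, "omics_store"))
  if (is.null(store$oncogenes)) {
    stop("store has no oncogene annotation layer")
  }
  altered <- altered_genes(store, cell_line, amp_threshold, cosmic_min,
                           hotspot_mode)
  genes <- intersect(altered, store$oncogenes)
  .signature_rows(store, cell_line, genes, cosmic_min, hotspot_mode)
}

#' Overall oncogene signature
#'
#' Genes that are genomically altered and were hits in the functional
#' screen, whether or not they are annotated oncogenes.
#'
#' @inheritParams candidate_signature
#' @return Signature data frame; see [candidate_signature()].
#' @export
overall_signature <- function(cell_line, store, amp_threshold = 0.8,
                              cosmic_min = 5, hotspot_mode = FALSE) {
  stopifnot(inherits(store, "omics_store"))
  h <- .hit_table(store, cell_line)
  altered <- altered_genes(store, cell_line, amp_threshold, cosmic_min,
                           hotspot_mode)
  genes <- intersect(altered, h$gene[h$is_hit])
  .signature_rows(store, cell_line, genes, cosmic_min, hotspot_mode)
}

#' Functional oncogene signature
#'
#' The synthesis of the candidate and overall signatures: genes genomically
#' altered, annotated as oncogenes, and hits in the functional screen.
#'
#' @inheritParams candidate_signature
#' @return Signature data frame; see [candidate_signature()].
#' @export
functional_signature <- function(cell_line, store, amp_threshold = 0.8,
                                 cosmic_min = 5, hotspot_mode = FALSE) {
  stopifnot(inherits(store, "omics_store"))
  if (is.null(store$oncogenes)) {
    stop("store has no oncogene annotation layer")
  }
  h <- .hit_table(store, cell_line)
  altered <- altered_genes(store, cell_line, amp_threshold, cosmic_min,
                           hotspot_mode)
  genes <- Reduce(intersect,
                  list(altered, store$oncogenes, h$gene[h$is_hit]))
  .signature_rows(store, cell_line, genes, cosmic_min, hotspot_mode)
}

#' Functional-druggable signature
#'
#' Screen hits that have at least one mapped targeted agent, each row
#' carrying the gene's full drug list, ordered by screen rank ascending.
#'
#' @param cell_line Cell-line name.
#' @param store An [omics_store()] with hit calls and a drug map.
#' @return Data frame `gene`, `rank`, `drugs`.
#' @export
druggable_signature <- function(cell_line, store) {
  stopifnot(inherits(store, "omics_store"))
  if (is.null(store$drugs)) stop("store has no drug map layer")
  h <- .hit_table(store, cell_line)
  h <- h[h$is_hit, , drop = FALSE]
  druggable <- unique(store$drugs$gene)
  h <- h[h$gene %in% druggable, , drop = FALSE]
  out <- data.frame(
    gene = h$gene,
    rank = h$rank,
    drugs = vapply(h$gene, function(g) .gene_drugs(store, g), character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
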