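# Shared fixtures and independent oracles.

# Brute-force linear-interpolation quantile: sort the list, index
# h = (n - 1) * p + 1 and interpolate between the bracketing order
# statistics.  Written out by hand so it stays independent of
# stats::quantile.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Small hand-built omics store with fully controlled layers.
toy_store <- function(cell_line = "LINE1",
                      cna = NULL, expr = NULL, mutations = NULL,
                      oncogenes = NULL, drugs = NULL, hit_genes = NULL,
                      all_genes = NULL) {
  hits <- NULL
  if (!is.null(all_genes)) {
    is_hit <- all_genes %in% hit_genes
    # hits first, then the rest; scores consistent with the ordering
    ord <- order(!is_hit, all_genes)
    hits <- list(data.frame(
      gene = all_genes[ord],
      quant_log = seq(5, 0, length.out = length(all_genes)),
      rank = seq_along(all_genes),
      is_hit = is_hit[ord],
      stringsAsFactors = FALSE
    ))
    names(hits) <- cell_line
  }
  omics_store(
    cna = if (!is.null(cna)) {
      data.frame(cell_line = cell_line, gene = names(cna),
                 dna_amp = as.numeric(cna), stringsAsFactors = FALSE)
    },
    expr = if (!is.null(expr)) {
      data.frame(cell_line = cell_line, gene = names(expr),
                 expression_lfc = as.numeric(expr), stringsAsFactors = FALSE)
    },
    mutations = mutations,
    oncogenes = oncogenes,
    drugs = drugs,
    hits = hits
  )
}

# Minimal hand-written KGML document: entries is a list of character gene
# vectors (names become entry ids), relations a list of c(id1, id2).
write_toy_kgml <- function(path, entries, relations = list(),
                           extra_entries = character(0)) {
  lines <- c('<?xml version="1.0"?>',
             '<pathway name="path:toy1" org="hsa" number="1" title="toy">')
  for (eid in names(entries)) {
    lines <- c(lines, sprintf(
      '<entry id="%s" name="%s" type="gene"/>',
      eid, paste0("hsa:", entries[[eid]], collapse = " ")))
  }
  lines <- c(lines, extra_entries)
  for (r in relations) {
    lines <- c(lines, sprintf(
      '<relation entry1="%s" entry2="%s" type="PPrel"/>', r[1], r[2]))
  }
  writeLines(c(lines, "</pathway>"), path)
  path
}
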