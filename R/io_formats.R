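# Tab-separated, UTF-8, header-required table I/O with a fixed column order
# per row type, plus the KGML pathway reader.  Missing values are written as
# the empty string and numerics are serialised with "%.17g" so that
# read(write(x)) reproduces doubles bit-for-bit.

# Registry of row types: internal column name -> (header label, class).
# Header labels for signature rows follow the published table layout
# (Gene, QuantLog, Rank, ScreenHit, LogFoldChange, DnaAmp, Mutation,
# CosmicOccurrences, Drugs).
.table_registry <- list(
  counts = list(
    cols = c(shrna_id = "character", gene = "character",
             count_ref = "integer", count_final = "integer"),
    labels = c("shrna_id", "gene", "count_ref", "count_final")
  ),
  hits = list(
    cols = c(gene = "character", quant_log = "numeric", rank = "integer",
             is_hit = "logical"),
    labels = c("gene", "quant_log", "rank", "is_hit")
  ),
  signature = list(
    cols = c(gene = "character", quant_log = "numeric", rank = "integer",
             is_hit = "logical", expression_lfc = "numeric",
             dna_amp = "numeric", mutation = "character",
             cosmic_occurrences = "integer", drugs = "character"),
    labels = c("Gene", "QuantLog", "Rank", "ScreenHit", "LogFoldChange",
               "DnaAmp", "Mutation", "CosmicOccurrences", "Drugs")
  ),
  druggable = list(
    cols = c(gene = "character", rank = "integer", drugs = "character"),
    labels = c("Gene", "Rank", "Drugs")
  ),
  pathway_scores = list(
    cols = c(pathway_id = "character", title = "character",
             score = "numeric", n_hits = "integer", proportion = "numeric",
             rank = "integer"),
    labels = c("pathway_id", "title", "score", "n_hits", "proportion", "rank")
  ),
  pathway_annotation = list(
    cols = c(gene = "character", rank = "integer", expression_lfc = "numeric",
             drugs = "character", intensity = "numeric"),
    labels = c("gene", "rank", "expression_lfc", "drugs", "intensity")
  ),
  gene_query = list(
    cols = c(cell_line = "character", rank = "integer", is_hit = "logical",
             expression_lfc = "numeric", dna_amp = "numeric"),
    labels = c("cell_line", "rank", "is_hit", "expression_lfc", "dna_amp")
  ),
  zscores = list(
    cols = c(cell_line = "character", drug = "character", ic50 = "numeric",
             z = "numeric", sensitive = "logical"),
    labels = c("cell_line", "drug", "ic50", "z", "sensitive")
  ),
  ic50 = list(
    cols = c(ic50 = "numeric", error = "numeric", method = "character"),
    labels = c("ic50", "error", "method")
  )
)

#' Row types with a pinned on-disk column order
#'
#' @return Character vector of row-type names accepted by [write_table()] and
#'   [read_table()].
#' @export
table_types <- function() names(.table_registry)

.fmt_cell <- function(x) {
  if (is.numeric(x) && !is.integer(x)) {
    out <- ifelse(is.na(x), "", sprintf("%.17g", x))
  } else if (is.logical(x)) {
    out <- ifelse(is.na(x), "", as.character(as.integer(x)))
  } else {
    out <- ifelse(is.na(x), "", as.character(x))
  }
  out
}

#' Write a typed table in the pinned tab-separated dialect
#'
#' Columns are emitted in the documented order for `type`, tab-separated,
#' UTF-8, header first; missing values become empty strings; doubles are
#' written with enough digits to round-trip exactly; logicals as 0/1.
#'
#' @param rows Data frame whose columns include the registry columns for
#'   `type` (extra columns are dropped on write).
#' @param path Output file path.
#' @param type One of [table_types()].
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path, type) {
  reg <- .table_registry[[match.arg(type, table_types())]]
  stopifnot(is.data.frame(rows))
  missing_cols <- setdiff(names(reg$cols), names(rows))
  if (length(missing_cols) > 0) {
    stop("rows lack required column(s): ", paste(missing_cols, collapse = ", "))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(reg$labels, collapse = "\t"), con)
  if (nrow(rows) > 0) {
    cells <- vapply(names(reg$cols), function(nm) .fmt_cell(rows[[nm]]),
                    character(nrow(rows)))
    if (nrow(rows) == 1L) cells <- matrix(cells, nrow = 1L)
    writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

.parse_col <- function(x, cls, col, what = "table") {
  x[x == ""] <- NA
  switch(cls,
    character = as.character(x),
    numeric = {
      bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
      if (any(bad)) {
        stop(sprintf("%s: non-numeric value '%s' in column '%s' (row %d)",
                     what, x[which(bad)[1]], col, which(bad)[1]))
      }
      as.numeric(x)
    },
    integer = {
      num <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & (is.na(num) | num != floor(num))
      if (any(bad)) {
        stop(sprintf("%s: non-integer value '%s' in column '%s' (row %d)",
                     what, x[which(bad)[1]], col, which(bad)[1]))
      }
      as.integer(num)
    },
    logical = {
      num <- suppressWarnings(as.numeric(x))
      bad <- !is.na(x) & (is.na(num) | !(num %in% c(0, 1)))
      if (any(bad)) {
        stop(sprintf("%s: non-0/1 value '%s' in column '%s' (row %d)",
                     what, x[which(bad)[1]], col, which(bad)[1]))
      }
      as.logical(num)
    },
    stop("unknown column class: ", cls)
  )
}

.read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty file (no header): ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  cells <- strsplit(body, "\t", fixed = TRUE)
  mat <- matrix("", nrow = length(body), ncol = length(header))
  for (i in seq_along(cells)) {
    row <- cells[[i]]
    length(row) <- length(header)   # trailing empty fields
    row[is.na(row)] <- ""
    mat[i, ] <- row
  }
  colnames(mat) <- header
  mat
}

#' Read a typed table written by [write_table()]
#'
#' @param path File path.
#' @param type One of [table_types()].
#' @return Data frame with the registry's internal column names and classes.
#' @export
read_table <- function(path, type) {
  reg <- .table_registry[[match.arg(type, table_types())]]
  mat <- .read_tsv_raw(path)
  missing_cols <- setdiff(reg$labels, colnames(mat))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         " in ", path)
  }
  out <- lapply(seq_along(reg$cols), function(i) {
    .parse_col(mat[, reg$labels[i]], reg$cols[[i]], reg$labels[i],
               what = basename(path))
  })
  names(out) <- names(reg$cols)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read an shRNA count table
#'
#' Expects a tab-separated file whose header contains `shrna_id`, `gene`,
#' `count_ref` and `count_final`.  Counts must be non-negative integers;
#' malformed cells raise an error naming the offending data row rather than
#' being coerced.
#'
#' @param path File path.
#' @return Data frame with columns `shrna_id`, `gene`, `count_ref`,
#'   `count_final`, one row per input data row, in file order.
#' @export
read_count_table <- function(path) {
  counts <- read_table(path, "counts")
  for (col in c("count_ref", "count_final")) {
    bad <- which(is.na(counts[[col]]) | counts[[col]] < 0L)
    if (length(bad) > 0) {
      stop(sprintf("%s: negative or missing %s in row %d",
                   basename(path), col, bad[1]))
    }
  }
  if (anyNA(counts$gene) || any(!nzchar(counts$gene))) {
    stop("count table has empty gene symbols")
  }
  if (anyDuplicated(counts$shrna_id)) {
    stop("duplicate shrna_id in count table: ",
         counts$shrna_id[anyDuplicated(counts$shrna_id)])
  }
  counts
}

#' Write an shRNA count table
#'
#' @param counts Data frame as returned by [read_count_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(counts, path) write_table(counts, path, "counts")

# ---------------------------------------------------------------------------
# KGML

.strip_db_prefix <- function(x) sub("^[A-Za-z]+:", "", x)

#' Parse a KGML pathway file into a gene graph
#'
#' Entries of type `gene` become nodes; an entry whose `name` attribute
#' carries k gene identifiers expands to k nodes that all inherit the entry's
#' relations.  `group` entries are flattened to their component gene entries;
#' `map`, `compound` and `ortholog` entries are dropped.  Relations collapse
#' to simple undirected edges (no self loops, no multi-edges).  Database
#' prefixes such as `hsa:` are stripped from gene identifiers.
#'
#' @param path Path to a KGML XML file.
#' @return A `pathway_graph`: list with `pathway_id`, `title`, `genes`
#'   (character vector of node symbols), `edges` (two-column character
#'   matrix) and `empty` (TRUE when the file held no gene entries, in which
#'   case a warning is also raised).
#' @export
read_kgml <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("not a KGML document (no <pathway> root): ", path)
  pathway_id <- xml2::xml_attr(root, "name")
  title <- xml2::xml_attr(root, "title")
  if (is.na(title)) title <- ""

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  entry_genes <- list()   # entry id -> character vector of gene symbols
  for (e in entries) {
    type <- xml2::xml_attr(e, "type")
    id <- xml2::xml_attr(e, "id")
    if (identical(type, "gene")) {
      nm <- xml2::xml_attr(e, "name")
      genes <- .strip_db_prefix(strsplit(trimws(nm), "\\s+")[[1]])
      entry_genes[[id]] <- genes[nzchar(genes)]
    }
  }
  # Flatten groups to the union of their component gene entries.
  for (e in entries) {
    if (identical(xml2::xml_attr(e, "type"), "group")) {
      comp <- xml2::xml_find_all(e, "component")
      ids <- xml2::xml_attr(comp, "id")
      entry_genes[[xml2::xml_attr(e, "id")]] <-
        unique(unlist(entry_genes[ids], use.names = FALSE))
    }
  }

  genes <- sort(unique(unlist(entry_genes, use.names = FALSE)))
  relations <- xml2::xml_find_all(doc, "/pathway/relation")
  edges <- matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  if (length(relations) > 0 && length(genes) > 0) {
    pairs <- list()
    for (r in relations) {
      g1 <- entry_genes[[xml2::xml_attr(r, "entry1")]]
      g2 <- entry_genes[[xml2::xml_attr(r, "entry2")]]
      if (length(g1) == 0 || length(g2) == 0) next
      grid <- expand.grid(from = g1, to = g2, stringsAsFactors = FALSE)
      pairs[[length(pairs) + 1L]] <- grid
    }
    if (length(pairs) > 0) {
      all_pairs <- do.call(rbind, pairs)
      all_pairs <- all_pairs[all_pairs$from != all_pairs$to, , drop = FALSE]
      if (nrow(all_pairs) > 0) {
        a <- pmin(all_pairs$from, all_pairs$to)
        b <- pmax(all_pairs$from, all_pairs$to)
        keep <- !duplicated(paste(a, b, sep = "\r"))
        edges <- cbind(from = a[keep], to = b[keep])
      }
    }
  }
  empty <- length(genes) == 0
  if (empty) warning("KGML file has no gene entries: ", path)
  structure(
    list(pathway_id = pathway_id, title = title, genes = genes,
         edges = edges, empty = empty),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph '%s' (%s): %d gene nodes, %d edges\n",
              x$title, x$pathway_id, length(x$genes), nrow(x$edges)))
  invisible(x)
}

# igraph view of a pathway_graph, restricted to `universe` when given.
.pathway_igraph <- function(graph, universe = NULL) {
  genes <- graph$genes
  edges <- graph$edges
  if (!is.null(universe)) {
    genes <- intersect(genes, universe)
    keep <- edges[, 1] %in% genes & edges[, 2] %in% genes
    edges <- edges[keep, , drop = FALSE]
  }
  igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE)
  )
}

# ---------------------------------------------------------------------------
# Omics store I/O

.check_layer_dupes <- function(df, layer) {
  key <- paste(df$cell_line, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate (%s, %s) row in %s layer", d$cell_line, d$gene,
                 layer))
  }
  invisible(df)
}

.read_layer <- function(path, cols, layer) {
  mat <- .read_tsv_raw(path)
  missing_cols <- setdiff(names(cols), colnames(mat))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", layer, " table: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- lapply(names(cols), function(nm) {
    .parse_col(mat[, nm], cols[[nm]], nm, what = layer)
  })
  names(out) <- names(cols)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Assemble an in-memory omics store
#'
#' The store joins per-cell-line, per-gene omics layers under one object:
#' copy number (`cna`), expression (`expr`), mutations, oncogene
#' annotations, a gene-to-drug map, per-line screen hit tables and RPPA
#' protein values.  Any layer may be absent (`NULL`); queries against an
#' absent layer report it as missing rather than guessing.  Gene identity is
#' the case-sensitive symbol string.
#'
#' @param cna Data frame `cell_line`, `gene`, `dna_amp` (log2 ratio), or NULL.
#' @param expr Data frame `cell_line`, `gene`, `expression_lfc`, or NULL.
#' @param mutations Data frame `cell_line`, `gene`, `protein_change`,
#'   `cosmic_occurrences`, `hotspot`, or NULL.
#' @param oncogenes Character vector of annotated oncogene symbols, or NULL.
#' @param drugs Data frame `gene`, `drug` (one row per pair), or NULL.
#' @param hits Named list (cell line -> hit-call data frame with `gene`,
#'   `quant_log`, `rank`, `is_hit`), or NULL.
#' @param rppa Data frame `cell_line`, `protein`, `value`, or NULL.
#' @param expr_dialect `"vs_normal"` (log2 ratio against a normal reference)
#'   or `"median_centered"` (panel dialect); a store never mixes the two.
#' @return An `omics_store` object.
#' @export
omics_store <- function(cna = NULL, expr = NULL, mutations = NULL,
                        oncogenes = NULL, drugs = NULL, hits = NULL,
                        rppa = NULL,
                        expr_dialect = c("vs_normal", "median_centered")) {
  expr_dialect <- match.arg(expr_dialect)
  if (!is.null(cna)) .check_layer_dupes(cna, "cna")
  if (!is.null(expr)) .check_layer_dupes(expr, "expr")
  if (!is.null(mutations) && nrow(mutations) > 0 &&
      any(mutations$cosmic_occurrences < 0, na.rm = TRUE)) {
    stop("negative cosmic_occurrences in mutations layer")
  }
  structure(
    list(cna = cna, expr = expr, mutations = mutations,
         oncogenes = oncogenes, drugs = drugs, hits = hits, rppa = rppa,
         expr_dialect = expr_dialect),
    class = "omics_store"
  )
}

#' @export
print.omics_store <- function(x, ...) {
  n <- function(df) if (is.null(df)) "absent" else nrow(df)
  cat("omics_store (expression dialect: ", x$expr_dialect, ")\n", sep = "")
  cat("  cna: ", n(x$cna), "  expr: ", n(x$expr), "  mutations: ",
      n(x$mutations), "\n", sep = "")
  cat("  oncogenes: ",
      if (is.null(x$oncogenes)) "absent" else length(x$oncogenes),
      "  drug pairs: ", n(x$drugs),
      "  hit tables: ", if (is.null(x$hits)) "absent" else length(x$hits),
      "  rppa: ", n(x$rppa), "\n", sep = "")
  invisible(x)
}

#' Cell lines known to a store
#'
#' Union of cell lines seen in any per-line layer.
#'
#' @param store An `omics_store`.
#' @return Sorted character vector.
#' @export
store_cell_lines <- function(store) {
  stopifnot(inherits(store, "omics_store"))
  sort(unique(c(
    if (!is.null(store$cna)) store$cna$cell_line,
    if (!is.null(store$expr)) store$expr$cell_line,
    if (!is.null(store$mutations)) store$mutations$cell_line,
    if (!is.null(store$hits)) names(store$hits),
    if (!is.null(store$rppa)) store$rppa$cell_line
  )))
}

.layer_cols <- list(
  cna = c(cell_line = "character", gene = "character", dna_amp = "numeric"),
  expr = c(cell_line = "character", gene = "character",
           expression_lfc = "numeric"),
  mutations = c(cell_line = "character", gene = "character",
                protein_change = "character",
                cosmic_occurrences = "integer", hotspot = "logical"),
  drugs = c(gene = "character", drug = "character"),
  rppa = c(cell_line = "character", protein = "character", value = "numeric")
)

#' Read an omics store from tab-separated layer files
#'
#' `config` names paths for any subset of the layers; absent entries leave
#' the layer absent in the store.  A duplicate (cell line, gene) row within
#' one layer is a format error.
#'
#' @param config Named list with any of `cna`, `expr`, `mutations`,
#'   `oncogenes`, `drugs`, `rppa` (file paths), `hits` (directory of
#'   `<cell_line>.tsv` hit tables) and `expr_dialect`.
#' @return An `omics_store`.
#' @export
read_omics_tables <- function(config) {
  get_layer <- function(nm) {
    if (is.null(config[[nm]])) return(NULL)
    .read_layer(config[[nm]], .layer_cols[[nm]], nm)
  }
  hits <- NULL
  if (!is.null(config$hits)) {
    files <- sort(list.files(config$hits, pattern = "\\.tsv$",
                             full.names = TRUE))
    hits <- lapply(files, read_table, type = "hits")
    names(hits) <- sub("\\.tsv$", "", basename(files))
  }
  oncogenes <- NULL
  if (!is.null(config$oncogenes)) {
    oncogenes <- readLines(config$oncogenes, encoding = "UTF-8")
    oncogenes <- oncogenes[nzchar(oncogenes)]
  }
  omics_store(
    cna = get_layer("cna"), expr = get_layer("expr"),
    mutations = get_layer("mutations"), oncogenes = oncogenes,
    drugs = get_layer("drugs"), hits = hits, rppa = get_layer("rppa"),
    expr_dialect = if (is.null(config$expr_dialect)) "vs_normal"
                   else config$expr_dialect
  )
}

#' Write an omics store as a directory of layer files
#'
#' Layout: `cna.tsv`, `expr.tsv`, `mutations.tsv`, `oncogenes.txt`,
#' `drugs.tsv`, `rppa.tsv`, `hits/<cell_line>.tsv` and `meta.json` (which
#' records the expression dialect).  Absent layers produce no file.
#'
#' @param store An `omics_store`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_omics_store <- function(store, dir) {
  stopifnot(inherits(store, "omics_store"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_layer <- function(df, nm) {
    if (is.null(df)) return()
    cols <- .layer_cols[[nm]]
    con <- file(file.path(dir, paste0(nm, ".tsv")), "wt", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    writeLines(paste(names(cols), collapse = "\t"), con)
    if (nrow(df) > 0) {
      cells <- vapply(names(cols), function(x) .fmt_cell(df[[x]]),
                      character(nrow(df)))
      if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
      writeLines(apply(cells, 1L, paste, collapse = "\t"), con)
    }
  }
  write_layer(store$cna, "cna")
  write_layer(store$expr, "expr")
  write_layer(store$mutations, "mutations")
  write_layer(store$drugs, "drugs")
  write_layer(store$rppa, "rppa")
  if (!is.null(store$oncogenes)) {
    writeLines(store$oncogenes, file.path(dir, "oncogenes.txt"))
  }
  if (!is.null(store$hits)) {
    hd <- file.path(dir, "hits")
    dir.create(hd, showWarnings = FALSE)
    for (cl in names(store$hits)) {
      write_table(store$hits[[cl]], file.path(hd, paste0(cl, ".tsv")), "hits")
    }
  }
  jsonlite::write_json(list(expr_dialect = store$expr_dialect),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an omics store directory written by [write_omics_store()]
#'
#' @param dir Store directory.
#' @return An `omics_store`.
#' @export
read_omics_store <- function(dir) {
  p <- function(nm) {
    fp <- file.path(dir, nm)
    if (file.exists(fp)) fp else NULL
  }
  meta <- p("meta.json")
  dialect <- "vs_normal"
  if (!is.null(meta)) {
    dialect <- jsonlite::read_json(meta)$expr_dialect
  }
  read_omics_tables(list(
    cna = p("cna.tsv"), expr = p("expr.tsv"), mutations = p("mutations.tsv"),
    oncogenes = p("oncogenes.txt"), drugs = p("drugs.tsv"),
    rppa = p("rppa.tsv"),
    hits = if (dir.exists(file.path(dir, "hits"))) file.path(dir, "hits")
           else NULL,
    expr_dialect = dialect
  ))
}
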