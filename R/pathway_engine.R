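# Pathway essentialness: map screen hits onto KGML-derived gene graphs and
# score each pathway by how many hits it contains, what fraction of its
# measured genes are hits, and how directly the hit genes are linked to one
# another.
#
# The score is deliberately simple and isolated here so alternative
# weightings can be swapped in: restricted to the screen universe, each hit
# node g gets weight
#
#     w(g) = alpha + lambda * (hit neighbours of g) / max(1, degree(g)),
#
# the raw score is the sum of w over hit nodes, and the pathway score is
# raw * proportion, where proportion = n_hits / (pathway genes in the
# universe).  With alpha = lambda = 1 (defaults) a hit with an all-hit
# neighbourhood counts twice as much as an isolated hit.

.as_hit_genes <- function(hits) {
  if (is.data.frame(hits)) hits$gene[hits$is_hit] else as.character(hits)
}

#' Score the essentialness of one pathway
#'
#' @param graph A `pathway_graph` from [read_kgml()].
#' @param hits Hit-call data frame from [call_hits()] or a character vector
#'   of hit gene symbols.
#' @param universe Character vector of all genes measured in the screen;
#'   pathway genes outside it are ignored entirely.
#' @param alpha Base weight per hit node.  Default 1.
#' @param lambda Weight of the hit-neighbour fraction.  Default 1.
#' @return List (`pathway_score`) with `pathway_id`, `title`, `score`,
#'   `n_hits`, `proportion`.
#' @export
pathway_score <- function(graph, hits, universe, alpha = 1, lambda = 1) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (length(universe) == 0) stop("empty screen universe")
  hit_genes <- .as_hit_genes(hits)
  g <- .pathway_igraph(graph, universe = universe)
  nodes <- igraph::V(g)$name
  hit_nodes <- intersect(nodes, hit_genes)
  n_hits <- length(hit_nodes)
  proportion <- if (length(nodes) == 0) 0 else n_hits / length(nodes)
  score <- 0
  if (n_hits > 0) {
    deg <- igraph::degree(g)
    w <- vapply(hit_nodes, function(v) {
      nbrs <- igraph::neighbors(g, v)$name
      alpha + lambda * sum(nbrs %in% hit_nodes) / max(1, deg[[v]])
    }, numeric(1))
    score <- sum(w) * proportion
  }
  structure(
    list(pathway_id = graph$pathway_id, title = graph$title, score = score,
         n_hits = n_hits, proportion = proportion),
    class = "pathway_score"
  )
}

#' Rank all pathways within one cell line
#'
#' @param hits Hit calls for the cell line ([call_hits()] output or a hit
#'   gene vector).
#' @param graphs List of `pathway_graph` objects.
#' @param universe Genes measured in the screen.
#' @param alpha,lambda Scoring weights; see [pathway_score()].
#' @return Data frame `pathway_id`, `title`, `score`, `n_hits`,
#'   `proportion`, `rank`, sorted by score descending (ties by proportion
#'   descending, then pathway id).
#' @export
rank_pathways <- function(hits, graphs, universe, alpha = 1, lambda = 1) {
  stopifnot(length(graphs) >= 1)
  rows <- lapply(graphs, function(gr) {
    s <- pathway_score(gr, hits, universe, alpha = alpha, lambda = lambda)
    data.frame(pathway_id = s$pathway_id, title = s$title, score = s$score,
               n_hits = as.integer(s$n_hits), proportion = s$proportion,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, -out$proportion, out$pathway_id), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank cell lines by their reliance on one pathway
#'
#' Scores the pathway under each cell line's hit set and sorts lines by that
#' score; `rank_in_line` is the pathway's position within the line's own
#' full pathway ranking over `graphs`.
#'
#' @param graph The pathway of interest (must be among `graphs`).
#' @param hit_sets Named list: cell line -> hit calls or hit gene vector.
#' @param graphs All pathway graphs used for the within-line ranking.
#' @param universe Genes measured in the screen.
#' @param alpha,lambda Scoring weights; see [pathway_score()].
#' @return Data frame `cell_line`, `rank_in_line`, `score`, sorted by score
#'   descending, ties alphabetically by cell line.
#' @export
rank_cell_lines <- function(graph, hit_sets, graphs = list(graph), universe,
                            alpha = 1, lambda = 1) {
  stopifnot(inherits(graph, "pathway_graph"), length(hit_sets) >= 1)
  if (!any(vapply(graphs, function(g) identical(g$pathway_id,
                                                graph$pathway_id),
                  logical(1)))) {
    stop("graph '", graph$pathway_id, "' is not among the supplied graphs")
  }
  rows <- lapply(names(hit_sets), function(cl) {
    ranking <- rank_pathways(hit_sets[[cl]], graphs, universe,
                             alpha = alpha, lambda = lambda)
    i <- match(graph$pathway_id, ranking$pathway_id)
    data.frame(cell_line = cl, rank_in_line = ranking$rank[i],
               score = ranking$score[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$cell_line), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a pathway's screen hits for map export
#'
#' One annotation per hit gene present in the pathway graph, carrying the
#' screen rank, the expression value (when a store is supplied), the mapped
#' drugs, and a red colour intensity in [0, 1]: the rank-1 hit gets 1 and
#' intensity falls linearly with rank across the screen,
#' `1 - (rank - 1) / (n_screen_genes - 1)`, clipped to [0, 1].
#'
#' @param graph A `pathway_graph`.
#' @param hits Hit-call data frame from [call_hits()].
#' @param store Optional [omics_store()] supplying expression and drugs.
#' @param cell_line Cell line used for the expression lookup.
#' @param n_screen_genes Number of genes scored in the screen; defaults to
#'   `nrow(hits)`.
#' @return Data frame `gene`, `rank`, `expression_lfc`, `drugs`,
#'   `intensity`, sorted by rank.
#' @export
map_hits_to_pathway <- function(graph, hits, store = NULL, cell_line = NULL,
                                n_screen_genes = nrow(hits)) {
  stopifnot(inherits(graph, "pathway_graph"), is.data.frame(hits))
  h <- hits[hits$is_hit & hits$gene %in% graph$genes, , drop = FALSE]
  intensity <- if (n_screen_genes > 1) {
    pmin(1, pmax(0, 1 - (h$rank - 1) / (n_screen_genes - 1)))
  } else {
    rep(1, nrow(h))
  }
  out <- data.frame(
    gene = h$gene,
    rank = h$rank,
    expression_lfc = if (!is.null(store) && !is.null(cell_line)) {
      vapply(h$gene, function(g) {
        .store_lookup(store$expr, cell_line, g, "expression_lfc")
      }, numeric(1))
    } else rep(NA_real_, nrow(h)),
    drugs = if (!is.null(store)) {
      vapply(h$gene, function(g) .gene_drugs(store, g), character(1))
    } else rep(NA_character_, nrow(h)),
    intensity = intensity,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
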