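make_graph <- function(genes, edges = NULL) {
  structure(list(
    pathway_id = "path:test1", title = "test",
    genes = genes,
    edges = if (is.null(edges)) {
      matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
    } else edges,
    empty = length(genes) == 0), class = "pathway_graph")
}

test_that("the essentialness score matches its hand-evaluated formula", {
  genes <- c("A", "B", "C", "D")
  g0 <- make_graph(genes)                                # no edges
  s <- pathway_score(g0, hits = c("A", "B"), universe = genes)
  expect_equal(s$n_hits, 2)
  expect_equal(s$proportion, 0.5)
  expect_equal(s$score, 2 * (1 + 0) * 0.5)               # = 1.0

  g1 <- make_graph(genes, cbind(from = "A", to = "B"))   # hits now adjacent
  s1 <- pathway_score(g1, hits = c("A", "B"), universe = genes)
  expect_equal(s1$score, 2 * (1 + 1) * 0.5)              # = 2.0 > 1.0

  s_none <- pathway_score(g1, hits = character(0), universe = genes)
  expect_equal(s_none$score, 0)
  expect_equal(s_none$proportion, 0)

  expect_error(pathway_score(g1, "A", universe = character(0)), "universe")
})

test_that("score properties hold on random toy KGML graphs", {
  for (seed in 1:30) {
    path <- tempfile(fileext = ".xml")
    kg <- make_toy_kgml(path, n_nodes = 10, density = 0.3,
                        multi_gene_entry_frac = 0.3, seed = seed)
    g <- read_kgml(path)
    unlink(path)
    universe <- kg$genes
    set.seed(seed + 1000)
    hits2 <- sample(universe, 5)
    hits1 <- hits2[1:2]

    s1 <- pathway_score(g, hits1, universe)
    s2 <- pathway_score(g, hits2, universe)
    expect_lte(s1$score, s2$score)                   # monotone in hits
    expect_identical(s1$score == 0, s1$n_hits == 0)  # zero iff no hits
    expect_identical(s2$score == 0, s2$n_hits == 0)

    # genes outside the universe never affect the score
    s_extra <- pathway_score(g, c(hits2, "NOT_IN_UNIVERSE"), universe)
    expect_equal(s_extra$score, s2$score)
    half <- universe[1:5]
    s_half <- pathway_score(g, hits2, half)
    expect_equal(s_half$n_hits, length(intersect(hits2, half)))
    expect_lte(s_half$proportion, 1)
  }
})

test_that("linking two isolated hit genes strictly raises the score", {
  genes <- sprintf("N%d", 1:6)
  edges <- cbind(from = c("N3", "N4"), to = c("N4", "N5"))
  g_apart <- make_graph(genes, edges)
  g_linked <- make_graph(genes, rbind(edges, c("N1", "N2")))
  hits <- c("N1", "N2")
  expect_gt(pathway_score(g_linked, hits, genes)$score,
            pathway_score(g_apart, hits, genes)$score)

  # an edge between two non-hit nodes leaves hit weights untouched here
  g_nonhit <- make_graph(genes, rbind(edges, c("N5", "N6")))
  expect_equal(pathway_score(g_nonhit, hits, genes)$score,
               pathway_score(g_apart, hits, genes)$score)
})

test_that("pathway ranking is a descending sort with stable ties", {
  genes <- sprintf("N%d", 1:8)
  graphs <- lapply(1:50, function(i) {
    set.seed(i)
    gs <- sample(genes, sample(3:8, 1))
    gr <- make_graph(gs)
    gr$pathway_id <- sprintf("path:p%02d", i)
    gr
  })
  set.seed(123)
  hits <- sample(genes, 3)
  ranked <- rank_pathways(hits, graphs, genes)
  expect_equal(ranked$rank, 1:50)
  expect_equal(order(-ranked$score, -ranked$proportion, ranked$pathway_id),
               1:50)

  single <- rank_pathways(hits, graphs[1], genes)
  expect_equal(single$rank, 1L)

  # adding a hit belonging to one pathway never lowers that pathway's score
  target <- graphs[[5]]
  extra <- setdiff(target$genes, hits)[1]
  if (!is.na(extra)) {
    before <- ranked$score[ranked$pathway_id == target$pathway_id]
    after <- rank_pathways(c(hits, extra), graphs, genes)
    expect_gte(after$score[after$pathway_id == target$pathway_id], before)
  }
})

test_that("cell lines rank by pathway reliance with consistent in-line ranks", {
  genes <- sprintf("N%d", 1:10)
  g1 <- make_graph(genes[1:5]); g1$pathway_id <- "path:a"
  g2 <- make_graph(genes[4:10]); g2$pathway_id <- "path:b"
  graphs <- list(g1, g2)
  hit_sets <- list(
    lineA = genes[1:4],      # heavy in path:a
    lineB = genes[8:10],     # only in path:b
    lineC = character(0)
  )
  rows <- rank_cell_lines(g1, hit_sets, graphs, genes)
  expect_equal(rows$cell_line[1], "lineA")       # hit-bearing line first
  expect_equal(rows$score[rows$cell_line == "lineC"], 0)

  # rank_in_line agrees with the line's own full ranking
  for (cl in names(hit_sets)) {
    own <- rank_pathways(hit_sets[[cl]], graphs, genes)
    expect_equal(rows$rank_in_line[rows$cell_line == cl],
                 own$rank[own$pathway_id == "path:a"])
  }

  # identical hit sets -> identical scores, alphabetical order
  same <- rank_cell_lines(g1, list(zeb = genes[1:3], alp = genes[1:3]),
                          graphs, genes)
  expect_equal(same$score[1], same$score[2])
  expect_equal(same$cell_line, c("alp", "zeb"))

  expect_error(rank_cell_lines(make_graph("X"), hit_sets, graphs, genes),
               "not among")
})

test_that("hit annotations join rank, expression, drugs and intensity", {
  g <- make_graph(c("A", "B", "C"))
  hits <- data.frame(
    gene = c("A", "B", "D", "C"),
    quant_log = c(5, 4, 3, 1),
    rank = c(1L, 2L, 3L, 4L),
    is_hit = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  ann <- map_hits_to_pathway(g, hits, n_screen_genes = 15000)
  expect_equal(ann$gene, c("A", "B"))            # C not a hit, D not in graph
  expect_equal(ann$intensity[1], 1.0)            # rank-1 hit is darkest
  expect_equal(ann$intensity[2], 1 - 1 / 14999)

  none <- map_hits_to_pathway(g, hits[hits$gene == "D", ])
  expect_equal(nrow(none), 0L)

  # join oracle over a 5-hit fixture with store-backed columns
  st <- toy_store(cell_line = "L", all_genes = sprintf("A%d", 1:6),
                  hit_genes = sprintf("A%d", 1:5),
                  expr = setNames(seq(0.1, 0.6, by = 0.1),
                                  sprintf("A%d", 1:6)),
                  drugs = data.frame(gene = "A2", drug = "drugX",
                                     stringsAsFactors = FALSE))
  g5 <- make_graph(sprintf("A%d", c(1:3, 6)))
  ann5 <- map_hits_to_pathway(g5, st$hits$L, store = st, cell_line = "L")
  hit_tbl <- st$hits$L
  manual <- intersect(hit_tbl$gene[hit_tbl$is_hit], g5$genes)
  expect_setequal(ann5$gene, manual)
  expect_equal(ann5$drugs[ann5$gene == "A2"], "drugX")
  expect_equal(ann5$expression_lfc[ann5$gene == "A3"], 0.3)
})
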