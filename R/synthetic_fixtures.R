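# Seeded generators for every input the toolkit consumes: screens with
# planted essential genes, omics stores with planted drivers, toy KGML
# pathways with known topology, and dose-response curves with known IC50.
# Each generator is a pure function of its parameters (seed included) and
# returns the ground truth beside the data.

.with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a pooled shRNA dropout screen
#'
#' Reference counts are negative-binomial (pooled-screen reads are
#' overdispersed relative to Poisson); final counts share the noise model
#' but essential genes have their expected final count divided by
#' `2^effect_log2` for all of their hairpins, optionally jittered per
#' hairpin to emulate unequal knock-down efficacy.
#'
#' @param n_genes Number of genes.
#' @param shrnas_per_gene Hairpins per gene.
#' @param frac_essential Fraction of genes planted as essential, in [0, 1).
#' @param effect_log2 Log2 depletion effect applied to essential genes
#'   (>= 0).
#' @param depth Mean reference read count per hairpin.  Default 500.
#' @param dispersion Negative-binomial size parameter; smaller is more
#'   overdispersed.  Default 10.
#' @param jitter_sd Per-hairpin sd of the effect (log2), truncated at 0.
#'   Default 0.
#' @param seed Integer seed (required).
#' @return List with `counts` (data frame `shrna_id`, `gene`, `count_ref`,
#'   `count_final`) and `truth` (essential gene set, per-hairpin effects,
#'   generator parameters).
#' @export
simulate_screen <- function(n_genes, shrnas_per_gene, frac_essential,
                            effect_log2, depth = 500, dispersion = 10,
                            jitter_sd = 0, seed) {
  stopifnot(n_genes >= 1, shrnas_per_gene >= 1,
            frac_essential >= 0, frac_essential < 1, effect_log2 >= 0,
            depth > 0, dispersion > 0, jitter_sd >= 0)
  .with_seed(seed, {
    genes <- sprintf("G%0*d", nchar(n_genes), seq_len(n_genes))
    n_ess <- round(n_genes * frac_essential)
    essential <- sort(sample(genes, n_ess))
    gene_col <- rep(genes, each = shrnas_per_gene)
    shrna_id <- paste0(gene_col, "_sh", seq_len(shrnas_per_gene))
    n <- length(gene_col)
    effect <- ifelse(gene_col %in% essential, effect_log2, 0)
    if (jitter_sd > 0) {
      effect <- ifelse(effect > 0,
                       pmax(0, effect + stats::rnorm(n, 0, jitter_sd)),
                       effect)
    }
    counts <- data.frame(
      shrna_id = shrna_id,
      gene = gene_col,
      count_ref = stats::rnbinom(n, mu = depth, size = dispersion),
      count_final = stats::rnbinom(n, mu = depth * 2^(-effect),
                                   size = dispersion),
      stringsAsFactors = FALSE
    )
    list(
      counts = counts,
      truth = list(
        essential = essential,
        effect = stats::setNames(effect, shrna_id),
        params = list(n_genes = n_genes, shrnas_per_gene = shrnas_per_gene,
                      frac_essential = frac_essential,
                      effect_log2 = effect_log2, depth = depth,
                      dispersion = dispersion, jitter_sd = jitter_sd,
                      seed = seed)
      )
    )
  })
}

#' Simulate an omics store with planted drivers
#'
#' Each cell line gets a planted driver set constructed to satisfy all three
#' signature predicates at the default thresholds: amplified (log2 ratio in
#' [1, 4.5]) and/or carrying a recurrent mutation (COSMIC count >= 10,
#' hotspot), annotated as an oncogene, over-expressed, and a screen hit.
#' Decoys exercise the set logic: altered annotated oncogenes that are not
#' hits (candidate-only), altered hit genes that are not oncogenes
#' (overall-only), non-altered oncogenes, background low-recurrence
#' mutations (COSMIC <= 5, dropped by the filter) and background copy
#' numbers clipped below the amplification cut.  A drug map covers every
#' driver and a sample of other genes.
#'
#' @param n_lines Number of cell lines.
#' @param n_genes Genes in the universe.
#' @param drivers_per_line Planted drivers per line.
#' @param driver_genes Optional character vector of driver symbols for line
#'   1 (added to the universe if absent); remaining lines sample their own.
#' @param n_decoys Candidate-only and overall-only decoys per line.
#'   Default 2 each.
#' @param hit_frac Fraction of genes called hits per line.  Default 0.1.
#' @param cell_lines Optional cell-line names (default `CL01`, ...).
#' @param seed Integer seed (required).
#' @return List with `store` (an [omics_store()]) and `truth` (per-line
#'   drivers, candidate-only and overall-only decoy sets, hit sets).
#' @export
simulate_omics <- function(n_lines = 1, n_genes = 200, drivers_per_line = 3,
                           driver_genes = NULL, n_decoys = 2,
                           hit_frac = 0.1, cell_lines = NULL, seed) {
  stopifnot(n_lines >= 1, drivers_per_line >= 0,
            drivers_per_line + 2 * n_decoys <= n_genes)
  .with_seed(seed, {
    genes <- sprintf("GENE%0*d", nchar(n_genes), seq_len(n_genes))
    if (!is.null(driver_genes)) {
      genes <- unique(c(driver_genes, genes))[seq_len(max(n_genes,
                                                          length(driver_genes)))]
    }
    if (is.null(cell_lines)) {
      cell_lines <- sprintf("CL%02d", seq_len(n_lines))
    }
    stopifnot(length(cell_lines) == n_lines)

    cna <- expr <- mut <- NULL
    hits <- list()
    truth <- list()
    oncogenes <- character(0)
    drug_rows <- list()
    drug_pool <- sprintf("drug-%02d", 1:40)

    for (li in seq_len(n_lines)) {
      cl <- cell_lines[li]
      pool <- genes
      drivers <- if (li == 1 && !is.null(driver_genes)) {
        driver_genes
      } else if (drivers_per_line > 0) {
        sort(sample(pool, drivers_per_line))
      } else {
        character(0)
      }
      pool <- setdiff(pool, drivers)
      cand_only <- sort(sample(pool, n_decoys))     # altered oncogene, no hit
      pool <- setdiff(pool, cand_only)
      over_only <- sort(sample(pool, n_decoys))     # altered hit, no oncogene
      pool <- setdiff(pool, over_only)
      plain_onco <- sort(sample(pool, n_decoys))    # oncogene, unaltered

      n_hits <- max(length(drivers) + length(over_only),
                    round(length(genes) * hit_frac))
      extra_hits <- sample(setdiff(genes, c(drivers, over_only, cand_only)),
                           n_hits - length(drivers) - length(over_only))
      hit_genes <- c(drivers, over_only, extra_hits)

      # Screen table: hits share a high-score block so ranks are contiguous.
      quant_log <- stats::rnorm(length(genes), 0, 0.5)
      names(quant_log) <- genes
      quant_log[hit_genes] <- stats::runif(length(hit_genes), 3, 6)
      ord <- order(-quant_log, names(quant_log))
      hits[[cl]] <- data.frame(
        gene = names(quant_log)[ord],
        quant_log = as.numeric(quant_log[ord]),
        rank = seq_along(genes),
        is_hit = names(quant_log)[ord] %in% hit_genes,
        stringsAsFactors = FALSE
      )

      altered <- c(drivers, cand_only, over_only)
      amp <- pmin(stats::rnorm(length(genes), 0, 0.15), 0.6)
      names(amp) <- genes
      amp[altered] <- stats::runif(length(altered), 1.0, 4.5)
      cna <- rbind(cna, data.frame(cell_line = cl, gene = genes,
                                   dna_amp = as.numeric(amp),
                                   stringsAsFactors = FALSE))

      lfc <- stats::rnorm(length(genes), 0, 0.3)
      names(lfc) <- genes
      lfc[drivers] <- stats::runif(length(drivers), 1, 3)
      expr <- rbind(expr, data.frame(cell_line = cl, gene = genes,
                                     expression_lfc = as.numeric(lfc),
                                     stringsAsFactors = FALSE))

      # Recurrent (retained) mutations on a subset of drivers; background
      # low-recurrence mutations that the COSMIC filter must drop.
      mut_drivers <- drivers[seq_len(ceiling(length(drivers) / 2))]
      bg_genes <- sample(setdiff(genes, altered), n_decoys)
      mut <- rbind(
        mut,
        if (length(mut_drivers) > 0) {
          data.frame(cell_line = cl, gene = mut_drivers,
                     protein_change = paste0(mut_drivers, "p.H1047R"),
                     cosmic_occurrences = sample(10:2000,
                                                 length(mut_drivers)),
                     hotspot = TRUE, stringsAsFactors = FALSE)
        },
        data.frame(cell_line = cl, gene = bg_genes,
                   protein_change = paste0(bg_genes, "p.A1B"),
                   cosmic_occurrences = sample(0:5, length(bg_genes),
                                               replace = TRUE),
                   hotspot = FALSE, stringsAsFactors = FALSE)
      )

      oncogenes <- c(oncogenes, drivers, cand_only, plain_onco)
      for (g in c(drivers, sample(extra_hits,
                                  min(3, length(extra_hits))))) {
        drug_rows[[length(drug_rows) + 1L]] <- data.frame(
          gene = g, drug = sample(drug_pool, sample(1:2, 1)),
          stringsAsFactors = FALSE)
      }
      truth[[cl]] <- list(drivers = sort(drivers),
                          candidate_only = cand_only,
                          overall_only = over_only,
                          hits = sort(hit_genes))
    }
    drugs <- unique(do.call(rbind, drug_rows))
    rownames(drugs) <- NULL
    store <- omics_store(
      cna = cna, expr = expr, mutations = mut,
      oncogenes = sort(unique(oncogenes)), drugs = drugs, hits = hits,
      expr_dialect = "vs_normal"
    )
    list(store = store, truth = truth)
  })
}

#' Write a toy KGML pathway file with known topology
#'
#' Generates a valid KGML document whose gene entries and relations expand,
#' under [read_kgml()], to a requested gene graph.  With
#' `multi_gene_entry_frac > 0` some entries carry several gene identifiers
#' and a relation touching such an entry fans out to all of its genes.  One
#' `map`-type entry is always included so readers must filter non-gene
#' entries.
#'
#' @param path Output file path.
#' @param n_nodes Number of gene nodes (>= 1).
#' @param edges Optional two-column matrix of gene indices (1-based) for an
#'   explicit entry-level edge list.
#' @param density When `edges` is NULL, probability of a relation between
#'   each entry pair.  Default 0.2.
#' @param multi_gene_entry_frac Fraction of entries carrying 2-3 genes.
#'   Default 0.
#' @param pathway_id,title Pathway metadata.
#' @param seed Integer seed (required).
#' @return List with `path`, `genes`, `edges` (expected gene-level edge
#'   matrix after expansion) and `entries` (entry id -> gene vector).
#' @export
make_toy_kgml <- function(path, n_nodes, edges = NULL, density = 0.2,
                          multi_gene_entry_frac = 0,
                          pathway_id = "path:toy00001",
                          title = "toy pathway", seed) {
  stopifnot(n_nodes >= 1)
  .with_seed(seed, {
    genes <- sprintf("TG%0*d", nchar(n_nodes), seq_len(n_nodes))
    # Partition genes into entries.
    entries <- list()
    i <- 1
    while (i <= n_nodes) {
      k <- if (multi_gene_entry_frac > 0 &&
               stats::runif(1) < multi_gene_entry_frac) {
        min(sample(2:3, 1), n_nodes - i + 1)
      } else 1
      entries[[length(entries) + 1L]] <- genes[i:(i + k - 1)]
      i <- i + k
    }
    names(entries) <- as.character(seq_along(entries))
    m <- length(entries)
    # Entry-level relations.
    if (is.null(edges)) {
      rel <- list()
      if (m >= 2) {
        for (a in seq_len(m - 1)) {
          for (b in (a + 1):m) {
            if (stats::runif(1) < density) {
              rel[[length(rel) + 1L]] <- c(a, b)
            }
          }
        }
      }
    } else {
      stopifnot(multi_gene_entry_frac == 0)   # explicit edges are per-gene
      rel <- lapply(seq_len(nrow(edges)), function(r) as.numeric(edges[r, ]))
    }

    lines <- c(
      '<?xml version="1.0"?>',
      sprintf('<pathway name="%s" org="hsa" number="1" title="%s">',
              pathway_id, title)
    )
    for (eid in names(entries)) {
      lines <- c(lines, sprintf(
        '  <entry id="%s" name="%s" type="gene"><graphics name="%s"/></entry>',
        eid, paste0("hsa:", entries[[eid]], collapse = " "),
        paste(entries[[eid]], collapse = ", ")))
    }
    map_id <- as.character(m + 1L)
    lines <- c(lines, sprintf(
      '  <entry id="%s" name="path:hsa01100" type="map"/>', map_id))
    for (r in rel) {
      lines <- c(lines, sprintf(
        '  <relation entry1="%d" entry2="%d" type="PPrel"><subtype name="activation" value="--&gt;"/></relation>',
        r[1], r[2]))
    }
    lines <- c(lines, "</pathway>")
    writeLines(lines, path)

    # Expected gene-level edges after expansion.
    exp_edges <- matrix(character(0), ncol = 2,
                        dimnames = list(NULL, c("from", "to")))
    if (length(rel) > 0) {
      pairs <- do.call(rbind, lapply(rel, function(r) {
        expand.grid(from = entries[[r[1]]], to = entries[[r[2]]],
                    stringsAsFactors = FALSE)
      }))
      pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
      if (nrow(pairs) > 0) {
        a <- pmin(pairs$from, pairs$to)
        b <- pmax(pairs$from, pairs$to)
        keep <- !duplicated(paste(a, b, sep = "\r"))
        exp_edges <- cbind(from = a[keep], to = b[keep])
      }
    }
    list(path = path, genes = genes, edges = exp_edges, entries = entries)
  })
}

#' Simulate a dose-response curve from a four-parameter logistic
#'
#' `y(c) = floor + (top - floor) / (1 + (c / ic50)^hill)` plus Gaussian
#' noise truncated at 0.  At `c = ic50` the noiseless response is exactly
#' midway between `top` and `floor`.
#'
#' @param ic50 True midpoint concentration (uM, > 0).
#' @param hill Hill slope.  Default 1.
#' @param floor Lower asymptote.  Default 0.
#' @param top Upper asymptote (untreated survival).  Default 1.
#' @param noise_sd Gaussian noise sd.  Default 0.
#' @param concentrations Positive concentrations (uM); default 9 log-spaced
#'   points spanning `ic50 / 100` to `ic50 * 100`.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return Data frame `concentration_uM`, `surviving_fraction`.
#' @export
simulate_dose_response <- function(ic50, hill = 1, floor = 0, top = 1,
                                   noise_sd = 0, concentrations = NULL,
                                   seed = NULL) {
  stopifnot(ic50 > 0, noise_sd >= 0)
  if (is.null(concentrations)) {
    concentrations <- 10^seq(log10(ic50) - 2, log10(ic50) + 2,
                             length.out = 9)
  }
  stopifnot(all(concentrations > 0))
  y <- floor + (top - floor) / (1 + (concentrations / ic50)^hill)
  if (noise_sd > 0) {
    y <- .with_seed(seed, pmax(0, y + stats::rnorm(length(y), 0, noise_sd)))
  }
  data.frame(concentration_uM = concentrations, surviving_fraction = y)
}
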