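# Gene-level essentiality scoring for pooled shRNA dropout screens.
#
# Per-shRNA fold depletion is (count_ref + c) / (count_final + c); the gene
# score is the 80th percentile of the gene's log2 depletion scores.  The
# null is a normal distribution fitted robustly to the gene-score
# population: mean = median, sd = (q97.5 - q2.5) / 4, and a gene is a hit
# when its score exceeds the null's 95th percentile.

# Standard-normal 95th percentile, pinned to 4 decimals for reproducibility.
.Z95 <- 1.6449

#' Per-shRNA depletion scores
#'
#' @param counts Data frame with `shrna_id`, `gene`, `count_ref`,
#'   `count_final` (see [read_count_table()]).
#' @param pseudocount Non-negative value added to both counts before taking
#'   the ratio; must be positive whenever any `count_final` is zero.
#'   Default 1.
#' @return Data frame `shrna_id`, `gene`, `fold_depletion`, `log_depletion`
#'   (log2), one row per shRNA, input order preserved.
#' @export
compute_depletion_scores <- function(counts, pseudocount = 1) {
  stopifnot(is.data.frame(counts), pseudocount >= 0)
  zero_final <- counts$count_final == 0
  if (pseudocount == 0 && any(zero_final)) {
    stop("count_final is 0 for shRNA '", counts$shrna_id[which(zero_final)[1]],
         "' and pseudocount is 0; use a positive pseudocount")
  }
  fold <- (counts$count_ref + pseudocount) / (counts$count_final + pseudocount)
  data.frame(
    shrna_id = counts$shrna_id,
    gene = counts$gene,
    fold_depletion = fold,
    log_depletion = log2(fold),
    stringsAsFactors = FALSE
  )
}

#' Gene-level quantile scores
#'
#' Summarises each gene's per-shRNA log depletion scores by their 80th
#' percentile (linear interpolation between order statistics, the type-7
#' convention), which is insensitive to the varying number of hairpins per
#' gene.  Genes are ranked by descending score, ties broken lexicographically
#' by gene symbol; rank 1 is the most depleted gene.
#'
#' @param depletions Data frame from [compute_depletion_scores()].
#' @param min_shrnas Minimum hairpins per gene; genes with fewer are not
#'   scored and are listed in the `skipped` attribute.  Default 2.
#' @param probs Quantile level of the gene score.  Default 0.8.
#' @return Data frame `gene`, `quant_log`, `n_shrnas`, `rank`, sorted by
#'   rank, with attribute `skipped` (character vector of unscored genes).
#' @export
gene_quantile_scores <- function(depletions, min_shrnas = 2, probs = 0.8) {
  if (!is.data.frame(depletions) || nrow(depletions) == 0) {
    stop("no depletion scores supplied")
  }
  by_gene <- split(depletions$log_depletion, depletions$gene)
  n <- lengths(by_gene)
  skipped <- names(by_gene)[n < min_shrnas]
  by_gene <- by_gene[n >= min_shrnas]
  if (length(by_gene) == 0) stop("no gene has >= ", min_shrnas, " shRNAs")
  scores <- data.frame(
    gene = names(by_gene),
    quant_log = vapply(by_gene, stats::quantile, numeric(1), probs = probs,
                       type = 7, names = FALSE),
    n_shrnas = lengths(by_gene),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ord <- order(-scores$quant_log, scores$gene)
  scores <- scores[ord, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  attr(scores, "skipped") <- skipped
  scores
}

.score_values <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot("quant_log" %in% names(scores))
    scores$quant_log
  } else {
    as.numeric(scores)
  }
}

#' Fit the robust normal null model for gene scores
#'
#' Assumes the large majority of genes are not depleted and their scores are
#' normal: the null mean is the score median, the null sd is the 2.5--97.5
#' inter-quantile range divided by 4 (95% of a normal lies within about two
#' sd of its mean), and the hit threshold is the null's 95th percentile,
#' `mu + 1.6449 * sigma`.
#'
#' @param scores Gene-score data frame from [gene_quantile_scores()], or a
#'   bare numeric vector of gene scores.
#' @param lower,upper Quantile levels defining the robust sd.  Defaults
#'   0.025 and 0.975.
#' @param hit_quantile Null percentile used as the hit cut.  Default 0.95
#'   (its standard-normal quantile is pinned to 1.6449 at the default; other
#'   levels use [stats::qnorm()]).
#' @return A `null_model`: list with `mu`, `sigma`, `threshold`, `n_genes`.
#' @export
fit_null_model <- function(scores, lower = 0.025, upper = 0.975,
                           hit_quantile = 0.95) {
  x <- .score_values(scores)
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite gene scores")
  if (length(x) < 40) {
    warning("null model fitted on ", length(x),
            " genes; the tail quantiles are poorly determined below 40")
  }
  mu <- stats::median(x)
  qs <- stats::quantile(x, c(lower, upper), type = 7, names = FALSE)
  sigma <- (qs[2] - qs[1]) / 4
  if (sigma <= 0) {
    stop("degenerate null: all gene scores are (effectively) equal")
  }
  z <- if (identical(hit_quantile, 0.95)) .Z95 else stats::qnorm(hit_quantile)
  structure(
    list(mu = mu, sigma = sigma, threshold = mu + z * sigma,
         n_genes = length(x)),
    class = "null_model"
  )
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf(
    "null_model: mu = %.4f, sigma = %.4f, hit threshold = %.4f (%d genes)\n",
    x$mu, x$sigma, x$threshold, x$n_genes))
  invisible(x)
}

#' Call screen hits against a fitted null
#'
#' A gene is a hit when its quantile score is strictly greater than the null
#' threshold, so hits occupy a contiguous top block of ranks.
#'
#' @param scores Gene-score data frame from [gene_quantile_scores()] or a
#'   numeric vector (gene names taken from `names()` or generated).
#' @param null A `null_model` from [fit_null_model()], fitted on the same
#'   score population.
#' @return Data frame `gene`, `quant_log`, `rank`, `is_hit`, sorted by rank.
#' @export
call_hits <- function(scores, null) {
  stopifnot(inherits(null, "null_model"))
  if (!is.data.frame(scores)) {
    x <- as.numeric(scores)
    nm <- names(scores)
    if (is.null(nm)) nm <- sprintf("G%0*d", nchar(length(x)), seq_along(x))
    scores <- data.frame(gene = nm, quant_log = x, stringsAsFactors = FALSE)
    ord <- order(-scores$quant_log, scores$gene)
    scores <- scores[ord, , drop = FALSE]
    scores$rank <- seq_len(nrow(scores))
  }
  out <- data.frame(
    gene = scores$gene,
    quant_log = scores$quant_log,
    rank = as.integer(scores$rank),
    is_hit = scores$quant_log > null$threshold,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hit count diagnostic: shRNAs above the cut per called hit
#'
#' For each called hit, counts how many of the gene's individual shRNA log
#' depletion scores lie above the hit threshold.  In deeply depleted genes
#' all hairpins typically clear the cut; borderline hits may clear it on a
#' single strong hairpin because the interpolated gene quantile can exceed a
#' level that only the top order statistic exceeds.
#'
#' @param hits Hit-call data frame from [call_hits()].
#' @param depletions Per-shRNA scores from [compute_depletion_scores()].
#' @param null The fitted `null_model`.
#' @return Data frame `gene`, `rank`, `n_shrnas_above_cut` for hit genes.
#' @export
hit_shrna_support <- function(hits, depletions, null) {
  stopifnot(inherits(null, "null_model"))
  hit_genes <- hits$gene[hits$is_hit]
  by_gene <- split(depletions$log_depletion, depletions$gene)
  data.frame(
    gene = hit_genes,
    rank = hits$rank[hits$is_hit],
    n_shrnas_above_cut = vapply(
      by_gene[hit_genes], function(x) sum(x > null$threshold), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Hit calls from CERES gene-effect scores
#'
#' CRISPR gene effects estimated by CERES are more negative for more
#' essential genes; a gene is a hit when its score is at or below the
#' threshold (inclusive), -0.5 by default.
#'
#' @param records Named numeric vector (gene -> CERES score) or data frame
#'   with columns `gene` and `ceres`.
#' @param threshold Hit cut, inclusive.  Default -0.5.
#' @return Data frame `gene`, `ceres`, `is_hit`.
#' @export
ceres_hits <- function(records, threshold = -0.5) {
  if (is.data.frame(records)) {
    stopifnot(all(c("gene", "ceres") %in% names(records)))
    gene <- records$gene
    ceres <- records$ceres
  } else {
    gene <- names(records)
    ceres <- as.numeric(records)
    if (is.null(gene)) stop("records must be named or a data frame")
  }
  if (any(!is.finite(ceres))) {
    stop("non-finite CERES score for gene '", gene[which(!is.finite(ceres))[1]],
         "'")
  }
  data.frame(gene = gene, ceres = ceres, is_hit = ceres <= threshold,
             stringsAsFactors = FALSE)
}
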