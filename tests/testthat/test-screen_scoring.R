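test_that("depletion scores follow (ref + c) / (final + c) on log2 scale", {
  counts <- data.frame(shrna_id = c("a", "b"), gene = c("G1", "G1"),
                       count_ref = c(100L, 400L), count_final = c(100L, 50L),
                       stringsAsFactors = FALSE)
  dep <- compute_depletion_scores(counts, pseudocount = 0)
  expect_equal(dep$fold_depletion[1], 1.0)
  expect_equal(dep$log_depletion[1], 0.0)

  dep <- compute_depletion_scores(counts, pseudocount = 1)
  expect_equal(dep$fold_depletion[2], 401 / 51)
  expect_equal(dep$log_depletion[2], log2(401 / 51))
  expect_equal(dep$log_depletion[2], 2.9750, tolerance = 1e-4)

  counts$count_final[2] <- 0L
  expect_error(compute_depletion_scores(counts, pseudocount = 0), "'b'")
  expect_silent(compute_depletion_scores(counts, pseudocount = 1))
})

test_that("gene quantile scores interpolate, rank and skip sparse genes", {
  dep <- data.frame(
    shrna_id = sprintf("sh%d", 1:9),
    gene = c(rep("A", 5), rep("B", 3), "C"),
    log_depletion = c(0, 1, 2, 3, 4, 1, 1, 1, 9),
    stringsAsFactors = FALSE
  )
  sc <- gene_quantile_scores(dep, min_shrnas = 2)
  expect_equal(sc$quant_log[sc$gene == "A"], 3.2)  # interpolated 80th pct
  expect_equal(sc$quant_log[sc$gene == "B"], 1.0)  # constant list
  expect_equal(attr(sc, "skipped"), "C")           # single-hairpin gene
  expect_equal(sc$rank[order(sc$gene)], c(1L, 2L)) # A(3.2) above B(1.0)

  # ties broken lexicographically by symbol
  dep2 <- data.frame(shrna_id = sprintf("s%d", 1:4),
                     gene = c("ZZZ", "ZZZ", "AAA", "AAA"),
                     log_depletion = c(2, 2, 2, 2), stringsAsFactors = FALSE)
  sc2 <- gene_quantile_scores(dep2)
  expect_equal(sc2$gene, c("AAA", "ZZZ"))
  expect_equal(sc2$rank, c(1L, 2L))

  expect_error(gene_quantile_scores(dep[0, ]), "no depletion")
})

test_that("quantile scores match a brute-force interpolation oracle", {
  set.seed(42)
  dep <- do.call(rbind, lapply(1:1000, function(i) {
    n <- sample(2:8, 1)
    data.frame(shrna_id = sprintf("g%d_s%d", i, 1:n),
               gene = sprintf("g%04d", i),
               log_depletion = rnorm(n, 0, 1.5), stringsAsFactors = FALSE)
  }))
  sc <- gene_quantile_scores(dep)
  by_gene <- split(dep$log_depletion, dep$gene)
  expected <- vapply(by_gene[sc$gene], oracle_quantile, numeric(1), p = 0.8)
  expect_equal(sc$quant_log, unname(expected), tolerance = 1e-12)
})

test_that("the null model matches its hand-computed and closed-form values", {
  nm <- suppressWarnings(fit_null_model(c(-2, -1, 0, 1, 2)))
  expect_equal(nm$mu, 0)
  expect_equal(nm$sigma, 0.95)          # (1.9 - (-1.9)) / 4
  expect_equal(nm$threshold, 1.6449 * 0.95)

  set.seed(99)
  big <- fit_null_model(rnorm(1e6))
  expect_equal(big$mu, 0, tolerance = 0.01)
  # standard normal: q97.5 - q2.5 = 3.9199, so sigma estimates ~0.980
  expect_equal(big$sigma, 0.980, tolerance = 0.005)

  expect_error(fit_null_model(rep(2, 100)), "degenerate")
})

test_that("hit calls use a strict cut and the expected false-positive rate", {
  scores <- data.frame(gene = c("A", "B"), quant_log = c(2, 1),
                       rank = 1:2, stringsAsFactors = FALSE)
  nm <- structure(list(mu = 0, sigma = 1, threshold = 2, n_genes = 2),
                  class = "null_model")
  h <- call_hits(scores, nm)
  expect_false(h$is_hit[h$gene == "A"])  # exactly at threshold: not a hit
  nm$threshold <- 1.99
  expect_true(call_hits(scores, nm)$is_hit[1])

  # 15,000 i.i.d. normal scores: expected hit fraction ~5.35% because the
  # inter-quantile sigma estimate is mildly biased low (P(Z > 1.612))
  set.seed(7)
  x <- rnorm(15000)
  h <- call_hits(x, fit_null_model(x))
  expect_gt(mean(h$is_hit), 0.040)
  expect_lt(mean(h$is_hit), 0.070)
  # hits occupy a contiguous top block of ranks
  expect_true(all(diff(h$is_hit) <= 0))
})

test_that("shift equivariance: a constant added to scores shifts the cut", {
  sim <- simulate_screen(300, 4, 0.05, 3, seed = 13)
  dep <- compute_depletion_scores(sim$counts)
  sc <- gene_quantile_scores(dep)
  nm <- fit_null_model(sc)
  h <- call_hits(sc, nm)

  dep2 <- dep
  dep2$log_depletion <- dep$log_depletion + 1.7
  sc2 <- gene_quantile_scores(dep2)
  nm2 <- fit_null_model(sc2)
  expect_equal(sc2$quant_log, sc$quant_log + 1.7, tolerance = 1e-12)
  expect_equal(nm2$mu, nm$mu + 1.7, tolerance = 1e-12)
  expect_equal(nm2$threshold, nm$threshold + 1.7, tolerance = 1e-12)
  expect_equal(call_hits(sc2, nm2)$is_hit, h$is_hit)
})

test_that("planted essential genes are recovered", {
  sim <- simulate_screen(2000, 5, 0.02, 4, seed = 3)
  dep <- compute_depletion_scores(sim$counts)
  sc <- gene_quantile_scores(dep)
  h <- call_hits(sc, fit_null_model(sc))
  recovered <- mean(sim$truth$essential %in% h$gene[h$is_hit])
  expect_gte(recovered, 0.95)
})

test_that("CERES hit rule is inclusive at the threshold", {
  rec <- ceres_hits(c(EGFR = -0.6, KRAS = -0.5, TP53 = 0.0, MYC = -0.49))
  expect_equal(rec$is_hit, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(ceres_hits(c(A = NaN)), "non-finite")
  df <- ceres_hits(data.frame(gene = "A", ceres = -1), threshold = -2)
  expect_false(df$is_hit)
})
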