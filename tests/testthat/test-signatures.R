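test_that("candidate keeps altered oncogenes regardless of hit status", {
  # HER2-amplified line in which ERBB2 is not a screen hit
  st <- toy_store(
    cell_line = "SUM190",
    all_genes = c("ERBB2", "PIK3CA", "BG1", "BG2"),
    hit_genes = "PIK3CA",
    cna = c(ERBB2 = 4.4293, PIK3CA = 0.0, BG1 = 4.0, BG2 = 0.1),
    expr = c(ERBB2 = 3.48529258, PIK3CA = 0.4, BG1 = 2.0, BG2 = 0.0),
    mutations = data.frame(
      cell_line = "SUM190", gene = "PIK3CA",
      protein_change = "PIK3CAp.H1047R", cosmic_occurrences = 1889L,
      hotspot = TRUE, stringsAsFactors = FALSE),
    oncogenes = c("ERBB2", "PIK3CA"),
    drugs = data.frame(gene = "ERBB2", drug = "Lapatinib",
                       stringsAsFactors = FALSE)
  )
  cand <- candidate_signature("SUM190", st)
  expect_setequal(cand$gene, c("ERBB2", "PIK3CA"))
  expect_false(cand$is_hit[cand$gene == "ERBB2"])
  expect_equal(cand$dna_amp[cand$gene == "ERBB2"], 4.4293)
  expect_equal(cand$mutation[cand$gene == "PIK3CA"], "PIK3CAp.H1047R")
  expect_equal(cand$cosmic_occurrences[cand$gene == "PIK3CA"], 1889L)
  # BG1 is amplified but not an annotated oncogene -> excluded
  expect_false("BG1" %in% cand$gene)
  # sorted by expression descending
  expect_equal(cand$gene[1], "ERBB2")

  over <- overall_signature("SUM190", st)
  expect_false("ERBB2" %in% over$gene)   # altered oncogene but not a hit
  expect_true("PIK3CA" %in% over$gene)   # altered + hit, oncogene or not

  fun <- functional_signature("SUM190", st)
  expect_equal(fun$gene, "PIK3CA")
})

test_that("a line planted with three druggable drivers recovers exactly them", {
  sim <- simulate_omics(n_lines = 1, n_genes = 120,
                        driver_genes = c("FGFR3", "PIK3CA", "BCL2L1"),
                        cell_lines = "SUM185", seed = 185)
  fun <- functional_signature("SUM185", sim$store)
  expect_setequal(fun$gene, c("FGFR3", "PIK3CA", "BCL2L1"))
  expect_true(all(fun$is_hit))
  expect_true(all(fun$gene %in% sim$store$drugs$gene))  # drivers druggable
})

test_that("signature set identities hold on random fixtures", {
  for (seed in 1:25) {
    sim <- simulate_omics(n_lines = 1, n_genes = 50, drivers_per_line = 3,
                          n_decoys = 2, seed = seed)
    st <- sim$store
    cl <- names(sim$truth)[1]
    cand <- candidate_signature(cl, st)$gene
    over <- overall_signature(cl, st)$gene
    fun <- functional_signature(cl, st)$gene
    expect_true(all(fun %in% cand))
    expect_true(all(fun %in% over))
    expect_setequal(fun, intersect(cand, over))
    expect_setequal(intersect(over, st$oncogenes), fun)
    expect_setequal(fun, sim$truth[[cl]]$drivers)
    # decoys land where the set logic says they must
    expect_true(all(sim$truth[[cl]]$candidate_only %in% setdiff(cand, over)))
    expect_true(all(sim$truth[[cl]]$overall_only %in% setdiff(over, cand)))
  }
})

test_that("enlarging the hit set never shrinks hit-gated signatures", {
  sim <- simulate_omics(n_lines = 1, n_genes = 60, drivers_per_line = 3,
                        seed = 31)
  st <- sim$store
  cl <- names(sim$truth)[1]
  before_over <- overall_signature(cl, st)$gene
  before_fun <- functional_signature(cl, st)$gene
  before_drug <- druggable_signature(cl, st)$gene
  st$hits[[cl]]$is_hit <- TRUE   # every gene a hit
  expect_true(all(before_over %in% overall_signature(cl, st)$gene))
  expect_true(all(before_fun %in% functional_signature(cl, st)$gene))
  expect_true(all(before_drug %in% druggable_signature(cl, st)$gene))
})

test_that("druggable signature is hits joined to the drug map, rank order", {
  st <- toy_store(
    cell_line = "SUM44",
    all_genes = c("KIF11", "MAP4K2", "CDK6", "BCL2", "PIK3CD", "NODRUG",
                  "NOTHIT"),
    hit_genes = c("KIF11", "MAP4K2", "CDK6", "BCL2", "PIK3CD", "NODRUG"),
    drugs = data.frame(
      gene = c("KIF11", "KIF11", "MAP4K2", "CDK6", "CDK6", "BCL2", "PIK3CD",
               "NOTHIT"),
      drug = c("S-Trityl-l-cysteine", "Ispinesib Mesylate", "NG-25",
               "AT-7519", "Palbociclib", "Navitoclax", "Idelalisib",
               "Zibotentan"),
      stringsAsFactors = FALSE)
  )
  sig <- druggable_signature("SUM44", st)
  expect_setequal(sig$gene, c("KIF11", "MAP4K2", "CDK6", "BCL2", "PIK3CD"))
  expect_equal(sig$drugs[sig$gene == "CDK6"], "AT-7519, Palbociclib")
  expect_false("NODRUG" %in% sig$gene)   # hit without an agent
  expect_false("NOTHIT" %in% sig$gene)   # agent without a hit
  expect_equal(sig$rank, sort(sig$rank)) # screen-rank order

  st$drugs <- NULL
  expect_error(druggable_signature("SUM44", st), "drug map")
})

test_that("signature rows carry store values verbatim", {
  sim <- simulate_omics(n_lines = 1, n_genes = 40, drivers_per_line = 2,
                        seed = 77)
  st <- sim$store
  cl <- names(sim$truth)[1]
  fun <- functional_signature(cl, st)
  for (i in seq_len(nrow(fun))) {
    g <- fun$gene[i]
    expect_equal(fun$dna_amp[i],
                 st$cna$dna_amp[st$cna$gene == g & st$cna$cell_line == cl])
    expect_equal(fun$expression_lfc[i],
                 st$expr$expression_lfc[st$expr$gene == g &
                                          st$expr$cell_line == cl])
    h <- st$hits[[cl]]
    expect_equal(fun$quant_log[i], h$quant_log[h$gene == g])
    expect_equal(fun$rank[i], h$rank[h$gene == g])
  }
})
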