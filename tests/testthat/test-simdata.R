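test_that("configuration is validated", {
  expect_error(sim_config(class_proportions = c(common = 0.5, silent = 0.4)),
               "sum to 1")
  expect_error(sim_config(n_reps_a = 1), "at least 2 replicates")
  expect_error(sim_config(contamination_fraction = 1.5), "contamination")
  expect_error(generate_comparison(data.frame(), 1.2), "concordant_fraction")
})

test_that("identical configs give bit-identical experiments", {
  a <- generate_counts(sim_config(n_genes = 200, seed = 5))
  b <- generate_counts(sim_config(n_genes = 200, seed = 5))
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$comparison, b$comparison)
})

test_that("truth class counts match rounded proportions exactly", {
  p <- c(common = 0.503, de_up_a = 0.101, de_up_b = 0.099,
         exclusive_a = 0.05, exclusive_b = 0.05, glial_contaminant = 0.097,
         silent = 0.10)
  exp <- generate_counts(sim_config(n_genes = 333, class_proportions = p,
                                    seed = 2))
  tab <- table(exp$truth$true_class)
  expect_equal(sum(tab), 333)
  # largest-remainder: each count within 1 of n*p and the total exact
  for (cl in names(p))
    expect_lte(abs(tab[[cl]] - 333 * p[[cl]]), 1)
})

test_that("null configuration yields only common/silent genes with unit mean ratio", {
  p <- c(common = 0.9, de_up_a = 0, de_up_b = 0, exclusive_a = 0,
         exclusive_b = 0, glial_contaminant = 0, silent = 0.1)
  exp <- generate_counts(sim_config(n_genes = 1000, class_proportions = p,
                                    contamination_fraction = 0, seed = 3))
  expect_setequal(unique(exp$truth$true_class), c("common", "silent"))
  iA <- exp$condition == "A"; iB <- exp$condition == "B"
  common <- exp$truth$true_class == "common"
  ratio <- rowMeans(exp$counts[common, iB]) / rowMeans(exp$counts[common, iA])
  expect_equal(median(ratio), 1, tolerance = 0.1)
})

test_that("exclusive genes have literal zeros in the off condition", {
  p <- c(common = 0.6, de_up_a = 0, de_up_b = 0, exclusive_a = 0.2,
         exclusive_b = 0.2, glial_contaminant = 0, silent = 0)
  exp <- generate_counts(sim_config(n_genes = 300, class_proportions = p,
                                    contamination_fraction = 0, seed = 4))
  iA <- exp$condition == "A"; iB <- exp$condition == "B"
  ex_a <- exp$truth$true_class == "exclusive_a"
  ex_b <- exp$truth$true_class == "exclusive_b"
  expect_true(all(exp$counts[ex_a, iB] == 0))
  expect_true(all(exp$counts[ex_b, iA] == 0))
  expect_true(all(rowSums(exp$counts[ex_a, iA]) > 0))
})

test_that("generated counts carry the configured NB dispersion", {
  p <- c(common = 1, de_up_a = 0, de_up_b = 0, exclusive_a = 0,
         exclusive_b = 0, glial_contaminant = 0, silent = 0)
  exp <- generate_counts(sim_config(n_genes = 2000, class_proportions = p,
                                    dispersion = 0.2, seed = 6))
  iA <- which(exp$condition == "A"); iB <- which(exp$condition == "B")
  a_hat <- mom_dispersion_oracle(exp$counts, iA, iB)
  expect_gte(median(a_hat), 0.1)
  expect_lte(median(a_hat), 0.3)
})

test_that("contamination scales neuronal means by (1 - fraction)", {
  p <- c(common = 0.9, de_up_a = 0, de_up_b = 0, exclusive_a = 0,
         exclusive_b = 0, glial_contaminant = 0.1, silent = 0)
  base <- sim_config(n_genes = 100, n_reps_a = 200, n_reps_b = 2,
                     class_proportions = p, contamination_fraction = 0,
                     dispersion = 0.1, seed = 8)
  cont <- base; cont$contamination_fraction <- 0.2
  e0 <- generate_counts(base)
  e1 <- generate_counts(cont)
  iA <- e0$condition == "A"
  common <- e0$truth$true_class == "common"
  # same seed draws the same baseline means; condition-A means shrink by 0.8
  ratio <- rowMeans(e1$counts[common, iA]) / rowMeans(e0$counts[common, iA])
  expect_equal(median(ratio), 0.8, tolerance = 0.03)
  # glial genes receive counts only through the admixture
  glial <- e0$truth$true_class == "glial_contaminant"
  expect_true(all(e0$counts[glial, ] == 0))
  expect_true(any(e1$counts[glial, iA] > 0))
})

test_that("reference presence equals a brute-force filter of the truth table", {
  exp <- generate_counts(sim_config(n_genes = 500, seed = 9))
  ref <- generate_reference_presence(exp$truth)
  brute <- character(0)
  for (i in seq_len(nrow(exp$truth)))
    if (exp$truth$neuronal[i] && exp$truth$true_class[i] != "silent")
      brute <- c(brute, exp$truth$gene_id[i])
  expect_identical(ref, brute)
  glial_ids <- exp$truth$gene_id[!exp$truth$neuronal]
  expect_length(intersect(ref, glial_ids), 0)
})

test_that("comparison concordance is exact at the extremes", {
  exp <- generate_counts(sim_config(n_genes = 400, seed = 10))
  de_truth <- exp$truth[exp$truth$true_class %in%
                          c("de_up_a", "de_up_b", "exclusive_a",
                            "exclusive_b"), ]
  de_tbl <- data.frame(symbol = de_truth$symbol,
                       log2fc = sign(de_truth$true_log2fc))
  for (cf in c(1, 0)) {
    comp <- generate_comparison(exp$truth, cf, seed = 11)
    tc <- trend_concordance(de_tbl, comp)
    expect_equal(tc$frac_same_trend, cf)
    expect_equal(tc$n_compared, nrow(de_tbl))
  }
})

test_that("written experiment files round-trip", {
  exp <- generate_counts(sim_config(n_genes = 50, seed = 12))
  dir <- withr::local_tempdir()
  paths <- write_experiment(exp, dir)
  counts2 <- read_counts_tsv(paths[["counts"]])
  expect_equal(counts2, exp$counts + 0, ignore_attr = FALSE)
  expect_identical(read_reference_presence(paths[["reference"]]),
                   exp$reference)
  ann2 <- read_annotation_tsv(paths[["annotation"]])
  expect_equal(ann2$length_bp, exp$annotation$length_bp)
})
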