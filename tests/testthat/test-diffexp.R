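test_that("median-of-ratios size factors behave on toy matrices", {
  same <- matrix(rep(c(10L, 20L, 30L), 3), 3, 3,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_true(all(abs(estimate_size_factors(same) - 1) < 1e-12))

  m <- matrix(c(10L, 20L, 30L, 20L, 40L, 60L, 10L, 20L, 30L), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2)

  perm <- m[, c(3, 1, 2)]
  expect_equal(unname(estimate_size_factors(perm)),
               unname(sf[c(3, 1, 2)]))

  with_zero <- rbind(m, g4 = c(0L, 0L, 0L))
  expect_equal(estimate_size_factors(with_zero), sf)

  all_zero_somewhere <- matrix(c(0L, 5L, 5L, 0L), 2, 2,
                               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(estimate_size_factors(all_zero_somewhere), "no gene")
})

test_that("dispersion estimates recover Poisson and NB truth", {
  cond <- rep(c("A", "B"), c(6, 4))
  set.seed(30)
  mu <- exp(runif(2000, log(20), log(2000)))
  pois <- vapply(1:10, function(j) rpois(2000, mu), numeric(2000))
  storage.mode(pois) <- "integer"
  rownames(pois) <- sprintf("g%04d", 1:2000)
  colnames(pois) <- paste0("s", 1:10)
  sf <- estimate_size_factors(pois)
  d0 <- estimate_dispersion(pois, sf, cond)
  expect_lte(median(d0$final), 0.01)

  nb <- vapply(1:10, function(j) rnbinom(2000, mu = mu, size = 5),
               numeric(2000))
  storage.mode(nb) <- "integer"
  dimnames(nb) <- dimnames(pois)
  sf <- estimate_size_factors(nb)
  d2 <- estimate_dispersion(nb, sf, cond)
  expect_gte(median(d2$final), 0.1)
  expect_lte(median(d2$final), 0.3)
  # final estimates stay at or above the floor and are finite
  expect_true(all(d2$final >= 1e-8 & is.finite(d2$final)))
})

test_that("zero within-condition variance gives zero gene-wise dispersion", {
  counts <- matrix(c(rep(10L, 6), rep(20L, 4),
                     rep(50L, 6), rep(100L, 4),
                     rep(7L, 6), rep(14L, 4)), 3, 10, byrow = TRUE,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:10)))
  cond <- rep(c("A", "B"), c(6, 4))
  sf <- rep(1, 10)
  d <- estimate_dispersion(counts, sf, cond)
  expect_true(all(d$genewise == 0))
})

test_that("Wald test recovers a twofold change and flags degenerate genes", {
  p <- c(common = 0.6, de_up_a = 0.2, de_up_b = 0.2, exclusive_a = 0,
         exclusive_b = 0, glial_contaminant = 0, silent = 0)
  exp <- generate_counts(sim_config(n_genes = 1000, class_proportions = p,
                                    baseline_mean_log_range = log(c(100, 100)),
                                    dispersion = 0.05, seed = 31))
  counts <- exp$counts
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, sf, exp$condition)
  de <- nb_wald_test(counts, sf, disp, exp$condition)
  up_b <- exp$truth$true_class == "de_up_b"
  up_a <- exp$truth$true_class == "de_up_a"
  expect_equal(mean(de$log2fc[up_b]), 1, tolerance = 0.1)
  expect_equal(mean(-de$log2fc[up_a]), 1, tolerance = 0.1)

  # swapping condition labels negates the fold change, p-values unchanged
  swapped <- ifelse(exp$condition == "A", "B", "A")
  disp_s <- estimate_dispersion(counts, sf, swapped)
  de_s <- nb_wald_test(counts, sf, disp_s, swapped)
  expect_equal(de_s$log2fc, -de$log2fc)
  expect_equal(de_s$pvalue, de$pvalue)

  # an all-zero gene is flagged, not an error
  counts2 <- rbind(counts, zzz = rep(0L, ncol(counts)))
  disp2 <- estimate_dispersion(counts2, sf, exp$condition)
  de2 <- nb_wald_test(counts2, sf, disp2, exp$condition)
  row <- de2[de2$gene_id == "zzz", ]
  expect_equal(row$log2fc, 0)
  expect_equal(row$pvalue, 1)
  expect_true(row$all_zero)
})

test_that("one-sided zero groups get large finite fold changes", {
  set.seed(32)
  counts <- rbind(ex = c(rpois(6, 200), rep(0L, 4)),
                  matrix(rpois(50 * 10, 100), 50, 10))
  rownames(counts)[-1] <- sprintf("g%02d", 1:50)
  colnames(counts) <- paste0("s", 1:10)
  storage.mode(counts) <- "integer"
  cond <- rep(c("A", "B"), c(6, 4))
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersion(counts, sf, cond)
  de <- nb_wald_test(counts, sf, disp, cond)
  ex <- de[de$gene_id == "ex", ]
  expect_true(is.finite(ex$log2fc))
  expect_lt(ex$log2fc, -5)
  expect_true(ex$significant)
})

test_that("BH adjustment matches hand results and stays above the input", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.04, 0.03, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  expect_error(adjust_bh(c(0.2, 1.4)), "in \\[0, 1\\]")
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- adjust_bh(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_equal(adj, p.adjust(p, "BH"))
    expect_equal(adj, brute_force_bh(p))
  }
})

test_that("raw p-values are near-uniform under the null", {
  # genes within one run share size factors and the dispersion trend, so the
  # single-run KS distance is noisy; the uniformity property is asserted on
  # the median KS over replicate null simulations
  p <- c(common = 1, de_up_a = 0, de_up_b = 0, exclusive_a = 0,
         exclusive_b = 0, glial_contaminant = 0, silent = 0)
  ks <- vapply(34:37, function(s) {
    exp <- generate_counts(sim_config(n_genes = 5000, class_proportions = p,
                                      dispersion = 0.2, seed = s))
    sf <- estimate_size_factors(exp$counts)
    disp <- estimate_dispersion(exp$counts, sf, exp$condition)
    de <- nb_wald_test(exp$counts, sf, disp, exp$condition)
    unname(suppressWarnings(ks.test(de$pvalue, "punif")$statistic))
  }, numeric(1))
  expect_lt(median(ks), 0.02)
})
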