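mk_mat <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), dimnames = list(genes, samples))
}

samples12 <- expand.grid(stage = c("young", "enlargement", "coloring",
                                   "mature"),
                         tissue = c("rind", "flesh", "seed"),
                         stringsAsFactors = FALSE)
samples12 <- data.frame(sample_id = paste(samples12$tissue, samples12$stage,
                                          sep = "_"),
                        tissue = samples12$tissue, stage = samples12$stage,
                        stringsAsFactors = FALSE)

test_that("FPKM follows the closed-form definition", {
  counts <- matrix(c(10, 0), nrow = 2,
                   dimnames = list(c("a", "b"), "s1"))
  out <- fpkm(counts, c(a = 1000, b = 1000), c(s1 = 1e6))
  expect_equal(out["a", "s1"], 10.0)
  expect_equal(out["b", "s1"], 0.0)
  # doubling the library total halves every FPKM in that sample
  out2 <- fpkm(counts, c(a = 1000, b = 1000), c(s1 = 2e6))
  expect_equal(out2, out / 2)
  expect_error(fpkm(counts, c(a = 0, b = 1000), c(s1 = 1e6)), "positive")
  expect_error(fpkm(counts, c(a = 1000, b = 1000), c(s1 = 0)), "positive")
})

test_that("FPKM conserves the scaled library total", {
  set.seed(12)
  counts <- matrix(rpois(60, 50), nrow = 10,
                   dimnames = list(sprintf("g%d", 1:10),
                                   sprintf("s%d", 1:6)))
  L <- setNames(sample(500:3000, 10), rownames(counts))
  N <- setNames(colSums(counts), colnames(counts))
  out <- fpkm(counts, L, N)
  for (s in colnames(counts))
    expect_equal(sum(out[, s] * L), 1e9 * sum(counts[, s]) / N[[s]])
})

test_that("expression categories cut on the maximum FPKM", {
  m <- mk_mat(c(35, 10, 0, 1, 2, 0, 31, 30, 2), genes = c("hi", "lo", "off"),
              samples = c("s1", "s2", "s3"))
  cats <- categorize_expression(m)
  expect_equal(unname(cats["hi"]), "intermediate_high")  # max 35 > 30
  expect_equal(unname(cats["lo"]), "low")                # max 30 in [3,30]
  expect_equal(unname(cats["off"]), "very_low")          # max 2 below band
  zero <- categorize_expression(mk_mat(rep(0, 3), "z", c("s1", "s2", "s3")))
  expect_equal(unname(zero), "not_detected")
  expect_error(categorize_expression(m, low_band = c(30, 3)), "ordered")
  # monotone: raising a value never lowers the category
  m2 <- m; m2["lo", "s1"] <- 50
  expect_equal(unname(categorize_expression(m2)["lo"]), "intermediate_high")
})

test_that("tissue assignment takes the argmax with the fixed tie order", {
  g <- mk_mat(c(rep(8, 4), rep(0.1, 8)), "g", samples12$sample_id)
  ta <- tissue_assignment(g, samples12)
  expect_equal(ta$assignment$tissue, "rind")
  tie <- mk_mat(rep(2, 12), "t", samples12$sample_id)
  tt <- tissue_assignment(tie, samples12)
  expect_equal(tt$assignment$tissue, "rind")
  expect_true(tt$assignment$tied)
  off <- mk_mat(rep(0, 12), "o", samples12$sample_id)
  to <- tissue_assignment(off, samples12)
  expect_true(is.na(to$assignment$tissue))
  expect_equal(sum(to$per_tissue$n), 0)
})

test_that("tissue means are grand means per tissue", {
  m <- mk_mat(rep(3, 24), c("a", "b"), samples12$sample_id)
  tm <- tissue_means(m, samples12)
  expect_equal(tm$mean_fpkm, rep(3, 3))
  expect_error(tissue_means(m[0, , drop = FALSE], samples12), "empty")
})

test_that("heatmap export log-transforms and orders genes by group", {
  m <- mk_mat(c(0, 1, 3), c("t1", "c1", "r1"), "s1")
  labels <- data.frame(gene_id = c("t1", "c1", "r1"),
                       group = c("TNL", "CNL", "RNL"))
  hm <- export_heatmap_matrix(m, labels)
  expect_equal(rownames(hm), c("c1", "t1", "r1"))
  expect_equal(unname(hm["t1", 1]), 0)
  expect_equal(unname(hm["c1", 1]), 1.0)
  hm2 <- export_heatmap_matrix(m, labels)
  expect_identical(hm, hm2)
})
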