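test_that("pair selection applies the identity/length window and drops
           near-identical paralog sets", {
  labels <- data.frame(gene_id = c("a", "b", "c", "d", "r1", "r2", "r3",
                                   "r4"),
                       group = c(rep("CNL", 4), rep("RNL", 4)))
  pairs <- data.frame(
    gene_a = c("a", "a", "c", "r1", "r1", "r2"),
    gene_b = c("b", "b", "d", "r2", "r3", "r3"),
    identity = c(0.7, 0.7, 1.0, 0.995, 0.995, 0.995),
    aligned_length = c(200, 200, 300, 400, 400, 400))
  sel <- select_pairs(pairs, labels)
  expect_equal(nrow(sel), 1)  # duplicate removed, identity-1 and RNLs out
  expect_equal(sel$gene_a, "a")
  short <- data.frame(gene_a = "a", gene_b = "b", identity = 0.7,
                      aligned_length = 50)
  expect_equal(nrow(select_pairs(short, labels)), 0)
})

test_that("subfamily contrast recovers planted omega difference and is flat
           under the null", {
  set.seed(5)
  # identical group compositions: the contrast is exactly flat
  same <- seq(0.2, 0.5, length.out = 20)
  null_res <- data.frame(omega = c(same, same),
                         group = rep(c("CNL", "TNL"), each = 20))
  p_null <- subfamily_kaks_contrast(null_res)$p
  expect_gt(p_null, 0.99)
  res <- data.frame(omega = c(rnorm(20, 0.31, 0.02), rnorm(20, 0.42, 0.02)),
                    group = rep(c("CNL", "TNL"), each = 20))
  ct <- subfamily_kaks_contrast(res)
  expect_lt(ct$p, 0.01)
  expect_lt(abs(ct$means_raw[["CNL"]] - 0.31), 0.05)
  expect_lt(abs(ct$means_raw[["TNL"]] - 0.42), 0.05)
  expect_error(subfamily_kaks_contrast(res[res$group == "CNL", ]), ">=2")
})

rank_map_one <- function(n_per_chr, chrs = c("chrA", "chrB")) {
  do.call(rbind, lapply(chrs, function(ch)
    data.frame(gene_id = paste0(ch, "_", seq_len(n_per_chr)),
               chromosome = ch, rank = seq_len(n_per_chr))))
}

test_that("collinear blocks require length, order consistency and small
           gaps", {
  rm <- rank_map_one(30)
  planted <- data.frame(gene_a = paste0("chrA_", 5:10),
                        gene_b = paste0("chrB_", 11:16))
  b <- detect_collinear_blocks(rm, planted)
  expect_equal(nrow(b), 6)
  expect_equal(length(unique(b$block_id)), 1)
  set.seed(2)
  shuffled <- data.frame(gene_a = paste0("chrA_", c(5, 20, 8, 28)),
                         gene_b = paste0("chrB_", c(25, 3, 17, 9)))
  expect_equal(nrow(detect_collinear_blocks(rm, shuffled)), 0)
  short_run <- planted[1:4, ]
  expect_equal(nrow(detect_collinear_blocks(rm, short_run)), 0)
})

test_that("duplication typing follows the rank rules with the documented
           priority", {
  rm <- rank_map_one(40)
  pairs <- data.frame(
    gene_a = c("chrA_1", "chrA_10", "chrA_20", "chrA_30"),
    gene_b = c("chrA_2", "chrA_15", "chrB_20", "chrB_39"),
    identity = 0.8, aligned_length = 300)
  calls <- classify_duplications(c("chrA_1", "chrA_2", "chrA_10", "chrA_15",
                                   "chrA_20", "chrA_30", "chrA_40"),
                                 rm, pairs)
  ty <- setNames(calls$dup_type, calls$gene_id)
  expect_equal(ty[["chrA_1"]], "tandem")
  expect_equal(ty[["chrA_2"]], "tandem")
  expect_equal(ty[["chrA_10"]], "proximal")
  expect_equal(ty[["chrA_20"]], "dispersed")
  expect_equal(ty[["chrA_40"]], "singleton")
  expect_error(classify_duplications("ghost", rm, pairs), "rank map")
  # WGD/segmental evidence wins over a tandem-range partner
  blocks <- data.frame(block_id = 1,
                       gene_a = paste0("chrA_", c(1, 5:8)),
                       gene_b = paste0("chrB_", c(1, 5:8)))
  calls2 <- classify_duplications("chrA_1", rm, pairs, blocks)
  expect_equal(calls2$dup_type, "wgd_segmental")
})

test_that("duplication calls partition genes and every gene gets exactly
           one type", {
  g <- generate_genome(sim_config(seed = 17, n_nbs_genes = 20,
                                  cluster_spec = list(c(4, 50000),
                                                      c(4, 50000)),
                                  duplication_spec = c(wgd = 2, tandem = 8,
                                                       proximal = 4,
                                                       dispersed = 6),
                                  n_background_genes = 300),
                       with_cds = FALSE)
  blocks <- detect_collinear_blocks(g$rank_map, g$pairs)
  calls <- classify_duplications(g$genes$gene_id, g$rank_map, g$pairs,
                                 blocks)
  expect_equal(sort(calls$gene_id), sort(g$genes$gene_id))
  expect_equal(anyDuplicated(calls$gene_id), 0)
  truth <- g$truth$genes
  expect_equal(calls$dup_type,
               truth$dup_type[match(calls$gene_id, truth$gene_id)])
})

test_that("duplication summary percentages reproduce the published
           fractions", {
  calls <- data.frame(gene_id = sprintf("g%02d", 1:73),
                      dup_type = rep(c("tandem", "dispersed", "proximal",
                                       "wgd_segmental"),
                                     c(33, 29, 9, 2)))
  s <- duplication_summary(calls)
  pct <- setNames(s$pct, s$dup_type)
  expect_equal(pct[["tandem"]], 45.2)
  expect_equal(pct[["dispersed"]], 39.7)
  expect_equal(pct[["proximal"]], 12.3)
  expect_equal(pct[["wgd_segmental"]], 2.7)
})
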