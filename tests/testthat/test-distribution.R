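gene_tab <- function(starts, ends, chr = "chr1") {
  data.frame(gene_id = sprintf("g%02d", seq_along(starts)),
             chromosome = chr, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

test_that("mapped/unmapped split keys on assembled chromosome names", {
  g <- data.frame(gene_id = c("a", "b", "c"),
                  chromosome = c("chr1", "scaffold_3", "unplaced"),
                  start = 1, end = 10)
  sp <- split_mapped_unmapped(g)
  expect_equal(sp$mapped$gene_id, "a")
  expect_equal(sort(sp$unmapped$gene_id), c("b", "c"))
  all_placed <- split_mapped_unmapped(g[1, ])
  expect_equal(nrow(all_placed$unmapped), 0)
  none_placed <- split_mapped_unmapped(g[2:3, ])
  expect_equal(nrow(none_placed$mapped), 0)
})

test_that("gap chaining joins genes within the window and splits beyond it", {
  g <- gene_tab(c(1, 150000, 500000), c(5000, 155000, 505000))
  loci <- call_clusters(g, window_bp = 250000)
  expect_equal(loci$kind, c("cluster", "singleton"))
  expect_equal(loci$members, c("g01,g02", "g03"))
  expect_identical(loci_sets(loci), cluster_oracle(g, 250000))
})

test_that("limit cases: one gene per chromosome, huge window", {
  g <- gene_tab(c(1e6, 2e6), c(1e6 + 1000, 2e6 + 1000),
                chr = c("chr1", "chr2"))
  expect_true(all(call_clusters(g)$kind == "singleton"))
  g2 <- gene_tab(c(1, 5e6, 9e6), c(1000, 5e6 + 1000, 9e6 + 1000))
  expect_equal(nrow(call_clusters(g2, window_bp = 1e9)), 1)
})

test_that("chaining equals the brute-force windowing oracle on random
           instances and partitions the genes", {
  set.seed(77)
  for (i in 1:200) {
    g <- random_gene_table(sample(2:25, 1))
    w <- sample(c(1e4, 1e5, 25e4, 1e6), 1)
    loci <- call_clusters(g, w)
    expect_identical(loci_sets(loci), cluster_oracle(g, w))
    expect_setequal(unlist(strsplit(loci$members, ",")), g$gene_id)
    expect_equal(sum(loci$n_genes), nrow(g))
  }
})

test_that("cluster calling is invariant to input order and monotone in the
           window", {
  set.seed(13)
  g <- random_gene_table(20)
  l1 <- call_clusters(g)
  l2 <- call_clusters(g[sample.int(nrow(g)), ])
  expect_identical(l1, l2)
  windows <- c(1e3, 1e4, 1e5, 1e6, 1e7)
  n_loci <- vapply(windows, function(w) nrow(call_clusters(g, w)),
                   numeric(1))
  expect_false(is.unsorted(rev(n_loci)))  # loci only merge as window grows
})

test_that("cluster summaries reproduce the published mapped-gene
           accounting", {
  # 12 clusters with the published size composition + 23 singletons
  sizes <- c(2, 2, 2, 2, 2, 3, 3, 4, 4, 4, 6, 7)
  starts <- integer(0); ends <- integer(0); chr <- character(0)
  pos <- 1
  for (i in seq_along(sizes)) {
    for (j in seq_len(sizes[i])) {
      starts <- c(starts, pos); ends <- c(ends, pos + 2000)
      pos <- pos + 50000
    }
    pos <- pos + 400000
  }
  for (j in 1:23) {
    starts <- c(starts, pos); ends <- c(ends, pos + 2000)
    pos <- pos + 400000
  }
  g <- gene_tab(starts, ends)
  s <- cluster_summary(call_clusters(g))
  expect_equal(s$n_clusters, 12)
  expect_equal(s$n_singletons, 23)
  expect_equal(s$n_clustered_genes, 41)
  expect_equal(s$clustered_pct, 64.1)
  expect_equal(s$mean_genes_per_cluster, 3.42)
  s0 <- cluster_summary(call_clusters(g[1, ]))
  expect_equal(s0$mean_genes_per_cluster, 0)
  expect_true(s0$no_clusters)
})
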