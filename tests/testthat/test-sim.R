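small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, n_nbs_genes = 12,
             cluster_spec = list(c(3, 50000)),
             duplication_spec = c(wgd = 0, tandem = 2, proximal = 2,
                                  dispersed = 2),
             codon_length = 60, n_background_genes = 150, ...)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(subclass_mix = c(CNL = 0.5, TNL = 0.4)),
               "sum to 1")
  expect_error(sim_config(n_nbs_genes = 4,
                          cluster_spec = list(c(10, 50000))),
               "cluster_spec")
  expect_error(sim_config(duplication_spec = c(tandem = 3, proximal = 0,
                                               dispersed = 0, wgd = 0)),
               "even")
  expect_error(sim_config(n_nbs_genes = 4,
                          cluster_spec = list(c(2, 5e4)),
                          duplication_spec = c(tandem = 4, proximal = 2,
                                               dispersed = 0, wgd = 0)),
               "exceed|covers|capacity")
  expect_error({cfg <- small_cfg(); cfg$expr_spec$dispersion <- -1
                generate_counts(cfg, c(a = 1000))}, "positive")
  expect_error(evolve_codon_pair("ATGAAA", omega = -1, 5, 1), "positive")
})

test_that("a fixed seed reproduces byte-identical genome files", {
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_genome_files(generate_genome(small_cfg(7), with_cds = TRUE,
                                     with_counts = TRUE), d1)
  write_genome_files(generate_genome(small_cfg(7), with_cds = TRUE,
                                     with_counts = TRUE), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     info = f)
  }
  g3 <- generate_genome(small_cfg(8))
  g1 <- generate_genome(small_cfg(7))
  expect_false(identical(g1$genes$start, g3$genes$start))
})

test_that("planted duplication and cluster bookkeeping matches the
           configuration exactly", {
  cfg <- sim_config(seed = 3, n_nbs_genes = 14,
                    cluster_spec = list(c(4, 50000)),
                    duplication_spec = c(wgd = 0, tandem = 4, proximal = 2,
                                         dispersed = 4),
                    n_background_genes = 200)
  g <- generate_genome(cfg, with_cds = FALSE)
  tt <- table(g$truth$genes$dup_type)
  expect_equal(unname(tt[["tandem"]]), 4)
  expect_equal(unname(tt[["proximal"]]), 2)
  expect_equal(unname(tt[["dispersed"]]), 4)
  expect_equal(nrow(g$truth$genes), 14)
  expect_equal(anyDuplicated(g$truth$genes$gene_id), 0)
  # subclass counts follow the mix by largest remainder
  expect_equal(sum(g$truth$genes$group == "CNL") +
                 sum(g$truth$genes$group == "TNL") +
                 sum(g$truth$genes$group == "RNL"), 14)
})

test_that("the planted cluster is recovered by chaining and by the
           brute-force oracle", {
  g <- generate_genome(small_cfg(21), with_cds = FALSE)
  sp <- split_mapped_unmapped(g$genes)
  loci <- call_clusters(sp$mapped, window_bp = 250000)
  expect_identical(loci_sets(loci), cluster_oracle(sp$mapped, 250000))
  cl <- loci[loci$kind == "cluster", ]
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_genes, 3)
  truth_cluster <- g$truth$genes
  truth_counts <- table(truth_cluster$locus)
  expect_equal(sort(unname(truth_counts[truth_counts >= 2])), 3)
})

test_that("codon-pair evolution honours its contract", {
  anc <- paste(rep("ATGGATAAACTG", 15), collapse = "")
  same <- evolve_codon_pair(anc, omega = 0.5, expected_subs = 0, seed = 4)
  expect_equal(same$a, anc)
  expect_equal(same$b, anc)
  p1 <- evolve_codon_pair(anc, omega = 0.5, expected_subs = 20, seed = 4)
  p2 <- evolve_codon_pair(anc, omega = 0.5, expected_subs = 20, seed = 4)
  expect_identical(p1, p2)
  expect_false(identical(p1$a, anc) && identical(p1$b, anc))
  # no stop codons ever introduced
  gc_map <- Biostrings::GENETIC_CODE
  codons <- substring(p1$a, seq(1, nchar(p1$a), 3), seq(3, nchar(p1$a), 3))
  expect_false(any(gc_map[codons] == "*"))
  expect_error(evolve_codon_pair("ATGTAAAAA", 0.5, 3, 1), "stop")
})

test_that("counts are reproducible non-negative integers with planted
           tissue structure", {
  cfg <- small_cfg(5)
  lens <- c(a = 1500, b = 2400, c = 900)
  c1 <- generate_counts(cfg, lens)
  c2 <- generate_counts(cfg, lens)
  expect_identical(c1$counts, c2$counts)
  expect_true(all(c1$counts >= 0))
  expect_true(all(c1$counts == round(c1$counts)))
  expect_equal(dim(c1$counts), c(3, 12))
  # all-zero means give an all-zero matrix
  cfg0 <- small_cfg(5)
  cfg0$expr_spec$tissue_means <- c(rind = 0, flesh = 0, seed = 0)
  expect_true(all(generate_counts(cfg0, lens)$counts == 0))
  # rind late-stage means exceed early-stage means as configured
  mf <- c1$mean_fpkm
  expect_gt(mf[1, "rind_mature"], mf[1, "rind_young"])
})

test_that("a planted high-expression gene is flagged above 30 FPKM in
           nearly all simulations", {
  # Monte-Carlo over negative-binomial sampling: true mean 50 FPKM in rind,
  # 5 elsewhere, 2-kb gene, 20M-fragment libraries, dispersion size 10
  sample_ids <- paste0("s", 1:12)
  L <- c(hi = 2000); N <- setNames(rep(2e7, 12), sample_ids)
  mu_fpkm <- c(rep(50, 4), rep(5, 8))
  hit <- 0; n_rep <- 100
  set.seed(404)
  for (s in seq_len(n_rep)) {
    counts <- matrix(rnbinom(12, mu = mu_fpkm * L * N / 1e9, size = 10),
                     nrow = 1, dimnames = list("hi", sample_ids))
    fp <- fpkm(counts, L, N)
    if (categorize_expression(fp)[["hi"]] == "intermediate_high")
      hit <- hit + 1
  }
  expect_gte(hit / n_rep, 0.95)
})
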