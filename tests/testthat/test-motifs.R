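lib <- default_motif_library()

consensus_of <- function(name, terminal = NULL) {
  m <- lib[[name]]
  s <- vapply(m$classes, `[`, character(1), 1)
  if (!is.null(terminal)) s[length(s)] <- terminal
  paste(s, collapse = "")
}

test_that("planted consensus motifs are found in order", {
  seq <- paste0(consensus_of("P-loop"), strrep("A", 20),
                consensus_of("Kinase-2"))
  hits <- scan_motifs(seq, lib)
  expect_equal(hits$motif, c("P-loop", "Kinase-2"))
  expect_true(all(diff(hits$start) > 0))
})

test_that("featureless sequences yield no hits and empty input is not an
           error", {
  expect_equal(nrow(scan_motifs(strrep("A", 100), lib)), 0)
  expect_equal(nrow(scan_motifs("", lib)), 0)
})

test_that("motif-order verdicts follow the canonical-order rules", {
  mk <- function(names) data.frame(motif = names,
                                   start = seq(1, by = 60,
                                               length.out = length(names)),
                                   end = seq(50, by = 60,
                                             length.out = length(names)),
                                   match = "", score = 10)
  expect_equal(classify_motif_order(
    mk(c("P-loop", "Kinase-2", "GLPL")))$verdict, "conserved")
  expect_equal(classify_motif_order(
    mk(c("P-loop", "P-loop", "Kinase-2", "GLPL")))$verdict, "flanked_repeat")
  expect_equal(classify_motif_order(
    mk(c("Kinase-2", "P-loop", "GLPL")))$verdict, "core_change")
  expect_equal(classify_motif_order(
    mk(c("P-loop", "Kinase-2", "GLPL", "GLPL")))$verdict, "flanked_repeat")
  expect_equal(classify_motif_order(mk("GLPL"))$verdict, "insufficient")
})

test_that("a single motif repeated any number of times is never a core
           change", {
  mk <- function(names) data.frame(motif = names,
                                   start = seq(1, by = 60,
                                               length.out = length(names)),
                                   end = seq(50, by = 60,
                                             length.out = length(names)),
                                   match = "", score = 10)
  for (n in 1:5)
    expect_equal(classify_motif_order(
      mk(rep("RNBS-B", n)))$verdict, "insufficient")
})

test_that("every gene with two distinct motifs receives exactly one
           non-insufficient verdict", {
  canonical <- c("P-loop", "RNBS-A", "Kinase-2", "RNBS-B",
                 "RNBS-C", "GLPL", "RNBS-D", "MHDL")
  set.seed(21)
  for (i in 1:50) {
    names <- sample(canonical, sample(2:8, 1), replace = TRUE)
    if (length(unique(names)) < 2) next
    v <- classify_motif_order(data.frame(
      motif = names, start = seq(1, by = 60, length.out = length(names)),
      end = seq(50, by = 60, length.out = length(names)),
      match = "", score = 10))$verdict
    expect_true(v %in% c("conserved", "flanked_repeat", "core_change"))
  }
})

test_that("kinase-2 terminal residue typing follows the W/D rule", {
  w_seq <- paste0(strrep("A", 15), consensus_of("Kinase-2", "W"),
                  strrep("A", 15))
  d_seq <- paste0(strrep("A", 15), consensus_of("Kinase-2", "D"),
                  strrep("A", 15))
  expect_equal(kinase2_terminal_residue(scan_motifs(w_seq, lib)), "W")
  expect_equal(kinase2_terminal_residue(scan_motifs(d_seq, lib)), "D")
  expect_true(is.na(kinase2_terminal_residue(scan_motifs(strrep("A", 50),
                                                         lib))))
})

test_that("terminal-residue frequencies reproduce the published W/D split", {
  labels <- data.frame(
    gene_id = sprintf("g%02d", 1:73),
    group = rep(c("CNL", "RNL", "TNL"), c(50, 4, 19)))
  residues <- setNames(c(rep("W", 48), rep("D", 6),   # 54 non-TNL
                         rep("D", 13), rep("W", 6)),  # 19 TNL
                       labels$gene_id)
  tab <- kinase2_frequency_table(labels, residues)
  expect_equal(tab$pct[tab$type == "nTNL" & tab$residue == "W"], 88.9)
  expect_equal(tab$pct[tab$type == "TNL" & tab$residue == "D"], 68.4)
  empty <- kinase2_frequency_table(labels[0, ], residues[0])
  expect_equal(nrow(empty), 0)
})

test_that("scan output is deterministic and position-sorted on synthetic
           proteins", {
  g <- generate_genome(sim_config(seed = 5, n_nbs_genes = 10,
                                  cluster_spec = list(c(4, 50000)),
                                  duplication_spec = c(tandem = 4,
                                                       proximal = 0,
                                                       dispersed = 2,
                                                       wgd = 0),
                                  n_background_genes = 200),
                       with_cds = FALSE)
  h1 <- lapply(g$proteins, scan_motifs)
  h2 <- lapply(g$proteins, scan_motifs)
  expect_identical(h1, h2)
  for (h in h1) expect_false(is.unsorted(h$start))
  # planted consensus: P-loop recall is total on truth genes
  expect_true(all(vapply(h1, function(h) "P-loop" %in% h$motif,
                         logical(1))))
})
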