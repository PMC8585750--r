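dom_row <- function(gene, type, e = 1e-10, cc = NA) {
  data.frame(gene_id = gene, domain_type = type, start = 1, end = 100,
             e_value = e, cc_score = cc, source = "t",
             stringsAsFactors = FALSE)
}

test_that("candidate merging is a deduplicated sorted union", {
  expect_equal(merge_candidates(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_equal(merge_candidates(character(0), "X"), "X")
  expect_equal(merge_candidates(c("a1", "a1"), character(0)), "a1")
  # ids are case-sensitive strings
  expect_equal(merge_candidates("g1", "G1"), c("G1", "g1"))
})

test_that("NBS verification enforces the E-value threshold and drops
           unknown candidates with a warning", {
  dm <- rbind(dom_row("kept", "NBS", 1e-6),
              dom_row("weak", "NBS", 1e-3),
              dom_row("lrr_only", "LRR", 1e-9))
  expect_equal(verify_nbs(c("kept", "weak", "lrr_only"), dm), "kept")
  expect_warning(v <- verify_nbs(c("kept", "ghost"), dm), "absent")
  expect_equal(v, "kept")
})

test_that("domain architectures map onto the nine subclasses", {
  cl <- function(dm, k2 = NA_character_)
    classify_architecture(dm$gene_id[1], dm, k2)
  r <- cl(rbind(dom_row("g", "NBS"), dom_row("g", "CC", NA, 0.7),
                dom_row("g", "LRR")))
  expect_equal(c(r$group, r$subclass), c("CNL", "CNL"))
  r <- cl(rbind(dom_row("g", "NBS"), dom_row("g", "RPW8"),
                dom_row("g", "LRR")))
  expect_equal(c(r$group, r$subclass), c("RNL", "RNL"))
  r <- cl(rbind(dom_row("g", "NBS"), dom_row("g", "TIR")))
  expect_equal(c(r$group, r$subclass), c("TNL", "TN"))
  r <- cl(rbind(dom_row("g", "NBS"), dom_row("g", "LRR")), k2 = "D")
  expect_equal(c(r$group, r$subclass), c("TNL", "NL_TIR"))
  r <- cl(rbind(dom_row("g", "NBS"), dom_row("g", "LRR")), k2 = "W")
  expect_equal(c(r$group, r$subclass), c("CNL", "NL_CC"))
  # bare NBS without kinase-2 evidence: CNL by default, low confidence
  r <- cl(dom_row("g", "NBS"))
  expect_equal(r$subclass, "N_CC")
  expect_true(r$low_confidence)
  # a sub-threshold CC score does not make a CC architecture
  r <- cl(rbind(dom_row("g", "NBS"), dom_row("g", "CC", NA, 0.3)), k2 = "W")
  expect_equal(r$subclass, "N_CC")
  expect_error(cl(dom_row("g", "LRR")), "NBS")
})

test_that("RPW8 takes precedence over CC and TIR", {
  dm <- rbind(dom_row("g", "NBS"), dom_row("g", "RPW8"),
              dom_row("g", "CC", NA, 0.9), dom_row("g", "TIR"),
              dom_row("g", "LRR"))
  expect_equal(classify_architecture("g", dm)$subclass, "RNL")
})

test_that("classification is invariant to domain-row order", {
  dm <- rbind(dom_row("g", "LRR"), dom_row("g", "TIR"), dom_row("g", "NBS"))
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    r <- classify_architecture("g", dm[perm, ])
    expect_equal(r$subclass, "TNL")
  }
})

test_that("classification summaries reproduce the genome-proportion
           arithmetic", {
  labels <- data.frame(gene_id = sprintf("g%02d", 1:73),
                       group = rep(c("CNL", "TNL", "RNL"), c(50, 19, 4)),
                       subclass = rep(c("CNL", "TNL", "RNL"),
                                      c(50, 19, 4)))
  s <- summarize_classification(labels, 24138)
  expect_equal(s$proportion_pct, 0.30)
  expect_equal(s$by_group$n, c(50, 19, 4))
  s0 <- summarize_classification(labels[0, ], 100)
  expect_equal(s0$proportion_pct, 0)
  expect_equal(nrow(s0$by_subclass), 0)
  expect_error(summarize_classification(labels, 0), "positive")
  mix <- data.frame(gene_id = sprintf("m%d", 1:10),
                    group = rep(c("CNL", "TNL", "RNL"), c(5, 3, 2)),
                    subclass = rep(c("CN", "TN", "RNL"), c(5, 3, 2)))
  expect_equal(summarize_classification(mix, 100)$by_group$n, c(5, 3, 2))
})

test_that("group totals always sum to the verified count", {
  g <- generate_genome(sim_config(seed = 31, n_nbs_genes = 15,
                                  cluster_spec = list(c(3, 40000)),
                                  duplication_spec = c(tandem = 2,
                                                       proximal = 2,
                                                       dispersed = 2,
                                                       wgd = 0),
                                  n_background_genes = 150),
                       with_cds = FALSE)
  ver <- verify_nbs(merge_candidates(g$candidates$list_a,
                                     g$candidates$list_b), g$domains)
  k2 <- vapply(g$proteins, function(p)
    kinase2_terminal_residue(scan_motifs(p)), character(1))
  labels <- classify_all(ver, g$domains, k2)
  expect_equal(sum(table(labels$group)), length(ver))
  expect_false(any(is.na(labels$subclass)))
})
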