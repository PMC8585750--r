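# The reference genome is expensive enough to build once per test run.
.ref_cache <- new.env()

ref_genome_cached <- function() {
  if (is.null(.ref_cache$g))
    .ref_cache$g <- reference_genome(seed = 1, with_cds = FALSE)
  .ref_cache$g
}

# Full identification -> classification pipeline on a sim_genome.
classify_pipeline <- function(g) {
  cand <- merge_candidates(g$candidates$list_a, g$candidates$list_b)
  verified <- verify_nbs(cand, g$domains)
  hits <- lapply(g$proteins, scan_motifs)
  k2 <- vapply(hits, kinase2_terminal_residue, character(1))
  list(labels = classify_all(verified, g$domains, k2),
       hits = hits, k2 = k2, verified = verified)
}
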