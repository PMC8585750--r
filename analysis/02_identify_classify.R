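#!/usr/bin/env Rscript
# Merge the two candidate lists, verify the NBS domain at E <= 1e-4, and
# classify every verified gene into the three groups / nine subclasses
# (CC score >= 0.5; bare NBS and NBS-LRR genes split by the kinase-2
# terminal residue).
suppressMessages({library(nbsprofiler); library(Biostrings)})

dir <- "results/reference_genome"
domains <- read.delim(file.path(dir, "domains.tsv"))
cand <- merge_candidates(readLines(file.path(dir, "candidates_a.txt")),
                         readLines(file.path(dir, "candidates_b.txt")))
proteins <- readAAStringSet(file.path(dir, "proteins.faa"))

verified <- verify_nbs(cand, domains)
k2 <- vapply(as.character(proteins), function(p)
  kinase2_terminal_residue(scan_motifs(p)), character(1))
labels <- classify_all(verified, domains, k2)
s <- summarize_classification(labels, n_annotated_genes = 24138)

write.table(labels, "results/classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Verified NBS genes:", s$n_nbs, "of", length(cand), "candidates ->",
    sprintf("%.2f%% of %d annotated genes\n", s$proportion_pct,
            s$n_annotated))
print(s$by_group, row.names = FALSE)
print(s$by_subclass, row.names = FALSE)
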