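#!/usr/bin/env Rscript
# Scan the eight conserved NBS-domain motifs, judge motif-order
# conservation, tabulate the kinase-2 terminal residue by lineage, and
# compute gene-structure statistics and the cross-species genome-size
# correlation.
suppressMessages({library(nbsprofiler); library(Biostrings)})

dir <- "results/reference_genome"
proteins <- readAAStringSet(file.path(dir, "proteins.faa"))
labels <- read.delim("results/classification.tsv")

hits <- lapply(as.character(proteins), scan_motifs)
hit_tab <- do.call(rbind, Map(function(h, g)
  if (nrow(h)) cbind(gene_id = g, h), hits, names(hits)))
write.table(hit_tab, "results/motif_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

verdicts <- vapply(hits, function(h) classify_motif_order(h)$verdict,
                   character(1))
cat("Motif order:", sum(verdicts == "conserved"), "conserved,",
    sum(verdicts == "flanked_repeat"), "flanked by repeats,",
    sum(verdicts == "core_change"), "core changes\n")

k2 <- vapply(hits, kinase2_terminal_residue, character(1))
print(kinase2_frequency_table(labels, k2), row.names = FALSE)

gm <- read_gene_models(file.path(dir, "annotation.gff3"))
nbs <- list(genes = gm$genes[gm$genes$gene_id %in% labels$gene_id, ],
            exons = gm$exons[gm$exons$gene_id %in% labels$gene_id, ])
st <- structure_from_gff(nbs)
st$group <- labels$group[match(st$gene_id, labels$gene_id)]
write.table(st, "results/structure.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Exons: %d total, mean %.2f per gene\n", sum(st$exon_count),
            mean(st$exon_count)))
cat(sprintf("Exon count vs gene length: r = %.2f (all genes)\n",
            exon_length_correlation(st)$r))
an <- subfamily_comparison(st, "gene_length_bp")
cat("Gene-length ANOVA p =", signif(an$anova_p, 3), "- letters:",
    paste(names(an$letters), an$letters, sep = ":", collapse = " "), "\n")

sp <- load_species_table()
cat(sprintf("Genome size vs NBS count: r = %.2f (13 species), %.2f without wheat\n",
            species_correlation(sp)$r,
            species_correlation(sp, exclude = "Triticum aestivum")$r))
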