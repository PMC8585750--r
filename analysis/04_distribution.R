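#!/usr/bin/env Rscript
# Map NBS genes to chromosomes and call cluster/singleton loci with the
# 250-kb chaining rule.
suppressMessages(library(nbsprofiler))

dir <- "results/reference_genome"
gm <- read_gene_models(file.path(dir, "annotation.gff3"))
labels <- read.delim("results/classification.tsv")
genes <- gm$genes[gm$genes$gene_id %in% labels$gene_id, ]

sp <- split_mapped_unmapped(genes)
cat(nrow(sp$mapped), "mapped genes;", nrow(sp$unmapped),
    "on unassembled scaffolds\n")
loci <- call_clusters(sp$mapped, window_bp = 250000)
write.table(loci, "results/loci.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
s <- cluster_summary(loci)
cat(sprintf("%d loci: %d clusters (%d genes, %.1f%%) + %d singletons; mean %.2f genes/cluster\n",
            s$n_loci, s$n_clusters, s$n_clustered_genes, s$clustered_pct,
            s$n_singletons, s$mean_genes_per_cluster))
dens <- aggregate(cbind(n_genes = start) ~ chromosome, data = sp$mapped,
                  FUN = length)
write.table(dens, "results/chromosome_density.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
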