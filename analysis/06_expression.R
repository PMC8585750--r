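#!/usr/bin/env Rscript
# FPKM from the counts matrix, expression categories from the per-gene
# maximum, dominant-tissue assignment and the heatmap-ready export.
suppressMessages(library(nbsprofiler))

dir <- "results/reference_genome"
counts_df <- read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
counts <- as.matrix(counts_df[, -1]); rownames(counts) <- counts_df$gene_id
samples <- read.delim(file.path(dir, "samples.tsv"))
gm <- read_gene_models(file.path(dir, "annotation.gff3"))
labels <- read.delim("results/classification.tsv")

exons <- gm$exons[gm$exons$gene_id %in% rownames(counts), ]
lens <- tapply(exons$end - exons$start + 1, exons$gene_id, sum)
fp <- fpkm(counts, lens[rownames(counts)],
           setNames(samples$total_fragments, samples$sample_id))
write.table(data.frame(gene_id = rownames(fp), round(fp, 3),
                       check.names = FALSE),
            "results/fpkm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cats <- categorize_expression(fp)
write.table(data.frame(gene_id = names(cats), category = cats),
            "results/expression_categories.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Detected:", sum(cats != "not_detected"), "of", length(cats), "genes;",
    sum(cats == "intermediate_high"), "intermediate/high,",
    sum(cats == "low"), "low,", sum(cats == "very_low"), "very low\n")
print(tissue_means(fp, samples), row.names = FALSE)
ta <- tissue_assignment(fp, samples)
print(ta$per_tissue, row.names = FALSE)
export_heatmap_matrix(fp, labels, path = "results/heatmap_log2fpkm.tsv")
cat("Wrote results/heatmap_log2fpkm.tsv\n")
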