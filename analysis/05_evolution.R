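#!/usr/bin/env Rscript
# Ka/Ks selection pressure per analyzable paralog pair (NG86 with
# Jukes-Cantor correction) and duplication-type classification from homolog
# ranks and collinear blocks.
suppressMessages({library(nbsprofiler); library(Biostrings)})

dir <- "results/reference_genome"
pairs <- read.delim(file.path(dir, "homolog_pairs.tsv"))
cds <- readDNAStringSet(file.path(dir, "cds.fna"))
labels <- read.delim("results/classification.tsv")
gm <- read_gene_models(file.path(dir, "annotation.gff3"))

sel <- select_pairs(pairs, labels)
cat(nrow(sel), "analyzable pairs (near-identical RNL quartet excluded)\n")
kk <- kaks_pairs(cds, sel)
kk$group <- sel$group_a
write.table(kk, "results/kaks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Selection calls:", paste(names(table(kk$selection_call)),
                              table(kk$selection_call), collapse = ", "),
    "\n")
ct <- subfamily_kaks_contrast(kk)
cat(sprintf("Mean Ka/Ks: CNL %.2f vs TNL %.2f (Welch p = %.3g)\n",
            ct$means[["CNL"]], ct$means[["TNL"]], ct$p))

rank_map <- do.call(rbind, lapply(split(gm$genes, gm$genes$chromosome),
  function(d) data.frame(gene_id = d$gene_id, chromosome = d$chromosome,
                         rank = order(order(d$start)))))
blocks <- detect_collinear_blocks(rank_map, pairs)
dups <- classify_duplications(labels$gene_id, rank_map, pairs, blocks)
write.table(dups, "results/duplications.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(duplication_summary(dups), row.names = FALSE)
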