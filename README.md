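# nbsprofiler

Genome-wide characterization of the plant **NBS-LRR** resistance-gene
family (nucleotide-binding site + leucine-rich repeat proteins, the largest
class of plant *R* genes), packaged as a tested R analysis pipeline. It was
built around the profile of the *Akebia trifoliata* family — 73 genes in a
24,138-gene annotation — and ships a synthetic-genome simulator with planted
ground truth so that every stage is testable without any external download.

The pipeline covers six analyses:

1. **Identification & classification** — merge two candidate lists, verify
   the NBS (NB-ARC) domain at E ≤ 10⁻⁴, and classify genes into the CNL /
   TNL / RNL groups and nine architecture subclasses from CC (coiled-coil
   score ≥ 0.5), TIR, RPW8 and LRR domain evidence. Bare NBS and NBS-LRR
   genes are assigned a lineage by the terminal residue of the kinase-2
   motif (W → non-TNL, D → TNL).
2. **Conserved motifs** — scan the eight canonical NB-ARC motifs (P-loop,
   RNBS-A, Kinase-2, RNBS-B, RNBS-C, GLPL, RNBS-D, MHDL), judge whether
   their observed order is conserved, flanked by repeats, or core-changed.
3. **Chromosomal distribution** — partition mapped genes into cluster and
   singleton loci by transitive gap chaining with a 250-kb window.
4. **Gene structure** — exon/length statistics, Pearson correlations, and
   one-way ANOVA + Tukey HSD subfamily contrasts with compact letters.
5. **Evolution** — Ka/Ks per paralog pair with the Nei–Gojobori (1986)
   method (equal weighting of minimal codon substitution pathways,
   Jukes–Cantor correction):

   Ks = −¾·ln(1 − 4/3·pS), Ka likewise, ω = Ka/Ks,
   with ω < 1, = 1, > 1 read as purifying, neutral and positive selection;
   plus duplication-origin classification (WGD/segmental > tandem >
   proximal > dispersed) from homolog ranks and simplified collinear-block
   detection.
6. **Expression** — FPKM = 10⁹·C/(N·L) from a counts matrix over 3 fruit
   tissues × 4 developmental stages, categorization by the per-gene maximum
   (0 / <3 / 3–30 / >30 FPKM), dominant-tissue assignment, heatmap export.

## Worked example

The numbered scripts under `analysis/` run the whole study on the reference
synthetic genome (73 NBS genes with planted truth, seed 1):

```sh
Rscript analysis/01_simulate_reference.R
Rscript analysis/02_identify_classify.R
...
Rscript analysis/06_expression.R
```

`02_identify_classify.R` prints

```
Verified NBS genes: 73 of 73 candidates -> 0.30% of 24138 annotated genes
 group  n
   CNL 50
   TNL 19
   RNL  4
```

i.e. the family is small (0.30% of the annotation) and CNL-dominated.
`04_distribution.R` prints

```
64 mapped genes; 9 on unassembled scaffolds
35 loci: 12 clusters (41 genes, 64.1%) + 23 singletons; mean 3.42 genes/cluster
```

showing that about two thirds of the mapped family sits in clusters, and
`05_evolution.R` prints

```
Selection calls: purifying 39
Mean Ka/Ks: CNL 0.31 vs TNL 0.46 (Welch p = 2.69e-05)
```

— every analyzable paralog pair is under purifying selection, with CNLs
under significantly stronger constraint than TNLs. Tables land under
`results/` (classification, motif hits, loci, Ka/Ks, duplication types,
FPKM, categories, heatmap matrix).

A quick interactive tour:

```r
library(nbsprofiler)
g <- reference_genome(seed = 1)
k2 <- vapply(g$proteins, function(p)
  kinase2_terminal_residue(scan_motifs(p)), character(1))
labels <- classify_all(verify_nbs(g$genes$gene_id, g$domains), g$domains, k2)
summarize_classification(labels, 24138)$by_group
cluster_summary(call_clusters(split_mapped_unmapped(g$genes)$mapped))
```

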