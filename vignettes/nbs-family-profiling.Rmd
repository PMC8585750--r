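---
title: "Profiling a plant NBS-LRR gene family: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling a plant NBS-LRR gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsprofiler)
```

# The scientific setting

Plant genomes defend themselves largely through NBS-LRR proteins: a
nucleotide-binding site (NB-ARC) domain coupled to C-terminal leucine-rich
repeats, with an N-terminal coiled-coil (CC), TIR or RPW8 domain defining
the three subfamilies CNL, TNL and RNL (CNL + RNL are jointly "non-TNL").
Characterizing such a family genome-wide means answering a fixed set of
questions: how many genes, in which architecture subclasses; where they sit
on chromosomes (clusters versus singletons); which duplication mechanisms
built the family; what selection pressure its paralogs experience; and
where and how strongly the genes are expressed. nbsprofiler implements that
question set as composable functions plus a simulator that generates
genomes in which every answer is known in advance.

# Classification model

A gene is an NBS gene if it carries at least one NB-ARC domain call at
E ≤ 10⁻⁴ (`thresholds()$nbs_evalue_max`); candidates missing from the
domain table are dropped with a warning rather than silently retained. The
nine-subclass scheme is determined by domain presence with the precedence
RPW8 > TIR > CC:

* RPW8 → RNL (the canonical RNL carries the full RPW8-NBS-LRR set; RPW8
  without LRR is still grouped RNL but flagged low-confidence),
* TIR → TNL (with LRR) or TN,
* CC (coiled-coil score ≥ 0.5, a propensity score rather than an E-value,
  since coiled-coils are poorly captured by profile searches) → CNL or CN.

Genes with none of the three N-terminal domains (bare NBS "N" and NBS-LRR
"NL" architectures) occur in both lineages, and domain content alone cannot
place them. We resolve them with the kinase-2 terminal residue: tryptophan
(W) is the non-TNL signature and aspartate (D) the TNL signature, a
distinction strong enough in practice (about 89% of non-TNLs and 68% of
TNLs in the motivating family) to serve as the tie-breaker; genes with
neither residue default to the CNL group and are flagged low-confidence.
Whether real studies resolve these genes by phylogeny instead is usually
unstated; the residue rule is our explicit, testable substitute.

# Motif scanning instead of de-novo discovery

De-novo motif discovery (MEME-style) is replaced by scanning a curated
library of the eight canonical NB-ARC motifs, shipped as YAML
(`inst/extdata/motif_library.yaml`). Each motif is a list of per-position
residue classes, width 6–50; a window scores one point per position whose
residue falls in the class and is a candidate hit at ≥ 80% of the width
(rounded up; configurable per motif via `min_score`). Overlaps are resolved
highest-score-first, ties leftmost, then by canonical motif order — all
deterministic. This preserves everything downstream analyses need (motif
locations, order, the kinase-2 terminal residue) while removing an external
binary; it does not attempt to reproduce any particular published
position-weight matrices, which are not recoverable from text.

Motif-order conservation is judged on the position-ordered name sequence:
*conserved* when no name repeats and the sequence follows the canonical
N-to-C order; *flanked_repeat* when a contiguous core run in canonical
order exists and every extra occurrence repeats a core motif outside the
run; *core_change* otherwise; *insufficient* with fewer than two distinct
motifs (so a single motif repeated any number of times is never a core
change).

# Cluster calling

"Genes within a 250-kb sliding window" is operationalized as transitive gap
chaining: genes on a chromosome, sorted by start, join one locus while the
gap from the running maximum end to the next start (floored at zero for
overlaps) stays within the window. This is order-free, deterministic, and
provably equivalent to merging every pair of genes whose pairwise gap is
within the window and taking the transitive closure — the test suite
asserts that equivalence against a brute-force union-find oracle on a
thousand random instances, along with monotonicity (loci only merge as the
window grows). Whether published cluster conventions additionally bound the
number of intervening non-NBS genes is not stated in our source material;
we deliberately use the distance-only rule.

# Duplication typing

Duplication origins are assigned per gene with the priority
WGD/segmental > tandem > proximal > dispersed: membership in a collinear
block wins; otherwise a same-chromosome homolog within 2 ranks (at most one
intervening gene) makes a tandem, within 10 ranks a proximal; any remaining
homolog evidence means dispersed; no homolog above thresholds leaves a
singleton. Collinear blocks are detected by simplified order-consistent
chaining of homolog pairs (≥ 5 pairs, rank gaps ≤ 25, one direction per
chain) rather than a full dynamic program with E-value scoring — at the
scale of planted blocks the two agree, and the tests pin the behaviour with
planted, shuffled and sub-threshold fixtures.

# Ka/Ks

`kaks_ng86()` implements Nei–Gojobori (1986) counting: per codon, the
synonymous site count is the fraction of its nine one-step nucleotide
changes that preserve the amino acid, with changes to stop codons counted
as nonsynonymous so that sites always sum to exactly three per codon;
differences between codons are partitioned by averaging equally over all
minimal substitution pathways, excluding pathways through stop codons; both
proportions get the Jukes–Cantor correction, and proportions ≥ 3/4 are
reported as saturated (undefined ω) rather than extrapolated. Pathway
counts are precomputed for all 61 × 61 sense-codon pairs and cached, which
makes the estimator fast enough for simulation studies; an independently
coded exhaustive-pathway oracle in the test suite checks the table exactly.

Pair selection mirrors the "lower limit for orthologs" filtering of
published pipelines as an identity window [0.4, 0.99] with ≥ 100 aligned
residues: near-identical paralog sets (such as the reference RNL quartet at
0.995 identity) fall above the window and drop out of the Ka/Ks analysis as
a group. Subfamily means are contrasted with a Welch two-sample t test; the
choice of test in the motivating study is unstated, and Welch is the
conservative default for unequal group sizes and variances.

# The synthetic-data generator

The generator is the package's substitute for a sequenced genome. A
`sim_config()` fixes the seed, chromosome count, NBS gene count, subclass
mix, cluster plan, duplication plan, per-subfamily ω, codon length, and a
negative-binomial expression specification. Layout proceeds chromosome by
chromosome: loci (planted clusters and singleton loci) separated by
background-gene runs whose spacing guarantees inter-locus gaps above the
chaining window; tandem partners occupy adjacent ranks inside clusters;
proximal partners are consecutive singleton loci separated by a small
background run (rank distance ≤ 10 yet physically beyond the window);
dispersed partners land on different chromosomes; each WGD pair is embedded
in a collinear run of five background homolog pairs spanning two
chromosomes, and WGD loci are padded with ≥ 31 background genes on both
sides so no unrelated pair can chain into the block.

Design choices worth knowing:

* **Motif implantation uses the exact library consensus strings**, so
  scanner recall on truth genes is exactly 100%. Filler (non-motif) protein
  regions are drawn from a reduced ten-letter residue alphabet chosen so
  that every library motif has several positions a filler residue can never
  match — a filler window therefore cannot reach any score threshold, and
  planted motif content is *provably* what the scanner reports. This is a
  determinism device, not a claim about real protein composition.
* **Codon evolution is a minimal Markov scheme**, not a realistic
  substitution model: single-nucleotide proposals uniform over sites and
  alternative bases, stop-codon proposals rejected, synonymous proposals
  accepted, nonsynonymous proposals accepted with probability ∝ ω. Because
  NG86 books mutations-to-stop as nonsynonymous sites while the simulator
  never performs them, the acceptance probability is scaled by the
  ancestor's ratio of all nonsynonymous one-step changes (stops included)
  to those excluding stops; without this correction the estimated ω would
  sit ~5% below nominal. Only the ω ratio is controlled — transition bias,
  rate variation and indels are out of scope.
* **Proteins and coding sequences are decoupled.** The protein file carries
  the implanted motif architecture and is authoritative for domain and
  motif analyses; homolog-family coding sequences are evolved from a shared
  random ancestor at the configured ω and are authoritative for Ka/Ks. A
  descendant CDS is not re-translated into the protein file. The homolog
  table's identity column is likewise planted metadata (driving the pair
  filter), not recomputed from the sequences.
* **Counts are negative-binomial** with per-sample lognormal library-size
  factors (σ = 0.1 on the log scale), dispersion size 10, and expected
  counts from the FPKM identity μ = FPKM·L·N/10⁹, over the fixed 3-tissue ×
  4-stage design (one library each). Stage multipliers (0.6, 0.8, 1.2, 1.4)
  shape rind expression across development.

## The reference genome

`reference_genome()` realizes a fixed 73-gene profile reconstructing the
published summary tallies of the *A. trifoliata* family: subclass counts
(31 CNL, 13 CN, 4 NL, 2 N; 5 TNL, 1 TN, 10 NL, 3 N; 4 RNL), 64 mapped +
9 unplaced genes, the exact cluster size spectrum (five 2s, two 3s, three
4s, one 6, one 7 = 12 clusters, 41 genes, plus 23 singletons), duplication
counts 33/29/9/2 (tandem/dispersed/proximal/WGD), 249 exons with the
published per-group means, kinase-2 residues W in 48 of 54 non-TNLs and D
in 13 of 19 TNLs, motif order conserved/flanked/changed in 57/14/2 genes,
P-loop in 66 and GLPL in 68 genes, and an expression profile with 7 silent
genes, 1 intermediate/high (an RNL, rind), 27 low and 38 very low, dominant
in rind/seed/flesh for 46/16/4 of the 66 expressed genes. Published
summaries do not pin down the cross-tabulations (which subclass sits in
which cluster, which gene carries which exon count), so those assignments
are fixed synthetic choices made once for internal consistency — the
profile is a reconstruction constrained by the printed marginals, not
recovered data. Per-gene×tissue expression means use a dominant-tissue base
level with a 0.25 off-tissue ratio, and per-tissue scale factors are solved
at run time so the grand tissue means hit 2.2/1.5/1.4 FPKM
(rind/flesh/seed) exactly in expectation.

One reconstruction note: the kinase-2 motif is implanted in all 73
reference genes although published counts list it in 70, because the
published residue frequencies are quoted over all 54 + 19 genes and the
architecture tie-break needs the residue on every NL/N gene; the motivating
material is internally inconsistent on this point and we resolved it in
favour of the frequency denominators.

# What the tests do and do not show

Passing tests show that each stage implements its stated rule exactly
(oracle equivalences, planted-truth recovery at 100% for noise-free domain
tables, ≥ 95% duplication-type recovery across 100 random genomes, ω
recovery within ±0.05 at 1,000 codons and 200 replicates, ANOVA type-I
error within 0.05 ± 0.02 over 1,000 null simulations), and that the
composed pipeline reproduces the published family statistics on the
reference genome. They do not show robustness to the noise real annotation
pipelines produce — fragmented gene models, spurious domain calls,
ambiguous coiled-coil scores, alignment error in CDS pairs — because the
generator deliberately produces clean evidence; nor do they validate the
motif library against real NB-ARC sequence diversity.

# Problem sizes and numerical conventions

The test suite and acceptance script run the reference genome (24,138
genes, 73 NBS), 100 randomized 20-gene genomes for duplication recovery,
200 codon-pair replicates of 1,000 codons for ω recovery, 1,000 random
instances for the cluster oracle and 1,000 null simulations for the ANOVA
calibration — sizes chosen so the full suite completes in a few minutes on
one CPU while keeping Monte-Carlo error well inside the asserted bands.
Rounding follows the conventions of the field's tables: correlations to 2
decimals, percentages to 1, means to 2. Coordinates are GFF3 (1-based,
closed); chromosome order is natural sort; all tie-breaks (overlapping
motif hits, tissue argmax, locus numbering) are fixed and documented so
identical inputs give identical outputs.

# Known limitations

* The CC/TIR/RPW8/LRR evidence boundary is a domain-call table; the package
  neither runs nor wraps homology search tools.
* Collinearity detection is desk-scale: planted blocks, not genome-scale
  synteny with inversions and nested duplications.
* NG86 is the only Ka/Ks model (no gamma-series or maximum-likelihood
  variants); saturated pairs are reported as undefined rather than
  rescued.
* FPKM uses summed exon length as the effective length; whether published
  values used exonic or full gene length is typically unstated.
* Expression categories cut on the per-gene maximum FPKM across samples —
  a single sample above 30 FPKM makes a gene intermediate/high, which
  matches how single high-sample genes are described in practice, but a
  mean- or median-based rule would be stricter.
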