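#' Reference synthetic genome: a 73-gene NBS family
#'
#' A fixed per-gene layout reconstructing the published summary tallies of
#' the Akebia trifoliata NBS family: 73 genes in three groups (50 CNL, 19
#' TNL, 4 RNL) and nine subclasses; 64 genes mapped on 14 chromosomes and 9
#' on unassembled scaffolds; 12 clusters (five of 2 genes, two of 3, three
#' of 4, one of 6, one of 7) plus 23 singleton loci; duplication origins 33
#' tandem, 29 dispersed, 9 proximal, 2 WGD; 249 exons in total; kinase-2
#' terminal residues W in 48 of 54 non-TNLs and D in 13 of 19 TNLs; motif
#' order conserved in 57 genes, flanked by repeats in 14, core-changed in 2;
#' P-loop present in 66 genes and GLPL in 68; 66 genes expressed (1
#' intermediate/high, 27 low, 38 very low) with 46 rind-, 16 seed- and 4
#' flesh-dominant genes. Cross-tabulations the published summaries do not
#' pin down (which subclass sits in which cluster, etc.) are fixed synthetic
#' choices made once for internal consistency.
#'
#' @name reference
NULL

# One locus of the reference layout.
ref_locus <- function(chromosome, subclass, dup, hg,
                      ivg = NULL, pre_bg = NA, max_gap = NA) {
  n <- length(subclass)
  if (is.null(ivg)) ivg <- rep(0L, n)
  data.frame(chromosome = chromosome, subclass = subclass,
             dup_type = dup, hgroup = hg, ivg = as.integer(ivg),
             pre_bg = c(as.integer(pre_bg), rep(0L, n - 1)),
             max_gap = max_gap, stringsAsFactors = FALSE)
}

#' Build the reference 73-gene profile
#'
#' @return A layout-ordered profile data frame consumable by the genome
#'   realizer, with planted subclass, cluster, duplication, motif and
#'   expression truth per gene.
#' @export
reference_profile <- function() {
  CNL <- "CNL"; CN <- "CN"; NLC <- "NL_CC"; NC <- "N_CC"
  TNL <- "TNL"; TN <- "TN"; NLT <- "NL_TIR"; NT <- "N_TIR"; RNL <- "RNL"
  td <- "tandem"; px <- "proximal"; dp <- "dispersed"; wg <- "wgd_segmental"
  L <- list()
  # hgroups: T1-T14 tandem, RQ the RNL quartet, PX1-PX4 proximal,
  # W1 the WGD pair, D1-D11 CNL dispersed, E1 (TNL pair), E2 (TNL triple)
  H <- function(x) x  # readable tags; converted to integers below
  # --- chr1: two 4-gene clusters + two dispersed singletons
  L <- c(L, list(
    ref_locus("chr1", c(CNL, CNL, CNL, CNL), td, H(c("T1","T1","T2","T2")),
              ivg = c(0, 0, 2, 0), max_gap = 60000),
    ref_locus("chr1", c(CN, CN, CNL, CNL), td, H(c("T3","T3","T4","T4")),
              ivg = c(0, 0, 2, 0), max_gap = 60000),
    ref_locus("chr1", CNL, dp, "D5"),
    ref_locus("chr1", CNL, dp, "D6")))
  # --- chr2: proximal pair + first WGD gene
  L <- c(L, list(
    ref_locus("chr2", CN, px, "PX1"),
    ref_locus("chr2", CN, px, "PX1", pre_bg = 6),
    ref_locus("chr2", CN, wg, "W1")))
  # --- chr3: 7-gene cluster (tandem triple + pair + 2 dispersed) + 2 singles
  L <- c(L, list(
    ref_locus("chr3", c(CNL, CNL, CNL, CN, CN, CNL, CNL),
              c(td, td, td, td, td, dp, dp),
              H(c("T5","T5","T5","T6","T6","D1","D2")),
              ivg = c(0, 0, 0, 2, 0, 2, 2), max_gap = 60000),
    ref_locus("chr3", CNL, dp, "D5"),
    ref_locus("chr3", CNL, dp, "D7")))
  # --- chr4: 6-gene cluster (RNL pair + TNL pair + 2 dispersed),
  #     the third RNL as a distant singleton, one dispersed single
  L <- c(L, list(
    ref_locus("chr4", c(RNL, RNL, TNL, TNL, TNL, CNL),
              c(td, td, td, td, dp, dp),
              H(c("RQ","RQ","T7","T7","E1","D3")),
              ivg = c(0, 0, 2, 0, 2, 2), max_gap = 60000),
    ref_locus("chr4", RNL, dp, "RQ"),
    ref_locus("chr4", CNL, dp, "D6")))
  # --- chr5
  L <- c(L, list(ref_locus("chr5", NLC, dp, "D1")))
  # --- chr7: 2-gene cluster + single
  L <- c(L, list(
    ref_locus("chr7", c(CNL, CNL), td, H(c("T8","T8")), max_gap = 60000),
    ref_locus("chr7", CNL, dp, "D7")))
  # --- chr8: 2-gene TNL cluster
  L <- c(L, list(
    ref_locus("chr8", c(TNL, NLT), td, H(c("T9","T9")), max_gap = 60000)))
  # --- chr9: 3-gene cluster (TNL pair + TNL dispersed) + single
  L <- c(L, list(
    ref_locus("chr9", c(NLT, NLT, TNL), c(td, td, dp),
              H(c("T10","T10","E1")), ivg = c(0, 0, 2), max_gap = 60000),
    ref_locus("chr9", CNL, dp, "D3")))
  # --- chr10: proximal CN triple, proximal TNL pair, second WGD gene,
  #     one dispersed single
  L <- c(L, list(
    ref_locus("chr10", CN, px, "PX2"),
    ref_locus("chr10", CN, px, "PX2", pre_bg = 5),
    ref_locus("chr10", CN, px, "PX2", pre_bg = 5),
    ref_locus("chr10", NLT, px, "PX3"),
    ref_locus("chr10", NT, px, "PX3", pre_bg = 6),
    ref_locus("chr10", CN, wg, "W1"),
    ref_locus("chr10", CNL, dp, "D4")))
  # --- chr11: 3-gene cluster, 2-gene cluster, 2-gene proximal cluster
  L <- c(L, list(
    ref_locus("chr11", c(NLT, NLT, CNL), c(td, td, dp),
              H(c("T11","T11","D4")), ivg = c(0, 0, 2), max_gap = 60000),
    ref_locus("chr11", c(NLT, NT), td, H(c("T12","T12")), max_gap = 60000),
    ref_locus("chr11", c(CNL, CNL), px, H(c("PX4","PX4")),
              ivg = c(0, 3), max_gap = 200000)))
  # --- chr13: 4-gene cluster + two singles
  L <- c(L, list(
    ref_locus("chr13", c(CN, CN, CNL, CNL), td, H(c("T13","T13","T14","T14")),
              ivg = c(0, 0, 2, 0), max_gap = 60000),
    ref_locus("chr13", NC, dp, "D8"),
    ref_locus("chr13", CNL, dp, "D9")))
  # --- chr14, chr15
  L <- c(L, list(ref_locus("chr14", NLT, dp, "E2")))
  L <- c(L, list(ref_locus("chr15", NLC, dp, "D2")))
  # --- chr16: 2-gene TNL cluster
  L <- c(L, list(
    ref_locus("chr16", c(TN, NLT), td, H(c("T15","T15")), max_gap = 60000)))
  # --- unassembled scaffolds: 6 CNL-group, 2 TNL-group, 1 RNL
  scf <- list(c(NC, "D8"), c(CNL, "D9"), c(NLC, "D10"), c(CNL, "D10"),
              c(NLC, "D11"), c(CNL, "D11"), c(NLT, "E2"), c(NT, "E2"),
              c(RNL, "RQ"))
  for (i in seq_along(scf))
    L <- c(L, list(ref_locus(paste0("scaffold_", i), scf[[i]][1], dp,
                             scf[[i]][2])))

  prof <- do.call(rbind, L)
  block_sizes <- vapply(L, nrow, integer(1))
  prof$locus <- rep(seq_along(L), block_sizes)
  prof$group <- SUBCLASSES$group[match(prof$subclass, SUBCLASSES$subclass)]
  prof$hgroup <- match(prof$hgroup, unique(prof$hgroup))
  prof$identity <- ifelse(prof$subclass == "RNL", 0.995, NA_real_)
  prof$gene_id <- sprintf("nbs_%03d", seq_len(nrow(prof)))

  # Exon-count multisets per group, spread over the layout with a fixed
  # permutation. CNL: 36 of 50 genes below 3 exons, one 15-exon gene, sum
  # 162 (mean 3.24); TNL: sum 69 (mean 3.63), 11 genes above 3; RNL: sum 18
  # (mean 4.50). Group totals give 249 exons over 73 genes (mean 3.41).
  cnl_exons <- with_seed(101, sample(c(rep(1, 9), rep(2, 27), rep(5, 4),
                                       rep(6, 6), 9, 9, 10, 15)))
  tnl_exons <- with_seed(102, sample(c(rep(1, 5), rep(3, 3), rep(4, 4),
                                       rep(5, 6), 9)))
  rnl_exons <- c(2, 4, 6, 6)
  prof$exon_count <- NA_integer_
  prof$exon_count[prof$group == "CNL"] <- cnl_exons
  prof$exon_count[prof$group == "TNL"] <- tnl_exons
  prof$exon_count[prof$group == "RNL"] <- rnl_exons

  # kinase-2 terminal residue: D in the 13 TNL-group genes lacking TIR
  # (their classification relies on it) plus none else in that group; D in
  # 6 CC-carrying CNL-group genes (the proximal CNs and one WGD CN); W
  # everywhere else, including all RNLs.
  prof$kinase2 <- "W"
  prof$kinase2[prof$subclass %in% c("NL_TIR", "N_TIR")] <- "D"
  cn_d <- prof$gene_id[prof$subclass == "CN" &
                         prof$dup_type %in% c("proximal", "wgd_segmental")]
  prof$kinase2[prof$gene_id %in% head(cn_d, 6)] <- "D"

  # planted motif irregularities
  prof$motif_order <- "conserved"
  flanked <- c("nbs_002", "nbs_006", "nbs_012", "nbs_018", "nbs_021",
               "nbs_024", "nbs_032", "nbs_036", "nbs_040", "nbs_043",
               "nbs_047", "nbs_052", "nbs_059", "nbs_070")
  core_change <- c("nbs_010", "nbs_027")
  prof$motif_order[prof$gene_id %in% flanked] <- "flanked_repeat"
  prof$motif_order[prof$gene_id %in% core_change] <- "core_change"
  prof$p_loop <- !(prof$gene_id %in% c("nbs_007", "nbs_017", "nbs_035",
                                       "nbs_042", "nbs_050", "nbs_062",
                                       "nbs_066"))
  prof$glpl <- !(prof$gene_id %in% c("nbs_004", "nbs_019", "nbs_057",
                                     "nbs_033", "nbs_072"))

  # expression truth: 7 silent; 1 intermediate/high (the first RNL, rind);
  # 27 low (20 rind / 6 seed / 1 flesh); 38 very low (25 rind / 10 seed /
  # 3 flesh)
  prof$expr_category <- NA_character_
  prof$dominant_tissue <- NA_character_
  prof$expr_base <- 0
  silent <- c("nbs_009", "nbs_011", "nbs_014", "nbs_028", "nbs_065",
              "nbs_067", "nbs_071")
  high <- prof$gene_id[prof$subclass == "RNL"][1]
  prof$expr_category[prof$gene_id %in% silent] <- "not_detected"
  prof$expr_category[prof$gene_id == high] <- "intermediate_high"
  prof$dominant_tissue[prof$gene_id == high] <- "rind"
  prof$expr_base[prof$gene_id == high] <- 60
  rest <- prof$gene_id[is.na(prof$expr_category)]
  low_set <- rest[round(seq(1, length(rest), length.out = 27))]
  vlow_set <- setdiff(rest, low_set)
  prof$expr_category[prof$gene_id %in% low_set] <- "low"
  prof$expr_base[prof$gene_id %in% low_set] <- 8
  prof$expr_category[prof$gene_id %in% vlow_set] <- "very_low"
  prof$expr_base[prof$gene_id %in% vlow_set] <- 0.8
  dom_for <- function(set, n_rind, n_seed, n_flesh)
    rep(c("rind", "seed", "flesh"), c(n_rind, n_seed, n_flesh))
  prof$dominant_tissue[prof$gene_id %in% low_set] <- dom_for(low_set, 20, 6, 1)
  prof$dominant_tissue[prof$gene_id %in% vlow_set] <-
    dom_for(vlow_set, 25, 10, 3)

  # integrity checks against the published marginals
  stopifnot(
    nrow(prof) == 73,
    sum(prof$group == "CNL") == 50, sum(prof$group == "TNL") == 19,
    sum(prof$group == "RNL") == 4,
    sum(prof$exon_count) == 249,
    sum(prof$dup_type == "tandem") == 33,
    sum(prof$dup_type == "dispersed") == 29,
    sum(prof$dup_type == "proximal") == 9,
    sum(prof$dup_type == "wgd_segmental") == 2,
    sum(prof$kinase2 == "W" & prof$group != "TNL") == 48,
    sum(prof$kinase2 == "D" & prof$group == "TNL") == 13,
    sum(prof$motif_order == "conserved") == 57,
    sum(prof$motif_order == "flanked_repeat") == 14,
    sum(prof$motif_order == "core_change") == 2,
    sum(prof$p_loop) == 66, sum(prof$glpl) == 68,
    sum(prof$expr_category == "not_detected") == 7,
    sum(prof$expr_category == "low") == 27,
    sum(prof$expr_category == "very_low") == 38,
    sum(prof$expr_category == "intermediate_high") == 1
  )
  rownames(prof) <- NULL
  prof
}

#' Configuration matching the reference study conditions
#'
#' @param seed Master seed.
#' @return A `sim_config` whose annotated-gene total is 24,138 (73 NBS +
#'   24,065 background genes), with the cluster chaining window at 250 kb,
#'   subfamily Ka/Ks ratios 0.31 (CNL), 0.42 (TNL) and 0.10 (RNL),
#'   1,000-codon coding sequences and tissue mean FPKM 2.2/1.5/1.4
#'   (rind/flesh/seed).
#' @export
reference_config <- function(seed = 1) {
  mix <- c(CNL = 31, CN = 13, NL_CC = 4, N_CC = 2, TNL = 5, TN = 1,
           NL_TIR = 10, N_TIR = 3, RNL = 4) / 73
  cfg <- list(seed = seed, n_chromosomes = 16, chrom_length_bp = 4e7,
              n_nbs_genes = 73, subclass_mix = mix,
              cluster_spec = lapply(c(4, 4, 7, 6, 2, 3, 2, 3, 2, 2, 4, 2),
                                    function(m) c(m, 60000)),
              duplication_spec = c(wgd = 2, tandem = 33, proximal = 9,
                                   dispersed = 29),
              omega_values = c(CNL = 0.31, TNL = 0.42, RNL = 0.10),
              codon_length = 1000,
              expr_spec = list(tissue_means = c(rind = 2.2, flesh = 1.5,
                                                seed = 1.4),
                               stage_multipliers = c(young = 0.6,
                                                     enlargement = 0.8,
                                                     coloring = 1.2,
                                                     mature = 1.4),
                               dispersion = 10, library_size = 2e7,
                               off_tissue_ratio = 0.25),
              n_background_genes = 24065, n_unplaced = 9,
              window_bp = 250000)
  class(cfg) <- "sim_config"
  cfg
}

# Per-gene x tissue mean FPKM: dominant tissue carries the base level,
# other tissues a fixed fraction; per-tissue scale factors are solved so the
# grand tissue means hit the configured targets exactly.
reference_expression_means <- function(profile, expr_spec) {
  base <- profile$expr_base
  dom <- profile$dominant_tissue
  off <- expr_spec$off_tissue_ratio
  raw <- vapply(TISSUE_ORDER, function(t)
    ifelse(base == 0, 0, ifelse(!is.na(dom) & dom == t, base, off * base)),
    numeric(length(base)))
  alpha <- expr_spec$tissue_means[TISSUE_ORDER] * nrow(profile) /
    colSums(raw)
  m <- sweep(raw, 2, alpha, "*")
  rownames(m) <- profile$gene_id
  m
}

#' Generate the reference synthetic genome
#'
#' Realizes the fixed reference profile under a seed: coordinates, protein
#' and coding sequences, domain table, homolog pairs, rank map, expression
#' counts and ground truth.
#'
#' @param seed Master seed (default 1).
#' @param with_cds Evolve coding sequences (default TRUE).
#' @return A `sim_genome` list (see [generate_genome()]).
#' @export
reference_genome <- function(seed = 1, with_cds = TRUE) {
  cfg <- reference_config(seed)
  prof <- reference_profile()
  g <- realize_genome(prof, cfg, with_cds = with_cds)
  tmat <- reference_expression_means(prof, cfg$expr_spec)
  samples <- make_sample_sheet()
  mean_fpkm <- matrix(0, nrow(prof), nrow(samples),
                      dimnames = list(prof$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    v <- tmat[, samples$tissue[j]]
    if (samples$tissue[j] == "rind")
      v <- v * cfg$expr_spec$stage_multipliers[[samples$stage[j]]]
    mean_fpkm[, j] <- v
  }
  g$counts <- with_seed(child_seed(seed, "refcounts"), {
    sf <- exp(stats::rnorm(nrow(samples), 0, 0.1))
    totals <- round(cfg$expr_spec$library_size * sf)
    samples$total_fragments <- totals
    simulate_counts_matrix(mean_fpkm,
                           g$exonic_length[prof$gene_id],
                           totals, cfg$expr_spec$dispersion)
  })
  g$samples <- samples
  g$mean_fpkm <- mean_fpkm
  g$truth$expression <- prof[, c("gene_id", "expr_category",
                                 "dominant_tissue", "expr_base")]
  class(g) <- "sim_genome"
  g
}
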