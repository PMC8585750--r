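#' Simulation configuration
#'
#' Describes a synthetic genome annotation whose NBS family has controlled
#' subclass composition, cluster geometry, planted duplication types, codon
#' pairs evolved at chosen Ka/Ks ratios, and negative-binomial expression
#' counts. A fixed seed yields byte-identical outputs.
#'
#' @param seed Integer master seed.
#' @param n_chromosomes Number of assembled chromosomes.
#' @param chrom_length_bp Nominal chromosome length in bp.
#' @param n_nbs_genes Number of NBS genes to plant.
#' @param subclass_mix Named proportions over the nine subclasses (must sum
#'   to 1 within 1e-9).
#' @param cluster_spec List of `c(n_genes, max_gap_bp)` planted clusters;
#'   genes not in clusters are placed as singletons violating the chaining
#'   window.
#' @param duplication_spec Named counts per duplication type (`wgd`,
#'   `tandem`, `proximal`, `dispersed`); `tandem`, `proximal`, `dispersed`
#'   and `wgd` counts must be even (genes are planted in pairs); genes not
#'   covered are singletons without homologs. All tandem genes must fit into
#'   the planted clusters.
#' @param omega_values Named Ka/Ks ratios per group (`CNL`, `TNL`, `RNL`)
#'   used when evolving homolog-pair coding sequences.
#' @param codon_length Codons per coding sequence.
#' @param expr_spec List with `tissue_means` (named per-tissue mean FPKM),
#'   `stage_multipliers` (named per-stage factors applied to rind),
#'   `dispersion` (negative-binomial size parameter) and `library_size`
#'   (mean mapped fragments per sample).
#' @param n_background_genes Non-NBS annotated genes providing rank
#'   structure.
#' @param n_unplaced NBS genes placed on unassembled scaffolds.
#' @param window_bp Cluster chaining window the layout respects (default
#'   250000).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 4,
                       chrom_length_bp = 3e7,
                       n_nbs_genes = 20,
                       subclass_mix = c(CNL = 0.35, CN = 0.15, NL_CC = 0.05,
                                        N_CC = 0.05, TNL = 0.1, TN = 0.05,
                                        NL_TIR = 0.1, N_TIR = 0.05,
                                        RNL = 0.1),
                       cluster_spec = list(c(3, 50000), c(2, 100000)),
                       duplication_spec = c(wgd = 0, tandem = 4, proximal = 2,
                                            dispersed = 4),
                       omega_values = c(CNL = 0.31, TNL = 0.42, RNL = 0.1),
                       codon_length = 500,
                       expr_spec = list(tissue_means = c(rind = 2.2,
                                                         flesh = 1.5,
                                                         seed = 1.4),
                                        stage_multipliers = c(young = 0.6,
                                                              enlargement = 0.8,
                                                              coloring = 1.2,
                                                              mature = 1.4),
                                        dispersion = 10,
                                        library_size = 2e7),
                       n_background_genes = 400,
                       n_unplaced = 0,
                       window_bp = 250000) {
  assert_that(abs(sum(subclass_mix) - 1) <= 1e-9,
              "subclass_mix must sum to 1 (got %.12f)", sum(subclass_mix))
  assert_that(all(subclass_mix >= 0), "subclass_mix proportions must be >= 0")
  assert_that(all(names(subclass_mix) %in% SUBCLASSES$subclass),
              "unknown subclass in subclass_mix")
  assert_that(n_nbs_genes >= 0 && n_background_genes >= 0 && n_unplaced >= 0,
              "all counts must be >= 0")
  cluster_genes <- sum(vapply(cluster_spec, `[`, numeric(1), 1))
  assert_that(cluster_genes <= n_nbs_genes - n_unplaced,
              "cluster_spec requests %d genes but only %d placeable NBS genes",
              cluster_genes, n_nbs_genes - n_unplaced)
  dup <- duplication_spec
  for (k in c("wgd", "tandem", "proximal", "dispersed"))
    if (is.na(dup[k])) dup[k] <- 0
  assert_that(all(dup >= 0), "duplication counts must be >= 0")
  assert_that(all(dup[c("wgd", "tandem", "proximal", "dispersed")] %% 2 == 0),
              "duplication counts must be even (genes are planted in pairs)")
  assert_that(sum(dup) <= n_nbs_genes,
              "duplication_spec covers more genes than n_nbs_genes")
  assert_that(dup[["tandem"]] <= cluster_genes,
              "tandem genes (%d) exceed cluster capacity (%d)",
              dup[["tandem"]], cluster_genes)
  if (dup[["wgd"]] > 0)
    assert_that(n_chromosomes >= 2, "WGD pairs need at least 2 chromosomes")
  assert_that(all(omega_values > 0), "omega values must be positive")
  assert_that(expr_spec$dispersion > 0, "dispersion must be positive")
  assert_that(codon_length >= 10, "codon_length too short")
  structure(list(seed = seed, n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 n_nbs_genes = n_nbs_genes, subclass_mix = subclass_mix,
                 cluster_spec = cluster_spec, duplication_spec = dup,
                 omega_values = omega_values, codon_length = codon_length,
                 expr_spec = expr_spec,
                 n_background_genes = n_background_genes,
                 n_unplaced = n_unplaced, window_bp = window_bp),
            class = "sim_config")
}
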