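#' Negative-binomial count simulation
#'
#' Counts emulate an RNA-seq experiment over 3 fruit tissues (rind, flesh,
#' seed) x 4 developmental stages (young, enlargement, coloring, mature),
#' one library per tissue-stage combination. Per-sample library sizes get a
#' lognormal factor; expected counts follow the FPKM identity
#' `mu = fpkm_mean * L * N / 1e9`.
#'
#' @name sim_counts
NULL

make_sample_sheet <- function() {
  grid <- expand.grid(stage = STAGE_ORDER, tissue = TISSUE_ORDER,
                      stringsAsFactors = FALSE)
  data.frame(sample_id = paste(grid$tissue, grid$stage, sep = "_"),
             tissue = grid$tissue, stage = grid$stage,
             stringsAsFactors = FALSE)
}

# Core: counts from a gene x sample matrix of expected FPKM.
simulate_counts_matrix <- function(mean_fpkm, lengths, totals, dispersion) {
  assert_that(dispersion > 0, "dispersion must be positive")
  mu <- sweep(sweep(mean_fpkm, 1, lengths, "*"), 2, totals, "*") / 1e9
  counts <- matrix(rnbinom(length(mu), mu = mu, size = dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mean_fpkm))
  counts[mu == 0] <- 0L
  counts
}

#' Generate a count matrix from a simulation config
#'
#' All genes share the config's per-tissue mean FPKM; the stage multipliers
#' are applied to the rind samples so that rind late-stage means exceed
#' early-stage means when the spec says so.
#'
#' @param config A [sim_config()].
#' @param gene_lengths Named effective lengths (bp).
#' @return List with `counts` (genes x 12 samples), `samples` (sample sheet
#'   with `total_fragments`), and `mean_fpkm` (the expected FPKM matrix).
#' @export
generate_counts <- function(config, gene_lengths) {
  es <- config$expr_spec
  samples <- make_sample_sheet()
  n_g <- length(gene_lengths)
  mean_fpkm <- matrix(0, n_g, nrow(samples),
                      dimnames = list(names(gene_lengths),
                                      samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    m <- es$tissue_means[[samples$tissue[j]]]
    if (samples$tissue[j] == "rind")
      m <- m * es$stage_multipliers[[samples$stage[j]]]
    mean_fpkm[, j] <- m
  }
  with_seed(child_seed(config$seed, "counts"), {
    sf <- exp(stats::rnorm(nrow(samples), 0, 0.1))
    totals <- round(es$library_size * sf)
    counts <- simulate_counts_matrix(mean_fpkm, gene_lengths, totals,
                                     es$dispersion)
    samples$total_fragments <- totals
    list(counts = counts, samples = samples, mean_fpkm = mean_fpkm)
  })
}
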