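#' Expression profiling: FPKM, categories, tissue assignment
#'
#' FPKM (fragments per kilobase of transcript per million mapped fragments)
#' is computed from a raw count matrix with exonic effective lengths and
#' per-sample mapped-fragment totals. Genes are categorized by their maximum
#' FPKM across samples (0: not detected; below 3: very low; 3-30: low;
#' above 30: intermediate/high) and assigned the tissue with the highest
#' mean FPKM.
#'
#' @name expression
NULL

TISSUE_ORDER <- c("rind", "flesh", "seed")
STAGE_ORDER <- c("young", "enlargement", "coloring", "mature")

#' FPKM from counts
#'
#' `FPKM[g,s] = 1e9 * C[g,s] / (N[s] * L[g])`.
#'
#' @param counts Integer matrix, genes x samples.
#' @param lengths Per-gene effective (exonic) length in bp, named or in row
#'   order.
#' @param totals Per-sample mapped-fragment totals, named or in column
#'   order.
#' @return Numeric matrix of FPKM values with the same dimnames.
#' @export
fpkm <- function(counts, lengths, totals) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (!is.null(names(totals)) && !is.null(colnames(counts)))
    totals <- totals[colnames(counts)]
  assert_that(length(lengths) == nrow(counts),
              "lengths must match the number of genes")
  assert_that(length(totals) == ncol(counts),
              "totals must match the number of samples")
  assert_that(all(lengths > 0), "gene lengths must be positive")
  assert_that(all(totals > 0), "sample totals must be positive")
  1e9 * sweep(sweep(counts, 2, totals, "/"), 1, lengths, "/")
}

#' Categorize genes by maximum FPKM
#'
#' @param mat FPKM matrix (genes x samples).
#' @param low_band Inclusive FPKM band for low expression (default
#'   `c(3, 30)`).
#' @param high_min FPKM above which a gene is intermediate/high (default 30).
#' @return Named character vector: `not_detected`, `very_low`, `low` or
#'   `intermediate_high` per gene.
#' @export
categorize_expression <- function(mat, low_band = c(3, 30), high_min = 30) {
  assert_that(low_band[1] < low_band[2] && low_band[2] <= high_min,
              "thresholds must be ordered")
  mx <- apply(mat, 1, max)
  out <- ifelse(mx == 0, "not_detected",
         ifelse(mx < low_band[1], "very_low",
         ifelse(mx <= high_min, "low", "intermediate_high")))
  setNames(out, rownames(mat))
}

#' Assign each gene to its dominant tissue
#'
#' The dominant tissue maximizes the mean FPKM across that tissue's stages;
#' exact ties are broken by the fixed order rind > flesh > seed and flagged.
#' Genes with no detectable expression (max FPKM of 0) get `NA` and are
#' excluded from the per-tissue tallies.
#'
#' @param mat FPKM matrix.
#' @param samples Sample sheet (`sample_id`, `tissue`, `stage`).
#' @return List with `assignment` (data frame `gene_id`, `tissue`, `tied`)
#'   and `per_tissue` counts.
#' @export
tissue_assignment <- function(mat, samples) {
  tissues <- intersect(TISSUE_ORDER, unique(samples$tissue))
  assert_that(length(tissues) >= 1, "no known tissues in sample sheet")
  tm <- vapply(tissues, function(t) {
    cols <- samples$sample_id[samples$tissue == t]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  tm <- matrix(tm, nrow = nrow(mat), dimnames = list(rownames(mat), tissues))
  best <- apply(tm, 1, function(v) which(v == max(v))[1])  # first = fixed order
  tied <- apply(tm, 1, function(v) sum(v == max(v)) > 1)
  detected <- apply(mat, 1, max) > 0
  assignment <- data.frame(gene_id = rownames(mat),
                           tissue = ifelse(detected, tissues[best],
                                           NA_character_),
                           tied = tied & detected,
                           stringsAsFactors = FALSE)
  counts <- table(factor(assignment$tissue, tissues))
  list(assignment = assignment, per_tissue = as.data.frame(counts,
       responseName = "n", stringsAsFactors = FALSE))
}

#' Mean FPKM per tissue
#'
#' Grand mean over all genes and that tissue's samples.
#'
#' @param mat FPKM matrix.
#' @param samples Sample sheet.
#' @return Data frame `tissue`, `mean_fpkm` (raw), `printed` (1 decimal).
#' @export
tissue_means <- function(mat, samples) {
  assert_that(nrow(mat) > 0, "empty gene set")
  tissues <- intersect(TISSUE_ORDER, unique(samples$tissue))
  m <- vapply(tissues, function(t) {
    cols <- samples$sample_id[samples$tissue == t]
    mean(mat[, cols, drop = FALSE])
  }, numeric(1))
  data.frame(tissue = tissues, mean_fpkm = unname(m),
             printed = round1(unname(m)), stringsAsFactors = FALSE)
}

#' Export a heatmap-ready matrix
#'
#' Genes ordered by classification group (CNL, TNL, RNL) then id; values
#' transformed to `log2(FPKM + 1)`.
#'
#' @param mat FPKM matrix.
#' @param labels Classification table (`gene_id`, `group`).
#' @param path Optional TSV output path.
#' @param plot Optional PNG path; drawn with pheatmap when available.
#' @return The transformed, reordered matrix (invisibly when written).
#' @export
export_heatmap_matrix <- function(mat, labels, path = NULL, plot = NULL) {
  ord <- order(match(labels$group[match(rownames(mat), labels$gene_id)],
                     c("CNL", "TNL", "RNL")), rownames(mat))
  hm <- log2(mat[ord, , drop = FALSE] + 1)
  if (!is.null(path))
    write.table(data.frame(gene_id = rownames(hm), hm, check.names = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot) && requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::png(plot, width = 900, height = 1200, res = 120)
    pheatmap::pheatmap(hm, cluster_rows = FALSE, cluster_cols = FALSE)
    grDevices::dev.off()
  }
  if (is.null(path)) hm else invisible(hm)
}
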