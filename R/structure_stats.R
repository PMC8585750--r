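#' Gene-structure statistics and cross-species correlations
#'
#' Exon counts and gene lengths are taken from GFF3 gene models; bivariate
#' relationships (exon count vs gene length within subfamilies, NBS count vs
#' genome size across species) use the Pearson product-moment correlation
#' with the two-sided t test on n - 2 degrees of freedom. Subfamily
#' contrasts use one-way ANOVA with Tukey HSD multiple comparisons and a
#' compact-letter display at alpha = 0.05.
#'
#' @name structure_stats
NULL

#' Per-gene structure records from gene models
#'
#' @param gene_models Gene-model list from [read_gene_models()] (or any list
#'   with a `genes` data frame and an `exons` data frame holding `gene_id`,
#'   `start`, `end`).
#' @return Data frame: `gene_id`, `exon_count`, `gene_length_bp`. Genes
#'   without exon features get `exon_count = 1` with a warning.
#' @export
structure_from_gff <- function(gene_models) {
  genes <- gene_models$genes
  exons <- gene_models$exons
  cnt <- table(exons$gene_id)
  exon_count <- as.integer(cnt[genes$gene_id])
  if (any(is.na(exon_count))) {
    warning(sprintf("%d gene(s) without exon features; assuming single exon",
                    sum(is.na(exon_count))), call. = FALSE)
    exon_count[is.na(exon_count)] <- 1L
  }
  data.frame(gene_id = genes$gene_id,
             exon_count = exon_count,
             gene_length_bp = genes$end - genes$start + 1L,
             stringsAsFactors = FALSE)
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  assert_that(length(x) >= 3, "need at least 3 observations")
  assert_that(stats::var(x) > 0 && stats::var(y) > 0,
              "zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Load the packaged cross-species NBS census
#'
#' Published counts of predicted NBS genes (CNL/TNL/RNL), predicted
#' proteins and genome sizes for 13 sequenced plant genomes. Absent RNL
#' entries are 0.
#'
#' @param path Optional alternative TSV.
#' @return Data frame with `species`, `cnl`, `tnl`, `rnl`, `total_nbs`,
#'   `predicted_proteins`, `genome_size_mb`.
#' @export
load_species_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_species.tsv",
                        package = "nbsprofiler")
  sp <- read.delim(path, stringsAsFactors = FALSE)
  sp$rnl[is.na(sp$rnl)] <- 0L
  sp$tnl[is.na(sp$tnl)] <- 0L
  # The published wheat row is internally inconsistent (subclass counts sum
  # to 2156 against a printed total of 2151); the printed totals are kept
  # as-is since they are what the published correlation uses.
  bad <- sp$total_nbs != sp$cnl + sp$tnl + sp$rnl
  if (any(bad & !grepl("Triticum", sp$species)))
    warning("species rows with inconsistent totals: ",
            paste(sp$species[bad], collapse = ", "), call. = FALSE)
  sp
}

#' Genome size vs NBS count correlation across species
#'
#' @param records Species table from [load_species_table()].
#' @param exclude Species names to drop (e.g. a large-genome outgroup).
#' @return List with `r` (2 decimals), `r_raw`, `p`, `n`.
#' @export
species_correlation <- function(records, exclude = character(0)) {
  keep <- !(records$species %in% exclude)
  assert_that(sum(keep) >= 3, "fewer than 3 species after exclusion")
  pr <- pearson_r(records$genome_size_mb[keep], records$total_nbs[keep])
  list(r = round2(pr$r), r_raw = pr$r, p = pr$p, n = pr$n)
}

#' Exon count vs gene length correlation within a subfamily
#'
#' @param records Structure records joined with a `group` column.
#' @param group Optional group filter (`"CNL"`, `"TNL"`, `"RNL"`); `NULL`
#'   uses all records.
#' @return List with `r` (2 decimals), `r_raw`, `p`, `n`.
#' @export
exon_length_correlation <- function(records, group = NULL) {
  if (!is.null(group)) records <- records[records$group %in% group, ]
  pr <- pearson_r(records$exon_count, records$gene_length_bp)
  list(r = round2(pr$r), r_raw = pr$r, p = pr$p, n = pr$n)
}

# Compact-letter display from a pairwise significance matrix
# (insert-absorb algorithm; groups ordered by decreasing mean).
compact_letters <- function(groups, sig_pairs) {
  sets <- list(groups)  # start: everyone shares one letter
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$a[k]; b <- sig_pairs$b[k]
    for (i in seq_along(sets)) {
      if (a %in% sets[[i]] && b %in% sets[[i]]) {
        sets[[length(sets) + 1]] <- setdiff(sets[[i]], a)
        sets[[i]] <- setdiff(sets[[i]], b)
      }
    }
    keep <- !vapply(seq_along(sets), function(i)
      any(vapply(seq_along(sets), function(j)
        i != j && all(sets[[i]] %in% sets[[j]]), logical(1))), logical(1))
    sets <- unique(sets[keep])
  }
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (g in sets[[i]])
      letters_out[g] <- paste0(letters_out[g], letters[i])
  letters_out
}

#' Subfamily comparison: one-way ANOVA with Tukey HSD
#'
#' @param records Data frame with `group` and the metric column.
#' @param metric `"gene_length_bp"` or `"exon_count"`.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List with `anova_f`, `anova_p`, `pairwise` (Tukey-adjusted
#'   p-values), `letters` (compact-letter display) and `group_means`.
#' @export
subfamily_comparison <- function(records, metric = "gene_length_bp",
                                 alpha = 0.05) {
  assert_that(metric %in% names(records), "metric %s not in records", metric)
  records$group <- factor(records$group)
  sizes <- table(records$group)
  assert_that(length(sizes) >= 2 && all(sizes >= 2),
              "need >=2 groups with >=2 members each")
  fit <- aov(records[[metric]] ~ group, data = records)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairs <- data.frame(
    a = sub("-.*", "", rownames(tk)),
    b = sub(".*-", "", rownames(tk)),
    diff = tk[, "diff"], p_adj = tk[, "p adj"],
    stringsAsFactors = FALSE)
  means <- tapply(records[[metric]], records$group, mean)
  ord <- names(sort(means, decreasing = TRUE))
  sig <- pairs[pairs$p_adj < alpha, , drop = FALSE]
  list(anova_f = an[["F value"]][1],
       anova_p = an[["Pr(>F)"]][1],
       pairwise = pairs,
       letters = compact_letters(ord, sig),
       group_means = means)
}
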