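#' Chromosomal distribution: cluster and singleton loci
#'
#' Mapped NBS genes are partitioned into loci by transitive gap chaining:
#' position-sorted genes on a chromosome join one locus when the gap from
#' the running end of the locus to the next gene start is at most the window
#' (250 kb by default, after the sliding-window convention used for plant
#' resistance-gene clusters). Loci with two or more members are clusters,
#' the rest singletons.
#'
#' @name distribution
NULL

#' Split genes into mapped and unmapped sets
#'
#' @param genes Data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`.
#' @param chromosomes Character vector of assembled chromosome names. When
#'   `NULL`, sequence names matching `^chr` are taken as chromosomes and
#'   everything else (scaffolds, `"unplaced"`) as unmapped.
#' @return List with data frames `mapped` and `unmapped`.
#' @export
split_mapped_unmapped <- function(genes, chromosomes = NULL) {
  if (is.null(chromosomes))
    chromosomes <- unique(grep("^chr", genes$chromosome, value = TRUE))
  mapped <- genes$chromosome %in% chromosomes & genes$chromosome != "unplaced"
  list(mapped = genes[mapped, , drop = FALSE],
       unmapped = genes[!mapped, , drop = FALSE])
}

#' Call cluster and singleton loci by 250-kb gap chaining
#'
#' @param genes Mapped genes (`gene_id`, `chromosome`, `start`, `end`).
#' @param window_bp Maximum inter-gene gap joining a locus (default 250000).
#'   Gaps are `next start - running max end`, floored at 0 for overlaps.
#' @return Data frame of loci ordered by chromosome (natural sort) then
#'   position: `locus_id`, `chromosome`, `kind` (`cluster`/`singleton`),
#'   `n_genes`, `start`, `end`, `members` (comma-joined, position-sorted).
#' @export
call_clusters <- function(genes, window_bp = 250000) {
  assert_that(window_bp > 0, "window_bp must be positive")
  if (!nrow(genes))
    return(data.frame(locus_id = integer(0), chromosome = character(0),
                      kind = character(0), n_genes = integer(0),
                      start = integer(0), end = integer(0),
                      members = character(0), stringsAsFactors = FALSE))
  out <- list()
  for (chr in natural_sort(unique(genes$chromosome))) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    run_end <- g$end[1]
    locus <- integer(nrow(g)); locus[1] <- 1L
    for (i in seq_len(nrow(g))[-1]) {
      gap <- max(0, g$start[i] - run_end)
      locus[i] <- if (gap <= window_bp) locus[i - 1] else locus[i - 1] + 1L
      run_end <- if (gap <= window_bp) max(run_end, g$end[i]) else g$end[i]
    }
    for (l in unique(locus)) {
      m <- g[locus == l, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chromosome = chr,
        kind = if (nrow(m) >= 2) "cluster" else "singleton",
        n_genes = nrow(m), start = min(m$start), end = max(m$end),
        members = paste(m$gene_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, out)
  loci <- cbind(locus_id = seq_len(nrow(loci)), loci)
  rownames(loci) <- NULL
  loci
}

#' Summarize cluster loci
#'
#' @param loci Locus table from [call_clusters()].
#' @return List with `n_loci`, `n_clusters`, `n_singletons`,
#'   `n_mapped_genes`, `n_clustered_genes`, `clustered_pct` (1 decimal),
#'   `mean_genes_per_cluster` (2 decimals; 0 with `no_clusters = TRUE` when
#'   there are none) and a `per_chromosome` locus count table.
#' @export
cluster_summary <- function(loci) {
  cl <- loci[loci$kind == "cluster", , drop = FALSE]
  n_mapped <- sum(loci$n_genes)
  n_clustered <- sum(cl$n_genes)
  per_chr <- if (nrow(loci))
    aggregate(cbind(n_loci = locus_id) ~ chromosome, data = loci, FUN = length)
  else data.frame(chromosome = character(0), n_loci = integer(0))
  list(n_loci = nrow(loci),
       n_clusters = nrow(cl),
       n_singletons = sum(loci$kind == "singleton"),
       n_mapped_genes = n_mapped,
       n_clustered_genes = n_clustered,
       clustered_pct = if (n_mapped) round1(100 * n_clustered / n_mapped) else 0,
       mean_genes_per_cluster = if (nrow(cl)) round2(n_clustered / nrow(cl)) else 0,
       no_clusters = nrow(cl) == 0,
       per_chromosome = per_chr)
}
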