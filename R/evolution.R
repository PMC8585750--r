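#' Selection-pressure contrasts and duplication-type classification
#'
#' Paralog pairs passing an identity/length window are analyzed for Ka/Ks
#' (see [kaks_ng86()]); subfamily means are contrasted with a Welch test.
#' Duplication origins are assigned per gene from homolog evidence with the
#' priority whole-genome/segmental > tandem > proximal > dispersed: a gene
#' inside a collinear block is WGD/segmental; otherwise a same-chromosome
#' homolog within the tandem rank bound makes it tandem, within the proximal
#' bound proximal; any remaining homolog makes it dispersed; no homolog at
#' all leaves a singleton.
#'
#' @name evolution
NULL

#' Select analyzable paralog pairs
#'
#' @param pairs Homolog pairs (`gene_a`, `gene_b`, `identity`,
#'   `aligned_length`).
#' @param labels Classification table (`gene_id`, `group`); both members
#'   must be classified.
#' @param min_aligned Minimum aligned length in amino acids (default 100).
#' @param identity_window Inclusive identity window (default `c(0.4, 0.99)`);
#'   near-identical paralog sets (e.g. the RNL quartet) fall above it and
#'   are excluded, mirroring the ortholog lower-limit filter.
#' @return Deduplicated pair table with `group_a`, `group_b` appended.
#' @export
select_pairs <- function(pairs, labels, min_aligned = 100,
                         identity_window = c(0.4, 0.99)) {
  p <- pairs
  key <- ifelse(p$gene_a < p$gene_b,
                paste(p$gene_a, p$gene_b), paste(p$gene_b, p$gene_a))
  p <- p[!duplicated(key) & p$gene_a != p$gene_b, , drop = FALSE]
  p <- p[p$aligned_length >= min_aligned &
           p$identity >= identity_window[1] &
           p$identity <= identity_window[2], , drop = FALSE]
  p$group_a <- labels$group[match(p$gene_a, labels$gene_id)]
  p$group_b <- labels$group[match(p$gene_b, labels$gene_id)]
  p <- p[!is.na(p$group_a) & !is.na(p$group_b), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Contrast subfamily Ka/Ks ratios
#'
#' @param results Ka/Ks table (from [kaks_pairs()]) with a `group` column.
#' @param groups Two groups to contrast (default CNL vs TNL).
#' @return List with `means` (2 decimals), `means_raw`, `statistic`, `p`
#'   (Welch two-sample t test on defined omegas) and `n` per group.
#' @export
subfamily_kaks_contrast <- function(results, groups = c("CNL", "TNL")) {
  r <- results[results$group %in% groups & !is.na(results$omega), ,
               drop = FALSE]
  n <- table(factor(r$group, groups))
  assert_that(all(n >= 2), "need >=2 defined omega values per group")
  means_raw <- tapply(r$omega, factor(r$group, groups), mean)
  tt <- t.test(omega ~ factor(group, groups), data = r)
  list(means = round2(means_raw), means_raw = means_raw,
       statistic = unname(tt$statistic), p = tt$p.value, n = as.vector(n))
}

#' Detect collinear blocks from homolog pairs
#'
#' Simplified order-consistent chaining: within each chromosome pair,
#' homolog pairs sorted by rank on the first chromosome are chained while
#' consecutive rank gaps on both chromosomes stay within `max_gap` and the
#' second-chromosome ranks move monotonically in one direction. Chains of at
#' least `min_block` pairs are reported.
#'
#' @param rank_map Data frame `gene_id`, `chromosome`, `rank` (1-based gene
#'   order per chromosome over all annotated genes).
#' @param pairs Homolog pairs (`gene_a`, `gene_b`).
#' @param min_block Minimum pairs per block (default 5).
#' @param max_gap Maximum rank gap between consecutive chained pairs
#'   (default 25).
#' @return Data frame `block_id`, `gene_a`, `gene_b` (one row per pair in a
#'   block); zero rows when no block is found.
#' @export
detect_collinear_blocks <- function(rank_map, pairs, min_block = 5,
                                    max_gap = 25) {
  empty <- data.frame(block_id = integer(0), gene_a = character(0),
                      gene_b = character(0), stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  idx <- match(pairs$gene_a, rank_map$gene_id)
  idy <- match(pairs$gene_b, rank_map$gene_id)
  ok <- !is.na(idx) & !is.na(idy)
  p <- data.frame(gene_a = pairs$gene_a[ok], gene_b = pairs$gene_b[ok],
                  chr_a = rank_map$chromosome[idx[ok]],
                  chr_b = rank_map$chromosome[idy[ok]],
                  rank_a = rank_map$rank[idx[ok]],
                  rank_b = rank_map$rank[idy[ok]],
                  stringsAsFactors = FALSE)
  # orient each pair so chr_a <= chr_b for grouping
  flip <- p$chr_a > p$chr_b | (p$chr_a == p$chr_b & p$rank_a > p$rank_b)
  p[flip, c("gene_a", "gene_b", "chr_a", "chr_b", "rank_a", "rank_b")] <-
    p[flip, c("gene_b", "gene_a", "chr_b", "chr_a", "rank_b", "rank_a")]
  blocks <- list()
  for (key in unique(paste(p$chr_a, p$chr_b))) {
    q <- p[paste(p$chr_a, p$chr_b) == key, , drop = FALSE]
    q <- q[order(q$rank_a, q$rank_b), , drop = FALSE]
    chain <- 1L; ids <- integer(nrow(q)); ids[1] <- chain; dir <- 0
    for (i in seq_len(nrow(q))[-1]) {
      da <- q$rank_a[i] - q$rank_a[i - 1]
      db <- q$rank_b[i] - q$rank_b[i - 1]
      step_dir <- sign(db)
      ok_step <- da > 0 && da <= max_gap && abs(db) > 0 && abs(db) <= max_gap &&
        (dir == 0 || step_dir == dir)
      if (ok_step) dir <- step_dir
      else { chain <- chain + 1L; dir <- 0 }
      ids[i] <- chain
    }
    for (cid in unique(ids)) {
      m <- q[ids == cid, , drop = FALSE]
      if (nrow(m) >= min_block)
        blocks[[length(blocks) + 1]] <- m[, c("gene_a", "gene_b")]
    }
  }
  if (!length(blocks)) return(empty)
  out <- do.call(rbind, Map(function(b, i) cbind(block_id = i, b),
                            blocks, seq_along(blocks)))
  rownames(out) <- NULL
  out
}

#' Classify duplication origin per gene
#'
#' @param gene_ids NBS gene ids to classify.
#' @param rank_map Rank map over all annotated genes (`gene_id`,
#'   `chromosome`, `rank`).
#' @param pairs Homolog pairs (`gene_a`, `gene_b`, `identity`,
#'   `aligned_length`).
#' @param blocks Collinear blocks from [detect_collinear_blocks()].
#' @param tandem_max Maximum rank distance for tandem (default 2, i.e. at
#'   most one intervening gene).
#' @param proximal_max Maximum rank distance for proximal (default 10).
#' @param min_identity,min_aligned Evidence thresholds for homolog pairs
#'   (defaults 0.3 and 100).
#' @return Data frame `gene_id`, `dup_type`, `partner`, `rank_distance`.
#' @export
classify_duplications <- function(gene_ids, rank_map, pairs, blocks = NULL,
                                  tandem_max = 2, proximal_max = 10,
                                  min_identity = 0.3, min_aligned = 100) {
  assert_that(all(gene_ids %in% rank_map$gene_id),
              "gene(s) absent from rank map: %s",
              paste(head(setdiff(gene_ids, rank_map$gene_id), 3),
                    collapse = ", "))
  p <- pairs[pairs$identity >= min_identity &
               pairs$aligned_length >= min_aligned, , drop = FALSE]
  block_genes <- if (!is.null(blocks) && nrow(blocks))
    unique(c(blocks$gene_a, blocks$gene_b)) else character(0)
  chr_of <- setNames(rank_map$chromosome, rank_map$gene_id)
  rank_of <- setNames(rank_map$rank, rank_map$gene_id)
  rows <- lapply(gene_ids, function(g) {
    partners <- unique(c(p$gene_b[p$gene_a == g], p$gene_a[p$gene_b == g]))
    partners <- partners[partners %in% rank_map$gene_id & partners != g]
    mk <- function(type, partner = NA_character_, rd = NA_integer_)
      data.frame(gene_id = g, dup_type = type, partner = partner,
                 rank_distance = rd, stringsAsFactors = FALSE)
    if (g %in% block_genes) {
      mate <- c(blocks$gene_b[blocks$gene_a == g],
                blocks$gene_a[blocks$gene_b == g])[1]
      return(mk("wgd_segmental", mate))
    }
    if (!length(partners)) return(mk("singleton"))
    same <- partners[chr_of[partners] == chr_of[g]]
    if (length(same)) {
      rd <- abs(rank_of[same] - rank_of[g])
      same <- same[order(rd)]; rd <- sort(rd)
      if (rd[1] <= tandem_max) return(mk("tandem", same[1], as.integer(rd[1])))
      if (rd[1] <= proximal_max)
        return(mk("proximal", same[1], as.integer(rd[1])))
    }
    mk("dispersed", partners[1])
  })
  do.call(rbind, rows)
}

#' Summarize duplication calls
#'
#' @param calls Output of [classify_duplications()].
#' @return Data frame `dup_type`, `n`, `pct` (1 decimal, of all calls).
#' @export
duplication_summary <- function(calls) {
  lv <- c("wgd_segmental", "tandem", "proximal", "dispersed", "singleton")
  tab <- as.data.frame(table(dup_type = factor(calls$dup_type, lv)),
                       stringsAsFactors = FALSE)
  names(tab)[2] <- "n"
  tab$pct <- round1(100 * tab$n / nrow(calls))
  tab
}
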