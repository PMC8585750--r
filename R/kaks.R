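#' Ka/Ks estimation by the Nei-Gojobori (1986) counting method
#'
#' Synonymous and nonsynonymous substitution rates are estimated from a pair
#' of aligned coding sequences by codon counting: each codon contributes
#' synonymous/nonsynonymous *site* counts given by the fraction of its nine
#' one-step nucleotide changes that preserve the encoded amino acid (changes
#' creating a stop codon count as nonsynonymous, so sites always sum to three
#' per codon), and observed differences between codons are partitioned by
#' averaging equally over all minimal substitution pathways, excluding
#' pathways that pass through a stop codon. Proportions are corrected for
#' multiple hits with the Jukes-Cantor formula.
#'
#' @name kaks
NULL

.codon_cache <- new.env(parent = emptyenv())

# Genetic-code lookup tables used by both the estimator and the codon-pair
# simulator: per-codon synonymous site counts and, for every ordered pair of
# sense codons, pathway-averaged synonymous/nonsynonymous difference counts.
codon_tables <- function() {
  if (!is.null(.codon_cache$tables)) return(.codon_cache$tables)
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  names(aa) <- codons
  sense <- codons[aa != "*"]
  bases <- c("A", "C", "G", "T")

  neighbours <- function(codon) {
    out <- character(0)
    s <- strsplit(codon, "")[[1]]
    for (pos in 1:3) for (b in setdiff(bases, s[pos])) {
      t <- s; t[pos] <- b
      out <- c(out, paste(t, collapse = ""))
    }
    out
  }

  # Site counts: fraction of one-step changes that are synonymous; mutations
  # to stop codons are nonsynonymous, hence syn + nonsyn = 3 exactly.
  syn_sites <- vapply(sense, function(cd) {
    nb <- neighbours(cd)
    sum(aa[nb] == aa[cd] & aa[nb] != "*") / 3
  }, numeric(1))

  n_sense <- length(sense)
  sd_tab <- matrix(0, n_sense, n_sense, dimnames = list(sense, sense))
  nd_tab <- sd_tab

  path_counts <- function(c1, c2) {
    s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
    diffs <- which(s1 != s2)
    k <- length(diffs)
    if (k == 0) return(c(0, 0))
    perms <- if (k == 1) list(diffs) else {
      idx <- if (k == 2) list(c(1, 2), c(2, 1)) else
        list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(i) diffs[i])
    }
    acc <- matrix(NA_real_, length(perms), 2)
    for (p in seq_along(perms)) {
      cur <- s1; sd <- 0; nd <- 0; ok <- TRUE
      for (pos in perms[[p]]) {
        nxt <- cur; nxt[pos] <- s2[pos]
        from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
        if (aa[to] == "*" && to != c2) { ok <- FALSE; break }
        if (aa[from] == aa[to]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) acc[p, ] <- c(sd, nd)
    }
    valid <- !is.na(acc[, 1])
    if (!any(valid)) valid <- rep(TRUE, nrow(acc))  # all pathways blocked: average all
    c(mean(acc[valid, 1]), mean(acc[valid, 2]))
  }

  for (i in seq_len(n_sense)) for (j in seq_len(n_sense)) {
    if (i < j) {
      pc <- path_counts(sense[i], sense[j])
      sd_tab[i, j] <- sd_tab[j, i] <- pc[1]
      nd_tab[i, j] <- nd_tab[j, i] <- pc[2]
    }
  }

  .codon_cache$tables <- list(codons = codons, aa = aa, sense = sense,
                              bases = bases, syn_sites = syn_sites,
                              sd_tab = sd_tab, nd_tab = nd_tab)
  .codon_cache$tables
}

# Split a CDS string into codons, validating length.
split_codons <- function(cds, what = "sequence") {
  cds <- toupper(as.character(cds))
  assert_that(nchar(cds) %% 3 == 0, "%s length must be divisible by 3", what)
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

jukes_cantor <- function(p) -3 / 4 * log(1 - 4 / 3 * p)

#' Estimate Ka, Ks and omega for one aligned codon pair
#'
#' @param cds_a,cds_b Aligned coding sequences (character or
#'   [Biostrings::DNAString]) of equal length divisible by 3. Codon positions
#'   where either sequence carries a gap (`-`) are skipped pairwise; internal
#'   stop codons are an error.
#' @return A list with elements `ka`, `ks`, `omega`, `s_sites`, `n_sites`,
#'   `sd`, `nd`, `codons` (number of compared codons) and `selection_call`
#'   (`"positive"` for omega > 1, `"neutral"` for omega = 1, `"purifying"`
#'   for omega < 1, `"undefined"` when omega cannot be computed because
#'   Ks = 0 or a proportion is saturated).
#' @examples
#' kaks_ng86("ATGAAA", "ATGAAG")$sd  # third-position synonymous change
#' @export
kaks_ng86 <- function(cds_a, cds_b) {
  tb <- codon_tables()
  ca <- split_codons(cds_a, "cds_a")
  cb <- split_codons(cds_b, "cds_b")
  assert_that(length(ca) == length(cb),
              "aligned sequences must have equal length (got %d vs %d codons)",
              length(ca), length(cb))
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  assert_that(length(ca) > 0, "no ungapped codons to compare")
  bad <- !(ca %in% tb$sense) | !(cb %in% tb$sense)
  if (any(bad)) {
    if (any(tb$aa[ca[bad]] == "*", na.rm = TRUE) ||
        any(tb$aa[cb[bad]] == "*", na.rm = TRUE))
      stop_invalid("internal stop codon in input sequence")
    ca <- ca[!bad]; cb <- cb[!bad]  # ambiguous codons skipped pairwise
  }
  n_codon <- length(ca)
  s_sites <- (sum(tb$syn_sites[ca]) + sum(tb$syn_sites[cb])) / 2
  n_sites <- 3 * n_codon - s_sites
  idx <- cbind(match(ca, tb$sense), match(cb, tb$sense))
  sd <- sum(tb$sd_tab[idx])
  nd <- sum(tb$nd_tab[idx])
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  saturated <- ps >= 3 / 4 || pn >= 3 / 4
  ks <- if (saturated) NA_real_ else jukes_cantor(ps)
  ka <- if (saturated) NA_real_ else jukes_cantor(pn)
  omega <- if (saturated || is.na(ks) || ks == 0) NA_real_ else ka / ks
  call <- if (is.na(omega)) "undefined"
          else if (omega > 1) "positive"
          else if (omega == 1) "neutral"
          else "purifying"
  list(ka = ka, ks = ks, omega = omega,
       s_sites = s_sites, n_sites = n_sites, sd = sd, nd = nd,
       codons = n_codon, selection_call = call)
}

#' Ka/Ks over a table of sequence pairs
#'
#' @param cds A named character vector or [Biostrings::DNAStringSet] of
#'   aligned coding sequences.
#' @param pairs Data frame with columns `gene_a`, `gene_b` naming entries of
#'   `cds`.
#' @return Data frame with one row per pair: `gene_a`, `gene_b`, `ka`, `ks`,
#'   `omega`, `selection_call`.
#' @export
kaks_pairs <- function(cds, pairs) {
  nm <- names(cds)
  cds <- as.character(cds)
  names(cds) <- nm
  assert_that(all(c(pairs$gene_a, pairs$gene_b) %in% names(cds)),
              "pairs reference sequences absent from `cds`")
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- kaks_ng86(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
    data.frame(gene_a = pairs$gene_a[i], gene_b = pairs$gene_b[i],
               ka = r$ka, ks = r$ks, omega = r$omega,
               selection_call = r$selection_call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
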