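#' Conserved NBS-domain motif scanning
#'
#' The NB-ARC domain of plant NBS-LRR proteins carries eight conserved
#' sequence motifs in a canonical N-to-C order: P-loop, RNBS-A, Kinase-2,
#' RNBS-B, RNBS-C, GLPL, RNBS-D and MHDL. The scanner locates occurrences of
#' a curated motif library (position-specific residue classes) and downstream
#' helpers judge whether the observed motif order is conserved and extract
#' the terminal residue of the kinase-2 motif, which distinguishes the TNL
#' (aspartate, D) from the non-TNL (tryptophan, W) lineages.
#'
#' @name motifs
NULL

CANONICAL_MOTIF_ORDER <- c("P-loop", "RNBS-A", "Kinase-2", "RNBS-B",
                           "RNBS-C", "GLPL", "RNBS-D", "MHDL")

parse_motif_pattern <- function(pattern) {
  # "G[MS]G..." -> list of per-position allowed residue sets
  chars <- strsplit(pattern, "")[[1]]
  out <- list(); i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1
      while (chars[j] != "]") j <- j + 1
      out[[length(out) + 1]] <- chars[(i + 1):(j - 1)]
      i <- j + 1
    } else {
      out[[length(out) + 1]] <- chars[i]
      i <- i + 1
    }
  }
  out
}

#' Read a motif library from YAML
#'
#' The library file holds a list of motifs, each with `name`, `pattern`
#' (regex-style residue classes, width 6-50) and optional `min_score`
#' (defaults to 80% of the motif width, rounded up). Motif names must be the
#' eight canonical NBS motifs; their canonical order is fixed.
#'
#' @param path YAML file; defaults to the curated library shipped with the
#'   package.
#' @return A `motif_library`: named list of motifs with elements `name`,
#'   `classes` (list of residue sets), `width`, `min_score`, `consensus`.
#' @export
read_motif_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motif_library.yaml", package = "nbsprofiler")
  raw <- yaml::read_yaml(path)
  lib <- lapply(raw$motifs, function(m) {
    classes <- parse_motif_pattern(m$pattern)
    width <- length(classes)
    assert_that(width >= 6 && width <= 50,
                "motif %s width %d outside [6, 50]", m$name, width)
    list(name = m$name, classes = classes, width = width,
         min_score = if (!is.null(m$min_score)) m$min_score
                     else ceiling(0.8 * width),
         consensus = paste(vapply(classes, `[`, character(1), 1),
                           collapse = ""))
  })
  names(lib) <- vapply(lib, `[[`, character(1), "name")
  assert_that(all(names(lib) %in% CANONICAL_MOTIF_ORDER),
              "unknown motif names in library")
  lib <- lib[intersect(CANONICAL_MOTIF_ORDER, names(lib))]
  class(lib) <- "motif_library"
  lib
}

#' @rdname read_motif_library
#' @export
default_motif_library <- function() read_motif_library()

# Consensus string for one motif; kinase-2 accepts a chosen terminal residue.
motif_consensus <- function(library, name, terminal = NULL) {
  m <- library[[name]]
  s <- strsplit(m$consensus, "")[[1]]
  if (!is.null(terminal)) s[length(s)] <- terminal
  paste(s, collapse = "")
}

#' Scan a protein sequence for conserved NBS motifs
#'
#' Every window scoring at least the motif's `min_score` (one point per
#' position whose residue lies in the allowed class) is a candidate hit.
#' Overlapping candidates are resolved greedily, highest score first, ties
#' broken leftmost then by canonical motif order; surviving hits are reported
#' in position order.
#'
#' @param sequence Amino-acid sequence (character or
#'   [Biostrings::AAString]); the 20-letter alphabet plus `X` (never matches).
#' @param library A `motif_library`.
#' @return Data frame of hits: `motif`, `start` (1-based), `end`, `match`,
#'   `score`. Zero rows for an empty sequence or no matches.
#' @export
scan_motifs <- function(sequence, library = default_motif_library()) {
  seq_chr <- strsplit(toupper(as.character(sequence)), "")[[1]]
  n <- length(seq_chr)
  empty <- data.frame(motif = character(0), start = integer(0),
                      end = integer(0), match = character(0),
                      score = integer(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  cand <- list()
  for (mi in seq_along(library)) {
    m <- library[[mi]]
    w <- m$width
    if (n < w) next
    n_start <- n - w + 1
    score <- integer(n_start)
    for (k in seq_len(w))
      score <- score + (seq_chr[seq_len(n_start) + k - 1] %in% m$classes[[k]])
    hit <- which(score >= m$min_score)
    if (length(hit))
      cand[[length(cand) + 1]] <- data.frame(
        motif = m$name, start = hit, end = hit + w - 1L,
        score = score[hit], order = mi, stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$score, cand$start, cand$order), , drop = FALSE]
  taken <- rep(FALSE, n)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(taken[span])) { keep[i] <- TRUE; taken[span] <- TRUE }
  }
  hits <- cand[keep, c("motif", "start", "end", "score")]
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$match <- vapply(seq_len(nrow(hits)), function(i)
    paste(seq_chr[hits$start[i]:hits$end[i]], collapse = ""), character(1))
  rownames(hits) <- NULL
  hits[, c("motif", "start", "end", "match", "score")]
}

#' Judge motif-order conservation
#'
#' Classifies the position-ordered motif-name sequence of a gene:
#' `conserved` when no motif repeats and the names follow the canonical
#' N-to-C order; `flanked_repeat` when a contiguous core run in canonical
#' order exists and every extra occurrence is a repeat of a core motif lying
#' outside the run; `core_change` otherwise; `insufficient` with fewer than
#' two distinct motifs.
#'
#' @param hits Hit table from [scan_motifs()] (position-sorted).
#' @return List with `verdict` and `observed` (motif-name sequence).
#' @export
classify_motif_order <- function(hits) {
  nm <- hits$motif[order(hits$start)]
  res <- function(v) list(verdict = v, observed = nm)
  if (length(unique(nm)) < 2) return(res("insufficient"))
  canon_idx <- match(nm, CANONICAL_MOTIF_ORDER)
  increasing <- function(x) all(diff(x) > 0)
  if (!anyDuplicated(nm) && increasing(canon_idx)) return(res("conserved"))
  n <- length(nm)
  for (i in seq_len(n)) for (j in i:n) {
    win <- nm[i:j]
    if (anyDuplicated(win)) next
    if (length(win) > 1 && !increasing(canon_idx[i:j])) next
    extras <- nm[setdiff(seq_len(n), i:j)]
    if (length(win) >= 2 && all(extras %in% win)) return(res("flanked_repeat"))
  }
  res("core_change")
}

#' Terminal residue of the kinase-2 motif
#'
#' @param hits Hit table from [scan_motifs()].
#' @return Single character (last residue of the best-scoring kinase-2 hit,
#'   ties broken leftmost) or `NA_character_` if the motif was not found.
#' @export
kinase2_terminal_residue <- function(hits) {
  k2 <- hits[hits$motif == "Kinase-2", , drop = FALSE]
  if (!nrow(k2)) return(NA_character_)
  k2 <- k2[order(-k2$score, k2$start), , drop = FALSE]
  substring(k2$match[1], nchar(k2$match[1]))
}

#' Kinase-2 terminal-residue frequencies by lineage
#'
#' Tabulates the terminal kinase-2 residue per gene against the TNL versus
#' non-TNL (CNL + RNL) split, the contrast in which tryptophan (W) typifies
#' non-TNLs and aspartate (D) typifies TNLs.
#'
#' @param labels Data frame with `gene_id` and `group` (`CNL`/`TNL`/`RNL`).
#' @param residues Named character vector of terminal residues keyed by
#'   gene_id (`NA` entries are dropped).
#' @param collapse_ntnl Collapse CNL and RNL into `nTNL` (default `TRUE`).
#' @return Data frame: `type`, `residue`, `n`, `n_type`, `pct` (1 decimal).
#' @export
kinase2_frequency_table <- function(labels, residues, collapse_ntnl = TRUE) {
  res <- residues[labels$gene_id]
  type <- labels$group
  if (collapse_ntnl) type <- ifelse(type == "TNL", "TNL", "nTNL")
  ok <- !is.na(res)
  if (!any(ok))
    return(data.frame(type = character(0), residue = character(0),
                      n = integer(0), n_type = integer(0), pct = numeric(0)))
  tab <- as.data.frame(table(type = type[ok], residue = res[ok]),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0 | TRUE, ]
  totals <- tapply(tab$n, tab$type, sum)
  tab$n_type <- as.integer(totals[tab$type])
  tab$pct <- round1(100 * tab$n / tab$n_type)
  tab[order(tab$type, -tab$n), ]
}
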