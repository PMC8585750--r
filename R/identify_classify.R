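#' Identification and domain-architecture classification of NBS genes
#'
#' Candidate NBS genes from two homology searches are merged and
#' deduplicated, verified for a conserved NBS (NB-ARC) domain at a stringent
#' E-value, and classified into three groups (CNL, TNL, RNL) and nine
#' subclasses by the presence of N-terminal coiled-coil (CC), TIR or RPW8
#' domains and a C-terminal LRR. CC domains are accepted from a coiled-coil
#' propensity score rather than an E-value. Genes carrying neither CC, TIR
#' nor RPW8 (bare NBS or NBS-LRR architectures) are assigned a lineage by
#' the terminal residue of their kinase-2 motif: aspartate (D) places them in
#' the TNL group, tryptophan (W) in the CNL group, and anything else falls
#' back to CNL flagged as low confidence.
#'
#' @name identify_classify
NULL

SUBCLASSES <- data.frame(
  subclass = c("CNL", "CN", "NL_CC", "N_CC", "TNL", "TN", "NL_TIR", "N_TIR",
               "RNL"),
  group = c("CNL", "CNL", "CNL", "CNL", "TNL", "TNL", "TNL", "TNL", "RNL"),
  stringsAsFactors = FALSE
)

#' Thresholds for NBS identification and classification
#'
#' @param nbs_evalue_max Maximum Pfam/CDD E-value for a verified NBS domain
#'   (and for TIR/RPW8/LRR presence). Default `1e-4`.
#' @param cc_score_min Minimum coiled-coil propensity score for a CC call.
#'   Default `0.5`.
#' @param search_evalue_max E-value used by the upstream candidate searches;
#'   kept as provenance metadata only. Default `1.0`.
#' @export
thresholds <- function(nbs_evalue_max = 1e-4, cc_score_min = 0.5,
                       search_evalue_max = 1.0) {
  assert_that(nbs_evalue_max > 0 && cc_score_min > 0 && search_evalue_max > 0,
              "all thresholds must be positive")
  list(nbs_evalue_max = nbs_evalue_max, cc_score_min = cc_score_min,
       search_evalue_max = search_evalue_max)
}

#' Merge candidate gene lists
#'
#' Set union of two candidate id lists with within-list deduplication;
#' returned sorted lexicographically for determinism. Ids are compared as
#' exact case-sensitive strings.
#'
#' @param list_a,list_b Character vectors of gene ids.
#' @export
merge_candidates <- function(list_a, list_b) {
  sort(unique(c(as.character(list_a), as.character(list_b))))
}

#' Verify the NBS domain of candidate genes
#'
#' A candidate is retained iff the domain table holds at least one NBS call
#' with `e_value <= nbs_evalue_max`. Candidates absent from the table are
#' dropped with a warning.
#'
#' @param candidates Character vector of gene ids.
#' @param domains Domain-call data frame with columns `gene_id`,
#'   `domain_type`, `e_value` (and `cc_score` for CC rows).
#' @param th Thresholds from [thresholds()].
#' @return Sorted character vector of verified gene ids.
#' @export
verify_nbs <- function(candidates, domains, th = thresholds()) {
  candidates <- unique(as.character(candidates))
  missing <- setdiff(candidates, unique(domains$gene_id))
  if (length(missing))
    warning(sprintf("%d candidate(s) absent from domain table, dropped: %s",
                    length(missing),
                    paste(head(missing, 5), collapse = ", ")),
            call. = FALSE)
  nbs <- domains[domains$domain_type == "NBS" &
                   !is.na(domains$e_value) &
                   domains$e_value <= th$nbs_evalue_max, "gene_id"]
  sort(intersect(candidates, nbs))
}

#' Classify one gene's domain architecture
#'
#' Precedence RPW8 > TIR > CC. RPW8 with NBS (and LRR) yields RNL; TIR
#' yields TNL (LRR present) or TN; CC yields CNL or CN; bare NBS/NBS-LRR
#' genes are split by the kinase-2 terminal residue (D: TNL lineage,
#' W: CNL lineage, otherwise CNL by default, flagged low confidence).
#'
#' @param gene_id Gene id (the gene must have passed [verify_nbs()]).
#' @param domains Domain calls for this gene (rows of the domain table).
#' @param kinase2_residue Optional terminal kinase-2 residue from
#'   [kinase2_terminal_residue()].
#' @param th Thresholds from [thresholds()].
#' @return List with `gene_id`, `group`, `subclass`, `low_confidence`.
#' @export
classify_architecture <- function(gene_id, domains,
                                  kinase2_residue = NA_character_,
                                  th = thresholds()) {
  d <- domains[domains$gene_id == gene_id, , drop = FALSE]
  has <- function(type) {
    rows <- d[d$domain_type == type, , drop = FALSE]
    if (!nrow(rows)) return(FALSE)
    if (type == "CC") any(!is.na(rows$cc_score) &
                            rows$cc_score >= th$cc_score_min)
    else any(!is.na(rows$e_value) & rows$e_value <= th$nbs_evalue_max)
  }
  assert_that(has("NBS"),
              "gene %s has no verified NBS domain (contract violation)",
              gene_id)
  lrr <- has("LRR")
  low_conf <- FALSE
  if (has("RPW8")) {
    subclass <- "RNL"
    low_conf <- !lrr  # scheme defines RNL with full RPW8-NBS-LRR
  } else if (has("TIR")) {
    subclass <- if (lrr) "TNL" else "TN"
  } else if (has("CC")) {
    subclass <- if (lrr) "CNL" else "CN"
  } else {
    k2 <- if (is.null(kinase2_residue)) NA_character_ else kinase2_residue
    lineage <- if (!is.na(k2) && k2 == "D") "TIR"
               else if (!is.na(k2) && k2 == "W") "CC"
               else { low_conf <- TRUE; "CC" }
    subclass <- paste(if (lrr) "NL" else "N", lineage, sep = "_")
  }
  group <- SUBCLASSES$group[match(subclass, SUBCLASSES$subclass)]
  list(gene_id = gene_id, group = group, subclass = subclass,
       low_confidence = low_conf)
}

#' Classify all verified genes
#'
#' @param gene_ids Verified gene ids.
#' @param domains Domain-call table.
#' @param kinase2 Named character vector of kinase-2 terminal residues.
#' @param th Thresholds.
#' @return Data frame: `gene_id`, `group`, `subclass`, `low_confidence`.
#' @export
classify_all <- function(gene_ids, domains, kinase2 = NULL,
                         th = thresholds()) {
  rows <- lapply(gene_ids, function(g) {
    k2 <- if (is.null(kinase2)) NA_character_ else unname(kinase2[g])
    as.data.frame(classify_architecture(g, domains, k2, th),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize a classification
#'
#' @param labels Classification data frame from [classify_all()].
#' @param n_annotated_genes Total annotated genes in the genome.
#' @return List with `n_nbs`, `proportion_pct` (2 decimals), `by_group` and
#'   `by_subclass` count tables.
#' @export
summarize_classification <- function(labels, n_annotated_genes) {
  assert_that(n_annotated_genes > 0, "n_annotated_genes must be positive")
  n <- nrow(labels)
  assert_that(n_annotated_genes >= n,
              "n_annotated_genes smaller than number of labels")
  by_group <- as.data.frame(table(group = factor(labels$group,
                                                 c("CNL", "TNL", "RNL"))),
                            stringsAsFactors = FALSE)
  names(by_group)[2] <- "n"
  by_sub <- as.data.frame(table(subclass = factor(labels$subclass,
                                                  SUBCLASSES$subclass)),
                          stringsAsFactors = FALSE)
  names(by_sub)[2] <- "n"
  by_sub <- by_sub[by_sub$n > 0, , drop = FALSE]
  list(n_nbs = n,
       n_annotated = n_annotated_genes,
       proportion_pct = round2(100 * n / n_annotated_genes),
       by_group = by_group,
       by_subclass = by_sub)
}
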