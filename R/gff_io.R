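#' GFF3 gene-model input/output
#'
#' Gene models use 1-based closed coordinates throughout, following GFF3.
#' Reading and writing go through rtracklayer; the in-memory representation
#' is a plain list of two data frames (`genes`, `exons`) convenient for the
#' downstream statistics.
#'
#' @name gff_io
NULL

#' Read gene models from a GFF3 file
#'
#' @param path GFF3 file with `gene` features (and `exon` features carrying
#'   a `Parent`/`gene_id` attribute chain).
#' @return List with `genes` (`gene_id`, `chromosome`, `start`, `end`,
#'   `strand`) and `exons` (`gene_id`, `start`, `end`).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes_gr <- gr[type == "gene"]
  genes <- data.frame(
    gene_id = as.character(genes_gr$ID),
    chromosome = as.character(GenomicRanges::seqnames(genes_gr)),
    start = GenomicRanges::start(genes_gr),
    end = GenomicRanges::end(genes_gr),
    strand = as.character(GenomicRanges::strand(genes_gr)),
    stringsAsFactors = FALSE)
  mrna_gr <- gr[type == "mRNA"]
  mrna_parent <- setNames(vapply(mrna_gr$Parent, `[`, character(1), 1),
                          as.character(mrna_gr$ID))
  exons_gr <- gr[type == "exon"]
  if (length(exons_gr)) {
    parent <- vapply(exons_gr$Parent, `[`, character(1), 1)
    gene_of <- ifelse(parent %in% names(mrna_parent),
                      mrna_parent[parent], parent)
    exons <- data.frame(gene_id = unname(gene_of),
                        start = GenomicRanges::start(exons_gr),
                        end = GenomicRanges::end(exons_gr),
                        stringsAsFactors = FALSE)
  } else {
    exons <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  }
  list(genes = genes, exons = exons)
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and exon features (one mRNA per gene). Genes without
#' exon rows are written as gene features only.
#'
#' @param gene_models List with `genes` and `exons` data frames.
#' @param path Output file.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  genes <- gene_models$genes
  exons <- gene_models$exons
  has_exons <- genes$gene_id %in% exons$gene_id
  exon_gene_idx <- match(exons$gene_id, genes$gene_id)
  n_g <- nrow(genes); n_m <- sum(has_exons); n_e <- nrow(exons)
  gr <- GenomicRanges::GRanges(
    seqnames = c(genes$chromosome, genes$chromosome[has_exons],
                 genes$chromosome[exon_gene_idx]),
    ranges = IRanges::IRanges(
      start = c(genes$start, genes$start[has_exons], exons$start),
      end = c(genes$end, genes$end[has_exons], exons$end)),
    strand = c(genes$strand, genes$strand[has_exons],
               genes$strand[exon_gene_idx]))
  gr$type <- c(rep("gene", n_g), rep("mRNA", n_m), rep("exon", n_e))
  exon_num <- stats::ave(rep(1L, max(n_e, 1L))[seq_len(n_e)],
                         exons$gene_id, FUN = seq_along)
  gr$ID <- c(genes$gene_id,
             paste0(genes$gene_id[has_exons], ".t1"),
             paste0(exons$gene_id, ".e", exon_num))
  gr$Parent <- IRanges::CharacterList(
    c(rep(list(character(0)), n_g),
      as.list(genes$gene_id[has_exons]),
      as.list(paste0(exons$gene_id, ".t1"))))
  gr$source <- "nbsprofiler"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
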