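# Independent oracles, coded without reference to the package internals.

.GC <- Biostrings::GENETIC_CODE

# Random sense-codon sequence (oracle-side helper).
rand_cds <- function(n_codons) {
  sense <- names(.GC)[.GC != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Exhaustive-pathway Nei-Gojobori counts for one aligned pair: recursive
# enumeration of substitution orders, dropping pathways through stops.
ng86_oracle <- function(cds_a, cds_b) {
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(toupper(cds_a)); cb <- split3(toupper(cds_b))
  stopifnot(length(ca) == length(cb))
  syn_sites_codon <- function(cd) {
    s <- strsplit(cd, "")[[1]]
    n_syn <- 0
    for (pos in 1:3) for (b in setdiff(c("A","C","G","T"), s[pos])) {
      t <- s; t[pos] <- b
      mut <- paste(t, collapse = "")
      if (.GC[[mut]] != "*" && .GC[[mut]] == .GC[[cd]]) n_syn <- n_syn + 1
    }
    n_syn / 3
  }
  paths <- function(from, to) {
    # returns matrix of (sd, nd) for every stop-free pathway
    d <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(d)) return(matrix(numeric(0), ncol = 2))
    out <- NULL
    for (pos in d) {
      s <- strsplit(from, "")[[1]]
      s[pos] <- strsplit(to, "")[[1]][pos]
      mid <- paste(s, collapse = "")
      step <- if (.GC[[from]] == .GC[[mid]]) c(1, 0) else c(0, 1)
      if (.GC[[mid]] == "*" && mid != to) next
      if (mid == to) out <- rbind(out, step)
      else {
        rest <- paths(mid, to)
        if (nrow(rest)) out <- rbind(out, sweep(rest, 2, step, "+"))
      }
    }
    if (is.null(out)) matrix(numeric(0), ncol = 2) else out
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (syn_sites_codon(ca[i]) + syn_sites_codon(cb[i])) / 2
    pp <- paths(ca[i], cb[i])
    if (nrow(pp) == 0 && ca[i] != cb[i]) {
      # all pathways blocked by stops: fall back to averaging every order
      pp <- paths_all(ca[i], cb[i])
    }
    if (nrow(pp)) { Sd <- Sd + mean(pp[, 1]); Nd <- Nd + mean(pp[, 2]) }
  }
  list(S = S, N = 3 * length(ca) - S, Sd = Sd, Nd = Nd)
}

paths_all <- function(from, to) {
  d <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (!length(d)) return(matrix(numeric(0), ncol = 2))
  out <- NULL
  for (pos in d) {
    s <- strsplit(from, "")[[1]]
    s[pos] <- strsplit(to, "")[[1]][pos]
    mid <- paste(s, collapse = "")
    step <- if (.GC[[from]] == .GC[[mid]]) c(1, 0) else c(0, 1)
    if (mid == to) out <- rbind(out, step)
    else out <- rbind(out, sweep(paths_all(mid, to), 2, step, "+"))
  }
  out
}

# Brute-force cluster oracle: union-find over all gene pairs whose gap is
# within the window, then transitive closure.
cluster_oracle <- function(genes, window_bp) {
  res <- list()
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, , drop = FALSE]
    n <- nrow(g)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
      # gap between non-overlapping intervals, 0 if they overlap
      lo <- if (g$start[i] < g$start[j]) i else j
      hi <- if (lo == i) j else i
      gap <- max(0, g$start[hi] - g$end[lo])
      if (gap <= window_bp) { ri <- find(i); rj <- find(j); parent[ri] <- rj }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    res[[chr]] <- split(g$gene_id, comp)
  }
  # canonical form: sorted membership sets
  sets <- unlist(res, recursive = FALSE, use.names = FALSE)
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, character(1), 1))]
}

# Canonical membership sets from the package's locus table.
loci_sets <- function(loci) {
  sets <- lapply(strsplit(loci$members, ","), sort)
  sets[order(vapply(sets, `[`, character(1), 1))]
}

random_gene_table <- function(n, n_chr = 2, span = 2e6) {
  starts <- sample.int(span, n, replace = TRUE)
  len <- sample(500:20000, n, replace = TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             chromosome = paste0("chr", sample.int(n_chr, n, replace = TRUE)),
             start = starts, end = starts + len,
             stringsAsFactors = FALSE)
}
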