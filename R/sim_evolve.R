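#' Codon-pair evolution at a controlled Ka/Ks ratio
#'
#' A simple Markov substitution scheme: single-nucleotide changes are
#' proposed uniformly over sites and alternative bases; proposals creating a
#' stop codon are rejected outright, synonymous proposals are accepted, and
#' nonsynonymous proposals are accepted with probability proportional to the
#' target omega. Because rejected stop proposals would otherwise deflate the
#' realized nonsynonymous rate relative to the Nei-Gojobori site counting
#' (which books mutations to stops as nonsynonymous sites), the acceptance
#' probability is scaled by the ancestor's ratio of all nonsynonymous
#' one-step changes (stops included) to those excluding stops, so the
#' NG86-estimated omega is centred on the nominal value.
#'
#' @name sim_evolve
NULL

# Apply exactly n_subs accepted substitutions to a codon vector.
evolve_codons <- function(codons, omega, n_subs, kappa = 1) {
  tb <- codon_tables()
  w_non <- omega * kappa
  p_non <- min(1, w_non)
  p_syn <- if (w_non > 1) 1 / w_non else 1
  accepted <- 0
  while (accepted < n_subs) {
    ci <- sample.int(length(codons), 1)
    pos <- sample.int(3, 1)
    s <- strsplit(codons[ci], "")[[1]]
    alt <- sample(setdiff(tb$bases, s[pos]), 1)
    t <- s; t[pos] <- alt
    new_codon <- paste(t, collapse = "")
    if (tb$aa[new_codon] == "*") next
    syn <- tb$aa[new_codon] == tb$aa[codons[ci]]
    p_acc <- if (syn) p_syn else p_non
    if (runif(1) <= p_acc) {
      codons[ci] <- new_codon
      accepted <- accepted + 1
    }
  }
  codons
}

stop_proposal_kappa <- function(codons) {
  tb <- codon_tables()
  non_all <- 0; non_nostop <- 0
  for (cd in unique(codons)) {
    k <- sum(codons == cd)
    sc <- strsplit(cd, "")[[1]]
    for (pos in 1:3) for (b in setdiff(tb$bases, sc[pos])) {
      t <- sc; t[pos] <- b
      nc <- paste(t, collapse = "")
      if (tb$aa[nc] == tb$aa[cd]) next
      non_all <- non_all + k
      if (tb$aa[nc] != "*") non_nostop <- non_nostop + k
    }
  }
  if (non_nostop == 0) 1 else non_all / non_nostop
}

#' Evolve two descendants from an ancestral coding sequence
#'
#' @param ancestral_cds Coding sequence (character or DNAString), length
#'   divisible by 3, no internal stop codons.
#' @param omega Target Ka/Ks ratio (> 0).
#' @param expected_subs Total number of substitutions separating the two
#'   descendants (split binomially between the lineages); 0 returns two
#'   copies of the ancestor.
#' @param seed Integer seed; fixed seed gives identical descendants.
#' @return List with `a` and `b`, the descendant sequences (character).
#' @export
evolve_codon_pair <- function(ancestral_cds, omega, expected_subs, seed) {
  assert_that(omega > 0, "omega must be positive")
  assert_that(expected_subs >= 0, "expected_subs must be non-negative")
  tb <- codon_tables()
  codons <- split_codons(ancestral_cds, "ancestral_cds")
  assert_that(all(tb$aa[codons] != "*"), "internal stop codon in ancestor")
  if (expected_subs == 0)
    return(list(a = paste(codons, collapse = ""),
                b = paste(codons, collapse = "")))
  with_seed(seed, {
    kappa <- stop_proposal_kappa(codons)
    n_a <- rbinom(1, expected_subs, 0.5)
    a <- evolve_codons(codons, omega, n_a, kappa)
    b <- evolve_codons(codons, omega, expected_subs - n_a, kappa)
    list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
  })
}

# Random sense-codon sequence of n codons (uses current RNG stream).
random_cds <- function(n_codons) {
  tb <- codon_tables()
  paste(sample(tb$sense, n_codons, replace = TRUE), collapse = "")
}

# Reverse-translate a protein into codons, sampling synonymous codons
# uniformly (uses current RNG stream). Optionally appends a stop codon.
reverse_translate <- function(protein, stop_codon = FALSE) {
  tb <- codon_tables()
  by_aa <- split(tb$sense, tb$aa[tb$sense])
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  assert_that(all(aa %in% names(by_aa)), "protein contains unknown residues")
  codons <- vapply(aa, function(a) {
    opts <- by_aa[[a]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
  paste0(paste(codons, collapse = ""), if (stop_codon) "TAA" else "")
}
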