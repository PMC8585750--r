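#' Synthetic genome generation with planted ground truth
#'
#' A synthetic annotation is laid out chromosome by chromosome as an ordered
#' sequence of loci (planted clusters and singleton loci) separated by runs
#' of background genes. Background runs between loci always span more than
#' the cluster chaining window; within-cluster gaps respect each cluster's
#' declared maximum gap. Duplication types are planted through the homolog
#' pair table and gene ranks: tandem partners sit at adjacent ranks inside
#' clusters, proximal partners are consecutive singleton loci separated by a
#' small background run (rank distance <= 10 but physical gap above the
#' window), dispersed partners live on different chromosomes, and each WGD
#' pair is embedded in a collinear run of background homolog pairs spanning
#' two chromosomes. Proteins carry the exact motif-library consensus strings
#' (in canonical order for conserved genes, perturbed for planted
#' exceptions); homolog-pair coding sequences are evolved from a shared
#' random ancestor at the configured Ka/Ks ratio.
#'
#' @name sim_genome
NULL

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

# Non-motif (filler) protein regions are drawn from a reduced alphabet that
# leaves several positions of every library motif unmatched, so a filler
# window can never reach a motif's score threshold: planted motif content is
# exactly what the scanner reports.
FILLER_AA <- c("A","C","G","H","M","N","P","Q","W","Y")

random_protein <- function(n) paste(sample(FILLER_AA, n, replace = TRUE),
                                    collapse = "")

# Build one NBS protein and its domain-call rows.
build_protein <- function(gene_id, subclass, kinase2, p_loop, glpl,
                          motif_order, exon_count,
                          lib = default_motif_library()) {
  nterm_len <- switch(substr(subclass, 1, 1),
                      "C" = 120L, "T" = 150L, "R" = 110L, 30L)
  if (subclass %in% c("NL_CC", "N_CC", "NL_TIR", "N_TIR")) nterm_len <- 30L
  has_lrr <- subclass %in% c("CNL", "TNL", "RNL", "NL_CC", "NL_TIR")
  lrr_len <- if (has_lrr) 150L + 30L * exon_count else 0L
  linker <- function() random_protein(10 + sample.int(8, 1) + 5 * exon_count)

  motif_names <- CANONICAL_MOTIF_ORDER
  if (!p_loop) motif_names <- setdiff(motif_names, "P-loop")
  if (!glpl) motif_names <- setdiff(motif_names, "GLPL")
  if (motif_order == "core_change" && all(c("Kinase-2", "RNBS-B") %in%
                                          motif_names)) {
    i <- match(c("Kinase-2", "RNBS-B"), motif_names)
    motif_names[i] <- motif_names[rev(i)]
  }
  cons <- vapply(motif_names, function(m)
    motif_consensus(lib, m, terminal = if (m == "Kinase-2") kinase2), "")
  nbs_parts <- as.vector(rbind(vapply(seq_along(cons),
                                      function(i) linker(), ""), cons))
  if (motif_order == "flanked_repeat") {
    extra <- cons[[1]]  # repeat the first core motif upstream of the core
    nbs_parts <- c(linker(), extra, nbs_parts)
  }
  nbs_region <- paste(c(nbs_parts, linker()), collapse = "")
  protein <- paste0(random_protein(nterm_len), nbs_region,
                    if (has_lrr) random_protein(lrr_len) else "")
  plen <- nchar(protein)
  nbs_start <- nterm_len + 1L
  nbs_end <- nterm_len + nchar(nbs_region)
  dom <- data.frame(gene_id = gene_id, domain_type = "NBS",
                    start = nbs_start, end = nbs_end, e_value = 1e-20,
                    cc_score = NA_real_, source = "sim",
                    stringsAsFactors = FALSE)
  add <- function(type, s, e, ev = 1e-12, cc = NA_real_)
    rbind(dom, data.frame(gene_id = gene_id, domain_type = type, start = s,
                          end = e, e_value = ev, cc_score = cc,
                          source = "sim", stringsAsFactors = FALSE))
  if (subclass %in% c("CNL", "CN"))
    dom <- add("CC", 5L, nterm_len, ev = NA_real_, cc = 0.8)
  if (subclass %in% c("TNL", "TN"))
    dom <- add("TIR", 5L, nterm_len)
  if (subclass == "RNL")
    dom <- add("RPW8", 5L, nterm_len)
  if (has_lrr)
    dom <- add("LRR", nbs_end + 1L, plen)
  list(protein = protein, domains = dom)
}

# Partition an exonic length into exon pieces (each >= 40 bp) and draw
# intron lengths; returns list(exon_len, intron_len, gene_length).
draw_gene_structure <- function(exonic_len, exon_count) {
  if (exon_count == 1) {
    exon_len <- exonic_len
  } else {
    free <- exonic_len - 40L * exon_count
    cuts <- sort(sample.int(max(free, exon_count), exon_count - 1))
    parts <- diff(c(0L, cuts, max(free, exon_count)))
    exon_len <- 40L + round(parts / sum(parts) * free)
    exon_len[exon_count] <- exonic_len - sum(exon_len[-exon_count])
  }
  intron_len <- if (exon_count > 1)
    150L + sample.int(1650L, exon_count - 1, replace = TRUE) else integer(0)
  list(exon_len = as.integer(exon_len), intron_len = intron_len,
       gene_length = sum(exon_len) + sum(intron_len))
}

default_identity <- function(dup_type) {
  switch(dup_type,
         tandem = runif(1, 0.80, 0.92),
         proximal = runif(1, 0.75, 0.88),
         dispersed = runif(1, 0.60, 0.80),
         wgd = runif(1, 0.70, 0.80),
         runif(1, 0.55, 0.75))
}

# ---------------------------------------------------------------------------
# Generic profile from a sim_config: layout-ordered data frame of NBS genes.
profile_from_config <- function(config) {
  n <- config$n_nbs_genes
  mix <- config$subclass_mix
  # exact subclass counts by largest remainder
  raw <- mix * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  subclass <- sample(rep(names(cnt), cnt))
  group <- SUBCLASSES$group[match(subclass, SUBCLASSES$subclass)]

  dup <- config$duplication_spec
  pool <- sample.int(n)  # random gene indices to receive dup types
  take <- function(k) {
    if (k == 0) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  idx_tandem <- take(dup[["tandem"]])
  idx_prox <- take(dup[["proximal"]])
  idx_wgd <- take(dup[["wgd"]])
  idx_disp <- take(dup[["dispersed"]])
  idx_single <- pool

  row <- function(i, dup_type, hgroup, locus_role) {
    data.frame(idx = i, subclass = subclass[i], group = group[i],
               dup_type = dup_type, hgroup = hgroup,
               locus_role = locus_role, stringsAsFactors = FALSE)
  }
  hg <- 0
  tandem_pairs <- split(idx_tandem,
                        rep(seq_len(length(idx_tandem) / 2), each = 2))
  prox_pairs <- split(idx_prox, rep(seq_len(max(length(idx_prox) / 2, 0)),
                                    each = 2))
  wgd_pairs <- split(idx_wgd, rep(seq_len(max(length(idx_wgd) / 2, 0)),
                                  each = 2))
  disp_pairs <- split(idx_disp, rep(seq_len(max(length(idx_disp) / 2, 0)),
                                    each = 2))

  # Units: each unit is a list of loci; each locus a data frame of genes.
  units <- list()
  disp_hg <- setNames(rep(NA_integer_, n), seq_len(n))
  disp_partner <- setNames(rep(NA_integer_, n), seq_len(n))
  for (p in disp_pairs) {
    hg <- hg + 1
    disp_hg[as.character(p)] <- hg
    disp_partner[as.character(p[1])] <- p[2]
    disp_partner[as.character(p[2])] <- p[1]
  }
  used_filler <- integer(0)

  for (cs in config$cluster_spec) {
    m <- cs[1]; max_gap <- cs[2]
    genes <- list(); slots <- m
    while (slots >= 2 && length(tandem_pairs)) {
      hg <- hg + 1
      pr <- tandem_pairs[[1]]; tandem_pairs <- tandem_pairs[-1]
      genes[[length(genes) + 1]] <- row(pr[1], "tandem", hg, "cluster")
      genes[[length(genes) + 1]] <- row(pr[2], "tandem", hg, "cluster")
      slots <- slots - 2
    }
    while (slots > 0) {
      # fill with plain singles first; dispersed genes only if needed, and
      # never both members of one dispersed pair inside clusters
      avail <- setdiff(idx_single, used_filler)
      if (length(avail)) {
        i <- avail[1]; dt <- "singleton"; hgi <- NA_integer_
      } else {
        avail <- setdiff(idx_disp, used_filler)
        avail <- avail[!(disp_partner[as.character(avail)] %in% used_filler)]
        assert_that(length(avail) > 0,
                    "not enough non-tandem genes to fill planted clusters")
        i <- avail[1]; dt <- "dispersed"
        hgi <- disp_hg[[as.character(i)]]
      }
      used_filler <- c(used_filler, i)
      genes[[length(genes) + 1]] <- row(i, dt, hgi, "cluster")
      slots <- slots - 1
    }
    locus <- do.call(rbind, genes)
    locus$ivg <- ifelse(seq_len(nrow(locus)) == 1, 0L,
                        ifelse(!is.na(locus$hgroup) &
                                 duplicated(locus$hgroup) &
                                 locus$dup_type == "tandem", 0L, 2L))
    locus$max_gap <- max_gap
    units[[length(units) + 1]] <- list(kind = "cluster", loci = list(locus))
  }
  assert_that(length(tandem_pairs) == 0,
              "tandem genes exceed planted cluster capacity")

  for (p in prox_pairs) {
    hg <- hg + 1
    l1 <- row(p[1], "proximal", hg, "singleton")
    l2 <- row(p[2], "proximal", hg, "singleton")
    l1$ivg <- 0L; l2$ivg <- 0L; l1$max_gap <- NA; l2$max_gap <- NA
    l2$pre_bg <- 3L + sample.int(5, 1)  # rank distance pre_bg + 1 <= 9
    l1$pre_bg <- NA_integer_
    units[[length(units) + 1]] <- list(kind = "proximal",
                                       loci = list(l1, l2))
  }
  for (p in wgd_pairs) {
    hg <- hg + 1
    for (i in p) {
      l <- row(i, "wgd_segmental", hg, "singleton")
      l$ivg <- 0L; l$max_gap <- NA; l$pre_bg <- NA_integer_
      units[[length(units) + 1]] <- list(kind = "wgd", loci = list(l),
                                         split_pair = TRUE)
    }
  }
  remaining_disp <- setdiff(idx_disp, used_filler)
  for (i in remaining_disp) {
    l <- row(i, "dispersed", disp_hg[[as.character(i)]], "singleton")
    l$ivg <- 0L; l$max_gap <- NA; l$pre_bg <- NA_integer_
    units[[length(units) + 1]] <- list(kind = "dispersed", loci = list(l),
                                       split_pair = TRUE)
  }
  singles_left <- setdiff(idx_single, used_filler)
  n_unplaced <- config$n_unplaced
  assert_that(length(singles_left) >= n_unplaced,
              "not enough free singleton genes to mark as unplaced")
  unplaced_idx <- tail(singles_left, n_unplaced)
  for (i in setdiff(singles_left, unplaced_idx)) {
    l <- row(i, "singleton", NA_integer_, "singleton")
    l$ivg <- 0L; l$max_gap <- NA; l$pre_bg <- NA_integer_
    units[[length(units) + 1]] <- list(kind = "single", loci = list(l))
  }

  # Chromosome assignment: cycle; members of split pairs must differ.
  k <- config$n_chromosomes
  chr_names <- paste0("chr", seq_len(k))
  next_chr <- 0
  hg_chr <- new.env()  # hgroup -> chromosome of first-placed member
  rows <- list()
  locus_counter <- 0
  for (u in units) {
    cand <- chr_names[next_chr %% k + 1]
    cross_hgs <- unique(unlist(lapply(u$loci, function(l)
      l$hgroup[l$dup_type %in% c("dispersed", "wgd_segmental")])))
    cross_hgs <- as.character(cross_hgs[!is.na(cross_hgs)])
    taken <- unlist(lapply(cross_hgs, function(h)
      if (exists(h, envir = hg_chr)) get(h, envir = hg_chr) else NULL))
    if (length(taken) && cand %in% taken)
      cand <- setdiff(chr_names, taken)[1]
    for (h in cross_hgs)
      if (!exists(h, envir = hg_chr)) assign(h, cand, envir = hg_chr)
    next_chr <- next_chr + 1
    for (l in u$loci) {
      locus_counter <- locus_counter + 1
      l$chromosome <- cand
      l$locus_tag <- locus_counter
      if (!"pre_bg" %in% names(l)) l$pre_bg <- NA_integer_
      rows[[length(rows) + 1]] <- l
    }
  }
  prof <- do.call(rbind, rows)
  # unplaced genes on scaffolds
  if (n_unplaced > 0) {
    up <- do.call(rbind, lapply(seq_along(unplaced_idx), function(j) {
      l <- row(unplaced_idx[j], "singleton", NA_integer_, "singleton")
      l$ivg <- 0L; l$max_gap <- NA; l$pre_bg <- NA_integer_
      l$chromosome <- paste0("scaffold_", j)
      l$locus_tag <- locus_counter + j
      l
    }))
    prof <- rbind(prof, up)
  }
  # order by chromosome layout order (stable within chromosome) and assign ids
  prof$ord <- seq_len(nrow(prof))
  chr_order <- c(chr_names, grep("^scaffold", unique(prof$chromosome),
                                 value = TRUE))
  prof <- prof[order(match(prof$chromosome, chr_order), prof$ord), ]
  prof$locus <- match(prof$locus_tag, unique(prof$locus_tag))
  prof$gene_id <- sprintf("nbs_%03d", seq_len(nrow(prof)))
  rownames(prof) <- NULL
  prof$kinase2 <- ifelse(prof$group == "TNL", "D", "W")
  prof$p_loop <- TRUE
  prof$glpl <- TRUE
  prof$motif_order <- "conserved"
  prof$identity <- NA_real_
  prof$exon_count <- sample(1:8, nrow(prof), replace = TRUE,
                            prob = c(3, 6, 5, 4, 3, 2, 1, 1))
  prof
}

# ---------------------------------------------------------------------------
# Realize a layout-ordered profile into coordinates, sequences and tables.
realize_genome <- function(profile, config, with_cds = TRUE) {
  with_seed(child_seed(config$seed, "realize"), {
    lib <- default_motif_library()
    window <- config$window_bp
    chroms <- unique(profile$chromosome)
    real_chroms <- grep("^chr", chroms, value = TRUE)

    # Background budget: explicit pre-locus runs are honoured; undeclared
    # inter-locus runs scale with the remaining budget (3-18 genes each; the
    # spacing formula keeps the inter-locus gap above the window for any run
    # size); whatever is left trails after the last locus per chromosome.
    prof <- profile
    first_of_locus <- !duplicated(prof$locus)
    # Isolate WGD loci by at least 31 background genes on both sides so no
    # unrelated homolog pair can fall within the collinearity chaining gap
    # of the planted block runs.
    for (chr in unique(prof$chromosome)) {
      lids <- unique(prof$locus[prof$chromosome == chr])
      for (k in seq_along(lids)) {
        rows_k <- which(prof$locus == lids[k])
        if (any(prof$dup_type[rows_k] == "wgd_segmental")) {
          bump <- function(rows) {
            i <- rows[1]
            prof$pre_bg[i] <<- max(31L, prof$pre_bg[i], na.rm = TRUE)
          }
          bump(rows_k)
          if (k < length(lids)) bump(which(prof$locus == lids[k + 1]))
        }
      }
    }
    auto_run <- first_of_locus & is.na(prof$pre_bg) &
      grepl("^chr", prof$chromosome)
    prof$pre_bg[first_of_locus & is.na(prof$pre_bg)] <- 0L
    prof$pre_bg[!first_of_locus] <- 0L
    trailing_min <- 6L
    needed_min <- sum(prof$pre_bg) + 3L * sum(auto_run) + sum(prof$ivg) +
      trailing_min * length(real_chroms)
    assert_that(config$n_background_genes >= needed_min,
                "n_background_genes (%d) below layout requirement (%d)",
                config$n_background_genes, needed_min)
    leftover <- config$n_background_genes - needed_min
    auto_extra <- if (sum(auto_run)) min(15L, leftover %/% sum(auto_run))
                  else 0L
    prof$pre_bg[auto_run] <- 3L + auto_extra
    leftover <- leftover - auto_extra * sum(auto_run)
    trailing <- setNames(rep(trailing_min, length(real_chroms)), real_chroms)
    share <- leftover %/% length(real_chroms)
    trailing <- trailing + share
    rem <- leftover - share * length(real_chroms)
    if (rem > 0) trailing[seq_len(rem)] <- trailing[seq_len(rem)] + 1L

    genes <- list(); exons <- list(); bg <- list()
    proteins <- character(0); domains <- list()
    plen_of <- numeric(0)

    emit_bg_run <- function(chr, n, pos, spacing_each, len_min, len_max) {
      if (n <= 0) return(pos)
      for (i in seq_len(n)) {
        len <- sample(len_min:len_max, 1)
        start <- pos + spacing_each
        bg[[length(bg) + 1]] <<- data.frame(
          gene_id = sprintf("bg_%s_%04d", chr, length(bg) + 1),
          chromosome = chr, start = start, end = start + len - 1L,
          strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE)
        pos <- start + len - 1L
      }
      pos
    }

    for (chr in chroms) {
      rows <- prof[prof$chromosome == chr, , drop = FALSE]
      is_scaffold <- !grepl("^chr", chr)
      pos <- if (is_scaffold) 5000L else 10000L
      for (li in unique(rows$locus)) {
        lrows <- rows[rows$locus == li, , drop = FALSE]
        n_pre <- lrows$pre_bg[1]
        spacing <- ceiling(window * 1.08 / (n_pre + 1))
        if (is_scaffold) spacing <- 1000L
        pos <- emit_bg_run(chr, n_pre, pos, spacing, 1500L, 4500L)
        for (gi in seq_len(nrow(lrows))) {
          g <- lrows[gi, ]
          if (gi == 1) {
            pos <- pos + spacing
          } else {
            max_gap <- if (is.na(g$max_gap)) 60000 else g$max_gap
            intra <- max(1200, floor(0.6 * max_gap))
            if (g$ivg > 0) {
              bg_space <- max(200, floor((intra - g$ivg * 2600) /
                                           (g$ivg + 1)))
              pos <- emit_bg_run(chr, g$ivg, pos, bg_space, 2000L, 3200L)
              pos <- pos + bg_space
            } else {
              pos <- pos + max(600, min(3000, floor(intra / 4)))
            }
          }
          bp <- build_protein(g$gene_id, g$subclass, g$kinase2, g$p_loop,
                              g$glpl, g$motif_order, g$exon_count, lib)
          plen <- nchar(bp$protein)
          proteins[g$gene_id] <- bp$protein
          plen_of[g$gene_id] <- plen
          domains[[length(domains) + 1]] <- bp$domains
          st <- draw_gene_structure(3L * plen, g$exon_count)
          gstart <- pos
          epos <- gstart
          for (e in seq_len(g$exon_count)) {
            exons[[length(exons) + 1]] <- data.frame(
              gene_id = g$gene_id, start = epos,
              end = epos + st$exon_len[e] - 1L, stringsAsFactors = FALSE)
            epos <- epos + st$exon_len[e]
            if (e < g$exon_count) epos <- epos + st$intron_len[e]
          }
          gend <- gstart + st$gene_length - 1L
          genes[[length(genes) + 1]] <- data.frame(
            gene_id = g$gene_id, chromosome = chr, start = gstart,
            end = gend, strand = sample(c("+", "-"), 1),
            stringsAsFactors = FALSE)
          pos <- gend
        }
      }
      if (!is_scaffold)
        pos <- emit_bg_run(chr, trailing[[chr]], pos, 25000L, 1500L, 4500L)
    }

    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    background <- if (length(bg)) do.call(rbind, bg) else
      data.frame(gene_id = character(0), chromosome = character(0),
                 start = integer(0), end = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    domains <- do.call(rbind, domains)

    all_genes <- rbind(genes[, names(background)], background)
    all_genes <- all_genes[order(match(all_genes$chromosome, chroms),
                                 all_genes$start), ]
    rank_map <- do.call(rbind, lapply(split(all_genes,
                                            all_genes$chromosome), function(d)
      data.frame(gene_id = d$gene_id, chromosome = d$chromosome,
                 rank = order(order(d$start)), stringsAsFactors = FALSE)))
    rownames(rank_map) <- NULL

    # homolog pairs within hgroups
    pairs <- list()
    hgs <- unique(prof$hgroup[!is.na(prof$hgroup)])
    for (h in hgs) {
      members <- prof$gene_id[!is.na(prof$hgroup) & prof$hgroup == h]
      idov <- prof$identity[!is.na(prof$hgroup) & prof$hgroup == h][1]
      dt <- prof$dup_type[!is.na(prof$hgroup) & prof$hgroup == h][1]
      dtype <- sub("_segmental", "", dt)
      cmb <- utils::combn(members, 2)
      for (ci in seq_len(ncol(cmb))) {
        idv <- if (!is.na(idov)) idov else default_identity(dtype)
        pairs[[length(pairs) + 1]] <- data.frame(
          gene_a = cmb[1, ci], gene_b = cmb[2, ci], identity = idv,
          aligned_length = round(0.95 * min(plen_of[cmb[, ci]])),
          hgroup = h, stringsAsFactors = FALSE)
      }
    }
    pairs <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(gene_a = character(0), gene_b = character(0),
                 identity = numeric(0), aligned_length = numeric(0),
                 hgroup = integer(0), stringsAsFactors = FALSE)

    # collinear runs of background homologs around each WGD pair
    for (h in unique(prof$hgroup[prof$dup_type == "wgd_segmental" &
                                 !is.na(prof$hgroup)])) {
      members <- prof$gene_id[!is.na(prof$hgroup) & prof$hgroup == h]
      flank <- lapply(members, function(m) {
        chr <- genes$chromosome[genes$gene_id == m]
        r <- rank_map$rank[rank_map$gene_id == m]
        cand <- rank_map[rank_map$chromosome == chr &
                           rank_map$rank > r &
                           grepl("^bg_", rank_map$gene_id), , drop = FALSE]
        cand <- cand[order(cand$rank), ]
        head(cand$gene_id, 5)
      })
      assert_that(all(lengths(flank) >= 5),
                  "insufficient background genes to embed WGD block")
      for (i in 1:5)
        pairs <- rbind(pairs, data.frame(
          gene_a = flank[[1]][i], gene_b = flank[[2]][i], identity = 0.70,
          aligned_length = 300, hgroup = NA_integer_,
          stringsAsFactors = FALSE))
    }

    # coding sequences: one evolved family per hgroup
    cds <- character(0)
    truth_pairs <- NULL
    if (with_cds) {
      L <- config$codon_length
      for (h in hgs) {
        sel <- !is.na(prof$hgroup) & prof$hgroup == h
        members <- prof$gene_id[sel]
        grp <- prof$group[sel][1]
        om <- config$omega_values[[grp]]
        idov <- prof$identity[sel][1]
        subs <- if (!is.na(idov) && idov >= 0.99)
          max(1L, round(0.0025 * 3 * L)) else round(0.06 * 3 * L)
        anc <- split_codons(random_cds(L))
        kappa <- stop_proposal_kappa(anc)
        for (m in members)
          cds[m] <- paste(evolve_codons(anc, om, subs, kappa),
                          collapse = "")
        cmb <- utils::combn(members, 2)
        truth_pairs <- rbind(truth_pairs, data.frame(
          gene_a = cmb[1, ], gene_b = cmb[2, ], omega = om, hgroup = h,
          stringsAsFactors = FALSE))
      }
      for (m in setdiff(prof$gene_id, names(cds)))
        cds[m] <- random_cds(L)
      cds <- cds[prof$gene_id]
    }

    exonic_len <- tapply(exons$end - exons$start + 1, exons$gene_id, sum)
    exonic_len <- setNames(as.numeric(exonic_len), names(exonic_len))
    exonic_len <- exonic_len[genes$gene_id]

    idx <- seq_len(nrow(prof))
    candidates <- list(list_a = sort(prof$gene_id[idx %% 3 != 0]),
                       list_b = sort(prof$gene_id[idx %% 3 != 1]))

    truth <- list(
      genes = data.frame(gene_id = prof$gene_id, subclass = prof$subclass,
                         group = prof$group, dup_type = prof$dup_type,
                         chromosome = prof$chromosome, locus = prof$locus,
                         hgroup = prof$hgroup,
                         exon_count = prof$exon_count,
                         kinase2 = prof$kinase2,
                         motif_order = prof$motif_order,
                         stringsAsFactors = FALSE),
      pairs = truth_pairs)

    list(genes = genes, exons = exons, background = background,
         rank_map = rank_map, domains = domains, proteins = proteins,
         cds = cds, pairs = pairs, exonic_length = exonic_len,
         candidates = candidates, truth = truth, profile = prof,
         config = config)
  })
}

#' Generate a synthetic genome from a configuration
#'
#' @param config A [sim_config()].
#' @param with_cds Evolve coding sequences for homolog families (disable to
#'   speed up layout-only studies; proteins and domain tables are always
#'   generated).
#' @param with_counts Also simulate the expression count matrix.
#' @return A `sim_genome` list: `genes`, `exons`, `background`, `rank_map`,
#'   `domains`, `proteins`, `cds`, `pairs` (homolog table),
#'   `exonic_length`, `candidates` (two overlapping candidate id lists),
#'   `truth` (planted ground truth), `counts`/`samples` when requested, and
#'   the `config`.
#' @export
generate_genome <- function(config, with_cds = TRUE, with_counts = FALSE) {
  prof <- with_seed(child_seed(config$seed, "profile"),
                    profile_from_config(config))
  g <- realize_genome(prof, config, with_cds = with_cds)
  if (with_counts) {
    cc <- generate_counts(config, setNames(g$exonic_length, g$genes$gene_id))
    g$counts <- cc$counts
    g$samples <- cc$samples
    g$mean_fpkm <- cc$mean_fpkm
  }
  class(g) <- "sim_genome"
  g
}

#' Write a synthetic genome to standard files
#'
#' Emits GFF3 (gene/mRNA/exon features for NBS and background genes),
#' protein and CDS FASTA, domain TSV, homolog-pair TSV, candidate id lists,
#' counts and sample-sheet TSV when present, and the ground truth as JSON.
#'
#' @param genome A `sim_genome` from [generate_genome()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- list(genes = rbind(genome$genes,
                           cbind(genome$background)),
             exons = genome$exons)
  write_gene_models_gff3(gm, file.path(dir, "annotation.gff3"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(genome$proteins),
    file.path(dir, "proteins.faa"))
  if (length(genome$cds))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$cds),
      file.path(dir, "cds.fna"))
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(genome$domains, "domains.tsv")
  wt(genome$pairs, "homolog_pairs.tsv")
  writeLines(genome$candidates$list_a, file.path(dir, "candidates_a.txt"))
  writeLines(genome$candidates$list_b, file.path(dir, "candidates_b.txt"))
  if (!is.null(genome$counts)) {
    wt(data.frame(gene_id = rownames(genome$counts), genome$counts,
                  check.names = FALSE), "counts.tsv")
    wt(genome$samples, "samples.tsv")
  }
  jsonlite::write_json(genome$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}
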