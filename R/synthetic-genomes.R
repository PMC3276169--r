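# Genome-evolution simulator.
#
# Produces an ancestor genome with the structural features the analysis
# modules assume -- planted CDE point centromeres inside AT-rich troughs,
# telomeric tandem-repeat arrays at both chromosome ends, ordered gene
# features with occasional introns and tRNAs -- and evolves a descendant from
# it through inversions, reciprocal and telomeric translocations,
# centromere-loss arm translocations, tandem duplications, gene losses,
# intergenic contraction, and protein sequence divergence. Every applied
# event is recorded with full coordinates in a truth log that replays
# deterministically.

#' Simulator configuration
#'
#' Defaults mirror an Eremothecium-like genome at one tenth scale: eight
#' chromosomes of 60 genes (~1.5 kb genes, ~0.55 kb intergenics, matching a
#' ~2 kb/gene density), 40% background GC with 20 kb AT-rich centromeric
#' troughs at 25% GC, a 24 bp telomere unit in ~20-copy arrays, a ~160 bp
#' AT-rich CDEII, and a descendant history of 8 inversions, 3 reciprocal and
#' 1 telomeric translocation, one centromere-loss arm translocation
#' (chromosome count 8 -> 7), 3% gene loss, 2 tandem duplications, 20%
#' intergenic contraction and 40% per-site protein divergence (~60% mean
#' identity).
#'
#' @param seed Integer seed; every simulator draw flows from it.
#' @param n_chromosomes,genes_per_chromosome Genome shape.
#' @param mean_gene_bp,mean_intergenic_bp Mean feature/spacer lengths.
#' @param base_gc,centromere_gc Background and centromeric GC fractions.
#' @param centromere_trough_bp Width of the planted AT-rich trough.
#' @param telomere_unit,telomere_copies Telomeric tandem repeat.
#' @param cdeII_bp,cdeII_at CDEII spacer length and AT fraction.
#' @param n_inversions,n_reciprocal_translocations,n_telomeric_translocations
#'   Rearrangement counts for [evolve()].
#' @param n_centromere_loss_events Centromere-loss arm translocations (each
#'   reduces chromosome count by one without gene loss).
#' @param gene_loss_rate Per-gene loss probability.
#' @param tandem_dup_count Number of tandem gene duplications.
#' @param protein_mutation_rate Per-site substitution probability for
#'   descendant proteins.
#' @param intergenic_scale Fraction of each intergenic gap retained in the
#'   descendant (contraction emulates inter-ORF streamlining).
#' @param mean_protein_aa Mean protein length.
#' @param intron_rate Per-gene probability of carrying one intron.
#' @param trna_per_chromosome tRNA features per chromosome.
#' @param rdna_bp Length of the single planted rDNA repeat region (0 = none).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 8,
                       genes_per_chromosome = 60,
                       mean_gene_bp = 1500,
                       mean_intergenic_bp = 550,
                       base_gc = 0.40,
                       centromere_gc = 0.25,
                       centromere_trough_bp = 20000,
                       telomere_unit = "CACACCGCTGAGAGACCCGTACAC",
                       telomere_copies = 20,
                       cdeII_bp = 160,
                       cdeII_at = 0.9,
                       n_inversions = 8,
                       n_reciprocal_translocations = 3,
                       n_telomeric_translocations = 1,
                       n_centromere_loss_events = 1,
                       gene_loss_rate = 0.03,
                       tandem_dup_count = 2,
                       protein_mutation_rate = 0.4,
                       intergenic_scale = 0.8,
                       mean_protein_aa = 400,
                       intron_rate = 0.05,
                       trna_per_chromosome = 2,
                       rdna_bp = 10000) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              mean_gene_bp = mean_gene_bp,
              mean_intergenic_bp = mean_intergenic_bp,
              base_gc = base_gc, centromere_gc = centromere_gc,
              centromere_trough_bp = as.integer(centromere_trough_bp),
              telomere_unit = toupper(telomere_unit),
              telomere_copies = as.integer(telomere_copies),
              cdeII_bp = as.integer(cdeII_bp), cdeII_at = cdeII_at,
              n_inversions = as.integer(n_inversions),
              n_reciprocal_translocations = as.integer(n_reciprocal_translocations),
              n_telomeric_translocations = as.integer(n_telomeric_translocations),
              n_centromere_loss_events = as.integer(n_centromere_loss_events),
              gene_loss_rate = gene_loss_rate,
              tandem_dup_count = as.integer(tandem_dup_count),
              protein_mutation_rate = protein_mutation_rate,
              intergenic_scale = intergenic_scale,
              mean_protein_aa = as.integer(mean_protein_aa),
              intron_rate = intron_rate,
              trna_per_chromosome = as.integer(trna_per_chromosome),
              rdna_bp = as.integer(rdna_bp))
  counts <- cfg[grep("^n_|_count$|_copies$|per_chromosome$", names(cfg))]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  rates <- c(cfg$gene_loss_rate, cfg$protein_mutation_rate, cfg$base_gc,
             cfg$centromere_gc, cfg$cdeII_at, cfg$intergenic_scale)
  if (any(rates < 0 | rates > 1)) stop("rates and fractions must be in [0, 1]")
  if (cfg$n_chromosomes < 1 || cfg$genes_per_chromosome < 1) {
    stop("need at least one chromosome and one gene per chromosome")
  }
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

mutate_protein <- function(seq, rate) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(v)) < rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(a) sample(setdiff(AA20, a), 1),
                     character(1))
  }
  paste(v, collapse = "")
}

resolve_iupac <- function(consensus) {
  codes <- Biostrings::IUPAC_CODE_MAP
  v <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  paste(vapply(v, function(cc) {
    opts <- strsplit(codes[[cc]], "", fixed = TRUE)[[1]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

random_at_rich <- function(n, at_fraction) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at_fraction / 2, at_fraction / 2,
                        (1 - at_fraction) / 2, (1 - at_fraction) / 2)),
        collapse = "")
}

#' Simulate an ancestor genome
#'
#' Chromosomes are assembled left to right: telomere array, alternating
#' intergenic spacers and genes, a centromeric AT-rich trough with a
#' CDEI-CDEII-CDEIII element at its center inserted after half the genes,
#' and a closing telomere array. One chromosome (the fourth, if present)
#' additionally carries an rDNA-class repeat region. Gene ids follow the
#' `<prefix>_<chrom><ordinal>` convention (first ORF on chromosome 1 is
#' `<prefix>_1001`).
#'
#' @param config A [sim_config()].
#' @param id Genome label and gene-id prefix.
#' @return List with `genome` (a `genome` whose extra fields `centromeres`,
#'   `cde`, `telomeres` hold the planted truth intervals) and `proteins`
#'   (named character vector for protein-coding genes).
#' @export
simulate_ancestor <- function(config, id = "anc") {
  set.seed(config$seed)
  cde_cfg <- cde_config()
  telomere_arr <- strrep(config$telomere_unit, config$telomere_copies)
  chroms <- vector("list", config$n_chromosomes)
  cen_tab <- list(); cde_tab <- list(); tel_tab <- list()
  proteins <- character()
  for (ci in seq_len(config$n_chromosomes)) {
    parts <- character()
    feats <- list()
    pos <- 0L
    push <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }
    tel_left <- c(0L, nchar(telomere_arr))
    push(telomere_arr)
    cen_after <- ceiling(config$genes_per_chromosome / 2)
    n_trna <- config$trna_per_chromosome
    trna_at <- if (n_trna > 0) {
      sort(sample(seq_len(config$genes_per_chromosome), n_trna))
    } else integer()
    for (gi in seq_len(config$genes_per_chromosome)) {
      push(random_dna(max(50L, round(rgamma(1, shape = 2,
                                            scale = config$mean_intergenic_bp / 2))),
                      config$base_gc))
      glen <- max(300L, round(rnorm(1, config$mean_gene_bp,
                                    config$mean_gene_bp / 4)))
      gid <- sprintf("%s_%d%03d", id, ci, gi)
      gstart <- pos
      introns <- intron_matrix()
      if (runif(1) < config$intron_rate && glen > 600) {
        # valid intron: GT ... TACTAAC ... AG, planted mid-gene
        ilen <- sample(80:250, 1)
        ioff <- sample(60:(glen %/% 3), 1)
        iseq <- paste0("GT", random_dna(ilen - 18, config$base_gc),
                       "TACTAAC", random_dna(5, config$base_gc), "AG")
        gseq <- paste0(random_dna(ioff, config$base_gc), iseq,
                       random_dna(glen - ioff, config$base_gc))
        introns <- intron_matrix(gstart + ioff, gstart + ioff + nchar(iseq))
        push(gseq)
      } else {
        push(random_dna(glen, config$base_gc))
      }
      feats[[length(feats) + 1L]] <- data.frame(
        gene_id = gid, start = gstart, end = pos,
        strand = sample(c("+", "-"), 1), feature_class = "protein_coding",
        introns = I(list(introns)), stringsAsFactors = FALSE)
      proteins[[gid]] <- random_protein(
        max(80L, round(rnorm(1, config$mean_protein_aa,
                             config$mean_protein_aa / 5))))
      if (gi %in% trna_at) {
        push(random_dna(200L, config$base_gc))
        tstart <- pos
        push(random_dna(75L, config$base_gc))
        feats[[length(feats) + 1L]] <- data.frame(
          gene_id = sprintf("%s_t%d%02d", id, ci, match(gi, trna_at)),
          start = tstart, end = pos, strand = sample(c("+", "-"), 1),
          feature_class = "tRNA", introns = I(list(intron_matrix())),
          stringsAsFactors = FALSE)
      }
      if (gi == cen_after) {
        push(random_dna(200L, config$base_gc))
        cen_start <- pos
        cde_len <- config$cdeII_bp + nchar(cde_cfg$cdeI) +
          nchar(cde_cfg$cdeIII)
        flank <- (config$centromere_trough_bp - cde_len) %/% 2
        push(random_dna(flank, config$centromere_gc))
        cde_start <- pos
        push(resolve_iupac(cde_cfg$cdeI))
        push(random_at_rich(config$cdeII_bp, config$cdeII_at))
        push(resolve_iupac(cde_cfg$cdeIII))
        cde_end <- pos
        push(random_dna(config$centromere_trough_bp - cde_len - flank,
                        config$centromere_gc))
        cen_tab[[length(cen_tab) + 1L]] <- data.frame(
          chrom = sprintf("chr%d", ci), start = cen_start, end = pos)
        cde_tab[[length(cde_tab) + 1L]] <- data.frame(
          chrom = sprintf("chr%d", ci), start = cde_start, end = cde_end)
      }
      if (ci == 4 && gi == cen_after + 2 && config$rdna_bp > 0) {
        push(random_dna(150L, config$base_gc))
        rstart <- pos
        push(random_dna(config$rdna_bp, config$base_gc + 0.05))
        feats[[length(feats) + 1L]] <- data.frame(
          gene_id = sprintf("%s_rdna", id), start = rstart, end = pos,
          strand = "+", feature_class = "rDNA",
          introns = I(list(intron_matrix())), stringsAsFactors = FALSE)
      }
    }
    push(random_dna(max(50L, round(rgamma(1, shape = 2,
                                          scale = config$mean_intergenic_bp / 2))),
                    config$base_gc))
    tel_right_start <- pos
    push(telomere_arr)
    tel_tab[[length(tel_tab) + 1L]] <- data.frame(
      chrom = rep(sprintf("chr%d", ci), 2), end_label = c("left", "right"),
      start = c(tel_left[1], tel_right_start),
      end = c(tel_left[2], pos))
    chroms[[ci]] <- new_chromosome(sprintf("chr%d", ci),
                                   paste(parts, collapse = ""),
                                   features = do.call(rbind, feats))
  }
  g <- new_genome(id, chroms)
  g$centromeres <- do.call(rbind, cen_tab)
  g$cde <- do.call(rbind, cde_tab)
  g$telomeres <- do.call(rbind, tel_tab)
  list(genome = g, proteins = proteins)
}

# ---- event application ------------------------------------------------------
# Events operate on a working representation: per-chromosome sequence string,
# feature table, and annotation intervals (centromere trough + telomeres),
# all in current coordinates. Each applier takes explicit coordinates so the
# truth log can be replayed verbatim.

ws_from_genome <- function(sim) {
  g <- sim$genome
  lapply(names(g$chromosomes), function(cid) {
    ch <- g$chromosomes[[cid]]
    cen <- g$centromeres[g$centromeres$chrom == cid, , drop = FALSE]
    tel <- g$telomeres[g$telomeres$chrom == cid, , drop = FALSE]
    list(id = cid, seq = ch$sequence, features = ch$features,
         cen = cen[, c("start", "end"), drop = FALSE],
         tel = tel[, c("end_label", "start", "end"), drop = FALSE])
  })
}

ws_to_genome <- function(ws, id) {
  chroms <- lapply(ws, function(w) {
    new_chromosome(w$id, w$seq, features = w$features)
  })
  g <- new_genome(id, chroms)
  cen <- lapply(ws, function(w) {
    if (nrow(w$cen) == 0) return(NULL)
    cbind(data.frame(chrom = w$id), w$cen)
  })
  tel <- lapply(ws, function(w) {
    if (nrow(w$tel) == 0) return(NULL)
    cbind(data.frame(chrom = w$id), w$tel)
  })
  cen <- cen[!vapply(cen, is.null, logical(1))]
  tel <- tel[!vapply(tel, is.null, logical(1))]
  g$centromeres <- if (length(cen)) do.call(rbind, cen) else
    data.frame(chrom = character(), start = integer(), end = integer())
  g$telomeres <- if (length(tel)) do.call(rbind, tel) else
    data.frame(chrom = character(), end_label = character(),
               start = integer(), end = integer())
  g
}

shift_intervals <- function(tab, from, by) {
  for (col in intersect(c("start", "end"), names(tab))) {
    sel <- tab[[col]] >= from
    tab[[col]][sel] <- tab[[col]][sel] + by
  }
  tab
}

# reverse-complement of interval [s, e) within segment [a, b)
flip_interval <- function(s, e, a, b) c(a + (b - e), a + (b - s))

apply_inversion <- function(w, s, e) {
  L <- nchar(w$seq)
  seg <- substr(w$seq, s + 1, e)
  w$seq <- paste0(substr(w$seq, 1, s), revcomp_str(seg),
                  substr(w$seq, e + 1, L))
  remap <- function(tab) {
    inside <- tab$start >= s & tab$end <= e
    if (any(inside)) {
      ns <- s + (e - tab$end[inside])
      ne <- s + (e - tab$start[inside])
      tab$start[inside] <- ns
      tab$end[inside] <- ne
      if ("strand" %in% names(tab)) {
        tab$strand[inside] <- ifelse(tab$strand[inside] == "+", "-", "+")
      }
    }
    tab
  }
  ft <- remap(w$features)
  for (i in which(w$features$start >= s & w$features$end <= e)) {
    m <- w$features$introns[[i]]
    if (!is.null(m) && nrow(m) > 0) {
      fl <- t(apply(m, 1, function(r) flip_interval(r["start"], r["end"], s, e)))
      ft$introns[[i]] <- intron_matrix(rev(fl[, 1]), rev(fl[, 2]))
    }
  }
  w$features <- ft[order(ft$start), , drop = FALSE]
  rownames(w$features) <- NULL
  w$cen <- remap(w$cen)
  w$tel <- remap(w$tel)
  w
}

# remove [s, e) from w, returning the segment as a detached piece
cut_segment <- function(w, s, e) {
  seg_seq <- substr(w$seq, s + 1, e)
  pick <- function(tab) {
    inside <- tab$start >= s & tab$end <= e
    inner <- tab[inside, , drop = FALSE]
    for (col in c("start", "end")) inner[[col]] <- inner[[col]] - s
    rest <- tab[!inside, , drop = FALSE]
    rest <- shift_intervals(rest, e, -(e - s))
    list(inner = inner, rest = rest)
  }
  f <- pick(w$features)
  cenp <- pick(w$cen)
  telp <- pick(w$tel)
  piece <- list(seq = seg_seq, features = f$inner, cen = cenp$inner,
                tel = telp$inner)
  # shift inner intron coords by -s
  for (i in seq_len(nrow(piece$features))) {
    m <- piece$features$introns[[i]]
    if (!is.null(m) && nrow(m) > 0) {
      piece$features$introns[[i]] <- intron_matrix(m[, "start"] - s,
                                                   m[, "end"] - s)
    }
  }
  w$seq <- paste0(substr(w$seq, 1, s), substr(w$seq, e + 1, nchar(w$seq)))
  w$features <- f$rest
  for (i in seq_len(nrow(w$features))) {
    m <- w$features$introns[[i]]
    if (!is.null(m) && nrow(m) > 0 && m[1, "start"] >= e) {
      w$features$introns[[i]] <- intron_matrix(m[, "start"] - (e - s),
                                               m[, "end"] - (e - s))
    }
  }
  w$cen <- cenp$rest
  w$tel <- telp$rest
  list(w = w, piece = piece)
}

# insertion shift: spans ending exactly at pos stay put, spans starting at
# pos move right
shift_insert <- function(tab, pos, by) {
  tab$start[tab$start >= pos] <- tab$start[tab$start >= pos] + by
  tab$end[tab$end > pos] <- tab$end[tab$end > pos] + by
  tab
}

# insert a detached piece at position pos of w
insert_segment <- function(w, piece, pos) {
  plen <- nchar(piece$seq)
  w$seq <- paste0(substr(w$seq, 1, pos), piece$seq,
                  substr(w$seq, pos + 1, nchar(w$seq)))
  shift_piece <- function(tab) {
    for (col in c("start", "end")) tab[[col]] <- tab[[col]] + pos
    tab
  }
  w$features <- shift_insert(w$features, pos, plen)
  for (i in seq_len(nrow(w$features))) {
    m <- w$features$introns[[i]]
    if (!is.null(m) && nrow(m) > 0 && m[1, "start"] >= pos) {
      w$features$introns[[i]] <- intron_matrix(m[, "start"] + plen,
                                               m[, "end"] + plen)
    }
  }
  pf <- shift_piece(piece$features)
  for (i in seq_len(nrow(pf))) {
    m <- pf$introns[[i]]
    if (!is.null(m) && nrow(m) > 0) {
      pf$introns[[i]] <- intron_matrix(m[, "start"] + pos, m[, "end"] + pos)
    }
  }
  w$features <- rbind(w$features, pf)
  w$features <- w$features[order(w$features$start), , drop = FALSE]
  rownames(w$features) <- NULL
  cen_in <- shift_piece(piece$cen)
  tel_in <- shift_piece(piece$tel)
  w$cen <- rbind(shift_insert(w$cen, pos, plen),
                 cen_in[, names(w$cen), drop = FALSE])
  w$tel <- rbind(shift_insert(w$tel, pos, plen),
                 tel_in[, names(w$tel), drop = FALSE])
  w
}

# intergenic positions safe for cutting: not inside any feature, centromere
# trough, or telomere array; at least `margin` bp from each
safe_cut_positions <- function(w, margin = 20L) {
  L <- nchar(w$seq)
  blocked <- rbind(
    data.frame(start = w$features$start, end = w$features$end),
    w$cen[, c("start", "end"), drop = FALSE],
    w$tel[, c("start", "end"), drop = FALSE])
  blocked$start <- pmax(0L, blocked$start - margin)
  blocked$end <- pmin(L, blocked$end + margin)
  blocked <- blocked[order(blocked$start), , drop = FALSE]
  free <- integer()
  cur <- 0L
  for (i in seq_len(nrow(blocked))) {
    if (blocked$start[i] > cur) {
      mid <- (cur + blocked$start[i]) %/% 2L
      free <- c(free, mid)
    }
    cur <- max(cur, blocked$end[i])
  }
  if (cur < L) free <- c(free, (cur + L) %/% 2L)
  free
}

gene_count_between <- function(w, s, e) {
  sum(w$features$start >= s & w$features$end <= e &
        w$features$feature_class == "protein_coding")
}

# ---- evolve -----------------------------------------------------------------

#' Evolve a descendant genome from a simulated ancestor
#'
#' Applies, in fixed order: inversions, reciprocal translocations, telomeric
#' translocations, centromere-loss arm translocations, tandem duplications,
#' per-gene losses, intergenic contraction, and protein divergence. All cut
#' points fall in intergenic sequence away from planted centromeres and
#' telomere arrays (resampled if a draw collides, with a retry cap), so no
#' event destroys a gene. Every event is recorded with its realized
#' coordinates in the returned truth log; [replay_log()] reproduces the
#' descendant from the log alone.
#'
#' @param ancestor Output of [simulate_ancestor()].
#' @param config The same [sim_config()] (event counts, rates).
#' @param id Label for the descendant genome.
#' @return List of class `sim_evolution`: `genome` (descendant), `proteins`,
#'   `orthologs` (data frame `gene_a, gene_b, identity`; A = ancestor),
#'   `log` (class `evolution_log`).
#' @export
evolve <- function(ancestor, config, id = "desc") {
  set.seed(config$seed + 1L)
  ws <- ws_from_genome(ancestor)
  log <- list()
  record <- function(ev) log[[length(log) + 1L]] <<- ev

  pick_chrom <- function(min_free = 2) {
    lens <- vapply(ws, function(w) nchar(w$seq), numeric(1))
    ok <- which(vapply(ws, function(w) length(safe_cut_positions(w)) >= min_free,
                       logical(1)))
    if (length(ok) == 0) stop("no chromosome with enough intergenic cut sites")
    if (length(ok) == 1) return(ok)
    sample(ok, 1, prob = lens[ok])
  }

  # inversions: two intergenic cuts on one chromosome, >= 1 gene inside
  for (k in seq_len(config$n_inversions)) {
    for (try in 1:50) {
      ci <- pick_chrom()
      cuts <- safe_cut_positions(ws[[ci]])
      if (length(cuts) < 2) next
      se <- sort(sample(cuts, 2))
      if (gene_count_between(ws[[ci]], se[1], se[2]) < 1) next
      ws[[ci]] <- apply_inversion(ws[[ci]], se[1], se[2])
      record(list(type = "inversion", chrom = ws[[ci]]$id,
                  start = se[1], end = se[2]))
      break
    }
  }

  # reciprocal translocations: exchange suffixes; each product keeps one
  # centromere, so cuts fall on the same side of both centromeres
  do_reciprocal <- function(c1, c2, cut1, cut2) {
    r1 <- cut_segment(ws[[c1]], cut1, nchar(ws[[c1]]$seq))
    r2 <- cut_segment(ws[[c2]], cut2, nchar(ws[[c2]]$seq))
    ws[[c1]] <<- insert_segment(r1$w, r2$piece, cut1)
    ws[[c2]] <<- insert_segment(r2$w, r1$piece, cut2)
  }
  for (k in seq_len(config$n_reciprocal_translocations)) {
    if (length(ws) < 2) break
    for (try in 1:100) {
      cs <- sample(length(ws), 2)
      c1 <- cs[1]; c2 <- cs[2]
      cuts1 <- safe_cut_positions(ws[[c1]])
      cuts2 <- safe_cut_positions(ws[[c2]])
      cen1 <- ws[[c1]]$cen; cen2 <- ws[[c2]]$cen
      if (nrow(cen1) == 0 || nrow(cen2) == 0) next
      right1 <- cuts1[cuts1 > cen1$end[1]]
      right2 <- cuts2[cuts2 > cen2$end[1]]
      if (length(right1) == 0 || length(right2) == 0) next
      cut1 <- sample(right1, 1); cut2 <- sample(right2, 1)
      do_reciprocal(c1, c2, cut1, cut2)
      record(list(type = "reciprocal_translocation",
                  chrom1 = ws[[c1]]$id, cut1 = cut1,
                  chrom2 = ws[[c2]]$id, cut2 = cut2))
      break
    }
  }

  # telomeric translocations: an interior segment adjacent to one telomere
  # moves next to a telomere of another chromosome
  do_telomeric <- function(c1, cut1, c2) {
    w1 <- ws[[c1]]
    tel_r <- w1$tel[w1$tel$end_label == "right", , drop = FALSE]
    res <- cut_segment(w1, cut1, tel_r$start[1])
    w2 <- ws[[c2]]
    tel_r2 <- w2$tel[w2$tel$end_label == "right", , drop = FALSE]
    ws[[c1]] <<- res$w
    ws[[c2]] <<- insert_segment(w2, res$piece, tel_r2$start[1])
  }
  for (k in seq_len(config$n_telomeric_translocations)) {
    if (length(ws) < 2) break
    for (try in 1:100) {
      cs <- sample(length(ws), 2)
      c1 <- cs[1]; c2 <- cs[2]
      w1 <- ws[[c1]]
      cen1 <- w1$cen
      if (nrow(cen1) == 0) next
      tel_r <- w1$tel[w1$tel$end_label == "right", , drop = FALSE]
      if (nrow(tel_r) == 0) next
      cuts <- safe_cut_positions(w1)
      cand <- cuts[cuts > cen1$end[1] & cuts < tel_r$start[1] - 1000]
      if (length(cand) == 0) next
      cut1 <- sample(cand, 1)
      do_telomeric(c1, cut1, c2)
      record(list(type = "telomeric_translocation",
                  chrom1 = ws[[c1]]$id, cut = cut1, chrom2 = ws[[c2]]$id))
      break
    }
  }

  # centromere loss: both arms of one chromosome translocate to telomere-
  # adjacent positions of two other chromosomes; the centromere (and its
  # trough) is discarded; chromosome count decreases by one; no gene is lost
  do_cen_loss <- function(ci, d1, d2) {
    w <- ws[[ci]]
    cen <- w$cen
    left_arm <- cut_segment(w, 0L, cen$start[1])$piece
    right_arm <- cut_segment(w, cen$end[1], nchar(w$seq))$piece
    # strip the arms' own terminal telomere arrays records (they become
    # interstitial in the recipients; sequences stay, annotations drop)
    left_arm$tel <- left_arm$tel[0, , drop = FALSE]
    right_arm$tel <- right_arm$tel[0, , drop = FALSE]
    wd1 <- ws[[d1]]
    tel_r1 <- wd1$tel[wd1$tel$end_label == "right", , drop = FALSE]
    ws[[d1]] <<- insert_segment(wd1, left_arm, tel_r1$start[1])
    wd2 <- ws[[d2]]
    tel_r2 <- wd2$tel[wd2$tel$end_label == "right", , drop = FALSE]
    ws[[d2]] <<- insert_segment(wd2, right_arm, tel_r2$start[1])
    ws[[ci]] <<- NULL
  }
  for (k in seq_len(config$n_centromere_loss_events)) {
    if (length(ws) < 3) break
    with_cen <- which(vapply(ws, function(w) nrow(w$cen) > 0, logical(1)))
    if (length(with_cen) == 0) break
    ci <- if (length(with_cen) == 1) with_cen else sample(with_cen, 1)
    others <- setdiff(seq_along(ws), ci)
    ds <- sample(others, 2)
    lost_chrom <- ws[[ci]]$id
    left_to <- ws[[ds[1]]]$id
    right_to <- ws[[ds[2]]]$id
    cen_span <- ws[[ci]]$cen[1, ]
    do_cen_loss(ci, ds[1], ds[2])
    record(list(type = "centromere_loss", chrom = lost_chrom,
                cen_start = cen_span$start, cen_end = cen_span$end,
                left_to = left_to, right_to = right_to))
  }

  # tandem duplications: copy a gene right after itself with a short spacer
  dup_pairs <- list()
  do_tandem_dup <- function(ci, gid, spacer) {
    w <- ws[[ci]]
    fi <- which(w$features$gene_id == gid)
    f <- w$features[fi, ]
    gseq <- substr(w$seq, f$start + 1, f$end)
    piece <- list(seq = paste0(spacer, gseq),
                  features = data.frame(
                    gene_id = paste0(gid, "d"), start = nchar(spacer),
                    end = nchar(spacer) + (f$end - f$start), strand = f$strand,
                    feature_class = f$feature_class,
                    introns = I(list(intron_matrix())),
                    stringsAsFactors = FALSE),
                  cen = data.frame(start = integer(), end = integer()),
                  tel = data.frame(end_label = character(), start = integer(),
                                   end = integer()))
    ws[[ci]] <<- insert_segment(w, piece, f$end)
  }
  dup_done <- character()
  for (k in seq_len(config$tandem_dup_count)) {
    for (try in 1:50) {
      ci <- pick_chrom()
      w <- ws[[ci]]
      pc <- w$features[w$features$feature_class == "protein_coding" &
                         !grepl("d$", w$features$gene_id) &
                         !w$features$gene_id %in% dup_done, , drop = FALSE]
      if (nrow(pc) == 0) next
      gid <- sample(pc$gene_id, 1)
      dup_done <- c(dup_done, gid)
      spacer <- random_dna(100L, config$base_gc)
      do_tandem_dup(ci, gid, spacer)
      record(list(type = "tandem_duplication", chrom = ws[[ci]]$id,
                  gene = gid, copy = paste0(gid, "d"), spacer = spacer))
      dup_pairs[[length(dup_pairs) + 1L]] <- c(gid, paste0(gid, "d"))
      break
    }
  }

  # gene losses: annotation removed, sequence left in place
  anc_pc <- names(ancestor$proteins)
  lose <- anc_pc[runif(length(anc_pc)) < config$gene_loss_rate]
  if (length(lose) > 0) {
    for (ci in seq_along(ws)) {
      sel <- ws[[ci]]$features$gene_id %in% lose
      ws[[ci]]$features <- ws[[ci]]$features[!sel, , drop = FALSE]
    }
    record(list(type = "gene_loss", genes = lose))
  }

  # intergenic contraction: shrink each unprotected gap to intergenic_scale
  if (config$intergenic_scale < 1) {
    for (ci in seq_along(ws)) {
      w <- ws[[ci]]
      cuts <- contraction_cuts(w, config$intergenic_scale)
      # remove from the right so earlier cut coordinates stay valid
      for (ri in rev(seq_len(nrow(cuts)))) {
        w <- cut_segment(w, cuts$start[ri], cuts$end[ri])$w
      }
      ws[[ci]] <- w
      record(list(type = "intergenic_contraction", chrom = w$id,
                  scale = config$intergenic_scale))
    }
  }

  # protein divergence under a dedicated recorded seed (replayable)
  protein_seed <- config$seed + 2L
  surviving <- setdiff(anc_pc, lose)
  set.seed(protein_seed)
  proteins <- character()
  identities <- numeric()
  for (gid in surviving) {
    mut <- mutate_protein(ancestor$proteins[[gid]], config$protein_mutation_rate)
    proteins[[gid]] <- mut
    va <- strsplit(ancestor$proteins[[gid]], "", fixed = TRUE)[[1]]
    vb <- strsplit(mut, "", fixed = TRUE)[[1]]
    identities[[gid]] <- 100 * sum(va == vb) / length(va)
  }
  for (dp in dup_pairs) {
    if (dp[1] %in% names(proteins)) {
      proteins[[dp[2]]] <- mutate_protein(proteins[[dp[1]]], 0.05)
    }
  }

  # descendant genes carry the descendant prefix; orthology maps across
  rename <- function(ids) sub(paste0("^", ancestor$genome$id, "_"),
                              paste0(id, "_"), ids)
  g <- ws_to_genome(ws, id)
  for (ci in seq_along(g$chromosomes)) {
    g$chromosomes[[ci]]$features$gene_id <-
      rename(g$chromosomes[[ci]]$features$gene_id)
  }
  names(proteins) <- rename(names(proteins))
  orthologs <- data.frame(gene_a = surviving, gene_b = rename(surviving),
                          identity = unname(identities[surviving]),
                          stringsAsFactors = FALSE)
  final_order <- gene_order(g)
  log_obj <- structure(list(
    events = log,
    config_seed = config$seed,
    protein_seed = protein_seed,
    protein_mutation_rate = config$protein_mutation_rate,
    lost_genes = lose,
    duplicated_genes = vapply(dup_pairs, `[`, character(1), 1),
    final_gene_order = final_order
  ), class = "evolution_log")
  structure(list(genome = g, proteins = proteins, orthologs = orthologs,
                 log = log_obj),
            class = "sim_evolution")
}

# middle chunks to delete from unprotected intergenic gaps
contraction_cuts <- function(w, scale) {
  L <- nchar(w$seq)
  blocked <- rbind(
    data.frame(start = w$features$start, end = w$features$end),
    w$cen[, c("start", "end"), drop = FALSE],
    w$tel[, c("start", "end"), drop = FALSE])
  blocked <- blocked[order(blocked$start), , drop = FALSE]
  gaps <- list()
  cur <- 0L
  for (i in seq_len(nrow(blocked))) {
    if (blocked$start[i] > cur) {
      gaps[[length(gaps) + 1L]] <- c(cur, blocked$start[i])
    }
    cur <- max(cur, blocked$end[i])
  }
  if (cur < L) gaps[[length(gaps) + 1L]] <- c(cur, L)
  out <- list()
  for (gp in gaps) {
    wdt <- gp[2] - gp[1]
    drop <- floor(wdt * (1 - scale))
    if (drop < 10) next
    mid <- (gp[1] + gp[2]) %/% 2L
    out[[length(out) + 1L]] <- data.frame(start = mid - drop %/% 2L,
                                          end = mid - drop %/% 2L + drop)
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  do.call(rbind, out)
}

#' Replay a truth log on the ancestor
#'
#' Re-applies every recorded event with its logged coordinates (no random
#' draws except protein divergence, which re-runs under the logged seed) and
#' returns the reconstructed descendant. `identical()` to the genome
#' produced by [evolve()].
#'
#' @param ancestor Output of [simulate_ancestor()].
#' @param log An `evolution_log` from [evolve()].
#' @param config The [sim_config()] used for the run.
#' @param id Descendant label.
#' @return A `genome` object.
#' @export
replay_log <- function(ancestor, log, config, id = "desc") {
  ws <- ws_from_genome(ancestor)
  idx_of <- function(cid) which(vapply(ws, function(w) w$id, character(1)) == cid)
  for (ev in log$events) {
    if (ev$type == "inversion") {
      i <- idx_of(ev$chrom)
      ws[[i]] <- apply_inversion(ws[[i]], ev$start, ev$end)
    } else if (ev$type == "reciprocal_translocation") {
      i1 <- idx_of(ev$chrom1); i2 <- idx_of(ev$chrom2)
      r1 <- cut_segment(ws[[i1]], ev$cut1, nchar(ws[[i1]]$seq))
      r2 <- cut_segment(ws[[i2]], ev$cut2, nchar(ws[[i2]]$seq))
      ws[[i1]] <- insert_segment(r1$w, r2$piece, ev$cut1)
      ws[[i2]] <- insert_segment(r2$w, r1$piece, ev$cut2)
    } else if (ev$type == "telomeric_translocation") {
      i1 <- idx_of(ev$chrom1); i2 <- idx_of(ev$chrom2)
      w1 <- ws[[i1]]
      tel_r <- w1$tel[w1$tel$end_label == "right", , drop = FALSE]
      res <- cut_segment(w1, ev$cut, tel_r$start[1])
      w2 <- ws[[i2]]
      tel_r2 <- w2$tel[w2$tel$end_label == "right", , drop = FALSE]
      ws[[i1]] <- res$w
      ws[[i2]] <- insert_segment(w2, res$piece, tel_r2$start[1])
    } else if (ev$type == "centromere_loss") {
      ci <- idx_of(ev$chrom)
      w <- ws[[ci]]
      left_arm <- cut_segment(w, 0L, ev$cen_start)$piece
      right_arm <- cut_segment(w, ev$cen_end, nchar(w$seq))$piece
      left_arm$tel <- left_arm$tel[0, , drop = FALSE]
      right_arm$tel <- right_arm$tel[0, , drop = FALSE]
      d1 <- idx_of(ev$left_to); d2 <- idx_of(ev$right_to)
      tel1 <- ws[[d1]]$tel[ws[[d1]]$tel$end_label == "right", , drop = FALSE]
      ws[[d1]] <- insert_segment(ws[[d1]], left_arm, tel1$start[1])
      tel2 <- ws[[d2]]$tel[ws[[d2]]$tel$end_label == "right", , drop = FALSE]
      ws[[d2]] <- insert_segment(ws[[d2]], right_arm, tel2$start[1])
      ws[[ci]] <- NULL
    } else if (ev$type == "tandem_duplication") {
      # re-derive insertion deterministically from the logged gene
      ci <- which(vapply(ws, function(w) ev$gene %in% w$features$gene_id,
                         logical(1)))
      w <- ws[[ci]]
      fi <- which(w$features$gene_id == ev$gene)
      f <- w$features[fi, ]
      gseq <- substr(w$seq, f$start + 1, f$end)
      # the random spacer must match evolve(): impossible without the draw,
      # so the spacer is logged
      piece <- list(seq = paste0(ev$spacer, gseq),
                    features = data.frame(
                      gene_id = ev$copy, start = nchar(ev$spacer),
                      end = nchar(ev$spacer) + (f$end - f$start),
                      strand = f$strand, feature_class = f$feature_class,
                      introns = I(list(intron_matrix())),
                      stringsAsFactors = FALSE),
                    cen = data.frame(start = integer(), end = integer()),
                    tel = data.frame(end_label = character(),
                                     start = integer(), end = integer()))
      ws[[ci]] <- insert_segment(w, piece, f$end)
    } else if (ev$type == "gene_loss") {
      for (ci in seq_along(ws)) {
        sel <- ws[[ci]]$features$gene_id %in% ev$genes
        ws[[ci]]$features <- ws[[ci]]$features[!sel, , drop = FALSE]
      }
    } else if (ev$type == "intergenic_contraction") {
      ci <- idx_of(ev$chrom)
      w <- ws[[ci]]
      cuts <- contraction_cuts(w, ev$scale)
      if (nrow(cuts) > 0) {
        for (ri in rev(seq_len(nrow(cuts)))) {
          w <- cut_segment(w, cuts$start[ri], cuts$end[ri])$w
        }
      }
      ws[[ci]] <- w
    }
  }
  g <- ws_to_genome(ws, id)
  rename <- function(ids) sub(paste0("^", ancestor$genome$id, "_"),
                              paste0(id, "_"), ids)
  for (ci in seq_along(g$chromosomes)) {
    g$chromosomes[[ci]]$features$gene_id <-
      rename(g$chromosomes[[ci]]$features$gene_id)
  }
  g
}

#' Write a truth log as JSON
#' @param log An `evolution_log`.
#' @param path Output path.
#' @export
write_evolution_log <- function(log, path) {
  jsonlite::write_json(
    list(events = log$events, config_seed = log$config_seed,
         protein_seed = log$protein_seed, lost_genes = log$lost_genes,
         duplicated_genes = log$duplicated_genes),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(log)
}
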