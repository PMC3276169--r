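# Synteny-block detection by ortholog anchor chaining.
#
# An anchor is a one-to-one ortholog pair placed at its ordinal gene position
# on each genome; a block is a maximal run of consecutive anchors that is
# colinear on both genomes (strictly monotone ordinal indices, gaps bounded by
# max_gap_genes, one consistent direction on the second genome).

#' Build ortholog anchors between two genomes
#'
#' @param genome_a A `genome` object.
#' @param genome_b A `genome` or `ancestral_order` object.
#' @param orthologs Data frame `gene_a, gene_b, identity` with a resolved
#'   one-to-one mapping (a gene appears in at most one pair).
#' @return Data frame of anchors with ordinal indices and bp coordinates on
#'   genome A (bp coordinates on B are `NA` for an ancestral order).
#' @export
build_anchors <- function(genome_a, genome_b, orthologs) {
  if (nrow(orthologs) == 0) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      chrom_a = character(), index_a = integer(),
                      start_a = integer(), end_a = integer(),
                      strand_a = character(), chrom_b = character(),
                      index_b = integer(), start_b = integer(),
                      end_b = integer(), strand_b = character(),
                      orientation = character(), identity = numeric()))
  }
  if (anyDuplicated(orthologs$gene_a) || anyDuplicated(orthologs$gene_b)) {
    stop("ortholog map is not one-to-one; resolve many-to-many pairs first")
  }
  ord_a <- gene_order(genome_a)
  ord_b <- gene_order(genome_b)
  ia <- match(orthologs$gene_a, ord_a$gene_id)
  ib <- match(orthologs$gene_b, ord_b$gene_id)
  if (anyNA(ia)) {
    stop("ortholog gene(s) absent from genome A: ",
         paste(head(orthologs$gene_a[is.na(ia)], 5), collapse = ", "))
  }
  if (anyNA(ib)) {
    stop("ortholog gene(s) absent from genome B: ",
         paste(head(orthologs$gene_b[is.na(ib)], 5), collapse = ", "))
  }
  anchors <- data.frame(
    gene_a = orthologs$gene_a, gene_b = orthologs$gene_b,
    chrom_a = ord_a$chrom[ia], index_a = ord_a$index[ia],
    start_a = ord_a$start[ia], end_a = ord_a$end[ia],
    strand_a = ord_a$strand[ia],
    chrom_b = ord_b$chrom[ib], index_b = ord_b$index[ib],
    start_b = ord_b$start[ib], end_b = ord_b$end[ib],
    strand_b = ord_b$strand[ib],
    stringsAsFactors = FALSE
  )
  anchors$orientation <- ifelse(anchors$strand_a == anchors$strand_b,
                                "same", "inverted")
  anchors$identity <- orthologs$identity
  anchors <- anchors[order(anchors$chrom_a, anchors$index_a), , drop = FALSE]
  rownames(anchors) <- NULL
  anchors
}

colinear_step <- function(anchors, i, j, dir, max_gap) {
  # can anchor j (next row) extend a run ending at row i with direction dir?
  if (anchors$chrom_a[j] != anchors$chrom_a[i]) return(NULL)
  if (anchors$chrom_b[j] != anchors$chrom_b[i]) return(NULL)
  if (anchors$index_a[j] - anchors$index_a[i] - 1L > max_gap) return(NULL)
  db <- anchors$index_b[j] - anchors$index_b[i]
  if (db == 0L) return(NULL)
  if (abs(db) - 1L > max_gap) return(NULL)
  step_dir <- sign(db)
  if (!is.na(dir) && step_dir != dir) return(NULL)
  step_dir
}

#' Chain anchors into synteny blocks
#'
#' Greedy left-to-right chaining: anchors are scanned in genome-A order and
#' each block is the maximal colinear run starting at the first unassigned
#' anchor (ties between adjacent blocks therefore resolve to the left block).
#' Runs shorter than `min_anchors` are returned as singletons -- the orphan
#' orthologs that fall between blocks.
#'
#' @param anchors Output of [build_anchors()].
#' @param max_gap_genes Maximum number of intervening unanchored genes
#'   tolerated between consecutive anchors, on either genome.
#' @param min_anchors Minimum anchors per block (must be >= 2).
#' @return List with `blocks` (data frame sorted by `chrom_a`, `start_a`) and
#'   `singletons` (anchor rows not assigned to any block).
#' @export
chain_blocks <- function(anchors, max_gap_genes = 3, min_anchors = 2) {
  if (min_anchors < 2) stop("min_anchors must be >= 2: a block needs >= 2 anchors")
  n <- nrow(anchors)
  empty_blocks <- data.frame(
    block_id = integer(), chrom_a = character(), chrom_b = character(),
    start_a = integer(), end_a = integer(), length_a = integer(),
    start_b = integer(), end_b = integer(), index_b_min = integer(),
    orientation = character(), n_anchors = integer(),
    anchor_rows = I(list()))
  if (n == 0) return(list(blocks = empty_blocks, singletons = anchors))
  anchors <- anchors[order(anchors$chrom_a, anchors$index_a), , drop = FALSE]
  rownames(anchors) <- NULL
  runs <- list()
  run <- 1L
  dir <- NA_integer_
  i <- 1L
  while (i < n) {
    step <- colinear_step(anchors, i, i + 1L, dir, max_gap_genes)
    if (is.null(step)) {
      runs[[length(runs) + 1L]] <- list(rows = run, dir = dir)
      run <- i + 1L
      dir <- NA_integer_
    } else {
      run <- c(run, i + 1L)
      dir <- step
    }
    i <- i + 1L
  }
  runs[[length(runs) + 1L]] <- list(rows = run, dir = dir)

  is_block <- vapply(runs, function(r) length(r$rows) >= min_anchors, logical(1))
  singleton_rows <- unlist(lapply(runs[!is_block], `[[`, "rows"))
  blocks <- lapply(runs[is_block], function(r) {
    a <- anchors[r$rows, , drop = FALSE]
    data.frame(
      chrom_a = a$chrom_a[1], chrom_b = a$chrom_b[1],
      start_a = min(a$start_a), end_a = max(a$end_a),
      length_a = max(a$end_a) - min(a$start_a),
      start_b = if (all(is.na(a$start_b))) NA_integer_ else min(a$start_b),
      end_b = if (all(is.na(a$end_b))) NA_integer_ else max(a$end_b),
      index_b_min = min(a$index_b),
      orientation = if (r$dir < 0) "inverted" else "same",
      n_anchors = nrow(a),
      anchor_rows = I(list(r$rows)),
      stringsAsFactors = FALSE)
  })
  blocks <- if (length(blocks)) do.call(rbind, blocks) else empty_blocks
  if (nrow(blocks)) {
    blocks <- blocks[order(blocks$chrom_a, blocks$start_a), , drop = FALSE]
    blocks$block_id <- seq_len(nrow(blocks))
    blocks <- blocks[, c("block_id", setdiff(names(blocks), "block_id"))]
    rownames(blocks) <- NULL
  }
  singles <- anchors[sort(singleton_rows), , drop = FALSE]
  rownames(singles) <- NULL
  list(blocks = blocks, singletons = singles)
}

#' Summary statistics of a block decomposition
#'
#' @param blocks Block data frame from [chain_blocks()].
#' @param genome_a Genome A (supplies per-chromosome totals and the non-rDNA
#'   genome length used for the half-genome block number).
#' @return List of class `block_statistics`: per-chromosome counts, total
#'   count, mean block length on A in kb (1 decimal), and the half-genome
#'   block number `half_genome_blocks` -- the smallest k such that the k
#'   largest blocks cover at least 50% of the genome-A length (`NA` if all
#'   blocks together cover less).
#' @export
block_statistics <- function(blocks, genome_a) {
  chroms <- names(genome_a$chromosomes)
  counts <- table(factor(blocks$chrom_a, levels = chroms))
  counts <- setNames(as.integer(counts), chroms)
  total <- nrow(blocks)
  mean_kb <- if (total > 0) round(mean(blocks$length_a) / 1000, 1) else NA_real_
  genome_bp <- genome_statistics(genome_a)$total_bp
  h <- NA_integer_
  if (total > 0) {
    lens <- sort(blocks$length_a, decreasing = TRUE)
    cum <- cumsum(as.numeric(lens))
    hit <- which(cum >= genome_bp / 2)
    if (length(hit)) h <- hit[1]
  }
  structure(list(per_chromosome = counts, total = total,
                 mean_block_kb = mean_kb, genome_bp = genome_bp,
                 half_genome_blocks = h),
            class = "block_statistics")
}

#' @export
print.block_statistics <- function(x, ...) {
  cat("Synteny block statistics\n")
  for (ch in names(x$per_chromosome)) {
    cat(sprintf("  %-8s %d\n", ch, x$per_chromosome[[ch]]))
  }
  cat(sprintf("  Total    %d\n", x$total))
  cat(sprintf("  Mean block length  %.1f kb\n", x$mean_block_kb))
  cat(sprintf("  Half-genome block number  %s\n", x$half_genome_blocks))
  invisible(x)
}

#' Compare the gene neighborhood of a locus between two genomes
#'
#' For the `flank_k` genes on each side of the focal span on genome A, reports
#' whether each gene is conserved in the corresponding genome-B neighborhood,
#' missing from B altogether, or present in B but relocated (different
#' chromosome, or far outside the neighborhood window). Used e.g. to compare
#' the conserved flanks of mating-type loci.
#'
#' @param genome_a,genome_b `genome` objects.
#' @param focal_genes_a Character vector of focal gene ids on one chromosome
#'   of A.
#' @param flank_k Number of flanking genes per side (>= 1).
#' @param orthologs One-to-one ortholog table `gene_a, gene_b, identity`.
#' @return List of class `locus_neighborhood` with a per-gene `report` data
#'   frame (order and strand preserved) and truncation flags for loci at
#'   chromosome ends.
#' @export
compare_locus_neighborhood <- function(genome_a, genome_b, focal_genes_a,
                                       flank_k, orthologs) {
  if (flank_k < 1) stop("flank_k must be >= 1")
  ord_a <- gene_order(genome_a)
  ord_b <- gene_order(genome_b)
  fi <- match(focal_genes_a, ord_a$gene_id)
  if (anyNA(fi)) {
    stop("focal gene(s) not found in genome A: ",
         paste(focal_genes_a[is.na(fi)], collapse = ", "))
  }
  if (length(unique(ord_a$chrom[fi])) != 1) {
    stop("focal genes must lie on a single chromosome")
  }
  chrom <- ord_a$chrom[fi[1]]
  on_chrom <- which(ord_a$chrom == chrom)
  pos <- match(fi, on_chrom)          # positions within the chromosome
  lo <- min(pos); hi <- max(pos)
  left_pos <- if (lo > 1) seq(max(1, lo - flank_k), lo - 1) else integer()
  right_pos <- if (hi < length(on_chrom)) {
    seq(hi + 1, min(length(on_chrom), hi + flank_k))
  } else integer()
  left_idx <- on_chrom[left_pos]
  right_idx <- on_chrom[right_pos]
  truncated_left <- (lo - 1) < flank_k
  truncated_right <- (length(on_chrom) - hi) < flank_k

  rows <- c(left_idx, on_chrom[lo:hi], right_idx)
  side <- c(rep("left", length(left_idx)), rep("focal", hi - lo + 1),
            rep("right", length(right_idx)))
  genes <- ord_a$gene_id[rows]
  b_gene <- orthologs$gene_b[match(genes, orthologs$gene_a)]
  bi <- match(b_gene, ord_b$gene_id)
  b_chrom <- ord_b$chrom[bi]
  b_index <- ord_b$index[bi]

  present <- !is.na(bi)
  status <- rep("missing_in_b", length(genes))
  if (any(present)) {
    modal <- names(sort(table(b_chrom[present]), decreasing = TRUE))[1]
    anchor_idx <- b_index[present & b_chrom == modal]
    center <- stats::median(anchor_idx)
    tol <- 2 * flank_k + (hi - lo + 1)
    conserved <- present & b_chrom == modal & abs(b_index - center) <= tol
    status[conserved] <- "conserved"
    status[present & !conserved] <- "rearranged"
  }
  report <- data.frame(gene_a = genes, side = side,
                       strand_a = ord_a$strand[rows],
                       gene_b = b_gene, chrom_b = b_chrom,
                       strand_b = ord_b$strand[bi],
                       status = status, stringsAsFactors = FALSE)
  structure(list(chrom_a = chrom, report = report,
                 truncated_left = truncated_left,
                 truncated_right = truncated_right,
                 n_missing = sum(status == "missing_in_b"),
                 n_rearranged = sum(status == "rearranged")),
            class = "locus_neighborhood")
}

#' Assign chromosome correspondence via shared centromeric blocks
#'
#' Maps each chromosome of genome A to the chromosome of genome B whose
#' centromere lies in (or immediately flanks) a synteny block shared with the
#' region around the A centromere. Centromeres with no such partner -- the
#' signature of a centromere-loss arm translocation -- are reported as
#' orphans.
#'
#' @param genome_a,genome_b `genome` objects (labels only; coordinates come
#'   from `blocks` and the centromere tables).
#' @param blocks Block data frame from [chain_blocks()] run A vs B.
#' @param centromeres_a,centromeres_b Data frames `chrom, start, end` of
#'   centromere calls for each genome.
#' @param flank_bp How far beyond a centromere span a block may start and
#'   still count as centromere-flanking.
#' @return List with `assignments` (data frame `chrom_a, chrom_b`),
#'   `orphans_a`, and `orphans_b`.
#' @export
assign_centromeric_chromosome_ids <- function(genome_a, genome_b, blocks,
                                              centromeres_a, centromeres_b,
                                              flank_bp = 20000) {
  overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
  assignments <- data.frame(chrom_a = character(), chrom_b = character(),
                            stringsAsFactors = FALSE)
  orphans_a <- character()
  matched_b <- character()
  for (i in seq_len(nrow(centromeres_a))) {
    ca <- centromeres_a[i, ]
    near <- blocks[blocks$chrom_a == ca$chrom &
                     overlaps(blocks$start_a, blocks$end_a,
                              ca$start - flank_bp, ca$end + flank_bp), ,
                   drop = FALSE]
    cand <- character()
    for (j in seq_len(nrow(near))) {
      bl <- near[j, ]
      cb <- centromeres_b[centromeres_b$chrom == bl$chrom_b, , drop = FALSE]
      if (nrow(cb) == 0 || is.na(bl$start_b)) next
      if (any(overlaps(cb$start, cb$end,
                       bl$start_b - flank_bp, bl$end_b + flank_bp))) {
        cand <- union(cand, bl$chrom_b)
      }
    }
    if (length(cand) == 0) {
      orphans_a <- c(orphans_a, ca$chrom)
    } else if (length(cand) == 1) {
      assignments <- rbind(assignments,
                           data.frame(chrom_a = ca$chrom, chrom_b = cand,
                                      stringsAsFactors = FALSE))
      matched_b <- c(matched_b, cand)
    } else {
      stop("ambiguous centromere assignment for ", ca$chrom, ": candidates ",
           paste(sort(cand), collapse = ", "))
    }
  }
  if (anyDuplicated(matched_b)) {
    dup <- unique(matched_b[duplicated(matched_b)])
    stop("ambiguous centromere assignment: chromosome(s) of B matched twice: ",
         paste(dup, collapse = ", "))
  }
  orphans_b <- setdiff(centromeres_b$chrom, matched_b)
  list(assignments = assignments, orphans_a = orphans_a, orphans_b = orphans_b)
}

#' Write synteny blocks as BED-like TSV on genome A coordinates
#'
#' @param blocks Block data frame from [chain_blocks()].
#' @param path Output path.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(chrom = blocks$chrom_a, start = blocks$start_a,
                    end = blocks$end_a,
                    name = paste0("block", blocks$block_id, "|",
                                  blocks$chrom_b, ":",
                                  ifelse(is.na(blocks$start_b), ".",
                                         blocks$start_b)),
                    score = blocks$n_anchors,
                    strand = ifelse(blocks$orientation == "same", "+", "-"))
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(blocks)
}
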