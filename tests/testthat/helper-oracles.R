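# Independent oracles and fixture builders. These deliberately re-derive
# results by enumeration or direct definition, separate from the package's
# own code paths.

# --- toy genome builders -----------------------------------------------------

# genome from a list of per-chromosome gene-id vectors; genes 500 bp at 1 kb
# spacing, all "+" unless strands given
toy_genome <- function(id, orders, strands = NULL, classes = NULL) {
  chroms <- lapply(seq_along(orders), function(ci) {
    ids <- orders[[ci]]
    n <- length(ids)
    st <- if (is.null(strands)) rep("+", n) else strands[[ci]]
    cl <- if (is.null(classes)) rep("protein_coding", n) else classes[[ci]]
    feats <- data.frame(gene_id = ids,
                        start = seq_len(n) * 1000L,
                        end = seq_len(n) * 1000L + 500L,
                        strand = st, feature_class = cl,
                        introns = I(rep(list(eremosyn:::intron_matrix()), n)),
                        stringsAsFactors = FALSE)
    new_chromosome(paste0("c", ci), length = n * 1000L + 2000L,
                   features = feats)
  })
  new_genome(id, chroms)
}

identity_orthologs <- function(ids_a, ids_b = ids_a, identity = 80) {
  data.frame(gene_a = ids_a, gene_b = ids_b, identity = identity,
             stringsAsFactors = FALSE)
}

# --- synteny oracle ----------------------------------------------------------

# whole-run colinearity predicate, checked over the complete candidate run
oracle_is_colinear <- function(a, rows, max_gap) {
  if (length(rows) == 1) return(TRUE)
  if (length(unique(a$chrom_a[rows])) > 1) return(FALSE)
  if (length(unique(a$chrom_b[rows])) > 1) return(FALSE)
  da <- diff(a$index_a[rows])
  if (any(da < 1) || any(da - 1 > max_gap)) return(FALSE)
  db <- diff(a$index_b[rows])
  if (any(db == 0)) return(FALSE)
  if (!(all(db > 0) || all(db < 0))) return(FALSE)
  if (any(abs(db) - 1 > max_gap)) return(FALSE)
  TRUE
}

# leftmost-maximal partition of anchors (sorted by chrom_a, index_a) into
# colinear runs, by exhaustive prefix search from each start
oracle_partition <- function(anchors, max_gap) {
  a <- anchors[order(anchors$chrom_a, anchors$index_a), , drop = FALSE]
  n <- nrow(a)
  runs <- list()
  pos <- 1L
  while (pos <= n) {
    len <- 1L
    while (pos + len <= n &&
           oracle_is_colinear(a, pos:(pos + len), max_gap)) {
      len <- len + 1L
    }
    runs[[length(runs) + 1L]] <- pos:(pos + len - 1L)
    pos <- pos + len
  }
  list(anchors = a, runs = runs)
}

random_anchor_set <- function(n_anchors, n_chrom_a = 2, n_chrom_b = 2) {
  ca <- sort(sample(paste0("a", seq_len(n_chrom_a)), n_anchors, replace = TRUE))
  ia <- unlist(lapply(split(seq_len(n_anchors), ca), function(rows) {
    sort(sample(0:(5 * length(rows)), length(rows)))
  }), use.names = FALSE)
  cb <- sample(paste0("b", seq_len(n_chrom_b)), n_anchors, replace = TRUE)
  ib <- integer(n_anchors)
  for (c in unique(cb)) {
    rows <- which(cb == c)
    ib[rows] <- sample(0:(5 * length(rows)), length(rows))
  }
  data.frame(gene_a = paste0("ga", seq_len(n_anchors)),
             gene_b = paste0("gb", seq_len(n_anchors)),
             chrom_a = ca, index_a = ia,
             start_a = ia * 1000L, end_a = ia * 1000L + 500L,
             strand_a = sample(c("+", "-"), n_anchors, TRUE),
             chrom_b = cb, index_b = ib,
             start_b = ib * 1000L, end_b = ib * 1000L + 500L,
             strand_b = sample(c("+", "-"), n_anchors, TRUE),
             orientation = "same", identity = 80,
             stringsAsFactors = FALSE)
}

# --- repeat oracles ----------------------------------------------------------

oracle_rotations <- function(u) {
  n <- nchar(u)
  out <- character(n)
  for (k in 0:(n - 1)) out[k + 1] <- paste0(substring(u, k + 1), substring(u, 1, k))
  out
}

oracle_revcomp <- function(u) {
  v <- rev(strsplit(chartr("ACGT", "TGCA", u), "", fixed = TRUE)[[1]])
  paste(v, collapse = "")
}

oracle_repeat_distance <- function(a, b) {
  va <- strsplit(a, "", fixed = TRUE)[[1]]
  best <- Inf
  for (cand in c(oracle_rotations(b), oracle_rotations(oracle_revcomp(b)))) {
    vb <- strsplit(cand, "", fixed = TRUE)[[1]]
    best <- min(best, sum(va != vb))
  }
  best
}

# --- rearrangement oracle ----------------------------------------------------

oracle_adjacencies <- function(perm) {
  keys <- character()
  for (ch in perm$chromosomes) {
    ext <- c(0L, ch, 0L)
    for (i in seq_len(length(ext) - 1L)) {
      a <- ext[i]; b <- ext[i + 1L]
      k1 <- paste(a, b); k2 <- paste(-b, -a)
      keys <- c(keys, min(k1, k2))
    }
  }
  keys
}

oracle_breakpoints <- function(source, target) {
  length(setdiff(oracle_adjacencies(source), oracle_adjacencies(target)))
}

# --- block-count oracle from a truth log -------------------------------------

# maximal-colinear-run counts per chromosome of A, derived directly from the
# ancestor's and the log's final gene orders (restricted to shared genes,
# with ordinal positions over all features)
truth_run_lengths <- function(ord_a, ord_b, orthologs, max_gap = 0) {
  map_b <- setNames(orthologs$gene_b, orthologs$gene_a)
  shared_a <- ord_a[ord_a$gene_id %in% names(map_b), , drop = FALSE]
  shared_a <- shared_a[map_b[shared_a$gene_id] %in% ord_b$gene_id, ,
                       drop = FALSE]
  bi <- match(map_b[shared_a$gene_id], ord_b$gene_id)
  anch <- data.frame(chrom_a = shared_a$chrom, index_a = shared_a$index,
                     chrom_b = ord_b$chrom[bi], index_b = ord_b$index[bi],
                     stringsAsFactors = FALSE)
  part <- oracle_partition(anch, max_gap)
  chrom_of_run <- vapply(part$runs, function(r) part$anchors$chrom_a[r[1]],
                         character(1))
  lens <- vapply(part$runs, length, integer(1))
  split(lens, chrom_of_run)
}
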