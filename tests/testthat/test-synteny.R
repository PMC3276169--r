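test_that("anchors mirror the ortholog map with ordinal indices", {
  ga <- toy_genome("A", list(c("a1", "a2", "a3")))
  gb <- toy_genome("B", list(c("b1", "b2", "b3")))
  orth <- identity_orthologs(c("a1", "a2", "a3"), c("b1", "b2", "b3"))
  anch <- build_anchors(ga, gb, orth)
  expect_equal(nrow(anch), 3)
  expect_equal(anch$index_a, 0:2)
  expect_equal(anch$index_b, 0:2)
  expect_true(all(anch$orientation == "same"))

  expect_equal(nrow(build_anchors(ga, gb, orth[0, ])), 0)
  bad <- rbind(orth, data.frame(gene_a = "a1", gene_b = "b3", identity = 50))
  expect_error(build_anchors(ga, gb, bad), "one-to-one")
})

test_that("a perfectly colinear chromosome pair yields exactly one block", {
  ids <- paste0("g", 1:10)
  ga <- toy_genome("A", list(ids))
  gb <- toy_genome("B", list(paste0("h", 1:10)))
  orth <- identity_orthologs(ids, paste0("h", 1:10))
  cb <- chain_blocks(build_anchors(ga, gb, orth), max_gap_genes = 0)
  expect_equal(nrow(cb$blocks), 1)
  expect_equal(cb$blocks$n_anchors, 10)
  expect_equal(nrow(cb$singletons), 0)
})

test_that("an internal inversion of 3 genes splits a chromosome into 3 blocks", {
  ids <- paste0("g", 1:10)
  ga <- toy_genome("A", list(ids))
  # B carries g4..g6 inverted: order g1 g2 g3 g6 g5 g4 g7..g10
  order_b <- c("g1", "g2", "g3", "g6", "g5", "g4", paste0("g", 7:10))
  gb <- toy_genome("B", list(order_b))
  cb <- chain_blocks(build_anchors(ga, gb, identity_orthologs(ids)),
                     max_gap_genes = 0)
  expect_equal(nrow(cb$blocks), 3)
  expect_equal(sort(cb$blocks$orientation), c("inverted", "same", "same"))
  expect_equal(nrow(cb$singletons), 0)
})

test_that("chaining rejects min_anchors below 2", {
  expect_error(chain_blocks(random_anchor_set(5), min_anchors = 1), ">= 2")
})

test_that("chain_blocks matches the brute-force maximal-run oracle", {
  set.seed(42)
  for (trial in 1:200) {
    n <- sample(2:30, 1)
    gap <- sample(0:3, 1)
    anch <- random_anchor_set(n, n_chrom_a = sample(1:3, 1),
                              n_chrom_b = sample(1:3, 1))
    cb <- chain_blocks(anch, max_gap_genes = gap)
    part <- oracle_partition(anch, gap)
    lens <- vapply(part$runs, length, integer(1))
    expect_equal(nrow(cb$blocks), sum(lens >= 2))
    expect_equal(nrow(cb$singletons), sum(lens == 1))
    # partition property: every anchor in exactly one block or singleton
    n_assigned <- sum(cb$blocks$n_anchors) + nrow(cb$singletons)
    expect_equal(n_assigned, n)
  }
})

test_that("reversing every chromosome of B flips orientations only", {
  set.seed(7)
  cfg <- sim_config(seed = 7, n_chromosomes = 3, genes_per_chromosome = 15,
                    n_inversions = 2, n_reciprocal_translocations = 1,
                    n_telomeric_translocations = 0,
                    n_centromere_loss_events = 0, gene_loss_rate = 0,
                    tandem_dup_count = 0)
  anc <- simulate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  anch <- build_anchors(anc$genome, ev$genome, ev$orthologs)
  cb <- chain_blocks(anch, max_gap_genes = 1)

  # reverse B: flip index and strand per chromosome
  anch_rev <- anch
  for (cb_id in unique(anch$chrom_b)) {
    rows <- anch$chrom_b == cb_id
    anch_rev$index_b[rows] <- max(anch$index_b[rows]) - anch$index_b[rows]
    anch_rev$strand_b[rows] <- ifelse(anch$strand_b[rows] == "+", "-", "+")
    anch_rev$start_b[rows] <- -anch$end_b[rows]
    anch_rev$end_b[rows] <- -anch$start_b[rows]
  }
  anch_rev$orientation <- ifelse(anch_rev$strand_a == anch_rev$strand_b,
                                 "same", "inverted")
  cb_rev <- chain_blocks(anch_rev, max_gap_genes = 1)
  expect_equal(nrow(cb_rev$blocks), nrow(cb$blocks))
  expect_equal(sort(cb_rev$blocks$length_a), sort(cb$blocks$length_a))
  m <- match(cb$blocks$start_a, cb_rev$blocks$start_a)
  expect_false(any(is.na(m)))
  expect_true(all(cb$blocks$orientation !=
                    cb_rev$blocks$orientation[m]))
})

test_that("block statistics: totals, means, and the half-genome number", {
  # single block covering half the genome
  ga <- toy_genome("A", list(paste0("g", 1:8)))
  genome_bp <- genome_statistics(ga)$total_bp
  blocks <- data.frame(block_id = 1L, chrom_a = "c1", chrom_b = "x",
                       start_a = 0L, end_a = as.integer(genome_bp / 2),
                       length_a = as.integer(genome_bp / 2),
                       start_b = 0L, end_b = 1L, index_b_min = 0L,
                       orientation = "same", n_anchors = 2L,
                       anchor_rows = I(list(1:2)))
  bs <- block_statistics(blocks, ga)
  expect_equal(bs$half_genome_blocks, 1L)
  expect_equal(bs$total, 1L)

  # randomized block set: H matches exhaustive subset search
  set.seed(99)
  for (trial in 1:5) {
    n <- 12
    lens <- sample(1000:30000, n)
    blocks <- data.frame(block_id = seq_len(n), chrom_a = "c1", chrom_b = "x",
                         start_a = cumsum(c(0, head(lens, -1))),
                         end_a = cumsum(lens), length_a = lens,
                         start_b = 0L, end_b = 1L, index_b_min = 0L,
                         orientation = "same", n_anchors = 2L,
                         anchor_rows = I(as.list(seq_len(n))))
    bs <- block_statistics(blocks, ga)
    half <- genome_statistics(ga)$total_bp / 2
    h_brute <- NA
    for (k in seq_len(n)) {
      best <- max(combn(lens, k, sum))
      if (best >= half) { h_brute <- k; break }
    }
    expect_equal(bs$half_genome_blocks, h_brute)
    expect_equal(bs$mean_block_kb, round(mean(lens) / 1000, 1))
  }
})

test_that("locus neighborhoods report conserved, missing, and truncated flanks", {
  ids <- paste0("g", 1:12)
  ga <- toy_genome("A", list(ids))
  gb <- toy_genome("B", list(paste0("h", 1:12)))
  orth <- identity_orthologs(ids, paste0("h", 1:12))
  nb <- compare_locus_neighborhood(ga, gb, "g6", flank_k = 3, orth)
  expect_equal(nb$n_missing, 0)
  expect_equal(nb$n_rearranged, 0)
  expect_false(nb$truncated_left)

  # B lacks three flank genes
  keep <- setdiff(ids, c("g3", "g4", "g8"))
  gb2 <- toy_genome("B2", list(paste0("h", match(keep, ids))))
  orth2 <- identity_orthologs(keep, paste0("h", match(keep, ids)))
  nb2 <- compare_locus_neighborhood(ga, gb2, "g6", flank_k = 3, orth2)
  expect_equal(nb2$n_missing, 3)
  missing <- nb2$report$gene_a[nb2$report$status == "missing_in_b"]
  expect_setequal(missing, c("g3", "g4", "g8"))

  # focal gene at the chromosome end truncates, does not fail
  nb3 <- compare_locus_neighborhood(ga, gb, "g1", flank_k = 3, orth)
  expect_true(nb3$truncated_left)
})

test_that("centromere-based chromosome assignment finds the orphan", {
  # identical genomes: identity mapping through shared blocks
  cfg <- sim_config(seed = 21, n_chromosomes = 3, genes_per_chromosome = 12,
                    n_inversions = 0, n_reciprocal_translocations = 0,
                    n_telomeric_translocations = 0,
                    n_centromere_loss_events = 0, gene_loss_rate = 0,
                    tandem_dup_count = 0, intergenic_scale = 1)
  anc <- simulate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  anch <- build_anchors(anc$genome, ev$genome, ev$orthologs)
  cb <- chain_blocks(anch)
  cen_a <- anc$genome$centromeres
  cen_b <- ev$genome$centromeres
  res <- assign_centromeric_chromosome_ids(anc$genome, ev$genome, cb$blocks,
                                           cen_a, cen_b)
  expect_equal(nrow(res$assignments), 3)
  expect_equal(res$assignments$chrom_a, res$assignments$chrom_b)
  expect_length(res$orphans_a, 0)
})
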