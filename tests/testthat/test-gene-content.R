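test_that("presence/absence partitions both gene sets", {
  # toy: 10 + 10 genes, 7 mapped, 2 A-only with outgroup, 1 A orphan
  ga <- toy_genome("A", list(paste0("a", 1:10)))
  gb <- toy_genome("B", list(paste0("b", 1:10)))
  orth <- identity_orthologs(paste0("a", 1:7), paste0("b", 1:7))
  outg <- c("a8", "a9", paste0("b", 8:10))
  pa <- classify_presence_absence(ga, gb, orth, outg)
  expect_equal(pa$shared, 7)
  expect_setequal(pa$a_specific_with_outgroup, c("a8", "a9"))
  expect_equal(pa$a_orphans, "a10")
  expect_length(pa$b_specific_with_outgroup, 3)
  expect_length(pa$b_orphans, 0)
  # category sizes sum to the gene counts
  expect_equal(pa$shared + length(pa$a_specific_with_outgroup) +
                 length(pa$a_orphans), pa$n_genes_a)

  # all genes mapped: both specific lists empty
  pa2 <- classify_presence_absence(ga, gb,
                                   identity_orthologs(paste0("a", 1:10),
                                                      paste0("b", 1:10)))
  expect_length(pa2$a_specific_with_outgroup, 0)
  expect_length(pa2$a_orphans, 0)
})

test_that("a simulated multi-gene loss shows up as A-specific genes", {
  cfg <- sim_config(seed = 41, n_chromosomes = 2, genes_per_chromosome = 20,
                    n_inversions = 1, n_reciprocal_translocations = 0,
                    n_telomeric_translocations = 0,
                    n_centromere_loss_events = 0, gene_loss_rate = 0.1,
                    tandem_dup_count = 0)
  anc <- simulate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  lost <- ev$log$lost_genes
  expect_gt(length(lost), 0)
  pa <- classify_presence_absence(anc$genome, ev$genome, ev$orthologs,
                                  outgroup_homologs = lost)
  expect_setequal(pa$a_specific_with_outgroup, lost)
  expect_length(pa$a_orphans, 0)
})

test_that("tandem duplication detection respects adjacency and identity", {
  # two adjacent paralogs -> one locus of size 2
  g <- toy_genome("G", list(paste0("g", 1:6)))
  pp <- data.frame(gene_a = "g2", gene_b = "g3", identity = 85)
  td <- find_tandem_duplications(g, pp)
  expect_equal(nrow(td), 1)
  expect_equal(td$n_genes, 1 + 1)
  expect_equal(td$members[[1]], c("g2", "g3"))

  # triplication -> single locus of size 3
  pp3 <- data.frame(gene_a = c("g2", "g3"), gene_b = c("g3", "g4"),
                    identity = 85)
  td3 <- find_tandem_duplications(g, pp3)
  expect_equal(nrow(td3), 1)
  expect_equal(td3$n_genes, 3)

  # separation beyond max_intervening: no locus
  far <- data.frame(gene_a = "g1", gene_b = "g5", identity = 85)
  expect_equal(nrow(find_tandem_duplications(g, far, max_intervening = 1)), 0)

  # identity below the threshold: no locus
  weak <- data.frame(gene_a = "g2", gene_b = "g3", identity = 10)
  expect_equal(nrow(find_tandem_duplications(g, weak)), 0)
})

test_that("conserved duplications require two orthologous members in one B locus", {
  ga <- toy_genome("A", list(paste0("a", 1:8)))
  gb <- toy_genome("B", list(paste0("b", 1:8)))
  pa <- data.frame(gene_a = c("a2", "a5"), gene_b = c("a3", "a6"),
                   identity = 85)
  pb <- data.frame(gene_a = "b2", gene_b = "b3", identity = 85)
  dups_a <- find_tandem_duplications(ga, pa)
  dups_b <- find_tandem_duplications(gb, pb)
  expect_equal(nrow(dups_a), 2)
  orth <- identity_orthologs(paste0("a", 1:8), paste0("b", 1:8))
  cons <- conserved_duplications(dups_a, dups_b, orth)
  expect_equal(nrow(cons), 1)           # only the a2/a3 locus survives in B
  expect_equal(cons$members[[1]], c("a2", "a3"))
  # empty ortholog map: nothing conserved
  expect_equal(nrow(conserved_duplications(dups_a, dups_b, orth[0, ])), 0)
})

test_that("identity follows the fixed global-alignment scoring", {
  prots <- c(p1 = "ACDEFG", p2 = "ACDEFA", p3 = "ACDEFG")
  pairs <- data.frame(gene_a = c("p1", "p1"), gene_b = c("p3", "p2"))
  d <- identity_distribution(pairs, prots)
  expect_equal(d$identities$identity[1], 100)
  expect_equal(d$identities$identity[2], 100 * 5 / 6, tolerance = 1e-10)
  # symmetry in the two sequences
  expect_equal(eremosyn:::protein_identity_pct("ACDEFA", "ACDEFG"),
               eremosyn:::protein_identity_pct("ACDEFG", "ACDEFA"))
  # mean is invariant under pair order
  d_rev <- identity_distribution(pairs[2:1, ], prots)
  expect_equal(d$mean_identity, d_rev$mean_identity)
  # missing sequences are skipped with a warning
  expect_warning(identity_distribution(
    data.frame(gene_a = "p1", gene_b = "absent"), prots), "skipping")
})

test_that("simulated divergence lands near the configured identity target", {
  set.seed(55)
  n <- 60
  rate <- 0.4
  prots <- character()
  pairs <- data.frame(gene_a = paste0("x", 1:n), gene_b = paste0("y", 1:n))
  for (i in 1:n) {
    a <- eremosyn:::random_protein(300)
    prots[[paste0("x", i)]] <- a
    prots[[paste0("y", i)]] <- eremosyn:::mutate_protein(a, rate)
  }
  d <- identity_distribution(pairs, prots)
  expect_equal(d$mean_identity, 100 * (1 - rate), tolerance = 0.04)
  expect_equal(sum(d$histogram$count), n)
})

test_that("intron validation implements the GT..TACTAAC..AG rule", {
  ok <- validate_intron("GTAAGTCCCTACTAACGGCAG")
  expect_true(ok$valid)
  bad <- validate_intron("AAAA")
  expect_false(bad$valid)
  expect_length(bad$violations, 3)
  nobranch <- validate_intron("GTAAGTCCCCCCAG")
  expect_false(nobranch$valid)
  expect_length(nobranch$violations, 1)
  expect_match(nobranch$violations, "TACTAAC")
  # branch motif too close to the acceptor does not count
  late <- validate_intron("GTAAGTACTAACAG")
  expect_false(late$valid)
  # simulator introns obey the rule
  cfg <- sim_config(seed = 61, n_chromosomes = 2, genes_per_chromosome = 30,
                    intron_rate = 0.5)
  anc <- simulate_ancestor(cfg)
  ft <- genome_features(anc$genome)
  n_checked <- 0
  for (i in seq_len(nrow(ft))) {
    m <- ft$introns[[i]]
    if (is.null(m) || nrow(m) == 0) next
    seqs <- anc$genome$chromosomes[[ft$chrom[i]]]$sequence
    iseq <- substr(seqs, m[1, "start"] + 1, m[1, "end"])
    expect_true(validate_intron(iseq)$valid)
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 5)
})
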