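test_that("configs validate their counts and rates", {
  expect_error(sim_config(n_inversions = -1), "counts")
  expect_error(sim_config(gene_loss_rate = 1.5), "rates")
  expect_error(sim_config(n_chromosomes = 0), "at least one")
})

test_that("the ancestor has the configured shape and planted features", {
  cfg <- sim_config(seed = 1, n_chromosomes = 8, genes_per_chromosome = 60)
  anc <- simulate_ancestor(cfg)
  expect_length(anc$genome$chromosomes, 8)
  st <- genome_statistics(anc$genome)
  expect_equal(st$n_genes, 8 * 60 + cfg$tandem_dup_count * 0)  # no dups yet
  expect_equal(nrow(anc$genome$centromeres), 8)
  expect_equal(nrow(anc$genome$telomeres), 16)
  expect_length(anc$proteins, 480)
  # planted troughs are at least the configured width
  expect_true(all(anc$genome$centromeres$end - anc$genome$centromeres$start >=
                    cfg$centromere_trough_bp))
})

test_that("runs are byte-identical at a fixed seed", {
  cfg <- sim_config(seed = 17, n_chromosomes = 2, genes_per_chromosome = 10)
  a1 <- simulate_ancestor(cfg); a2 <- simulate_ancestor(cfg)
  expect_identical(a1, a2)
  e1 <- evolve(a1, cfg); e2 <- evolve(a2, cfg)
  expect_identical(e1$genome, e2$genome)
  expect_identical(e1$orthologs, e2$orthologs)
  expect_identical(e1$proteins, e2$proteins)
})

test_that("a zero-event config returns the ancestor unchanged", {
  cfg <- sim_config(seed = 23, n_chromosomes = 2, genes_per_chromosome = 8,
                    n_inversions = 0, n_reciprocal_translocations = 0,
                    n_telomeric_translocations = 0,
                    n_centromere_loss_events = 0, gene_loss_rate = 0,
                    tandem_dup_count = 0, intergenic_scale = 1,
                    protein_mutation_rate = 0)
  anc <- simulate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  for (cid in names(anc$genome$chromosomes)) {
    expect_identical(ev$genome$chromosomes[[cid]]$sequence,
                     anc$genome$chromosomes[[cid]]$sequence)
  }
  expect_equal(nrow(ev$orthologs), length(anc$proteins))
  expect_true(all(ev$orthologs$identity == 100))
  # identity map up to the genome prefix
  expect_identical(sub("^desc", "anc", ev$orthologs$gene_b),
                   ev$orthologs$gene_a)
})

test_that("gene conservation follows the log exactly", {
  cfg <- sim_config(seed = 29, n_chromosomes = 3, genes_per_chromosome = 20,
                    gene_loss_rate = 0.08, tandem_dup_count = 2)
  anc <- simulate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  n_anc <- sum(genome_features(anc$genome)$feature_class == "protein_coding")
  n_desc <- sum(genome_features(ev$genome)$feature_class == "protein_coding")
  expect_equal(n_desc,
               n_anc - length(ev$log$lost_genes) +
                 length(ev$log$duplicated_genes))
  # ortholog map links exactly the surviving originals
  expect_equal(nrow(ev$orthologs),
               length(anc$proteins) - length(ev$log$lost_genes))
})

test_that("replaying the log reproduces the descendant exactly", {
  cfg <- sim_config(seed = 37, n_chromosomes = 4, genes_per_chromosome = 15)
  anc <- simulate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  rep <- replay_log(anc, ev$log, cfg)
  expect_identical(rep$chromosomes, ev$genome$chromosomes)
})

test_that("a centromere-loss event removes one chromosome but no genes", {
  cfg <- sim_config(seed = 43, n_chromosomes = 8, genes_per_chromosome = 12,
                    n_inversions = 0, n_reciprocal_translocations = 0,
                    n_telomeric_translocations = 0,
                    n_centromere_loss_events = 1, gene_loss_rate = 0,
                    tandem_dup_count = 0)
  anc <- simulate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  expect_length(ev$genome$chromosomes, 7)
  expect_equal(sum(genome_features(ev$genome)$feature_class == "protein_coding"),
               sum(genome_features(anc$genome)$feature_class == "protein_coding"))
  expect_equal(nrow(ev$genome$centromeres), 7)
  lost <- Filter(function(e) e$type == "centromere_loss", ev$log$events)
  expect_length(lost, 1)
})

test_that("gene loss counts follow the configured binomial rate", {
  cfg <- sim_config(seed = 47, n_chromosomes = 8, genes_per_chromosome = 60,
                    gene_loss_rate = 0.03)
  anc <- simulate_ancestor(cfg)
  ev <- evolve(anc, cfg)
  n <- length(anc$proteins)
  expected <- n * 0.03
  # within 4 sd of the binomial expectation
  expect_lt(abs(length(ev$log$lost_genes) - expected),
            4 * sqrt(n * 0.03 * 0.97) + 1)
})

test_that("telomere arrays at every end recover the configured unit", {
  cfg <- sim_config(seed = 53, n_chromosomes = 3, genes_per_chromosome = 10)
  anc <- simulate_ancestor(cfg)
  tel <- genome_telomeres(anc$genome, scan_bp = 1000)
  expect_equal(nrow(tel), 6)            # both ends of all chromosomes
  expect_true(all(tel$period == nchar(cfg$telomere_unit)))
  expect_true(all(tel$unit == canonical_repeat_unit(cfg$telomere_unit)))
})
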