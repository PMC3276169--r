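test_that("read/write round trip is lossless for simulator output", {
  cfg <- sim_config(seed = 11, n_chromosomes = 2, genes_per_chromosome = 8)
  anc <- simulate_ancestor(cfg)
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genome(anc$genome, fa, tsv)
  g2 <- read_genome(fa, tsv, id = anc$genome$id)
  expect_identical(names(g2$chromosomes), names(anc$genome$chromosomes))
  for (cid in names(g2$chromosomes)) {
    expect_identical(g2$chromosomes[[cid]]$sequence,
                     anc$genome$chromosomes[[cid]]$sequence)
    f1 <- anc$genome$chromosomes[[cid]]$features
    f2 <- g2$chromosomes[[cid]]$features
    rownames(f1) <- rownames(f2) <- NULL
    expect_equal(f2[c("gene_id", "start", "end", "strand", "feature_class")],
                 f1[c("gene_id", "start", "end", "strand", "feature_class")])
    expect_identical(lapply(f2$introns, unname), lapply(f1$introns, unname))
  }
})

test_that("reading rejects unknown chromosomes and duplicate gene ids", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGTACGTACGT"), fa)
  ann <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tstrand\tclass\tgene_id",
               "c2\t0\t4\t+\tprotein_coding\tg1"), ann)
  expect_error(read_genome(fa, ann), "c2")
  writeLines(c("chrom\tstart\tend\tstrand\tclass\tgene_id",
               "c1\t0\t4\t+\tprotein_coding\tg1",
               "c1\t6\t10\t+\tprotein_coding\tg1"), ann)
  expect_error(read_genome(fa, ann), "duplicate gene ids")
})

test_that("unknown feature classes map to 'other' and features sort by start", {
  feats <- data.frame(gene_id = c("g2", "g1"), start = c(10L, 2L),
                      end = c(14L, 6L), strand = c("+", "-"),
                      feature_class = c("pseudogene", "protein_coding"),
                      introns = I(list(eremosyn:::intron_matrix(),
                                       eremosyn:::intron_matrix())),
                      stringsAsFactors = FALSE)
  ch <- new_chromosome("c1", length = 20L, features = feats)
  expect_identical(ch$features$gene_id, c("g1", "g2"))
  expect_identical(ch$features$feature_class, c("protein_coding", "other"))
})

test_that("genome statistics follow the comparison-table arithmetic", {
  # single gene spanning a whole single chromosome
  g <- new_genome("t", list(new_chromosome("c1", strrep("ACGT", 250),
    features = data.frame(gene_id = "g1", start = 0L, end = 1000L,
                          strand = "+", feature_class = "protein_coding",
                          introns = I(list(eremosyn:::intron_matrix())),
                          stringsAsFactors = FALSE))))
  st <- genome_statistics(g)
  expect_equal(st$coding_fraction, 100)
  expect_equal(st$gene_density_kb, round(1000 / 1000 / 1, 2))
  expect_equal(st$gc_content, 50)

  # rDNA-class spans are excluded from genome size; introns from coding bp
  feats <- data.frame(gene_id = c("g1", "r1"), start = c(100L, 2000L),
                      end = c(1100L, 2600L), strand = c("+", "+"),
                      feature_class = c("protein_coding", "rDNA"),
                      introns = I(list(eremosyn:::intron_matrix(300L, 400L),
                                       eremosyn:::intron_matrix())),
                      stringsAsFactors = FALSE)
  g2 <- new_genome("t2", list(new_chromosome("c1", length = 4000L,
                                             features = feats)))
  st2 <- genome_statistics(g2)
  expect_equal(st2$total_bp, 4000 - 600)
  expect_equal(st2$coding_bp, 1000 - 100)
  expect_equal(st2$n_introns, 1L)
  expect_true(is.na(st2$gc_content))
})

test_that("statistics are invariant under chromosome reordering", {
  cfg <- sim_config(seed = 5, n_chromosomes = 3, genes_per_chromosome = 6)
  g <- simulate_ancestor(cfg)$genome
  g_rev <- new_genome(g$id, rev(g$chromosomes))
  s1 <- genome_statistics(g)
  s2 <- genome_statistics(g_rev)
  s1$id <- s2$id <- NULL
  expect_equal(s1, s2)
})

test_that("density is undefined at zero genes and positive otherwise", {
  g <- new_genome("t", list(new_chromosome("c1", length = 1000L)))
  st <- genome_statistics(g)
  expect_true(is.na(st$gene_density_kb))
  expect_equal(st$n_genes, 0L)
  expect_true(gene_density_kb(9671, 4711) > 0)
})

test_that("GFF3 annotations are converted from 1-based closed coordinates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", strrep("ACGT", 30)), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\ttest\tgene\t11\t40\t.\t+\t.\tID=g1",
               "c1\ttest\ttRNA\t61\t80\t.\t-\t.\tID=t1"), gff)
  g <- read_genome(fa, gff)
  ft <- genome_features(g)
  expect_equal(ft$start, c(10L, 60L))
  expect_equal(ft$end, c(40L, 80L))
  expect_identical(ft$feature_class, c("protein_coding", "tRNA"))
})
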