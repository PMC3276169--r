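PRINTED_UNIT <- "CACACCGCTGAGAGACCCGTACAC"

test_that("a clean tandem array at the right end is recovered at period 24", {
  set.seed(3)
  lead <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  chrom <- paste0(lead, strrep(PRINTED_UNIT, 20))
  r <- infer_telomere_repeat(chrom, "right", scan_bp = 1000)
  expect_equal(r$period, 24L)
  expect_equal(r$copy_number, 20)
  expect_equal(r$unit, canonical_repeat_unit(PRINTED_UNIT))
})

test_that("terminal poly-A has period 1", {
  set.seed(4)
  lead <- paste(sample(c("C", "G"), 300, TRUE), collapse = "")
  r <- infer_telomere_repeat(paste0(lead, strrep("A", 100)), "right", 200)
  expect_equal(r$period, 1L)
  expect_equal(r$copy_number, 100)
})

test_that("degenerate arrays are found and the period is minimal", {
  set.seed(5)
  unit <- paste(sample(c("A", "C", "G", "T"), 17, TRUE), collapse = "")
  copies <- strrep(unit, 6)
  v <- strsplit(copies, "", fixed = TRUE)[[1]]
  v[40] <- setdiff(c("A", "C", "G", "T"), v[40])[1]   # one substitution
  chrom <- paste0(strrep("G", 400), paste(v, collapse = ""))
  r <- infer_telomere_repeat(chrom, "right", scan_bp = 300)
  expect_equal(r$period, 17L)
  # no divisor of the period also generates the array
  divs <- setdiff(which(17 %% seq_len(16) == 0), 17)
  for (d in divs) {
    expect_false(substr(chrom, nchar(chrom) - 2 * d + 1,
                        nchar(chrom) - d) ==
                   substr(chrom, nchar(chrom) - d + 1, nchar(chrom)) &&
                   d < 17)
  }
  expect_null(infer_telomere_repeat(paste(sample(c("A", "C", "G", "T"), 600,
                                                 TRUE), collapse = ""),
                                    "right", 400))
})

test_that("left ends and reverse-complemented chromosomes give the same unit", {
  set.seed(6)
  tail_seq <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  chrom <- paste0(strrep(PRINTED_UNIT, 12), tail_seq)
  rl <- infer_telomere_repeat(chrom, "left", 600)
  expect_equal(rl$period, 24L)
  expect_equal(rl$unit, canonical_repeat_unit(PRINTED_UNIT))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chrom)))
  rr <- infer_telomere_repeat(rc, "right", 600)
  expect_equal(rr$period, rl$period)
  expect_equal(rr$unit, rl$unit)
})

test_that("repeat distance equals the exhaustive rotation/strand minimum", {
  expect_equal(repeat_distance(PRINTED_UNIT, PRINTED_UNIT), 0)
  mut <- PRINTED_UNIT
  substr(mut, 5, 5) <- "T"
  expect_equal(repeat_distance(PRINTED_UNIT, mut), 1)
  expect_error(repeat_distance("ACGT", "ACGTA"), "unequal")
  set.seed(8)
  for (trial in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
    expect_equal(repeat_distance(a, b), oracle_repeat_distance(a, b))
  }
})

test_that("rotated copies of one unit are identified as identical", {
  rot <- paste0(substr(PRINTED_UNIT, 7, 24), substr(PRINTED_UNIT, 1, 6))
  expect_equal(repeat_distance(PRINTED_UNIT, rot), 0)
  expect_equal(canonical_repeat_unit(rot), canonical_repeat_unit(PRINTED_UNIT))
})

test_that("planted CDE centromeres are found with the right CDEII length", {
  set.seed(9)
  cfg <- cde_config()
  cdeI <- eremosyn:::resolve_iupac(cfg$cdeI)
  cdeIII <- eremosyn:::resolve_iupac(cfg$cdeIII)
  spacer <- eremosyn:::random_at_rich(160, 0.9)
  bg <- function(n) paste(sample(c("G", "C"), n, TRUE), collapse = "")
  chrom <- paste0(bg(3000), cdeI, spacer, cdeIII, bg(3000))
  calls <- find_centromeres(chrom)
  expect_equal(sum(calls$primary), 1)
  best <- calls[calls$primary, ]
  expect_equal(best$orientation, "forward")
  expect_equal(best$cdeII_end - best$cdeII_start, 160)
  expect_equal(best$cdeI_start, 3000)

  # pure GC chromosome: nothing to find
  expect_equal(nrow(find_centromeres(bg(5000))), 0)

  # reverse orientation: same span, opposite strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chrom)))
  calls_rc <- find_centromeres(rc)
  best_rc <- calls_rc[calls_rc$primary, ]
  expect_equal(best_rc$orientation, "reverse")
  expect_equal(best_rc$end - best_rc$start, best$end - best$start)
  expect_equal(best_rc$start, nchar(chrom) - best$end)
})

test_that("centromere calls are translation-invariant", {
  set.seed(10)
  cfg <- cde_config()
  chrom <- paste0(
    paste(sample(c("G", "C"), 2000, TRUE), collapse = ""),
    eremosyn:::resolve_iupac(cfg$cdeI),
    eremosyn:::random_at_rich(150, 0.9),
    eremosyn:::resolve_iupac(cfg$cdeIII),
    paste(sample(c("G", "C"), 2000, TRUE), collapse = ""))
  shift <- paste(sample(c("G", "C"), 500, TRUE), collapse = "")
  c1 <- find_centromeres(chrom)
  c2 <- find_centromeres(paste0(shift, chrom))
  expect_equal(c2[c2$primary, ]$start, c1[c1$primary, ]$start + 500)
  expect_equal(c2[c2$primary, ]$end, c1[c1$primary, ]$end + 500)
})

test_that("simulator genomes yield one centromere call per chromosome at the planted CDE", {
  cfg <- sim_config(seed = 12, n_chromosomes = 3, genes_per_chromosome = 10)
  anc <- simulate_ancestor(cfg)
  calls <- genome_centromeres(anc$genome)
  expect_equal(nrow(calls), 3)
  m <- match(calls$chrom, anc$genome$cde$chrom)
  expect_equal(calls$start, anc$genome$cde$start[m])
  expect_equal(calls$end, anc$genome$cde$end[m])
})
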