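# Orchestration: run the full comparison pipeline and emit report tables.

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full genome-comparison pipeline
#'
#' Executes statistics, synteny (against genome B and, optionally, an
#' ancestral gene order), GC landscape, telomere/centromere detection, and
#' gene-content stages, and assembles a comparison report shaped like the
#' genome-statistics and block-count tables of comparative genome papers.
#'
#' @param genome_a,genome_b `genome` objects.
#' @param orthologs One-to-one ortholog table `gene_a, gene_b, identity`.
#' @param ancestor Optional `ancestral_order` plus ortholog table, as
#'   `list(order = , orthologs = )`.
#' @param proteins Optional named character vector of protein sequences for
#'   the identity distribution.
#' @param max_gap_genes,min_anchors Synteny chaining parameters.
#' @param window_bp,step_bp,z_threshold,min_trough_bp GC landscape
#'   parameters.
#' @param telomere_scan_bp Scan depth for telomere repeat inference.
#' @param cde CDE scan configuration from [cde_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `report.json`, `table1.tsv` (genome statistics), `table2.tsv`
#'   (per-chromosome block counts), `blocks.bed`, `troughs.bed`,
#'   `telomeres.bed`, and `centromeres.bed`.
#' @return List of class `comparison_report`.
#' @export
run_comparison <- function(genome_a, genome_b, orthologs, ancestor = NULL,
                           proteins = NULL, max_gap_genes = 3,
                           min_anchors = 2, window_bp = 5000, step_bp = 1000,
                           z_threshold = 1.0, min_trough_bp = 15000,
                           telomere_scan_bp = 5000, cde = cde_config(),
                           out_dir = NULL) {
  stats_a <- run_stage("statistics_a", genome_statistics(genome_a))
  stats_b <- run_stage("statistics_b", genome_statistics(genome_b))

  chain_b <- run_stage("synteny_vs_b", {
    anchors <- build_anchors(genome_a, genome_b, orthologs)
    chain_blocks(anchors, max_gap_genes, min_anchors)
  })
  blockstats_b <- run_stage("block_statistics_vs_b",
                            block_statistics(chain_b$blocks, genome_a))

  chain_anc <- NULL
  blockstats_anc <- NULL
  if (!is.null(ancestor)) {
    chain_anc <- run_stage("synteny_vs_ancestor", {
      anchors <- build_anchors(genome_a, ancestor$order, ancestor$orthologs)
      chain_blocks(anchors, max_gap_genes, min_anchors)
    })
    blockstats_anc <- run_stage("block_statistics_vs_ancestor",
                                block_statistics(chain_anc$blocks, genome_a))
  }

  has_seq <- function(g) !any(vapply(g$chromosomes,
                                     function(ch) is.na(ch$sequence),
                                     logical(1)))
  gc_a <- NULL; troughs_a <- NULL; telomeres_a <- NULL; centromeres_a <- NULL
  if (has_seq(genome_a)) {
    gc_a <- run_stage("gc_profiles", genome_gc_profiles(genome_a, window_bp,
                                                        step_bp))
    centromeres_a <- run_stage("centromeres", genome_centromeres(genome_a, cde))
    telomeres_a <- run_stage("telomeres",
                             genome_telomeres(genome_a, telomere_scan_bp))
    tel_spans <- NULL
    if (!is.null(genome_a$telomeres)) tel_spans <- genome_a$telomeres
    troughs_a <- run_stage("troughs", detect_troughs(
      gc_a, z_threshold = z_threshold, min_trough_bp = min_trough_bp,
      centromeres = centromeres_a, telomeres = tel_spans))
  }

  identity_dist <- NULL
  if (!is.null(proteins)) {
    identity_dist <- run_stage("identity_distribution",
                               identity_distribution(orthologs, proteins))
  }

  block_table <- data.frame(chrom = names(genome_a$chromosomes),
                            stringsAsFactors = FALSE)
  if (!is.null(blockstats_anc)) {
    block_table$blocks_vs_ancestor <-
      blockstats_anc$per_chromosome[block_table$chrom]
  }
  block_table$blocks_vs_b <- blockstats_b$per_chromosome[block_table$chrom]

  report <- structure(list(
    statistics = list(a = stats_a, b = stats_b),
    blocks_vs_b = chain_b$blocks,
    singletons_vs_b = chain_b$singletons,
    block_statistics_vs_b = blockstats_b,
    blocks_vs_ancestor = if (is.null(chain_anc)) NULL else chain_anc$blocks,
    block_statistics_vs_ancestor = blockstats_anc,
    block_table = block_table,
    gc_profiles = gc_a,
    troughs = troughs_a,
    telomeres = telomeres_a,
    centromeres = centromeres_a,
    identity_distribution = identity_dist,
    parameters = list(max_gap_genes = max_gap_genes,
                      min_anchors = min_anchors, window_bp = window_bp,
                      step_bp = step_bp, z_threshold = z_threshold,
                      min_trough_bp = min_trough_bp,
                      telomere_scan_bp = telomere_scan_bp)
  ), class = "comparison_report")
  if (!is.null(out_dir)) write_comparison_report(report, out_dir)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("== Comparison report ==\n\n")
  print(x$statistics$a); cat("\n")
  print(x$statistics$b); cat("\n")
  cat("Blocks vs B: ", x$block_statistics_vs_b$total, " (mean ",
      x$block_statistics_vs_b$mean_block_kb, " kb, half-genome ",
      x$block_statistics_vs_b$half_genome_blocks, ")\n", sep = "")
  if (!is.null(x$block_statistics_vs_ancestor)) {
    cat("Blocks vs ancestor: ", x$block_statistics_vs_ancestor$total, "\n",
        sep = "")
  }
  if (!is.null(x$troughs)) {
    cat("GC troughs: ", nrow(x$troughs), "\n", sep = "")
  }
  invisible(x)
}

stats_row <- function(s) {
  c(chromosomes = s$n_chromosomes,
    genome_kb = round(s$total_bp / 1000),
    genes = s$n_genes,
    gene_density_kb = s$gene_density_kb,
    coding_kb = round(s$coding_bp / 1000),
    coding_pct = s$coding_fraction,
    introns = s$n_introns,
    tRNAs = s$n_trna,
    gc_pct = if (is.na(s$gc_content)) NA else round(s$gc_content, 1))
}

#' Write a comparison report to disk
#'
#' @param report A `comparison_report`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the report.
#' @export
write_comparison_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  t1 <- data.frame(statistic = names(stats_row(report$statistics$a)),
                   a = unname(stats_row(report$statistics$a)),
                   b = unname(stats_row(report$statistics$b)))
  names(t1)[2:3] <- c(report$statistics$a$id, report$statistics$b$id)
  write.table(t1, p("table1.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  t2 <- report$block_table
  totals <- c(chrom = "Total",
              lapply(t2[-1], function(col) sum(col, na.rm = TRUE)))
  t2_out <- rbind(t2, as.data.frame(totals, stringsAsFactors = FALSE))
  write.table(t2_out, p("table2.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  write_blocks_bed(report$blocks_vs_b, p("blocks.bed"))
  if (!is.null(report$troughs)) write_bed(report$troughs, p("troughs.bed"))
  if (!is.null(report$telomeres) && nrow(report$telomeres)) {
    tel <- report$telomeres
    tel_bed <- data.frame(chrom = tel$chrom, start = 0, end = tel$period,
                          unit = tel$unit, end_label = tel$end,
                          copies = tel$copy_number)
    write_bed(tel_bed, p("telomeres.bed"))
  }
  if (!is.null(report$centromeres) && nrow(report$centromeres)) {
    write_bed(report$centromeres[, c("chrom", "start", "end", "orientation")],
              p("centromeres.bed"))
  }

  json <- list(
    statistics = list(a = unclass(report$statistics$a),
                      b = unclass(report$statistics$b)),
    block_totals = list(
      vs_b = report$block_statistics_vs_b$total,
      vs_ancestor = if (is.null(report$block_statistics_vs_ancestor)) NULL
      else report$block_statistics_vs_ancestor$total),
    mean_block_kb = list(
      vs_b = report$block_statistics_vs_b$mean_block_kb,
      vs_ancestor = if (is.null(report$block_statistics_vs_ancestor)) NULL
      else report$block_statistics_vs_ancestor$mean_block_kb),
    half_genome_blocks = list(
      vs_b = report$block_statistics_vs_b$half_genome_blocks,
      vs_ancestor = if (is.null(report$block_statistics_vs_ancestor)) NULL
      else report$block_statistics_vs_ancestor$half_genome_blocks),
    per_chromosome_blocks = report$block_table,
    n_troughs = if (is.null(report$troughs)) NULL else nrow(report$troughs),
    mean_identity = if (is.null(report$identity_distribution)) NULL
    else report$identity_distribution$mean_identity,
    parameters = report$parameters)
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
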