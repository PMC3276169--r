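#' @importFrom stats rbinom rexp rgamma rnorm runif sd ave
#' @importFrom utils head read.delim tail write.table
NULL

# ---- constructors -----------------------------------------------------------

FEATURE_CLASSES <- c("protein_coding", "tRNA", "rDNA", "transposon", "other")

#' Create an empty feature table
#'
#' Feature tables hold one row per gene-scale feature with 0-based, half-open
#' coordinates. The `introns` column is a list of integer matrices (columns
#' `start`, `end`), one row per intron, in the same coordinate system.
#'
#' @return A zero-row data frame with the canonical feature columns.
#' @export
empty_features <- function() {
  data.frame(
    gene_id = character(), start = integer(), end = integer(),
    strand = character(), feature_class = character(),
    introns = I(list()), stringsAsFactors = FALSE
  )
}

intron_matrix <- function(starts = integer(), ends = integer()) {
  m <- cbind(start = as.integer(starts), end = as.integer(ends))
  m
}

#' Construct a chromosome
#'
#' @param id Chromosome label.
#' @param sequence Nucleotide string over A,C,G,T,N, or `NA` if unavailable.
#' @param length Chromosome length in bp; inferred from `sequence` if absent.
#' @param features Feature table as produced by [empty_features()].
#' @return An object of class `chromosome`.
#' @export
new_chromosome <- function(id, sequence = NA_character_, length = NULL,
                           features = empty_features()) {
  if (is.null(length)) {
    if (is.na(sequence)) stop("chromosome '", id, "': need sequence or length")
    length <- nchar(sequence)
  }
  length <- as.integer(length)
  if (!is.na(sequence) && nchar(sequence) != length) {
    stop("chromosome '", id, "': length ", length,
         " does not match sequence length ", nchar(sequence))
  }
  features <- validate_features(features, id, length)
  structure(list(id = id, sequence = sequence, length = length,
                 features = features),
            class = "chromosome")
}

validate_features <- function(features, chrom_id, chrom_len) {
  if (nrow(features) == 0) return(features)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (any(features$start >= features$end)) {
    stop("chromosome '", chrom_id, "': feature with start >= end")
  }
  if (any(features$start < 0) || any(features$end > chrom_len)) {
    stop("chromosome '", chrom_id, "': feature span outside [0, length)")
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("chromosome '", chrom_id, "': strand must be '+' or '-'")
  }
  features$feature_class[!features$feature_class %in% FEATURE_CLASSES] <- "other"
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  for (i in seq_len(nrow(features))) {
    m <- features$introns[[i]]
    if (is.null(m) || nrow(m) == 0) next
    if (any(m[, "start"] <= features$start[i]) ||
        any(m[, "end"] >= features$end[i])) {
      stop("feature '", features$gene_id[i], "': intron outside gene span")
    }
    o <- order(m[, "start"])
    m <- m[o, , drop = FALSE]
    if (nrow(m) > 1 && any(m[-1, "start"] < m[-nrow(m), "end"])) {
      stop("feature '", features$gene_id[i], "': overlapping introns")
    }
    features$introns[[i]] <- m
  }
  features
}

#' Construct a genome
#'
#' @param id Short species label.
#' @param chromosomes List of [new_chromosome()] objects.
#' @return An object of class `genome`.
#' @export
new_genome <- function(id, chromosomes) {
  if (length(chromosomes) == 0) stop("genome needs at least one chromosome")
  ids <- vapply(chromosomes, function(ch) ch$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate chromosome ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(chromosomes) <- ids
  gid <- unlist(lapply(chromosomes, function(ch) ch$features$gene_id))
  if (anyDuplicated(gid)) {
    stop("duplicate gene ids within genome: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  }
  structure(list(id = id, chromosomes = chromosomes), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  nf <- sum(vapply(x$chromosomes, function(ch) nrow(ch$features), integer(1)))
  cat("<genome> ", x$id, ": ", length(x$chromosomes), " chromosomes, ",
      nf, " features\n", sep = "")
  invisible(x)
}

#' Combined feature table of a genome
#'
#' @param genome A `genome` object.
#' @return Data frame with a leading `chrom` column, features in chromosomal
#'   order within each chromosome.
#' @export
genome_features <- function(genome) {
  parts <- lapply(genome$chromosomes, function(ch) {
    if (nrow(ch$features) == 0) return(NULL)
    cbind(data.frame(chrom = ch$id, stringsAsFactors = FALSE), ch$features)
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts) == 0) {
    return(cbind(data.frame(chrom = character()), empty_features()))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Per-chromosome gene order with ordinal indices
#'
#' @param genome A `genome` or `ancestral_order` object.
#' @return Data frame `chrom, gene_id, strand, index, start, end` where
#'   `index` is the 0-based ordinal position of the feature on its chromosome
#'   (ancestral orders have `NA` bp coordinates).
#' @export
gene_order <- function(genome) {
  if (inherits(genome, "ancestral_order")) {
    ord <- genome$order
    idx <- stats::ave(seq_len(nrow(ord)), ord$chrom, FUN = seq_along) - 1L
    return(data.frame(chrom = ord$chrom, gene_id = ord$gene_id,
                      strand = ord$strand, index = as.integer(idx),
                      start = NA_integer_, end = NA_integer_,
                      stringsAsFactors = FALSE))
  }
  ft <- genome_features(genome)
  if (nrow(ft) == 0) {
    return(data.frame(chrom = character(), gene_id = character(),
                      strand = character(), index = integer(),
                      start = integer(), end = integer()))
  }
  idx <- stats::ave(seq_len(nrow(ft)), ft$chrom, FUN = seq_along) - 1L
  data.frame(chrom = ft$chrom, gene_id = ft$gene_id, strand = ft$strand,
             index = as.integer(idx), start = ft$start, end = ft$end,
             stringsAsFactors = FALSE)
}

# ---- readers / writers ------------------------------------------------------

parse_intron_field <- function(s) {
  if (is.na(s) || s == "" || s == ".") return(intron_matrix())
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  intron_matrix(vapply(parts, function(p) as.integer(p[1]), integer(1)),
                vapply(parts, function(p) as.integer(p[2]), integer(1)))
}

format_intron_field <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(".")
  paste(paste0(m[, "start"], "-", m[, "end"]), collapse = ";")
}

read_feature_tsv <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "class", "gene_id")
  if (!all(need %in% names(ann))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  introns <- if ("introns" %in% names(ann)) {
    lapply(ann$introns, parse_intron_field)
  } else {
    rep(list(intron_matrix()), nrow(ann))
  }
  data.frame(chrom = as.character(ann$chrom), gene_id = as.character(ann$gene_id),
             start = as.integer(ann$start), end = as.integer(ann$end),
             strand = as.character(ann$strand),
             feature_class = as.character(ann$class),
             introns = I(introns), stringsAsFactors = FALSE)
}

read_feature_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  keep_types <- c(gene = "protein_coding", mRNA = "protein_coding",
                  CDS = "protein_coding", tRNA = "tRNA", rRNA = "rDNA",
                  tRNA_gene = "tRNA", transposable_element = "transposon")
  type <- as.character(md$type)
  take <- type %in% c("gene", "tRNA", "rRNA", "tRNA_gene",
                      "transposable_element")
  gr <- gr[take]
  md <- S4Vectors::mcols(gr)
  cls <- unname(keep_types[as.character(md$type)])
  cls[is.na(cls)] <- "other"
  ids <- as.character(md$ID)
  if (all(is.na(ids)) && "Name" %in% names(md)) ids <- as.character(md$Name)
  # GFF3 is 1-based closed; convert to 0-based half-open
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             gene_id = ids,
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             feature_class = cls,
             introns = I(rep(list(intron_matrix()), length(gr))),
             stringsAsFactors = FALSE)
}

#' Read a genome from FASTA plus annotation
#'
#' Annotations may be a 7-column TSV (`chrom, start, end, strand, class,
#' gene_id[, introns]`; coordinates 0-based half-open) or a GFF3 file
#' (1-based closed, converted on read). Feature classes outside the known
#' vocabulary are mapped to `other`.
#'
#' @param fasta_path FASTA file of chromosome sequences.
#' @param annotation_path Annotation TSV or GFF3 (`.gff`/`.gff3`).
#' @param id Genome label; defaults to the FASTA basename.
#' @return A `genome` object with features sorted by start.
#' @export
read_genome <- function(fasta_path, annotation_path,
                        id = sub("\\.[^.]*$", "", basename(fasta_path))) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ft <- if (grepl("\\.gff3?$", annotation_path, ignore.case = TRUE)) {
    read_feature_gff3(annotation_path)
  } else {
    read_feature_tsv(annotation_path)
  }
  bad <- setdiff(unique(ft$chrom), names(seqs))
  if (length(bad) > 0) {
    stop("annotation references chromosome(s) absent from FASTA: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(ft$gene_id)) {
    stop("duplicate gene ids in annotation: ",
         paste(unique(ft$gene_id[duplicated(ft$gene_id)]), collapse = ", "))
  }
  chroms <- lapply(names(seqs), function(cid) {
    rows <- ft[ft$chrom == cid, setdiff(names(ft), "chrom"), drop = FALSE]
    new_chromosome(cid, as.character(seqs[[cid]]), features = rows)
  })
  new_genome(id, chroms)
}

#' Write a genome to FASTA plus annotation TSV
#'
#' Inverse of [read_genome()] for the TSV annotation format; round-trips all
#' simulator output losslessly.
#'
#' @param genome A `genome` object.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, `genome`.
#' @export
write_genome <- function(genome, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(genome$chromosomes, function(ch) {
      if (is.na(ch$sequence)) strrep("N", ch$length) else ch$sequence
    }, character(1)))
  Biostrings::writeXStringSet(seqs, fasta_path)
  ft <- genome_features(genome)
  out <- data.frame(chrom = ft$chrom, start = ft$start, end = ft$end,
                    strand = ft$strand, class = ft$feature_class,
                    gene_id = ft$gene_id,
                    introns = vapply(ft$introns, format_intron_field,
                                     character(1)),
                    stringsAsFactors = FALSE)
  write.table(out, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(genome)
}

#' Read a one-to-one ortholog table
#'
#' @param path TSV with columns `gene_a, gene_b, identity` (percent, 0-100).
#' @return Data frame of ortholog pairs.
#' @export
read_orthologs <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "identity")
  if (!all(need %in% names(x))) {
    stop("ortholog TSV must have columns: ", paste(need, collapse = ", "))
  }
  x[need]
}

#' Write an ortholog table
#' @param orthologs Data frame `gene_a, gene_b, identity`.
#' @param path Output TSV path.
#' @export
write_orthologs <- function(orthologs, path) {
  write.table(orthologs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(orthologs)
}

#' Read an ancestral gene order
#'
#' @param path TSV with columns `chrom, gene_id, strand`, rows in chromosomal
#'   order.
#' @return An object of class `ancestral_order`.
#' @export
read_ancestral_order <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  new_ancestral_order(x)
}

#' Construct an ancestral gene order
#'
#' @param order Data frame `chrom, gene_id, strand` in chromosomal order.
#' @return An object of class `ancestral_order`.
#' @export
new_ancestral_order <- function(order) {
  need <- c("chrom", "gene_id", "strand")
  if (!all(need %in% names(order))) {
    stop("ancestral order needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(order$gene_id)) {
    stop("ancestral gene labels must be unique")
  }
  structure(list(order = order[need]), class = "ancestral_order")
}

# ---- statistics -------------------------------------------------------------

#' Gene density in kb per gene
#'
#' Reported at 2-decimal precision, the convention of published genome
#' comparison tables.
#'
#' @param total_kb Genome size in kb (excluding rDNA).
#' @param n_genes Number of protein-coding genes.
#' @return kb/gene rounded to 2 decimals; `NA` when `n_genes` is 0.
#' @export
gene_density_kb <- function(total_kb, n_genes) {
  if (n_genes == 0) return(NA_real_)
  round(total_kb / n_genes, 2)
}

#' Coding fraction of the genome in percent
#'
#' @param coding_kb Coding DNA in kb (or bp, if `total_kb` is in bp too).
#' @param total_kb Genome size in the same unit.
#' @return Percentage rounded to 2 decimals.
#' @export
coding_fraction_pct <- function(coding_kb, total_kb) {
  round(100 * coding_kb / total_kb, 2)
}

#' Summary statistics of a genome
#'
#' Mirrors the layout of genome-comparison tables: chromosome count, genome
#' size in bp excluding rDNA-class features, protein-coding gene count, gene
#' density (kb/gene, 2 decimals), coding bp (gene spans minus introns) and
#' coding fraction, intron and tRNA counts, and GC content over the non-N
#' bases of all available sequence.
#'
#' @param genome A `genome` object.
#' @return A list of class `genome_statistics`.
#' @export
genome_statistics <- function(genome) {
  ft <- genome_features(genome)
  chrom_len <- vapply(genome$chromosomes, function(ch) ch$length, integer(1))
  rdna_bp <- if (nrow(ft)) sum((ft$end - ft$start)[ft$feature_class == "rDNA"]) else 0L
  total_bp <- sum(as.numeric(chrom_len)) - rdna_bp
  pc <- ft[ft$feature_class == "protein_coding", , drop = FALSE]
  intron_bp <- vapply(pc$introns, function(m) {
    if (is.null(m) || nrow(m) == 0) 0L else sum(m[, "end"] - m[, "start"])
  }, integer(1))
  coding_bp <- sum(as.numeric(pc$end - pc$start)) - sum(as.numeric(intron_bp))
  n_introns <- sum(vapply(pc$introns, function(m) if (is.null(m)) 0L else nrow(m),
                          integer(1)))
  gc <- genome_gc_content(genome)
  structure(list(
    id = genome$id,
    n_chromosomes = length(genome$chromosomes),
    total_bp = total_bp,
    n_genes = nrow(pc),
    gene_density_kb = gene_density_kb(total_bp / 1000, nrow(pc)),
    coding_bp = coding_bp,
    coding_fraction = coding_fraction_pct(coding_bp, total_bp),
    n_introns = n_introns,
    n_trna = sum(ft$feature_class == "tRNA"),
    gc_content = gc
  ), class = "genome_statistics")
}

#' @export
print.genome_statistics <- function(x, ...) {
  cat("Genome statistics:", x$id, "\n")
  cat(sprintf("  Chromosomes            %d\n", x$n_chromosomes))
  cat(sprintf("  Size without rDNA      %.0f kb\n", x$total_bp / 1000))
  cat(sprintf("  Genes                  %d\n", x$n_genes))
  cat(sprintf("  Gene density           %.2f kb/gene\n", x$gene_density_kb))
  cat(sprintf("  Gene coding DNA        %.0f kb (%.2f%%)\n",
              x$coding_bp / 1000, x$coding_fraction))
  cat(sprintf("  Introns                %d\n", x$n_introns))
  cat(sprintf("  tRNAs                  %d\n", x$n_trna))
  if (!is.na(x$gc_content)) {
    cat(sprintf("  GC content             %.1f%%\n", x$gc_content))
  }
  invisible(x)
}

#' GC content of a genome in percent
#'
#' Computed over non-N bases of all chromosomes that carry sequence;
#' `NA` if no sequence is available.
#'
#' @param genome A `genome` object.
#' @return Percent GC (not rounded).
#' @export
genome_gc_content <- function(genome) {
  gc <- 0; acgt <- 0
  for (ch in genome$chromosomes) {
    if (is.na(ch$sequence)) next
    s <- Biostrings::DNAString(ch$sequence)
    f <- Biostrings::letterFrequency(s, c("G", "C", "A", "T"))
    gc <- gc + f[["G"]] + f[["C"]]
    acgt <- acgt + sum(f)
  }
  if (acgt == 0) return(NA_real_)
  100 * gc / acgt
}
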