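# Cross-species gene presence/absence, tandem duplications and their
# conservation, protein identity distributions, and intron splice-rule checks.

#' Classify genes as shared, species-specific, or orphan
#'
#' Genes mapped in the A-B ortholog table are `shared`. Unmapped genes split
#' by whether they have a homolog in an outgroup (e.g. S. cerevisiae):
#' species-specific-with-outgroup versus orphans with no homolog anywhere.
#' Only protein-coding features are classified.
#'
#' @param genome_a,genome_b `genome` objects.
#' @param ab_orthologs One-to-one ortholog table `gene_a, gene_b, identity`.
#' @param outgroup_homologs Character vector (or data frame with a `gene_id`
#'   column) of gene ids, from either genome, that have an outgroup homolog.
#' @return List of class `presence_absence`: `shared` (pair count),
#'   `a_specific_with_outgroup`, `b_specific_with_outgroup`, `a_orphans`,
#'   `b_orphans` (gene id vectors), plus per-genome totals.
#' @export
classify_presence_absence <- function(genome_a, genome_b, ab_orthologs,
                                      outgroup_homologs = character()) {
  if (anyDuplicated(ab_orthologs$gene_a) || anyDuplicated(ab_orthologs$gene_b)) {
    stop("ortholog map is not one-to-one; resolve many-to-many pairs first")
  }
  if (is.data.frame(outgroup_homologs)) {
    outgroup_homologs <- outgroup_homologs$gene_id
  }
  pc_ids <- function(g) {
    ft <- genome_features(g)
    ft$gene_id[ft$feature_class == "protein_coding"]
  }
  genes_a <- pc_ids(genome_a)
  genes_b <- pc_ids(genome_b)
  mapped_a <- intersect(genes_a, ab_orthologs$gene_a)
  mapped_b <- intersect(genes_b, ab_orthologs$gene_b)
  un_a <- setdiff(genes_a, mapped_a)
  un_b <- setdiff(genes_b, mapped_b)
  a_spec <- intersect(un_a, outgroup_homologs)
  b_spec <- intersect(un_b, outgroup_homologs)
  res <- structure(list(
    shared = length(mapped_a),
    a_specific_with_outgroup = a_spec,
    b_specific_with_outgroup = b_spec,
    a_orphans = setdiff(un_a, a_spec),
    b_orphans = setdiff(un_b, b_spec),
    n_genes_a = length(genes_a),
    n_genes_b = length(genes_b)
  ), class = "presence_absence")
  stopifnot(res$shared + length(res$a_specific_with_outgroup) +
              length(res$a_orphans) == res$n_genes_a,
            length(mapped_b) + length(res$b_specific_with_outgroup) +
              length(res$b_orphans) == res$n_genes_b)
  res
}

#' @export
print.presence_absence <- function(x, ...) {
  cat("Gene presence/absence\n")
  cat(sprintf("  shared ortholog pairs        %d\n", x$shared))
  cat(sprintf("  A-specific (outgroup homolog) %d\n",
              length(x$a_specific_with_outgroup)))
  cat(sprintf("  B-specific (outgroup homolog) %d\n",
              length(x$b_specific_with_outgroup)))
  cat(sprintf("  A orphans                    %d\n", length(x$a_orphans)))
  cat(sprintf("  B orphans                    %d\n", length(x$b_orphans)))
  invisible(x)
}

#' Find tandemly duplicated gene loci
#'
#' Clusters within-genome paralog pairs whose members lie on the same
#' chromosome with at most `max_intervening` genes between them
#' (single-linkage), keeping clusters of two or more genes.
#'
#' @param genome A `genome` object.
#' @param paralog_pairs Data frame `gene_a, gene_b, identity` of within-genome
#'   homolog pairs (percent amino-acid identity).
#' @param max_intervening Maximum intervening genes between locus members.
#' @param min_identity Minimum percent identity for a pair to count.
#' @return Data frame of loci sorted by chrom and start: `locus_id, chrom,
#'   n_genes, start, end, members` (list column of ordered gene ids).
#' @export
find_tandem_duplications <- function(genome, paralog_pairs,
                                     max_intervening = 1, min_identity = 30) {
  empty <- data.frame(locus_id = integer(), chrom = character(),
                      n_genes = integer(), start = integer(), end = integer(),
                      members = I(list()))
  if (nrow(paralog_pairs) == 0) return(empty)
  pp <- paralog_pairs[paralog_pairs$identity >= min_identity, , drop = FALSE]
  if (nrow(pp) == 0) return(empty)
  ord <- gene_order(genome)
  ia <- match(pp$gene_a, ord$gene_id)
  ib <- match(pp$gene_b, ord$gene_id)
  ok <- !is.na(ia) & !is.na(ib) & ord$chrom[ia] == ord$chrom[ib] &
    abs(ord$index[ia] - ord$index[ib]) - 1L <= max_intervening &
    ord$index[ia] != ord$index[ib]
  if (!any(ok)) return(empty)
  ia <- ia[ok]; ib <- ib[ok]
  # union-find over gene rows
  parent <- seq_len(nrow(ord))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(nrow(ord)), find, integer(1))
  touched <- unique(c(ia, ib))
  groups <- split(touched, roots[touched])
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) == 0) return(empty)
  loci <- lapply(groups, function(rows) {
    rows <- rows[order(ord$index[rows])]
    data.frame(chrom = ord$chrom[rows[1]], n_genes = length(rows),
               start = min(ord$start[rows]), end = max(ord$end[rows]),
               members = I(list(ord$gene_id[rows])), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, loci)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(locus_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Tandem duplications conserved between two genomes
#'
#' A duplication locus of genome A counts as conserved when at least two of
#' its member genes have orthologs that belong to one duplication locus of
#' genome B.
#'
#' @param dups_a,dups_b Locus tables from [find_tandem_duplications()].
#' @param ab_orthologs One-to-one ortholog table `gene_a, gene_b, identity`.
#' @return Subset of `dups_a` with an added `b_locus_id` column.
#' @export
conserved_duplications <- function(dups_a, dups_b, ab_orthologs) {
  out <- dups_a[0, , drop = FALSE]
  out$b_locus_id <- integer()
  if (nrow(dups_a) == 0 || nrow(dups_b) == 0 || nrow(ab_orthologs) == 0) {
    return(out)
  }
  b_locus_of <- rep(dups_b$locus_id, vapply(dups_b$members, length, integer(1)))
  names(b_locus_of) <- unlist(dups_b$members)
  keep <- list()
  for (i in seq_len(nrow(dups_a))) {
    mem <- dups_a$members[[i]]
    orth <- ab_orthologs$gene_b[match(mem, ab_orthologs$gene_a)]
    loci <- b_locus_of[orth[!is.na(orth)]]
    loci <- loci[!is.na(loci)]
    if (length(loci) == 0) next
    tab <- table(loci)
    if (max(tab) >= 2) {
      row <- dups_a[i, , drop = FALSE]
      row$b_locus_id <- as.integer(names(tab)[which.max(tab)])
      keep[[length(keep) + 1L]] <- row
    }
  }
  if (length(keep) == 0) return(out)
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  res
}

# fixed alignment scoring so identity values are reproducible bit-exactly
ALIGN_GAP_OPEN <- 10
ALIGN_GAP_EXTEND <- 1

protein_identity_pct <- function(seq_a, seq_b) {
  letters_ab <- unique(strsplit(paste0(seq_a, seq_b), "", fixed = TRUE)[[1]])
  al <- union(Biostrings::AA_STANDARD, letters_ab)
  m <- matrix(0, length(al), length(al), dimnames = list(al, al))
  diag(m) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = m,
    gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / cols
}

#' Percent-identity distribution of ortholog pairs
#'
#' Identity per pair is computed by global (Needleman-Wunsch) alignment with
#' match +1, mismatch 0, affine gaps (open -10, extend -1); identity =
#' matches / alignment columns x 100. The histogram uses 5%-wide bins over
#' [20, 100], the range typical of Eremothecium ortholog comparisons.
#'
#' @param ortholog_pairs Data frame `gene_a, gene_b` (extra columns ignored).
#' @param proteins Named character vector (or `AAStringSet`) of protein
#'   sequences covering both genomes' gene ids.
#' @return List of class `identity_distribution`: `identities` data frame,
#'   `mean_identity`, and `histogram` (`bin_low, bin_high, count`).
#' @export
identity_distribution <- function(ortholog_pairs, proteins) {
  if (methods::is(proteins, "XStringSet")) {
    proteins <- setNames(as.character(proteins), names(proteins))
  }
  ids <- numeric(0)
  ga <- character(0); gb <- character(0)
  for (i in seq_len(nrow(ortholog_pairs))) {
    a <- ortholog_pairs$gene_a[i]; b <- ortholog_pairs$gene_b[i]
    sa <- if (a %in% names(proteins)) proteins[[a]] else NA_character_
    sb <- if (b %in% names(proteins)) proteins[[b]] else NA_character_
    if (is.na(sa) || is.na(sb) || nchar(sa) == 0 || nchar(sb) == 0) {
      warning("skipping pair ", a, "/", b, ": missing or empty sequence")
      next
    }
    ids <- c(ids, protein_identity_pct(sa, sb))
    ga <- c(ga, a); gb <- c(gb, b)
  }
  breaks <- seq(20, 100, by = 5)
  binned <- ids[ids >= 20 & ids <= 100]
  nbin <- length(breaks) - 1L
  counts <- tabulate(pmin(findInterval(binned, breaks), nbin), nbins = nbin)
  structure(list(
    identities = data.frame(gene_a = ga, gene_b = gb, identity = ids,
                            stringsAsFactors = FALSE),
    mean_identity = if (length(ids)) mean(ids) else NA_real_,
    histogram = data.frame(bin_low = head(breaks, -1),
                           bin_high = breaks[-1], count = counts)
  ), class = "identity_distribution")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate an intron against the splice rule 5'-GT...TACTAAC...AG-3'
#'
#' Valid introns start with the GT donor, end with the AG acceptor, and carry
#' the TACTAAC branch motif ending at least 3 bp upstream of the terminal AG.
#'
#' @param intron_sequence Nucleotide string (length >= 4).
#' @return List with `valid` (logical) and `violations` (character vector).
#' @export
validate_intron <- function(intron_sequence) {
  s <- toupper(intron_sequence)
  n <- nchar(s)
  violations <- character()
  if (substr(s, 1, 2) != "GT") {
    violations <- c(violations, "no 5' GT donor")
  }
  if (n < 2 || substr(s, n - 1, n) != "AG") {
    violations <- c(violations, "no 3' AG acceptor")
  }
  hits <- gregexpr("TACTAAC", s, fixed = TRUE)[[1]]
  branch_ok <- any(hits > 0 & (hits + 6) <= n - 5)
  if (!branch_ok) {
    violations <- c(violations,
                    "no TACTAAC branch motif ending >= 3 bp before the 3' AG")
  }
  list(valid = length(violations) == 0, violations = violations)
}
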