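# Telomere tandem-repeat unit inference and point-centromere detection.
#
# Telomeres of Eremothecium-like genomes are tandem arrays of a short unit
# (24 bp in E. cymbalariae); the unit is rotation-ambiguous, so units are
# reported in a canonical form. Point centromeres follow the
# CDEI - CDEII (AT-rich spacer, ~160 bp in Eremothecium) - CDEIII layout.

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

rotations_of <- function(u) {
  n <- nchar(u)
  vapply(seq_len(n) - 1L,
         function(k) paste0(substr(u, k + 1, n), substr(u, 1, k)),
         character(1))
}

#' Canonical form of a tandem-repeat unit
#'
#' The lexicographically smallest string over all rotations of the unit and
#' of its reverse complement. This makes the representation invariant to the
#' register in which an array is read and to the strand of the chromosome.
#'
#' @param unit Nucleotide string.
#' @return Canonical unit string.
#' @export
canonical_repeat_unit <- function(unit) {
  unit <- toupper(unit)
  min(c(rotations_of(unit), rotations_of(revcomp_str(unit))))
}

hamming_chr <- function(a, b) sum(a != b)

# Longest terminal tandem array anchored at position 1 of character vector v,
# for a given period p: whole copies, adjacent copies >= min_ident identical.
terminal_copies <- function(v, p, min_ident) {
  n <- length(v)
  if (2L * p > n) return(0L)
  max_mm <- floor((1 - min_ident) * p + 1e-9)
  copies <- 1L
  prev <- v[seq_len(p)]
  pos <- p + 1L
  while (pos + p - 1L <= n) {
    cand <- v[pos:(pos + p - 1L)]
    if (hamming_chr(cand, prev) > max_mm) break
    copies <- copies + 1L
    prev <- cand
    pos <- pos + p
  }
  copies
}

#' Infer the telomeric tandem-repeat unit at a chromosome end
#'
#' Scans the terminal `scan_bp` for the tandem array anchored at the
#' chromosome end (>= 2 whole copies, adjacent copies >= 90% identical) with
#' the largest copy number, breaking ties toward the shorter period. Copy
#' number, not bp length, is maximized so that a long spurious period cannot
#' absorb flanking non-repeat sequence within the identity tolerance; a
#' divisor of the true period that also generates the array would have more
#' copies and win, so the reported period is automatically minimal.
#'
#' @param chromosome A `chromosome` object or nucleotide string.
#' @param end `"left"` or `"right"`.
#' @param scan_bp How many terminal bp to scan.
#' @param min_identity Minimum identity between adjacent copies.
#' @return Object of class `repeat_unit` (fields `unit` -- canonical form --,
#'   `unit_forward` as read on the forward strand at the end, `period`,
#'   `copy_number`, `end`, `chrom`), or `NULL` if no array is found.
#' @export
infer_telomere_repeat <- function(chromosome, end = c("right", "left"),
                                  scan_bp = 5000, min_identity = 0.9) {
  end <- match.arg(end)
  s <- toupper(seq_of(chromosome))
  L <- nchar(s)
  scan_bp <- min(scan_bp, L)
  term <- if (end == "right") substr(s, L - scan_bp + 1L, L) else
    substr(s, 1L, scan_bp)
  v <- strsplit(term, "", fixed = TRUE)[[1]]
  if (end == "right") v <- rev(v)   # anchor the array at v[1] in both cases
  best_p <- NA_integer_; best_copies <- 0L
  for (p in seq_len(floor(length(v) / 2))) {
    copies <- terminal_copies(v, p, min_identity)
    if (copies >= 2L && copies > best_copies) {
      best_p <- p
      best_copies <- copies
    }
  }
  if (is.na(best_p)) return(NULL)
  arr <- v[seq_len(best_p)]
  if (end == "right") arr <- rev(arr)   # terminal copy on the forward strand
  unit_fwd <- paste(arr, collapse = "")
  structure(list(unit = canonical_repeat_unit(unit_fwd),
                 unit_forward = unit_fwd,
                 unit_revcomp = revcomp_str(unit_fwd),
                 period = best_p,
                 copy_number = as.numeric(best_copies),
                 end = end,
                 chrom = chrom_id_of(chromosome)),
            class = "repeat_unit")
}

#' @export
print.repeat_unit <- function(x, ...) {
  cat(sprintf("<repeat_unit> %s %s end: (%s)n, period %d bp, %.1f copies\n",
              x$chrom, x$end, x$unit_forward, x$period, x$copy_number))
  invisible(x)
}

#' Substitution distance between two repeat units
#'
#' Minimal Hamming distance over all rotations of the second unit and of its
#' reverse complement (telomere units are rotation- and strand-ambiguous).
#'
#' @param unit_a,unit_b Nucleotide strings of equal length.
#' @return Integer substitution count.
#' @export
repeat_distance <- function(unit_a, unit_b) {
  unit_a <- toupper(unit_a); unit_b <- toupper(unit_b)
  if (nchar(unit_a) != nchar(unit_b)) {
    stop("repeat units have unequal periods (", nchar(unit_a), " vs ",
         nchar(unit_b), ")")
  }
  va <- strsplit(unit_a, "", fixed = TRUE)[[1]]
  cands <- c(rotations_of(unit_b), rotations_of(revcomp_str(unit_b)))
  min(vapply(strsplit(cands, "", fixed = TRUE),
             function(vb) hamming_chr(va, vb), numeric(1)))
}

# ---- centromeres ------------------------------------------------------------

#' Configuration for the CDE centromere scan
#'
#' Defaults follow the S. cerevisiae-style consensus elements (CDEI
#' `RTCACRTG`; a TGT-rich CDEIII core carrying the invariant `CCGAA`), with
#' CDEII bounds widened to the ~160 bp AT-rich spacer typical of
#' Eremothecium (about twice the S. cerevisiae length).
#'
#' @param cdeI,cdeIII IUPAC consensus strings.
#' @param cdeII_min,cdeII_max Allowed CDEII (spacer) length range in bp.
#' @param min_at Minimum AT fraction of the spacer.
#' @param max_mismatch Mismatches tolerated per consensus element.
#' @return List of class `cde_config`.
#' @export
cde_config <- function(cdeI = "RTCACRTG", cdeIII = "TGTTTWTGNTTTCCGAA",
                       cdeII_min = 120, cdeII_max = 200, min_at = 0.7,
                       max_mismatch = 1) {
  structure(list(cdeI = toupper(cdeI), cdeIII = toupper(cdeIII),
                 cdeII_min = as.integer(cdeII_min),
                 cdeII_max = as.integer(cdeII_max),
                 min_at = min_at, max_mismatch = as.integer(max_mismatch)),
            class = "cde_config")
}

iupac_match_count <- function(consensus, s) {
  # number of positions of s matching the IUPAC consensus
  codes <- Biostrings::IUPAC_CODE_MAP
  cv <- strsplit(consensus, "", fixed = TRUE)[[1]]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  sum(mapply(function(cc, sc) grepl(sc, codes[[cc]], fixed = TRUE), cv, sv))
}

at_fraction <- function(s) {
  v <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  n <- sum(v %in% c("A", "C", "G", "T"))
  if (n == 0) return(0)
  sum(v == "A" | v == "T") / n
}

scan_cde_strand <- function(seqstr, cfg) {
  subject <- Biostrings::DNAString(seqstr)
  mI <- Biostrings::matchPattern(cfg$cdeI, subject, fixed = FALSE,
                                 max.mismatch = cfg$max_mismatch)
  mIII <- Biostrings::matchPattern(cfg$cdeIII, subject, fixed = FALSE,
                                   max.mismatch = cfg$max_mismatch)
  if (length(mI) == 0 || length(mIII) == 0) return(NULL)
  sI <- Biostrings::start(mI); eI <- Biostrings::end(mI)
  sIII <- Biostrings::start(mIII); eIII <- Biostrings::end(mIII)
  out <- list()
  for (i in seq_along(sI)) {
    gap <- sIII - eI[i] - 1L
    ok <- which(gap >= cfg$cdeII_min & gap <= cfg$cdeII_max)
    for (j in ok) {
      spacer <- substr(seqstr, eI[i] + 1L, sIII[j] - 1L)
      atf <- at_fraction(spacer)
      if (atf < cfg$min_at) next
      score <- iupac_match_count(cfg$cdeI, substr(seqstr, sI[i], eI[i])) +
        iupac_match_count(cfg$cdeIII, substr(seqstr, sIII[j], eIII[j])) + atf
      out[[length(out) + 1L]] <- data.frame(
        s_cdeI = sI[i], e_cdeI = eI[i], s_cdeIII = sIII[j],
        e_cdeIII = eIII[j], cdeII_len = gap[j], cdeII_at = atf,
        score = score)
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Detect point centromeres via the CDEI-CDEII-CDEIII model
#'
#' Scans both strands for a CDEI consensus hit followed, within the
#' configured spacer length range, by a CDEIII consensus hit across an
#' AT-rich spacer. Candidates are ranked by motif-match score; the top call
#' per chromosome is flagged `primary`, the rest are retained as secondary
#' candidates. Coordinates are 0-based half-open on the forward strand.
#'
#' @param chromosome A `chromosome` object or nucleotide string.
#' @param config A [cde_config()].
#' @return Data frame of calls (`chrom, start, end, cdeI_start, cdeI_end,
#'   cdeII_start, cdeII_end, cdeIII_start, cdeIII_end, orientation,
#'   cdeII_at, score, primary`), empty when nothing matches.
#' @export
find_centromeres <- function(chromosome, config = cde_config()) {
  s <- toupper(seq_of(chromosome))
  chrom <- chrom_id_of(chromosome)
  L <- nchar(s)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      cdeI_start = integer(), cdeI_end = integer(),
                      cdeII_start = integer(), cdeII_end = integer(),
                      cdeIII_start = integer(), cdeIII_end = integer(),
                      orientation = character(), cdeII_at = numeric(),
                      score = numeric(), primary = logical(),
                      stringsAsFactors = FALSE)
  res <- list()
  fwd <- scan_cde_strand(s, config)
  if (!is.null(fwd)) {
    res[[1]] <- data.frame(
      chrom = chrom,
      start = fwd$s_cdeI - 1L, end = fwd$e_cdeIII,
      cdeI_start = fwd$s_cdeI - 1L, cdeI_end = fwd$e_cdeI,
      cdeII_start = fwd$e_cdeI, cdeII_end = fwd$s_cdeIII - 1L,
      cdeIII_start = fwd$s_cdeIII - 1L, cdeIII_end = fwd$e_cdeIII,
      orientation = "forward", cdeII_at = fwd$cdeII_at, score = fwd$score,
      stringsAsFactors = FALSE)
  }
  rev <- scan_cde_strand(revcomp_str(s), config)
  if (!is.null(rev)) {
    # map 1-based coords on the reverse strand back to forward 0-based
    res[[length(res) + 1L]] <- data.frame(
      chrom = chrom,
      start = L - rev$e_cdeIII, end = L - rev$s_cdeI + 1L,
      cdeI_start = L - rev$e_cdeI, cdeI_end = L - rev$s_cdeI + 1L,
      cdeII_start = L - rev$s_cdeIII + 1L, cdeII_end = L - rev$e_cdeI,
      cdeIII_start = L - rev$e_cdeIII, cdeIII_end = L - rev$s_cdeIII + 1L,
      orientation = "reverse", cdeII_at = rev$cdeII_at, score = rev$score,
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(empty)
  calls <- do.call(rbind, res)
  calls <- calls[order(-calls$score, calls$start), , drop = FALSE]
  # collapse near-duplicate spans (same locus hit at slightly shifted motifs)
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))[-1]) {
    prev <- which(keep[seq_len(i - 1)])
    if (any(calls$start[prev] < calls$end[i] &
            calls$start[i] < calls$end[prev])) keep[i] <- FALSE
  }
  calls <- calls[keep, , drop = FALSE]
  calls$primary <- seq_len(nrow(calls)) == 1L
  rownames(calls) <- NULL
  calls
}

#' Centromere calls for a whole genome
#'
#' Runs [find_centromeres()] on every chromosome and returns the primary
#' call per chromosome (chromosomes without a call are absent).
#'
#' @param genome A `genome` object.
#' @param config A [cde_config()].
#' @return Data frame of primary calls.
#' @export
genome_centromeres <- function(genome, config = cde_config()) {
  out <- lapply(genome$chromosomes, function(ch) {
    calls <- find_centromeres(ch, config)
    calls[calls$primary, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Telomere repeat calls at all chromosome ends of a genome
#'
#' @param genome A `genome` object.
#' @inheritParams infer_telomere_repeat
#' @return Data frame with one row per end where an array was found
#'   (`chrom, end, unit, unit_forward, period, copy_number`).
#' @export
genome_telomeres <- function(genome, scan_bp = 5000, min_identity = 0.9) {
  rows <- list()
  for (ch in genome$chromosomes) {
    for (e in c("left", "right")) {
      r <- infer_telomere_repeat(ch, e, scan_bp, min_identity)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch$id, end = e, unit = r$unit, unit_forward = r$unit_forward,
        period = r$period, copy_number = r$copy_number,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), end = character(),
                      unit = character(), unit_forward = character(),
                      period = integer(), copy_number = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
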