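# Windowed GC profiling and detection of AT-rich troughs.
#
# Point centromeres of Saccharomyces-complex fungi sit in regions of markedly
# reduced GC extending over at least ~15 kb; some telomeres and occasional
# internal coldspots show the same signature. Profiles are computed in
# fixed-step sliding windows; troughs are maximal runs of windows below
# mean - z*sd, merged where their spans overlap.

seq_of <- function(chromosome) {
  if (inherits(chromosome, "chromosome")) {
    if (is.na(chromosome$sequence)) stop("chromosome '", chromosome$id,
                                         "' carries no sequence")
    chromosome$sequence
  } else {
    as.character(chromosome)
  }
}

chrom_id_of <- function(chromosome, default = "chr") {
  if (inherits(chromosome, "chromosome")) chromosome$id else default
}

#' Sliding-window GC profile of a chromosome
#'
#' One window starts every `step_bp` from position 0; the terminal windows are
#' included at their true (shorter) length. GC fraction is computed over non-N
#' bases only; all-N windows yield `NA`.
#'
#' @param chromosome A `chromosome` object or nucleotide string.
#' @param window_bp Window size in bp (>= `step_bp`).
#' @param step_bp Step between window starts in bp.
#' @return Object of class `gc_profile`: chrom label, parameters, and a table
#'   of `start` (0-based), `width`, `gc` (fraction in 0-1).
#' @export
gc_profile <- function(chromosome, window_bp = 5000, step_bp = 1000) {
  if (window_bp < step_bp) stop("window_bp must be >= step_bp")
  s <- toupper(seq_of(chromosome))
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  len <- length(v)
  if (len == 0) stop("empty sequence")
  is_gc <- v == "G" | v == "C"
  is_acgt <- is_gc | v == "A" | v == "T"
  cgc <- c(0, cumsum(is_gc))
  cv <- c(0, cumsum(is_acgt))
  starts <- seq(0L, len - 1L, by = step_bp)
  width <- pmin(window_bp, len - starts)
  gc_ct <- cgc[starts + width + 1L] - cgc[starts + 1L]
  valid <- cv[starts + width + 1L] - cv[starts + 1L]
  gc <- ifelse(valid > 0, gc_ct / valid, NA_real_)
  structure(list(chrom = chrom_id_of(chromosome),
                 window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp),
                 table = data.frame(start = starts, width = as.integer(width),
                                    gc = gc)),
            class = "gc_profile")
}

#' GC profiles for every chromosome of a genome
#'
#' @param genome A `genome` object.
#' @inheritParams gc_profile
#' @return Named list of `gc_profile` objects.
#' @export
genome_gc_profiles <- function(genome, window_bp = 5000, step_bp = 1000) {
  lapply(genome$chromosomes, gc_profile, window_bp = window_bp,
         step_bp = step_bp)
}

label_interval <- function(chrom, start, end, centromeres, telomeres) {
  overlaps_any <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0) return(FALSE)
    t <- tab[tab$chrom == chrom, , drop = FALSE]
    nrow(t) > 0 && any(t$start < end & start < t$end)
  }
  if (overlaps_any(centromeres)) return("centromere")
  if (overlaps_any(telomeres)) return("telomere")
  if (!is.null(centromeres) || !is.null(telomeres)) return("internal")
  "none"
}

#' Detect GC troughs across a set of profiles
#'
#' A trough is a maximal run of consecutive windows with GC below
#' `mean - z_threshold * sd` (mean and sd pooled over all windows of all
#' profiles, unless a genome mean is supplied). Runs whose bp spans overlap
#' are merged, and only troughs spanning at least `min_trough_bp` are kept.
#' A genome of uniform GC (sd = 0) yields no troughs.
#'
#' @param profiles List of `gc_profile` objects (e.g. from
#'   [genome_gc_profiles()]).
#' @param genome_mean_gc Optional genome mean GC fraction; defaults to the
#'   pooled window mean.
#' @param z_threshold Depth threshold in pooled-sd units.
#' @param min_trough_bp Minimum trough span in bp.
#' @param centromeres,telomeres Optional annotation tables `chrom, start, end`
#'   used to label each trough `centromere`, `telomere`, or `internal`
#'   (`none` when no annotations are given).
#' @return Data frame `chrom, start, end, mean_gc, deficit, label`, pairwise
#'   non-overlapping, sorted by chrom and start.
#' @export
detect_troughs <- function(profiles, genome_mean_gc = NULL, z_threshold = 1.0,
                           min_trough_bp = 15000, centromeres = NULL,
                           telomeres = NULL) {
  all_gc <- unlist(lapply(profiles, function(p) p$table$gc))
  all_gc <- all_gc[!is.na(all_gc)]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      mean_gc = numeric(), deficit = numeric(),
                      label = character(), stringsAsFactors = FALSE)
  if (length(all_gc) < 2) return(empty)
  mu <- if (is.null(genome_mean_gc)) mean(all_gc) else genome_mean_gc
  sdev <- sd(all_gc)
  if (is.na(sdev) || sdev == 0) return(empty)
  thr <- mu - z_threshold * sdev
  out <- list()
  for (p in profiles) {
    tab <- p$table
    below <- !is.na(tab$gc) & tab$gc < thr
    if (!any(below)) next
    r <- rle(below)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    runs <- which(r$values)
    cand <- data.frame(
      start = tab$start[starts_i[runs]],
      end = tab$start[ends_i[runs]] + tab$width[ends_i[runs]],
      i1 = starts_i[runs], i2 = ends_i[runs])
    # windows overlap when step < window, so adjacent runs may touch: merge
    merged <- list()
    cur <- cand[1, ]
    for (k in seq_len(nrow(cand))[-1]) {
      if (cand$start[k] < cur$end) {
        cur$end <- max(cur$end, cand$end[k])
        cur$i2 <- cand$i2[k]
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- cand[k, ]
      }
    }
    merged[[length(merged) + 1L]] <- cur
    for (m in merged) {
      if (m$end - m$start < min_trough_bp) next
      vals <- tab$gc[m$i1:m$i2]
      mg <- mean(vals, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        chrom = p$chrom, start = m$start, end = m$end, mean_gc = mg,
        deficit = mu - mg,
        label = label_interval(p$chrom, m$start, m$end, centromeres,
                               telomeres),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write a GC profile as wiggle-style TSV
#' @param profile A `gc_profile` object.
#' @param path Output path.
#' @export
write_gc_profile <- function(profile, path) {
  out <- data.frame(chrom = profile$chrom, start = profile$table$start,
                    end = profile$table$start + profile$table$width,
                    gc = profile$table$gc)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}

#' Write troughs (or any chrom/start/end table) as BED
#' @param intervals Data frame with `chrom, start, end` (extra columns become
#'   the BED name field).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  extra <- setdiff(names(intervals), c("chrom", "start", "end"))
  name <- if (length(extra)) {
    apply(intervals[extra], 1, function(r) paste(r, collapse = "|"))
  } else "."
  bed <- data.frame(intervals$chrom, intervals$start, intervals$end, name)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(intervals)
}
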