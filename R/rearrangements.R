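# Signed genome permutations, breakpoint counts, and exhaustive minimal
# rearrangement scenarios.
#
# A genome permutation is a list of chromosomes, each an ordered vector of
# signed block labels. The operation alphabet matches the event vocabulary of
# small-genome comparative studies: inversions, reciprocal translocations
# (prefix/suffix exchange; a cut at a chromosome end makes the event a
# telomeric translocation, and an empty product a fusion), and fission. All
# operations are self-inverse or have their inverse in the set, so the state
# graph is undirected and a bidirectional breadth-first search returns a
# provably minimal scenario.

#' Construct a signed genome permutation
#'
#' @param chromosomes List of integer vectors of signed block labels; each
#'   label must appear exactly once across the genome (in absolute value).
#' @return Object of class `genome_perm`.
#' @export
genome_perm <- function(chromosomes) {
  chromosomes <- lapply(chromosomes, as.integer)
  labs <- abs(unlist(chromosomes))
  if (length(labs) == 0) stop("permutation has no elements")
  if (any(labs == 0)) stop("block labels must be non-zero")
  if (anyDuplicated(labs)) stop("each block label must appear exactly once")
  structure(list(chromosomes = chromosomes), class = "genome_perm")
}

#' @export
print.genome_perm <- function(x, ...) {
  for (ch in x$chromosomes) {
    cat("(", paste(ifelse(ch > 0, paste0("+", ch), ch), collapse = " "), ")\n")
  }
  invisible(x)
}

perm_elements <- function(perm) sort(abs(unlist(perm$chromosomes)))

# canonical state key: chromosomes sorted by smallest absolute label; flips
# are NOT normalized (a reversed chromosome differs by one inversion)
perm_key <- function(chroms) {
  if (length(chroms) == 0) return("")
  keys <- vapply(chroms, function(ch) min(abs(ch)), numeric(1))
  paste(vapply(chroms[order(keys)], paste, character(1), collapse = ","),
        collapse = "|")
}

canon_adjacency <- function(a, b) {
  x <- c(a, b); y <- c(-b, -a)
  if (x[1] < y[1] || (x[1] == y[1] && x[2] <= y[2])) x else y
}

adjacency_keys <- function(perm) {
  out <- character()
  for (ch in perm$chromosomes) {
    ext <- c(0L, ch, 0L)      # 0 caps the telomeric adjacencies
    for (i in seq_len(length(ext) - 1L)) {
      out <- c(out, paste(canon_adjacency(ext[i], ext[i + 1L]),
                          collapse = ","))
    }
  }
  out
}

#' Breakpoint count between two signed permutations
#'
#' Number of adjacencies (including chromosome-end caps) present in the
#' source but absent from the target. An adjacency and its reverse-complement
#' reading are identified.
#'
#' @param source,target `genome_perm` objects over the same element set.
#' @return Integer breakpoint count.
#' @export
breakpoint_count <- function(source, target) {
  if (!identical(perm_elements(source), perm_elements(target))) {
    stop("source and target carry different element sets")
  }
  length(setdiff(adjacency_keys(source), adjacency_keys(target)))
}

# ---- operations -------------------------------------------------------------

apply_op_chroms <- function(chroms, op) {
  switch(op$type,
    inversion = {
      ch <- chroms[[op$chrom]]
      ch[op$i:op$j] <- -rev(ch[op$i:op$j])
      chroms[[op$chrom]] <- ch
      chroms
    },
    translocation = {
      x1 <- chroms[[op$c1]]; x2 <- chroms[[op$c2]]
      n1 <- length(x1); n2 <- length(x2)
      suf <- function(x, i) if (i < length(x)) x[(i + 1L):length(x)] else
        integer(0)
      chroms[[op$c1]] <- c(x1[seq_len(op$i)], suf(x2, op$j))
      chroms[[op$c2]] <- c(x2[seq_len(op$j)], suf(x1, op$i))
      chroms[vapply(chroms, length, integer(1)) > 0]
    },
    fission = {
      ch <- chroms[[op$chrom]]
      chroms[[op$chrom]] <- ch[seq_len(op$i)]
      chroms[[length(chroms) + 1L]] <- ch[(op$i + 1L):length(ch)]
      chroms
    },
    stop("unknown operation type: ", op$type))
}

classify_translocation <- function(chroms, op) {
  n1 <- length(chroms[[op$c1]]); n2 <- length(chroms[[op$c2]])
  if ((op$i == 0 && op$j == n2) || (op$i == n1 && op$j == 0)) return("fusion")
  if (op$i %in% c(0L, n1) || op$j %in% c(0L, n2)) return("telomeric_translocation")
  "reciprocal_translocation"
}

enumerate_ops <- function(chroms) {
  ops <- list()
  nc <- length(chroms)
  for (c1 in seq_len(nc)) {
    n <- length(chroms[[c1]])
    for (i in seq_len(n)) for (j in i:n) {
      ops[[length(ops) + 1L]] <- list(type = "inversion", chrom = c1,
                                      i = i, j = j)
    }
  }
  if (nc > 1) {
    for (c1 in seq_len(nc - 1)) for (c2 in (c1 + 1):nc) {
      n1 <- length(chroms[[c1]]); n2 <- length(chroms[[c2]])
      for (i in 0:n1) for (j in 0:n2) {
        if (i == 0 && j == 0) next          # no-op / whole-chromosome swap
        if (i == n1 && j == n2) next
        ops[[length(ops) + 1L]] <- list(type = "translocation",
                                        c1 = c1, c2 = c2, i = i, j = j)
      }
    }
  }
  for (c1 in seq_len(nc)) {
    n <- length(chroms[[c1]])
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      ops[[length(ops) + 1L]] <- list(type = "fission", chrom = c1, i = i)
    }
  }
  ops
}

#' Apply a scenario's operations to a permutation
#'
#' @param perm A `genome_perm`.
#' @param operations List of operation records (as in a
#'   `rearrangement_scenario`).
#' @return The resulting `genome_perm`.
#' @export
apply_operations <- function(perm, operations) {
  chroms <- perm$chromosomes
  for (op in operations) chroms <- apply_op_chroms(chroms, op)
  genome_perm(chroms)
}

expand_state <- function(chroms) {
  ops <- enumerate_ops(chroms)
  lapply(ops, function(op) {
    nxt <- apply_op_chroms(chroms, op)
    if (op$type == "translocation") {
      op$label <- classify_translocation(chroms, op)
    } else {
      op$label <- op$type
    }
    list(op = op, chroms = nxt, key = perm_key(nxt))
  })
}

#' Minimal rearrangement scenario by exhaustive search
#'
#' Bidirectional breadth-first search over the operation alphabet (inversion,
#' reciprocal/telomeric translocation, fusion, fission) returns a
#' provably minimal-length operation sequence transforming `source` into
#' `target`. Operations are enumerated in a fixed deterministic order, so the
#' returned scenario is reproducible across runs. States are deduplicated by
#' a canonical form with chromosomes sorted by smallest absolute label.
#'
#' @param source,target `genome_perm` objects over the same element set.
#' @param max_elements Hard cap on total elements (exhaustive search only).
#' @return Object of class `rearrangement_scenario` with `operations`
#'   (list; each has a `label` among inversion, reciprocal_translocation,
#'   telomeric_translocation, fusion, fission) and `length`.
#' @export
minimal_scenario <- function(source, target, max_elements = 10) {
  if (!identical(perm_elements(source), perm_elements(target))) {
    stop("source and target carry different element sets")
  }
  n_el <- length(perm_elements(source))
  if (n_el > max_elements) {
    stop("instance has ", n_el, " elements, above the exhaustive-search cap ",
         "of ", max_elements, "; use breakpoint_count() for large instances")
  }
  src_key <- perm_key(source$chromosomes)
  tgt_key <- perm_key(target$chromosomes)
  finish <- function(ops) {
    got <- apply_operations(source, ops)
    stopifnot(perm_key(got$chromosomes) == tgt_key)
    structure(list(operations = ops, length = length(ops)),
              class = "rearrangement_scenario")
  }
  if (src_key == tgt_key) return(finish(list()))

  # seen maps: key -> list(chroms, parent_key, op); roots have parent NULL
  fwd_seen <- new.env(parent = emptyenv())
  bwd_seen <- new.env(parent = emptyenv())
  assign(src_key, list(chroms = source$chromosomes, parent = NULL, op = NULL),
         envir = fwd_seen)
  assign(tgt_key, list(chroms = target$chromosomes, parent = NULL, op = NULL),
         envir = bwd_seen)
  fwd <- src_key
  bwd <- tgt_key

  chain_to_root <- function(key, seen) {
    # keys from `key` back to the root, inclusive
    keys <- character()
    while (!is.null(key)) {
      keys <- c(keys, key)
      key <- get(key, envir = seen)$parent
    }
    keys
  }

  join <- function(meet_key) {
    # forward half: recorded ops along source -> meet
    fchain <- rev(chain_to_root(meet_key, fwd_seen))   # source ... meet
    ops <- lapply(fchain[-1], function(k) get(k, envir = fwd_seen)$op)
    # backward half: walk meet -> target; backward ops were recorded in the
    # target -> meet direction, so re-derive each step by neighbor search
    # (every operation's inverse is itself in the alphabet)
    bchain <- chain_to_root(meet_key, bwd_seen)        # meet ... target
    state <- get(meet_key, envir = fwd_seen)$chroms
    for (k in seq_len(length(bchain) - 1L)) {
      want <- bchain[k + 1L]
      found <- NULL
      for (nb in expand_state(state)) {
        if (nb$key == want) { found <- nb; break }
      }
      if (is.null(found)) stop("internal error: broken backward chain")
      ops <- c(ops, list(found$op))
      state <- found$chroms
    }
    finish(ops)
  }

  meets <- character()
  repeat {
    expand_fwd <- length(fwd) <= length(bwd)
    frontier <- if (expand_fwd) fwd else bwd
    seen <- if (expand_fwd) fwd_seen else bwd_seen
    other <- if (expand_fwd) bwd_seen else fwd_seen
    nxt <- character()
    for (key in frontier) {
      node <- get(key, envir = seen)
      for (nb in expand_state(node$chroms)) {
        if (exists(nb$key, envir = seen, inherits = FALSE)) next
        assign(nb$key, list(chroms = nb$chroms, parent = key, op = nb$op),
               envir = seen)
        if (exists(nb$key, envir = other, inherits = FALSE)) {
          meets <- c(meets, nb$key)
        } else {
          nxt <- c(nxt, nb$key)
        }
      }
    }
    if (length(meets) > 0) {
      # a node in both trees caps the optimum at this level; among all meets
      # the smallest summed depth is provably minimal once the level is done
      depth_of <- function(k) {
        length(chain_to_root(k, fwd_seen)) + length(chain_to_root(k, bwd_seen)) - 2L
      }
      best <- meets[which.min(vapply(meets, depth_of, integer(1)))]
      return(join(best))
    }
    if (length(nxt) == 0) stop("no scenario found: state space exhausted")
    if (expand_fwd) fwd <- nxt else bwd <- nxt
  }
}

#' @export
print.rearrangement_scenario <- function(x, ...) {
  cat("<rearrangement_scenario> length", x$length, "\n")
  for (op in x$operations) {
    params <- op[setdiff(names(op), c("type", "label"))]
    cat("  ", op$label, " (",
        paste(names(params), unlist(params), sep = "=", collapse = ", "),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Convert synteny blocks to a pair of signed permutations
#'
#' Blocks are numbered 1..n along genome A (by chromosome, then span start);
#' the target permutation orders them along genome B (bp start, or ancestral
#' ordinal position for ancestor comparisons), with inverted-orientation
#' blocks carrying a negative sign.
#'
#' @param blocks Block data frame from [chain_blocks()].
#' @return List with `source` and `target` `genome_perm` objects.
#' @export
blocks_to_permutation <- function(blocks) {
  if (nrow(blocks) == 0) stop("no blocks to convert")
  blocks <- blocks[order(blocks$chrom_a, blocks$start_a), , drop = FALSE]
  blocks$element <- seq_len(nrow(blocks))
  source <- lapply(split(blocks$element, blocks$chrom_a), as.integer)
  b_pos <- ifelse(is.na(blocks$start_b), blocks$index_b_min, blocks$start_b)
  tgt <- lapply(split(seq_len(nrow(blocks)), blocks$chrom_b), function(rows) {
    rows <- rows[order(b_pos[rows])]
    as.integer(blocks$element[rows] *
                 ifelse(blocks$orientation[rows] == "inverted", -1L, 1L))
  })
  list(source = genome_perm(unname(source)), target = genome_perm(unname(tgt)))
}
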