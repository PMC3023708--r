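# Independent oracles and fixture builders used across the suite. These are
# deliberately written against the definitions, not against the package
# internals, so they can adjudicate the implementation.

# Brute-force architecture checker: reads the segment table directly and
# re-derives every condition from first principles.
oracle_classify <- function(top, rule) {
  seg <- top$segments
  L <- seg$end[nrow(seg)]
  fails <- character(0)
  if (L < rule$min_len || L > rule$max_len) fails <- c(fails, "length_out_of_range")
  tm_rows <- which(seg$kind == "TM")
  if (length(tm_rows) != rule$tm_required) fails <- c(fails, "tm_count_mismatch")
  k <- rule$loop_after_tm
  if (length(tm_rows) < k + 1L) {
    fails <- c(fails, "too_few_tms")
  } else {
    # residues strictly between TM k and TM k+1, counted position by position
    lo <- seg$end[tm_rows[k]] + 1L
    hi <- seg$start[tm_rows[k + 1L]] - 1L
    span <- if (hi >= lo) hi - lo + 1L else 0L
    if (span < rule$loop_min || span > rule$loop_max) {
      fails <- c(fails, "loop_out_of_range")
    }
    if (rule$require_outside) {
      between <- seg$kind[(tm_rows[k] + 1L):(tm_rows[k + 1L] - 1L)]
      if (!all(between == "O")) fails <- c(fails, "loop_side_mismatch")
    }
  }
  list(passed = length(fails) == 0L, failures = fails)
}

# Random valid topology, length-weighted to hit the rule boundaries often.
random_topology <- function(id = "t") {
  n_tm <- sample(0:12, 1L, prob = c(1, 1, 4, 2, 1, 1, 1, 1, 1, 2, 4, 1, 1))
  loop_pool <- c(1:30, 8:16, 90:110, 160:180, 195:215, 390:410)
  tm_pool <- 15:25
  if (n_tm == 0L) {
    return(topology_from_lengths(id, sample(c("I", "O"), 1L),
                                 sample(50:900, 1L)))
  }
  side <- sample(c("I", "O"), 1L)
  kinds <- character(0)
  lens <- integer(0)
  if (stats::runif(1) < 0.8) {       # N-terminal tail
    kinds <- side
    lens <- sample(1:60, 1L)
  }
  for (k in seq_len(n_tm)) {
    kinds <- c(kinds, "TM")
    lens <- c(lens, sample(tm_pool, 1L))
    side <- if (side == "I") "O" else "I"
    if (k < n_tm) {
      kinds <- c(kinds, side)
      lens <- c(lens, sample(loop_pool, 1L))
    }
  }
  if (stats::runif(1) < 0.8) {       # C-terminal tail
    kinds <- c(kinds, side)
    lens <- c(lens, sample(1:300, 1L))
  } else if (kinds[length(kinds)] == "TM" && stats::runif(1) < 0.5) {
    kinds <- c(kinds, side)
    lens <- c(lens, 1L)
  }
  topology_from_lengths(id, kinds, lens)
}

# Quadratic local-alignment DP with a flat per-symbol gap cost (no affine
# bookkeeping); equals sw_align when gap_extend == gap_open.
sw_oracle <- function(a, b, gap = 11) {
  mat <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1L, j + 1L] <- max(0,
                               H[i, j] + mat[av[i], bv[j]],
                               H[i, j + 1L] - gap,
                               H[i + 1L, j] - gap)
      best <- max(best, H[i + 1L, j + 1L])
    }
  }
  best
}

# Gap-scan clustering oracle: exhaustive over the ordered component flags.
cluster_oracle <- function(ranks, is_component, max_gap) {
  hits <- which(is_component)
  if (!length(hits)) return(list())
  groups <- list(hits[1L])
  for (h in hits[-1L]) {
    last <- groups[[length(groups)]]
    if (ranks[h] - ranks[last[length(last)]] - 1L <= max_gap) {
      groups[[length(groups)]] <- c(last, h)
    } else {
      groups[[length(groups) + 1L]] <- h
    }
  }
  groups
}

# Convenience topologies at the published seed dimensions.
make_hk_top <- function(id = "hk", loop = 8L, total = 334L, n_tm = 2L) {
  kinds <- c("I")
  lens <- c(15L)
  side <- "O"
  for (k in seq_len(n_tm)) {
    kinds <- c(kinds, "TM")
    lens <- c(lens, 20L)
    if (k < n_tm) {
      kinds <- c(kinds, side)
      lens <- c(lens, loop)
      side <- if (side == "O") "I" else "O"
    }
  }
  kinds <- c(kinds, side)
  lens <- c(lens, total - sum(lens))
  topology_from_lengths(id, kinds, lens)
}

make_msd_top <- function(id = "msd", o4 = 205L, total = 646L) {
  kinds <- c("I", "TM", "O", "TM", "I", "TM", "O", "TM", "I", "TM", "O",
             "TM", "I", "TM", "O", "TM", "I", "TM", "O", "TM", "I")
  lens <- c(10L, 20L, 15L, 20L, 20L, 20L, 15L, 20L, 20L, 20L, 15L, 20L,
            20L, 20L, o4, 20L, 20L, 20L, 15L, 20L, NA)
  lens[21L] <- total - sum(lens, na.rm = TRUE)
  topology_from_lengths(id, kinds, lens)
}

# Tiny feature table builder: genes laid out in rank order on one contig.
make_features <- function(gene_ids, genome = "g1", contig = "c1",
                          products = NULL, pseudo = NULL) {
  n <- length(gene_ids)
  starts <- seq(100L, by = 1000L, length.out = n)
  df <- data.frame(gene_id = gene_ids, genome_id = genome, contig = contig,
                   start = starts, end = starts + 899L, strand = "+",
                   product = if (is.null(products)) "" else products,
                   pseudo = if (is.null(pseudo)) FALSE else pseudo,
                   stringsAsFactors = FALSE)
  bcescan:::validate_features(df)
}

make_calls <- function(gene_ids, components) {
  data.frame(seq_id = gene_ids, component = components,
             best_seed = NA_character_, score = 100,
             normalized_score = 0.5, stringsAsFactors = FALSE)
}
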