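#' Membrane topology of one protein
#'
#' An ordered segmentation of the residue range `[1, length]` into inside
#' (`I`), outside (`O`) and transmembrane (`TM`) segments, 1-based inclusive.
#' The segments must tile the protein exactly, two TM segments may never be
#' adjacent, and the non-TM segments must alternate sides across each TM
#' (crossing a membrane helix flips the compartment).
#'
#' @param seq_id protein identifier.
#' @param kinds character vector of segment kinds (`"I"`, `"O"`, `"TM"`).
#' @param starts,ends 1-based inclusive segment coordinates.
#' @return an object of class `bce_topology` with fields `seq_id`, `length`
#'   and `segments` (a data.frame of `kind`, `start`, `end`).
#' @examples
#' topology("BceS_like", c("I", "TM", "O", "TM", "I"),
#'          c(1, 16, 36, 44, 64), c(15, 35, 43, 63, 334))
#' @export
topology <- function(seq_id, kinds, starts, ends) {
  stopifnot(length(kinds) == length(starts), length(starts) == length(ends))
  kinds <- as.character(kinds)
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  if (!length(kinds)) stop("topology for ", seq_id, " has no segments")
  if (!all(kinds %in% c("I", "O", "TM"))) {
    stop("unknown segment kind(s) for ", seq_id, ": ",
         paste(setdiff(kinds, c("I", "O", "TM")), collapse = ", "))
  }
  if (any(starts > ends)) stop("segment with start > end for ", seq_id)
  if (starts[1L] != 1L) stop("first segment of ", seq_id, " does not start at 1")
  if (length(starts) > 1L && any(starts[-1L] != ends[-length(ends)] + 1L)) {
    stop("segments of ", seq_id, " do not tile the sequence")
  }
  if (any(kinds[-1L] == "TM" & kinds[-length(kinds)] == "TM")) {
    stop("adjacent TM segments in ", seq_id)
  }
  non_tm <- kinds[kinds != "TM"]
  if (length(non_tm) > 1L && any(non_tm[-1L] == non_tm[-length(non_tm)])) {
    stop("non-TM sides of ", seq_id, " do not alternate across TM segments")
  }
  structure(list(seq_id = seq_id,
                 length = ends[length(ends)],
                 segments = data.frame(kind = kinds, start = starts, end = ends,
                                       stringsAsFactors = FALSE)),
            class = "bce_topology")
}

#' Build a topology from consecutive segment lengths
#'
#' Convenience constructor used heavily by the synthetic-data generator:
#' segment coordinates are accumulated from lengths instead of being spelled
#' out.
#'
#' @param seq_id protein identifier.
#' @param kinds segment kinds in order.
#' @param lengths segment lengths in residues.
#' @return a `bce_topology`.
#' @export
topology_from_lengths <- function(seq_id, kinds, lengths) {
  lengths <- as.integer(lengths)
  stopifnot(all(lengths >= 1L))
  ends <- cumsum(lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  topology(seq_id, kinds, starts, ends)
}

#' @export
print.bce_topology <- function(x, ...) {
  cat(sprintf("bce_topology %s: %d aa, %d TM segment(s)\n",
              x$seq_id, x$length, tm_count(x)))
  seg <- x$segments
  cat(paste(sprintf("%s[%d-%d]", seg$kind, seg$start, seg$end), collapse = " "), "\n")
  invisible(x)
}

#' Number of transmembrane segments
#' @param top a `bce_topology`.
#' @return non-negative integer count of TM segments.
#' @export
tm_count <- function(top) {
  stopifnot(inherits(top, "bce_topology"))
  sum(top$segments$kind == "TM")
}

#' Inter-TM loop spans
#'
#' For a topology with `k >= 2` TM segments, returns the `k - 1` loops: span
#' `j` covers every residue strictly between TM `j` and TM `j + 1`, with the
#' side (`I`/`O`) copied from the intervening non-TM segment. The kinase
#' filter reads span 1 (the short extracytoplasmic linker, 3-11 residues in
#' the *B. subtilis* kinases); the translocator filter reads span 7 (the
#' large O4 loop, 197-213 residues in *B. subtilis*).
#'
#' @param top a `bce_topology`.
#' @return a data.frame with columns `after_tm`, `before_tm`, `side`,
#'   `length`; zero rows when there are fewer than two TM segments.
#' @export
inter_tm_loops <- function(top) {
  stopifnot(inherits(top, "bce_topology"))
  seg <- top$segments
  tm_idx <- which(seg$kind == "TM")
  if (length(tm_idx) < 2L) {
    return(data.frame(after_tm = integer(0), before_tm = integer(0),
                      side = character(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  n <- length(tm_idx) - 1L
  out <- data.frame(after_tm = seq_len(n), before_tm = seq_len(n) + 1L,
                    side = character(n), length = integer(n),
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    a <- tm_idx[j]
    b <- tm_idx[j + 1L]
    out$length[j] <- seg$start[b] - seg$end[a] - 1L
    # under the validated topology exactly one non-TM segment lies between
    out$side[j] <- seg$kind[a + 1L]
  }
  out
}

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

#' Predict a membrane topology from hydropathy
#'
#' A deliberately simple sliding-window predictor used when no TMHMM output
#' is supplied (and by the synthetic-data generator): positions whose
#' centered-window mean Kyte-Doolittle hydropathy reaches `cutoff` are TM
#' candidates, maximal candidate runs of at least `min_run` residues become
#' TM segments, and non-TM side labels start inside at the N-terminus and
#' alternate across each TM. The N-in convention is documentation, not
#' biology: the architecture filters ignore loop sidedness by default.
#'
#' The default `min_run` of 9 (half a window) reflects the window geometry:
#' a canonical ~20-residue helix flanked by hydrophilic loops produces a
#' candidate run of only 11-13 positions, because windows overhanging the
#' helix ends dilute the mean below the cutoff. Demanding longer runs would
#' reject real-sized helices outright.
#'
#' @param seq a residue string or a one-row data.frame with `id` and `seq`.
#' @param window odd window width in residues.
#' @param cutoff mean-hydropathy threshold for a TM candidate position.
#' @param min_run minimum run length (residues) kept as a TM segment.
#' @param seq_id identifier used when `seq` is a bare string.
#' @return a `bce_topology`.
#' @export
predict_topology_kd <- function(seq, window = 19L, cutoff = 1.6, min_run = 9L,
                                seq_id = "query") {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L)
    seq_id <- seq$id[1L]
    seq <- seq$seq[1L]
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("window must be odd")
  L <- nchar(seq)
  if (L < window) stop("sequence ", seq_id, " shorter than window (",
                       L, " < ", window, ")")
  h <- KD_SCALE[strsplit(toupper(seq), "")[[1L]]]
  if (anyNA(h)) h[is.na(h)] <- 0
  half <- (window - 1L) %/% 2L
  means <- stats::filter(h, rep(1 / window, window), sides = 2)
  cand <- !is.na(means) & means >= cutoff
  runs <- rle(as.vector(cand))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_run
  tm_start <- starts[keep]
  tm_end <- ends[keep]
  kinds <- character(0)
  lens <- integer(0)
  pos <- 1L
  for (j in seq_along(tm_start)) {
    if (tm_start[j] > pos) {
      kinds <- c(kinds, "X")            # placeholder side, filled below
      lens <- c(lens, tm_start[j] - pos)
    }
    kinds <- c(kinds, "TM")
    lens <- c(lens, tm_end[j] - tm_start[j] + 1L)
    pos <- tm_end[j] + 1L
  }
  if (pos <= L) {
    kinds <- c(kinds, "X")
    lens <- c(lens, L - pos + 1L)
  }
  side <- "I"
  for (j in seq_along(kinds)) {
    if (kinds[j] == "TM") side <- if (side == "I") "O" else "I"
    else kinds[j] <- side
  }
  topology_from_lengths(seq_id, kinds, lens)
}

#' Predict topologies for a whole sequence set
#' @param seqs data.frame from [read_fasta()].
#' @param ... passed to [predict_topology_kd()].
#' @return named list of `bce_topology` objects.
#' @export
predict_topologies <- function(seqs, ...) {
  out <- lapply(seq_len(nrow(seqs)), function(i) {
    predict_topology_kd(seqs$seq[i], seq_id = seqs$id[i], ...)
  })
  stats::setNames(out, seqs$id)
}
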