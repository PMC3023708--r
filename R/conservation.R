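#' Partition alignment columns into topology-derived regions
#'
#' Walks the reference sequence N-terminus to C-terminus, mapping each
#' non-gap reference residue to the topology segment it falls in; region
#' labels number the segments per kind in order (`I1..`, `O1..`, `TM1..`),
#' so a ten-TM translocator yields the 21 labels `I1..I6`, `O1..O5`,
#' `TM1..TM10`, with `O4` the large extracytoplasmic loop. Columns where the
#' reference is gapped belong to no region: region sizes are defined by the
#' reference, not by the alignment.
#'
#' @param msa a `bce_msa` from [read_msa()].
#' @param ref_id id of the reference sequence in the alignment.
#' @param ref_top `bce_topology` of the reference; its length must equal the
#'   ungapped reference length in the alignment.
#' @return an object of class `bce_region_partition`: a list with `labels`
#'   (region labels in N-to-C order), `columns` (named list of 1-based MSA
#'   column indices), `ref_id`.
#' @export
partition_regions <- function(msa, ref_id, ref_top) {
  stopifnot(inherits(msa, "bce_msa"), inherits(ref_top, "bce_topology"))
  if (!ref_id %in% msa$ids) stop("reference ", ref_id, " not in alignment")
  ref <- strsplit(msa$seqs[match(ref_id, msa$ids)], "")[[1L]]
  non_gap <- which(ref != "-")
  if (length(non_gap) != ref_top$length) {
    stop("ungapped reference length (", length(non_gap),
         ") does not match topology length (", ref_top$length, ")")
  }
  seg <- ref_top$segments
  counts <- stats::setNames(integer(3), c("I", "O", "TM"))
  labels <- character(nrow(seg))
  for (k in seq_len(nrow(seg))) {
    counts[seg$kind[k]] <- counts[seg$kind[k]] + 1L
    labels[k] <- paste0(seg$kind[k], counts[seg$kind[k]])
  }
  residue_seg <- rep(seq_len(nrow(seg)), seg$end - seg$start + 1L)
  columns <- lapply(seq_len(nrow(seg)), function(k) non_gap[residue_seg == k])
  names(columns) <- labels
  structure(list(labels = labels, columns = columns, ref_id = ref_id),
            class = "bce_region_partition")
}

#' @export
print.bce_region_partition <- function(x, ...) {
  cat(sprintf("bce_region_partition (ref %s): %d regions, %d columns\n",
              x$ref_id, length(x$labels), sum(lengths(x$columns))))
  invisible(x)
}

#' Per-region identity of one sequence against the reference
#'
#' For each region, the fraction of its columns where the other sequence
#' carries the same residue as the reference. Columns where the other
#' sequence is gapped count as mismatches (the region size stays
#' reference-defined); a region with no columns is reported as `NA`, not 0.
#'
#' @param msa a `bce_msa`.
#' @param ref_id,other_id sequence ids in the alignment.
#' @param part a `bce_region_partition` for `ref_id`.
#' @return named numeric vector of identities in `[0,1]`, one per region.
#' @export
region_identity <- function(msa, ref_id, other_id, part) {
  stopifnot(inherits(part, "bce_region_partition"), part$ref_id == ref_id)
  for (id in c(ref_id, other_id)) {
    if (!id %in% msa$ids) stop("id ", id, " not in alignment")
  }
  ref <- strsplit(msa$seqs[match(ref_id, msa$ids)], "")[[1L]]
  oth <- strsplit(msa$seqs[match(other_id, msa$ids)], "")[[1L]]
  vapply(part$columns, function(cols) {
    if (!length(cols)) return(NA_real_)
    mean(oth[cols] == ref[cols] & oth[cols] != "-")
  }, numeric(1))
}

#' Per-region conservation profile of an alignment
#'
#' For every topology-derived region of the reference (plus the whole
#' protein), the mean and sample standard deviation of the identity between
#' the reference and each non-reference sequence. In the published
#' subfamily-IV comparison this is the profile in which the large
#' extracytoplasmic loop O4 is systematically the least conserved region.
#' A Poisson-corrected distance column (`-ln(identity)`) is included because
#' the original figure is labelled as an evolutionary distance; raw
#' fractional identity is the operative definition.
#'
#' @param msa a `bce_msa` with at least two sequences.
#' @param ref_id reference sequence id.
#' @param part a `bce_region_partition` for `ref_id`.
#' @return an object of class `bce_profile`: a list with `profile` (a
#'   data.frame of `region`, `n_cols`, `mean`, `sd`, `n`, `mean_poisson_dist`,
#'   ordered N-to-C with a final `whole` row), `per_pair` (matrix of
#'   identities, sequences x regions), and `ranking` (regions ordered by
#'   increasing mean identity).
#' @export
conservation_profile <- function(msa, ref_id, part) {
  stopifnot(inherits(msa, "bce_msa"))
  others <- setdiff(msa$ids, ref_id)
  if (length(others) < 1L) stop("alignment needs at least 2 sequences")
  per_pair <- t(vapply(others, function(oid) {
    region_identity(msa, ref_id, oid, part)
  }, numeric(length(part$labels))))
  rownames(per_pair) <- others
  sizes <- lengths(part$columns)
  whole <- as.vector(per_pair %*% sizes / sum(sizes))
  prof <- data.frame(
    region = c(part$labels, "whole"),
    n_cols = c(unname(sizes), sum(sizes)),
    mean = c(colMeans(per_pair), mean(whole)),
    sd = c(apply(per_pair, 2L, stats::sd), stats::sd(whole)),
    n = length(others),
    stringsAsFactors = FALSE)
  prof$mean_poisson_dist <- ifelse(prof$mean > 0, -log(prof$mean), Inf)
  rownames(prof) <- NULL
  region_rows <- prof[prof$region != "whole", , drop = FALSE]
  structure(list(profile = prof, per_pair = per_pair,
                 ranking = region_rows$region[order(region_rows$mean)]),
            class = "bce_profile")
}

#' @export
print.bce_profile <- function(x, ...) {
  cat("bce_profile:\n")
  print(x$profile, digits = 3)
  cat("least conserved region:", x$ranking[1L], "\n")
  invisible(x)
}
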