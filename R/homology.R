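COMPONENT_ORDER <- c("RR", "HK", "NBD", "MSD")

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

#' Local (Smith-Waterman) alignment of two protein sequences
#'
#' Optimal local alignment under BLOSUM62 with affine gaps, computed by
#' `Biostrings::pairwiseAlignment`. A gap of length `L` costs
#' `gap_open + (L - 1) * gap_extend`: the first gapped residue pays the
#' opening penalty. Alignments whose best score is not positive are reported
#' as the empty alignment with score 0.
#'
#' @param a,b residue strings, or one-row data.frames with `id` and `seq`.
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @param ids optional character vector of length 2 naming query and subject.
#' @return a list with `query_id`, `subject_id`, `score`, `aligned_pairs`,
#'   `identical_pairs`, `identity` (`NA` for an empty alignment).
#' @export
sw_align <- function(a, b, gap_open = 11, gap_extend = 1,
                     ids = c("query", "subject")) {
  take <- function(x, fallback) {
    if (is.data.frame(x)) list(id = x$id[1L], seq = x$seq[1L])
    else list(id = fallback, seq = x)
  }
  qa <- take(a, ids[1L])
  sb <- take(b, ids[2L])
  stopifnot(nzchar(qa$seq), nzchar(sb$seq))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qa$seq), Biostrings::AAString(sb$seq),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(query_id = qa$id, subject_id = sb$id, score = 0,
                aligned_pairs = 0L, identical_pairs = 0L, identity = NA_real_))
  }
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  list(query_id = qa$id, subject_id = sb$id, score = sc,
       aligned_pairs = nm + nmm, identical_pairs = nm,
       identity = nm / (nm + nmm))
}

# Vectorized local-alignment scores of many sequences against one subject.
sw_scores <- function(seqs, subject, gap_open = 11, gap_extend = 1) {
  if (!length(seqs)) return(numeric(0))
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seqs), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend,
    scoreOnly = TRUE)
  pmax(sc, 0)
}

#' Read tagged seed sequences
#'
#' Seeds are FASTA records whose description carries a `component=RR|HK|NBD|MSD`
#' tag. Exactly one seed per component is required for component calling.
#'
#' @param path seeds FASTA file.
#' @return a data.frame with columns `id`, `desc`, `seq`, `component`.
#' @export
read_seeds <- function(path) {
  seeds <- read_fasta(path)
  m <- regmatches(seeds$desc, regexpr("component=(RR|HK|NBD|MSD)", seeds$desc))
  if (length(m) != nrow(seeds) || any(!nzchar(m))) {
    stop("every seed header must carry a component=RR|HK|NBD|MSD tag")
  }
  seeds$component <- sub("component=", "", m)
  seeds
}

#' Call component types by similarity to the four module seeds
#'
#' Each protein is aligned locally against one seed per component
#' (RR, HK, NBD, MSD); the score is normalized by the seed's self-alignment
#' score, so a seed scores exactly 1 against itself. The best seed wins
#' (ties broken in the fixed order RR < HK < NBD < MSD) and the protein is
#' assigned that component when the normalized score reaches
#' `min_norm_score`, otherwise `none`. The threshold is a declared,
#' configurable parameter -- it is echoed into report headers, not hidden.
#'
#' @param proteome data.frame from [read_fasta()].
#' @param seeds data.frame with `id`, `seq`, `component` (one seed per
#'   component), e.g. from [read_seeds()] or [synthetic_seeds()].
#' @param min_norm_score minimum self-score-normalized alignment score.
#' @return a data.frame with columns `seq_id`, `component`, `best_seed`,
#'   `score`, `normalized_score` (one row per protein).
#' @export
call_components <- function(proteome, seeds, min_norm_score = 0.2) {
  stopifnot(is.data.frame(proteome), is.data.frame(seeds))
  if (!setequal(seeds$component, COMPONENT_ORDER) ||
      nrow(seeds) != length(COMPONENT_ORDER)) {
    stop("seeds must contain exactly one sequence per component RR/HK/NBD/MSD")
  }
  seeds <- seeds[match(COMPONENT_ORDER, seeds$component), , drop = FALSE]
  if (!nrow(proteome)) {
    return(data.frame(seq_id = character(0), component = character(0),
                      best_seed = character(0), score = numeric(0),
                      normalized_score = numeric(0), stringsAsFactors = FALSE))
  }
  norm <- sapply(seq_len(nrow(seeds)), function(i) {
    self <- sw_scores(seeds$seq[i], seeds$seq[i])
    sw_scores(proteome$seq, seeds$seq[i]) / self
  })
  norm <- matrix(norm, nrow = nrow(proteome))
  best <- apply(norm, 1L, which.max)   # which.max takes the first tie = RR<HK<NBD<MSD
  best_norm <- norm[cbind(seq_len(nrow(norm)), best)]
  comp <- ifelse(best_norm >= min_norm_score, COMPONENT_ORDER[best], "none")
  self_scores <- vapply(seq_len(nrow(seeds)),
                        function(i) sw_scores(seeds$seq[i], seeds$seq[i]),
                        numeric(1))
  data.frame(seq_id = proteome$id, component = comp,
             best_seed = ifelse(comp == "none", NA_character_, seeds$id[best]),
             score = best_norm * self_scores[best],
             normalized_score = best_norm, stringsAsFactors = FALSE)
}

#' Import component evidence from BLAST tabular output
#'
#' Reads 12-column `-outfmt 6` rows (`query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore`) in which
#' the subjects are the tagged seeds. Rows are filtered by percent identity
#' and by subject coverage (aligned fraction of the seed length); the best
#' bitscore per query wins, with the same RR < HK < NBD < MSD tie-break as
#' [call_components()].
#'
#' @param path BLAST tabular file.
#' @param seeds data.frame with `id`, `seq`, `component` mapping subject ids
#'   to components (and supplying seed lengths for coverage).
#' @param min_identity minimum percent identity (0-100).
#' @param min_coverage minimum aligned fraction of the seed length.
#' @return a data.frame with columns `seq_id`, `component`, `best_seed`,
#'   `score` (bitscore), `identity`, `coverage`; queries whose every row is
#'   filtered out are absent.
#' @export
import_blast_tab <- function(path, seeds, min_identity = 25,
                             min_coverage = 0.5) {
  stopifnot(file.exists(path), is.data.frame(seeds))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(data.frame(seq_id = character(0), component = character(0),
                      best_seed = character(0), score = numeric(0),
                      identity = numeric(0), coverage = numeric(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12L)
  if (length(bad)) {
    stop("malformed BLAST tabular row (expected 12 columns) at line ",
         lineno[bad[1L]])
  }
  f <- function(k) vapply(parts, `[[`, "", k)
  num <- function(k, what) {
    v <- suppressWarnings(as.numeric(f(k)))
    if (anyNA(v)) {
      stop("non-numeric ", what, " in BLAST tabular row at line ",
           lineno[which(is.na(v))[1L]])
    }
    v
  }
  tab <- data.frame(query = f(1L), subject = f(2L),
                    pident = num(3L, "pident"),
                    sstart = num(9L, "sstart"), send = num(10L, "send"),
                    bitscore = num(12L, "bitscore"), stringsAsFactors = FALSE)
  unknown <- setdiff(unique(tab$subject), seeds$id)
  if (length(unknown)) {
    stop("BLAST subject(s) not among the tagged seeds: ",
         paste(unknown, collapse = ", "))
  }
  si <- match(tab$subject, seeds$id)
  tab$component <- seeds$component[si]
  tab$coverage <- (abs(tab$send - tab$sstart) + 1) / nchar(seeds$seq[si])
  tab <- tab[tab$pident >= min_identity & tab$coverage >= min_coverage, ,
             drop = FALSE]
  if (!nrow(tab)) {
    return(data.frame(seq_id = character(0), component = character(0),
                      best_seed = character(0), score = numeric(0),
                      identity = numeric(0), coverage = numeric(0),
                      stringsAsFactors = FALSE))
  }
  tab$comp_rank <- match(tab$component, COMPONENT_ORDER)
  tab <- tab[order(tab$query, -tab$bitscore, tab$comp_rank), , drop = FALSE]
  best <- tab[!duplicated(tab$query), , drop = FALSE]
  data.frame(seq_id = best$query, component = best$component,
             best_seed = best$subject, score = best$bitscore,
             identity = best$pident / 100, coverage = best$coverage,
             stringsAsFactors = FALSE)
}
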