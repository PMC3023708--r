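#' Read protein sequences from a FASTA file
#'
#' Returns one record per `>` header with line wrapping collapsed and the
#' original record order preserved. The record id is the first
#' whitespace-delimited word of the header; the remainder is kept as the
#' description. Residues are uppercased and any letter outside the 20 standard
#' amino acids plus X is replaced by X with a warning, so real proteome files
#' with rare selenocysteines or ambiguity codes are tolerated.
#'
#' @param path path to a FASTA text file.
#' @return a `data.frame` with columns `id`, `desc`, `seq`.
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 a kinase", "MKT", "LLV"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  if (any(grepl("[-.]", seqs))) {
    stop("gap characters found in unaligned FASTA ", path,
         "; use read_msa() for alignments")
  }
  seqs <- clean_residues(seqs, ids)
  data.frame(id = ids, desc = desc, seq = unname(seqs), stringsAsFactors = FALSE)
}

# Replace letters outside the 20+X alphabet by X, warning once per file.
clean_residues <- function(seqs, ids) {
  bad_pat <- paste0("[^", paste(AA_ALLOWED, collapse = ""), "]")
  hits <- grepl(bad_pat, seqs)
  if (any(hits)) {
    warning("non-standard residues replaced by X in: ",
            paste(utils::head(ids[hits], 5L), collapse = ", "),
            if (sum(hits) > 5L) sprintf(" (and %d more)", sum(hits) - 5L) else "")
    seqs[hits] <- gsub(bad_pat, "X", seqs[hits])
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param x data.frame with columns `id`, `seq` and optionally `desc`.
#' @param path output file.
#' @param width line-wrap width in residues.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- x$id[i]
    if (!is.null(x$desc) && !is.na(x$desc[i]) && nzchar(x$desc[i])) {
      hdr <- paste(hdr, x$desc[i])
    }
    writeLines(paste0(">", hdr), con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene features from GFF3 or a tab-separated feature table
#'
#' Coordinates are kept 1-based inclusive as in the source. Features are
#' sorted by (contig, start) within each genome and `rank` (the 0-based
#' ordinal position of the gene along its contig) is assigned after sorting;
#' the chromosomal clustering stage counts intervening genes in rank units.
#'
#' The TSV dialect expects a header row with columns
#' `genome, contig, gene_id, start, end, strand` and optionally `product` and
#' `pseudo`. The GFF3 dialect uses `gene`/`CDS` rows and takes the gene id
#' from the `ID` attribute, falling back to `locus_tag`.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"gff3"`.
#' @param genome_id genome identifier used for GFF3 input (which carries none);
#'   defaults to the file name without extension.
#' @return a `data.frame` with columns `gene_id`, `genome_id`, `contig`,
#'   `start`, `end`, `strand`, `rank`, `product`, `pseudo`.
#' @export
read_features <- function(path, dialect = c("tsv", "gff3"), genome_id = NULL) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    need <- c("genome", "contig", "gene_id", "start", "end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("feature TSV missing column(s): ", paste(miss, collapse = ", "))
    feat <- data.frame(
      gene_id = as.character(tab$gene_id),
      genome_id = as.character(tab$genome),
      contig = as.character(tab$contig),
      start = as.integer(tab$start),
      end = as.integer(tab$end),
      strand = as.character(tab$strand),
      product = if ("product" %in% names(tab)) as.character(tab$product) else "",
      pseudo = if ("pseudo" %in% names(tab)) as.logical(tab$pseudo) else FALSE,
      stringsAsFactors = FALSE
    )
  } else {
    g <- rtracklayer::readGFF(path)
    g <- as.data.frame(g, stringsAsFactors = FALSE)
    g <- g[as.character(g$type) %in% c("gene", "CDS"), , drop = FALSE]
    if (!nrow(g)) stop("no gene/CDS rows in GFF3 file ", path)
    id <- if ("ID" %in% names(g)) as.character(g$ID) else rep(NA_character_, nrow(g))
    lt <- if ("locus_tag" %in% names(g)) as.character(g$locus_tag) else rep(NA_character_, nrow(g))
    gid <- ifelse(is.na(id) | id == "", lt, id)
    if (anyNA(gid)) stop("GFF3 row without ID or locus_tag attribute in ", path)
    if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
    feat <- data.frame(
      gene_id = gid,
      genome_id = genome_id,
      contig = as.character(g$seqid),
      start = as.integer(g$start),
      end = as.integer(g$end),
      strand = as.character(g$strand),
      product = if ("product" %in% names(g)) {
        ifelse(is.na(g$product), "", as.character(g$product))
      } else "",
      pseudo = FALSE,
      stringsAsFactors = FALSE
    )
    # a gene and its CDS share the locus id; keep one row per gene id
    feat <- feat[!duplicated(feat$gene_id), , drop = FALSE]
  }
  validate_features(feat)
}

# Shared validation + rank assignment for feature tables built anywhere.
validate_features <- function(feat) {
  bad <- which(feat$start > feat$end)
  if (length(bad)) {
    stop("start > end for gene(s): ", paste(feat$gene_id[bad], collapse = ", "))
  }
  if (!all(feat$strand %in% c("+", "-"))) {
    bad <- unique(feat$strand[!feat$strand %in% c("+", "-")])
    stop("unknown strand symbol(s): ", paste(bad, collapse = ", "))
  }
  for (gm in unique(feat$genome_id)) {
    ids <- feat$gene_id[feat$genome_id == gm]
    if (anyDuplicated(ids)) {
      stop("duplicate gene_id within genome ", gm, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
  }
  feat <- feat[order(feat$genome_id, feat$contig, feat$start), , drop = FALSE]
  key <- paste(feat$genome_id, feat$contig, sep = "\r")
  feat$rank <- stats::ave(seq_len(nrow(feat)), key, FUN = seq_along) - 1L
  rownames(feat) <- NULL
  feat
}

#' Write a feature table in the TSV dialect read by [read_features()]
#' @param feat feature data.frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_features <- function(feat, path) {
  out <- data.frame(genome = feat$genome_id, contig = feat$contig,
                    gene_id = feat$gene_id, start = feat$start, end = feat$end,
                    strand = feat$strand, product = feat$product,
                    pseudo = feat$pseudo, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse TMHMM long-format output into topologies
#'
#' Expects the per-segment lines
#' `<id> <tool> <inside|outside|TMhelix> <start> <end>` (whitespace-separated;
#' `#` comment lines are ignored). For every id the segments must be ordered,
#' contiguous from residue 1 and 1-based inclusive; segment kinds map to
#' `I`/`O`/`TM`.
#'
#' @param path TMHMM long output file.
#' @return named list of [topology()] objects, one per id.
#' @export
parse_tmhmm <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 5L)) {
    stop("malformed TMHMM line (expected 5 fields) at line ", which(nf != 5L)[1L])
  }
  tab <- data.frame(
    id = vapply(parts, `[[`, "", 1L),
    kind = vapply(parts, `[[`, "", 3L),
    start = as.integer(vapply(parts, `[[`, "", 4L)),
    end = as.integer(vapply(parts, `[[`, "", 5L)),
    stringsAsFactors = FALSE
  )
  kind_map <- c(inside = "I", outside = "O", TMhelix = "TM")
  unk <- setdiff(unique(tab$kind), names(kind_map))
  if (length(unk)) stop("unknown TMHMM segment label(s): ", paste(unk, collapse = ", "))
  tab$kind <- unname(kind_map[tab$kind])
  out <- lapply(split(tab, factor(tab$id, levels = unique(tab$id))), function(d) {
    if (d$start[1L] != 1L) {
      stop("segments for ", d$id[1L], " do not start at residue 1")
    }
    if (nrow(d) > 1L) {
      gap_at <- which(d$start[-1L] != d$end[-nrow(d)] + 1L)
      if (length(gap_at)) {
        stop("non-contiguous segments for ", d$id[1L], " at residue ",
             d$end[gap_at[1L]] + 1L)
      }
    }
    topology(d$id[1L], d$kind, d$start, d$end)
  })
  out
}

#' Write topologies in TMHMM long format
#' @param tops named list of [topology()] objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_tmhmm <- function(tops, path) {
  kind_map <- c(I = "inside", O = "outside", TM = "TMhelix")
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (tp in tops) {
    seg <- tp$segments
    writeLines(sprintf("%s\tTMHMM2.0\t%s\t%d\t%d", tp$seq_id,
                       kind_map[seg$kind], seg$start, seg$end), con)
  }
  invisible(path)
}

#' Parse a newick string into an `ape` tree with normalized supports
#'
#' Internal node labels that parse as numbers are treated as clade supports;
#' values greater than 1 are read as bootstrap percentages and divided by 100
#' so that posterior probabilities and bootstrap trees share one `[0,1]`
#' scale. Leaf labels must be unique.
#'
#' @param text a single newick statement terminated by `;`.
#' @return an object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced parenthesis at character ", i)
    }
  }
  if (depth != 0L) stop("unbalanced parenthesis at character ", length(chars))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse failure: ", conditionMessage(e)))
  if (is.null(tree)) stop("newick parse failure for: ", text)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  normalize_supports(tree)
}

normalize_supports <- function(tree) {
  if (!is.null(tree$node.label)) {
    num <- suppressWarnings(as.numeric(tree$node.label))
    pct <- !is.na(num) & num > 1
    num[pct] <- num[pct] / 100
    if (any(!is.na(num) & (num < 0 | num > 1))) {
      stop("node support outside [0,1] after normalization")
    }
    lab <- tree$node.label
    lab[!is.na(num)] <- format(num[!is.na(num)], trim = TRUE, digits = 6)
    tree$node.label <- lab
  }
  tree
}

#' Read a newick tree file
#' @param path file containing one newick statement.
#' @return a `phylo` tree with supports normalized to `[0,1]`.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path), collapse = ""))
}

#' Write a tree to newick
#' @param tree a `phylo` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Node supports of a tree as numbers in `[0,1]`
#'
#' Unannotated or non-numeric labels are reported as `NA`; downstream clade
#' queries treat `NA` as full support (1.0).
#' @param tree a `phylo` object.
#' @return numeric vector of length `tree$Nnode`.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' All records must have identical aligned length; `.` gap characters are
#' unified to `-`; all-gap columns are rejected.
#'
#' @param path aligned FASTA file.
#' @return an object of class `bce_msa`: a list with `ids`, `desc`, `seqs`
#'   (aligned residue strings) and `n_cols`.
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate id(s) in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- gsub(".", "-", toupper(as.character(aa)), fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    off <- ids[lens != lens[1L]]
    stop("unequal aligned lengths; offending record(s): ",
         paste(off, collapse = ", "))
  }
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  msa <- new_msa(ids, unname(seqs), desc)
  m <- msa_matrix(msa)
  if (any(colSums(m != "-") == 0L)) stop("alignment contains all-gap column(s)")
  msa
}

new_msa <- function(ids, seqs, desc = rep("", length(ids))) {
  stopifnot(length(ids) == length(seqs))
  structure(list(ids = ids, desc = desc, seqs = seqs,
                 n_cols = if (length(seqs)) nchar(seqs[1L]) else 0L),
            class = "bce_msa")
}

# Character matrix view (rows = sequences, columns = alignment columns).
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$seqs, ""))
  rownames(m) <- msa$ids
  m
}

#' @export
print.bce_msa <- function(x, ...) {
  cat(sprintf("bce_msa: %d sequences x %d columns\n", length(x$ids), x$n_cols))
  invisible(x)
}

#' Write an alignment to aligned FASTA
#' @param msa a `bce_msa` object.
#' @param path output file.
#' @param width line-wrap width.
#' @return invisibly, `path`.
#' @export
write_msa <- function(msa, path, width = 60L) {
  write_fasta(data.frame(id = msa$ids, desc = msa$desc, seq = msa$seqs,
                         stringsAsFactors = FALSE), path, width = width)
}

#' Write a TSV report with a reproducibility header
#'
#' Every pipeline report starts with `#`-prefixed comment lines carrying the
#' tool version and the parameters the run resolved to, so a report is
#' self-describing.
#'
#' @param df the table to write.
#' @param path output file.
#' @param params named list of parameters to echo into the header.
#' @return invisibly, `path`.
#' @export
write_report <- function(df, path, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("bcescan"))
  writeLines(sprintf("# bcescan %s", ver), con)
  for (nm in names(params)) {
    writeLines(sprintf("# %s=%s", nm, paste(params[[nm]], collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
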