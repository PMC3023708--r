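#' Group component-called genes into chromosomal module clusters
#'
#' Within each contig, a maximal run of component-annotated genes in which
#' consecutive component genes are separated by at most `max_gap` intervening
#' non-component genes forms one cluster; singletons are allowed. Strand is
#' recorded but never splits a cluster: the modules are defined by physical
#' proximity, not co-orientation.
#'
#' @param features feature data.frame from [read_features()] (rank-annotated).
#' @param calls component calls from [call_components()] or
#'   [import_blast_tab()]; genes without a call, or called `none`, count as
#'   intervening.
#' @param max_gap maximum number of intervening non-component genes between
#'   consecutive members.
#' @return a list of `bce_cluster` objects, each with fields `cluster_id`,
#'   `genome_id`, `contig`, `members` (data.frame of `gene_id`, `component`,
#'   `rank`, `start`, `end`, `strand`, `pseudo`), `intervening_counts`,
#'   `composition` (named counts over RR/HK/NBD/MSD) and `cluster_class`
#'   (`NA` until [classify_cluster()]).
#' @export
build_clusters <- function(features, calls, max_gap = 3L) {
  stopifnot(is.data.frame(features), is.data.frame(calls))
  orphan <- setdiff(calls$seq_id[calls$component != "none"], features$gene_id)
  if (length(orphan)) {
    warning("component call(s) for id(s) absent from features ignored: ",
            paste(orphan, collapse = ", "))
  }
  comp <- calls$component[match(features$gene_id, calls$seq_id)]
  comp[is.na(comp)] <- "none"
  features$component <- comp
  clusters <- list()
  n_cl <- 0L
  for (key in unique(paste(features$genome_id, features$contig, sep = "\r"))) {
    sub <- features[paste(features$genome_id, features$contig, sep = "\r") == key, ,
                    drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    hits <- which(sub$component %in% COMPONENT_ORDER)
    if (!length(hits)) next
    grp <- cumsum(c(1L, diff(sub$rank[hits]) - 1L > max_gap))
    for (g in unique(grp)) {
      idx <- hits[grp == g]
      mem <- sub[idx, c("gene_id", "component", "rank", "start", "end",
                        "strand", "pseudo"), drop = FALSE]
      rownames(mem) <- NULL
      n_cl <- n_cl + 1L
      comp_counts <- table(factor(mem$component, levels = COMPONENT_ORDER))
      clusters[[n_cl]] <- structure(list(
        cluster_id = sprintf("%s|%s|cl%02d", sub$genome_id[1L],
                             sub$contig[1L], g),
        genome_id = sub$genome_id[1L], contig = sub$contig[1L],
        members = mem,
        intervening_counts = if (nrow(mem) > 1L) diff(mem$rank) - 1L else integer(0),
        composition = c(comp_counts),
        cluster_class = NA_character_), class = "bce_cluster")
    }
  }
  clusters
}

#' @export
print.bce_cluster <- function(x, ...) {
  cat(sprintf("bce_cluster %s [%s]: %s\n", x$cluster_id,
              if (is.na(x$cluster_class)) "unclassified" else x$cluster_class,
              paste(sprintf("%s(%s)", x$members$gene_id, x$members$component),
                    collapse = " ")))
  invisible(x)
}

#' Assign a composition class to a cluster
#'
#' `complete` requires at least one copy of each of RR, HK, NBD and MSD.
#' A transporter pair (only NBD/MSD present) is `foreign_regulator` when a
#' gene that is annotated as a regulator or kinase by its product text
#' (matching `response regulator|histidine kinase|sensor`, case-insensitive)
#' but NOT component-called lies within `nearby_regulator_scan` genes of the
#' cluster -- the salXY situation, where a transporter is driven by a
#' non-homologous two-component system; it is `transporter_only` when no such
#' gene and no RR/HK component call is nearby. Everything else is `partial`.
#'
#' @param cluster a `bce_cluster`.
#' @param features the feature table the cluster was built from.
#' @param calls the component calls used for clustering.
#' @param nearby_regulator_scan window, in genes on either side, scanned for
#'   regulator evidence.
#' @return the cluster with `cluster_class`, `duplicated_msd`,
#'   `duplicated_nbd` and `pseudo_members` set.
#' @export
classify_cluster <- function(cluster, features, calls,
                             nearby_regulator_scan = 5L) {
  stopifnot(inherits(cluster, "bce_cluster"))
  comp <- cluster$composition
  cluster$duplicated_msd <- unname(comp["MSD"] > 1L)
  cluster$duplicated_nbd <- unname(comp["NBD"] > 1L)
  cluster$pseudo_members <- sum(cluster$members$pseudo)
  if (all(comp[COMPONENT_ORDER] >= 1L)) {
    cluster$cluster_class <- "complete"
    return(cluster)
  }
  transporter_only_comp <- comp["RR"] == 0L && comp["HK"] == 0L &&
    (comp["NBD"] > 0L || comp["MSD"] > 0L)
  if (!transporter_only_comp) {
    cluster$cluster_class <- "partial"
    return(cluster)
  }
  sub <- features[features$genome_id == cluster$genome_id &
                    features$contig == cluster$contig, , drop = FALSE]
  lo <- min(cluster$members$rank) - nearby_regulator_scan
  hi <- max(cluster$members$rank) + nearby_regulator_scan
  nearby <- sub[sub$rank >= lo & sub$rank <= hi &
                  !sub$gene_id %in% cluster$members$gene_id, , drop = FALSE]
  nearby_comp <- calls$component[match(nearby$gene_id, calls$seq_id)]
  nearby_comp[is.na(nearby_comp)] <- "none"
  if (any(nearby_comp %in% c("RR", "HK"))) {
    # a cognate regulator pair sits just outside the gap tolerance
    cluster$cluster_class <- "partial"
    return(cluster)
  }
  foreign <- grepl("response regulator|histidine kinase|sensor",
                   nearby$product, ignore.case = TRUE) & nearby_comp == "none"
  cluster$cluster_class <- if (any(foreign)) "foreign_regulator" else "transporter_only"
  cluster
}

#' Classify every cluster in a list
#' @inheritParams classify_cluster
#' @param clusters list of `bce_cluster` objects.
#' @return the list with every cluster classified.
#' @export
classify_clusters <- function(clusters, features, calls,
                              nearby_regulator_scan = 5L) {
  lapply(clusters, classify_cluster, features = features, calls = calls,
         nearby_regulator_scan = nearby_regulator_scan)
}

#' Flat member-per-row view of a cluster list
#' @param clusters list of classified `bce_cluster` objects.
#' @return a data.frame with one row per cluster member.
#' @export
cluster_table <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(cluster_id = character(0), genome = character(0),
                      contig = character(0), cluster_class = character(0),
                      gene_id = character(0), component = character(0),
                      rank = integer(0), start = integer(0), end = integer(0),
                      strand = character(0), pseudo = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id, genome = cl$genome_id,
               contig = cl$contig, cluster_class = cl$cluster_class,
               cl$members, stringsAsFactors = FALSE)
  }))
}

#' Per-genome repertoire of module clusters
#'
#' One row per genome -- including genomes in `genomes` that have no cluster
#' at all, which are reported as zero rows (some Firmicutes carry no module
#' whatsoever).
#'
#' @param clusters list of classified `bce_cluster` objects.
#' @param genomes character vector of genome ids to report; defaults to the
#'   genomes seen in `clusters`.
#' @return a data.frame with columns `genome_id`, `clusters`, `complete`,
#'   `transporter_only`, `partial`, `foreign_regulator`, `duplicated_msd`,
#'   `duplicated_nbd`, `pseudo_members`.
#' @export
repertoire <- function(clusters, genomes = NULL) {
  cl_gen <- vapply(clusters, `[[`, "", "genome_id")
  if (is.null(genomes)) genomes <- unique(cl_gen)
  classes <- c("complete", "transporter_only", "partial", "foreign_regulator")
  rows <- lapply(genomes, function(gm) {
    cls <- clusters[cl_gen == gm]
    cc <- vapply(cls, `[[`, "", "cluster_class")
    if (length(cls) && anyNA(cc)) stop("repertoire() needs classified clusters")
    counts <- table(factor(cc, levels = classes))
    data.frame(genome_id = gm, clusters = length(cls),
               complete = unname(counts["complete"]),
               transporter_only = unname(counts["transporter_only"]),
               partial = unname(counts["partial"]),
               foreign_regulator = unname(counts["foreign_regulator"]),
               duplicated_msd = any(vapply(cls, `[[`, TRUE, "duplicated_msd")),
               duplicated_nbd = any(vapply(cls, `[[`, TRUE, "duplicated_nbd")),
               pseudo_members = sum(vapply(cls, `[[`, 0L, "pseudo_members")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
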