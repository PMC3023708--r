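SUBFAMILIES <- c("I", "II", "III", "IV", "V", "VI")

# Every edge bipartition of a tree under unrooted semantics, as the tip set
# on the child side plus the edge's support. Enumerating edges of the rooted
# representation (internal and terminal, root excluded) covers every
# bipartition of the unrooted tree; the rooting itself is never trusted.
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  supports <- node_supports(tree)
  pp <- ape::prop.part(tree)
  root <- ntip + 1L
  # a binary root's two child edges are one unrooted edge: share their support
  root_children <- tree$edge[tree$edge[, 1L] == root, 2L]
  leaf_support <- rep(NA_real_, ntip)
  if (length(root_children) == 2L) {
    ss <- ifelse(root_children > ntip, supports[root_children - ntip], NA_real_)
    unified <- if (all(is.na(ss))) NA_real_ else min(ss, na.rm = TRUE)
    for (ch in root_children) {
      if (ch > ntip) supports[ch - ntip] <- unified
      else leaf_support[ch] <- unified
    }
  }
  sides <- list()
  side_support <- numeric(0)
  for (node in seq_len(tree$Nnode) + ntip) {
    if (node == root) next
    tips <- tree$tip.label[pp[[node - ntip]]]
    sides[[length(sides) + 1L]] <- tips
    side_support <- c(side_support, supports[node - ntip])
  }
  for (leaf in seq_len(ntip)) {
    sides[[length(sides) + 1L]] <- tree$tip.label[leaf]
    # terminal edges elsewhere carry no support (trivial bipartitions)
    side_support <- c(side_support, leaf_support[leaf])
  }
  list(sides = sides, support = side_support, all_tips = tree$tip.label)
}

#' Test whether a set of leaves is monophyletic (unrooted semantics)
#'
#' True when some edge bipartition isolates exactly the given label set, i.e.
#' the set or its complement is the tip set on one side of an edge. The
#' support of that edge is returned; unannotated edges count as fully
#' supported (1.0).
#'
#' @param tree a `phylo` tree (supports normalized, see [parse_newick()]).
#' @param leaves character vector of leaf labels.
#' @return a list with `monophyletic` (logical) and `support` (numeric or
#'   `NA` when not monophyletic).
#' @export
is_monophyletic <- function(tree, leaves) {
  leaves <- unique(leaves)
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown)) {
    stop("label(s) not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(leaves) == length(tree$tip.label)) {
    return(list(monophyletic = TRUE, support = 1.0))
  }
  bp <- tree_bipartitions(tree)
  for (i in seq_along(bp$sides)) {
    side <- bp$sides[[i]]
    other <- setdiff(bp$all_tips, side)
    if (setequal(side, leaves) || setequal(other, leaves)) {
      s <- bp$support[i]
      return(list(monophyletic = TRUE, support = if (is.na(s)) 1.0 else s))
    }
  }
  list(monophyletic = FALSE, support = NA_real_)
}

#' Read a reference-leaf-to-subfamily map
#'
#' A TSV with columns `leaf_label` and `subfamily` (I-VI). The shipped
#' default map ([default_ref_map()]) contains only accessions named in the
#' survey text and is meant to be extended by the user.
#'
#' @param path TSV file.
#' @return a named character vector: leaf label -> subfamily.
#' @export
read_ref_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("leaf_label", "subfamily") %in% names(tab)))
  bad <- setdiff(tab$subfamily, SUBFAMILIES)
  if (length(bad)) stop("unknown subfamily label(s): ", paste(bad, collapse = ", "))
  stats::setNames(tab$subfamily, tab$leaf_label)
}

#' Default reference map of named subfamily anchors
#'
#' Subfamily II: the *Streptococcus mutans* Bce module (NP_721401-NP_721404)
#' and the *S. pneumoniae* transporter YP_001835606/7. Subfamily IV: the
#' *B. subtilis* Bce module itself plus the *S. aureus* VraFG transporter
#' (YP_416104/5) and its GraRS two-component system (YP_416102/3).
#' Subfamily V: the *L. monocytogenes* AnrAB transporter (NP_465638/9) and
#' the *S. pyogenes* SalXY pair (NP_269895/6). The remaining subfamilies are
#' figure-defined and must be supplied by the user.
#'
#' @return a named character vector: leaf label -> subfamily.
#' @export
default_ref_map <- function() {
  c(NP_721401 = "II", NP_721402 = "II", NP_721403 = "II", NP_721404 = "II",
    YP_001835606 = "II", YP_001835607 = "II",
    O34951 = "IV", O35044 = "IV", O34697 = "IV", O34741 = "IV",
    NP_390915 = "IV", NP_390916 = "IV",
    YP_416102 = "IV", YP_416103 = "IV", YP_416104 = "IV", YP_416105 = "IV",
    NP_465638 = "V", NP_465639 = "V", NP_269895 = "V", NP_269896 = "V")
}

#' Assign a query leaf to a subfamily from reference anchors
#'
#' Finds the smallest edge-bipartition side containing the query, at least
#' one reference leaf, and support at least `min_support` (unannotated edges
#' count as 1.0). If every reference in that side belongs to one subfamily
#' the query is assigned to it; if the side mixes subfamilies, or no side
#' qualifies, the query is `unclassified`. A query that is itself a
#' reference returns its mapped subfamily with support 1.0. The default
#' `min_support` of 0.5 matches the weakest clade support accepted in the
#' published classification (subfamily V, PP = 0.50).
#'
#' @param tree a `phylo` tree.
#' @param query leaf label to classify.
#' @param refs named character vector (leaf label -> subfamily).
#' @param min_support minimum edge support for a qualifying clade.
#' @return a list of class `bce_subfam_call` with `query`, `subfamily`
#'   (`"unclassified"` when no call), `support`, `n_refs_in_clade`.
#' @export
assign_subfamily <- function(tree, query, refs, min_support = 0.5) {
  stopifnot(length(query) == 1L)
  if (!query %in% tree$tip.label) stop("query ", query, " not in tree")
  refs <- refs[names(refs) %in% tree$tip.label]
  if (!length(refs)) stop("no reference leaf present in tree")
  if (query %in% names(refs)) {
    return(structure(list(query = query, subfamily = unname(refs[[query]]),
                          support = 1.0, n_refs_in_clade = 1L),
                     class = "bce_subfam_call"))
  }
  bp <- tree_bipartitions(tree)
  cand_idx <- integer(0)
  cand_size <- integer(0)
  cand_support <- numeric(0)
  sides <- vector("list", 0L)
  for (i in seq_along(bp$sides)) {
    for (side in list(bp$sides[[i]], setdiff(bp$all_tips, bp$sides[[i]]))) {
      if (!query %in% side) next
      n_refs <- sum(names(refs) %in% side)
      if (n_refs == 0L) next
      s <- bp$support[i]
      if (is.na(s)) s <- 1.0
      if (s < min_support) next
      sides[[length(sides) + 1L]] <- side
      cand_idx <- c(cand_idx, i)
      cand_size <- c(cand_size, length(side))
      cand_support <- c(cand_support, s)
    }
  }
  if (!length(cand_idx)) {
    return(structure(list(query = query, subfamily = "unclassified",
                          support = NA_real_, n_refs_in_clade = 0L),
                     class = "bce_subfam_call"))
  }
  best <- order(cand_size, -cand_support)[1L]
  side <- sides[[best]]
  in_refs <- refs[names(refs) %in% side]
  fams <- unique(unname(in_refs))
  if (length(fams) == 1L) {
    structure(list(query = query, subfamily = fams,
                   support = cand_support[best],
                   n_refs_in_clade = length(in_refs)),
              class = "bce_subfam_call")
  } else {
    structure(list(query = query, subfamily = "unclassified",
                   support = cand_support[best],
                   n_refs_in_clade = length(in_refs)),
              class = "bce_subfam_call")
  }
}

#' @export
print.bce_subfam_call <- function(x, ...) {
  cat(sprintf("%s -> %s (support %s, %d ref(s) in clade)\n", x$query,
              x$subfamily, format(x$support), x$n_refs_in_clade))
  invisible(x)
}

#' Assign many queries and return a table
#' @inheritParams assign_subfamily
#' @param queries character vector of leaf labels.
#' @return a data.frame with columns `query`, `subfamily`, `support`,
#'   `n_refs_in_clade`.
#' @export
assign_subfamilies <- function(tree, queries, refs, min_support = 0.5) {
  rows <- lapply(queries, function(q) {
    cl <- assign_subfamily(tree, q, refs, min_support)
    data.frame(query = cl$query, subfamily = cl$subfamily,
               support = cl$support, n_refs_in_clade = cl$n_refs_in_clade,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' A fallback tree builder (classical neighbor joining via `ape::nj`) for
#' when no externally inferred maximum-likelihood or Bayesian tree is
#' available. Input must be a symmetric matrix with zero diagonal and
#' non-negative entries; row/column names become leaf labels.
#'
#' @param d symmetric numeric distance matrix with labels.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), !is.null(rownames(d)))
  if (any(d < 0)) stop("negative distance in input matrix")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix has non-zero diagonal")
  ape::nj(d)
}

#' Poisson-corrected pairwise distances from local alignments
#'
#' Builds the distance matrix used by the [nj_tree()] fallback: for every
#' pair, the p-distance of the local alignment (gaps excluded) under the
#' correction `-ln(1 - p)`, with `p` capped just below 1 to keep distances
#' finite.
#'
#' @param seqs data.frame with `id` and `seq`.
#' @return a symmetric distance matrix.
#' @export
align_distances <- function(seqs) {
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- sw_align(seqs[i, , drop = FALSE], seqs[j, , drop = FALSE])
      p <- if (is.na(al$identity)) 0.95 else min(1 - al$identity, 0.95)
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  d
}

#' Robinson-Foulds distance between two trees on their shared leaves
#'
#' Both trees are pruned to the shared leaf set (at least four leaves
#' required) and compared as unrooted topologies; the distance is the number
#' of bipartitions present in exactly one tree. Used to quantify
#' cross-component tree congruence (co-evolving components give distances
#' near zero).
#'
#' @param t1,t2 `phylo` trees.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) {
    stop("fewer than 4 shared leaves (", length(shared), ")")
  }
  p1 <- ape::unroot(ape::keep.tip(t1, shared))
  p2 <- ape::unroot(ape::keep.tip(t2, shared))
  as.integer(phangorn::RF.dist(p1, p2, check.labels = TRUE))
}

#' Cross-component subfamily concordance of module clusters
#'
#' For each cluster, every member whose component has a tree is placed into
#' a subfamily with [assign_subfamily()]; a cluster agrees when all its
#' classified (non-`unclassified`) calls name the same subfamily. The global
#' agreement fraction is taken over clusters with at least two classified
#' components -- perfectly co-evolving components give 1.0.
#'
#' @param clusters list of `bce_cluster` objects (members' `gene_id` must
#'   match tree leaf labels).
#' @param trees named list of `phylo` trees per component (RR/HK/NBD/MSD).
#' @param refs named list of reference maps per component.
#' @param min_support passed to [assign_subfamily()].
#' @return a list of class `bce_concordance` with `per_member` (data.frame),
#'   `per_cluster` (data.frame with `agree`), and `global_agreement`.
#' @export
concordance <- function(clusters, trees, refs, min_support = 0.5) {
  stopifnot(is.list(trees), is.list(refs))
  member_rows <- list()
  cluster_rows <- list()
  for (cl in clusters) {
    mem <- cl$members
    calls <- character(0)
    for (k in seq_len(nrow(mem))) {
      comp <- mem$component[k]
      id <- mem$gene_id[k]
      if (!comp %in% names(trees)) next
      tree <- trees[[comp]]
      if (!id %in% tree$tip.label) {
        warning("cluster member ", id, " missing from ", comp, " tree")
        subfam <- "unclassified"
        supp <- NA_real_
      } else {
        sc <- assign_subfamily(tree, id, refs[[comp]], min_support)
        subfam <- sc$subfamily
        supp <- sc$support
      }
      calls <- c(calls, subfam)
      member_rows[[length(member_rows) + 1L]] <- data.frame(
        cluster_id = cl$cluster_id, gene_id = id, component = comp,
        subfamily = subfam, support = supp, stringsAsFactors = FALSE)
    }
    classified <- calls[calls != "unclassified"]
    cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
      cluster_id = cl$cluster_id, n_components = length(calls),
      n_classified = length(classified),
      agree = if (length(classified) >= 2L) length(unique(classified)) == 1L else NA,
      subfamily = if (length(classified) && length(unique(classified)) == 1L)
        classified[1L] else NA_character_,
      stringsAsFactors = FALSE)
  }
  per_cluster <- do.call(rbind, cluster_rows)
  eligible <- per_cluster[!is.na(per_cluster$agree), , drop = FALSE]
  structure(list(
    per_member = if (length(member_rows)) do.call(rbind, member_rows) else NULL,
    per_cluster = per_cluster,
    global_agreement = if (nrow(eligible)) mean(eligible$agree) else NA_real_),
    class = "bce_concordance")
}

#' @export
print.bce_concordance <- function(x, ...) {
  n <- sum(!is.na(x$per_cluster$agree))
  cat(sprintf("bce_concordance: %d cluster(s), %d with >=2 classified components, agreement %.3f\n",
              nrow(x$per_cluster), n, x$global_agreement))
  invisible(x)
}
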