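# Residue pools for constructed sequences. The hydrophilic pool keeps every
# Kyte-Doolittle value at or below -0.4 so no sliding window can reach the
# TM cutoff; the hydrophobic pool averages well above it.
AA_HYDROPHILIC <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "H", "P")
AA_HYDROPHOBIC <- c("L", "I", "V", "F", "A", "M")

rand_seq <- function(n, pool = AA_HYDROPHILIC) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# Substitute each site independently with probability p, drawing the new
# residue uniformly from the 20 standard amino acids (it may stay the same).
mutate_seq <- function(seq, p) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- stats::runif(length(chars)) < p
  chars[hit] <- sample(AA_STANDARD, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

# Segment layout of a ten-TM translocator with a given O4 loop and total
# length; every other segment keeps the canonical size and I6 absorbs the
# remainder.
msd_layout <- function(total_len, o4 = 205L) {
  kinds <- c("I", "TM", "O", "TM", "I", "TM", "O", "TM", "I", "TM", "O",
             "TM", "I", "TM", "O", "TM", "I", "TM", "O", "TM", "I")
  lens <- c(10L, 20L, 15L, 20L, 20L, 20L, 15L, 20L, 20L, 20L, 15L, 20L,
            20L, 20L, o4, 20L, 20L, 20L, 15L, 20L, NA)
  lens[21L] <- total_len - sum(lens, na.rm = TRUE)
  stopifnot(lens[21L] >= 1L)
  list(kinds = kinds, lens = lens)
}

build_seq_for_layout <- function(kinds, lens) {
  paste(vapply(seq_along(kinds), function(k) {
    rand_seq(lens[k], if (kinds[k] == "TM") AA_HYDROPHOBIC else AA_HYDROPHILIC)
  }, character(1)), collapse = "")
}

#' Synthetic seed sequences for the four module components
#'
#' A deterministic, clearly synthetic stand-in for the four *B. subtilis*
#' seed proteins (which cannot be redistributed here): one sequence per
#' component with the published seed lengths (RR 231, HK 334, NBD 253,
#' MSD 646 residues) and, for the membrane components, built-in topologies
#' that satisfy the default architecture rules -- the kinase carries two TM
#' segments with an 8-residue linker, the translocator ten TM segments with
#' a 205-residue O4 loop. Ids carry a `_syn` suffix to flag their synthetic
#' origin.
#'
#' @return a data.frame with columns `id`, `desc`, `seq`, `component`; the
#'   named list of `bce_topology` objects is attached as attribute
#'   `topologies`.
#' @export
synthetic_seeds <- function() {
  with_seed(20090201L, {
    hk_kinds <- c("I", "TM", "O", "TM", "I")
    hk_lens <- c(15L, 20L, 8L, 20L, 271L)
    msd <- msd_layout(646L)
    seeds <- data.frame(
      id = c("BceR_syn", "BceS_syn", "BceA_syn", "BceB_syn"),
      desc = c("synthetic response regulator seed component=RR",
               "synthetic intramembrane-sensing kinase seed component=HK",
               "synthetic ATP-binding protein seed component=NBD",
               "synthetic translocator seed component=MSD"),
      seq = c(rand_seq(231L),
              build_seq_for_layout(hk_kinds, hk_lens),
              rand_seq(253L),
              build_seq_for_layout(msd$kinds, msd$lens)),
      component = c("RR", "HK", "NBD", "MSD"),
      stringsAsFactors = FALSE)
    tops <- list(
      BceR_syn = topology_from_lengths("BceR_syn", "I", 231L),
      BceS_syn = topology_from_lengths("BceS_syn", hk_kinds, hk_lens),
      BceA_syn = topology_from_lengths("BceA_syn", "I", 253L),
      BceB_syn = topology_from_lengths("BceB_syn", msd$kinds, msd$lens))
    attr(seeds, "topologies") <- tops
    seeds
  })
}

#' Configuration for the synthetic genome generator
#'
#' The defaults describe the simulated study conditions: a handful of
#' genomes, one planted complete module and a small decoy complement per
#' genome, a background of hydrophilic non-module genes, and component
#' sequences at 20% site divergence from the seeds (comfortably within the
#' homolog recovery range, far above background similarity).
#'
#' @param seed integer RNG seed; identical configurations give bit-identical
#'   output.
#' @param n_genomes number of genomes to plant.
#' @param n_modules total number of complete modules planted (spread
#'   round-robin across genomes).
#' @param decoys named integer vector of decoy-unit counts by kind:
#'   `wrong_tm_count` (kinase with six TM segments), `loop_too_short`
#'   (translocator O4 of 99 residues), `loop_too_long` (O4 of 401 residues in
#'   an 850-residue translocator), `missing_component` (module lacking its
#'   translocator), `shuffled_order` (module split by a gap wider than the
#'   clustering tolerance).
#' @param n_background background genes per genome.
#' @param max_intervening maximum number of background genes planted between
#'   consecutive module members.
#' @param divergence per-site substitution probability applied to seed
#'   sequences.
#' @param shuffle_gap intervening genes inserted inside `shuffled_order`
#'   decoys; must exceed the clustering `max_gap` to split the unit.
#' @return an object of class `bce_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genomes = 5L, n_modules = 5L,
                       decoys = c(wrong_tm_count = 2L, loop_too_short = 2L,
                                  loop_too_long = 2L, missing_component = 2L,
                                  shuffled_order = 2L),
                       n_background = 30L, max_intervening = 2L,
                       divergence = 0.2, shuffle_gap = 6L) {
  kinds <- c("wrong_tm_count", "loop_too_short", "loop_too_long",
             "missing_component", "shuffled_order")
  full <- stats::setNames(rep(0L, length(kinds)), kinds)
  full[names(decoys)] <- as.integer(decoys)
  stopifnot(seed == as.integer(seed), n_genomes >= 1L, n_modules >= 0L,
            all(full >= 0L), n_background >= 0L, max_intervening >= 0L,
            divergence >= 0, divergence <= 1, shuffle_gap >= 1L)
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 n_modules = as.integer(n_modules), decoys = full,
                 n_background = as.integer(n_background),
                 max_intervening = as.integer(max_intervening),
                 divergence = divergence, shuffle_gap = as.integer(shuffle_gap)),
            class = "bce_sim_config")
}

# One planted gene: a list with id, seq, product, component, topology (or
# NULL), plus bookkeeping for the truth table.
plant_gene <- function(id, seq, product, component = "none", top = NULL) {
  list(id = id, seq = seq, product = product, component = component, top = top)
}

background_gene <- function(id) {
  products <- c("hypothetical protein", "ribosomal protein", "DNA polymerase III subunit",
                "elongation factor Tu", "cell division protein", "amino acid ligase")
  plant_gene(id, rand_seq(sample(120:280, 1L)), sample(products, 1L))
}

# Build the ordered gene list of one planted unit (module or decoy).
build_unit <- function(unit_id, kind, cfg, seeds, seed_tops, bg_counter) {
  retop <- function(top, id) topology(id, top$segments$kind,
                                      top$segments$start, top$segments$end)
  comp_gene <- function(comp, top_override = NULL, extra_tail = 0L) {
    srow <- seeds[seeds$component == comp, ]
    seq <- mutate_seq(srow$seq, cfg$divergence)
    if (extra_tail > 0L) seq <- paste0(seq, rand_seq(extra_tail))
    id <- paste(unit_id, comp, sep = "_")
    top <- if (!is.null(top_override)) retop(top_override, id)
           else retop(seed_tops[[srow$id]], id)
    prod <- c(RR = "BceR-like regulator", HK = "BceS-like kinase",
              NBD = "BceA-like ATP-binding protein",
              MSD = "BceB-like permease")[comp]
    plant_gene(id, seq, unname(prod), comp, top)
  }
  hk6 <- topology_from_lengths("x", c("I", "TM", "O", "TM", "I", "TM", "O",
                                      "TM", "I", "TM", "O", "TM", "I"),
                               c(15L, 20L, 8L, 20L, 20L, 20L, 20L, 20L, 20L,
                                 20L, 20L, 20L, 111L))
  genes <- switch(kind,
    module = list(comp_gene("RR"), comp_gene("HK"), comp_gene("NBD"),
                  comp_gene("MSD")),
    wrong_tm_count = list(comp_gene("RR"), comp_gene("HK", top_override = hk6),
                          comp_gene("NBD"), comp_gene("MSD")),
    loop_too_short = {
      lay <- msd_layout(646L, o4 = 99L)
      bad <- topology_from_lengths("x", lay$kinds, lay$lens)
      list(comp_gene("RR"), comp_gene("HK"), comp_gene("NBD"),
           comp_gene("MSD", top_override = bad))
    },
    loop_too_long = {
      lay <- msd_layout(850L, o4 = 401L)
      bad <- topology_from_lengths("x", lay$kinds, lay$lens)
      list(comp_gene("RR"), comp_gene("HK"), comp_gene("NBD"),
           comp_gene("MSD", top_override = bad, extra_tail = 204L))
    },
    missing_component = list(comp_gene("RR"), comp_gene("HK"),
                             comp_gene("NBD")),
    shuffled_order = list(comp_gene("RR"), comp_gene("HK"), comp_gene("NBD"),
                          comp_gene("MSD")),
    stop("unknown unit kind ", kind))
  # interleave background genes between consecutive members
  gaps <- if (kind == "shuffled_order") {
    c(0L, cfg$shuffle_gap, 0L)[seq_len(length(genes) - 1L)]
  } else if (length(genes) > 1L) {
    sample(0:cfg$max_intervening, length(genes) - 1L, replace = TRUE)
  } else integer(0)
  out <- list(genes[[1L]])
  for (j in seq_along(gaps)) {
    for (b in seq_len(gaps[j])) {
      bg_counter$n <- bg_counter$n + 1L
      out[[length(out) + 1L]] <- background_gene(sprintf("%s_bg%03d",
                                                         unit_id, bg_counter$n))
    }
    out[[length(out) + 1L]] <- genes[[j + 1L]]
  }
  list(genes = out, intervening = gaps,
       member_ids = vapply(genes, `[[`, "", "id"))
}

#' Plant synthetic genomes with known module truth
#'
#' Generates, deterministically under the configuration seed, a set of
#' genomes as ordered gene lists: hydrophilic background genes, complete
#' Bce-like modules whose component sequences are diverged copies of the
#' synthetic seeds with rule-conformant topologies, and decoy units that
#' each violate exactly one screening rule. Every stage of the pipeline can
#' be validated against the returned truth tables.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `bce_sim`: a list with `config`, `features`
#'   (rank-annotated feature table), `proteome` (FASTA-style data.frame),
#'   `topologies` (named list of `bce_topology`), `seeds`, and `truth` (a
#'   list with `units` and `proteins` data.frames).
#' @export
plant_genome <- function(cfg) {
  stopifnot(inherits(cfg, "bce_sim_config"))
  seeds <- synthetic_seeds()
  seed_tops <- attr(seeds, "topologies")
  with_seed(cfg$seed, {
    genomes <- sprintf("g%02d", seq_len(cfg$n_genomes))
    units <- character(0)
    unit_kind <- character(0)
    unit_genome <- character(0)
    gi <- 0L
    abbrev <- c(module = "mod", wrong_tm_count = "dtm", loop_too_short = "dls",
                loop_too_long = "dll", missing_component = "dmc",
                shuffled_order = "dso")
    assign_units <- function(kind, n) {
      for (k in seq_len(n)) {
        gi <<- gi + 1L
        units <<- c(units, sprintf("%s_%s%02d",
                                   genomes[(gi - 1L) %% cfg$n_genomes + 1L],
                                   abbrev[[kind]], k))
        unit_kind <<- c(unit_kind, kind)
        unit_genome <<- c(unit_genome, genomes[(gi - 1L) %% cfg$n_genomes + 1L])
      }
    }
    assign_units("module", cfg$n_modules)
    for (dk in names(cfg$decoys)) assign_units(dk, cfg$decoys[[dk]])

    feat_rows <- list()
    prot_rows <- list()
    tops <- list()
    unit_rows <- list()
    protein_truth <- list()
    for (gm in genomes) {
      bg_counter <- new.env()
      bg_counter$n <- 0L
      gene_list <- list()
      # leading background block
      for (b in seq_len(max(1L, cfg$n_background %/% 2L))) {
        bg_counter$n <- bg_counter$n + 1L
        gene_list[[length(gene_list) + 1L]] <- background_gene(
          sprintf("%s_bg%03d", gm, bg_counter$n))
      }
      my_units <- which(unit_genome == gm)
      for (u in my_units) {
        built <- build_unit(units[u], unit_kind[u], cfg, seeds, seed_tops,
                            bg_counter)
        gene_list <- c(gene_list, built$genes)
        # spacer background genes so consecutive units never merge
        for (b in seq_len(cfg$shuffle_gap)) {
          bg_counter$n <- bg_counter$n + 1L
          gene_list[[length(gene_list) + 1L]] <- background_gene(
            sprintf("%s_bg%03d", gm, bg_counter$n))
        }
        unit_rows[[length(unit_rows) + 1L]] <- data.frame(
          unit_id = units[u], genome = gm, kind = unit_kind[u],
          n_members = length(built$member_ids),
          member_ids = paste(built$member_ids, collapse = ";"),
          intervening = paste(built$intervening, collapse = ";"),
          complete_expected = unit_kind[u] == "module",
          stringsAsFactors = FALSE)
      }
      # trailing background block
      extra <- cfg$n_background - cfg$n_background %/% 2L
      for (b in seq_len(max(1L, extra))) {
        bg_counter$n <- bg_counter$n + 1L
        gene_list[[length(gene_list) + 1L]] <- background_gene(
          sprintf("%s_bg%03d", gm, bg_counter$n))
      }
      pos <- 101L
      for (g in gene_list) {
        len_nt <- 3L * nchar(g$seq) + 3L
        feat_rows[[length(feat_rows) + 1L]] <- data.frame(
          gene_id = g$id, genome_id = gm, contig = paste0(gm, "_c1"),
          start = pos, end = pos + len_nt - 1L, strand = "+",
          product = g$product, pseudo = FALSE, stringsAsFactors = FALSE)
        pos <- pos + len_nt + 100L
        prot_rows[[length(prot_rows) + 1L]] <- data.frame(
          id = g$id, desc = g$product, seq = g$seq, stringsAsFactors = FALSE)
        if (!is.null(g$top)) tops[[g$id]] <- g$top
        protein_truth[[length(protein_truth) + 1L]] <- data.frame(
          gene_id = g$id, genome = gm, component = g$component,
          stringsAsFactors = FALSE)
      }
    }
    features <- validate_features(do.call(rbind, feat_rows))
    structure(list(
      config = cfg,
      features = features,
      proteome = do.call(rbind, prot_rows),
      topologies = tops,
      seeds = seeds,
      truth = list(
        units = if (length(unit_rows)) do.call(rbind, unit_rows) else NULL,
        proteins = do.call(rbind, protein_truth))),
      class = "bce_sim")
  })
}

#' @export
print.bce_sim <- function(x, ...) {
  cat(sprintf("bce_sim: %d genomes, %d genes, %d planted unit(s)\n",
              x$config$n_genomes, nrow(x$features),
              if (is.null(x$truth$units)) 0L else nrow(x$truth$units)))
  invisible(x)
}

#' Write a simulated dataset to disk in the formats the readers accept
#'
#' Emits `proteome.faa`, `features.tsv`, `topology.tmhmm`, `seeds.faa`,
#' `truth_units.tsv` and `truth_proteins.tsv` under `dir`.
#'
#' @param sim a `bce_sim` from [plant_genome()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_sim_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "bce_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(proteome = file.path(dir, "proteome.faa"),
             features = file.path(dir, "features.tsv"),
             topology = file.path(dir, "topology.tmhmm"),
             seeds = file.path(dir, "seeds.faa"),
             truth_units = file.path(dir, "truth_units.tsv"),
             truth_proteins = file.path(dir, "truth_proteins.tsv"))
  write_fasta(sim$proteome, paths["proteome"])
  write_features(sim$features, paths["features"])
  write_tmhmm(sim$topologies, paths["topology"])
  write_fasta(sim$seeds, paths["seeds"])
  utils::write.table(sim$truth$units, paths["truth_units"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$proteins, paths["truth_proteins"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Evolve a protein family along a tree with per-site rates
#'
#' Each site evolves independently down the tree: on a branch of length `b`,
#' a site with rate `r` is substituted with probability `1 - exp(-r b)`, the
#' replacement drawn uniformly from the 20 standard residues (a
#' Jukes-Cantor-style model on 20 states, so the substitution may restore
#' the ancestral residue). Under this model the expected identity between
#' two leaves joined by total path length `d` is
#' `exp(-r d) + (1 - exp(-r d)) / 20`. No indels are introduced, so the true
#' alignment is the leaf sequences themselves. Randomness is drawn from the
#' current RNG state; seed it for reproducibility.
#'
#' @param ancestor residue string (or one-row data.frame with `id`, `seq`)
#'   at the root.
#' @param tree a `phylo` tree with branch lengths.
#' @param site_rates numeric vector of per-site rates, one per ancestor
#'   residue (recycled if length 1).
#' @return a list with `leaves` (data.frame `id`, `seq`), `alignment`
#'   (a gap-free `bce_msa`), `tree`.
#' @export
evolve_family <- function(ancestor, tree, site_rates) {
  if (is.data.frame(ancestor)) ancestor <- ancestor$seq[1L]
  stopifnot(is.character(ancestor), length(ancestor) == 1L)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  chars <- strsplit(ancestor, "")[[1L]]
  L <- length(chars)
  if (length(site_rates) == 1L) site_rates <- rep(site_rates, L)
  if (length(site_rates) != L) {
    stop("site_rates length (", length(site_rates),
         ") does not match ancestor length (", L, ")")
  }
  if (any(site_rates < 0)) stop("negative site rate")
  ntip <- length(tree$tip.label)
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- chars
  edges <- tree$edge
  for (e in seq_len(nrow(edges))) {        # cladewise order: parents first
    parent <- edges[e, 1L]
    child <- edges[e, 2L]
    p <- 1 - exp(-site_rates * tree$edge.length[e])
    st <- states[[parent]]
    hit <- stats::runif(L) < p
    if (any(hit)) st[hit] <- sample(AA_STANDARD, sum(hit), replace = TRUE)
    states[[child]] <- st
  }
  leaves <- data.frame(
    id = tree$tip.label,
    seq = vapply(seq_len(ntip), function(i) paste(states[[i]], collapse = ""),
                 character(1)),
    stringsAsFactors = FALSE)
  list(leaves = leaves, alignment = new_msa(leaves$id, leaves$seq),
       tree = tree)
}

# Ladder newick subtree over leaf name strings with per-node supports drawn
# by sup_fun(); each item may itself be a parenthesized subtree string.
ladder_newick <- function(items, sup_fun, brlen) {
  out <- items[1L]
  if (length(items) > 1L) {
    for (it in items[-1L]) {
      out <- sprintf("(%s,%s)%s:%g", out, it, sup_fun(), brlen)
    }
  }
  out
}

#' Plant reference trees with labelled subfamily clades and query truth
#'
#' Builds, per component, a tree containing six (five for RR/HK, which have
#' no transporter-only subfamily VI) monophyletic reference clades plus
#' query leaves attached inside known clades. All supports equal `support`
#' except a fraction `low_support_frac` downgraded to `low_support` to
#' exercise the unclassified path. Query groups share a subfamily across all
#' component trees, so planted clusters are perfectly concordant.
#'
#' @param n_refs reference leaves per subfamily and component.
#' @param n_queries number of query groups (spread round-robin over
#'   subfamilies I-V).
#' @param components component trees to build.
#' @param support support value written at every internal node.
#' @param low_support_frac fraction of internal nodes downgraded.
#' @param low_support the downgraded support value.
#' @param seed RNG seed (placement of downgraded nodes).
#' @param brlen branch length used throughout.
#' @return a list of class `bce_ref_bundle` with `trees` (named list of
#'   `phylo`), `refs` (named list of leaf->subfamily maps), `truth`
#'   (data.frame `group`, `subfamily`), and `query_leaves` (data.frame
#'   `group`, `component`, `leaf`).
#' @export
plant_reference_trees <- function(n_refs = 3L, n_queries = 12L,
                                  components = c("RR", "HK", "NBD", "MSD"),
                                  support = 1.0, low_support_frac = 0,
                                  low_support = 0.4, seed = 1L, brlen = 0.1) {
  stopifnot(n_refs >= 2L, n_queries >= 0L)
  with_seed(seed, {
    groups <- sprintf("q%03d", seq_len(n_queries))
    group_subfam <- SUBFAMILIES[1:5][(seq_len(n_queries) - 1L) %% 5L + 1L]
    trees <- list()
    refs <- list()
    q_rows <- list()
    for (comp in components) {
      fams <- if (comp %in% c("RR", "HK")) SUBFAMILIES[1:5] else SUBFAMILIES
      sup_fun <- function() {
        s <- if (stats::runif(1L) < low_support_frac) low_support else support
        format(s, trim = TRUE)
      }
      clade_strs <- character(0)
      ref_map <- character(0)
      for (fam in fams) {
        ref_leaves <- sprintf("ref%s_%s_%02d", fam, comp, seq_len(n_refs))
        ref_map[ref_leaves] <- fam
        q_leaves <- character(0)
        for (k in which(group_subfam == fam)) {
          leaf <- sprintf("%s_%s", groups[k], comp)
          q_leaves <- c(q_leaves, leaf)
          q_rows[[length(q_rows) + 1L]] <- data.frame(
            group = groups[k], component = comp, leaf = leaf,
            stringsAsFactors = FALSE)
        }
        leaves <- paste0(c(ref_leaves, q_leaves), ":", brlen)
        clade_strs <- c(clade_strs, ladder_newick(leaves, sup_fun, brlen))
      }
      text <- paste0("(", ladder_newick(clade_strs, sup_fun, 2 * brlen), ",",
                     sprintf("out_%s:%g", comp, 4 * brlen), ");")
      trees[[comp]] <- parse_newick(text)
      refs[[comp]] <- ref_map
    }
    structure(list(trees = trees, refs = refs,
                   truth = data.frame(group = groups, subfamily = group_subfam,
                                      stringsAsFactors = FALSE),
                   query_leaves = do.call(rbind, q_rows)),
              class = "bce_ref_bundle")
  })
}

#' Build module-cluster stand-ins from planted query groups
#'
#' Turns each planted query group into a minimal cluster object (one member
#' per component) whose member ids are the component-tree leaf labels, for
#' feeding [concordance()] directly.
#'
#' @param bundle a `bce_ref_bundle` from [plant_reference_trees()].
#' @return a list of `bce_cluster` objects.
#' @export
sim_clusters_from_groups <- function(bundle) {
  stopifnot(inherits(bundle, "bce_ref_bundle"))
  lapply(split(bundle$query_leaves, bundle$query_leaves$group), function(d) {
    mem <- data.frame(gene_id = d$leaf, component = d$component,
                      rank = seq_len(nrow(d)) - 1L, start = 1L, end = 1L,
                      strand = "+", pseudo = FALSE, stringsAsFactors = FALSE)
    structure(list(cluster_id = d$group[1L], genome_id = "sim", contig = "sim",
                   members = mem, intervening_counts = rep(0L, nrow(d) - 1L),
                   composition = table(factor(mem$component,
                                              levels = COMPONENT_ORDER)),
                   cluster_class = "complete"),
              class = "bce_cluster")
  })
}
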