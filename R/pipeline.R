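#' Scan a genome for Bce-like module clusters
#'
#' Runs the full screening pipeline: component calling against the four
#' seeds, architecture filtering of the membrane components, chromosomal
#' clustering, and composition classification. A protein called HK must pass
#' the kinase architecture rule and a protein called MSD the translocator
#' rule, otherwise its call is demoted to `none` before clustering (most
#' kinase homologs have the wrong number of TM segments or longer loops and
#' must not seed clusters); RR and NBD have no architecture gate -- no
#' topology constraint is defined for them and their Bce-like status comes
#' from homology and, downstream, tree placement.
#'
#' @param proteome data.frame from [read_fasta()].
#' @param features feature table from [read_features()].
#' @param topologies named list of `bce_topology`; if `NULL` and
#'   `use_fallback` is `TRUE`, topologies of HK/MSD candidates are predicted
#'   from hydropathy with a prominent warning.
#' @param seeds tagged seed data.frame (default [synthetic_seeds()]).
#' @param rules architecture rules, e.g. [default_rules()] or a
#'   [rule_preset()].
#' @param min_norm_score component-calling threshold, see [call_components()].
#' @param max_gap clustering gap tolerance, see [build_clusters()].
#' @param nearby_regulator_scan see [classify_cluster()].
#' @param use_fallback allow the hydropathy fallback when `topologies` is
#'   `NULL`.
#' @return an object of class `bce_scan`: a list with `calls` (component
#'   calls after the architecture gate, plus column `raw_component`),
#'   `architecture` (screen table for HK/MSD candidates), `clusters`
#'   (classified), `repertoire`, and `params`.
#' @export
scan_modules <- function(proteome, features, topologies = NULL,
                         seeds = synthetic_seeds(), rules = default_rules(),
                         min_norm_score = 0.2, max_gap = 3L,
                         nearby_regulator_scan = 5L, use_fallback = TRUE) {
  params <- list(min_norm_score = min_norm_score, max_gap = max_gap,
                 nearby_regulator_scan = nearby_regulator_scan,
                 hk_rule = rules$hk$name, hk_loop = c(rules$hk$loop_min, rules$hk$loop_max),
                 msd_rule = rules$msd$name,
                 msd_loop = c(rules$msd$loop_min, rules$msd$loop_max))
  calls <- call_components(proteome, seeds, min_norm_score = min_norm_score)
  calls$raw_component <- calls$component
  gate <- list(HK = rules$hk, MSD = rules$msd)
  gated_ids <- calls$seq_id[calls$component %in% names(gate)]
  if (is.null(topologies) && length(gated_ids)) {
    if (!use_fallback) {
      stop("no topologies supplied and the hydropathy fallback is disabled")
    }
    warning("no topology file supplied: predicting topologies of ",
            length(gated_ids), " membrane-component candidate(s) ",
            "by hydropathy (sliding-window fallback, not TMHMM)")
    topologies <- predict_topologies(
      proteome[proteome$id %in% gated_ids, , drop = FALSE])
  }
  arch_tabs <- list()
  for (comp in names(gate)) {
    ids <- calls$seq_id[calls$component == comp]
    if (!length(ids)) next
    tab <- screen_proteome(topologies[intersect(ids, names(topologies))],
                           rules = stats::setNames(list(gate[[comp]]),
                                                   gate[[comp]]$name),
                           expect_ids = ids)
    arch_tabs[[comp]] <- tab
    failed <- tab$seq_id[!tab$passed]
    calls$component[calls$seq_id %in% failed] <- "none"
  }
  architecture <- if (length(arch_tabs)) do.call(rbind, arch_tabs) else NULL
  if (!is.null(architecture)) rownames(architecture) <- NULL
  clusters <- build_clusters(features, calls, max_gap = max_gap)
  clusters <- classify_clusters(clusters, features, calls,
                                nearby_regulator_scan = nearby_regulator_scan)
  rep_tab <- repertoire(clusters, genomes = unique(features$genome_id))
  structure(list(calls = calls, architecture = architecture,
                 clusters = clusters, repertoire = rep_tab, params = params),
            class = "bce_scan")
}

#' @export
print.bce_scan <- function(x, ...) {
  comp_counts <- table(factor(x$calls$component,
                              levels = c(COMPONENT_ORDER, "none")))
  cat("bce_scan\n")
  cat("  component calls:",
      paste(sprintf("%s=%d", names(comp_counts), comp_counts), collapse = " "),
      "\n")
  classes <- vapply(x$clusters, `[[`, "", "cluster_class")
  if (length(classes)) {
    cc <- table(classes)
    cat("  clusters:", paste(sprintf("%s=%d", names(cc), cc), collapse = " "),
        "\n")
  } else {
    cat("  clusters: none\n")
  }
  invisible(x)
}

#' Write the scan reports to a directory
#'
#' Emits `architecture.tsv`, `clusters.tsv` and `repertoire.tsv`, each with
#' a reproducibility header echoing the resolved parameters.
#'
#' @param scan a `bce_scan`.
#' @param dir output directory.
#' @return invisibly, the vector of written paths.
#' @export
write_scan_reports <- function(scan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(architecture = file.path(dir, "architecture.tsv"),
             clusters = file.path(dir, "clusters.tsv"),
             repertoire = file.path(dir, "repertoire.tsv"))
  arch <- scan$architecture
  if (is.null(arch)) {
    arch <- data.frame(seq_id = character(0), rule = character(0),
                       passed = logical(0), tm_count = integer(0),
                       loop_len = integer(0), loop_side = character(0),
                       failures = character(0))
  }
  write_report(arch, paths["architecture"], scan$params)
  write_report(cluster_table(scan$clusters), paths["clusters"], scan$params)
  write_report(scan$repertoire, paths["repertoire"], scan$params)
  invisible(paths)
}

#' Compare detected complete clusters against a planted truth
#'
#' Matches detected `complete` clusters to planted complete modules by
#' exact member-id sets and reports precision and recall; used by the
#' end-to-end validation of the pipeline on synthetic genomes.
#'
#' @param scan a `bce_scan`.
#' @param sim the `bce_sim` the scan ran on.
#' @return a list with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
score_against_truth <- function(scan, sim) {
  stopifnot(inherits(scan, "bce_scan"), inherits(sim, "bce_sim"))
  planted <- sim$truth$units
  truth_sets <- lapply(strsplit(
    planted$member_ids[planted$complete_expected], ";"), sort)
  detected <- scan$clusters[vapply(scan$clusters, `[[`, "", "cluster_class") ==
                              "complete"]
  det_sets <- lapply(detected, function(cl) sort(cl$members$gene_id))
  matched <- vapply(det_sets, function(s) {
    any(vapply(truth_sets, identical, TRUE, x = s))
  }, TRUE)
  tp <- sum(matched)
  fp <- length(det_sets) - tp
  fn <- length(truth_sets) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (length(det_sets)) tp / length(det_sets) else NA_real_,
       recall = if (length(truth_sets)) tp / length(truth_sets) else NA_real_)
}
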