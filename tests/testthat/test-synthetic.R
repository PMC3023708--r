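test_that("synthetic seeds have the published dimensions and pass the rules", {
  seeds <- synthetic_seeds()
  expect_equal(nchar(seeds$seq),
               c(231L, 334L, 253L, 646L))   # RR, HK, NBD, MSD seed lengths
  tops <- attr(seeds, "topologies")
  rules <- default_rules()
  expect_true(classify_architecture(tops$BceS_syn, rules$hk)$passed)
  expect_true(classify_architecture(tops$BceB_syn, rules$msd)$passed)
  expect_equal(inter_tm_loops(tops$BceB_syn)$length[7], 205L)
  # deterministic: two calls give identical sequences
  expect_identical(seeds, synthetic_seeds())
})

test_that("identical configurations give byte-identical output files", {
  cfg <- sim_config(seed = 11L, n_genomes = 2L, n_modules = 2L,
                    decoys = c(wrong_tm_count = 1L), n_background = 6L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_sim_bundle(plant_genome(cfg), d1)
  p2 <- write_sim_bundle(plant_genome(cfg), d2)
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
  }
})

test_that("planted truth round-trips through the emitted files", {
  cfg <- sim_config(seed = 13L, n_genomes = 2L, n_modules = 3L,
                    decoys = c(loop_too_short = 1L, missing_component = 1L),
                    n_background = 8L)
  sim <- plant_genome(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_bundle(sim, dir)
  prot <- read_fasta(paths["proteome"])
  feat <- read_features(paths["features"], "tsv")
  tops <- parse_tmhmm(paths["topology"])
  expect_setequal(prot$id, sim$proteome$id)
  expect_equal(feat$gene_id, sim$features$gene_id)
  expect_equal(feat$rank, sim$features$rank)
  # every planted id exists in the emitted files and vice versa
  planted_ids <- unlist(strsplit(sim$truth$units$member_ids, ";"))
  expect_true(all(planted_ids %in% prot$id))
  expect_true(all(planted_ids %in% feat$gene_id))
  expect_setequal(names(tops), names(sim$topologies))
  expect_equal(tops[[planted_ids[1]]]$segments,
               sim$topologies[[planted_ids[1]]]$segments)
})

test_that("module members pass and each decoy fails for its planted reason", {
  cfg <- sim_config(seed = 17L, n_genomes = 3L, n_modules = 3L,
                    decoys = c(wrong_tm_count = 2L, loop_too_short = 2L,
                               loop_too_long = 2L, missing_component = 2L,
                               shuffled_order = 2L),
                    n_background = 10L)
  sim <- plant_genome(cfg)
  rules <- default_rules()
  units <- sim$truth$units
  for (u in seq_len(nrow(units))) {
    ids <- strsplit(units$member_ids[u], ";")[[1]]
    comps <- sub(".*_", "", ids)
    for (j in seq_along(ids)) {
      top <- sim$topologies[[ids[j]]]
      if (comps[j] == "HK") {
        call <- classify_architecture(top, rules$hk)
        if (units$kind[u] == "wrong_tm_count") {
          expect_false(call$passed)
          expect_equal(call$failures, "tm_count_mismatch")
        } else {
          expect_true(call$passed)
        }
      } else if (comps[j] == "MSD") {
        call <- classify_architecture(top, rules$msd)
        if (units$kind[u] %in% c("loop_too_short", "loop_too_long")) {
          expect_false(call$passed)
          expect_equal(call$failures, "loop_out_of_range")
        } else {
          expect_true(call$passed)
        }
      }
    }
    if (units$kind[u] == "missing_component") {
      expect_false("MSD" %in% comps)
    }
  }
})

test_that("zero-length branches leave every leaf equal to the ancestor", {
  tree <- parse_newick("((a:0,b:0):0,c:0);")
  anc <- strrep("MKTLIVAEDR", 5)
  fam <- evolve_family(anc, tree, 1.0)
  expect_true(all(fam$leaves$seq == anc))
})

test_that("an extreme rate randomizes a site to background identity", {
  tree <- parse_newick("(a:5,b:5);")
  anc <- strrep("A", 4000)
  set.seed(97)
  fam <- evolve_family(anc, tree, 50)
  a <- strsplit(fam$leaves$seq[1], "")[[1]]
  b <- strsplit(fam$leaves$seq[2], "")[[1]]
  obs <- mean(a == b)
  # identity between independent uniform draws is 1/20
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(obs - 0.05), 4 * se)
})

test_that("evolve_family validates rates and lengths", {
  tree <- parse_newick("(a:1,b:1);")
  expect_error(evolve_family("MKT", tree, c(-1, 1, 1)), "negative")
  expect_error(evolve_family("MKT", tree, c(1, 1)), "length")
})

test_that("planted reference trees recover truth or go unclassified", {
  high <- plant_reference_trees(n_refs = 3L, n_queries = 15L, seed = 19)
  msd_leaves <- high$query_leaves[high$query_leaves$component == "MSD", ]
  tab <- assign_subfamilies(high$trees$MSD, msd_leaves$leaf, high$refs$MSD)
  truth <- high$truth$subfamily[match(msd_leaves$group, high$truth$group)]
  expect_equal(tab$subfamily, truth)

  low <- plant_reference_trees(n_refs = 3L, n_queries = 15L, seed = 19,
                               support = 0.4)
  rr_leaves <- low$query_leaves[low$query_leaves$component == "RR", ]
  tab2 <- assign_subfamilies(low$trees$RR, rr_leaves$leaf, low$refs$RR,
                             min_support = 0.5)
  expect_true(all(tab2$subfamily == "unclassified"))

  # RR/HK trees carry no transporter-only subfamily VI references
  expect_false("VI" %in% low$refs$RR)
  expect_true("VI" %in% high$refs$MSD)
})
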