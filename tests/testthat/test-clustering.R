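test_that("contiguous components form one cluster; wide gaps split", {
  feat <- make_features(sprintf("g%02d", 1:12))
  # RR,HK at ranks 1-2, then 5 intervening, then NBD,MSD at ranks 8-9
  calls <- make_calls(c("g02", "g03", "g09", "g10"),
                      c("RR", "HK", "NBD", "MSD"))
  cl3 <- build_clusters(feat, calls, max_gap = 3L)
  expect_length(cl3, 2L)
  cl5 <- build_clusters(feat, calls, max_gap = 5L)
  expect_length(cl5, 1L)
  expect_equal(cl5[[1]]$intervening_counts, c(0L, 5L, 0L))

  # a contiguous four-component run, with intervening counts all zero
  calls2 <- make_calls(c("g05", "g06", "g07", "g08"),
                       c("RR", "HK", "NBD", "MSD"))
  one <- build_clusters(feat, calls2, max_gap = 3L)
  expect_length(one, 1L)
  expect_equal(one[[1]]$intervening_counts, c(0L, 0L, 0L))
  expect_equal(one[[1]]$members$component, c("RR", "HK", "NBD", "MSD"))

  # a lone translocator gene is a singleton cluster
  lone <- build_clusters(feat, make_calls("g04", "MSD"))
  expect_length(lone, 1L)
  expect_equal(nrow(lone[[1]]$members), 1L)
})

test_that("clusters partition the component genes and shrink with max_gap", {
  set.seed(53)
  for (rep in 1:20) {
    n <- 30L
    feat <- make_features(sprintf("x%02d", 1:n))
    comp_idx <- sort(sample(n, sample(3:10, 1)))
    calls <- make_calls(feat$gene_id[comp_idx],
                        sample(c("RR", "HK", "NBD", "MSD"),
                               length(comp_idx), replace = TRUE))
    prev <- Inf
    for (gap in c(0L, 2L, 4L, 8L)) {
      cls <- build_clusters(feat, calls, max_gap = gap)
      got <- sort(unlist(lapply(cls, function(cl) cl$members$gene_id)))
      expect_equal(got, sort(feat$gene_id[comp_idx]))   # exact partition
      expect_lte(length(cls), prev)                     # monotone in max_gap
      prev <- length(cls)
      # agreement with the exhaustive gap-scan oracle
      oracle <- cluster_oracle(feat$rank, feat$gene_id %in% calls$seq_id, gap)
      expect_length(cls, length(oracle))
    }
  }
})

test_that("calls for unknown genes warn and are ignored", {
  feat <- make_features(c("a1", "a2"))
  calls <- make_calls(c("a1", "phantom"), c("RR", "MSD"))
  expect_warning(cls <- build_clusters(feat, calls), "phantom")
  expect_length(cls, 1L)
})

test_that("composition classes follow the published categories", {
  ids <- sprintf("y%02d", 1:10)
  feat <- make_features(ids)
  mk <- function(calls) {
    cls <- build_clusters(feat, calls)
    classify_clusters(cls, feat, calls)
  }
  # at least one copy of each component: complete
  complete <- mk(make_calls(ids[1:4], c("RR", "HK", "NBD", "MSD")))
  expect_equal(complete[[1]]$cluster_class, "complete")

  # duplicated translocator genes stay one complete cluster, flagged
  dup <- mk(make_calls(ids[1:6], c("RR", "HK", "NBD", "MSD", "MSD", "MSD")))
  expect_equal(dup[[1]]$cluster_class, "complete")
  expect_true(dup[[1]]$duplicated_msd)
  expect_false(dup[[1]]$duplicated_nbd)

  # transporter pair with nothing regulatory nearby
  alone <- mk(make_calls(ids[5:6], c("NBD", "MSD")))
  expect_equal(alone[[1]]$cluster_class, "transporter_only")

  # transporter pair next to a non-homologous sensor kinase gene
  feat2 <- make_features(ids, products = c(rep("", 3),
                                           "sensor histidine kinase",
                                           rep("", 6)))
  calls2 <- make_calls(ids[5:6], c("NBD", "MSD"))
  cls2 <- classify_clusters(build_clusters(feat2, calls2), feat2, calls2)
  expect_equal(cls2[[1]]$cluster_class, "foreign_regulator")

  # an RR/HK pair without its transporter is partial
  partial <- mk(make_calls(ids[1:2], c("RR", "HK")))
  expect_equal(partial[[1]]$cluster_class, "partial")

  # a cognate HK just outside the clustering gap keeps the pair partial
  calls3 <- make_calls(c(ids[2], ids[7:8]), c("HK", "NBD", "MSD"))
  cls3 <- classify_clusters(build_clusters(feat, calls3, max_gap = 3L),
                            feat, calls3)
  expect_length(cls3, 2L)
  tr <- cls3[[which(vapply(cls3, function(x) nrow(x$members), 1L) == 2L)]]
  expect_equal(tr$cluster_class, "partial")
})

test_that("repertoire reports zero rows for module-free genomes", {
  ids <- sprintf("z%02d", 1:8)
  feat <- make_features(ids)
  calls <- make_calls(ids[1:6], c("RR", "HK", "NBD", "MSD", "NBD", "MSD"))
  cls <- classify_clusters(build_clusters(feat, calls, max_gap = 0L),
                           feat, calls)
  rep_tab <- repertoire(cls, genomes = c("g1", "empty_genome"))
  expect_equal(nrow(rep_tab), 2L)
  g1 <- rep_tab[rep_tab$genome_id == "g1", ]
  expect_equal(g1$clusters, g1$complete + g1$transporter_only +
                 g1$partial + g1$foreign_regulator)
  none <- rep_tab[rep_tab$genome_id == "empty_genome", ]
  expect_equal(none$clusters, 0L)
  expect_equal(none$complete, 0L)
})

test_that("pseudogene members count toward composition but are tallied", {
  ids <- sprintf("p%02d", 1:4)
  feat <- make_features(ids, pseudo = c(FALSE, FALSE, FALSE, TRUE))
  calls <- make_calls(ids, c("RR", "HK", "NBD", "MSD"))
  cls <- classify_clusters(build_clusters(feat, calls), feat, calls)
  expect_equal(cls[[1]]$cluster_class, "complete")
  expect_equal(cls[[1]]$pseudo_members, 1L)
  expect_equal(repertoire(cls)$pseudo_members, 1L)
})
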