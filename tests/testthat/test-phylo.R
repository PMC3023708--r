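test_that("monophyly uses unrooted bipartition semantics with supports", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B"))$monophyletic)
  expect_false(is_monophyletic(tr, c("A", "C"))$monophyletic)
  # the complement of a clade is monophyletic on the unrooted tree
  expect_true(is_monophyletic(tr, c("C", "D"))$monophyletic)

  tr2 <- parse_newick("((A,B)0.97,(C,D));")
  m <- is_monophyletic(tr2, c("A", "B"))
  expect_true(m$monophyletic)
  expect_equal(m$support, 0.97)

  expect_error(is_monophyletic(tr, c("A", "Z")), "Z")
})

test_that("subfamily assignment follows the smallest supported clade", {
  refs <- c(r4a = "IV", r4b = "IV", r2a = "II", r5a = "V")
  tr <- parse_newick("(((q1,r4a)1.0,r4b)1.0,((r2a,q2)0.9,(r5a,q3)0.5)0.9);")

  # query sister to a subfamily-IV reference inside fully supported clades
  call <- assign_subfamily(tr, "q1", refs)
  expect_equal(call$subfamily, "IV")
  expect_equal(call$support, 1.0)

  # support exactly at the threshold still qualifies (weakest published
  # subfamily was accepted at PP = 0.50)
  expect_equal(assign_subfamily(tr, "q3", refs, min_support = 0.5)$subfamily, "V")

  # raising the threshold above the best clade leaves the query unclassified
  # (the next supported clade mixes subfamilies II and V)
  expect_equal(assign_subfamily(tr, "q3", refs, min_support = 0.6)$subfamily,
               "unclassified")

  # a reference queried directly returns its own subfamily at full support
  self <- assign_subfamily(tr, "r2a", refs, min_support = 0)
  expect_equal(self$subfamily, "II")
  expect_equal(self$support, 1.0)
})

test_that("a smallest clade mixing subfamilies is unclassified", {
  refs <- c(rII = "II", rV = "V")
  tr <- parse_newick("(((rII,rV)1.0,q1)1.0,(x1,x2));")
  expect_equal(assign_subfamily(tr, "q1", refs)$subfamily, "unclassified")
})

test_that("nj_tree solves the 3-taxon case exactly and inverts additivity", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  # three-point closed form: a=(dAB+dAC-dBC)/2 etc.
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))

  src <- parse_newick("((A:1,B:2):1,(C:1,D:3):1);")
  d4 <- ape::cophenetic.phylo(src)
  expect_equal(rf_distance(nj_tree(d4), src), 0L)

  d[1, 2] <- d[2, 1] <- -1
  expect_error(nj_tree(d), "negative")
})

test_that("RF distance is the textbook bipartition count and a metric", {
  t1 <- parse_newick("((A,B),(C,D));")
  t2 <- parse_newick("((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_equal(rf_distance(t1, t2), rf_distance(t2, t1))

  set.seed(61)
  trees <- replicate(3, ape::rtree(8), simplify = FALSE)
  # identity and symmetry
  for (tr in trees) expect_equal(rf_distance(tr, tr), 0L)
  # triangle inequality spot-check
  d12 <- rf_distance(trees[[1]], trees[[2]])
  d23 <- rf_distance(trees[[2]], trees[[3]])
  d13 <- rf_distance(trees[[1]], trees[[3]])
  expect_lte(d13, d12 + d23)

  # pruning to shared leaves then self-comparison is 0
  big <- ape::rtree(12)
  small <- ape::keep.tip(big, big$tip.label[1:6])
  expect_equal(rf_distance(big, small), 0L)

  t3 <- parse_newick("((A,B),E);")
  expect_error(rf_distance(t1, t3), "4 shared")
})

test_that("concordance agrees on planted clusters and flags conflicts", {
  bundle <- plant_reference_trees(n_refs = 3L, n_queries = 10L, seed = 71)
  clusters <- sim_clusters_from_groups(bundle)
  cc <- concordance(clusters, bundle$trees, bundle$refs)
  expect_equal(cc$global_agreement, 1.0)
  expect_equal(nrow(cc$per_cluster), 10L)
  # every call matches the planted truth
  got <- merge(cc$per_cluster, bundle$truth,
               by.x = "cluster_id", by.y = "group")
  expect_equal(got$subfamily.x, got$subfamily.y)

  # move one member into the wrong component tree leaf: disagreement
  cl <- clusters[[1]]
  other_fam_leaf <- paste0(bundle$truth$group[
    bundle$truth$subfamily != bundle$truth$subfamily[1]][1], "_NBD")
  cl$members$gene_id[cl$members$component == "NBD"] <- other_fam_leaf
  cc2 <- concordance(list(cl), bundle$trees, bundle$refs)
  expect_false(cc2$per_cluster$agree[1])

  # members missing from their tree are warned about and unclassified
  cl2 <- clusters[[2]]
  cl2$members$gene_id[1] <- "not_a_leaf"
  expect_warning(cc3 <- concordance(list(cl2), bundle$trees, bundle$refs),
                 "not_a_leaf")
  expect_equal(sum(cc3$per_member$subfamily == "unclassified"), 1L)
})
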