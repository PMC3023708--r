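test_that("region partition walks the reference topology N to C", {
  msa <- bcescan:::new_msa(c("ref", "oth"), c("MKTLIVA", "MKALIVA"))
  top <- topology("ref", c("I", "TM", "O"), c(1, 3, 6), c(2, 5, 7))
  part <- partition_regions(msa, "ref", top)
  expect_equal(part$labels, c("I1", "TM1", "O1"))
  expect_equal(part$columns$I1, 1:2)
  expect_equal(part$columns$TM1, 3:5)
  expect_equal(part$columns$O1, 6:7)
  # regions are disjoint and cover exactly the non-gap reference columns
  expect_equal(sort(unname(unlist(part$columns))), 1:7)

  # a reference gap column belongs to no region
  msa2 <- bcescan:::new_msa(c("ref", "oth"), c("MK-TLIVA", "MKQTLIVA"))
  part2 <- partition_regions(msa2, "ref", top)
  expect_false(3L %in% unlist(part2$columns))
  expect_equal(sort(unname(unlist(part2$columns))), c(1:2, 4:8))

  expect_error(partition_regions(msa, "ref",
                                 topology_from_lengths("ref", "I", 10L)),
               "does not match")
})

test_that("a ten-TM reference yields the 21 labels ending at I6/O5", {
  top <- make_msd_top("ref")
  seqs <- strrep("A", top$length)
  msa <- bcescan:::new_msa(c("ref", "oth"), c(seqs, seqs))
  part <- partition_regions(msa, "ref", top)
  expect_length(part$labels, 21L)
  expect_equal(sum(grepl("^I", part$labels)), 6L)
  expect_equal(sum(grepl("^O", part$labels)), 5L)
  expect_equal(sum(grepl("^TM", part$labels)), 10L)
  expect_equal(part$labels[length(part$labels)], "I6")
  expect_equal(length(part$columns$O4), 205L)
})

test_that("region identity counts matches and treats other-gaps as mismatch", {
  top <- topology("ref", c("I", "TM"), c(1, 6), c(5, 15))
  ref <- "MKTLIVAEDRGHSTA"
  oth <- "MKALI-AEDRGHSTA"   # one mismatch in I1, one gap in TM1
  msa <- bcescan:::new_msa(c("ref", "oth"), c(ref, oth))
  part <- partition_regions(msa, "ref", top)
  ids <- region_identity(msa, "ref", "oth", part)
  expect_equal(unname(ids["I1"]), 4 / 5)
  expect_equal(unname(ids["TM1"]), 9 / 10)
  # self-comparison is 1 everywhere
  self <- region_identity(msa, "ref", "ref", part)
  expect_true(all(self == 1))
})

test_that("a constructed region with 4 matches in 10 columns scores 0.4", {
  ref <- strrep("A", 10)
  oth <- paste0(strrep("A", 4), strrep("C", 6))
  msa <- bcescan:::new_msa(c("ref", "oth"), c(ref, oth))
  part <- partition_regions(msa, "ref", topology_from_lengths("ref", "O", 10L))
  expect_equal(unname(region_identity(msa, "ref", "oth", part)["O1"]), 0.4)
})

test_that("profile means, whole-protein identity and ranking are coherent", {
  top <- make_msd_top("ref")
  seeds <- synthetic_seeds()
  ref_seq <- seeds$seq[seeds$component == "MSD"]
  set.seed(83)
  others <- vapply(1:7, function(i) bcescan:::mutate_seq(ref_seq, 0.3),
                   character(1))
  msa <- bcescan:::new_msa(c("ref", sprintf("h%d", 1:7)), c(ref_seq, others))
  part <- partition_regions(msa, "ref", top)
  prof <- conservation_profile(msa, "ref", part)
  expect_equal(prof$profile$n[1], 7L)
  expect_true(all(prof$profile$mean >= 0 & prof$profile$mean <= 1))

  # whole-protein identity equals the region-size-weighted mean, per pair
  sizes <- lengths(part$columns)
  for (oid in sprintf("h%d", 1:7)) {
    ids <- region_identity(msa, "ref", oid, part)
    whole <- sum(ids * sizes) / sum(sizes)
    ref_chars <- strsplit(ref_seq, "")[[1]]
    oth_chars <- strsplit(msa$seqs[match(oid, msa$ids)], "")[[1]]
    expect_equal(whole, mean(ref_chars == oth_chars))
  }

  # reordering non-reference rows changes nothing
  msa_shuf <- bcescan:::new_msa(c("ref", sprintf("h%d", 7:1)),
                                c(ref_seq, rev(others)))
  prof2 <- conservation_profile(msa_shuf, "ref", part)
  expect_equal(prof2$profile$mean, prof$profile$mean)
  expect_equal(prof2$profile$sd, prof$profile$sd)

  # duplicates of the reference give means 1 and SD 0
  msa_dup <- bcescan:::new_msa(c("ref", "d1", "d2"), rep(ref_seq, 3))
  prof3 <- conservation_profile(msa_dup, "ref", part)
  expect_true(all(prof3$profile$mean == 1))
  expect_true(all(prof3$profile$sd == 0))
})

test_that("a fast-evolving O4 ranks least conserved below every TM", {
  top <- make_msd_top("ref")
  seeds <- synthetic_seeds()
  ref_seq <- seeds$seq[seeds$component == "MSD"]
  seg <- top$segments
  rates <- numeric(top$length)
  for (k in seq_len(nrow(seg))) {
    rates[seg$start[k]:seg$end[k]] <- if (seg$kind[k] == "TM") 0.3 else 0.9
  }
  o4_seg <- which(seg$kind == "O")[4]
  rates[seg$start[o4_seg]:seg$end[o4_seg]] <- 2.7   # 3x the loop rate
  tree <- parse_newick(paste0("(", paste(sprintf("h%d:0.25", 1:8),
                                         collapse = ","), ");"))
  set.seed(89)
  fam <- evolve_family(ref_seq, tree, rates)
  msa <- bcescan:::new_msa(c("ref", fam$leaves$id),
                           c(ref_seq, fam$leaves$seq))
  part <- partition_regions(msa, "ref", top)
  prof <- conservation_profile(msa, "ref", part)
  means <- setNames(prof$profile$mean, prof$profile$region)
  expect_lt(means["O4"], min(means[grepl("^TM", names(means))]))
  expect_equal(prof$ranking[1], "O4")
})
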