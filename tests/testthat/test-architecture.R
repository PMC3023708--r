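test_that("default rules encode the published screening windows", {
  rules <- default_rules()
  expect_equal(rules$hk$loop_max, 20L)
  expect_equal(rules$hk$tm_required, 2L)
  expect_equal(c(rules$hk$min_len, rules$hk$max_len), c(50L, 1000L))
  expect_equal(rules$msd$tm_required, 10L)
  expect_equal(rules$msd$loop_after_tm, 7L)
  expect_equal(c(rules$msd$loop_min, rules$msd$loop_max), c(100L, 400L))
  expect_equal(c(rules$msd$min_len, rules$msd$max_len), c(400L, 1000L))
})

test_that("the survey-count presets tighten the loop windows", {
  expect_equal(rule_preset("results_hk12")$hk$loop_max, 12L)
  expect_equal(rule_preset("results_hk14")$hk$loop_max, 14L)
  expect_equal(rule_preset("results_msd170")$msd$loop_min, 171L)
  expect_equal(rule_preset("methods_default")$hk$loop_max, 20L)
})

test_that("seed-dimension topologies pass and boundary loops fail", {
  rules <- default_rules()
  # a 334-residue kinase with two TMs and an 8-residue linker
  expect_true(classify_architecture(make_hk_top(loop = 8L), rules$hk)$passed)
  # a 646-residue translocator with ten TMs and a 205-residue O4
  expect_true(classify_architecture(make_msd_top(o4 = 205L), rules$msd)$passed)

  over <- classify_architecture(make_hk_top(loop = 21L), rules$hk)
  expect_false(over$passed)
  expect_equal(over$failures, "loop_out_of_range")

  under <- classify_architecture(make_msd_top(o4 = 99L), rules$msd)
  expect_false(under$passed)
  expect_equal(under$failures, "loop_out_of_range")

  # exact boundaries pass
  expect_true(classify_architecture(make_hk_top(loop = 20L), rules$hk)$passed)
  expect_true(classify_architecture(make_msd_top(o4 = 100L), rules$msd)$passed)
  expect_true(classify_architecture(make_msd_top(o4 = 400L, total = 850L),
                                    rules$msd)$passed)
})

test_that("all violated conditions are reported, not just the first", {
  rules <- default_rules()
  # 6 TMs under the kinase rule: count mismatch but the loop after TM1 exists
  six <- make_hk_top(loop = 30L, total = 500L, n_tm = 6L)
  call <- classify_architecture(six, rules$hk)
  expect_setequal(call$failures, c("tm_count_mismatch", "loop_out_of_range"))

  # a soluble protein under the translocator rule
  sol <- topology_from_lengths("sol", "I", 646L)
  call <- classify_architecture(sol, rules$msd)
  expect_false(call$passed)
  expect_true("too_few_tms" %in% call$failures)
  expect_true("tm_count_mismatch" %in% call$failures)
})

test_that("widening a rule window never turns a pass into a fail", {
  set.seed(21)
  base <- default_rules()$msd
  wide <- architecture_rule("wide", base$min_len - 50L, base$max_len + 50L,
                            base$tm_required, base$loop_after_tm,
                            base$loop_min - 50L, base$loop_max + 50L)
  n_pass <- 0L
  for (k in 1:200) {
    o4 <- sample(60:440, 1L)
    top <- make_msd_top(o4 = o4, total = o4 + 350L + sample(10:260, 1L))
    if (classify_architecture(top, base)$passed) {
      n_pass <- n_pass + 1L
      expect_true(classify_architecture(top, wide)$passed)
    }
  }
  expect_gt(n_pass, 10L)   # the implication must not be vacuous
})

test_that("classify_architecture matches the brute-force oracle", {
  set.seed(31)
  rules <- default_rules()
  for (k in 1:300) {
    top <- random_topology(sprintf("t%03d", k))
    for (rule in rules) {
      got <- classify_architecture(top, rule)
      want <- oracle_classify(top, rule)
      expect_identical(got$passed, want$passed)
      expect_setequal(got$failures, want$failures)
    }
  }
  # repeated calls are identical (pure function)
  top <- random_topology()
  expect_identical(classify_architecture(top, rules$hk),
                   classify_architecture(top, rules$hk))
})

test_that("screen_proteome yields one row per id and rule plus summaries", {
  tops <- list(a = make_hk_top("a"), b = make_msd_top("b"),
               c = topology_from_lengths("c", "I", 200L))
  suppressMessages(tab <- screen_proteome(tops))
  expect_equal(nrow(tab), 6L)
  expect_equal(sum(tab$passed), 2L)
  expect_equal(unname(attr(tab, "summary")[c("hk", "msd")]), c(1L, 1L))

  suppressMessages(empty <- screen_proteome(list()))
  expect_equal(nrow(empty), 0L)

  suppressMessages(expect_warning(
    tab2 <- screen_proteome(tops["a"], rules = default_rules()["hk"],
                            expect_ids = c("a", "ghost")),
    "ghost"))
  ghost_row <- tab2[tab2$seq_id == "ghost", ]
  expect_false(ghost_row$passed)
  expect_equal(ghost_row$failures, "tm_count_mismatch")
})
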