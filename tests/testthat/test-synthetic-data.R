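test_that("simulation is deterministic: same seed gives byte-identical files", {
  b1 <- toy_bundle(seed = 7)
  b2 <- toy_bundle(seed = 7)
  expect_identical(b1$truth, b2$truth)
  d1 <- file.path(tempfile(), "w1"); d2 <- file.path(tempfile(), "w2")
  write_bundle(b1, d1); write_bundle(b2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  b3 <- toy_bundle(seed = 8)
  expect_false(identical(b1$truth, b3$truth))
})

test_that("one family without nesting yields one row and one entity per copy", {
  tree <- primate_tree()
  fams <- list(family_model("solo", mu = 0.5, sigma = 0.1, n_copies = 10))
  b <- simulate_succession(tree, fams, seed = 7, p_nest = 0)
  expect_equal(nrow(b$copies$human), 10L)
  expect_equal(nrow(group_entities(b$copies$human)), 10L)
  expect_true(all(is.na(b$truth$parent)))
})

test_that("disjoint activity supports give strictly one-sided nestings", {
  tree <- primate_tree()
  fams <- list(family_model("OLD", mu = 0.2, sigma = 0.03, n_copies = 60),
               family_model("YNG", mu = 0.8, sigma = 0.03, n_copies = 60))
  b <- simulate_succession(tree, fams, seed = 21, p_nest = 0.4)
  tn <- true_nestings(b)
  fam_of <- b$truth$family
  inner_f <- fam_of[tn$inner]; outer_f <- fam_of[tn$outer]
  expect_gt(sum(inner_f == "YNG" & outer_f == "OLD"), 0L)
  expect_equal(sum(inner_f == "OLD" & outer_f == "YNG"), 0L)
})

test_that("branch assignment controls per-species presence", {
  b <- toy_bundle(seed = 7, n = 30)
  tr <- b$truth
  # an insertion after the bushbaby split but before the tarsier split is in
  # the focal and tarsier outputs, absent from bushbaby
  btw <- tr[tr$branch == "between", ]
  expect_gt(nrow(btw), 0L)
  expect_true(all(btw$present_tarsier & !btw$present_bushbaby))
  expect_true(all(btw$repeat_id %in% b$copies$tarsier$repeat_id))
  expect_false(any(btw$repeat_id %in% b$copies$bushbaby$repeat_id))
  pre <- tr[tr$branch == "pre_hs", ]
  expect_true(all(pre$repeat_id %in% b$copies$bushbaby$repeat_id))
  hum <- tr[tr$branch == "focal_only", ]
  expect_false(any(hum$repeat_id %in% b$copies$tarsier$repeat_id))
})

test_that("every annotation row traces to a truth record and vice versa", {
  b <- toy_bundle(seed = 13, n = 25)
  for (s in names(b$copies)) {
    cp <- b$copies[[s]]
    expect_true(all(cp$repeat_id %in% b$truth$id))
    present <- switch(s, human = b$truth$id,
                      tarsier = b$truth$id[b$truth$present_tarsier],
                      bushbaby = b$truth$id[b$truth$present_bushbaby])
    expect_setequal(unique(cp$repeat_id), present)
  }
})

test_that("emitted chains are valid and lift there-and-back into the original", {
  b <- toy_bundle(seed = 13, n = 25)
  for (s in names(b$chains)) {
    ch <- b$chains[[s]]
    expect_silent(validate_chain(ch))
    # forward lift of a shared single-fragment element with no nested guest
    tr <- b$truth
    clean <- !is.na(tr[[paste0(s, "_start")]]) & tr$n_fragments == 1L &
      !(tr$id %in% tr$parent)
    shared <- tr[clean, ][1, ]
    lv <- lift_interval(list(ch), "chrSim", shared$human_start,
                        shared$human_end)
    expect_equal(lv$aligned_bases, shared$human_end - shared$human_start)
    expect_equal(lv$segments$q_start[1], shared[[paste0(s, "_start")]])
  }
})

test_that("chain degradation is deterministic, monotone, and bounded", {
  b <- toy_bundle(seed = 13, n = 25)
  ch <- b$chains$tarsier
  len <- b$genome_length[["human"]]
  expect_identical(degrade_chain(ch, 0, seed = 1), ch)
  ab <- vapply(c(0, 0.1, 0.3, 0.5, 0.8),
               function(f) aligned_bases(list(degrade_chain(ch, f, seed = 3)),
                                         "chrSim", 0L, len), 0L)
  expect_true(all(diff(ab) < 0))
  expect_identical(degrade_chain(ch, 0.3, seed = 3)$blocks,
                   degrade_chain(ch, 0.3, seed = 3)$blocks)
  # near-total degradation pushes an element under the 50-base presence rule
  tr1 <- b$truth[b$truth$present_tarsier, ][1, ]
  worst <- degrade_chain(ch, 0.95, seed = 5)
  expect_lt(aligned_bases(list(worst), "chrSim", tr1$human_start,
                          tr1$human_end), 50L)
})

test_that("planted structural variants appear in the requested LTRs only", {
  cons <- synthetic_the1_consensus()
  defs <- the1_variant_defs()
  pl <- plant_structural_variants(cons$ltr, cons$internal, defs, "canonical",
                                  n = 1, sub_rate = 0, seed = 1)
  expect_true(all(pl$truth$present))
  pli <- plant_structural_variants(cons$ltr, cons$internal, defs,
                                   "intermediate", n = 1, sub_rate = 0,
                                   seed = 1)
  t5 <- pli$truth[pli$truth$side == "ltr5", ]
  t3 <- pli$truth[pli$truth$side == "ltr3", ]
  expect_true(t5$present[t5$variant == "204del"])
  expect_false(t3$present[t3$variant == "204del"])
  expect_true(all(t3$present[t3$variant != "204del"]))
  # determinism
  pl2 <- plant_structural_variants(cons$ltr, cons$internal, defs, "canonical",
                                   n = 1, sub_rate = 0, seed = 1)
  expect_identical(pl$elements, pl2$elements)
})

test_that("the consensus-chain generator plants pair-specific markers", {
  ch <- simulate_consensus_chain(5, base_len = 300, feature_len = 30,
                                 n_subs = 4, seed = 2)
  expect_length(ch, 5L)
  # adjacent members are more similar than distant ones
  d_adj <- as.numeric(jc_distance(align_free_end_gaps(ch[["m2"]], ch[["m3"]])))
  d_far <- as.numeric(jc_distance(align_free_end_gaps(ch[["m1"]], ch[["m5"]])))
  expect_lt(d_adj, d_far)
})
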