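cons <- synthetic_the1_consensus()
defs <- the1_variant_defs()
model <- ltr_model(u3_end = 195, length = nchar(cons$ltr))

test_that("variant definitions validate coordinates and overlaps", {
  expect_error(variant_defs("x", "insertion", 5, 7), "start == end")
  expect_error(variant_defs("x", "delins", 5, 7, ""), "replacement")
  both <- variant_defs(c("d1", "d2"), c("deletion", "deletion"),
                       c(10, 15), c(20, 25))
  expect_error(apply_variants("ACGT", both, c("d1", "d2")), "overlapping|length")
  # the tarsier-lineage 16-bp deletion spans exactly 16 bases
  d <- the1_variant_defs(include_227_242del = TRUE)
  v <- d[d$name == "227_242del", ]
  expect_equal(v$end - v$start + 1L, 16L)
})

test_that("applying variants edits the consensus as named", {
  s <- paste(rep(c("A", "C", "G", "T"), 100), collapse = "")
  del <- apply_variants(s, defs, "204del")
  expect_equal(nchar(del), nchar(s) - 1L)
  expect_equal(substring(del, 1, 203), substring(s, 1, 203))
  expect_equal(substring(del, 204), substring(s, 205))
  ins <- apply_variants(s, defs, "186ins")
  expect_equal(nchar(ins), nchar(s) + 1L)
  di <- apply_variants(s, defs, "303_312delinsTT")
  expect_equal(nchar(di), nchar(s) - 10L + 2L)
  expect_equal(substring(di, 303, 304), "TT")
  all4 <- apply_variants(s, defs)
  expect_equal(nchar(all4), nchar(s) + 1L - 1L - 10L - 8L)
})

test_that("an exact consensus element calls every deletion absent", {
  el <- paste0(cons$ltr, cons$internal, cons$ltr)
  calls <- call_variants(el, cons$ltr, defs)
  expect_true(all(calls$status == "absent"))
  expect_true(all(calls$delta_len == 0L))
})

test_that("a 5'-only deletion is called present on that side alone", {
  ltr5 <- apply_variants(cons$ltr, defs, "204del")
  el <- paste0(ltr5, cons$internal, cons$ltr)
  calls <- call_variants(el, cons$ltr, defs)
  d5 <- calls[calls$side == "ltr5" & calls$variant == "204del", ]
  d3 <- calls[calls$side == "ltr3" & calls$variant == "204del", ]
  expect_equal(d5$status, "present")
  expect_equal(d3$status, "absent")
})

test_that("per-LTR status recovery against planted truth reaches 99% at 5% divergence", {
  pl <- plant_structural_variants(cons$ltr, cons$internal, defs, "canonical",
                                  n = 40, sub_rate = 0.05, seed = 31)
  pli <- plant_structural_variants(cons$ltr, cons$internal, defs,
                                   "intermediate", n = 30, sub_rate = 0.05,
                                   seed = 32, prefix = "int")
  plp <- plant_structural_variants(cons$ltr, cons$internal, defs, "precursor",
                                   n = 30, sub_rate = 0.05, seed = 33,
                                   prefix = "pre")
  els <- c(pl$elements, pli$elements, plp$elements)
  truth <- rbind(pl$truth, pli$truth, plp$truth)
  calls <- do.call(rbind, lapply(names(els), function(id)
    cbind(element = id, call_variants(els[[id]], cons$ltr, defs))))
  m <- merge(calls, truth, by = c("element", "side", "variant"))
  expect_equal(nrow(m), nrow(truth))
  recovery <- mean(m$status != "uncallable" & (m$status == "present") == m$present)
  expect_gte(recovery, 0.99)
})

test_that("stage classification matches the per-LTR patterns", {
  stage_of <- function(spec) {
    pl <- plant_structural_variants(cons$ltr, cons$internal, defs, spec,
                                    n = 1, sub_rate = 0, seed = 1)
    classify_stage(call_variants(pl$elements[[1]], cons$ltr, defs))$stage
  }
  expect_equal(stage_of("precursor"), "precursor")
  expect_equal(stage_of("intermediate"), "intermediate")
  expect_equal(stage_of("canonical"), "canonical")
  # an off-pattern element (204del in 3' only) is other
  odd <- plant_structural_variants(cons$ltr, cons$internal, defs,
                                   list(ltr5 = c("186ins", "226_235del",
                                                 "303_312delinsTT"),
                                        ltr3 = c("186ins", "226_235del",
                                                 "303_312delinsTT", "204del")),
                                   n = 1, sub_rate = 0, seed = 1)
  expect_equal(classify_stage(call_variants(odd$elements[[1]], cons$ltr,
                                            defs))$stage, "other")
})

test_that("solo LTRs are reported as such and skipped for staging", {
  expect_null(call_variants(cons$ltr, cons$ltr, defs))
  scan <- scan_for_stage(c(solo = cons$ltr), cons$ltr, defs)
  expect_equal(scan$stage, "solo_or_partial")
})

test_that("replication logic copies R/U5 from the 5' and U3 from the 3' LTR", {
  seg <- variant_segment(defs, model)
  expect_equal(unname(seg["204del"]), "RU5")    # downstream of the TSS
  # the intermediate pattern canonicalizes in one round
  pat <- list(ltr5 = c(`186ins` = TRUE, `204del` = TRUE, `226_235del` = TRUE,
                       `303_312delinsTT` = TRUE),
              ltr3 = c(`186ins` = TRUE, `204del` = FALSE, `226_235del` = TRUE,
                       `303_312delinsTT` = TRUE))
  prog <- predict_progeny_ltr(pat, defs, model)
  expect_true(all(prog$ltr5))
  expect_identical(prog$ltr5, prog$ltr3)
  # identical parental LTRs are a fixed point
  fix <- list(ltr5 = pat$ltr5, ltr3 = pat$ltr5)
  expect_identical(predict_progeny_ltr(fix, defs, model)$ltr5, pat$ltr5)
  # applying the rule twice changes nothing more (canonicalization converges)
  twice <- predict_progeny_ltr(prog, defs, model)
  expect_identical(twice, prog)
  # a U3-only variant present in the 3' LTR propagates to both
  u3def <- variant_defs("u3var", "deletion", 50, 55)
  patu <- list(ltr5 = c(u3var = FALSE), ltr3 = c(u3var = TRUE))
  expect_true(all(predict_progeny_ltr(patu, u3def, model)$ltr5))
  # a variant spanning the boundary demands explicit assignment
  span <- variant_defs("spanvar", "deletion", 190, 200)
  expect_error(predict_progeny_ltr(list(ltr5 = c(spanvar = TRUE),
                                        ltr3 = c(spanvar = TRUE)),
                                   span, model), "boundary")
})

test_that("scan isolates planted non-canonical elements and is order-invariant", {
  p1 <- plant_structural_variants(cons$ltr, cons$internal, defs, "canonical",
                                  n = 20, sub_rate = 0.05, seed = 41,
                                  prefix = "can")
  p2 <- plant_structural_variants(cons$ltr, cons$internal, defs, "precursor",
                                  n = 1, sub_rate = 0.05, seed = 42,
                                  prefix = "pre")
  els <- c(p1$elements, p2$elements)
  scan <- scan_for_stage(els, cons$ltr, defs)
  expect_equal(scan$element[scan$stage != "canonical"], "pre001")
  perm <- sample(length(els))
  scan2 <- scan_for_stage(els[perm], cons$ltr, defs)
  expect_equal(scan2$stage[match(scan$element, scan2$element)], scan$stage)
  expect_equal(nrow(scan_for_stage(character(), cons$ltr, defs)), 0L)
  expect_equal(sum(attr(scan, "summary")), length(els))
})

test_that("uniquely shared blocks are found only where planted", {
  ch <- simulate_consensus_chain(5, base_len = 300, feature_len = 30,
                                 n_subs = 4, seed = 2)
  # a = b with distinct backgrounds: one block spanning essentially everything
  bg <- c(bg1 = paste(rep("A", 300), collapse = ""))
  full <- shared_features(ch[["m2"]], ch[["m2"]], bg)
  expect_equal(nrow(full), 1L)
  expect_gte(full$length, 0.8 * nchar(ch[["m2"]]))
  # planted marker recovered at its position within a couple of columns
  blocks <- shared_features(ch[["m2"]], ch[["m3"]],
                            ch[setdiff(names(ch), c("m2", "m3"))])
  expect_equal(nrow(blocks), 1L)
  markers <- attr(ch, "markers")
  planted_start <- markers[2] + 30 + 1   # after marker 1 kept in m2
  expect_lte(abs(blocks$start - planted_start), 2)
  expect_gte(blocks$length, 28)
  # a pair identical to a background yields nothing
  none <- shared_features(ch[["m2"]], ch[["m3"]], c(bg = ch[["m2"]]))
  expect_equal(nrow(none), 0L)
  expect_error(shared_features("ACGT", "ACGT", character()), "background")
})

test_that("succession support concentrates on the true chain order", {
  ch <- simulate_consensus_chain(6, base_len = 400, feature_len = 35,
                                 n_subs = 5, seed = 3)
  sup <- succession_support(names(ch), ch)
  expect_equal(nrow(sup), 5L)
  expect_true(all(sup$n_blocks >= 1L))
  true_score <- sum(sup$n_blocks >= 1L)
  set.seed(9)
  shuffled <- replicate(10, {
    s2 <- succession_support(sample(names(ch)), ch)
    sum(s2$n_blocks >= 1L)
  })
  expect_true(all(shuffled < true_score))
  expect_error(succession_support(c("m1", "zz"), ch), "missing")
  # a 2-member chain reports its single pair, using the rest as background
  pair <- succession_support(c("m1", "m2"), ch)
  expect_equal(nrow(pair), 1L)
  expect_gte(pair$n_blocks, 1L)
})
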