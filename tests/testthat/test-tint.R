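test_that("a nested element between consensus-contiguous fragments is one event", {
  rows <- c(
    # outer B: fragments [0,500) and [800,1300), rep coords 1-500 then 501-1000
    out_row(sw = 900, start1 = 1, end1 = 500, name = "B", rb = 1, re = 500,
            rl = 500, id = 10),
    out_row(sw = 900, start1 = 801, end1 = 1300, name = "B", rb = 501,
            re = 1000, rl = 0, id = 10),
    # inner A fully inside the gap
    out_row(sw = 500, start1 = 521, end1 = 780, name = "A", rb = 1, re = 260,
            rl = 0, id = 11))
  cp <- read_rmsk_out(write_rmsk_fixture(rows))
  ev <- detect_tint_events(cp)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$inner_family, "A")
  expect_equal(ev$outer_family, "B")
})

test_that("containment and consensus-continuity violations suppress events", {
  base <- c(
    out_row(sw = 900, start1 = 1, end1 = 500, name = "B", rb = 1, re = 500,
            rl = 500, id = 10),
    out_row(sw = 900, start1 = 801, end1 = 1300, name = "B", rb = 501,
            re = 1000, rl = 0, id = 10))
  # inner overlapping an outer fragment boundary: no containment
  overlap <- c(base, out_row(sw = 500, start1 = 451, end1 = 780, name = "A",
                             rb = 1, re = 330, rl = 0, id = 11))
  expect_equal(nrow(detect_tint_events(read_rmsk_out(write_rmsk_fixture(overlap)))), 0L)
  # outer fragments overlapping on the consensus (tandem-like, not one
  # split insertion): continuity broken
  discont <- c(
    out_row(sw = 900, start1 = 1, end1 = 500, name = "B", rb = 1, re = 500,
            rl = 500, id = 10),
    out_row(sw = 900, start1 = 801, end1 = 1300, name = "B", rb = 400,
            re = 899, rl = 101, id = 10),
    out_row(sw = 500, start1 = 521, end1 = 780, name = "A", rb = 1, re = 260,
            rl = 0, id = 11))
  expect_equal(nrow(detect_tint_events(read_rmsk_out(write_rmsk_fixture(discont)))), 0L)
  # but a tolerant threshold readmits it
  expect_equal(nrow(detect_tint_events(read_rmsk_out(write_rmsk_fixture(discont)),
                                       tolerance = 120)), 1L)
  expect_equal(nrow(detect_tint_events(read_rmsk_out(write_rmsk_fixture(base))[0, ])), 0L)
})

test_that("detection against simulated truth is near-perfect", {
  b <- toy_bundle(seed = 7, n = 40, p_nest = 0.3)
  ev <- detect_tint_events(b$copies$human)
  got <- event_pairs(ev)
  want <- truth_pairs(b)
  expect_gte(mean(got %in% want), 0.95)
  expect_gte(mean(want %in% got), 0.95)
})

test_that("nesting matrices aggregate counts and permute consistently", {
  ev <- data.frame(inner_family = c("A", "A", "A", "C"),
                   outer_family = c("B", "B", "C", "B"))
  N <- build_nesting_matrix(ev, c("A", "B", "C"))
  expect_equal(N["A", "B"], 2L)
  expect_equal(N["B", "A"], 0L)
  expect_equal(sum(N), 4L)
  # zero matrix for no events
  expect_true(all(build_nesting_matrix(ev[0, ], c("A", "B")) == 0L))
  # family order permutation permutes rows/columns consistently
  N2 <- build_nesting_matrix(ev, c("C", "A", "B"))
  expect_equal(N2[c("A", "B", "C"), c("A", "B", "C")], N)
  # events touching families outside the list are ignored entirely
  N3 <- build_nesting_matrix(ev, c("A", "B"))
  expect_equal(sum(N3), 2L)
})

test_that("one-sided counts force the ordering of two families", {
  N <- matrix(0L, 2, 2, dimnames = list(inner = c("B", "A"),
                                        outer = c("B", "A")))
  N["A", "B"] <- 50L
  per <- infer_activity_periods(N, restarts = 5, seed = 1)
  expect_gt(per$mu[per$family == "A"], per$mu[per$family == "B"])
})

test_that("the conditional target probabilities form proper rows", {
  mu <- c(0, 1, 2.5); sigma <- c(1, 0.8, 1.2); cw <- c(3, 1, 2)
  p <- malrsucc:::.tint_p(mu, sigma, cw)
  expect_equal(rowSums(p), rep(1, 3))
  expect_true(all(p >= 0))
  # precedence propensity increases with the inner family's age rank
  q <- malrsucc:::.tint_q(mu, sigma, cw)
  expect_true(all(diff(q[, 1]) > 0))   # younger inner, larger q into family 1
})

test_that("parameters are recovered from the model's own generative form", {
  mu0 <- c(A = 0, B = 0.8, C = 1.6, D = 2.2, E = 3.1)
  sg0 <- c(1, 1.2, 0.9, 1, 1.1)
  N <- simulate_nesting_counts(mu0, sg0, n_events = 2000, seed = 5)
  per <- infer_activity_periods(N, restarts = 20, seed = 2)
  expect_gte(cor(per$mu, mu0, method = "spearman"), 0.9)
  expect_equal(order(per$mu), order(mu0))
  # intervals are nested and symmetric about mu
  expect_true(all(per$lo99 <= per$lo95 & per$lo95 <= per$lo75))
  expect_true(all(per$hi75 <= per$hi95 & per$hi95 <= per$hi99))
  expect_equal(per$hi75 - per$mu, per$mu - per$lo75)
})

test_that("a family with no events is flagged unconstrained, not placed", {
  N <- matrix(0L, 3, 3, dimnames = list(inner = c("A", "B", "Z"),
                                        outer = c("A", "B", "Z")))
  N["B", "A"] <- 40L
  per <- infer_activity_periods(N, restarts = 5, seed = 1)
  expect_true(per$unconstrained[per$family == "Z"])
  expect_false(any(per$unconstrained[per$family %in% c("A", "B")]))
  z <- per[per$family == "Z", ]
  expect_gt(z$sigma, max(per$sigma[!per$unconstrained]))
  # degenerate matrix without any off-diagonal count refuses to fit
  N0 <- N; N0[] <- 0L; diag(N0) <- 5L
  expect_error(infer_activity_periods(N0), "off-diagonal")
})

test_that("the youngest family's one-sided partners are reported", {
  N <- matrix(0L, 3, 3, dimnames = list(inner = c("A", "B", "C"),
                                        outer = c("A", "B", "C")))
  N["C", "A"] <- 12L; N["C", "B"] <- 7L; N["B", "A"] <- 20L
  per <- infer_activity_periods(N, restarts = 10, seed = 1)
  rep <- youngest_family_check(per, N)
  expect_equal(attr(rep, "youngest"), "C")
  expect_true(all(rep$one_sided))
  expect_setequal(rep$partner, c("A", "B"))
  # a symmetric matrix supports no one-sided claim
  Ns <- N; Ns["A", "C"] <- 12L; Ns["B", "C"] <- 7L; Ns["A", "B"] <- 20L
  per2 <- infer_activity_periods(Ns, restarts = 10, seed = 1)
  rep2 <- youngest_family_check(per2, Ns)
  expect_false(any(rep2$one_sided))
  # empty matrix: empty report
  N0 <- N; N0[] <- 0L
  expect_equal(nrow(youngest_family_check(per, N0)), 0L)
})

test_that("likelihood is invariant to family relabeling", {
  N <- matrix(c(0L, 3L, 30L, 0L), 2, 2,
              dimnames = list(inner = c("A", "B"), outer = c("A", "B")))
  perm <- c("B", "A")
  p1 <- infer_activity_periods(N, restarts = 10, seed = 3)
  p2 <- infer_activity_periods(N[perm, perm], restarts = 10, seed = 3)
  expect_equal(attr(p1, "loglik"), attr(p2, "loglik"), tolerance = 1e-4)
})
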