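test_that("free-end-gap alignment handles identity, containment and symmetry", {
  al <- align_free_end_gaps("ACGT", "ACGT")
  expect_equal(al$score, 4)
  expect_equal(al$columns, rep("match", 4))
  al2 <- align_free_end_gaps("ACGT", "CG")
  expect_equal(al2$score, 2)
  expect_equal(al2$a, "ACGT")
  expect_equal(al2$b, "-CG-")
  expect_equal(sum(al2$columns == "match"), 2L)
  expect_equal(sum(al2$columns == "end_gap"), 2L)
  # score invariant under argument swap
  set.seed(1)
  for (k in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(4:12, 1), TRUE), collapse = "")
    expect_equal(align_free_end_gaps(a, b)$score,
                 align_free_end_gaps(b, a)$score)
  }
  expect_error(align_free_end_gaps("", "ACGT"), "empty")
})

test_that("alignment score matches exhaustive enumeration on short sequences", {
  set.seed(11)
  for (k in 1:40) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(2:6, 1), TRUE), collapse = "")
    expect_equal(align_free_end_gaps(a, b)$score, enumerate_best_score(a, b),
                 info = paste(a, b))
  }
})

test_that("the returned alignment path scores exactly the DP optimum", {
  # includes the two-opposing-indels structure that once broke tracebacks
  score_path <- function(al, match = 1, mismatch = -1, go = -4, ge = -1) {
    ca <- strsplit(al$a, "")[[1]]; cb <- strsplit(al$b, "")[[1]]
    lead <- function(g) cumprod(g) > 0
    free <- lead(ca == "-") | lead(cb == "-") |
      rev(lead(rev(ca == "-"))) | rev(lead(rev(cb == "-")))
    s <- 0; in_a <- FALSE; in_b <- FALSE
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        if (!free[k]) s <- s + ge + ifelse(!in_a, go, 0)
        in_a <- TRUE; in_b <- FALSE
      } else if (cb[k] == "-") {
        if (!free[k]) s <- s + ge + ifelse(!in_b, go, 0)
        in_b <- TRUE; in_a <- FALSE
      } else {
        s <- s + ifelse(ca[k] == cb[k], 1, -1)
        in_a <- in_b <- FALSE
      }
    }
    s
  }
  set.seed(5)
  rnd <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  for (k in 1:25) {
    X1 <- rnd(sample(30:70, 1)); X2 <- rnd(sample(30:70, 1)); X3 <- rnd(40)
    a <- paste0(X1, rnd(sample(5:35, 1)), X2, X3)
    b <- paste0(X1, X2, rnd(sample(5:35, 1)), X3)
    al <- align_free_end_gaps(a, b)
    expect_equal(score_path(al), al$score)
  }
})

test_that("transition weighting changes scores only through ts columns", {
  # A/G is a transition: cheaper than a transversion when weighting is on
  plain <- align_free_end_gaps("AAAA", "AAGA")
  wt <- align_free_end_gaps("AAAA", "AAGA", transition = -0.5)
  expect_equal(plain$score, 2)
  expect_equal(wt$score, 2.5)
  expect_equal(wt$columns[3], "transition")
})

test_that("jukes-cantor correction matches the closed form and flags saturation", {
  mk <- function(n_match, n_mm) {
    structure(list(columns = c(rep("match", n_match),
                               rep("transversion", n_mm))),
              class = "pairwise_alignment")
  }
  expect_equal(as.numeric(jc_distance(mk(100, 0))), 0)
  d <- jc_distance(mk(70, 30))            # p = 0.3
  expect_equal(as.numeric(d), -0.75 * log(1 - 4 * 0.3 / 3), tolerance = 1e-12)
  expect_equal(attr(d, "p"), 0.3)
  d2 <- jc_distance(mk(90, 10))           # p = 0.1
  expect_equal(as.numeric(d2), -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)
  sat <- jc_distance(mk(25, 75))          # p = 0.75: formula singularity
  expect_true(attr(sat, "saturated"))
  expect_true(is.infinite(as.numeric(sat)))
  gap_only <- structure(list(columns = rep("gap", 5)),
                        class = "pairwise_alignment")
  expect_error(jc_distance(gap_only), "comparable")
})

test_that("jc distance is monotone increasing in p below saturation", {
  ps <- seq(0.01, 0.74, by = 0.04)
  ds <- -0.75 * log(1 - 4 * ps / 3)
  expect_true(all(diff(ds) > 0))
  # and via the alignment interface
  mk <- function(p) structure(
    list(columns = c(rep("match", round(100 * (1 - p))),
                     rep("transversion", round(100 * p)))),
    class = "pairwise_alignment")
  expect_lt(as.numeric(jc_distance(mk(0.1))), as.numeric(jc_distance(mk(0.3))))
})

test_that("neighbor joining recovers an additive 4-taxon tree exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  D <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  njt <- neighbor_joining(D)
  expect_true(same_topology(njt, tr))
  # exact branch lengths on the additive input
  expect_equal(sort(njt$edge.length), sort(tr$edge.length))
  # 3 taxa: three-point formulas
  D3 <- D[1:3, 1:3]
  t3 <- neighbor_joining(D3)
  expect_equal(sort(t3$edge.length), sort(c(1, 2, 4)))
})

test_that("neighbor joining recovers 50 random additive topologies", {
  set.seed(202)
  for (k in 1:50) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = FALSE, br = function(x) runif(x, 0.1, 1))
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    njt <- neighbor_joining(D)
    expect_true(same_topology(njt, tr))
    # independent implementation agrees on the topology
    expect_true(same_topology(njt, ape::nj(as.dist(D))))
  }
})

test_that("the NJ topology is the least-squares optimum over all topologies", {
  set.seed(301)
  for (k in 1:4) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, rooted = FALSE, br = function(x) runif(x, 0.2, 1))
    D <- ape::cophenetic.phylo(tr)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    expect_true(same_topology(neighbor_joining(D), ls_best_topology(D)))
  }
})

test_that("neighbor joining is invariant to taxon order and guards saturation", {
  tr <- ape::rtree(6, rooted = FALSE, br = function(x) runif(x, 0.1, 1))
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(D))
  t1 <- neighbor_joining(D)
  t2 <- neighbor_joining(D[perm, perm])
  expect_true(same_topology(t1, t2))
  Ds <- D
  Ds[1, 2] <- Ds[2, 1] <- Inf
  expect_error(neighbor_joining(Ds), "saturated")
  expect_message(x <- neighbor_joining(Ds, allow_saturated = TRUE), "capped")
  expect_s3_class(x, "phylo")
})

test_that("clade_check detects splits and reports the sister group", {
  # five a-taxa coalesce before joining b, then the rest
  nwk <- "((((a1:1,a2:1):1,(a3:1,(a4:1,a5:1):1):1):1,b:3):2,(c:1,d:1):4);"
  tr <- ape::read.tree(text = nwk)
  res <- clade_check(tr, paste0("a", 1:5))
  expect_true(res$is_clade)
  expect_equal(res$sister, "b")
  expect_true(clade_check(tr, "a1")$is_clade)              # single tip
  expect_true(clade_check(tr, tr$tip.label)$is_clade)      # trivial split
  expect_false(clade_check(tr, c("a1", "c"))$is_clade)
  expect_error(clade_check(tr, "nope"), "unknown")
})

test_that("consensus distance matrices are symmetric with zero diagonal", {
  set.seed(8)
  seqs <- c(x = paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""),
            y = NA, z = NA)
  seqs["y"] <- mutate_sequence(seqs[["x"]], 0.05)
  seqs["z"] <- mutate_sequence(seqs[["x"]], 0.20)
  D <- consensus_dist_matrix(seqs)
  expect_equal(D, t(D))
  expect_equal(diag(D), c(x = 0, y = 0, z = 0))
  expect_lt(D["x", "y"], D["x", "z"])   # heavier mutation, larger distance
})
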