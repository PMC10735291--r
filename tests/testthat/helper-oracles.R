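# Independent oracles: exhaustive alignment enumeration, per-base chain
# expansion, and least-squares topology search.  These never call the code
# paths they check.

# Maximum free-end-gap affine alignment score by enumerating every path of
# M/X/Y moves (feasible for sequences of half a dozen bases).  Terminal gap
# runs cost nothing.
enumerate_best_score <- function(a, b, match = 1, mismatch = -1,
                                 gap_open = -4, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  best <- -Inf
  score_path <- function(moves) {
    i <- 0L; j <- 0L; s <- 0
    gap_run <- ""          # which sequence the open gap is in
    # only a terminal run of gaps in ONE sequence is free: the maximal
    # homogeneous non-M prefix and suffix
    nmv <- length(moves)
    lead <- 0L
    while (lead < nmv && moves[lead + 1L] != "M" &&
           moves[lead + 1L] == moves[1L]) lead <- lead + 1L
    trail <- 0L
    while (trail < nmv - lead && moves[nmv - trail] != "M" &&
           moves[nmv - trail] == moves[nmv]) trail <- trail + 1L
    for (k in seq_along(moves)) {
      mv <- moves[k]
      free <- k <= lead || k > nmv - trail
      if (mv == "M") {
        i <- i + 1L; j <- j + 1L
        s <- s + if (ca[i] == cb[j]) match else mismatch
        gap_run <- ""
      } else if (mv == "X") {
        i <- i + 1L
        if (!free) s <- s + gap_extend + if (gap_run != "X") gap_open else 0
        gap_run <- "X"
      } else {
        j <- j + 1L
        if (!free) s <- s + gap_extend + if (gap_run != "Y") gap_open else 0
        gap_run <- "Y"
      }
    }
    s
  }
  recurse <- function(i, j, moves) {
    if (i == n && j == m) {
      if (!any(moves == "M")) {
        # the empty overlap: everything in terminal gaps, score zero
        if (0 > best) best <<- 0
        return(invisible())
      }
      s <- score_path(moves)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1L, j + 1L, c(moves, "M"))
    if (i < n) recurse(i + 1L, j, c(moves, "X"))
    if (j < m) recurse(i, j + 1L, c(moves, "Y"))
  }
  recurse(0L, 0L, character())
  best
}

# expand a chain into an explicit target-base -> query-base map
chain_base_map <- function(ch) {
  segs <- lapply(seq_len(nrow(ch$blocks)), function(k) NULL)
  t <- ch$t_start; q <- ch$q_start
  tpos <- integer(0); qpos <- integer(0)
  for (k in seq_len(nrow(ch$blocks))) {
    sz <- ch$blocks[k, "size"]
    tpos <- c(tpos, t + seq_len(sz) - 1L)
    qpos <- c(qpos, q + seq_len(sz) - 1L)
    t <- t + sz + ch$blocks[k, "dt"]
    q <- q + sz + ch$blocks[k, "dq"]
  }
  if (ch$q_strand == "-") qpos <- ch$q_size - 1L - qpos
  data.frame(t = tpos, q = qpos)
}

# least-squares branch-length fit of a fixed topology to a distance matrix
ls_sse <- function(tree, D) {
  tips <- tree$tip.label
  ne <- nrow(tree$edge)
  pairs <- utils::combn(length(tips), 2)
  A <- matrix(0, ncol(pairs), ne)
  d <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    nodes <- ape::nodepath(tree, i, j)
    for (k in seq_len(length(nodes) - 1L)) {
      e <- which((tree$edge[, 1] == nodes[k] & tree$edge[, 2] == nodes[k + 1]) |
                   (tree$edge[, 2] == nodes[k] & tree$edge[, 1] == nodes[k + 1]))
      A[p, e] <- 1
    }
    d[p] <- D[tips[i], tips[j]]
  }
  fit <- lm.fit(A, d)
  sum(fit$residuals^2)
}

# brute-force best topology by SSE over all unrooted topologies (n <= 6)
ls_best_topology <- function(D) {
  tips <- rownames(D)
  all_t <- phangorn::allTrees(length(tips), rooted = FALSE, tip.label = tips)
  sse <- vapply(all_t, ls_sse, 0, D = D)
  all_t[[which.min(sse)]]
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
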