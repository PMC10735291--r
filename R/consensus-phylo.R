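# Pairwise distances between family consensus sequences and the
# neighbor-joining tree built from them.  Distances come from global
# alignments with free end gaps (terminal gaps reflect model-length
# differences, not substitutions, so they are never counted), corrected with
# the Jukes-Cantor formula d = -(3/4) log(1 - 4p/3).

#' Global pairwise alignment with free end gaps
#'
#' Affine-gap (Gotoh) alignment in which terminal gaps cost nothing, the
#' standard choice for comparing consensus models of unequal length.  An
#' optional transition score implements transition/transversion weighting;
#' by default transitions score like any mismatch.  Ties are broken
#' deterministically (residue pairing preferred over a gap in the second
#' sequence, preferred over a gap in the first).
#'
#' @param a,b Character scalars over ACGTN (or objects coercible via
#'   `as.character`).
#' @param match,mismatch Scores for identical and differing residue pairs.
#' @param transition Score for transitions (A/G, C/T); `NA` (default) scores
#'   transitions as ordinary mismatches.
#' @param gap_open,gap_extend Affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @return An object of class `pairwise_alignment`: a list with aligned
#'   strings `a` and `b`, the optimal `score`, the scoring `params`, and
#'   `columns`, a character vector classifying every aligned column as
#'   `"match"`, `"transition"`, `"transversion"`, `"gap"`, `"end_gap"`, or
#'   `"ambiguous"` (an N in either row).
#' @export
align_free_end_gaps <- function(a, b, match = 1, mismatch = -1,
                                transition = NA, gap_open = -4,
                                gap_extend = -1) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  tr <- if (is.na(transition)) mismatch else transition
  raw <- .gotoh_free_end_gaps(a, b, match, mismatch, tr, gap_open, gap_extend)
  cols <- classify_columns(raw$a, raw$b)
  structure(list(a = raw$a, b = raw$b, score = raw$score,
                 params = list(match = match, mismatch = mismatch,
                               transition = transition, gap_open = gap_open,
                               gap_extend = gap_extend),
                 columns = cols),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise alignment, score", x$score, "\n")
  cat(substr(x$a, 1, 60), if (nchar(x$a) > 60) "...", "\n")
  cat(substr(x$b, 1, 60), if (nchar(x$b) > 60) "...", "\n")
  invisible(x)
}

#' Classify the columns of a pairwise alignment
#'
#' Terminal gap runs of either row are `"end_gap"`; remaining columns with a
#' gap are `"gap"`; residue pairs are `"match"`, `"transition"`,
#' `"transversion"`, or `"ambiguous"` when an N is involved.
#'
#' @param a_aln,b_aln Aligned strings of equal length (with `-` gaps).
#' @return Character vector, one entry per column.
#' @export
classify_columns <- function(a_aln, b_aln) {
  ca <- strsplit(a_aln, "")[[1]]
  cb <- strsplit(b_aln, "")[[1]]
  stopifnot(length(ca) == length(cb))
  n <- length(ca)
  end_run <- function(g) {       # TRUE inside the leading/trailing gap run
    lead <- cumprod(g) > 0
    trail <- rev(cumprod(rev(g)) > 0)
    lead | trail
  }
  is_end <- end_run(ca == "-") | end_run(cb == "-")
  out <- character(n)
  gap <- (ca == "-" | cb == "-")
  amb <- (!gap) & (ca == "N" | cb == "N")
  ts <- (ca == "A" & cb == "G") | (ca == "G" & cb == "A") |
        (ca == "C" & cb == "T") | (ca == "T" & cb == "C")
  out[gap] <- "gap"
  out[!gap & amb] <- "ambiguous"
  out[!gap & !amb & ca == cb] <- "match"
  out[!gap & !amb & ca != cb & ts] <- "transition"
  out[!gap & !amb & ca != cb & !ts] <- "transversion"
  out[is_end] <- "end_gap"
  out
}

#' Jukes-Cantor corrected distance of a pairwise alignment
#'
#' The observed mismatch fraction p is computed over internal residue-pair
#' columns only (gap, end-gap and ambiguous columns are excluded; all
#' mismatches count equally, as the one-parameter model assumes) and
#' corrected as d = -(3/4) log(1 - 4p/3).  At p >= 3/4 the correction is
#' undefined: the distance is returned as `Inf` with attribute
#' `saturated = TRUE`.
#'
#' @param alignment A `pairwise_alignment` from [align_free_end_gaps()].
#' @return Numeric distance with attributes `p` (observed proportion),
#'   `n_sites` (compared columns) and `saturated`.
#' @export
jc_distance <- function(alignment) {
  cols <- alignment$columns
  compared <- cols %in% c("match", "transition", "transversion")
  n <- sum(compared)
  if (n == 0L) stop("no comparable (internal, unambiguous) columns")
  p <- sum(cols %in% c("transition", "transversion")) / n
  if (p >= 0.75) {
    d <- Inf
    saturated <- TRUE
  } else {
    d <- -0.75 * log(1 - 4 * p / 3)
    saturated <- FALSE
  }
  structure(d, p = p, n_sites = n, saturated = saturated)
}

#' Pairwise Jukes-Cantor distance matrix of consensus sequences
#'
#' @param seqs Named character vector or `DNAStringSet` of consensus
#'   sequences.
#' @param ... Scoring parameters passed to [align_free_end_gaps()].
#' @return Symmetric numeric matrix with zero diagonal; saturated pairs are
#'   `Inf` and flagged in attribute `saturated` (logical matrix).
#' @export
consensus_dist_matrix <- function(seqs, ...) {
  nm <- names(seqs)
  seqs <- stats::setNames(as.character(seqs), nm)
  if (is.null(nm) || anyDuplicated(nm)) stop("sequences must have unique names")
  k <- length(seqs)
  D <- matrix(0, k, k, dimnames = list(nm, nm))
  S <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- jc_distance(align_free_end_gaps(seqs[[i]], seqs[[j]], ...))
    D[i, j] <- D[j, i] <- as.numeric(d)
    S[i, j] <- S[j, i] <- attr(d, "saturated")
  }
  attr(D, "saturated") <- S
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining (Q-matrix pair selection, standard branch-length
#' formulas), written out explicitly so the pair-selection tie-break is
#' defined: among equal-Q pairs the lexicographically first taxon pair (in
#' the current label order) is joined.  Negative branch lengths are clamped
#' to zero with a message.  The result is the unrooted tree as an
#' [ape::phylo] object.
#'
#' @param D Symmetric distance matrix with taxon dimnames, at least 3 taxa.
#' @param allow_saturated Proceed even if `D` contains non-finite
#'   (saturated) entries, capping them just beyond the largest finite
#'   distance (default `FALSE`: error).
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(D, allow_saturated = FALSE) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!all(is.finite(D)) && !allow_saturated)
    stop("distance matrix contains saturated (non-finite) entries")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(D)))
  if (!all(is.finite(D))) {
    # saturated pairs carry no usable signal; cap them at a distance beyond
    # every observed one so the join order degrades gracefully
    cap <- 1.25 * max(D[is.finite(D)])
    D[!is.finite(D)] <- cap
    message("saturated distances capped at ", format(cap, digits = 4))
  }
  sub <- labs                      # Newick subtree string per active node
  act <- D
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    format(max(x, 0), digits = 12, scientific = FALSE, trim = TRUE)
  }
  while (nrow(act) > 3L) {
    n <- nrow(act)
    r <- rowSums(act)
    Q <- (n - 2) * act - outer(r, r, "+")
    diag(Q) <- Inf
    # first minimum scanning pairs (i < j) in current order => lexicographic
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (Q[i, j] < bq) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    vi <- act[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- act[i, j] - vi
    du <- (act[i, ] + act[j, ] - act[i, j]) / 2
    new_sub <- sprintf("(%s:%s,%s:%s)", sub[i], bl(vi), sub[j], bl(vj))
    keep <- setdiff(seq_len(n), c(i, j))
    act <- rbind(cbind(act[keep, keep, drop = FALSE], du[keep]),
                 c(du[keep], 0))
    sub <- c(sub[keep], new_sub)
  }
  # three-point formulas close the unrooted tree
  va <- (act[1, 2] + act[1, 3] - act[2, 3]) / 2
  vb <- (act[1, 2] + act[2, 3] - act[1, 3]) / 2
  vc <- (act[1, 3] + act[2, 3] - act[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 sub[1], bl(va), sub[2], bl(vb), sub[3], bl(vc))
  if (clamped) message("negative branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

#' Does a taxon subset form a split of the unrooted tree?
#'
#' Tests whether `taxa_subset` is a clade on some rooting, i.e. whether an
#' edge of the unrooted tree separates exactly that subset from the rest.
#' When it does, the sister group is also reported: the two subtrees
#' attached on the far side of the split edge partition the complement, and
#' the smaller of the two (ties broken lexicographically) is returned as the
#' sister.
#'
#' @param tree A `phylo` tree.
#' @param taxa_subset Character vector of tip labels.
#' @return A list with `is_clade` (logical) and `sister` (character vector
#'   of tips, or `NULL` when not a clade or the split is trivial).
#' @export
clade_check <- function(tree, taxa_subset) {
  tips <- tree$tip.label
  unknown <- setdiff(taxa_subset, tips)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  sub <- unique(taxa_subset)
  if (length(sub) %in% c(1L, length(tips)))
    return(list(is_clade = TRUE, sister = NULL))
  tr <- ape::unroot(tree)
  ntip <- length(tips)
  # tip set below each edge (child side), on the current (arbitrary) rooting
  desc <- vector("list", max(tr$edge))
  for (k in seq_len(ntip)) desc[[k]] <- tips[k]
  for (e in ape::postorder(tr)) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  match_edge <- NA_integer_
  for (e in seq_len(nrow(tr$edge))) {
    below <- desc[[tr$edge[e, 2]]]
    if (setequal(below, sub) || setequal(setdiff(tips, below), sub)) {
      match_edge <- e
      break
    }
  }
  if (is.na(match_edge)) return(list(is_clade = FALSE, sister = NULL))
  comp <- setdiff(tips, sub)
  if (length(comp) == 1L) return(list(is_clade = TRUE, sister = comp))
  # node on the complement side of the split edge; the two subtrees hanging
  # off it partition the complement into the candidate sister groups
  below <- desc[[tr$edge[match_edge, 2]]]
  far <- if (setequal(below, sub)) tr$edge[match_edge, 1] else tr$edge[match_edge, 2]
  inc <- setdiff(which(tr$edge[, 1] == far | tr$edge[, 2] == far), match_edge)
  groups <- list()
  for (e in inc) {
    g <- if (tr$edge[e, 1] == far) desc[[tr$edge[e, 2]]]
         else setdiff(tips, desc[[far]])
    g <- sort(intersect(comp, g))
    if (length(g)) groups[[length(groups) + 1L]] <- g
  }
  groups <- unique(groups)
  if (!length(groups)) return(list(is_clade = TRUE, sister = NULL))
  sizes <- lengths(groups)
  firsts <- vapply(groups, `[`, character(1), 1)
  pick <- order(sizes, firsts)[1]
  list(is_clade = TRUE, sister = groups[[pick]])
}
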