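# Genotyping element copies against a family consensus for named structural
# variants, staging elements of the THE1B -> THE1A transition, and finding
# uniquely shared consensus features between family pairs.  Variant
# coordinates follow the 1-based consensus convention repeat biologists
# write (e.g. "204del" = deletion of consensus base 204); conversion to the
# package's internal conventions happens at this schema boundary.

#' Build a structural-variant definition table
#'
#' @param name Variant names (e.g. `"204del"`).
#' @param kind `"insertion"`, `"deletion"`, or `"delins"`.
#' @param start,end 1-based consensus coordinates.  For a deletion/delins,
#'   the deleted range; for an insertion, `start` is the consensus base
#'   after which material is inserted (`end` must equal `start`).
#' @param replacement Inserted/replacing sequence: required for insertion
#'   and delins (for a plain insertion it is used when planting, but its
#'   content is not matched when genotyping); empty for deletions.
#' @return A `variant_defs` data frame.
#' @export
variant_defs <- function(name, kind, start, end, replacement = "") {
  stopifnot(all(kind %in% c("insertion", "deletion", "delins")),
            all(start <= end), all(start >= 1))
  if (any(kind == "insertion" & start != end))
    stop("insertion variants must have start == end (the anchor base)")
  if (any(kind %in% c("insertion", "delins") & !nzchar(rep(replacement,
                                                           length.out = length(name)))))
    stop("insertion/delins variants need a replacement sequence")
  structure(data.frame(name = name, kind = kind, start = as.integer(start),
                       end = as.integer(end),
                       replacement = rep(replacement, length.out = length(name)),
                       stringsAsFactors = FALSE),
            class = c("variant_defs", "data.frame"))
}

#' The named structural variants of the THE1B -> THE1A transition
#'
#' The four variants distinguishing the THE1A from the THE1B LTR consensus
#' (186ins, 204del, 226_235del, 303_312delinsTT; the delins replacement TT
#' is matched by content, the 186ins content is not), plus the 16-bp
#' 227_242del that marks the tarsier-specific MSTB1 successor.  204del
#' falls inside the putative ZNF100-bound locus.
#'
#' @param include_227_242del Also include the 16-bp deletion used for the
#'   tarsier-lineage family (off by default: it overlaps 226_235del and the
#'   two are never genotyped on the same family).
#' @return A `variant_defs` table.
#' @export
the1_variant_defs <- function(include_227_242del = FALSE) {
  v <- variant_defs(
    name = c("186ins", "204del", "226_235del", "303_312delinsTT"),
    kind = c("insertion", "deletion", "deletion", "delins"),
    start = c(186L, 204L, 226L, 303L),
    end = c(186L, 204L, 235L, 312L),
    replacement = c("G", "", "", "TT"))
  if (include_227_242del) {
    v <- rbind(v, variant_defs("227_242del", "deletion", 227L, 242L, ""))
    class(v) <- c("variant_defs", "data.frame")
  }
  v
}

.check_overlap <- function(defs) {
  if (nrow(defs) < 2L) return(invisible())
  iv <- defs[order(defs$start), ]
  for (k in seq_len(nrow(iv) - 1L)) {
    hi <- if (iv$kind[k] == "insertion") iv$start[k] else iv$end[k]
    lo_next <- if (iv$kind[k + 1L] == "insertion") iv$start[k + 1L] + 1L
               else iv$start[k + 1L]
    if (lo_next <= hi)
      stop("overlapping variant definitions: ", iv$name[k], " and ",
           iv$name[k + 1L])
  }
  invisible()
}

#' Apply a subset of variants to a consensus sequence
#'
#' @param seq Consensus sequence (character).
#' @param defs [variant_defs()] table.
#' @param which_names Names of the variants to apply (default: all).
#' @return The edited sequence.
#' @export
apply_variants <- function(seq, defs, which_names = defs$name) {
  d <- defs[defs$name %in% which_names, , drop = FALSE]
  if (!all(which_names %in% defs$name))
    stop("unknown variant: ",
         paste(setdiff(which_names, defs$name), collapse = ", "))
  .check_overlap(d)
  if (any(d$end > nchar(seq))) stop("variant coordinates exceed consensus length")
  d <- d[order(d$start, decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(d))) {
    pre <- substring(seq, 1, if (d$kind[k] == "insertion") d$start[k]
                             else d$start[k] - 1L)
    post <- substring(seq, d$end[k] + 1L)
    mid <- switch(d$kind[k], insertion = d$replacement[k], deletion = "",
                  delins = d$replacement[k])
    seq <- paste0(pre, mid, post)
  }
  seq
}

#' Per-stage variant sets of the THE1B -> THE1A chronology
#'
#' The precursor stage carries the three indels (186ins, 226_235del,
#' 303_312delinsTT) in both LTRs; the intermediate stage adds 204del in the
#' 5' LTR only; the canonical stage carries all four in both LTRs.
#'
#' @param defs A [variant_defs()] table containing the four variants.
#' @return Named list of lists with `ltr5`/`ltr3` character vectors.
#' @export
stage_variant_sets <- function(defs = the1_variant_defs()) {
  three <- c("186ins", "226_235del", "303_312delinsTT")
  stopifnot(all(c(three, "204del") %in% defs$name))
  list(precursor = list(ltr5 = three, ltr3 = three),
       intermediate = list(ltr5 = c(three, "204del"), ltr3 = three),
       canonical = list(ltr5 = c(three, "204del"), ltr3 = c(three, "204del")))
}

#' Define the LTR segment boundaries used by the replication logic
#'
#' LTRs are composed of U3, R and U5 segments; the transcription start site
#' sits at the U3/R boundary.  One replication round copies the R and U5 of
#' the parental 5' LTR into both progeny LTRs and the U3 of the parental 3'
#' LTR into both, so a variant's segment decides which parental side it is
#' inherited from.  Boundaries are mandatory: the progeny prediction
#' refuses variants spanning the U3/R boundary.
#'
#' @param u3_end Last consensus position of U3 (= TSS - 1).
#' @param length LTR consensus length.
#' @param r_end Optional last position of R (only U3 vs R/U5 matters to the
#'   replication logic).
#' @return An `ltr_model` list.
#' @export
ltr_model <- function(u3_end, length, r_end = NULL) {
  stopifnot(u3_end >= 1, u3_end < length)
  if (!is.null(r_end)) stopifnot(r_end > u3_end, r_end <= length)
  structure(list(u3_end = as.integer(u3_end), length = as.integer(length),
                 r_end = r_end, tss = as.integer(u3_end) + 1L),
            class = "ltr_model")
}

#' Segment of a variant under an LTR model
#' @param defs [variant_defs()] rows.
#' @param model [ltr_model()].
#' @return `"U3"` or `"RU5"` per variant; error when one spans the boundary.
#' @export
variant_segment <- function(defs, model) {
  seg <- ifelse(defs$end <= model$u3_end, "U3",
                ifelse(defs$start > model$u3_end, "RU5", NA))
  if (anyNA(seg))
    stop("variant spans the U3/R boundary; assign its segment explicitly: ",
         paste(defs$name[is.na(seg)], collapse = ", "))
  stats::setNames(seg, defs$name)
}

# Locate the two LTRs of a full-length element by anchoring the consensus
# LTR at each end with a free-end-gap alignment.
.locate_ltrs <- function(element, consensus_ltr, min_internal = 50, ...) {
  L <- nchar(consensus_ltr)
  n <- nchar(element)
  win <- min(n, ceiling(1.6 * L))
  hit <- function(sub, offset) {
    al <- align_free_end_gaps(consensus_ltr, sub, ...)
    ca <- strsplit(al$a, "")[[1]]
    cb <- strsplit(al$b, "")[[1]]
    bpos <- cumsum(cb != "-")
    cov <- which(ca != "-" & cb != "-")
    if (!length(cov)) return(NULL)
    c(start = offset + bpos[cov[1]], end = offset + bpos[cov[length(cov)]])
  }
  h5 <- hit(substring(element, 1, win), 0L)
  h3 <- hit(substring(element, n - win + 1L, n), n - win)
  if (is.null(h5) || is.null(h3)) return(NULL)
  if (h3["start"] - h5["end"] - 1L < min_internal) return(NULL)
  list(ltr5 = substring(element, h5["start"], h5["end"]),
       ltr3 = substring(element, h3["start"], h3["end"]))
}

#' Genotype one element's LTRs for named structural variants
#'
#' Detects the 5' and 3' LTR by anchoring the consensus LTR at the two ends
#' of the element (an element without two LTRs separated by an internal
#' region is reported as solo/partial and is not staged) and aligns each
#' LTR globally (free end gaps) to the consensus.  Landmark consensus
#' positions are then placed midway between consecutive variant loci (and
#' `flank` bases outside the outermost ones), nudged by at most
#' `max_nudge` positions to a column where consensus and element residues
#' pair; each variant is read off the *element-side segment length*
#' between its two landmarks, so equally scoring alternative gap
#' placements inside the segment cannot disturb the call.  A deletion of k
#' bases is *present* when the segment is exactly k bases short, *absent*
#' when it has the full consensus length; an insertion is *present* when
#' the segment is longer than the consensus; a delins is *present* when
#' the length signature matches the replacement (the element bases at the
#' locus are compared with the replacement content and reported in
#' `content_ok`, tolerating `floor(r/2)` mismatches, but the length
#' signature decides the call — the replacement's own bases diverge like
#' any others).  Any other
#' segment length — an unrelated indel at the locus — and any landmark
#' that cannot be placed make the variant *uncallable* at that LTR.
#'
#' @param element_seq Element sequence (5'LTR-internal-3'LTR).
#' @param consensus_ltr Reference LTR consensus.
#' @param defs [variant_defs()].
#' @param flank Consensus bases beyond the outermost variants for the outer
#'   landmarks.
#' @param max_nudge Maximum landmark displacement towards a clean column.
#' @param ... Alignment parameters for [align_free_end_gaps()].
#' @return Data frame `side`, `variant`, `status`
#'   (`present`/`absent`/`uncallable`), `delta_len` (element-segment length
#'   minus consensus-segment length at the locus) and `content_ok`
#'   (delins content corroboration; `NA` for other kinds); or `NULL` when
#'   the element is solo/partial.
#' @export
call_variants <- function(element_seq, consensus_ltr, defs, flank = 25,
                          max_nudge = 6, ...) {
  ltrs <- .locate_ltrs(element_seq, consensus_ltr, ...)
  if (is.null(ltrs)) return(NULL)
  d <- defs[order(defs$start), , drop = FALSE]
  .check_overlap(d)
  Lc <- nchar(consensus_ltr)
  # landmark targets: outside the outermost variants and midway between
  # consecutive ones; landmark i-1 and i bracket variant i
  v_lo <- ifelse(d$kind == "insertion", d$start, d$start - 1L)
  v_hi <- ifelse(d$kind == "insertion", d$start + 1L, d$end + 1L)
  targets <- as.integer(c(max(1L, v_lo[1] - flank),
                          if (nrow(d) > 1L)
                            floor((v_hi[-nrow(d)] + v_lo[-1]) / 2),
                          min(Lc, v_hi[nrow(d)] + flank)))
  lo_bound <- as.integer(c(1L, v_hi[-nrow(d)]))  # nudging must stay between
  hi_bound <- as.integer(c(v_lo[-1], Lc))        # the neighboring variants
  out <- lapply(names(ltrs), function(side) {
    al <- align_free_end_gaps(consensus_ltr, ltrs[[side]], ...)
    ca <- strsplit(al$a, "")[[1]]
    cb <- strsplit(al$b, "")[[1]]
    apos <- cumsum(ca != "-")
    bpos <- cumsum(cb != "-")
    bcol <- rep(NA_integer_, Lc)               # column of consensus pos p
    bcol[apos[ca != "-"]] <- which(ca != "-")
    clean <- !is.na(bcol) & cb[pmax(bcol, 1L)] != "-"
    place <- function(k) {                     # landmark k
      p <- targets[k]
      lo <- if (k == 1L) 1L else lo_bound[k - 1L] + 1L
      hi <- if (k == length(targets)) Lc else hi_bound[k] - 1L
      for (off in c(0L, as.vector(rbind(seq_len(max_nudge),
                                        -seq_len(max_nudge))))) {
        q <- p + off
        if (q >= lo && q <= hi && q >= 1L && q <= Lc && clean[q]) return(as.integer(q))
      }
      NA_integer_
    }
    lm <- vapply(seq_along(targets), place, 0L)
    one <- function(k) {
      v <- d[k, ]
      pl <- lm[k]; pr <- lm[k + 1L]
      if (is.na(pl) || is.na(pr))
        return(data.frame(side = side, variant = v$name,
                          status = "uncallable", delta_len = NA_integer_,
                          stringsAsFactors = FALSE))
      seg_el <- bpos[bcol[pr]] - bpos[bcol[pl]] - 1L   # element bases between
      seg_cons <- pr - pl - 1L
      delta <- seg_el - seg_cons
      k_del <- if (v$kind == "insertion") 0L else v$end - v$start + 1L
      r <- nchar(v$replacement)
      content_ok <- NA
      status <- switch(v$kind,
        deletion = if (delta == -k_del) "present"
                   else if (delta == 0L) "absent" else "uncallable",
        insertion = if (delta >= 1L) "present"
                    else if (delta == 0L) "absent" else "uncallable",
        delins = {
          if (delta == r - k_del) {
            # the replacement sits a fixed element distance from the left
            # landmark (no other indels inside the segment at this delta);
            # its content corroborates the call but the length signature
            # decides it, since the replacement's own bases diverge like
            # any others
            at <- bpos[bcol[pl]] + (v$start - pl)
            core <- substring(ltrs[[side]], at, at + r - 1L)
            mism <- sum(strsplit(core, "")[[1]] !=
                          strsplit(v$replacement, "")[[1]])
            content_ok <- mism <= floor(r / 2)
            "present"
          } else if (delta == 0L) "absent" else "uncallable"
        })
      data.frame(side = side, variant = v$name, status = status,
                 delta_len = delta, content_ok = content_ok,
                 stringsAsFactors = FALSE)
    }
    do.call(rbind, lapply(seq_len(nrow(d)), one))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify an element's THE1A-lineage stage from its per-LTR calls
#'
#' Pattern-matches the stage definitions: *precursor* = the three indels
#' present in both LTRs and the late variant absent from both;
#' *intermediate* = the three indels in both plus the late variant in the
#' 5' LTR only; *canonical* = all four in both.  Anything else — including
#' any uncallable variant among the four — is `other`, with the observed
#' pattern attached.
#'
#' @param calls Call table from [call_variants()].
#' @param indels_both The three early variants expected in both LTRs.
#' @param late_variant The variant whose per-LTR spread orders the stages.
#' @return List with `stage` and `pattern` (side x variant status matrix).
#' @export
classify_stage <- function(calls,
                           indels_both = c("186ins", "226_235del",
                                           "303_312delinsTT"),
                           late_variant = "204del") {
  vars <- c(indels_both, late_variant)
  pat <- with(calls[calls$variant %in% vars, ],
              tapply(status, list(side, variant), identity))
  if (any(is.na(pat)) || any(pat == "uncallable"))
    return(list(stage = "other", pattern = pat, reason = "uncallable variant"))
  p5 <- pat["ltr5", ]; p3 <- pat["ltr3", ]
  three_both <- all(p5[indels_both] == "present") &&
    all(p3[indels_both] == "present")
  late5 <- p5[late_variant] == "present"
  late3 <- p3[late_variant] == "present"
  stage <- if (three_both && !late5 && !late3) "precursor"
  else if (three_both && late5 && !late3) "intermediate"
  else if (three_both && late5 && late3) "canonical"
  else "other"
  list(stage = stage, pattern = pat)
}

#' Predict the per-LTR variant pattern after one replication round
#'
#' LTR replication copies the R/U5 of the parental 5' LTR and the U3 of the
#' parental 3' LTR into both progeny LTRs (both progeny LTRs are identical
#' at birth).  Each variant is inherited from the parental side its segment
#' is read from.
#'
#' @param pattern List with named logical vectors `ltr5` and `ltr3`
#'   (variant present?), e.g. built from a [call_variants()] table.
#' @param defs [variant_defs()] for the variants in `pattern`.
#' @param model [ltr_model()].
#' @return List `ltr5`, `ltr3` (identical named logical vectors).
#' @export
predict_progeny_ltr <- function(pattern, defs, model) {
  vars <- names(pattern$ltr5)
  stopifnot(setequal(vars, names(pattern$ltr3)), all(vars %in% defs$name))
  seg <- variant_segment(defs[match(vars, defs$name), ], model)
  prog <- ifelse(seg[vars] == "U3", pattern$ltr3[vars], pattern$ltr5[vars])
  names(prog) <- vars
  list(ltr5 = prog, ltr3 = prog)
}

#' Pattern list from a call table
#' @param calls [call_variants()] output.
#' @return List `ltr5`, `ltr3` of named logicals (`NA` for uncallable).
#' @export
calls_to_pattern <- function(calls) {
  mk <- function(side) {
    x <- calls[calls$side == side, ]
    stats::setNames(ifelse(x$status == "uncallable", NA,
                           x$status == "present"), x$variant)
  }
  list(ltr5 = mk("ltr5"), ltr3 = mk("ltr3"))
}

#' Stage every element of a population
#'
#' @param elements Named character vector (or `DNAStringSet`) of
#'   full-length element sequences.
#' @param consensus_ltr Reference LTR consensus.
#' @param defs [variant_defs()].
#' @param ... Passed to [call_variants()].
#' @return Data frame `element`, `stage`, `pattern` (collapsed string);
#'   solo/partial elements get stage `solo_or_partial`.  Attribute
#'   `summary` holds the per-stage counts.
#' @export
scan_for_stage <- function(elements, consensus_ltr, defs, ...) {
  ids <- names(elements)
  elements <- as.character(elements)
  if (is.null(ids)) ids <- paste0("el", seq_along(elements))
  if (!length(elements)) {
    out <- data.frame(element = character(), stage = character(),
                      pattern = character(), stringsAsFactors = FALSE)
    attr(out, "summary") <- table(out$stage)
    return(out)
  }
  rows <- lapply(seq_along(elements), function(i) {
    calls <- call_variants(elements[[i]], consensus_ltr, defs, ...)
    if (is.null(calls))
      return(data.frame(element = ids[i], stage = "solo_or_partial",
                        pattern = NA_character_, stringsAsFactors = FALSE))
    st <- classify_stage(calls)
    pat <- paste(calls$side, calls$variant, calls$status, sep = ":",
                 collapse = ";")
    data.frame(element = ids[i], stage = st$stage, pattern = pat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- table(out$stage)
  out
}

#' Uniquely shared consensus blocks between two families
#'
#' Projects `b` and every background consensus onto `a`'s coordinate frame
#' through pairwise free-end-gap alignments and reports maximal column runs
#' of at least `min_len` positions where `a` and `b` carry the identical
#' residue while every background consensus differs or is gapped there; up
#' to `max_violation` of the columns inside a block may break the rule
#' (absorbing post-divergence substitutions).  Blocks are reported in `a`'s
#' 1-based coordinates.
#'
#' @param consensus_a,consensus_b The pair of sequences.
#' @param background_consensuses Named character vector (>= 1 sequence).
#' @param min_len Minimum block length in columns.
#' @param max_violation Tolerated fraction of violating columns per block.
#' @param ... Alignment parameters.
#' @return Data frame `start`, `end`, `length`, `n_violations`.
#' @export
shared_features <- function(consensus_a, consensus_b, background_consensuses,
                            min_len = 10, max_violation = 0.1, ...) {
  if (length(background_consensuses) < 1L)
    stop("uniqueness is undefined without at least one background consensus")
  a_chars <- strsplit(toupper(consensus_a), "")[[1]]
  proj <- function(s) {
    al <- align_free_end_gaps(consensus_a, s, ...)
    ca <- strsplit(al$a, "")[[1]]
    cb <- strsplit(al$b, "")[[1]]
    apos <- cumsum(ca != "-")
    res <- rep("-", length(a_chars))
    keep <- ca != "-"
    res[apos[keep]] <- cb[keep]
    res
  }
  pb <- proj(consensus_b)
  bg <- lapply(background_consensuses, proj)
  good <- pb == a_chars
  for (g in bg) good <- good & (g != a_chars)
  n <- length(good)
  blocks <- list()
  i <- 1L
  while (i <= n) {
    if (!good[i]) { i <- i + 1L; next }
    bad <- 0L
    best_j <- i
    best_bad <- 0L
    j <- i
    while (j < n) {
      j <- j + 1L
      bad <- bad + !good[j]
      if (good[j] && bad / (j - i + 1L) <= max_violation) {
        best_j <- j
        best_bad <- bad
      }
    }
    if (best_j - i + 1L >= min_len) {
      blocks[[length(blocks) + 1L]] <-
        data.frame(start = i, end = best_j, length = best_j - i + 1L,
                   n_violations = best_bad)
      i <- best_j + 1L
    } else i <- i + 1L
  }
  if (!length(blocks))
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), n_violations = integer()))
  do.call(rbind, blocks)
}

#' Shared-feature support for an ordered succession chain
#'
#' For each adjacent pair of the proposed chain, runs [shared_features()]
#' with the remaining chain members as background and reports the number of
#' uniquely shared blocks and their total length — the evidence expected to
#' concentrate on true predecessor/successor pairs.
#'
#' @param family_chain Character vector of family names in proposed order.
#' @param consensuses Named character vector covering the chain.
#' @param min_len,max_violation,... Passed to [shared_features()].
#' @return Data frame `member_a`, `member_b`, `n_blocks`, `total_len`.
#' @export
succession_support <- function(family_chain, consensuses, min_len = 10,
                               max_violation = 0.1, ...) {
  miss <- setdiff(family_chain, names(consensuses))
  if (length(miss)) stop("missing consensus for: ", paste(miss, collapse = ", "))
  if (length(family_chain) < 2L) stop("chain needs at least two members")
  rows <- lapply(seq_len(length(family_chain) - 1L), function(k) {
    a <- family_chain[k]; b <- family_chain[k + 1L]
    # background = every other consensus supplied (the rest of the chain,
    # plus any out-of-chain relatives passed along)
    bgn <- setdiff(names(consensuses), c(a, b))
    bl <- shared_features(consensuses[[a]], consensuses[[b]],
                          consensuses[bgn], min_len = min_len,
                          max_violation = max_violation, ...)
    data.frame(member_a = a, member_b = b, n_blocks = nrow(bl),
               total_len = sum(bl$length), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Synthetic THE1-like consensus sequences
#'
#' A deterministic, synthetic stand-in for the THE1B LTR and internal
#' consensus: random sequences of realistic lengths (364-bp LTR, 1.5-kb
#' internal) on which the named variant coordinates are valid.  Used by the
#' simulators, the worked examples and the tests; it is not the Dfam model.
#'
#' @param ltr_len,internal_len Sequence lengths.
#' @param seed Seed for the generating RNG stream.
#' @return List with `ltr` and `internal` character sequences.
#' @export
synthetic_the1_consensus <- function(ltr_len = 364, internal_len = 1500,
                                     seed = 42) {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  list(ltr = random_dna(ltr_len), internal = random_dna(internal_len))
}
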