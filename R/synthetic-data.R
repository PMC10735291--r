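# Synthetic genome evolution under successive transposon-family activity.
#
# The simulator emulates the inputs the pipeline consumes in the real world:
# per-species RepeatMasker-style annotations produced by family activity
# along a species tree, fragmented (nested) annotations, liftOver chains
# with gaps, consensus sequences, diverged copies, and a machine-readable
# truth table tying every annotation row to its generating insertion.
# Genomes are represented as coordinate systems (ordered "pieces") plus
# element sequences; small scenarios can additionally be assembled into
# chromosome FASTA.

.BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Three-species primate-like tree with two successive splits
#'
#' A rooted tree on (human, tarsier, bushbaby) with the bushbaby lineage
#' diverging at pseudo-time `split_hs` (the earlier split) and the tarsier
#' lineage at `split_st` (the later split); pseudo-time runs from 0 at the
#' root to 1 at the present.  An insertion on the focal (human) lineage at
#' time t is shared by all three species when t < `split_hs`, by human and
#' tarsier only when `split_hs <= t < split_st`, and is human-specific
#' afterwards.
#'
#' @param split_hs,split_st Split times in (0, 1), `split_hs < split_st`.
#' @return A list with the `phylo` tree, the `splits`, and `tips`.
#' @export
primate_tree <- function(split_hs = 0.3, split_st = 0.5) {
  stopifnot(0 < split_hs, split_hs < split_st, split_st < 1)
  nwk <- sprintf("((human:%g,tarsier:%g):%g,bushbaby:%g);",
                 1 - split_st, 1 - split_st, split_st - split_hs, 1 - split_hs)
  list(phylo = ape::read.tree(text = nwk),
       splits = c(hs = split_hs, st = split_st),
       tips = c("human", "tarsier", "bushbaby"))
}

#' Define one family's activity model
#'
#' Activity on pseudo-time is a Normal(mu, sigma^2) truncated to [0, 1]
#' (pseudo-time increases toward the present); each of the `n_copies`
#' simulated insertions draws its time from this distribution and diverges
#' from the consensus by iid substitutions and occasional short indels.
#'
#' @param name Family name.
#' @param consensus Consensus sequence (character); if `NULL` a random
#'   sequence of `length` bases is generated from the current RNG stream.
#' @param mu,sigma Activity center and width on pseudo-time.
#' @param n_copies Insertions to simulate.
#' @param sub_rate Per-base substitution probability per copy.
#' @param indel_rate Expected short (1-3 bp) indels per base per copy.
#' @param length Consensus length when `consensus` is `NULL`.
#' @return A `family_model` list.
#' @export
family_model <- function(name, consensus = NULL, mu, sigma, n_copies,
                         sub_rate = 0.05, indel_rate = 0.0005,
                         length = 400) {
  stopifnot(sigma > 0, n_copies >= 0)
  if (is.null(consensus)) consensus <- random_dna(length)
  structure(list(name = name, consensus = toupper(consensus), mu = mu,
                 sigma = sigma, n_copies = n_copies, sub_rate = sub_rate,
                 indel_rate = indel_rate),
            class = "family_model")
}

# truncated-normal draw on [0, 1] via the inverse CDF
.rtrunc01 <- function(n, mu, sigma) {
  lo <- stats::pnorm(0, mu, sigma)
  hi <- stats::pnorm(1, mu, sigma)
  stats::qnorm(stats::runif(n, lo, hi), mu, sigma)
}

#' Mutate a sequence by iid substitutions and short indels
#'
#' @param seq Character scalar.
#' @param sub_rate Per-base substitution probability.
#' @param indel_rate Expected 1-3 bp indels per base.
#' @return Mutated character scalar.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate = 0) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < sub_rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(.BASES, b), 1), "")
  }
  n_ind <- stats::rpois(1, length(ch) * indel_rate)
  for (k in seq_len(n_ind)) {
    w <- sample(3, 1)
    if (stats::runif(1) < 0.5 && length(ch) > w + 1) {         # deletion
      at <- sample(length(ch) - w, 1)
      ch <- ch[-(at:(at + w - 1))]
    } else {                                                    # insertion
      at <- sample(length(ch), 1)
      ch <- append(ch, sample(.BASES, w, replace = TRUE), after = at)
    }
  }
  paste(ch, collapse = "")
}

#' Simulate a succession scenario end to end
#'
#' Draws every insertion's pseudo-time from its family's truncated-normal
#' activity window, assigns it to the tree branch spanning that time (which
#' fixes its presence in each descendant species), places it on the focal
#' genome — either at a fresh top-level site, separated from its neighbors
#' by `spacer` bases of shared backbone, or, with probability `p_nest`,
#' inside an older copy drawn uniformly from the existing ones, splitting
#' the host annotation into consensus-contiguous fragments that share the
#' host's repeat ID (hosts may be hit more than once; the depth of
#' nesting chains is capped at 2) — and diverges the copy from its
#' consensus.  Chains from the focal
#' species to every other species are derived exactly from the simulated
#' coordinate maps: shared pieces become aligned blocks, focal-specific
#' pieces become target-side gaps.  Deterministic given `seed`.
#'
#' @param tree From [primate_tree()].
#' @param families List of [family_model()] objects, oldest first by
#'   convention (the order is not used, only the activity times are).
#' @param seed Integer seed (mandatory).
#' @param spacer Backbone bases between adjacent top-level insertions; must
#'   be at least twice the flank length used downstream so that flanks of
#'   neighboring insertions never overlap another element.
#' @param p_nest Probability that an insertion nests inside an eligible
#'   older copy.
#' @param nest_margin Minimum host bases left on each side of a nested
#'   insertion.
#' @return A `succession_bundle`: list with `copies` (per-species
#'   RepeatMasker-style copy tables), `chains` (focal genome to each other
#'   species), `truth` (one row per insertion), `consensus` (named character
#'   vector), `elements` (consensus-orientation element sequences),
#'   `pieces`, `genome_length` per species, and the scenario parameters.
#' @export
simulate_succession <- function(tree, families, seed, spacer = 700,
                                p_nest = 0.15, nest_margin = 25) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  spacer <- as.integer(spacer)
  nest_margin <- as.integer(nest_margin)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))

  fam_names <- vapply(families, `[[`, "", "name")
  names(families) <- fam_names
  total <- sum(vapply(families, `[[`, 0, "n_copies"))
  if (total == 0L) stop("no copies requested")

  # 1. insertion times and species presence
  ins <- do.call(rbind, lapply(families, function(f) {
    if (f$n_copies == 0) return(NULL)
    data.frame(family = f$name, t = .rtrunc01(f$n_copies, f$mu, f$sigma),
               stringsAsFactors = FALSE)
  }))
  ins <- ins[order(ins$t), , drop = FALSE]
  ins$id <- seq_len(nrow(ins))
  sp <- tree$splits
  ins$branch <- ifelse(ins$t < sp["hs"], "pre_hs",
                       ifelse(ins$t < sp["st"], "between", "focal_only"))
  ins$present_tarsier <- ins$branch %in% c("pre_hs", "between")
  ins$present_bushbaby <- ins$branch == "pre_hs"
  ins$strand <- sample(c("+", "-"), nrow(ins), replace = TRUE, prob = c(.7, .3))

  # 2. diverged copy sequences (consensus orientation), then genomic strand
  el_seq <- character(nrow(ins))
  for (i in seq_len(nrow(ins))) {
    f <- families[[ins$family[i]]]
    el_seq[i] <- mutate_sequence(f$consensus, f$sub_rate, f$indel_rate)
  }
  el_len <- nchar(el_seq)
  geno_seq <- ifelse(ins$strand == "-", vapply(el_seq, revcomp, ""), el_seq)

  # 3. placement: ordered pieces of (owner, genomic element coords); spacer
  # pieces carry their own backbone sequence
  pieces <- list()          # each: owner (0 = backbone), from, to, seq
  n_pieces_of <- integer(nrow(ins))
  depth_of <- integer(nrow(ins))
  parent_of <- rep(NA_integer_, nrow(ins))
  piece_len <- function(p) p$to - p$from + 1L
  for (i in seq_len(nrow(ins))) {
    placed <- seq_len(i - 1L)
    # hosts are drawn uniformly among older copies (so realized host-family
    # counts track copy numbers); a host may be hit more than once, giving
    # entities with three or more fragments as real annotations show
    hostable <- placed[depth_of[placed] < 2L]
    if (length(hostable)) {
      roomy <- vapply(pieces, function(p)
        p$owner > 0L && piece_len(p) >= 2L * nest_margin + 2L, logical(1))
      hostable <- intersect(hostable,
                            unique(vapply(pieces[roomy], `[[`, 0L, "owner")))
    }
    if (length(hostable) && stats::runif(1) < p_nest) {
      host <- if (length(hostable) == 1L) hostable else sample(hostable, 1)
      cand <- which(vapply(pieces, function(p)
        p$owner == host && piece_len(p) >= 2L * nest_margin + 2L, logical(1)))
      idx <- if (length(cand) == 1L) cand else sample(cand, 1)
      hp <- pieces[[idx]]
      hl <- piece_len(hp)
      cut <- sample(seq.int(nest_margin, hl - nest_margin), 1)
      left <- list(owner = host, from = hp$from, to = hp$from + cut - 1L)
      right <- list(owner = host, from = hp$from + cut, to = hp$to)
      inner <- list(owner = i, from = 1L, to = el_len[i])
      pieces[[idx]] <- left
      pieces <- append(pieces, list(inner, right), after = idx)
      n_pieces_of[host] <- n_pieces_of[host] + 1L
      n_pieces_of[i] <- 1L
      depth_of[i] <- depth_of[host] + 1L
      parent_of[i] <- host
    } else {
      pieces <- append(pieces, list(
        list(owner = 0L, from = 1L, to = as.integer(spacer), seq = random_dna(spacer)),
        list(owner = i, from = 1L, to = el_len[i])))
      n_pieces_of[i] <- 1L
      depth_of[i] <- 0L
    }
  }
  pieces <- append(pieces, list(
    list(owner = 0L, from = 1L, to = as.integer(spacer), seq = random_dna(spacer))))

  ptab <- data.frame(
    owner = vapply(pieces, `[[`, 0L, "owner"),
    from = vapply(pieces, `[[`, 0L, "from"),
    to = vapply(pieces, `[[`, 0L, "to"))
  ptab$len <- ptab$to - ptab$from + 1L
  spacer_seq <- lapply(pieces, function(p) if (p$owner == 0L) p$seq else NULL)

  present_in <- function(species) {
    ptab$owner == 0L | switch(species,
      human = TRUE,
      tarsier = ins$present_tarsier[pmax(ptab$owner, 1L)],
      bushbaby = ins$present_bushbaby[pmax(ptab$owner, 1L)])
  }
  species <- tree$tips
  pres <- lapply(stats::setNames(species, species), present_in)
  coords <- lapply(pres, function(keep) {
    len <- ifelse(keep, ptab$len, 0L)
    st <- cumsum(c(0L, len))[seq_len(nrow(ptab))]
    data.frame(start = st, end = st + len, present = keep)
  })
  glen <- vapply(coords, function(co) max(co$end), 0L)

  # 4. per-species copy tables (merging host pieces re-joined by an absent
  # nested element into a single fragment)
  chrom <- "chrSim"
  copies <- lapply(species, function(s) {
    co <- coords[[s]]
    keep <- which(co$present & ptab$owner > 0L)
    if (!length(keep)) return(.empty_copies())
    rows <- lapply(keep, function(k) {
      o <- ptab$owner[k]
      data.frame(k = k, owner = o, g_start = co$start[k], g_end = co$end[k],
                 from = ptab$from[k], to = ptab$to[k])
    })
    rows <- do.call(rbind, rows)
    # merge genomically adjacent, element-contiguous pieces of one owner
    merged <- list()
    for (r in seq_len(nrow(rows))) {
      cur <- rows[r, ]
      lastm <- if (length(merged)) merged[[length(merged)]] else NULL
      if (!is.null(lastm) && lastm$owner == cur$owner &&
          lastm$g_end == cur$g_start && lastm$to + 1L == cur$from) {
        lastm$g_end <- cur$g_end
        lastm$to <- cur$to
        merged[[length(merged)]] <- lastm
      } else merged[[length(merged) + 1L]] <- cur
    }
    rows <- do.call(rbind, merged)
    o <- rows$owner
    L <- el_len[o]
    minus <- ins$strand[o] == "-"
    rep_start <- ifelse(minus, L - rows$to + 1L, rows$from)
    rep_end <- ifelse(minus, L - rows$from + 1L, rows$to)
    frag_len <- rows$to - rows$from + 1L
    f_sub <- vapply(ins$family[o], function(fn) families[[fn]]$sub_rate, 0)
    data.frame(
      query_name = chrom,
      query_start = as.integer(rows$g_start),
      query_end = as.integer(rows$g_end),
      strand = ins$strand[o],
      rep_name = ins$family[o],
      rep_class_family = "LTR/ERVL-MaLR",
      rep_start = as.integer(rep_start),
      rep_end = as.integer(rep_end),
      rep_left = as.integer(L - rep_end),
      sw_score = pmax(110, round(frag_len * 2 * (1 - 3 * f_sub))),
      perc_div = round(100 * f_sub, 1),
      repeat_id = as.integer(o),
      stringsAsFactors = FALSE)
  })
  names(copies) <- species

  # 5. chains focal -> other species
  chains <- lapply(setdiff(species, "human"), function(s) {
    keep <- coords[[s]]$present
    hco <- coords$human
    blocks <- list()
    size <- 0L; dt <- 0L
    for (k in seq_len(nrow(ptab))) {
      if (keep[k]) {
        if (dt > 0L) {        # close previous block with its target gap
          blocks[[length(blocks) + 1L]] <- c(size, dt, 0L)
          size <- 0L; dt <- 0L
        }
        size <- size + ptab$len[k]
      } else dt <- dt + ptab$len[k]
    }
    blocks[[length(blocks) + 1L]] <- c(size, 0L, 0L)
    b <- do.call(rbind, blocks)
    colnames(b) <- c("size", "dt", "dq")
    ch <- list(score = sum(b[, "size"]), t_name = chrom,
               t_size = glen[["human"]], t_strand = "+",
               t_start = 0L, t_end = as.integer(sum(b[, "size"]) + sum(b[, "dt"])),
               q_name = chrom, q_size = glen[[s]], q_strand = "+",
               q_start = 0L, q_end = as.integer(sum(b[, "size"])),
               id = "1", blocks = b)
    validate_chain(ch)
    ch
  })
  names(chains) <- setdiff(species, "human")

  # 6. truth table
  span_in <- function(s) {
    co <- coords[[s]]
    t(vapply(seq_len(nrow(ins)), function(i) {
      ix <- which(ptab$owner == i & co$present)
      if (!length(ix)) return(c(NA_integer_, NA_integer_))
      c(min(co$start[ix]), max(co$end[ix]))
    }, integer(2)))
  }
  sp_h <- span_in("human"); sp_t <- span_in("tarsier"); sp_b <- span_in("bushbaby")
  truth <- data.frame(
    id = ins$id, family = ins$family, t = ins$t, branch = ins$branch,
    strand = ins$strand,
    present_tarsier = ins$present_tarsier,
    present_bushbaby = ins$present_bushbaby,
    human_start = sp_h[, 1], human_end = sp_h[, 2],
    tarsier_start = sp_t[, 1], tarsier_end = sp_t[, 2],
    bushbaby_start = sp_b[, 1], bushbaby_end = sp_b[, 2],
    parent = parent_of, depth = depth_of,
    n_fragments = n_pieces_of, el_len = el_len,
    repeat_id = ins$id,
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  structure(list(
    copies = copies, chains = chains, truth = truth,
    consensus = stats::setNames(vapply(families, `[[`, "", "consensus"),
                                fam_names),
    elements = stats::setNames(el_seq, paste0("el", ins$id)),
    pieces = ptab, spacer_seq = spacer_seq, coords = coords,
    genome_length = glen,
    params = list(seed = seed, spacer = spacer, p_nest = p_nest,
                  nest_margin = nest_margin, splits = tree$splits)),
    class = "succession_bundle")
}

#' All true containment pairs (inner inside outer) of a bundle
#'
#' Enumerates the directed nesting relations implied by the truth table,
#' including the transitive pairs created by depth-2 nesting (an element
#' inside an element inside an element lies between the fragments of both
#' ancestors).
#'
#' @param bundle A `succession_bundle`.
#' @return Data frame `inner`, `outer` (insertion ids).
#' @export
true_nestings <- function(bundle) {
  tr <- bundle$truth
  out <- list()
  for (i in which(!is.na(tr$parent))) {
    anc <- tr$parent[i]
    while (!is.na(anc)) {
      out[[length(out) + 1L]] <- c(inner = tr$id[i], outer = anc)
      anc <- tr$parent[anc]
    }
  }
  if (!length(out)) return(data.frame(inner = integer(), outer = integer()))
  as.data.frame(do.call(rbind, out))
}

#' Write a simulation bundle to disk
#'
#' Emits `<species>.fa.out`, `humanTo<Species>.chain`, `consensus.fa`,
#' `elements.fa` and `truth.tsv` under `dir`.  Byte-identical across runs
#' with the same bundle.
#'
#' @param bundle A `succession_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(bundle$copies))
    write_rmsk_out(bundle$copies[[s]], file.path(dir, paste0(s, ".fa.out")))
  for (s in names(bundle$chains)) {
    cap <- paste0(toupper(substring(s, 1, 1)), substring(s, 2))
    write_chain(bundle$chains[[s]], file.path(dir, paste0("humanTo", cap, ".chain")))
  }
  write_fasta(bundle$consensus, file.path(dir, "consensus.fa"))
  write_fasta(bundle$elements, file.path(dir, "elements.fa"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Assemble a species' chromosome FASTA from a bundle (toy-genome mode)
#'
#' Intended for small scenarios (about a megabase or less); the backbone
#' spacers and element sequences are spliced in genome order.
#'
#' @param bundle A `succession_bundle`.
#' @param species One of the bundle's species.
#' @return Named character vector of length one (the chromosome sequence).
#' @export
assemble_genome <- function(bundle, species) {
  pt <- bundle$pieces
  co <- bundle$coords[[species]]
  segs <- character(0)
  for (k in seq_len(nrow(pt))) {
    if (!co$present[k]) next
    segs[length(segs) + 1L] <- if (pt$owner[k] == 0L) {
      bundle$spacer_seq[[k]]
    } else {
      g <- bundle$elements[[pt$owner[k]]]
      tr <- bundle$truth
      if (tr$strand[pt$owner[k]] == "-") g <- revcomp(g)
      substring(g, pt$from[k], pt$to[k])
    }
  }
  stats::setNames(paste(segs, collapse = ""), "chrSim")
}

#' Degrade a chain by deleting aligned blocks
#'
#' Removes alignment over approximately `deletion_fraction` of the aligned
#' target bases (the per-block deleted amount is `round(size *
#' deletion_fraction)`, so the total is deterministic and monotone in the
#' fraction; only the position of each deletion within its block is
#' random).  Models lineage-specific sequence loss so that presence
#' thresholds are exercised.
#'
#' @param chain A single chain (see [read_chain()]).
#' @param deletion_fraction In `[0, 1)`.
#' @param seed Integer seed for deletion placement.
#' @return A valid chain with reduced aligned bases.
#' @export
degrade_chain <- function(chain, deletion_fraction, seed) {
  stopifnot(deletion_fraction >= 0, deletion_fraction < 1)
  if (deletion_fraction == 0) return(chain)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  b <- chain$blocks
  out <- list()
  lead_t <- 0L; lead_q <- 0L
  push_gap <- function(dt, dq) {
    if (length(out)) {
      out[[length(out)]][2:3] <<- out[[length(out)]][2:3] + c(dt, dq)
    } else {
      lead_t <<- lead_t + dt; lead_q <<- lead_q + dq
    }
  }
  for (k in seq_len(nrow(b))) {
    size <- b[k, "size"]; dt <- b[k, "dt"]; dq <- b[k, "dq"]
    d <- as.integer(round(size * deletion_fraction))
    if (d > 0L && size - d < 2L) d <- size               # drop whole block
    if (d == 0L) {
      out[[length(out) + 1L]] <- c(size, dt, dq)
    } else if (d >= size) {
      push_gap(size + dt, size + dq)
    } else {
      o <- sample.int(size - d - 1L, 1)                  # split point
      out[[length(out) + 1L]] <- c(o, d, d)
      out[[length(out) + 1L]] <- c(size - d - o, dt, dq)
    }
  }
  if (!length(out)) stop("degradation removed the entire chain")
  m <- do.call(rbind, out)
  colnames(m) <- c("size", "dt", "dq")
  # the final block must end the chain: fold any trailing gap into the ends
  n <- nrow(m)
  m[n, c("dt", "dq")] <- 0L
  ch <- chain
  ch$t_start <- chain$t_start + lead_t
  ch$q_start <- chain$q_start + lead_q
  ch$t_end <- ch$t_start + sum(m[, "size"]) + sum(m[, "dt"])
  ch$q_end <- ch$q_start + sum(m[, "size"]) + sum(m[, "dq"])
  ch$blocks <- m
  validate_chain(ch)
  ch
}

#' Simulate full-length elements carrying planted structural variants
#'
#' Emits elements structured as 5'LTR - internal - 3'LTR whose LTRs carry
#' the per-side variant subsets requested by `stage_spec`, then diverges
#' every element by iid substitutions.  The truth table lists the planted
#' per-LTR variant presence for each element.
#'
#' @param consensus_ltr Reference LTR consensus (character), the coordinate
#'   system of the variant definitions.
#' @param internal Internal-region sequence placed between the LTRs.
#' @param variant_defs Variant definition table from [variant_defs()].
#' @param stage_spec Either a stage name (`"precursor"`, `"intermediate"`,
#'   `"canonical"`) resolved through [stage_variant_sets()], or a list with
#'   character vectors `ltr5` and `ltr3` naming the variants on each side.
#' @param n Number of elements.
#' @param sub_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @param prefix Element-name prefix.
#' @return List with `elements` (named character vector) and `truth`
#'   (element, side, variant, present).
#' @export
plant_structural_variants <- function(consensus_ltr, internal, variant_defs,
                                      stage_spec, n = 1, sub_rate = 0,
                                      seed = 1, prefix = "el") {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  sets <- if (is.character(stage_spec)) stage_variant_sets(variant_defs)[[stage_spec]]
          else stage_spec
  if (is.null(sets)) stop("unknown stage_spec")
  ltr5 <- apply_variants(consensus_ltr, variant_defs, sets$ltr5)
  ltr3 <- apply_variants(consensus_ltr, variant_defs, sets$ltr3)
  base <- paste0(ltr5, internal, ltr3)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  els <- vapply(ids, function(id) mutate_sequence(base, sub_rate, 0), "")
  truth <- expand.grid(element = ids, side = c("ltr5", "ltr3"),
                       variant = variant_defs$name, stringsAsFactors = FALSE)
  truth$present <- ifelse(truth$side == "ltr5",
                          truth$variant %in% sets$ltr5,
                          truth$variant %in% sets$ltr3)
  list(elements = els, truth = truth[order(truth$element, truth$side), ])
}

#' Simulate a consensus chain with pair-specific shared features
#'
#' Generates `n_members` consensus sequences related by sequential descent:
#' each succession step inserts a fresh marker segment of `feature_len`
#' bases that survives for exactly two members before being deleted, so
#' every adjacent pair (k, k+1) uniquely shares one block that every other
#' member lacks — the signature expected of a true predecessor/successor
#' chain.  The shared backbone additionally accumulates about `n_subs`
#' substitutions per succession step, so sequence distance grows with chain
#' separation.
#'
#' @param n_members Chain length (>= 2).
#' @param base_len Shared backbone length.
#' @param feature_len Length of each pair-specific marker segment.
#' @param n_subs Expected backbone substitutions per succession step.
#' @param seed Integer seed.
#' @return Named character vector `m1 ... m<n>`, oldest first, with
#'   attribute `markers` giving each marker's backbone anchor position.
#' @export
simulate_consensus_chain <- function(n_members, base_len = 400,
                                     feature_len = 35, n_subs = 5, seed = 1) {
  stopifnot(n_members >= 2)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  n_slots <- n_members - 1L
  block <- base_len %/% (n_slots + 1L)
  backbone <- replicate(n_slots + 1L, random_dna(block))
  markers <- replicate(n_slots, random_dna(feature_len))
  out <- character(n_members)
  for (m in seq_len(n_members)) {
    if (m > 1L) {
      # substitutions accumulate along the chain: each member descends from
      # its predecessor's backbone
      backbone <- vapply(backbone, mutate_sequence,
                         sub_rate = n_subs / base_len, "")
    }
    parts <- character(0)
    for (k in seq_len(n_slots)) {
      parts <- c(parts, backbone[k],
                 if (m %in% c(k, k + 1L)) markers[k] else "")
    }
    out[m] <- paste(c(parts, backbone[n_slots + 1L]), collapse = "")
  }
  names(out) <- paste0("m", seq_len(n_members))
  attr(out, "markers") <- cumsum(rep(block, n_slots))
  out
}
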