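# Dating insertions against successive species splits by orthologous
# presence/absence.  An element present in the focal genome and in the
# orthologous loci of both outgroup species predates the earlier split; one
# present only in the nearer outgroup inserted between the two splits; one
# absent from both postdates the later split (or cannot be resolved).  All
# calls are conditional on the locus aligning well enough to trust absence,
# which is what the flank test certifies.

#' Default thresholds of the timing workflow
#'
#' @param min_sw_score Minimum Smith-Waterman score of an entity's best
#'   fragment (dimensionless RepeatMasker score).
#' @param flank_length Flank length examined on each side, in bases.
#' @param min_flank_aligned Minimum aligned bases per flank side for the
#'   locus to count as properly aligned.
#' @param min_presence An element is called present in a species when its
#'   orthologous sequence is strictly longer than this many bases.
#' @return A `timing_thresholds` list.
#' @export
timing_thresholds <- function(min_sw_score = 100, flank_length = 300,
                              min_flank_aligned = 200, min_presence = 50) {
  stopifnot(min_flank_aligned <= flank_length, min_sw_score >= 0,
            flank_length > 0, min_presence >= 0)
  structure(list(min_sw_score = min_sw_score, flank_length = flank_length,
                 min_flank_aligned = min_flank_aligned,
                 min_presence = min_presence),
            class = "timing_thresholds")
}

#' Filter entities by best-fragment alignment score
#'
#' @param entities Entity table from [group_entities()].
#' @param thresholds [timing_thresholds()].
#' @return The entities whose maximum fragment score reaches
#'   `min_sw_score` (boundary inclusive).
#' @export
filter_entities <- function(entities, thresholds = timing_thresholds()) {
  entities[entities$max_sw >= thresholds$min_sw_score, , drop = FALSE]
}

#' Assess orthologous alignment of each entity in each comparison species
#'
#' For every entity, lifts the `flank_length`-base flanks on each side of
#' the entity span (outermost fragment boundaries) through each species'
#' chains and counts aligned target bases; a species' locus is `flank_ok`
#' when both sides reach `min_flank_aligned`.  The entity span itself is
#' lifted the same way for the presence test, summing aligned bases across
#' all mapped pieces (the thresholds are expressed in base counts, not
#' contiguity).  An entity is *properly aligned* when `flank_ok` holds in
#' every comparison species simultaneously, which gives the workflow a
#' single denominator.
#'
#' @param entities Entity table from [group_entities()].
#' @param chains_per_species Named list: species -> list of chains
#'   ([read_chain()]).
#' @param thresholds [timing_thresholds()].
#' @return The entity table with, per species `s`, columns
#'   `left_aligned_<s>`, `right_aligned_<s>`, `flank_ok_<s>`,
#'   `element_aligned_<s>`, `present_<s>`, plus `properly_aligned`.
#' @export
assess_alignment <- function(entities, chains_per_species,
                             thresholds = timing_thresholds()) {
  if (is.null(names(chains_per_species)) || any(!nzchar(names(chains_per_species))))
    stop("chains_per_species must be a named list (species = chains)")
  th <- thresholds
  res <- entities
  flank_ok_all <- rep(TRUE, nrow(entities))
  for (s in names(chains_per_species)) {
    chains <- chains_per_species[[s]]
    if (is.null(chains)) stop("no chain configured for species ", s)
    if (!is.null(chains$blocks)) chains <- list(chains)   # single chain
    la <- ra <- ea <- integer(nrow(entities))
    for (i in seq_len(nrow(entities))) {
      e <- entities[i, ]
      la[i] <- aligned_bases(chains, e$query_name,
                             max(0L, e$span_start - th$flank_length),
                             e$span_start)
      ra[i] <- aligned_bases(chains, e$query_name, e$span_end,
                             e$span_end + th$flank_length)
      ea[i] <- aligned_bases(chains, e$query_name, e$span_start, e$span_end)
    }
    ok <- la >= th$min_flank_aligned & ra >= th$min_flank_aligned
    res[[paste0("left_aligned_", s)]] <- la
    res[[paste0("right_aligned_", s)]] <- ra
    res[[paste0("flank_ok_", s)]] <- ok
    res[[paste0("element_aligned_", s)]] <- ea
    res[[paste0("present_", s)]] <- ea > th$min_presence
    flank_ok_all <- flank_ok_all & ok
  }
  res$properly_aligned <- flank_ok_all
  res
}

#' Classify insertion timing from presence in the two outgroups
#'
#' @param presence_bushbaby,presence_tarsier Logical vectors: presence in
#'   the farther (earlier-splitting) and nearer outgroup.
#' @return Character vector of calls: `pre_HS_split` (present in both),
#'   `between_splits` (nearer outgroup only), `post_ST_split_or_unresolved`
#'   (absent from both), or `discordant` (farther outgroup only — hemiplasy
#'   or a lineage-specific deletion; reported, never binned).
#' @export
classify_timing <- function(presence_bushbaby, presence_tarsier) {
  stopifnot(length(presence_bushbaby) == length(presence_tarsier))
  ifelse(presence_bushbaby & presence_tarsier, "pre_HS_split",
    ifelse(!presence_bushbaby & presence_tarsier, "between_splits",
      ifelse(!presence_bushbaby & !presence_tarsier,
             "post_ST_split_or_unresolved", "discordant")))
}

#' Run the timing workflow over copies and chains
#'
#' Convenience wrapper: group, score-filter, assess, classify.
#'
#' @param copies Copy table ([read_rmsk_out()]).
#' @param chains_per_species Named list of chain lists; the first name is
#'   taken as the nearer outgroup ("tarsier" role) unless the names contain
#'   `tarsier`/`bushbaby`.
#' @param thresholds [timing_thresholds()].
#' @param nearer,farther Species names taking the nearer/farther outgroup
#'   roles; defaults to `"tarsier"`/`"bushbaby"` when present.
#' @return Entity table with alignment columns and `call`.
#' @export
timing_calls <- function(copies, chains_per_species,
                         thresholds = timing_thresholds(),
                         nearer = NULL, farther = NULL) {
  sp <- names(chains_per_species)
  if (is.null(nearer)) nearer <- if ("tarsier" %in% sp) "tarsier" else sp[1]
  if (is.null(farther)) farther <- if ("bushbaby" %in% sp) "bushbaby" else sp[2]
  ents <- filter_entities(group_entities(copies), thresholds)
  a <- assess_alignment(ents, chains_per_species, thresholds)
  a$call <- NA_character_
  pa <- a$properly_aligned
  a$call[pa] <- classify_timing(a[[paste0("present_", farther)]][pa],
                                a[[paste0("present_", nearer)]][pa])
  a
}

#' Per-family summary of timing calls
#'
#' @param calls Result of [timing_calls()] (or [assess_alignment()] plus a
#'   `call` column).
#' @return Data frame per family: `n_total`, `n_properly_aligned`, counts
#'   of each call category, and `frac_nearer_only` (the between-splits
#'   fraction of properly aligned entities; `NA` when none align).
#' @export
timing_summary <- function(calls) {
  fams <- sort(unique(calls$family))
  rows <- lapply(fams, function(f) {
    x <- calls[calls$family == f, ]
    pa <- x[which(x$properly_aligned), ]
    n_pa <- nrow(pa)
    data.frame(
      family = f,
      n_total = nrow(x),
      n_properly_aligned = n_pa,
      n_pre_HS = sum(pa$call == "pre_HS_split"),
      n_between = sum(pa$call == "between_splits"),
      n_post_ST = sum(pa$call == "post_ST_split_or_unresolved"),
      n_discordant = sum(pa$call == "discordant"),
      frac_nearer_only = if (n_pa > 0) sum(pa$call == "between_splits") / n_pa
                         else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
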