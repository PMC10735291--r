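#' @useDynLib malrsucc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# All genomic intervals are 0-based half-open internally.  The only places
# where other conventions appear are the format boundaries: RepeatMasker .out
# is 1-based inclusive on disk, UCSC chain is already 0-based half-open, and
# structural-variant definitions use the 1-based consensus coordinates that
# repeat biologists write (converted at the schema boundary).

.out_header <- c(
  "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
  "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
  "")

#' Read a RepeatMasker .out annotation file
#'
#' Parses the UCSC dialect of RepeatMasker \code{.out} (three header lines,
#' whitespace-delimited columns, trailing \code{ID} column linking fragments
#' of one insertion).  Genomic coordinates are converted from the on-disk
#' 1-based inclusive convention to 0-based half-open; rows annotated on the
#' \code{"C"} strand are normalized to strand \code{"-"} with their consensus
#' coordinates reoriented so that \code{rep_start <= rep_end} always holds.
#'
#' @param path Path to a \code{.out} file, plain or gzip-compressed.
#' @return A data frame of repeat copies with columns \code{query_name},
#'   \code{query_start}, \code{query_end} (0-based half-open), \code{strand}
#'   (\code{"+"}/\code{"-"}), \code{rep_name}, \code{rep_class_family},
#'   \code{rep_start}, \code{rep_end}, \code{rep_left} (consensus
#'   coordinates, 1-based as in the file), \code{sw_score},
#'   \code{perc_div}, and \code{repeat_id}.
#' @seealso [write_rmsk_out()], [group_entities()]
#' @export
read_rmsk_out <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  # header: up to 3 leading non-data lines (banner, column names, blank)
  is_data <- grepl("^\\s*\\d+\\s", lines)
  body <- lines[is_data]
  if (length(body) == 0L) return(.empty_copies())
  fields <- strsplit(trimws(body), "\\s+")
  n_fields <- lengths(fields)
  bad <- which(!(n_fields %in% c(15L, 16L)))  # 16 with optional '*' overlap flag
  if (length(bad)) {
    stop("malformed RepeatMasker .out row (", n_fields[bad[1]],
         " columns) at line ", which(is_data)[bad[1]], " of ", path)
  }
  if (any(n_fields == 15L)) {
    # 15 columns means no trailing ID (non-UCSC dialect) unless '*' absent;
    # distinguish: UCSC rows are swScore..repLeft + ID = 15 cols *without*
    # the '*' column only when ID present.  Column 15 must be an integer ID.
    id_like <- vapply(fields[n_fields == 15L],
                      function(f) grepl("^\\d+$", f[15]), logical(1))
    if (!all(id_like)) {
      stop("missing repeat ID column in ", path,
           ": this looks like a non-UCSC RepeatMasker dialect; ",
           "re-run with the UCSC-style output that carries the ID column")
    }
  }
  m <- t(vapply(fields, function(f) f[1:15], character(15)))
  strand <- ifelse(m[, 9] == "C", "-", m[, 9])
  paren <- function(x) as.integer(sub("^\\((-?\\d+)\\)$", "\\1", x))
  plain <- function(x) as.integer(x)
  # For '+' rows consensus columns are begin,end,(left); for 'C' rows they
  # are (left),end,begin.  Normalize so rep_start <= rep_end.
  plus <- strand == "+"
  n <- length(strand)
  rep_start <- rep_left <- integer(n)
  rep_start[plus] <- plain(m[plus, 12])
  rep_start[!plus] <- plain(m[!plus, 14])
  rep_end <- plain(m[, 13])
  rep_left[plus] <- paren(m[plus, 14])
  rep_left[!plus] <- paren(m[!plus, 12])
  out <- data.frame(
    query_name = m[, 5],
    query_start = as.integer(m[, 6]) - 1L,
    query_end = as.integer(m[, 7]),
    strand = strand,
    rep_name = m[, 10],
    rep_class_family = m[, 11],
    rep_start = rep_start,
    rep_end = rep_end,
    rep_left = rep_left,
    sw_score = as.numeric(m[, 1]),
    perc_div = as.numeric(m[, 2]),
    repeat_id = as.integer(m[, 15]),
    stringsAsFactors = FALSE)
  stopifnot(all(out$query_start < out$query_end), all(out$sw_score >= 0))
  out
}

.empty_copies <- function() {
  data.frame(query_name = character(), query_start = integer(),
             query_end = integer(), strand = character(),
             rep_name = character(), rep_class_family = character(),
             rep_start = integer(), rep_end = integer(),
             rep_left = integer(), sw_score = numeric(),
             perc_div = numeric(), repeat_id = integer(),
             stringsAsFactors = FALSE)
}

#' Write repeat copies as a RepeatMasker .out file
#'
#' Inverse of [read_rmsk_out()]: restores the 1-based inclusive genomic
#' coordinates and the \code{"C"}-strand consensus column order on disk.
#'
#' @param copies Data frame as returned by [read_rmsk_out()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmsk_out <- function(copies, path) {
  fmt_row <- function(i) {
    x <- copies[i, ]
    if (x$strand == "+") {
      rcols <- c(x$rep_start, x$rep_end, sprintf("(%d)", x$rep_left))
      s <- "+"
    } else {
      rcols <- c(sprintf("(%d)", x$rep_left), x$rep_end, x$rep_start)
      s <- "C"
    }
    paste(format(x$sw_score, trim = TRUE), format(x$perc_div, trim = TRUE),
          "0.0", "0.0", x$query_name, x$query_start + 1L, x$query_end,
          "(0)", s, x$rep_name, x$rep_class_family,
          rcols[1], rcols[2], rcols[3], x$repeat_id)
  }
  rows <- if (nrow(copies)) vapply(seq_len(nrow(copies)), fmt_row, character(1)) else character()
  writeLines(c(.out_header, rows), path)
  invisible(path)
}

#' Group repeat fragments into insertion entities
#'
#' RepeatMasker links fragments of one original insertion (e.g. a copy split
#' by a younger nested element) through a shared \code{ID}.  This groups the
#' copies of one genome into entities keyed by \code{(query_name,
#' repeat_id)}; fragments of one ID landing on different sequences are split
#' into separate entities with a warning, since a single insertion cannot
#' span chromosomes.
#'
#' @param copies Data frame from [read_rmsk_out()].
#' @return A data frame with one row per entity: \code{entity} (key),
#'   \code{query_name}, \code{repeat_id}, \code{family} (the rep_name of the
#'   highest-scoring fragment), \code{span_start}, \code{span_end}
#'   (outermost fragment boundaries, 0-based half-open), \code{n_fragments}
#'   and \code{max_sw}.  The fragment rows themselves can be recovered by
#'   matching \code{entity_key(copies)}.
#' @export
group_entities <- function(copies) {
  if (nrow(copies) == 0L) {
    return(data.frame(entity = character(), query_name = character(),
                      repeat_id = integer(), family = character(),
                      span_start = integer(), span_end = integer(),
                      n_fragments = integer(), max_sw = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- entity_key(copies)
  u <- unique(copies[, c("query_name", "repeat_id")])
  if (anyDuplicated(u$repeat_id))
    warning("repeat_id shared across different sequences; ",
            "split into separate entities")
  o <- order(key, copies$query_start)
  c2 <- copies[o, ]
  k2 <- key[o]
  first <- !duplicated(k2)
  fam <- vapply(split(seq_len(nrow(c2)), k2), function(ix) {
    c2$rep_name[ix[which.max(c2$sw_score[ix])]]
  }, character(1))
  ent <- data.frame(
    entity = k2[first],
    query_name = c2$query_name[first],
    repeat_id = c2$repeat_id[first],
    family = fam[match(k2[first], names(fam))],
    span_start = as.integer(tapply(c2$query_start, k2, min)[k2[first]]),
    span_end = as.integer(tapply(c2$query_end, k2, max)[k2[first]]),
    n_fragments = as.integer(table(k2)[k2[first]]),
    max_sw = as.numeric(tapply(c2$sw_score, k2, max)[k2[first]]),
    stringsAsFactors = FALSE)
  rownames(ent) <- NULL
  ent
}

#' Entity key of each copy row
#' @param copies Data frame from [read_rmsk_out()].
#' @return Character vector, one key per row, matching `group_entities()$entity`.
#' @export
entity_key <- function(copies) paste(copies$query_name, copies$repeat_id, sep = "#")

#' Per-family census of fragments and entities
#'
#' Counts, for one species' annotation, the number of annotated fragments
#' (\code{.out} rows) and of grouped insertion entities per family.  Both are
#' reported because published copy numbers do not always say which was
#' counted.
#'
#' @param copies Data frame from [read_rmsk_out()].
#' @param families Character vector of family names of interest; absent
#'   families are reported with zero counts.
#' @param species_label Label stored in the \code{species} column.
#' @return Data frame with columns \code{species}, \code{family},
#'   \code{n_fragments}, \code{n_entities}.
#' @export
family_census <- function(copies, families, species_label) {
  ent <- group_entities(copies)
  frag_tab <- table(factor(copies$rep_name, levels = families))
  ent_tab <- table(factor(ent$family, levels = families))
  data.frame(species = species_label, family = families,
             n_fragments = as.integer(frag_tab[families]),
             n_entities = as.integer(ent_tab[families]),
             stringsAsFactors = FALSE)
}

# ---- FASTA / Newick / BED plumbing -----------------------------------------

#' Read a FASTA file into a DNAStringSet, rejecting duplicate identifiers
#' @param path FASTA path (plain or gzip).
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(x)))
    stop("duplicate FASTA identifiers in ", path, ": ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x
}

#' Write sequences to FASTA
#' @param seqs Named character vector or DNAStringSet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (anyDuplicated(names(seqs))) stop("duplicate FASTA identifiers")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a phylo tree as Newick
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write entities (or any interval table) as BED
#'
#' @param x Data frame with \code{query_name}, \code{span_start},
#'   \code{span_end} (entity table) or \code{query_start}/\code{query_end}
#'   (copy table); a \code{name} column is used when present.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  s <- if ("span_start" %in% names(x)) x$span_start else x$query_start
  e <- if ("span_end" %in% names(x)) x$span_end else x$query_end
  nm <- if ("name" %in% names(x)) x$name else
    if ("entity" %in% names(x)) x$entity else rep(".", nrow(x))
  utils::write.table(data.frame(x$query_name, s, e, nm),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
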