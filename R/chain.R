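# UCSC chain files describe a gapped pairwise alignment between a target and
# a query assembly as runs of (size, dt, dq): `size` aligned bases, then a
# gap of `dt` bases on the target and `dq` on the query.  Coordinates are
# 0-based half-open on the strand given in the header.

#' Read a UCSC chain file
#'
#' @param path Chain file, plain or gzip-compressed.
#' @return A list of chains; each chain is a list with the header fields
#'   (\code{score}, \code{t_name}, \code{t_size}, \code{t_strand},
#'   \code{t_start}, \code{t_end}, \code{q_name}, \code{q_size},
#'   \code{q_strand}, \code{q_start}, \code{q_end}, \code{id}) and
#'   \code{blocks}, an integer matrix with columns \code{size}, \code{dt},
#'   \code{dq} (the final block has \code{dt = dq = 0}).
#' @export
read_chain <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!grepl("^#", lines)]
  hdr_at <- grep("^chain\\b", lines)
  if (!length(hdr_at)) stop("no chain records in ", path)
  ends <- c(hdr_at[-1] - 1L, length(lines))
  lapply(seq_along(hdr_at), function(k) {
    h <- strsplit(trimws(lines[hdr_at[k]]), "\\s+")[[1]]
    if (length(h) != 13L)
      stop("malformed chain header at line ", hdr_at[k], " of ", path)
    body <- lines[(hdr_at[k] + 1L):ends[k]]
    body <- body[nzchar(trimws(body))]
    parts <- strsplit(trimws(body), "\\s+")
    np <- lengths(parts)
    if (any(!(np %in% c(1L, 3L))) || np[length(np)] != 1L)
      stop("malformed chain block lines for chain id ", h[13], " in ", path)
    blocks <- t(vapply(parts, function(p) as.integer(c(p, 0L, 0L)[1:3]),
                       integer(3)))
    colnames(blocks) <- c("size", "dt", "dq")
    ch <- list(score = as.numeric(h[2]),
               t_name = h[3], t_size = as.integer(h[4]), t_strand = h[5],
               t_start = as.integer(h[6]), t_end = as.integer(h[7]),
               q_name = h[8], q_size = as.integer(h[9]), q_strand = h[10],
               q_start = as.integer(h[11]), q_end = as.integer(h[12]),
               id = h[13], blocks = blocks)
    validate_chain(ch)
    ch
  })
}

#' Validate a chain's block arithmetic against its header
#' @param ch A single chain as returned by [read_chain()].
#' @return `ch`, invisibly; stops on inconsistency.
#' @export
validate_chain <- function(ch) {
  b <- ch$blocks
  if (any(b[, "size"] <= 0L)) stop("chain ", ch$id, ": non-positive block size")
  if (sum(b[, "size"]) + sum(b[, "dt"]) != ch$t_end - ch$t_start)
    stop("chain ", ch$id, ": target span does not match block sums")
  if (sum(b[, "size"]) + sum(b[, "dq"]) != ch$q_end - ch$q_start)
    stop("chain ", ch$id, ": query span does not match block sums")
  invisible(ch)
}

#' Write chains to a UCSC chain file
#' @param chains A chain or list of chains (see [read_chain()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  if (!is.null(chains$blocks)) chains <- list(chains)
  out <- unlist(lapply(chains, function(ch) {
    validate_chain(ch)
    hdr <- paste("chain", format(ch$score, scientific = FALSE, trim = TRUE),
                 ch$t_name, ch$t_size, ch$t_strand, ch$t_start, ch$t_end,
                 ch$q_name, ch$q_size, ch$q_strand, ch$q_start, ch$q_end,
                 ch$id)
    b <- ch$blocks
    n <- nrow(b)
    body <- if (n > 1L)
      paste(b[-n, "size"], b[-n, "dt"], b[-n, "dq"], sep = "\t") else character()
    c(hdr, body, as.character(b[n, "size"]), "")
  }))
  writeLines(out, path)
  invisible(path)
}

# Aligned segments of one chain as a matrix of target/query starts (0-based,
# header strand) and sizes.
.chain_segments <- function(ch) {
  b <- ch$blocks
  t0 <- ch$t_start + c(0L, cumsum(b[, "size"] + b[, "dt"]))[seq_len(nrow(b))]
  q0 <- ch$q_start + c(0L, cumsum(b[, "size"] + b[, "dq"]))[seq_len(nrow(b))]
  cbind(t_start = t0, q_start = q0, size = b[, "size"])
}

#' Lift a target-genome interval through chains
#'
#' Maps a 0-based half-open interval on the target genome to query-genome
#' coordinates through every overlapping chain, restricted to aligned
#' blocks.  No contiguity is required: the mapped pieces are returned
#' individually together with the total count of target bases that aligned,
#' which is the quantity the presence/absence thresholds are expressed in.
#' Query coordinates on \code{"-"}-strand chains are reported on the forward
#' strand.
#'
#' @param chains A list of chains from [read_chain()].
#' @param query_name Target sequence name of the interval.
#' @param start,end 0-based half-open interval on the target genome.
#' @return A list with \code{segments}, a data frame of mapped pieces
#'   (\code{chain_id}, \code{q_name}, \code{q_start}, \code{q_end},
#'   \code{t_start}, \code{t_end}), and \code{aligned_bases}, the total
#'   number of target bases inside aligned blocks.  An interval outside all
#'   chains yields zero rows and zero aligned bases.
#' @export
lift_interval <- function(chains, query_name, start, end) {
  stopifnot(start < end)
  segs <- lapply(chains, function(ch) {
    if (ch$t_name != query_name || ch$t_strand != "+") return(NULL)
    if (ch$t_end <= start || ch$t_start >= end) return(NULL)
    m <- .chain_segments(ch)
    s <- pmax(m[, "t_start"], start)
    e <- pmin(m[, "t_start"] + m[, "size"], end)
    keep <- which(s < e)
    if (!length(keep)) return(NULL)
    off_s <- s[keep] - m[keep, "t_start"]
    qs <- m[keep, "q_start"] + off_s
    qe <- qs + (e[keep] - s[keep])
    if (ch$q_strand == "-") {        # report on the forward strand
      fs <- ch$q_size - qe
      fe <- ch$q_size - qs
      qs <- fs; qe <- fe
    }
    data.frame(chain_id = ch$id, q_name = ch$q_name,
               q_start = qs, q_end = qe,
               t_start = s[keep], t_end = e[keep],
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  if (is.null(segs))
    segs <- data.frame(chain_id = character(), q_name = character(),
                       q_start = integer(), q_end = integer(),
                       t_start = integer(), t_end = integer(),
                       stringsAsFactors = FALSE)
  list(segments = segs,
       aligned_bases = sum(segs$t_end - segs$t_start))
}

#' Count of target bases of an interval that align through chains
#' @inheritParams lift_interval
#' @return Integer count of aligned target bases.
#' @export
aligned_bases <- function(chains, query_name, start, end) {
  lift_interval(chains, query_name, start, end)$aligned_bases
}
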