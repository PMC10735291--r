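# Fixtures are built in code: RepeatMasker .out text, toy chains, and small
# scenario bundles shared across test files.

rmsk_out_text <- function(rows) {
  header <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    "")
  c(header, rows)
}

write_rmsk_fixture <- function(rows) {
  path <- tempfile(fileext = ".out")
  writeLines(rmsk_out_text(rows), path)
  path
}

# a plain UCSC-dialect row: 1-based inclusive genomic coordinates on disk
out_row <- function(sw = 463, div = 1.3, chrom = "chr1", start1 = 100,
                    end1 = 150, strand = "+", name = "MSTB1",
                    cls = "LTR/ERVL-MaLR", rb = 1, re = 50, rl = 300,
                    id = 697) {
  if (strand == "+") {
    sprintf("%d %.1f 0.0 0.0 %s %d %d (0) + %s %s %d %d (%d) %d",
            sw, div, chrom, start1, end1, name, cls, rb, re, rl, id)
  } else {
    sprintf("%d %.1f 0.0 0.0 %s %d %d (0) C %s %s (%d) %d %d %d",
            sw, div, chrom, start1, end1, name, cls, rl, re, rb, id)
  }
}

make_chain <- function(blocks, t_name = "chrT", q_name = "chrQ",
                       t_start = 0L, q_start = 0L, q_strand = "+",
                       t_size = NULL, q_size = NULL, id = "1") {
  b <- matrix(as.integer(blocks), ncol = 3, byrow = TRUE,
              dimnames = list(NULL, c("size", "dt", "dq")))
  b[nrow(b), c("dt", "dq")] <- 0L
  t_end <- t_start + sum(b[, "size"]) + sum(b[, "dt"])
  q_end <- q_start + sum(b[, "size"]) + sum(b[, "dq"])
  ch <- list(score = sum(b[, "size"]), t_name = t_name,
             t_size = if (is.null(t_size)) t_end else t_size,
             t_strand = "+", t_start = as.integer(t_start),
             t_end = as.integer(t_end), q_name = q_name,
             q_size = if (is.null(q_size)) q_end else q_size,
             q_strand = q_strand, q_start = as.integer(q_start),
             q_end = as.integer(q_end), id = id, blocks = b)
  validate_chain(ch)
}

identity_chain <- function(len = 1000L, ...) make_chain(c(len, 0, 0), ...)

# small three-family scenario used by several files; the family consensus
# draws come from the same seeded stream so the bundle is fully reproducible
toy_bundle <- function(seed = 7, n = 20, p_nest = 0.3) {
  tree <- primate_tree()
  fams <- withr::with_seed(seed, list(
    family_model("F1", mu = 0.1, sigma = 0.05, n_copies = n),
    family_model("F2", mu = 0.4, sigma = 0.05, n_copies = n),
    family_model("F3", mu = 0.8, sigma = 0.05, n_copies = n)))
  simulate_succession(tree, fams, seed = seed, p_nest = p_nest)
}

# map truth branches to the timing workflow's call vocabulary
branch_call <- c(pre_hs = "pre_HS_split", between = "between_splits",
                 focal_only = "post_ST_split_or_unresolved")

truth_expected_calls <- function(bundle, calls) {
  key <- paste("chrSim", bundle$truth$repeat_id, sep = "#")
  branch_call[bundle$truth$branch[match(calls$entity, key)]]
}

# detected event (inner, outer) id pairs and the truth's containment pairs
event_pairs <- function(events) {
  paste(sub(".*#", "", events$inner_entity), sub(".*#", "", events$outer_entity))
}
truth_pairs <- function(bundle) {
  tn <- true_nestings(bundle)
  paste(tn$inner, tn$outer)
}
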