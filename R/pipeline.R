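# One scenario configuration drives every stage; the run-all driver
# executes simulate -> census -> timing -> tint -> tree -> structvar on the
# synthetic scenario and records a manifest (seed, config hash, per-file
# checksums) so a run can be reproduced and compared byte for byte.

.pkg_version <- function() as.character(utils::packageVersion("malrsucc"))

.write_tsv <- function(x, path, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# malrsucc %s %s", .pkg_version(), stage), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default synthetic succession scenario
#'
#' Five families with staggered activity windows on pseudo-time: two
#' straddling or preceding the earlier (farther-outgroup) split, one
#' between the splits, two after the later split, emulating a succession in
#' which each family has a limited activity period.  All knobs are plain
#' values so the scenario round-trips through YAML.
#'
#' @param seed Integer seed (mandatory for any stochastic stage).
#' @return A nested list understood by [run_succession_pipeline()].
#' @export
default_scenario <- function(seed = 1) {
  list(
    seed = seed,
    tree = list(split_hs = 0.3, split_st = 0.5),
    genome = list(spacer = 700, p_nest = 0.25, nest_margin = 25,
                  consensus_step_subs = 0.06),
    families = list(
      list(name = "MALRSIM1", mu = 0.12, sigma = 0.05, n_copies = 100,
           sub_rate = 0.08, indel_rate = 0.0005, length = 420),
      list(name = "MALRSIM2", mu = 0.30, sigma = 0.05, n_copies = 100,
           sub_rate = 0.06, indel_rate = 0.0005, length = 400),
      list(name = "MALRSIM3", mu = 0.48, sigma = 0.05, n_copies = 100,
           sub_rate = 0.05, indel_rate = 0.0005, length = 380),
      list(name = "MALRSIM4", mu = 0.66, sigma = 0.05, n_copies = 100,
           sub_rate = 0.03, indel_rate = 0.0005, length = 400),
      list(name = "MALRSIM5", mu = 0.84, sigma = 0.05, n_copies = 100,
           sub_rate = 0.02, indel_rate = 0.0005, length = 360)),
    thresholds = list(min_sw_score = 100, flank_length = 300,
                      min_flank_aligned = 200, min_presence = 50),
    tint = list(tolerance = 30, restarts = 20),
    structvar = list(n_canonical = 98, n_precursor = 1, n_intermediate = 1,
                     sub_rate = 0.05, u3_end = 195))
}

#' Read / write a scenario configuration (YAML)
#' @param path YAML file.
#' @return The scenario list.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_scenario(cfg)
  cfg
}

#' @rdname read_scenario
#' @param config Scenario list.
#' @export
write_scenario <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Validate a scenario configuration
#' @param config Scenario list.
#' @return `config`, invisibly; stops with an informative error otherwise.
#' @export
validate_scenario <- function(config) {
  if (is.null(config$seed))
    stop("scenario validation: a seed is mandatory for stochastic stages")
  if (is.null(config$families) || !length(config$families))
    stop("scenario validation: at least one family is required")
  for (f in config$families)
    for (fld in c("name", "mu", "sigma", "n_copies"))
      if (is.null(f[[fld]]))
        stop("scenario validation: family missing field '", fld, "'")
  invisible(config)
}

#' Build the family models and bundle of a scenario
#'
#' Family consensus sequences are drawn from the seeded stream.  Unless a
#' family supplies its own `consensus`, each family's consensus descends
#' from its predecessor's by `consensus_step_subs` substitutions per base
#' (plus rare short indels), emulating the successive-emergence model in
#' which every member evolves from the one before it — so the consensus
#' tree of the scenario has a known backbone.  The succession is then
#' simulated; everything is deterministic given `config$seed`.
#'
#' @param config Scenario list.
#' @return A `succession_bundle`.
#' @export
scenario_bundle <- function(config) {
  validate_scenario(config)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(config$seed))
  step <- config$genome$consensus_step_subs %||% 0.06
  prev <- NULL
  families <- lapply(config$families, function(f) {
    cons <- if (!is.null(f$consensus)) f$consensus
    else if (is.null(prev)) random_dna(f$length %||% 400)
    else mutate_sequence(prev, step, 1e-3)
    prev <<- cons
    family_model(f$name, consensus = cons, mu = f$mu, sigma = f$sigma,
                 n_copies = f$n_copies,
                 sub_rate = f$sub_rate %||% 0.05,
                 indel_rate = f$indel_rate %||% 5e-4)
  })
  tree <- primate_tree(config$tree$split_hs %||% 0.3,
                       config$tree$split_st %||% 0.5)
  g <- config$genome %||% list()
  simulate_succession(tree, families, seed = config$seed,
                      spacer = g$spacer %||% 700,
                      p_nest = g$p_nest %||% 0.15,
                      nest_margin = g$nest_margin %||% 25)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline on a scenario
#'
#' Executes simulate, census, timing, tint, tree and structvar stages,
#' writing each stage's tables under `outdir` and a `manifest.json`
#' recording the package version, seed, config hash and per-file MD5
#' checksums.  Any stage failure aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param config Scenario list (see [default_scenario()]).
#' @param outdir Output directory.
#' @return The manifest, invisibly.
#' @export
run_succession_pipeline <- function(config, outdir) {
  validate_scenario(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  th <- do.call(timing_thresholds, config$thresholds %||% list())
  fam_names <- vapply(config$families, `[[`, "", "name")

  bundle <- stage("simulate", {
    b <- scenario_bundle(config)
    write_bundle(b, file.path(outdir, "bundle"))
    b
  })
  stage("census", {
    cen <- do.call(rbind, lapply(names(bundle$copies), function(s)
      family_census(bundle$copies[[s]], fam_names, s)))
    .write_tsv(cen, file.path(outdir, "census.tsv"), "census")
  })
  calls <- stage("timing", {
    calls <- timing_calls(bundle$copies$human, bundle$chains, th)
    .write_tsv(calls, file.path(outdir, "timing_calls.tsv"), "timing")
    .write_tsv(timing_summary(calls), file.path(outdir, "timing_summary.tsv"),
               "timing")
    for (cat in unique(stats::na.omit(calls$call)))
      write_bed(calls[which(calls$call == cat), ],
                file.path(outdir, paste0("timing_", cat, ".bed")))
    calls
  })
  stage("tint", {
    ev <- detect_tint_events(bundle$copies$human,
                             tolerance = config$tint$tolerance %||% 30)
    N <- build_nesting_matrix(ev, fam_names)
    .write_tsv(as.data.frame(N), file.path(outdir, "tint_matrix.tsv"), "tint")
    cw <- table(factor(group_entities(bundle$copies$human)$family,
                       levels = fam_names))
    per <- infer_activity_periods(N, copy_weights = as.numeric(cw) + 1,
                                  restarts = config$tint$restarts %||% 20,
                                  seed = config$seed)
    .write_tsv(per, file.path(outdir, "tint_periods.tsv"), "tint")
    .write_tsv(youngest_family_check(per, N),
               file.path(outdir, "tint_youngest.tsv"), "tint")
  })
  stage("tree", {
    D <- consensus_dist_matrix(bundle$consensus)
    .write_tsv(cbind(family = rownames(D), as.data.frame(D)),
               file.path(outdir, "consensus_dist.tsv"), "tree")
    write_newick(neighbor_joining(D), file.path(outdir, "consensus_nj.nwk"))
  })
  stage("structvar", {
    sv <- config$structvar %||% list()
    cons <- synthetic_the1_consensus()
    defs <- the1_variant_defs()
    model <- ltr_model(u3_end = sv$u3_end %||% 195, length = nchar(cons$ltr))
    pops <- mapply(function(stg, n, pref) {
      if (n <= 0) return(NULL)
      plant_structural_variants(cons$ltr, cons$internal, defs, stg, n = n,
                                sub_rate = sv$sub_rate %||% 0.05,
                                seed = config$seed + match(stg, c("canonical",
                                  "precursor", "intermediate")),
                                prefix = pref)
    }, c("canonical", "precursor", "intermediate"),
       c(sv$n_canonical %||% 98, sv$n_precursor %||% 1,
         sv$n_intermediate %||% 1),
       c("can", "pre", "int"), SIMPLIFY = FALSE)
    pops <- pops[!vapply(pops, is.null, logical(1))]
    els <- unlist(lapply(pops, `[[`, "elements"))
    names(els) <- unlist(lapply(pops, function(p) names(p$elements)))
    scan <- scan_for_stage(els, cons$ltr, defs)
    .write_tsv(scan, file.path(outdir, "structvar_stages.tsv"), "structvar")
    inter <- scan$element[scan$stage == "intermediate"]
    if (length(inter)) {
      calls <- call_variants(els[[inter[1]]], cons$ltr, defs)
      prog <- predict_progeny_ltr(calls_to_pattern(calls), defs, model)
      .write_tsv(data.frame(variant = names(prog$ltr5),
                            ltr5 = prog$ltr5, ltr3 = prog$ltr3),
                 file.path(outdir, "structvar_progeny.tsv"), "structvar")
    }
  })
  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "malrsucc", version = .pkg_version(),
    seed = config$seed,
    config_hash = unname(tools::md5sum(
      write_scenario(config, file.path(tempdir(), "scenario_hash.yaml")))),
    checksums = as.list(tools::md5sum(file.path(outdir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
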