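write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

default_pipeline_params <- function() {
  list(max_mismatch_flank = 1L, min_match_len = 12L,
       max_mismatch_frac = 0.02, pseudocount = 1, normalize = TRUE,
       top_n = 30L, n_sd = 5, k_mad = 6, min_separation = 5L,
       mode = "log_ratio", antibody_conc = 0.7)
}

#' Run the full epitope-mapping pipeline
#'
#' Executes classify -> enrich -> hot-spots over an unselected /
#' affinity-selected library pair (optionally produced by the built-in
#' simulator), plus an optional competition-ELISA K_D stage, writing
#' TSV/JSON reports and a machine-readable run manifest into a fresh
#' output directory.  Identical configuration and seed give identical
#' outputs.
#'
#' @param config Configuration list or path to a YAML file.  Blocks:
#'   `reference` (either `cds_file`/`protein_file`/`annotations`/
#'   `numbering_offset`, or `synthetic: true` with `n_res`,
#'   `numbering_offset`, `seed`); either `simulate` (fields of
#'   [sim_config()]; `epitope_required_sets` as a list of
#'   `(start, end, system)`) or `reads` (`unselected`, `selected`
#'   FASTA/FASTQ paths); optional `elisa` (`csv`, `reference_id`);
#'   `params` overriding stage defaults; `out_dir`; `seed`.
#' @return Invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config must name out_dir")
  if (is.null(config$reference)) stop("config must contain a reference block")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path))
    stop("output directory already holds a run (manifest.json exists); ",
         "outputs are write-once per run directory")
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  seed <- config$seed %||% 1L
  stage <- "setup"
  manifest <- list(package = "phagescan",
                   version = as.character(packageVersion("phagescan")),
                   seed = seed, params = params,
                   config = config[setdiff(names(config), "params")])
  fail_manifest <- function(e) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  res <- tryCatch({
    set.seed(seed)
    stage <- "reference"
    rb <- config$reference
    ref <- if (isTRUE(rb$synthetic)) {
      synthetic_reference(n_res = rb$n_res %||% 438L,
                          numbering_offset = rb$numbering_offset %||% 183L,
                          seed = rb$seed %||% 1L)
    } else {
      load_reference(rb$cds_file, rb$protein_file,
                     rb$annotations,
                     numbering_offset = rb$numbering_offset %||% 0L)
    }

    flanks <- unlist(config$flanks %||% default_flanks())
    sim <- NULL
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      sb <- config$simulate
      sets <- lapply(sb$epitope_required_sets %||% list(), function(s)
        residue_span(s$start, s$end, s$system %||% "antigen_local"))
      cfg <- sim_config(
        ref,
        n_clones = sb$n_clones %||% 5000L,
        empty_fraction = sb$empty_fraction %||% 0.1,
        fragment_length_range = unlist(
          sb$fragment_length_range %||% c(100L, 400L)),
        epitope_required_sets = sets,
        w_binder = sb$w_binder %||% 100,
        w_background = sb$w_background %||% 1,
        n_rounds = sb$n_rounds %||% 2L,
        reads_per_round = sb$reads_per_round %||% 50000L,
        seq_error_rate = sb$seq_error_rate %||% 0.001,
        flanks = flanks)
      lib <- simulate_library(cfg)
      selection <- simulate_selection(lib)
      write_fastq(lib$reads, file.path(out_dir, "unselected.fastq"))
      write_fastq(selection$reads, file.path(out_dir, "selected.fastq"))
      write_tsv(lib$clones[, setdiff(names(lib$clones), "insert")],
                file.path(out_dir, "truth.tsv"))
      reads_u <- setNames(lib$reads$sequence, lib$reads$read_id)
      reads_s <- setNames(selection$reads$sequence,
                          selection$reads$read_id)
      sim <- list(library = lib, selection = selection)
    } else {
      if (is.null(config$reads$unselected) ||
          is.null(config$reads$selected))
        stop("config must contain either a simulate block or ",
             "reads$unselected and reads$selected")
      reads_u <- read_sequences(config$reads$unselected)
      reads_s <- read_sequences(config$reads$selected)
    }

    stage <- "classify"
    cls_u <- classify_library(reads_u, ref, flanks = flanks,
                              max_mismatch_flank = params$max_mismatch_flank,
                              min_match_len = params$min_match_len,
                              max_mismatch_frac = params$max_mismatch_frac)
    cls_s <- classify_library(reads_s, ref, flanks = flanks,
                              max_mismatch_flank = params$max_mismatch_flank,
                              min_match_len = params$min_match_len,
                              max_mismatch_frac = params$max_mismatch_frac)
    write_tsv(cls_u$fragments,
              file.path(out_dir, "classification_unselected.tsv"))
    write_tsv(cls_s$fragments,
              file.path(out_dir, "classification_selected.tsv"))

    stage <- "enrich"
    cu <- library_counts(cls_u, "unselected")
    cs <- library_counts(cls_s, "selected")
    profile <- enrichment_factor(cs, cu, ref,
                                 pseudocount = params$pseudocount,
                                 normalize = params$normalize)
    write_tsv(as.data.frame(profile), file.path(out_dir, "profile.tsv"))
    ranked <- rank_fragments(cs, top_n = params$top_n, unsel = cu)
    write_tsv(ranked, file.path(out_dir, "ranked_fragments.tsv"))
    signif <- call_significant(cs, cu, n_sd = params$n_sd)
    write_tsv(signif, file.path(out_dir, "significant_fragments.tsv"))

    stage <- "hotspots"
    hs <- call_hotspots(profile, k_mad = params$k_mad,
                        min_separation = params$min_separation,
                        mode = params$mode)
    hs_out <- as.data.frame(hs)
    hs_out$candidate_span <- vapply(seq_len(nrow(hs_out)), function(i) {
      sp <- candidate_required_region(hs_out[i, ], profile)
      paste0(sp$start, "-", sp$end)
    }, character(1))
    write_tsv(hs_out, file.path(out_dir, "hotspots.tsv"))

    kd <- NULL
    if (!is.null(config$elisa)) {
      stage <- "kd"
      series <- read_elisa_csv(config$elisa$csv,
                               antibody_conc = params$antibody_conc)
      ref_id <- config$elisa$reference_id %||% names(series)[1]
      if (!ref_id %in% names(series))
        stop("elisa reference_id '", ref_id, "' not in the CSV")
      ref_est <- aggregate_kd(series[[ref_id]])
      kd <- lapply(series, aggregate_kd, reference = ref_est)
      kd_tab <- data.frame(
        antigen_id = names(kd),
        kd_mean_nM = vapply(kd, `[[`, numeric(1), "kd_mean"),
        kd_sd_nM = vapply(kd, `[[`, numeric(1), "kd_sd"),
        fold_change = vapply(kd, `[[`, numeric(1),
                             "fold_change_vs_reference"),
        no_binding = vapply(kd, `[[`, logical(1), "no_binding"))
      write_tsv(kd_tab, file.path(out_dir, "kd_estimates.tsv"))
    }

    stage <- "report"
    summary <- list(
      unselected = cls_u$summary, selected = cls_s$summary,
      n_unique_fragments_selected = nrow(cs$fragments),
      n_significant = sum(signif$significant),
      significance_threshold = attr(signif, "threshold"),
      hotspot_boundaries = hs_out$boundary,
      hotspot_threshold = attr(hs, "threshold"))
    if (!is.null(sim))
      summary$binder_fraction_per_round <-
        sim$selection$binder_fraction
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
    manifest$outputs <- union(list.files(out_dir), "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, force = TRUE)
    list(ref = ref, sim = sim, unselected = cls_u, selected = cls_s,
         profile = profile, ranked = ranked, significant = signif,
         hotspots = hs_out, kd = kd, summary = summary,
         out_dir = out_dir)
  }, error = fail_manifest)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a per-residue enrichment profile
#'
#' Base-graphics view of the enrichment-factor profile with called
#' hot-spot boundaries marked by arrows.
#'
#' @param x A `residue_enrichment_profile`.
#' @param hotspots Optional `hotspot_calls` to annotate.
#' @param log Use a logarithmic EF axis (default `TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.residue_enrichment_profile <- function(x, hotspots = NULL,
                                            log = TRUE, ...) {
  graphics::plot(x$residue, x$ef, type = "l",
                 log = if (log) "y" else "",
                 xlab = "residue (fusion numbering)",
                 ylab = "enrichment factor", ...)
  if (!is.null(hotspots) && nrow(hotspots)) {
    up <- hotspots$direction == "increase"
    graphics::abline(v = hotspots$boundary,
                     col = ifelse(up, "red", "blue"), lty = 2)
  }
  invisible(x)
}
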