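# pipeline: end-to-end orchestration (scan -> effectors -> clusters ->
# phylo) from a single config, with per-stage outputs, a provenance block
# and machine-readable reports.

#' Default pipeline configuration
#'
#' One nested list drives the whole run; the same structure can be stored
#' as YAML and loaded with [read_run_config()]. Unknown keys are rejected
#' so typos cannot silently disable a filter. Every default lands in the
#' report's provenance block, so the thresholds behind any candidate count
#' are always answerable.
#'
#' @return nested list of class `t3ss_run_config`
#' @export
default_run_config <- function() {
  structure(list(
    genome = list(path = NULL, format = "genbank", gff3 = NULL,
                  genome_id = NULL),
    motif = list(variant = "screening", min_dist = 30L, max_dist = 300L,
                 window = NULL, max_mismatch = 0L, both_strands = FALSE,
                 truncate_at_cds = FALSE),
    effectors = list(enabled = TRUE, window = 50L, min_ser_frac = 0.10,
                     min_polar_frac = 0.40, acidic_rule = "at_most_one",
                     require_aliphatic_34 = TRUE),
    clusters = list(enabled = TRUE, panel = NULL, min_identity = 30,
                    min_coverage = 0.5, matrix = "BLOSUM62", gap_open = 11,
                    gap_extend = 1, max_gap = 5000L),
    phylo = list(enabled = FALSE, alignment = NULL, model = "k80",
                 deletion = "pairwise", replicates = 1000L, seed = NULL),
    output_dir = NULL), class = "t3ss_run_config")
}

#' Read and validate a pipeline config
#'
#' @param path YAML file with the [default_run_config()] structure; absent
#'   keys take their defaults, unknown keys are an error
#' @param overrides named list merged over the file (CLI flags)
#' @return validated `t3ss_run_config`
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- modifyList(cfg, overrides)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a (possibly partial) config list
#' @export
validate_run_config <- function(cfg) {
  template <- default_run_config()
  check <- function(given, tmpl, where) {
    unknown <- setdiff(names(given), names(tmpl))
    if (length(unknown)) {
      stopf("unknown config key(s) under %s: %s", where,
            paste(unknown, collapse = ", "))
    }
    for (k in names(given)) {
      if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]]))) {
        check(given[[k]], tmpl[[k]], paste0(where, "$", k))
      }
    }
  }
  check(cfg, template, "config")
  merged <- template
  for (k in names(cfg)) {
    merged[[k]] <- if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      modifyList(template[[k]], cfg[[k]]) else cfg[[k]]
  }
  stopifnot(merged$motif$variant %in% c("screening", "consensus"),
            merged$motif$min_dist >= 0,
            merged$motif$min_dist <= merged$motif$max_dist,
            merged$effectors$acidic_rule %in% c("at_most_one", "none",
                                                "at_least_one"),
            merged$clusters$min_identity >= 0,
            merged$clusters$min_identity <= 100,
            merged$clusters$min_coverage > 0,
            merged$clusters$min_coverage <= 1,
            merged$phylo$model %in% c("k80", "jc_protein"))
  class(merged) <- "t3ss_run_config"
  merged
}

#' Run the full T3SS mining pipeline
#'
#' Stages run in order (genome_io -> motif_scan -> effector_filter ->
#' cluster_finder -> phylo); each stage's tables are persisted to
#' `output_dir` as they complete, so a failing stage still leaves a report
#' covering everything before it. Reruns with identical config and inputs
#' are bit-identical except for timestamps.
#'
#' @param config a `t3ss_run_config` (or path to its YAML)
#' @param genome optionally, an already-loaded [annotated_genome()]
#'   (overrides `config$genome$path`)
#' @return a `t3ss_run_report`: per-stage tables, funnel counts and a
#'   provenance block (config, config hash, package version, seeds,
#'   timestamps, per-stage log)
#' @export
run_pipeline <- function(config = default_run_config(), genome = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(unclass(config))
  out_dir <- config$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  report <- list(stages = list(), counts = list(), errors = list(),
                 provenance = list(
                   package_version = as.character(utils::packageVersion("t3ssmine")),
                   config = unclass(config),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   log = character()))
  note <- function(msg) {
    report$provenance$log <<- c(report$provenance$log, msg)
  }
  fail <- function(stage, e) {
    report$errors[[stage]] <<- conditionMessage(e)
    note(sprintf("stage %s FAILED: %s", stage, conditionMessage(e)))
  }
  persist <- function() {
    if (!is.null(out_dir)) {
      yaml::write_yaml(unclass(config), file.path(out_dir, "config_used.yaml"))
      report$provenance$config_hash <-
        unname(tools::md5sum(file.path(out_dir, "config_used.yaml")))
    }
    report
  }

  # stage: genome_io
  if (is.null(genome)) {
    genome <- tryCatch(
      read_genome(config$genome$path, config$genome$format,
                  gff3 = config$genome$gff3,
                  genome_id = config$genome$genome_id),
      error = function(e) { fail("genome_io", e); NULL })
    if (is.null(genome)) {
      report$provenance$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      return(structure(persist(), class = "t3ss_run_report"))
    }
  }
  report$counts$n_cds <- nrow(genome$cds)
  note(sprintf("genome_io: %d CDS on %d contig(s)", nrow(genome$cds),
               length(genome$contigs)))

  # stage: motif_scan
  pattern <- hrp_box_pattern(config$motif$variant)
  note(sprintf("motif_scan: pattern variant '%s' (screening and consensus renderings disagree; selection is a config key)",
               config$motif$variant))
  motif_table <- tryCatch(
    screen_genome(genome, pattern, config$motif$min_dist,
                  config$motif$max_dist, window = config$motif$window,
                  max_mismatch = config$motif$max_mismatch,
                  both_strands = config$motif$both_strands,
                  truncate_at_cds = config$motif$truncate_at_cds),
    error = function(e) { fail("motif_scan", e); NULL })
  if (!is.null(motif_table)) {
    report$stages$hrp_box_genes <- motif_table
    report$counts$n_hrp_box_genes <- nrow(motif_table)
    note(sprintf("motif_scan: %d gene(s) with an hrp box at %d-%d bp",
                 nrow(motif_table), config$motif$min_dist,
                 config$motif$max_dist))
    if (!is.null(out_dir)) {
      write.table(motif_table, file.path(out_dir, "hrp_box_genes.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_hits_tsv(motif_table, file.path(out_dir, "hrp_box_hits.tsv"))
      write_hits_bed(motif_table, file.path(out_dir, "hrp_box_hits.bed"))
    }
  }

  # stage: effector_filter
  if (isTRUE(config$effectors$enabled) && !is.null(motif_table)) {
    th <- effector_thresholds(window = config$effectors$window,
                              min_ser_frac = config$effectors$min_ser_frac,
                              min_polar_frac = config$effectors$min_polar_frac,
                              acidic_rule = config$effectors$acidic_rule,
                              require_aliphatic_34 = config$effectors$require_aliphatic_34)
    note(sprintf("effector_filter: acidic rule '%s' (source criteria are ambiguous; rule is a config key)",
                 th$acidic_rule))
    candidates <- tryCatch(run_effector_screen(genome, motif_table, th),
                           error = function(e) { fail("effector_filter", e); NULL })
    if (!is.null(candidates)) {
      report$stages$effector_candidates <- candidates
      report$counts$n_putative_effectors <-
        sum(candidates$is_putative_effector, na.rm = TRUE)
      report$counts$n_unevaluable <- sum(candidates$status == "unevaluable")
      note(sprintf("effector_filter: %d putative effector(s), %d unevaluable",
                   report$counts$n_putative_effectors,
                   report$counts$n_unevaluable))
      if (!is.null(out_dir)) {
        write_candidates_tsv(candidates,
                             file.path(out_dir, "effector_candidates.tsv"))
        write_candidates_json(candidates,
                              file.path(out_dir, "effector_candidates.json"))
      }
    }
  }

  # stage: cluster_finder
  if (isTRUE(config$clusters$enabled)) {
    clusters <- tryCatch({
      panel <- if (is.null(config$clusters$panel)) read_panel() else
        read_panel(config$clusters$panel)
      hits <- find_components(genome, panel,
                              min_identity = config$clusters$min_identity,
                              min_coverage = config$clusters$min_coverage,
                              matrix = config$clusters$matrix,
                              gap_open = config$clusters$gap_open,
                              gap_extend = config$clusters$gap_extend)
      report$stages$component_hits <- hits
      assemble_clusters(hits, max_gap = config$clusters$max_gap)
    }, error = function(e) { fail("cluster_finder", e); NULL })
    if (!is.null(clusters)) {
      report$stages$clusters <- clusters
      report$counts$n_clusters <- length(clusters)
      note(sprintf("cluster_finder: %d cluster(s)", length(clusters)))
      if (!is.null(out_dir)) {
        write_clusters_tsv(clusters, file.path(out_dir, "clusters.tsv"))
        write_clusters_json(clusters, file.path(out_dir, "clusters.json"))
        write_clusters_gff3(clusters, file.path(out_dir, "clusters.gff3"))
      }
    }
  }

  # stage: phylo
  if (isTRUE(config$phylo$enabled)) {
    bs <- tryCatch({
      if (is.null(config$phylo$alignment)) stopf("phylo stage needs an alignment path")
      if (is.null(config$phylo$seed)) stopf("phylo stage needs a seed")
      aln <- read_alignment(config$phylo$alignment)
      bootstrap_support(aln, n_replicates = config$phylo$replicates,
                        model = config$phylo$model, seed = config$phylo$seed,
                        deletion = config$phylo$deletion)
    }, error = function(e) { fail("phylo", e); NULL })
    if (!is.null(bs)) {
      report$stages$tree <- bs
      note(sprintf("phylo: NJ tree, %d replicates, %d skipped",
                   bs$n_replicates, bs$n_skipped))
      if (!is.null(out_dir)) {
        write_newick(bs$tree, file.path(out_dir, "tree.nwk"))
        write_tree_json(bs, file.path(out_dir, "tree.json"))
      }
    }
  }

  report$provenance$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  report <- persist()
  if (!is.null(out_dir)) {
    summary_json <- list(counts = report$counts, errors = report$errors,
                         provenance = report$provenance[
                           setdiff(names(report$provenance),
                                   c("started", "finished"))])
    jsonlite::write_json(summary_json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(report, class = "t3ss_run_report")
}

#' @export
print.t3ss_run_report <- function(x, ...) {
  cat("t3ss_run_report\n")
  for (k in names(x$counts)) cat(sprintf("  %s: %s\n", k, x$counts[[k]]))
  if (length(x$errors)) {
    for (s in names(x$errors)) cat(sprintf("  ERROR in %s: %s\n", s,
                                           x$errors[[s]]))
  }
  invisible(x)
}
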