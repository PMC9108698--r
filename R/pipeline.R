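#' Run the full serial repertoire analysis pipeline
#'
#' Orchestrates QC filtering, depth-normalized summary metrics, pairwise
#' similarity, edit-distance-1 network topology, longitudinal clone
#' tracking with optional database annotation, and group comparisons, and
#' writes every result as a TSV plus a JSON run manifest (configuration,
#' configuration hash, seed, package version, excluded samples). Running
#' the same cohort and configuration twice produces byte-identical output
#' files. Any stage failure aborts with the stage name in the error
#' message.
#'
#' @param x a `trb_cohort`.
#' @param out_dir output directory (created if needed).
#' @param config an [analysis_config()]; set `rng_seed` for reproducible
#'   downsampling.
#' @param dbs optional annotation data.frame(s) for trajectory labeling
#'   and annotated-abundance summaries.
#' @param gliph_groups optional `trb_specificity_groups`.
#' @param track_n clones per participant to track (defaults to
#'   `config$track_top_n`).
#' @return invisibly, a list with the in-memory results and the paths of
#'   the written files.
#' @export
run_pipeline <- function(x, out_dir, config = analysis_config(),
                         dbs = NULL, gliph_groups = NULL,
                         track_n = config$track_top_n) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  metrics <- stage("metrics", cohort_metrics(x, config))
  excluded <- attr(metrics, "excluded")
  if (!nrow(metrics)) stop("pipeline stage 'metrics' failed: no sample passed QC")
  kept <- cohort(x$repertoires[metrics$sample_id], x$participants,
                 mhc = x$mhc, clinical = x$clinical)
  paths <- list(metrics = tsv(metrics, "metrics.tsv"))

  sim <- stage("similarity", similarity_matrix(kept, config))
  sim_df <- data.frame(sample_id = rownames(sim$values), sim$values,
                       check.names = FALSE, stringsAsFactors = FALSE)
  paths$similarity <- tsv(sim_df, "similarity.tsv")
  paths$similarity_groups <- tsv(similarity_groups(sim),
                                 "similarity_groups.tsv")

  st <- samples_table(kept)
  degree_rows <- list()
  networks_by_group <- split(st$sample_id, st$group)
  dists <- list()
  for (grp in names(networks_by_group)) {
    nets <- stage(paste0("network[", grp, "]"),
                  lapply(networks_by_group[[grp]], function(sid) {
                    build_network(top_n_clonotypes(
                      filter_cdr3(kept$repertoires[[sid]],
                                  config$min_cdr3_length),
                      config$network_top_n))
                  }))
    dists[[grp]] <- degree_distribution(nets, group = grp)
    tab <- dists[[grp]]$table
    tab$group <- grp
    degree_rows[[grp]] <- tab[, c("group", "k", "frequency", "ccdf",
                                  "trend")]
  }
  paths$degrees <- tsv(do.call(rbind, degree_rows), "degrees.tsv")

  traj <- NULL
  if (any(st$group != "control")) {
    traj <- stage("tracking", track_cohort(kept, n = track_n))
    if (!is.null(traj) && !is.null(dbs)) {
      traj <- stage("annotation",
                    label_trajectories(traj, kept, dbs, gliph_groups))
    }
    if (!is.null(traj)) paths$trajectories <- tsv(traj, "trajectories.tsv")
  }

  abundance <- NULL
  if (!is.null(dbs)) {
    abundance <- stage("annotated_abundance",
                       annotated_abundance_by_group(kept, dbs))
    paths$annotated_abundance <- tsv(abundance, "annotated_abundance.tsv")
  }

  comparisons <- NULL
  grp_sizes <- table(metrics$group)
  if (length(grp_sizes) >= 2 && all(grp_sizes >= 2)) {
    comparisons <- stage("comparisons", compare_groups(
      metrics,
      metric_cols = c("clonality", "gini", "production_efficiency",
                      "unique_productive_aa", "max_clone_freq"),
      paired_pre_post = TRUE))
    paths$comparisons <- tsv(comparisons, "comparisons.tsv")
  }

  cfg_plain <- unclass(config)
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  saveRDS(cfg_plain, tmp, version = 2)
  manifest <- list(
    package = "trbserial",
    version = as.character(packageVersion("trbserial")),
    config = cfg_plain,
    config_md5 = unname(tools::md5sum(tmp)),
    n_samples = nrow(st) + nrow(excluded),
    n_kept = nrow(st),
    excluded_samples = excluded,
    sample_ids = st$sample_id)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(metrics = metrics, excluded = excluded, similarity = sim,
                 degree_distributions = dists, trajectories = traj,
                 annotated_abundance = abundance,
                 comparisons = comparisons, paths = paths))
}
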