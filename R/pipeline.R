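#' Configuration for an end-to-end screen analysis run
#'
#' Exactly one input mode: either `spots_files` (named by group, each a spot
#' table readable by [read_spots_table()]) or `synthetic` (a named list of
#' [cohort_group_spec()]s). The control group must be among the groups.
#'
#' @param spots_files named list of file paths (group -> path), or `NULL`.
#' @param synthetic named list of group specs, or `NULL`.
#' @param control_group control group label.
#' @param frame_interval minutes per frame.
#' @param timing a [timing_config()].
#' @param seed master seed for all randomness in the run.
#' @param outdir output directory, or `NULL` to skip writing files.
#' @param dialect a [spots_dialect()] for file input.
#' @param pca_after_outlier_removal run PCA on the outlier-filtered table
#'   (default) or on the unfiltered one.
#' @param unit statistical unit for group tests: `"cell"` (default) or
#'   `"gonad"` (per-gonad means).
#' @export
run_config <- function(spots_files = NULL, synthetic = NULL,
                       control_group = "control", frame_interval = 0.5,
                       timing = timing_config(), seed = 1L, outdir = NULL,
                       dialect = spots_dialect(),
                       pca_after_outlier_removal = TRUE,
                       unit = c("cell", "gonad")) {
  unit <- match.arg(unit)
  if (is.null(spots_files) == is.null(synthetic))
    stop("exactly one of spots_files or synthetic must be given")
  groups <- names(if (!is.null(synthetic)) synthetic else spots_files)
  if (!control_group %in% groups)
    stop("control group '", control_group, "' is not among the groups: ",
         paste(groups, collapse = ", "))
  structure(list(spots_files = spots_files, synthetic = synthetic,
                 control_group = control_group,
                 frame_interval = frame_interval, timing = timing,
                 seed = as.integer(seed), outdir = outdir,
                 dialect = dialect,
                 pca_after_outlier_removal = pca_after_outlier_removal,
                 unit = unit),
            class = "run_config")
}

per_gonad_means <- function(table, cols) {
  agg <- stats::aggregate(table[cols],
                          by = list(group = table$group,
                                    gonad_id = table$gonad_id),
                          FUN = mean, na.rm = TRUE)
  agg
}

#' Run the full screen analysis
#'
#' Chains the pipeline stages: tracks (from files or the synthetic
#' generator) -> spindle-length series -> landmark scoring -> feature
#' extraction -> per-genotype outlier removal -> control-relative heatmap
#' with group tests -> pooled-standardized duration correlations and PCA ->
#' delayed-cell classification. All stages are seeded from `config$seed`, so
#' two runs of the same config are identical.
#'
#' @param config a [run_config()].
#' @return a result bundle (list) with `features` (raw table), `filtered`
#'   (outlier-removed), `outlier_log`, `comparisons`, `heatmap`,
#'   `correlations`, `pca`, `delayed`, `per_gonad`, `truth` (synthetic runs
#'   only), `errors`, and `config`. If `config$outdir` is set, CSV/JSON
#'   outputs are written there.
#' @export
run_screen_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  truth <- NULL
  if (!is.null(config$synthetic)) {
    sim <- simulate_cohort(config$synthetic, seed = config$seed,
                           frame_interval = config$frame_interval)
    tracks <- sim$tracks
    truth <- sim$truth
  } else {
    tracks <- list()
    for (g in names(config$spots_files)) {
      spots <- read_spots_table(config$spots_files[[g]], config$dialect)
      trs <- pair_poles(spots, frame_interval = config$frame_interval)
      for (tr in trs) {
        tr$group <- g
        if (identical(tr$gonad_id, "unknown")) tr$gonad_id <- g
        tracks[[tr$cell_id]] <- tr
      }
    }
  }

  features <- cohort_feature_table(tracks, cfg = config$timing,
                                   seed = config$seed)
  errors <- attr(features, "errors")

  filt <- remove_outliers_per_group(features)
  stats_table <- if (config$unit == "gonad")
    cbind(per_gonad_means(filt$table, feature_cols_present(filt$table)),
          cell_id = NA_character_)
  else filt$table
  comparisons <- compare_groups_to_control(stats_table,
                                           config$control_group)
  heatmap <- build_heatmap_matrix(filt$table, config$control_group,
                                  comparisons = comparisons)

  pooled <- standardize_features(if (config$pca_after_outlier_removal)
    filt$table else features, reference = "pooled")
  correlations <- correlate_features_with_duration(pooled)
  pca <- run_pca(pooled)

  ctrl_dur <- features$B_duration[features$group == config$control_group]
  delayed <- classify_delayed(features$B_duration, ctrl_dur)
  per_gonad <- per_gonad_means(features, feature_cols_present(features))

  bundle <- list(features = features, filtered = filt$table,
                 outlier_log = filt$log, comparisons = comparisons,
                 heatmap = heatmap, correlations = correlations, pca = pca,
                 delayed = data.frame(cell_id = features$cell_id,
                                      group = features$group,
                                      duration = features$B_duration,
                                      delayed = as.logical(delayed)),
                 delayed_threshold = attr(delayed, "threshold"),
                 per_gonad = per_gonad, truth = truth, errors = errors,
                 config = config)
  if (!is.null(config$outdir)) write_bundle(bundle, config$outdir)
  bundle
}

write_bundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, name) utils::write.csv(
    x, file.path(outdir, name), row.names = FALSE)
  wcsv(bundle$features, "features.csv")
  wcsv(bundle$filtered, "features_filtered.csv")
  wcsv(bundle$outlier_log, "outlier_log.csv")
  wcsv(bundle$comparisons, "group_comparisons.csv")
  utils::write.csv(bundle$heatmap, file.path(outdir, "heatmap_matrix.csv"))
  wcsv(bundle$correlations, "duration_correlations.csv")
  wcsv(cbind(feature = rownames(bundle$pca$loadings),
             as.data.frame(bundle$pca$loadings)), "pca_loadings.csv")
  wcsv(bundle$pca$scores, "pca_scores.csv")
  wcsv(bundle$delayed, "delayed_cells.csv")
  wcsv(bundle$per_gonad, "per_gonad_means.csv")
  summary <- screen_summary(bundle)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

# Machine-readable per-group summary statistics.
screen_summary <- function(bundle) {
  feats <- feature_cols_present(bundle$features)
  groups <- unique(bundle$features$group)
  per_group <- lapply(groups, function(g) {
    sub <- bundle$features[bundle$features$group == g, ]
    stats <- lapply(feats, function(f)
      list(mean = mean(sub[[f]], na.rm = TRUE),
           sd = stats::sd(sub[[f]], na.rm = TRUE),
           median = stats::median(sub[[f]], na.rm = TRUE),
           n = sum(!is.na(sub[[f]]))))
    names(stats) <- feats
    list(n_cells = nrow(sub), features = stats)
  })
  names(per_group) <- groups
  list(seed = bundle$config$seed,
       control_group = bundle$config$control_group,
       n_cells = nrow(bundle$features),
       pc1_pc2_explained_pct = sum(bundle$pca$explained_pct[1:2]),
       delayed_threshold_min = bundle$delayed_threshold,
       groups = per_group)
}

boxplot_stats <- function(x) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  inliers <- x[x >= q[1] - 1.5 * iqr & x <= q[3] + 1.5 * iqr]
  c(median = q[2], q1 = q[1], q3 = q[3],
    whisker_lo = min(inliers), whisker_hi = max(inliers))
}

#' Write a human-readable report of a screen run
#'
#' Produces a plain-text summary plus per-group duration boxplot statistics
#' (median, quartiles, non-outlier whiskers - the plotting convention for
#' per-cell values with per-gonad means alongside), the heatmap matrix and
#' PCA coordinates as CSV.
#'
#' @param bundle result of [run_screen_analysis()].
#' @param outdir output directory.
#' @return path to the report file, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  groups <- unique(bundle$features$group)
  bp <- do.call(rbind, lapply(groups, function(g) {
    d <- bundle$features$B_duration[bundle$features$group == g]
    data.frame(group = g, n = length(d), t(boxplot_stats(d)))
  }))
  utils::write.csv(bp, file.path(outdir, "duration_boxplots.csv"),
                   row.names = FALSE)
  gon <- bundle$per_gonad[, c("group", "gonad_id", "B_duration")]
  utils::write.csv(gon, file.path(outdir, "duration_per_gonad.csv"),
                   row.names = FALSE)
  path <- file.path(outdir, "report.txt")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Screen analysis report (seed %d)", bundle$config$seed)
  w("Cells analysed: %d (%d groups); control: %s", nrow(bundle$features),
    length(groups), bundle$config$control_group)
  if (length(bundle$errors))
    w("Cells skipped at landmark scoring: %d", length(bundle$errors))
  w("")
  w("Mitotic duration (min) by group:")
  for (i in seq_len(nrow(bp)))
    w("  %-12s n=%3d  median %.2f  IQR [%.2f, %.2f]", bp$group[i], bp$n[i],
      bp$median[i], bp$q1[i], bp$q3[i])
  w("")
  sig <- bundle$comparisons[bundle$comparisons$significant, , drop = FALSE]
  w("Significant control contrasts (Kruskal-Wallis + Tukey-Kramer, p < 0.05):")
  if (nrow(sig)) for (i in seq_len(nrow(sig)))
    w("  %s / %s: effect %+.2f control SD, p_adj = %.2g", sig$feature[i],
      sig$group[i], sig$effect[i], sig$p_adj[i])
  else w("  none")
  w("")
  w("Duration correlations (Bonferroni; non-significant shown as 0):")
  for (i in seq_len(nrow(bundle$correlations)))
    w("  %-22s r = %+.2f", bundle$correlations$feature[i],
      bundle$correlations$r_reported[i])
  w("")
  w("PCA: PC1 %.1f%%, PC2 %.1f%% (PC1+PC2 %.1f%%) of total variance",
    bundle$pca$explained_pct[1], bundle$pca$explained_pct[2],
    sum(bundle$pca$explained_pct[1:2]))
  w("Delayed cells (duration > control P90 = %.2f min): %d of %d",
    bundle$delayed_threshold, sum(bundle$delayed$delayed),
    nrow(bundle$delayed))
  invisible(path)
}
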