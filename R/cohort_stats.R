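#' Read a per-cell feature table
#'
#' Loads a cells-by-features table in the layout of the candidate-screen
#' supplementary data: one row per cell, columns for the nine features (any
#' columns whose names start with the letters A-I followed by `_` or that
#' exactly match the single letters), plus a `group` (genotype) column.
#' Accepts CSV, TSV, or XLSX (the latter requires the `readxl` package).
#'
#' @param path file path.
#' @param group_col name of the genotype/condition column.
#' @param sheet sheet for XLSX input.
#' @return data.frame with columns renamed to [spindle_feature_names] where
#'   they can be identified.
#' @export
read_feature_table <- function(path, group_col = "group", sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading XLSX requires the readxl package")
      as.data.frame(readxl::read_excel(path, sheet = sheet))
    },
    tsv = utils::read.delim(path, stringsAsFactors = FALSE),
    utils::read.csv(path, stringsAsFactors = FALSE))
  for (f in spindle_feature_names) {
    letter <- substr(f, 1, 1)
    if (f %in% names(tab)) next
    hit <- which(names(tab) == letter |
                   startsWith(names(tab), paste0(letter, "_")))
    if (length(hit) == 1) names(tab)[hit] <- f
  }
  if (!group_col %in% names(tab))
    stop("no '", group_col, "' column found")
  names(tab)[names(tab) == group_col] <- "group"
  tab
}

feature_cols_present <- function(table) {
  intersect(spindle_feature_names, names(table))
}

#' Remove per-genotype outliers by the 1.5 x IQR rule
#'
#' Within each (feature, group) cell, values more than 1.5 times the
#' interquartile range above the third quartile or below the first quartile
#' are set to `NA` (the cell's other features are kept). The duration feature
#' is never filtered. Quartiles use linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param table cohort data.frame with a `group` column and feature columns.
#' @param features feature columns to screen; defaults to the feature columns
#'   present.
#' @param exclude features never filtered (default the mitotic duration).
#' @param min_group_size groups smaller than this are skipped (and logged).
#' @return list with `table` (filtered) and `log` (data.frame of removals and
#'   skipped groups).
#' @export
remove_outliers_per_group <- function(table, features = NULL,
                                      exclude = "B_duration",
                                      min_group_size = 4) {
  if (is.null(features)) features <- feature_cols_present(table)
  features <- setdiff(features, exclude)
  log <- list()
  for (f in features) {
    for (g in unique(table$group)) {
      idx <- which(table$group == g & !is.na(table[[f]]))
      if (length(idx) < min_group_size) {
        log[[length(log) + 1]] <- data.frame(feature = f, group = g,
                                             cell_id = NA_character_,
                                             value = NA_real_,
                                             action = "skipped_small_group")
        next
      }
      v <- table[[f]][idx]
      q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      out <- v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr
      if (any(out)) {
        rem <- idx[out]
        log[[length(log) + 1]] <-
          data.frame(feature = f, group = g,
                     cell_id = if ("cell_id" %in% names(table))
                       table$cell_id[rem] else as.character(rem),
                     value = table[[f]][rem], action = "removed")
        table[[f]][rem] <- NA_real_
      }
    }
  }
  list(table = table,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(feature = character(), group = character(),
                             cell_id = character(), value = numeric(),
                             action = character()))
}

#' Standardize feature columns
#'
#' Replaces each feature by `(x - mu) / sigma`, with `mu` and `sigma` taken
#' from the control group (for control-relative heatmaps) or from all cells
#' pooled (for correlation and PCA). Features with zero reference SD are
#' dropped and logged.
#'
#' @param table cohort data.frame.
#' @param reference `"pooled"` or `"control"`.
#' @param control_group group label used when `reference = "control"`.
#' @param features feature columns; defaults to those present.
#' @return the table with standardized feature columns; dropped features in
#'   the `dropped` attribute.
#' @export
standardize_features <- function(table, reference = c("pooled", "control"),
                                 control_group = "control",
                                 features = NULL) {
  reference <- match.arg(reference)
  if (is.null(features)) features <- feature_cols_present(table)
  dropped <- character()
  for (f in features) {
    ref <- if (reference == "control")
      table[[f]][table$group == control_group] else table[[f]]
    mu <- mean(ref, na.rm = TRUE)
    sigma <- stats::sd(ref, na.rm = TRUE)
    if (!is.finite(sigma) || sigma == 0) {
      dropped <- c(dropped, f)
      table[[f]] <- NULL
      next
    }
    table[[f]] <- (table[[f]] - mu) / sigma
  }
  if (length(dropped)) attr(table, "dropped") <- dropped
  table
}

# Tie-corrected rank variance used by the Kruskal-Wallis statistic and the
# Tukey-Kramer contrasts on mean ranks.
rank_variance <- function(r, n_total) {
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  n_total * (n_total + 1) / 12 -
    tie_term / (12 * (n_total - 1))
}

#' Compare each group to control per feature
#'
#' Per feature: a Kruskal-Wallis omnibus test across all groups, followed by
#' Tukey-Kramer contrasts on mean ranks (studentized-range distribution on
#' the tie-corrected rank variance, unequal group sizes). Only control
#' versus group contrasts are reported. The effect size is the difference of
#' group means in control-SD units.
#'
#' @param table cohort data.frame (raw, unstandardized values).
#' @param control_group control label.
#' @param features feature columns; defaults to those present.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with one row per (feature, non-control group):
#'   `feature`, `group`, `effect`, `p_omnibus`, `p_adj`, `significant`,
#'   `degenerate`.
#' @export
compare_groups_to_control <- function(table, control_group = "control",
                                      features = NULL, alpha = 0.05) {
  if (is.null(features)) features <- feature_cols_present(table)
  groups <- unique(table$group)
  if (!control_group %in% groups) stop("control group not present")
  others <- setdiff(groups, control_group)
  if (!length(others)) stop("need at least 2 groups")
  rows <- list()
  for (f in features) {
    ok <- !is.na(table[[f]])
    v <- table[[f]][ok]
    g <- factor(table$group[ok], levels = groups)
    n_by <- base::table(g)
    if (any(n_by < 3)) next
    degenerate <- length(unique(v)) == 1
    p_omni <- if (degenerate) NA_real_
              else stats::kruskal.test(v, g)$p.value
    r <- rank(v)
    rbar <- tapply(r, g, mean)
    vr <- rank_variance(r, length(r))
    mu_c <- mean(table[[f]][ok][g == control_group])
    sd_c <- stats::sd(table[[f]][ok][g == control_group])
    k <- length(groups)
    for (grp in others) {
      if (degenerate) {
        rows[[length(rows) + 1]] <-
          data.frame(feature = f, group = grp, effect = 0,
                     p_omnibus = NA_real_, p_adj = NA_real_,
                     significant = FALSE, degenerate = TRUE)
        next
      }
      se <- sqrt(vr * (1 / n_by[[control_group]] + 1 / n_by[[grp]]))
      q <- abs(rbar[[grp]] - rbar[[control_group]]) / se * sqrt(2)
      p_adj <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
      eff <- if (is.finite(sd_c) && sd_c > 0)
        (mean(v[g == grp]) - mu_c) / sd_c else NA_real_
      rows[[length(rows) + 1]] <-
        data.frame(feature = f, group = grp, effect = eff,
                   p_omnibus = p_omni, p_adj = p_adj,
                   significant = is.finite(p_adj) && p_adj < alpha,
                   degenerate = FALSE)
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Control-relative heatmap matrix
#'
#' Entry (feature, group) is the group mean minus the control mean, in
#' control-SD units: the number of standard deviations above or below the
#' control mean. A significance mask from [compare_groups_to_control()] is
#' attached as the `significant` attribute.
#'
#' @param table cohort data.frame after outlier removal (raw values).
#' @param control_group control label.
#' @param features feature columns; defaults to those present.
#' @param comparisons optional precomputed result of
#'   [compare_groups_to_control()].
#' @return numeric matrix features x groups.
#' @export
build_heatmap_matrix <- function(table, control_group = "control",
                                 features = NULL, comparisons = NULL) {
  if (is.null(features)) features <- feature_cols_present(table)
  groups <- unique(table$group)
  m <- matrix(NA_real_, length(features), length(groups),
              dimnames = list(features, groups))
  for (f in features) {
    ctrl <- table[[f]][table$group == control_group]
    mu <- mean(ctrl, na.rm = TRUE)
    sigma <- stats::sd(ctrl, na.rm = TRUE)
    if (!is.finite(sigma) || sigma == 0) next
    for (g in groups)
      m[f, g] <- (mean(table[[f]][table$group == g], na.rm = TRUE) - mu) /
        sigma
  }
  if (is.null(comparisons))
    comparisons <- tryCatch(compare_groups_to_control(table, control_group,
                                                      features),
                            error = function(e) NULL)
  if (!is.null(comparisons)) {
    sig <- matrix(FALSE, length(features), length(groups),
                  dimnames = dimnames(m))
    for (i in seq_len(nrow(comparisons)))
      if (comparisons$feature[i] %in% features)
        sig[comparisons$feature[i], comparisons$group[i]] <-
          comparisons$significant[i]
    attr(m, "significant") <- sig
  }
  m
}

#' Correlate each feature with mitotic duration
#'
#' Pearson correlation of each feature (all cells pooled) with the duration
#' feature, Bonferroni-corrected for the number of features tested; the
#' reported coefficient is `r` when the corrected p-value is below `alpha`
#' and 0 otherwise.
#'
#' @param table cohort data.frame.
#' @param duration_col duration column (excluded from the tested set).
#' @param features feature columns; defaults to those present.
#' @param alpha significance threshold.
#' @return data.frame `feature`, `r`, `p`, `p_adj`, `r_reported`, `flag`.
#' @export
correlate_features_with_duration <- function(table,
                                             duration_col = "B_duration",
                                             features = NULL, alpha = 0.05) {
  if (is.null(features)) features <- feature_cols_present(table)
  features <- setdiff(features, duration_col)
  m <- length(features)
  rows <- lapply(features, function(f) {
    ok <- !is.na(table[[f]]) & !is.na(table[[duration_col]])
    x <- table[[f]][ok]
    y <- table[[duration_col]][ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(feature = f, r = NA_real_, p = NA_real_,
                        p_adj = NA_real_, r_reported = 0,
                        flag = "degenerate"))
    ct <- stats::cor.test(x, y, method = "pearson")
    p_adj <- min(1, ct$p.value * m)
    data.frame(feature = f, r = unname(ct$estimate), p = ct$p.value,
               p_adj = p_adj,
               r_reported = if (p_adj < alpha) unname(ct$estimate) else 0,
               flag = "")
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Principal component analysis of the feature matrix
#'
#' Runs PCA on the standardized feature matrix (complete cases only; dropped
#' rows are logged in the `dropped_cells` attribute). Each loading vector's
#' sign is fixed so that its largest-magnitude element is positive.
#'
#' @param table standardized cohort data.frame
#'   (see [standardize_features()]).
#' @param features feature columns; defaults to those present.
#' @return list with `scores` (cells x PCs, with `cell_id`/`group` columns
#'   when present), `loadings` (features x PCs), `explained_pct` (summing to
#'   100), and `n_cells`.
#' @export
run_pca <- function(table, features = NULL) {
  if (is.null(features)) features <- feature_cols_present(table)
  x <- as.matrix(table[, features, drop = FALSE])
  complete <- stats::complete.cases(x)
  if (sum(complete) <= length(features))
    stop("fewer complete cells than features")
  xc <- x[complete, , drop = FALSE]
  pc <- stats::prcomp(xc, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  sc <- as.data.frame(scores)
  for (col in c("group", "cell_id"))
    if (col %in% names(table)) sc[[col]] <- table[[col]][complete]
  out <- list(scores = sc, loadings = rot, explained_pct = expl,
              n_cells = sum(complete))
  attr(out, "dropped_cells") <- which(!complete)
  out
}

#' Classify cells as delayed relative to a control duration distribution
#'
#' A cell is delayed when its mitotic duration exceeds the 90th percentile of
#' the control durations; the percentile uses linear interpolation between
#' order statistics (`stats::quantile` type 7).
#'
#' @param durations numeric vector of durations to classify (minutes).
#' @param control_durations control duration sample (>= 10 values).
#' @param prob percentile defining delay (default 0.9).
#' @return logical vector; the threshold is attached as the `threshold`
#'   attribute.
#' @export
classify_delayed <- function(durations, control_durations, prob = 0.9) {
  if (!length(control_durations)) stop("empty control duration set")
  if (length(control_durations) < 10)
    warning("fewer than 10 control durations; percentile is unstable")
  thr <- stats::quantile(control_durations, prob, type = 7, names = FALSE)
  out <- durations > thr
  attr(out, "threshold") <- thr
  out
}
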