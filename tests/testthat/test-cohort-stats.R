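make_cohort <- function(n_per_group = 30, groups = c("control", "g1", "g2"),
                        seed = 1) {
  set.seed(seed)
  rows <- lapply(groups, function(g) {
    d <- data.frame(cell_id = paste0(g, "_", seq_len(n_per_group)),
                    group = g,
                    gonad_id = paste0(g, "_gon",
                                      1 + (seq_len(n_per_group) - 1) %% 5))
    for (f in spindle_feature_names) d[[f]] <- rnorm(n_per_group, 10, 2)
    d
  })
  do.call(rbind, rows)
}

test_that("a zero-IQR group removes its single extreme value", {
  tab <- data.frame(group = "g", cell_id = as.character(1:8),
                    A_pole_sep_pre_nebd = c(5, 5, 5, 5, 5, 5, 5, 100))
  res <- remove_outliers_per_group(tab, features = "A_pole_sep_pre_nebd")
  expect_true(is.na(res$table$A_pole_sep_pre_nebd[8]))
  expect_equal(sum(is.na(res$table$A_pole_sep_pre_nebd)), 1)
  expect_equal(res$log$action, "removed")
})

test_that("the duration feature is never filtered", {
  tab <- data.frame(group = "g", cell_id = as.character(1:8),
                    B_duration = c(rep(4, 7), 400))
  res <- remove_outliers_per_group(tab)
  expect_false(anyNA(res$table$B_duration))
})

test_that("outlier mask equals a brute-force per-group double loop", {
  for (seed in 1:5) {
    tab <- make_cohort(seed = seed)
    # inject some extremes
    set.seed(seed + 100)
    for (f in spindle_feature_names)
      tab[[f]][sample.int(nrow(tab), 3)] <- rnorm(3, 10, 25)
    feats <- setdiff(spindle_feature_names, "B_duration")
    res <- remove_outliers_per_group(tab)
    mask_pkg <- sapply(feats, function(f) is.na(res$table[[f]]))
    mask_oracle <- oracle_outlier_mask(tab, feats)
    expect_equal(unname(mask_pkg), unname(mask_oracle))
  }
})

test_that("small groups are skipped and logged", {
  tab <- data.frame(group = c(rep("big", 10), rep("tiny", 3)),
                    cell_id = as.character(1:13),
                    A_pole_sep_pre_nebd = c(rnorm(10), 1, 2, 300))
  res <- remove_outliers_per_group(tab, features = "A_pole_sep_pre_nebd")
  expect_false(is.na(res$table$A_pole_sep_pre_nebd[13]))
  expect_true("skipped_small_group" %in% res$log$action)
})

test_that("standardization matches its definition for both references", {
  tab <- make_cohort(seed = 3)
  st <- standardize_features(tab, reference = "pooled")
  for (f in spindle_feature_names) {
    expect_lt(abs(mean(st[[f]])), 1e-10)
    expect_equal(sd(st[[f]]), 1, tolerance = 1e-10)
  }
  stc <- standardize_features(tab, reference = "control",
                              control_group = "control")
  f <- "C_mean_length"
  ctrl <- tab[[f]][tab$group == "control"]
  expect_equal(stc[[f]], (tab[[f]] - mean(ctrl)) / sd(ctrl),
               tolerance = 1e-12)
  # worked example: control mu = 10, sigma = 2, value 14 -> 2.0
  toy <- data.frame(group = c(rep("control", 5), "g"),
                    B_duration = c(12, 8, 12, 8, 10, 14))
  expect_equal(standardize_features(toy, "control",
                                    "control")$B_duration[6], 2)
})

test_that("group comparisons: exchangeable groups are not significant,
           separated groups are", {
  set.seed(7)
  v <- rnorm(30)
  tab <- data.frame(group = rep(c("control", "g1"), each = 30),
                    B_duration = c(v, sample(v)))
  res <- compare_groups_to_control(tab, features = "B_duration")
  expect_false(res$significant)

  tab2 <- data.frame(group = rep(c("control", "g1"), each = 30),
                     B_duration = c(rnorm(30), rnorm(30) + 10))
  res2 <- compare_groups_to_control(tab2, features = "B_duration")
  expect_true(res2$significant)
  expect_gt(res2$effect, 5)
})

test_that("all-tied features are flagged degenerate", {
  tab <- data.frame(group = rep(c("control", "g1"), each = 5),
                    B_duration = rep(3, 10))
  res <- compare_groups_to_control(tab, features = "B_duration")
  expect_true(res$degenerate)
  expect_false(res$significant)
})

test_that("small-n omnibus p is close to a permutation null", {
  set.seed(11)
  x <- c(rnorm(5), rnorm(5, 1))
  g <- factor(rep(c("control", "g1"), each = 5))
  tab <- data.frame(group = g, B_duration = x)
  res <- compare_groups_to_control(tab, features = "B_duration")
  p_perm <- oracle_kw_perm_p(x, g, n_perm = 2e4, seed = 2)
  # the omnibus test is the asymptotic chi-square approximation, so
  # agreement with the exact permutation null is approximate at n = 5
  expect_lt(abs(res$p_omnibus - p_perm), 0.05)
})

test_that("heatmap entries are control-SD distances with significance mask", {
  tab <- make_cohort(seed = 9)
  f <- "C_mean_length"
  ctrl <- tab[[f]][tab$group == "control"]
  tab[[f]][tab$group == "g1"] <- ctrl + 2 * sd(ctrl)  # exactly +2 SD
  hm <- build_heatmap_matrix(tab, "control")
  expect_equal(hm[f, "g1"], 2, tolerance = 1e-10)
  expect_equal(hm[f, "control"], 0, tolerance = 1e-10)
  expect_true(is.matrix(attr(hm, "significant")))
  # invariance to affine rescaling of raw units
  tab2 <- tab
  tab2[[f]] <- tab2[[f]] * 3.7 + 11
  hm2 <- build_heatmap_matrix(tab2, "control")
  expect_equal(hm2[f, ], hm[f, ], tolerance = 1e-9)
})

test_that("duration correlations report r only when Bonferroni-significant", {
  set.seed(13)
  n <- 200
  tab <- data.frame(group = "g", B_duration = rnorm(n))
  tab$A_pole_sep_pre_nebd <- -tab$B_duration          # r = -1
  tab$C_mean_length <- rnorm(n)                        # null
  res <- correlate_features_with_duration(tab)
  expect_equal(res$r[res$feature == "A_pole_sep_pre_nebd"], -1,
               tolerance = 1e-12)
  expect_equal(res$r_reported[res$feature == "A_pole_sep_pre_nebd"], -1,
               tolerance = 1e-12)
  # constant feature -> reported 0 and flagged
  tab$D_length_variance <- 5
  res2 <- correlate_features_with_duration(tab)
  expect_equal(res2$r_reported[res2$feature == "D_length_variance"], 0)
  expect_equal(res2$flag[res2$feature == "D_length_variance"], "degenerate")
})

test_that("Bonferroni reporting controls the family-wise error rate", {
  set.seed(17)
  n_cohorts <- 1000
  n <- 300
  fp <- vapply(seq_len(n_cohorts), function(b) {
    tab <- data.frame(group = "g", B_duration = rnorm(n))
    for (f in setdiff(spindle_feature_names, "B_duration"))
      tab[[f]] <- rnorm(n)
    any(correlate_features_with_duration(tab)$r_reported != 0)
  }, logical(1))
  fwer <- mean(fp)
  mc_sd <- sqrt(0.05 * 0.95 / n_cohorts)
  expect_lte(fwer, 0.05 + 3 * mc_sd)
})

test_that("PCA matches an independent eigen-solver and conserves variance", {
  tab <- standardize_features(make_cohort(seed = 21), "pooled")
  pca <- run_pca(tab)
  expect_equal(sum(pca$explained_pct), 100, tolerance = 1e-6)
  x <- as.matrix(tab[, spindle_feature_names])
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(cov(xc), symmetric = TRUE)
  scores_oracle <- xc %*% ev$vectors
  for (k in 1:3) {
    got <- pca$scores[[paste0("PC", k)]]
    ref <- scores_oracle[, k]
    expect_true(max(abs(got - ref)) < 1e-8 || max(abs(got + ref)) < 1e-8)
  }
  expect_equal(pca$explained_pct,
               100 * ev$values / sum(ev$values), tolerance = 1e-8)
  # sign convention: largest-magnitude loading element positive
  for (k in seq_len(ncol(pca$loadings))) {
    v <- pca$loadings[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("one-directional data loads 100% on PC1", {
  set.seed(23)
  t <- rnorm(50)
  tab <- data.frame(group = "g")[rep(1, 50), , drop = FALSE]
  for (i in seq_along(spindle_feature_names))
    tab[[spindle_feature_names[i]]] <- t * i
  pca <- run_pca(tab)
  expect_equal(pca$explained_pct[1], 100, tolerance = 1e-8)
})

test_that("delayed classification follows the stated P90 convention", {
  # control 1..10: P90 = 9.1 by linear interpolation
  lab <- classify_delayed(c(9.05, 9.1, 9.2, 10), 1:10)
  expect_equal(attr(lab, "threshold"), 9.1)
  expect_equal(as.logical(lab), c(FALSE, FALSE, TRUE, TRUE))
  # monotone: below the control median is never delayed
  expect_false(any(classify_delayed(c(1, 2, 4), 1:10)))
  # a large continuous control sample classifies ~10% of itself as delayed
  set.seed(29)
  ctrl <- rlnorm(1e4, log(4.5), 0.3)
  expect_equal(mean(classify_delayed(ctrl, ctrl)), 0.1, tolerance = 0.01)
})

test_that("outlier removal is idempotent as a single pass", {
  tab <- make_cohort(seed = 31)
  set.seed(31)
  tab$C_mean_length[sample.int(nrow(tab), 4)] <- c(50, -40, 60, 55)
  r1 <- remove_outliers_per_group(tab)
  r2 <- remove_outliers_per_group(r1$table)
  # the documented contract is one pass; re-running on the filtered table
  # must not resurrect removed values
  expect_true(all(is.na(r2$table$C_mean_length[
    is.na(r1$table$C_mean_length)])))
})

test_that("feature tables in the screen layout load from CSV", {
  tab <- make_cohort(seed = 33)
  names(tab)[names(tab) == "A_pole_sep_pre_nebd"] <- "A"
  names(tab)[names(tab) == "B_duration"] <- "B_duration_min"
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  got <- read_feature_table(path)
  expect_true(all(c("A_pole_sep_pre_nebd", "B_duration") %in% names(got)))
  expect_equal(got$A_pole_sep_pre_nebd, tab$A)
})
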