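# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

oracle_dist3 <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3)
  sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
}

# undirected angle between two vectors, degrees
oracle_angle <- function(u, v) {
  cu <- u / sqrt(sum(u^2))
  cv <- v / sqrt(sum(v^2))
  acos(min(1, abs(sum(cu * cv)))) * 180 / pi
}

# per-(feature, group) double loop applying the 1.5 x IQR rule
oracle_outlier_mask <- function(table, features, min_group = 4) {
  mask <- matrix(FALSE, nrow(table), length(features),
                 dimnames = list(NULL, features))
  for (f in features) {
    for (g in unique(table$group)) {
      idx <- which(table$group == g & !is.na(table[[f]]))
      if (length(idx) < min_group) next
      v <- table[[f]][idx]
      q1 <- as.numeric(quantile(v, 0.25, type = 7))
      q3 <- as.numeric(quantile(v, 0.75, type = 7))
      iqr <- q3 - q1
      for (i in idx)
        if (table[[f]][i] < q1 - 1.5 * iqr || table[[f]][i] > q3 + 1.5 * iqr)
          mask[i, f] <- TRUE
    }
  }
  mask
}

# greedy matching of detections to ground-truth centres within `radius`;
# returns recall and precision
oracle_match_pr <- function(gt, det, radius) {
  if (!nrow(det) || !nrow(gt))
    return(c(recall = 0, precision = 0))
  dm <- as.matrix(stats::dist(rbind(as.matrix(gt[, c("x", "y", "z")]),
                                    as.matrix(det[, c("x", "y", "z")]))))
  dm <- dm[seq_len(nrow(gt)), nrow(gt) + seq_len(nrow(det)), drop = FALSE]
  matched <- 0
  used <- rep(FALSE, nrow(det))
  for (i in order(apply(dm, 1, min))) {
    j <- which.min(ifelse(used, Inf, dm[i, ]))
    if (dm[i, j] <= radius) {
      matched <- matched + 1
      used[j] <- TRUE
    }
  }
  c(recall = matched / nrow(gt), precision = sum(used) / nrow(det))
}

# tie-corrected Kruskal-Wallis statistic computed from scratch
oracle_kw_stat <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tabulate(as.integer(g))
  h <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# permutation p-value of the Kruskal-Wallis statistic
oracle_kw_perm_p <- function(x, g, n_perm = 1e5, seed = 1) {
  set.seed(seed)
  h0 <- oracle_kw_stat(x, g)
  hits <- 0L
  for (b in seq_len(n_perm))
    if (oracle_kw_stat(x, sample(g)) >= h0 - 1e-12) hits <- hits + 1L
  hits / n_perm
}

# simulate one spindle track at the stated study conditions and score it
score_one_simulated <- function(duration, seed, plateau_noise_sd = 0.3) {
  p <- spindle_sim_params(t_nebd = 5, t_s = 7, t_ao = 7 + duration,
                          plateau_noise_sd = plateau_noise_sd,
                          n_frames = ceiling((7 + duration + 9) / 0.5),
                          seed = seed)
  sim <- simulate_spindle_track(p)
  lmk <- tryCatch(score_landmarks_from_length(spindle_length_series(sim$track)),
                  error = function(e) NULL)
  list(params = p, sim = sim, landmarks = lmk)
}
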