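#' Names of the nine spindle features
#'
#' Letter prefixes follow the conventional abbreviations of the per-cell
#' feature table: A pole separation prior to NEBD (um), B duration of mitosis
#' (min), C mean spindle length (um), D spindle length variance
#' (dimensionless), E spindle length fluctuation (%/min), F spindle rotation
#' (deg/min), G spindle elongation rate (um/min), H spindle rotation in
#' anaphase (deg/min), I pole separation in telophase (% of C).
#' @export
spindle_feature_names <- c("A_pole_sep_pre_nebd", "B_duration",
                           "C_mean_length", "D_length_variance",
                           "E_length_fluctuation", "F_rotation",
                           "G_elongation_rate", "H_rotation_anaphase",
                           "I_pole_sep_telophase")

# Mean angular velocity (deg/min) between consecutive-frame spindle axes,
# treating the axis as undirected (angles folded to <= 90 degrees).
# Consecutive means adjacent frames on the grid; pairs spanning a gap are
# skipped.
axis_rotation_rate <- function(axes, idx, frame_interval) {
  if (length(idx) < 2) return(NA_real_)
  u <- as.matrix(axes[idx, c("ux", "uy", "uz")])
  tt <- axes$t[idx]
  ang <- c()
  for (k in seq_len(length(idx) - 1)) {
    if (abs(tt[k + 1] - tt[k] - frame_interval) > frame_interval / 4) next
    d <- abs(sum(u[k, ] * u[k + 1, ]))
    ang <- c(ang, acos(pmin(pmax(d, -1), 1)) * 180 / pi)
  }
  if (!length(ang)) return(NA_real_)
  mean(ang) / frame_interval
}

#' Extract the nine spindle features for one cell
#'
#' Feature definitions (windows are closed at landmark frames; "within 3 min
#' prior" is the half-open window `(t_nebd - 3, t_nebd]`):
#' * A: mean of the 3 largest lengths within 3 min prior to NEBD.
#' * B: `t_ao - t_s` (minutes).
#' * C: mean length on `[t_s, t_ao]`.
#' * D: SD of a seeded random sample of 7 length/C values drawn without
#'   replacement from `[t_s, t_ao]` (all values, flagged, when fewer than 8
#'   in-mitosis frames are available).
#' * E: mean over consecutive in-mitosis frame pairs of
#'   `|dL| / C * 100 / frame_interval` (%/min).
#' * F: mean undirected angle between consecutive in-mitosis spindle axes
#'   divided by the frame interval (deg/min).
#' * G: least-squares slope of length vs time on `[t_ao, t_ao + 2.5 min]`.
#' * H: as F, on `[t_ao, t_ao + 2.5 min]`.
#' * I: second-largest length at `t >= t_ao + 7 min`, as a percent of C.
#'
#' Missing windows leave that feature `NA` with a flag; other features are
#' still computed.
#'
#' @param series data.frame `t`, `length` from [spindle_length_series()].
#' @param axes data.frame from [spindle_axes()], or `NULL` (F and H then NA).
#' @param landmarks a `mitotic_landmarks` object.
#' @param frame_interval minutes per frame.
#' @param seed integer seed for the D subsample (recorded in the output).
#' @param d_sample_size subsample size for D (default 7).
#' @param anaphase_window minutes after anaphase onset for G and H.
#' @param pre_nebd_window minutes before NEBD for A.
#' @param telophase_lead minutes after anaphase onset before I is measured.
#' @return one-row data.frame with the nine features, `seed` and `flags`
#'   (semicolon-separated).
#' @export
extract_features <- function(series, axes, landmarks,
                             frame_interval = NULL, seed = 1L,
                             d_sample_size = 7, anaphase_window = 2.5,
                             pre_nebd_window = 3, telophase_lead = 7) {
  stopifnot(inherits(landmarks, "mitotic_landmarks"))
  if (is.null(frame_interval))
    frame_interval <- attr(series, "frame_interval")
  stopifnot(!is.null(frame_interval))
  t <- series$t
  len <- series$length
  lm <- landmarks
  flags <- character()

  # A: mean of top 3 lengths in (t_nebd - 3, t_nebd]
  pre <- which(t > lm$t_nebd - pre_nebd_window & t <= lm$t_nebd)
  A <- if (length(pre) >= 3)
    mean(sort(len[pre], decreasing = TRUE)[1:3])
  else {
    flags <- c(flags, "A_absent")
    NA_real_
  }

  B <- lm$t_ao - lm$t_s

  mit <- which(t >= lm$t_s & t <= lm$t_ao)
  C <- if (length(mit)) mean(len[mit]) else NA_real_
  if (!length(mit)) flags <- c(flags, "C_absent")

  # D: SD of a seeded sample of 7 normalized lengths, without replacement
  D <- NA_real_
  if (length(mit)) {
    norm <- len[mit] / C
    if (length(norm) >= d_sample_size + 1) {
      set.seed(seed)
      D <- stats::sd(norm[sample.int(length(norm), d_sample_size)])
    } else {
      flags <- c(flags, "D_all_frames")
      D <- stats::sd(norm)
    }
  }

  # E: mean absolute frame-to-frame change, % of C per minute
  E <- NA_real_
  if (length(mit) >= 2) {
    dl <- c()
    for (k in seq_len(length(mit) - 1)) {
      i <- mit[k]; j <- mit[k + 1]
      if (abs(t[j] - t[i] - frame_interval) > frame_interval / 4) next
      dl <- c(dl, abs(len[j] - len[i]))
    }
    if (length(dl)) E <- mean(dl) / C * 100 / frame_interval
  }

  F_ <- if (!is.null(axes) && length(mit) >= 2) {
    aidx <- which(axes$t >= lm$t_s & axes$t <= lm$t_ao)
    axis_rotation_rate(axes, aidx, frame_interval)
  } else NA_real_

  # G: least-squares slope on [t_ao, t_ao + window]
  ana <- which(t >= lm$t_ao & t <= lm$t_ao + anaphase_window)
  G <- if (length(ana) >= 2)
    unname(stats::coef(stats::lm(len[ana] ~ t[ana]))[2])
  else {
    flags <- c(flags, "G_absent")
    NA_real_
  }

  H <- if (!is.null(axes)) {
    aidx <- which(axes$t >= lm$t_ao & axes$t <= lm$t_ao + anaphase_window)
    axis_rotation_rate(axes, aidx, frame_interval)
  } else NA_real_

  # I: second-largest length >= 7 min after anaphase onset, % of C
  telo <- which(t >= lm$t_ao + telophase_lead)
  I_ <- if (length(telo) >= 2)
    sort(len[telo], decreasing = TRUE)[2] * 100 / C
  else {
    flags <- c(flags, "I_absent")
    NA_real_
  }

  out <- data.frame(A_pole_sep_pre_nebd = A, B_duration = B,
                    C_mean_length = C, D_length_variance = D,
                    E_length_fluctuation = E, F_rotation = F_,
                    G_elongation_rate = G, H_rotation_anaphase = H,
                    I_pole_sep_telophase = I_, seed = as.integer(seed),
                    flags = paste(unique(c(flags, lm$flags)),
                                  collapse = ";"))
  out
}

#' Score landmarks and extract features for a list of tracks
#'
#' Convenience wrapper running [spindle_length_series()],
#' [score_landmarks_from_length()] and [extract_features()] per cell. Cells
#' whose landmark scoring fails are reported in the `errors` attribute and
#' omitted from the table.
#'
#' @param tracks list of `spindle_track`s.
#' @param cfg a [timing_config()].
#' @param seed master seed; per-cell D-sampling seeds are derived from it.
#' @return data.frame with `cell_id`, `group`, `gonad_id`, the landmark
#'   columns, the nine features, `seed` and `flags`.
#' @export
cohort_feature_table <- function(tracks, cfg = timing_config(), seed = 1L) {
  set.seed(seed)
  cell_seeds <- sample.int(2^31 - 2, length(tracks))
  rows <- list()
  errors <- character()
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    res <- tryCatch({
      s <- spindle_length_series(tr)
      lmk <- score_landmarks_from_length(s, cfg)
      fx <- extract_features(s, spindle_axes(tr), lmk,
                             frame_interval = tr$frame_interval,
                             seed = cell_seeds[i])
      cbind(data.frame(cell_id = tr$cell_id, group = tr$group,
                       gonad_id = tr$gonad_id, t_nebd = lmk$t_nebd,
                       t_s = lmk$t_s, t_ao = lmk$t_ao),
            fx)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errors[tr$cell_id] <- res else
      rows[[tr$cell_id]] <- res
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (length(errors)) attr(out, "errors") <- errors
  out
}
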