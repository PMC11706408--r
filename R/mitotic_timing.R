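#' Configuration for landmark scoring from spindle-length series
#'
#' All thresholds are relative to the plateau level (a robust re-estimate of
#' the minimum smoothed spindle length), so scoring is invariant to the
#' length unit.
#'
#' @param delta plateau band half-width: frames with smoothed length at most
#'   `(1 + delta)` times the plateau level belong to the metaphase plateau.
#' @param rise_frac anaphase is called when the smoothed length rises by at
#'   least `rise_frac` times the plateau level within `rise_window` minutes.
#' @param delta_nebd NEBD is the last pre-plateau frame whose smoothed length
#'   exceeds `(1 + delta_nebd)` times the plateau level on a decreasing run.
#' @param rise_window minutes after a candidate frame inspected for the
#'   anaphase rise.
#' @param min_frames minimum series length.
#' @param max_gap_frames longest tolerated run of missing frames inside the
#'   plateau before the cell is flagged.
#' @param smooth_window centred moving-median window (odd, frames).
#' @param noise_mult the band half-width is at least `noise_mult` SDs of the
#'   smoothed plateau residuals, so noisy plateaus are not truncated.
#' @export
timing_config <- function(delta = 0.10, rise_frac = 0.25, delta_nebd = 0.30,
                          rise_window = 2.5, min_frames = 8,
                          max_gap_frames = 2, smooth_window = 3,
                          noise_mult = 2) {
  stopifnot(delta > 0, rise_frac > 0, delta_nebd > delta, rise_window > 0,
            smooth_window %% 2 == 1)
  structure(as.list(environment()), class = "timing_config")
}

new_mitotic_landmarks <- function(t_nebd, t_s, t_ao, flags = character()) {
  structure(list(t_nebd = t_nebd, t_s = t_s, t_ao = t_ao,
                 duration = t_ao - t_s, flags = flags),
            class = "mitotic_landmarks")
}

#' @export
print.mitotic_landmarks <- function(x, ...) {
  cat(sprintf("<mitotic_landmarks> NEBD %.3g  start %.3g  AO %.3g  duration %.3g min%s\n",
              x$t_nebd, x$t_s, x$t_ao, x$duration,
              if (length(x$flags)) paste0("  [", paste(x$flags,
                                                       collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Score mitotic landmarks from a spindle-length series
#'
#' Deterministic replacement for manual scoring of spindle length-versus-time
#' plots. The series is smoothed with a centred moving median; the metaphase
#' plateau is the band of frames near the minimum smoothed length; anaphase
#' onset is the last plateau frame followed by a sufficient net rise; the
#' "start" of mitosis is the first plateau frame after the NEBD collapse; and
#' NEBD is the last decreasing pre-plateau frame above the NEBD threshold.
#' Ambiguities set `quality_flags` rather than silently guessing.
#'
#' @param series data.frame with `t` (minutes) and `length` (um), e.g. from
#'   [spindle_length_series()].
#' @param cfg a [timing_config()].
#' @param frame_interval minutes per frame; defaults to the series attribute
#'   or the smallest positive time step.
#' @return a `mitotic_landmarks` object (`t_nebd`, `t_s`, `t_ao`, `duration`,
#'   `flags`).
#' @export
score_landmarks_from_length <- function(series, cfg = timing_config(),
                                        frame_interval = NULL) {
  stopifnot(inherits(cfg, "timing_config"),
            all(c("t", "length") %in% names(series)))
  if (is.null(frame_interval))
    frame_interval <- attr(series, "frame_interval")
  if (is.null(frame_interval)) {
    dt <- diff(series$t)
    frame_interval <- min(dt[dt > 0])
  }
  n <- nrow(series)
  if (n < cfg$min_frames)
    stop("series has fewer than min_frames (", cfg$min_frames, ") frames")
  ord <- order(series$t)
  t <- series$t[ord]
  len <- series$length[ord]
  sm <- if (n >= cfg$smooth_window)
    as.numeric(stats::runmed(len, cfg$smooth_window, endrule = "median"))
  else len

  # plateau level: the raw minimum is an extreme value (a single deep noise
  # excursion can trap the band on itself), so start from the median of the
  # three smallest smoothed lengths and re-centre on the median of the
  # in-band frames until stable
  B <- stats::median(sort(sm)[seq_len(min(3, n))])
  for (k in 1:20) {
    Bnew <- stats::median(sm[sm <= B * (1 + cfg$delta)])
    if (abs(Bnew - B) < 1e-9) break
    B <- Bnew
  }
  # the band half-width adapts to the plateau noise: at least delta, at
  # least noise_mult SDs of the smoothed plateau level (noise estimated as
  # the robust MAD of raw-minus-smoothed residuals on in-band frames, scaled
  # to the moving-median output), so cells whose fluctuations exceed the
  # nominal band still keep their late plateau frames in the band
  band <- sm <= B * (1 + cfg$delta)
  resid <- (len - sm)[band]
  sigma_raw <- if (length(resid) >= 4)
    1.4826 * stats::median(abs(resid - stats::median(resid))) else 0
  sigma_sm <- 0.64 * sigma_raw  # median-of-3 shrinks the SD by ~0.64
  delta_eff <- max(cfg$delta, cfg$noise_mult * sigma_sm / B)
  band <- sm <= B * (1 + delta_eff)
  i_first <- which(band)[1]
  pre <- seq_len(max(i_first - 1, 0))
  if (!length(pre) || !any(sm[pre] > B * (1 + delta_eff)))
    stop("no metaphase plateau detected: no collapse precedes the length minimum")

  # anaphase onset: last plateau frame followed by a net rise
  rise_ok <- vapply(which(band), function(i) {
    j <- which(t > t[i] & t <= t[i] + cfg$rise_window)
    length(j) > 0 && max(sm[j]) - sm[i] >= cfg$rise_frac * B
  }, logical(1))
  if (!any(rise_ok))
    stop("no anaphase elongation detected")
  i_ao <- max(which(band)[rise_ok])

  flags <- character()
  # the "start" is the first band frame at a stable minimum: frames on the
  # tail of the NEBD collapse (still dropping by more than half the band
  # width to the next frame) are skipped
  i_s <- i_first
  while (i_s < i_ao && sm[i_s] - sm[i_s + 1] > delta_eff * B / 2)
    i_s <- i_s + 1
  if (i_s > i_ao) {
    flags <- c(flags, "start_after_anaphase")
    i_s <- i_ao
  }

  # NEBD: last decreasing frame above threshold before the start
  thr <- B * (1 + cfg$delta_nebd)
  cand <- which(seq_len(n) < i_s & sm > thr &
                  c(diff(sm) <= 0, FALSE))
  t_nebd <- if (length(cand)) t[max(cand)] else {
    flags <- c(flags, "nebd_not_found")
    t[i_s]
  }

  # gap policy inside the plateau
  fr <- round((t - t[1]) / frame_interval)
  gaps <- diff(fr[i_s:i_ao]) - 1
  if (length(gaps) && any(gaps > cfg$max_gap_frames))
    flags <- c(flags, "plateau_gap")

  new_mitotic_landmarks(t_nebd = t_nebd, t_s = t[i_s], t_ao = t[i_ao],
                        flags = flags)
}

#' Chromatin intensity-variance trace from an image stack
#'
#' For each frame, a mean-intensity projection of `n_slices` z-slices centred
#' on the tracked nucleus is computed and the pixel-intensity variance within
#' a circular nuclear ROI is recorded, then min-max normalized over the
#' cell's time span.
#'
#' @param stack array with dim `c(y, x, z, t)`.
#' @param rois data.frame with one row per frame: columns `x`, `y`, `z`
#'   (nucleus centre, um).
#' @param pixel_size,z_step voxel size, um.
#' @param roi_diameter nuclear ROI diameter, um (default 4.5).
#' @param n_slices z-slices averaged per frame (default 5).
#' @param frame_interval minutes per frame.
#' @return data.frame with `t`, `variance`, `normalized`.
#' @export
chromatin_variance_trace <- function(stack, rois, pixel_size, z_step,
                                     roi_diameter = 4.5, n_slices = 5,
                                     frame_interval = 0.5) {
  d <- dim(stack)
  stopifnot(length(d) == 4, nrow(rois) == d[4], d[3] >= n_slices)
  half <- (n_slices - 1) %/% 2
  v <- numeric(d[4])
  for (f in seq_len(d[4])) {
    zc <- round(rois$z[f] / z_step + 0.5)
    if (zc - half < 1 || zc + half > d[3])
      stop("ROI z-window outside the stack at frame ", f)
    proj <- apply(stack[, , (zc - half):(zc + half), f, drop = FALSE],
                  c(1, 2), mean)
    mask <- disk_mask(d[1:2], c(rois$x[f], rois$y[f]), roi_diameter / 2,
                      pixel_size)
    if (!any(mask)) stop("ROI outside the image at frame ", f)
    v[f] <- stats::var(proj[mask])
  }
  data.frame(t = (seq_len(d[4]) - 1) * frame_interval, variance = v,
             normalized = normalize_variance(v))
}

#' Min-max normalize a variance trace
#'
#' @param v numeric vector; errors on a flat trace.
#' @return `(v - min) / (max - min)`.
#' @export
normalize_variance <- function(v) {
  r <- range(v)
  if (diff(r) <= 0) stop("flat trace, cannot normalize")
  (v - r[1]) / diff(r)
}

#' Score NEBD and anaphase onset from a chromatin-variance trace
#'
#' NEBD is the last frame strictly before the global maximum whose
#' normalized variance is below 0.5; anaphase onset is the last frame whose
#' normalized variance exceeds 0.7. Restricting the NEBD search to frames
#' before the maximum disambiguates the 50% rule, which would otherwise also
#' match post-anaphase frames. Thresholds use strict inequalities.
#'
#' @param trace data.frame with `t` and `variance` (and optionally
#'   `normalized`; recomputed if absent).
#' @param nebd_frac,ao_frac thresholds on the normalized variance.
#' @return a `mitotic_landmarks` object with `t_s = t_nebd` (this method
#'   measures NEBD-to-anaphase time, so `duration = t_ao - t_nebd`).
#' @export
score_landmarks_from_variance <- function(trace, nebd_frac = 0.5,
                                          ao_frac = 0.7) {
  stopifnot(all(c("t", "variance") %in% names(trace)))
  v <- if ("normalized" %in% names(trace)) trace$normalized
       else normalize_variance(trace$variance)
  imax <- which.max(v)
  flags <- character()
  below <- which(seq_along(v) < imax & v < nebd_frac)
  if (!length(below)) {
    flags <- c(flags, "NEBD outside window")
    i_nebd <- 1L
  } else i_nebd <- max(below)
  i_ao <- max(which(v > ao_frac))  # guaranteed non-empty: max normalizes to 1
  if (i_ao < i_nebd) stop("anaphase onset scored before NEBD")
  lm <- new_mitotic_landmarks(t_nebd = trace$t[i_nebd],
                              t_s = trace$t[i_nebd],
                              t_ao = trace$t[i_ao], flags = flags)
  lm
}
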