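#' Simulation parameters for a single spindle-pole track
#'
#' Bundles the kinematic ground truth for one mitotic cell. The simulated
#' pole-to-pole distance follows the stereotypical GSPC profile: constant
#' pole separation before nuclear envelope breakdown (NEBD), a linear
#' collapse from NEBD to the "start" of mitosis, a noisy metaphase plateau,
#' linear anaphase elongation from anaphase onset, and a single telophase
#' peak followed by relaxation. Landmark times are snapped to the frame grid.
#'
#' @param frame_interval acquisition interval, minutes per frame.
#' @param t_nebd,t_s,t_ao landmark times in minutes (NEBD, mitosis start,
#'   anaphase onset); must satisfy `t_nebd < t_s <= t_ao`.
#' @param pre_nebd_separation pole separation before NEBD, um.
#' @param metaphase_length mean plateau spindle length, um.
#' @param plateau_noise_sd Gaussian noise added to plateau lengths, um.
#' @param elongation_rate anaphase elongation rate, um/min.
#' @param rotation_rate_sd SD of the per-minute spindle rotation, degrees/min.
#' @param telophase_peak maximum spindle length reached in telophase, um.
#' @param centroid_drift_sd per-frame random-walk drift of the spindle
#'   centroid, um/frame (per coordinate).
#' @param n_frames number of frames to simulate.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return an object of class `spindle_sim_params`.
#' @export
spindle_sim_params <- function(frame_interval = 0.5,
                               t_nebd = 5, t_s = 7, t_ao = 11.5,
                               pre_nebd_separation = 5.5,
                               metaphase_length = 4,
                               plateau_noise_sd = 0.3,
                               elongation_rate = 1.0,
                               rotation_rate_sd = 5,
                               telophase_peak = 8,
                               centroid_drift_sd = 0.05,
                               n_frames = 45,
                               seed = 1L) {
  stopifnot(frame_interval > 0, n_frames >= 2)
  snap <- function(t) round(t / frame_interval) * frame_interval
  t_nebd <- snap(t_nebd); t_s <- snap(t_s); t_ao <- snap(t_ao)
  if (!(t_nebd < t_s && t_s <= t_ao))
    stop("landmark times must satisfy t_nebd < t_s <= t_ao (after snapping ",
         "to the frame grid)")
  if (pre_nebd_separation <= 0 || metaphase_length <= 0 ||
      telophase_peak <= 0)
    stop("all lengths must be > 0")
  if (plateau_noise_sd < 0 || rotation_rate_sd < 0 || centroid_drift_sd < 0)
    stop("noise SDs must be >= 0")
  structure(list(frame_interval = frame_interval, t_nebd = t_nebd,
                 t_s = t_s, t_ao = t_ao,
                 pre_nebd_separation = pre_nebd_separation,
                 metaphase_length = metaphase_length,
                 plateau_noise_sd = plateau_noise_sd,
                 elongation_rate = elongation_rate,
                 rotation_rate_sd = rotation_rate_sd,
                 telophase_peak = telophase_peak,
                 centroid_drift_sd = centroid_drift_sd,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "spindle_sim_params")
}

# Closed-form (noise-free) spindle length at time t for the piecewise
# kinematic model. After the telophase peak the spindle relaxes at half the
# elongation rate, floored at 70% of the peak, so that the "second largest
# post-telophase length" is well defined.
spindle_length_closed_form <- function(t, p) {
  len <- numeric(length(t))
  pre <- t < p$t_nebd
  col <- t >= p$t_nebd & t < p$t_s
  pla <- t >= p$t_s & t <= p$t_ao
  ana <- t > p$t_ao
  len[pre] <- p$pre_nebd_separation
  len[col] <- p$pre_nebd_separation +
    (p$metaphase_length - p$pre_nebd_separation) *
    (t[col] - p$t_nebd) / (p$t_s - p$t_nebd)
  len[pla] <- p$metaphase_length
  if (any(ana)) {
    el <- p$metaphase_length + p$elongation_rate * (t[ana] - p$t_ao)
    if (p$elongation_rate > 0) {
      t_peak <- p$t_ao + (p$telophase_peak - p$metaphase_length) /
        p$elongation_rate
      past <- t[ana] > t_peak
      el[past] <- pmax(p$telophase_peak -
                         0.5 * p$elongation_rate * (t[ana][past] - t_peak),
                       0.7 * p$telophase_peak)
      el <- pmin(el, p$telophase_peak)
    }
    len[ana] <- el
  }
  len
}

# Rotate unit vector `v` by `theta` radians about a random axis
# perpendicular to it.
rotate_axis <- function(v, theta) {
  r <- stats::rnorm(3)
  u <- r - sum(r * v) * v
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) return(v)
  u <- u / nu
  w <- cos(theta) * v + sin(theta) * u
  w / sqrt(sum(w^2))
}

#' Simulate one spindle-pole track with known ground truth
#'
#' Generates paired pole trajectories whose pairwise distance follows the
#' closed-form kinematic profile of [spindle_sim_params()], with Gaussian
#' noise on the metaphase plateau, per-frame angular diffusion of the spindle
#' axis, and a shared random-walk centroid drift.
#'
#' @param params a [spindle_sim_params()] object.
#' @param cell_id,group,gonad_id metadata attached to the track.
#' @return a list with elements `track` (a `spindle_track`, see
#'   [pair_poles()]) and `truth` (landmark times, generating parameters, the
#'   realized noise-free lengths, realized lengths, per-frame spindle axes
#'   and per-frame rotation angles in degrees).
#' @export
simulate_spindle_track <- function(params, cell_id = "cell1",
                                   group = "control", gonad_id = "g1") {
  stopifnot(inherits(params, "spindle_sim_params"))
  p <- params
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(p$seed)
  t <- (seq_len(p$n_frames) - 1) * p$frame_interval
  len0 <- spindle_length_closed_form(t, p)
  len <- len0
  pla <- t >= p$t_s & t <= p$t_ao
  if (p$plateau_noise_sd > 0)
    len[pla] <- len[pla] + stats::rnorm(sum(pla), 0, p$plateau_noise_sd)
  len <- pmax(len, 0)

  # spindle axis: angular random walk on the unit sphere
  axes <- matrix(NA_real_, p$n_frames, 3)
  v <- stats::rnorm(3)
  v <- v / sqrt(sum(v^2))
  axes[1, ] <- v
  ang <- numeric(p$n_frames - 1)
  sd_rad <- p$rotation_rate_sd * p$frame_interval * pi / 180
  for (i in seq_len(p$n_frames - 1)) {
    theta <- if (sd_rad > 0) stats::rnorm(1, 0, sd_rad) else 0
    ang[i] <- abs(theta) * 180 / pi
    axes[i + 1, ] <- rotate_axis(axes[i, ], theta)
  }

  drift <- matrix(0, p$n_frames, 3)
  if (p$centroid_drift_sd > 0)
    drift <- apply(matrix(stats::rnorm(3 * p$n_frames, 0,
                                       p$centroid_drift_sd),
                          p$n_frames, 3), 2, cumsum)

  half <- axes * (len / 2)
  pole1 <- drift + half
  pole2 <- drift - half
  mk <- function(m) data.frame(frame = seq_len(p$n_frames) - 1L, t = t,
                               x = m[, 1], y = m[, 2], z = m[, 3])
  track <- new_spindle_track(cell_id = cell_id, group = group,
                             gonad_id = gonad_id, pole1 = mk(pole1),
                             pole2 = mk(pole2),
                             frame_interval = p$frame_interval)
  truth <- list(t_nebd = p$t_nebd, t_s = p$t_s, t_ao = p$t_ao,
                duration = p$t_ao - p$t_s, params = p,
                length_true = len0, length = len, axes = axes,
                rotation_deg = ang)
  list(track = track, truth = truth)
}

#' Simulate a chromatin intensity-variance trace
#'
#' Emulates the time course of the pixel-intensity variance of a
#' histone-marker signal within a nuclear ROI: flat at `baseline` before
#' NEBD, a sigmoid (smoothstep) rise to `peak` as chromosomes congress, a
#' plateau at `peak`, and a sharp exponential fall after anaphase onset as
#' chromatin segregates out of the ROI. With `noise_sd = 0` the trace
#' attains exactly `peak` and `baseline`, and
#' [score_landmarks_from_variance()] recovers the generating landmarks.
#'
#' @param t_nebd,t_ao landmark times in minutes, `t_nebd < t_ao`.
#' @param frame_interval minutes per frame.
#' @param n_frames number of frames.
#' @param baseline,peak variance levels, arbitrary units; `peak > baseline`.
#' @param noise_sd additive Gaussian noise SD.
#' @param rise_time minutes taken by the congression rise (default 2 frames).
#' @param seed integer seed.
#' @return list with `trace` (data.frame `t`, `variance`) and `truth`
#'   (`t_nebd`, `t_ao`).
#' @export
simulate_chromatin_trace <- function(t_nebd, t_ao, frame_interval = 0.5,
                                     n_frames = 40, baseline = 1, peak = 10,
                                     noise_sd = 0, rise_time = NULL,
                                     seed = 1L) {
  stopifnot(frame_interval > 0, n_frames >= 2)
  if (peak <= baseline) stop("peak must be greater than baseline")
  snap <- function(t) round(t / frame_interval) * frame_interval
  t_nebd <- snap(t_nebd); t_ao <- snap(t_ao)
  if (!(t_nebd < t_ao)) stop("t_nebd must be before t_ao")
  if (is.null(rise_time)) rise_time <- 2 * frame_interval
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(seed)
  t <- (seq_len(n_frames) - 1) * frame_interval
  s <- pmin(pmax((t - t_nebd) / rise_time, 0), 1)
  v <- baseline + (peak - baseline) * (3 * s^2 - 2 * s^3)
  post <- t > t_ao
  v[post] <- baseline + (peak - baseline) *
    exp(-(t[post] - t_ao) / (frame_interval / 4))
  if (noise_sd > 0) v <- v + stats::rnorm(n_frames, 0, noise_sd)
  list(trace = data.frame(t = t, variance = v),
       truth = list(t_nebd = t_nebd, t_ao = t_ao))
}

#' Rendering parameters for a synthetic nucleus image
#'
#' Ground-truth geometry for validating the nuclear-to-cytoplasmic ratio
#' measurement: a central nucleus disk at `true_nc_ratio *
#' cytoplasm_intensity` above background, uniform cytoplasm elsewhere,
#' optional neighbour nuclei, additive background and Gaussian noise.
#'
#' @param nucleus_diameter nucleus diameter, um.
#' @param true_nc_ratio ground-truth nuclear:cytoplasmic ratio (> 0).
#' @param cytoplasm_intensity,background_intensity arbitrary units.
#' @param neighbor_centers list of `c(x, y)` positions (um, relative to the
#'   image origin) of neighbouring nuclei.
#' @param pixel_size um per pixel (> 0).
#' @param noise_sd additive Gaussian noise SD.
#' @param image_size image side length, um.
#' @param seed integer seed.
#' @export
nucleus_render_params <- function(nucleus_diameter = 4.5,
                                  true_nc_ratio = 2,
                                  cytoplasm_intensity = 100,
                                  background_intensity = 0,
                                  neighbor_centers = list(),
                                  pixel_size = 0.15,
                                  noise_sd = 0,
                                  image_size = 18,
                                  seed = 1L) {
  stopifnot(true_nc_ratio > 0, pixel_size > 0, nucleus_diameter > 0,
            noise_sd >= 0)
  structure(list(nucleus_diameter = nucleus_diameter,
                 true_nc_ratio = true_nc_ratio,
                 cytoplasm_intensity = cytoplasm_intensity,
                 background_intensity = background_intensity,
                 neighbor_centers = neighbor_centers,
                 pixel_size = pixel_size, noise_sd = noise_sd,
                 image_size = image_size, seed = as.integer(seed)),
            class = "nucleus_render_params")
}

#' Render a synthetic nucleus image with ground-truth masks
#'
#' @param params a [nucleus_render_params()] object.
#' @return list with `image` (matrix, rows = y), `center` (um), masks
#'   `nucleus_mask` and `neighbor_mask`, and `params`.
#' @export
render_nucleus_image <- function(params) {
  stopifnot(inherits(params, "nucleus_render_params"))
  p <- params
  npx <- round(p$image_size / p$pixel_size)
  center <- c(p$image_size / 2, p$image_size / 2)
  r_nuc <- p$nucleus_diameter / 2
  if (center[1] - (r_nuc + 1) < 0 || center[1] + (r_nuc + 1) > p$image_size)
    stop("image too small to contain the nucleus plus a 1 um annulus")
  for (nc in p$neighbor_centers) {
    d <- sqrt(sum((nc - center)^2))
    if (d < p$nucleus_diameter)
      stop("neighbor nucleus overlaps the central nucleus disk")
  }
  nuc_mask <- disk_mask(c(npx, npx), center, r_nuc, p$pixel_size)
  nb_mask <- matrix(FALSE, npx, npx)
  for (nc in p$neighbor_centers)
    nb_mask <- nb_mask | disk_mask(c(npx, npx), nc, r_nuc, p$pixel_size)
  img <- matrix(p$background_intensity + p$cytoplasm_intensity, npx, npx)
  img[nuc_mask | nb_mask] <- p$background_intensity +
    p$true_nc_ratio * p$cytoplasm_intensity
  if (p$noise_sd > 0) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    }
    set.seed(p$seed)
    img <- img + matrix(stats::rnorm(npx * npx, 0, p$noise_sd), npx, npx)
  }
  list(image = img, center = center, nucleus_mask = nuc_mask,
       neighbor_mask = nb_mask, params = p)
}

#' Parameters for a synthetic proliferative-zone nucleus field
#'
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param nucleus_diameter nominal nucleus diameter, um (default 4.25, the
#'   blob diameter used by the detector); sets the default spacing and the
#'   match radius for benchmarking.
#' @param blob_fwhm FWHM of the rendered chromatin signal, um. A filled
#'   nucleus has much sharper edges than a Gaussian of its full diameter, so
#'   the bright core is rendered at 60% of the nominal diameter by default.
#' @param min_spacing minimum centre-to-centre distance, um; defaults to
#'   `nucleus_diameter` (nuclei cannot interpenetrate).
#' @param volume `c(x, y, z)` box size in um.
#' @param snr peak-to-noise-SD ratio; `Inf` for noise-free.
#' @param n_frames number of frames (nuclei persist through all frames).
#' @param pixel_size,z_step voxel size, um.
#' @param jitter_sd per-frame positional jitter SD, um.
#' @param amplitude blob peak intensity, arbitrary units.
#' @param seed integer seed.
#' @export
pz_field_params <- function(n_nuclei, nucleus_diameter = 4.25,
                            blob_fwhm = 0.6 * nucleus_diameter,
                            min_spacing = nucleus_diameter,
                            volume = c(48, 48, 12),
                            snr = 5, n_frames = 8, pixel_size = 0.25,
                            z_step = 1, jitter_sd = 0.1, amplitude = 100,
                            seed = 1L) {
  stopifnot(n_nuclei >= 0, min_spacing >= 0, blob_fwhm > 0,
            length(volume) == 3,
            all(volume > 0), snr > 0, n_frames >= 1, pixel_size > 0,
            z_step > 0)
  structure(list(n_nuclei = as.integer(n_nuclei),
                 nucleus_diameter = nucleus_diameter, blob_fwhm = blob_fwhm,
                 min_spacing = min_spacing, volume = volume, snr = snr,
                 n_frames = as.integer(n_frames), pixel_size = pixel_size,
                 z_step = z_step, jitter_sd = jitter_sd,
                 amplitude = amplitude, seed = as.integer(seed)),
            class = "pz_field_params")
}

#' Simulate a proliferative-zone image stack with ground-truth centres
#'
#' Places `n_nuclei` Gaussian blobs (FWHM `blob_fwhm`) at random
#' positions respecting `min_spacing`, jitters them slightly per frame, and
#' adds Gaussian noise with SD `amplitude / snr`.
#'
#' @param params a [pz_field_params()] object.
#' @return list with `stack` (array dim `c(y, x, z, t)` in pixels),
#'   `centers` (data.frame of ground-truth base positions in um), and
#'   `params`.
#' @export
simulate_pz_stack <- function(params) {
  stopifnot(inherits(params, "pz_field_params"))
  p <- params
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(p$seed)
  margin <- p$nucleus_diameter / 2
  lo <- rep(margin, 3)
  hi <- p$volume - margin
  if (any(hi <= lo) && p$n_nuclei > 0)
    stop("volume too small for the nucleus diameter")
  pos <- matrix(NA_real_, p$n_nuclei, 3)
  placed <- 0L
  attempts <- 0L
  max_attempts <- max(5000L, 2000L * p$n_nuclei)
  while (placed < p$n_nuclei && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- lo + stats::runif(3) * (hi - lo)
    ok <- placed == 0L ||
      min(sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 3, byrow = TRUE))^2))) >=
      p$min_spacing
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  if (placed < p$n_nuclei)
    stop(sprintf(paste0("could not place %d nuclei at %.2f um spacing in ",
                        "the given volume; achieved %d"),
                 p$n_nuclei, p$min_spacing, placed))
  nx <- round(p$volume[1] / p$pixel_size)
  ny <- round(p$volume[2] / p$pixel_size)
  nz <- round(p$volume[3] / p$z_step)
  sig_um <- p$blob_fwhm / (2 * sqrt(2 * log(2)))  # FWHM -> sigma
  stack <- array(0, dim = c(ny, nx, nz, p$n_frames))
  xs <- (seq_len(nx) - 0.5) * p$pixel_size
  ys <- (seq_len(ny) - 0.5) * p$pixel_size
  zs <- (seq_len(nz) - 0.5) * p$z_step
  for (f in seq_len(p$n_frames)) {
    vol <- array(0, dim = c(ny, nx, nz))
    for (i in seq_len(p$n_nuclei)) {
      c0 <- pos[i, ] + if (p$jitter_sd > 0) stats::rnorm(3, 0, p$jitter_sd)
                       else 0
      ix <- which(abs(xs - c0[1]) <= 3 * sig_um)
      iy <- which(abs(ys - c0[2]) <= 3 * sig_um)
      iz <- which(abs(zs - c0[3]) <= 3 * sig_um)
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- exp(-0.5 * ((xs[ix] - c0[1]) / sig_um)^2)
      gy <- exp(-0.5 * ((ys[iy] - c0[2]) / sig_um)^2)
      gz <- exp(-0.5 * ((zs[iz] - c0[3]) / sig_um)^2)
      blob <- p$amplitude * outer(gy, gx) %o% gz
      vol[iy, ix, iz] <- vol[iy, ix, iz] + blob
    }
    if (is.finite(p$snr))
      vol <- vol + array(stats::rnorm(length(vol), 0, p$amplitude / p$snr),
                         dim = dim(vol))
    stack[, , , f] <- vol
  }
  centers <- if (p$n_nuclei > 0)
    data.frame(id = seq_len(p$n_nuclei), x = pos[, 1], y = pos[, 2],
               z = pos[, 3])
  else data.frame(id = integer(), x = numeric(), y = numeric(),
                  z = numeric())
  list(stack = stack, centers = centers, params = p)
}

#' Specification of one cohort group for the synthetic screen
#'
#' Per-cell generative parameters are drawn around the group means so cells
#' within a genotype vary realistically; the defaults match an unperturbed
#' control (mitotic duration under 6 minutes on average).
#'
#' @param n_cells cells to simulate in this group.
#' @param duration_meanlog,duration_sdlog log-normal parameters of the
#'   mitotic duration (minutes).
#' @param nebd_to_start mean NEBD-to-start interval, minutes.
#' @param metaphase_length_mean,metaphase_length_sd plateau length, um.
#' @param pre_nebd_separation_mean,pre_nebd_separation_sd pre-NEBD pole
#'   separation, um.
#' @param plateau_noise_sd plateau noise, um.
#' @param rotation_rate_sd rotation SD, degrees/min.
#' @param elongation_rate_mean,elongation_rate_sd anaphase elongation rate,
#'   um/min.
#' @param telophase_peak_frac telophase peak as a multiple of the metaphase
#'   length.
#' @param n_gonads number of gonad arms the cells are spread over.
#' @export
cohort_group_spec <- function(n_cells = 35,
                              duration_meanlog = log(4.5),
                              duration_sdlog = 0.22,
                              nebd_to_start = 2,
                              metaphase_length_mean = 4,
                              metaphase_length_sd = 0.25,
                              pre_nebd_separation_mean = 5.5,
                              pre_nebd_separation_sd = 0.35,
                              plateau_noise_sd = 0.3,
                              rotation_rate_sd = 5,
                              elongation_rate_mean = 1.0,
                              elongation_rate_sd = 0.12,
                              telophase_peak_frac = 2.0,
                              n_gonads = 7) {
  as.list(environment())
}

#' Group specifications emulating the candidate screen
#'
#' Ten genotype groups: a control dividing in under 6 minutes on average,
#' three delayed groups with distinct spindle phenotypes (one with reduced
#' plateau fluctuations, one unchanged, one with increased fluctuations and
#' rotation), and six groups indistinguishable from control.
#'
#' @return named list of [cohort_group_spec()]s; the first element is the
#'   control group.
#' @export
screen_group_specs <- function() {
  ctrl <- cohort_group_spec()
  delayed_a <- cohort_group_spec(duration_meanlog = log(8),
                                 duration_sdlog = 0.45,
                                 plateau_noise_sd = 0.18)
  delayed_b <- cohort_group_spec(duration_meanlog = log(6.5),
                                 duration_sdlog = 0.35)
  delayed_c <- cohort_group_spec(duration_meanlog = log(7),
                                 duration_sdlog = 0.4,
                                 plateau_noise_sd = 0.45,
                                 rotation_rate_sd = 7)
  specs <- list(control = ctrl,
                mutantA = delayed_a, mutantB = delayed_b,
                mutantC = delayed_c)
  for (g in paste0("mutant", LETTERS[4:9])) specs[[g]] <- ctrl
  specs
}

#' Simulate a multi-group cohort of spindle tracks
#'
#' @param specs named list of [cohort_group_spec()]s; names are group labels.
#' @param seed master integer seed; per-cell seeds are derived from it.
#' @param frame_interval minutes per frame.
#' @return list with `tracks` (list of `spindle_track`) and `truth`
#'   (data.frame of per-cell ground-truth landmarks and parameters).
#' @export
simulate_cohort <- function(specs, seed = 1L, frame_interval = 0.5) {
  stopifnot(is.list(specs), !is.null(names(specs)), all(nzchar(names(specs))))
  set.seed(seed)
  tracks <- list()
  rows <- list()
  for (g in names(specs)) {
    s <- specs[[g]]
    for (i in seq_len(s$n_cells)) {
      dur <- stats::rlnorm(1, s$duration_meanlog, s$duration_sdlog)
      n2s <- max(frame_interval, stats::rnorm(1, s$nebd_to_start, 0.2))
      mlen <- max(1, stats::rnorm(1, s$metaphase_length_mean,
                                  s$metaphase_length_sd))
      psep <- max(mlen * 1.2,
                  stats::rnorm(1, s$pre_nebd_separation_mean,
                               s$pre_nebd_separation_sd))
      erate <- max(0.2, stats::rnorm(1, s$elongation_rate_mean,
                                     s$elongation_rate_sd))
      t_s <- 6
      t_nebd <- t_s - n2s
      t_ao <- t_s + max(frame_interval, dur)
      n_frames <- ceiling((t_ao + 8.5) / frame_interval) + 1
      cell_seed <- sample.int(2^31 - 2, 1)
      p <- spindle_sim_params(frame_interval = frame_interval,
                              t_nebd = t_nebd, t_s = t_s, t_ao = t_ao,
                              pre_nebd_separation = psep,
                              metaphase_length = mlen,
                              plateau_noise_sd = s$plateau_noise_sd,
                              elongation_rate = erate,
                              rotation_rate_sd = s$rotation_rate_sd,
                              telophase_peak = s$telophase_peak_frac * mlen,
                              n_frames = n_frames, seed = cell_seed)
      cid <- sprintf("%s_c%03d", g, i)
      gid <- sprintf("%s_g%d", g, 1 + (i - 1) %% s$n_gonads)
      sim <- simulate_spindle_track(p, cell_id = cid, group = g,
                                    gonad_id = gid)
      tracks[[cid]] <- sim$track
      rows[[cid]] <- data.frame(cell_id = cid, group = g, gonad_id = gid,
                                t_nebd = p$t_nebd, t_s = p$t_s,
                                t_ao = p$t_ao,
                                duration = p$t_ao - p$t_s,
                                metaphase_length = mlen,
                                pre_nebd_separation = psep,
                                elongation_rate = erate,
                                seed = cell_seed)
    }
  }
  list(tracks = tracks, truth = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Write spindle tracks as a TrackMate-style spots table
#'
#' One row per spot with `LABEL` encoding cell and pole (`<cell>_p1`,
#' `<cell>_p2`), positions in um and time in minutes. The file round-trips
#' through [read_spots_table()] and [pair_poles()].
#'
#' @param tracks a `spindle_track` or list of them.
#' @param path output CSV path.
#' @export
write_spots_table <- function(tracks, path) {
  if (inherits(tracks, "spindle_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    mk <- function(df, pole) data.frame(LABEL = sprintf("%s_p%d",
                                                        tr$cell_id, pole),
                                        POSITION_X = df$x, POSITION_Y = df$y,
                                        POSITION_Z = df$z, POSITION_T = df$t,
                                        FRAME = df$frame)
    rbind(mk(tr$pole1, 1L), mk(tr$pole2, 2L))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write an image stack as a multi-page TIFF
#'
#' Pages are ordered z within t. Intensities are rescaled to `[0, 1]` float.
#'
#' @param stack array with dim `c(y, x, z, t)` or `c(y, x, z)`.
#' @param path output path.
#' @export
write_stack_tiff <- function(stack, path) {
  d <- dim(stack)
  if (length(d) == 3) dim(stack) <- c(d, 1)
  rng <- range(stack)
  sc <- if (diff(rng) > 0) (stack - rng[1]) / diff(rng) else stack * 0
  pages <- list()
  for (f in seq_len(dim(sc)[4]))
    for (z in seq_len(dim(sc)[3]))
      pages[[length(pages) + 1]] <- sc[, , z, f]
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}
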