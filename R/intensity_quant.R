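#' Circular pixel mask
#'
#' Pixel (i, j) (1-based row y, column x) has its centre at
#' `((j - 0.5) * pixel_size, (i - 0.5) * pixel_size)` um; the mask selects
#' pixels whose centres lie within `radius` of `center`.
#'
#' @param dims image dim `c(ny, nx)`.
#' @param center `c(x, y)` in um.
#' @param radius radius in um.
#' @param pixel_size um per pixel.
#' @return logical matrix.
#' @export
disk_mask <- function(dims, center, radius, pixel_size) {
  xs <- (seq_len(dims[2]) - 0.5) * pixel_size
  ys <- (seq_len(dims[1]) - 0.5) * pixel_size
  outer(ys, xs, function(y, x) (x - center[1])^2 + (y - center[2])^2 <=
          radius^2)
}

#' Rectangular pixel mask
#'
#' Half-open rectangle `[x0, x0 + w) x [y0, y0 + h)` in um.
#'
#' @param dims image dim `c(ny, nx)`.
#' @param x0,y0 lower corner, um.
#' @param w,h width and height, um.
#' @param pixel_size um per pixel.
#' @return logical matrix.
#' @export
rect_mask <- function(dims, x0, y0, w, h, pixel_size) {
  xs <- (seq_len(dims[2]) - 0.5) * pixel_size
  ys <- (seq_len(dims[1]) - 0.5) * pixel_size
  outer(ys >= y0 & ys < y0 + h, xs >= x0 & xs < x0 + w, `&`)
}

#' Nuclear-to-cytoplasmic fluorescence ratio
#'
#' Mean intensity within a circular nuclear ROI divided by the mean intensity
#' within a surrounding annulus (the nuclear radius enlarged by
#' `annulus_expand`, nuclear disk excluded), after subtracting background
#' from both. Neighbouring nuclei can be excluded from the annulus via a
#' mask. Background is either a scalar, a list of rectangles (`list(x0, y0,
#' w, h)` in um) pooled per pixel, or a second matched image subtracted pixel
#' by pixel before measuring (autofluorescence correction).
#'
#' @param image matrix (rows = y).
#' @param center nucleus centre `c(x, y)`, um.
#' @param pixel_size um per pixel.
#' @param nucleus_diameter nuclear ROI diameter, um (default 4.5).
#' @param annulus_expand annulus width, um (default 1).
#' @param neighbor_mask logical matrix of pixels to exclude from the annulus.
#' @param background scalar, list of rectangles, or `NULL` for 0.
#' @param autofluorescence optional matched image subtracted first.
#' @param min_annulus_pixels minimum annulus size after exclusions.
#' @return data.frame `nuclear_fi`, `cytoplasmic_fi`, `background_fi`,
#'   `nc_ratio`, `flag` (`"undefined"` when cytoplasm minus background is not
#'   positive).
#' @export
measure_nc_ratio <- function(image, center, pixel_size,
                             nucleus_diameter = 4.5, annulus_expand = 1,
                             neighbor_mask = NULL, background = NULL,
                             autofluorescence = NULL,
                             min_annulus_pixels = 10) {
  d <- dim(image)
  if (!is.null(autofluorescence)) image <- image - autofluorescence
  r <- nucleus_diameter / 2
  if (center[1] - r - annulus_expand < 0 ||
      center[2] - r - annulus_expand < 0 ||
      center[1] + r + annulus_expand > d[2] * pixel_size ||
      center[2] + r + annulus_expand > d[1] * pixel_size)
    stop("ROI (nucleus + annulus) extends outside the image")
  nuc <- disk_mask(d, center, r, pixel_size)
  ann <- disk_mask(d, center, r + annulus_expand, pixel_size) & !nuc
  if (!is.null(neighbor_mask)) ann <- ann & !neighbor_mask
  if (sum(ann) < min_annulus_pixels)
    stop("annulus has fewer than ", min_annulus_pixels,
         " pixels after neighbor exclusion")
  bg <- 0
  if (is.numeric(background) && length(background) == 1) bg <- background
  else if (is.list(background) && length(background)) {
    px <- c()
    for (roi in background) {
      m <- rect_mask(d, roi$x0, roi$y0, roi$w, roi$h, pixel_size)
      px <- c(px, image[m])
    }
    bg <- mean(px)
  }
  nfi <- mean(image[nuc])
  cfi <- mean(image[ann])
  denom <- cfi - bg
  data.frame(nuclear_fi = nfi, cytoplasmic_fi = cfi, background_fi = bg,
             nc_ratio = if (denom > 0) (nfi - bg) / denom else NA_real_,
             flag = if (denom > 0) "" else "undefined")
}

#' Pre-mitotic nuclear-to-cytoplasmic ratio
#'
#' Mean of the highest three N:C values measured at least `lead_min` minutes
#' before NEBD. With fewer than three eligible frames the mean of those
#' available is returned with a flag; with none, an error.
#'
#' @param t frame times, minutes.
#' @param nc_ratio per-frame N:C values.
#' @param t_nebd NEBD time, minutes.
#' @param lead_min minimum lead time before NEBD (default 10).
#' @return scalar with attribute `flag`.
#' @export
premitotic_nc <- function(t, nc_ratio, t_nebd, lead_min = 10) {
  elig <- which(t <= t_nebd - lead_min & !is.na(nc_ratio))
  if (!length(elig)) stop("no frames at least ", lead_min,
                          " min before NEBD")
  v <- sort(nc_ratio[elig], decreasing = TRUE)
  out <- mean(v[seq_len(min(3, length(v)))])
  attr(out, "flag") <- if (length(v) < 3) "fewer_than_3_frames" else ""
  out
}

#' Count proliferative-zone nuclei in an image stack
#'
#' Reimplements the nucleus-counting chain: background subtraction, 3D median
#' filtering (X/Y radii 2 um, Z radius 1 um), Gaussian blurring (sigma 2
#' pixels), Difference-of-Gaussians blob detection at an estimated diameter
#' of 4.25 um, frame-to-frame greedy nearest-neighbour linking within 3.0 um
#' with up to 2 missed frames, and a count of tracks detected in at least 5
#' frames. Detection thresholds are relative to the strongest response, so
#' counting is invariant to intensity rescaling.
#'
#' @param stack array dim `c(y, x, z, t)`.
#' @param pixel_size,z_step voxel size, um.
#' @param roi optional rectangular PZ ROI `list(x0, y0, w, h)` in um; only
#'   tracks whose mean position falls inside are counted.
#' @param blob_diameter estimated nucleus diameter, um.
#' @param link_dist maximum link / gap-closing distance, um.
#' @param max_gap maximum missed frames within a track.
#' @param min_track_frames minimum detections per counted track.
#' @param median_radii_um median-filter radii `c(x, y, z)` in um.
#' @param gaussian_sigma_px Gaussian blur sigma in pixels (applied in x, y).
#' @param background one of `"median"` (subtract the volume median),
#'   `"none"`, or a numeric constant.
#' @param threshold_rel detection threshold as a fraction of the maximum DoG
#'   response per frame.
#' @return list with `count`, `centers` (data.frame of per-track mean
#'   positions, um), and `detections` (per frame).
#' @export
count_pz_nuclei <- function(stack, pixel_size, z_step, roi = NULL,
                            blob_diameter = 4.25, link_dist = 3.0,
                            max_gap = 2, min_track_frames = 5,
                            median_radii_um = c(2, 2, 1),
                            gaussian_sigma_px = 2,
                            background = "median",
                            threshold_rel = 0.25) {
  d <- dim(stack)
  stopifnot(length(d) == 4)
  if (missing(pixel_size) || missing(z_step))
    stop("pixel_size and z_step metadata are required")
  if (d[4] < min_track_frames)
    stop("stack has fewer than ", min_track_frames, " frames")
  rx <- max(0L, round(median_radii_um[1] / pixel_size))
  ry <- max(0L, round(median_radii_um[2] / pixel_size))
  rz <- max(0L, round(median_radii_um[3] / z_step))
  # DoG sigmas from the estimated diameter (Gaussian blob FWHM ~ diameter)
  s1_um <- blob_diameter / (2 * sqrt(2 * log(2))) / 1.2
  s2_um <- 1.6 * s1_um
  detections <- vector("list", d[4])
  for (f in seq_len(d[4])) {
    vol <- stack[, , , f, drop = TRUE]
    if (length(dim(vol)) == 2) dim(vol) <- c(d[1], d[2], 1)
    if (identical(background, "median")) vol <- vol - stats::median(vol)
    else if (is.numeric(background)) vol <- vol - background
    vol <- .median_filter_3d(vol, ry, rx, rz)
    vol <- .gaussian_blur_3d(vol, gaussian_sigma_px, gaussian_sigma_px, 0)
    g1 <- .gaussian_blur_3d(vol, s1_um / pixel_size, s1_um / pixel_size,
                            s1_um / z_step)
    g2 <- .gaussian_blur_3d(vol, s2_um / pixel_size, s2_um / pixel_size,
                            s2_um / z_step)
    dog <- g1 - g2
    mx <- max(dog)
    if (!(mx > 0)) {
      detections[[f]] <- data.frame(x = numeric(), y = numeric(),
                                    z = numeric())
      next
    }
    pk <- .local_maxima_3d(dog, threshold_rel * mx)
    detections[[f]] <- data.frame(x = (pk[, "x"] - 0.5) * pixel_size,
                                  y = (pk[, "y"] - 0.5) * pixel_size,
                                  z = (pk[, "z"] - 0.5) * z_step)
  }
  tracks <- link_detections(detections, link_dist, max_gap)
  keep <- vapply(tracks, function(tr) nrow(tr) >= min_track_frames,
                 logical(1))
  tracks <- tracks[keep]
  centers <- if (length(tracks))
    do.call(rbind, lapply(seq_along(tracks), function(i) {
      tr <- tracks[[i]]
      data.frame(id = i, x = mean(tr$x), y = mean(tr$y), z = mean(tr$z),
                 n_frames = nrow(tr))
    }))
  else data.frame(id = integer(), x = numeric(), y = numeric(),
                  z = numeric(), n_frames = integer())
  if (!is.null(roi) && nrow(centers)) {
    inside <- centers$x >= roi$x0 & centers$x < roi$x0 + roi$w &
      centers$y >= roi$y0 & centers$y < roi$y0 + roi$h
    centers <- centers[inside, , drop = FALSE]
  }
  list(count = nrow(centers), centers = centers, detections = detections)
}

# Greedy nearest-neighbour linking with gap closing: per frame, candidate
# (track head, detection) pairs within `link_dist` are linked in order of
# increasing distance; track heads stay eligible for `max_gap` missed frames.
link_detections <- function(detections, link_dist, max_gap) {
  tracks <- list()
  head_pos <- matrix(numeric(0), 0, 3)
  head_frame <- integer(0)
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    nd <- nrow(det)
    assigned <- rep(FALSE, nd)
    active <- which(f - head_frame <= max_gap + 1 & head_frame < f)
    if (length(active) && nd) {
      dm <- as.matrix(stats::dist(rbind(head_pos[active, , drop = FALSE],
                                        as.matrix(det[, c("x", "y", "z")]))))
      dm <- dm[seq_along(active), length(active) + seq_len(nd),
               drop = FALSE]
      pairs <- which(dm <= link_dist, arr.ind = TRUE)
      if (nrow(pairs)) {
        ord <- order(dm[pairs])
        used_tr <- logical(length(active))
        for (k in ord) {
          i <- pairs[k, 1]; j <- pairs[k, 2]
          if (used_tr[i] || assigned[j]) next
          used_tr[i] <- TRUE
          assigned[j] <- TRUE
          ti <- active[i]
          tracks[[ti]] <- rbind(tracks[[ti]],
                                data.frame(frame = f, x = det$x[j],
                                           y = det$y[j], z = det$z[j]))
          head_pos[ti, ] <- c(det$x[j], det$y[j], det$z[j])
          head_frame[ti] <- f
        }
      }
    }
    for (j in which(!assigned)) {
      tracks[[length(tracks) + 1]] <- data.frame(frame = f, x = det$x[j],
                                                 y = det$y[j], z = det$z[j])
      head_pos <- rbind(head_pos, c(det$x[j], det$y[j], det$z[j]))
      head_frame <- c(head_frame, f)
    }
  }
  tracks
}

#' Mitotic index
#'
#' @param n_mitotic number of mitotic cells (0 <= n_mitotic <= n_pz_nuclei).
#' @param n_pz_nuclei number of proliferative-zone nuclei (> 0).
#' @return `n_mitotic / n_pz_nuclei`.
#' @export
mitotic_index <- function(n_mitotic, n_pz_nuclei) {
  if (n_pz_nuclei <= 0) stop("n_pz_nuclei must be positive")
  if (n_mitotic < 0 || n_mitotic > n_pz_nuclei)
    stop("n_mitotic must be between 0 and n_pz_nuclei")
  n_mitotic / n_pz_nuclei
}

#' Germline depletion fluorescence
#'
#' Mean of three rectangular ROI means minus background; values at or below
#' background are clamped to 0; optionally normalized to a reference group
#' mean.
#'
#' @param image matrix (rows = y).
#' @param rois list of three rectangles `list(x0, y0, w, h)` in um.
#' @param pixel_size um per pixel.
#' @param background_value background FI (from matched no-reporter images).
#' @param reference_group_mean optional normalizer (> 0).
#' @return data.frame `fi_raw`, `fi_bgsub` (clamped), `fi_norm`.
#' @export
measure_depletion_fi <- function(image, rois, pixel_size,
                                 background_value = 0,
                                 reference_group_mean = NULL) {
  d <- dim(image)
  means <- vapply(rois, function(roi) {
    m <- rect_mask(d, roi$x0, roi$y0, roi$w, roi$h, pixel_size)
    if (!any(m)) stop("ROI outside image")
    mean(image[m])
  }, numeric(1))
  raw <- mean(means)
  sub <- max(0, raw - background_value)
  norm <- NA_real_
  if (!is.null(reference_group_mean)) {
    if (reference_group_mean <= 0) stop("reference mean must be positive")
    norm <- sub / reference_group_mean
  }
  data.frame(fi_raw = raw, fi_bgsub = sub, fi_norm = norm)
}

#' Assay ratios: mitotic-error classes and embryonic lethality
#'
#' Converts category counts to percentages. For mitotic errors the three
#' classes are (1) no obvious defects, (2) misaligned chromosomes during
#' prometaphase/metaphase, (3) lagging, bridging and/or misaligned
#' chromosomes during anaphase. For lethality, the input is
#' `c(unhatched = ..., hatched = ...)` and the percentage is unhatched over
#' total eggs laid.
#'
#' @param counts named non-negative integer vector; total must be positive.
#' @return data.frame `class`, `count`, `percent`.
#' @export
assay_ratios <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive")
  data.frame(class = names(counts), count = as.integer(counts),
             percent = 100 * counts / total, row.names = NULL)
}

#' Exact test of error frequencies between two conditions
#'
#' Collapses counts into error / no-error and runs Fisher's exact test on
#' the 2 x 2 table (condition x error status).
#'
#' @param counts_a,counts_b named count vectors with a `"none"` class; all
#'   other classes are treated as errors.
#' @return `htest` from [stats::fisher.test()].
#' @export
error_class_test <- function(counts_a, counts_b) {
  tab <- rbind(a = c(none = counts_a[["none"]],
                     error = sum(counts_a) - counts_a[["none"]]),
               b = c(none = counts_b[["none"]],
                     error = sum(counts_b) - counts_b[["none"]]))
  stats::fisher.test(tab)
}
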