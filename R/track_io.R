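#' Column mapping for a spot-table export
#'
#' Tracking tools export "spots" tables with varying column names and units;
#' this config maps them onto the fields the package needs. Defaults match
#' the TrackMate-style CSV written by [write_spots_table()].
#'
#' @param label,x,y,z,t,frame column names in the file. `frame` may be `NULL`
#'   (frames are then inferred from `t` and `frame_interval` downstream).
#' @param pole_pattern regex whose first capture group extracts the pole
#'   identity from the label; the remainder of the label is the cell id.
#' @param sep field separator; `dec` decimal separator.
#' @param skip number of extra header lines to skip after the column header
#'   (recent TrackMate versions emit three).
#' @param position_scale multiply positions by this to get um.
#' @param time_scale multiply times by this to get minutes.
#' @export
spots_dialect <- function(label = "LABEL", x = "POSITION_X",
                          y = "POSITION_Y", z = "POSITION_Z",
                          t = "POSITION_T", frame = "FRAME",
                          pole_pattern = "_p(\\d+)$", sep = ",", dec = ".",
                          skip = 0, position_scale = 1, time_scale = 1) {
  structure(list(label = label, x = x, y = y, z = z, t = t, frame = frame,
                 pole_pattern = pole_pattern, sep = sep, dec = dec,
                 skip = skip, position_scale = position_scale,
                 time_scale = time_scale),
            class = "spots_dialect")
}

#' Read a spot-table export
#'
#' Parses a TrackMate-style spots CSV/TXT into one row per spot with cell and
#' pole identity split out of the label. Rows with missing coordinates are
#' dropped (with a message); duplicate (cell, pole, frame) rows are an error.
#' Gaps are preserved: no interpolation happens at read time.
#'
#' @param path file path.
#' @param dialect a [spots_dialect()].
#' @return data.frame with columns `cell_id`, `pole_id`, `frame`, `t`, `x`,
#'   `y`, `z` (um / minutes).
#' @export
read_spots_table <- function(path, dialect = spots_dialect()) {
  stopifnot(inherits(dialect, "spots_dialect"))
  d <- dialect
  raw <- utils::read.table(path, header = TRUE, sep = d$sep, dec = d$dec,
                           skip = 0, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (d$skip > 0) raw <- raw[-seq_len(d$skip), , drop = FALSE]
  need <- c(d$label, d$x, d$y, d$z, d$t)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("cannot map columns ", paste(miss, collapse = ", "),
         "; file headers are: ", paste(names(raw), collapse = ", "))
  num <- function(col) as.numeric(raw[[col]])
  out <- data.frame(label = as.character(raw[[d$label]]),
                    t = num(d$t) * d$time_scale,
                    x = num(d$x) * d$position_scale,
                    y = num(d$y) * d$position_scale,
                    z = num(d$z) * d$position_scale,
                    stringsAsFactors = FALSE)
  out$frame <- if (!is.null(d$frame) && d$frame %in% names(raw))
    as.integer(num(d$frame)) else NA_integer_
  bad <- !stats::complete.cases(out[c("t", "x", "y", "z")])
  if (any(bad)) {
    message(sum(bad), " spot row(s) with missing coordinates dropped")
    out <- out[!bad, , drop = FALSE]
  }
  m <- regmatches(out$label, regexec(d$pole_pattern, out$label))
  pole <- vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_,
                 character(1))
  if (anyNA(pole))
    stop("some labels do not match the pole pattern '", d$pole_pattern, "'")
  out$pole_id <- as.integer(pole)
  out$cell_id <- sub(d$pole_pattern, "", out$label)
  key <- paste(out$cell_id, out$pole_id,
               ifelse(is.na(out$frame), out$t, out$frame))
  if (anyDuplicated(key))
    stop("duplicate (label, pole, frame) rows in spot table")
  out <- out[order(out$cell_id, out$pole_id, out$t),
             c("cell_id", "pole_id", "frame", "t", "x", "y", "z")]
  rownames(out) <- NULL
  out
}

new_spindle_track <- function(cell_id, group, gonad_id, pole1, pole2,
                              frame_interval) {
  stopifnot(nrow(pole1) > 0, nrow(pole2) > 0,
            !is.unsorted(pole1$t, strictly = TRUE),
            !is.unsorted(pole2$t, strictly = TRUE))
  structure(list(cell_id = cell_id, group = group, gonad_id = gonad_id,
                 pole1 = pole1, pole2 = pole2,
                 frame_interval = frame_interval),
            class = "spindle_track")
}

#' @export
print.spindle_track <- function(x, ...) {
  cat(sprintf("<spindle_track> cell %s (group %s, gonad %s): %d + %d spots, %.3g min/frame\n",
              x$cell_id, x$group, x$gonad_id, nrow(x$pole1), nrow(x$pole2),
              x$frame_interval))
  invisible(x)
}

#' Pair spindle poles into per-cell tracks
#'
#' Groups spots by cell label and pairs the two pole identities into a
#' `spindle_track`. Cells with one or more than two pole identities are
#' skipped and reported. Poles are ordered by their pole key so pairing is
#' deterministic.
#'
#' @param spots data.frame from [read_spots_table()].
#' @param frame_interval minutes per frame; if `NULL`, inferred as the
#'   smallest positive time difference in the data.
#' @param metadata optional data.frame with columns `cell_id`, `group`,
#'   `gonad_id`.
#' @return list of `spindle_track`s; skipped cells are attached as the
#'   `skipped` attribute (named character vector of reasons).
#' @export
pair_poles <- function(spots, frame_interval = NULL, metadata = NULL) {
  if (is.null(frame_interval)) {
    dt <- diff(sort(unique(spots$t)))
    dt <- dt[dt > 0]
    if (!length(dt)) dt <- 1
    frame_interval <- min(dt)
  }
  tracks <- list()
  skipped <- character()
  for (cid in unique(spots$cell_id)) {
    sub <- spots[spots$cell_id == cid, , drop = FALSE]
    poles <- sort(unique(sub$pole_id))
    if (length(poles) != 2) {
      skipped[cid] <- sprintf("ambiguous pairing: %d pole identities",
                              length(poles))
      next
    }
    grp <- "unknown"; gon <- "unknown"
    if (!is.null(metadata)) {
      mrow <- metadata[metadata$cell_id == cid, , drop = FALSE]
      if (nrow(mrow)) {
        grp <- mrow$group[1]
        gon <- mrow$gonad_id[1]
      }
    }
    ord <- function(df) df[order(df$t), c("frame", "t", "x", "y", "z")]
    tracks[[cid]] <- new_spindle_track(cell_id = cid, group = grp,
                                       gonad_id = gon,
                                       pole1 = ord(sub[sub$pole_id ==
                                                         poles[1], ]),
                                       pole2 = ord(sub[sub$pole_id ==
                                                         poles[2], ]),
                                       frame_interval = frame_interval)
  }
  if (length(skipped)) {
    warning(length(skipped), " cell(s) skipped: ",
            paste(names(skipped), collapse = ", "))
    attr(tracks, "skipped") <- skipped
  }
  tracks
}

#' Spindle length time series for one track
#'
#' Pole-to-pole Euclidean distance at every frame where both poles were
#' tracked; frames with either pole missing are absent from the series.
#'
#' @param track a `spindle_track`.
#' @return data.frame with columns `t` (minutes, sorted) and `length` (um),
#'   with attribute `frame_interval`.
#' @export
spindle_length_series <- function(track) {
  stopifnot(inherits(track, "spindle_track"))
  common <- intersect(track$pole1$t, track$pole2$t)
  if (!length(common))
    stop("no frames where both poles are present")
  common <- sort(common)
  p1 <- track$pole1[match(common, track$pole1$t), ]
  p2 <- track$pole2[match(common, track$pole2$t), ]
  len <- sqrt((p1$x - p2$x)^2 + (p1$y - p2$y)^2 + (p1$z - p2$z)^2)
  out <- data.frame(t = common, length = len)
  attr(out, "frame_interval") <- track$frame_interval
  out
}

#' Per-frame spindle axis unit vectors
#'
#' The axis is undirected (pole labelling is arbitrary); downstream angle
#' computations fold angles to at most 90 degrees.
#'
#' @param track a `spindle_track`.
#' @return data.frame with `t` and unit-vector components `ux`, `uy`, `uz`
#'   (NA where spindle length is zero).
#' @export
spindle_axes <- function(track) {
  stopifnot(inherits(track, "spindle_track"))
  common <- sort(intersect(track$pole1$t, track$pole2$t))
  p1 <- track$pole1[match(common, track$pole1$t), ]
  p2 <- track$pole2[match(common, track$pole2$t), ]
  v <- cbind(p1$x - p2$x, p1$y - p2$y, p1$z - p2$z)
  n <- sqrt(rowSums(v^2))
  u <- v / ifelse(n > 0, n, NA_real_)
  data.frame(t = common, ux = u[, 1], uy = u[, 2], uz = u[, 3])
}

#' Write spindle-length series as a tidy per-frame CSV
#'
#' @param tracks list of `spindle_track`s.
#' @param path output CSV (columns `cell_id`, `group`, `t_min`, `length_um`).
#' @export
write_length_series <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    s <- spindle_length_series(tr)
    data.frame(cell_id = tr$cell_id, group = tr$group, t_min = s$t,
               length_um = s$length)
  })
  utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)), path,
                   row.names = FALSE)
  invisible(path)
}
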