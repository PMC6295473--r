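#' Volume-weighted average concentration
#'
#' `sum(v * c) / sum(v)`: the whole-cell average of a concentration field
#' weighted by the local volume fraction of its compartment.
#'
#' @param c Concentration field (matrix or vector).
#' @param v Volume-fraction field, same shape, with `sum(v) > 0`.
#' @return Scalar average (uM).
#' @export
volume_weighted_average <- function(c, v) {
  if (length(c) != length(v)) stop("c and v must have the same shape")
  sv <- sum(v)
  if (sv <= 0) stop("weights must have a positive sum")
  sum(v * c) / sv
}

#' Strip average: trace or line scan
#'
#' Volume-weighted average over a strip of the cell.  With a 3D movie
#' (`nx x ny x nt`), `output = "trace"` returns one value per frame;
#' `output = "linescan"` averages across the strip per position along the
#' other axis, returning a position x time matrix.  A single matrix gives
#' one value (or one profile).
#'
#' `axis = "y"` selects a longitudinal strip (fixed y-range, e.g. the 1-um
#' subsarcolemmal band); `axis = "x"` a transversal strip (fixed x-range,
#' e.g. a 0.3-um band on a z-line).
#'
#' @param field Matrix (`nx x ny`) or array (`nx x ny x nt`).
#' @param geom The `cell_geometry` the field lives on.
#' @param axis `"y"` or `"x"`: the axis along which the strip is thin.
#' @param center Strip centre coordinate (um).
#' @param width Strip width (um).
#' @param output `"trace"` or `"linescan"`.
#' @return Numeric vector (trace), or matrix (line scan / profile).
#' @export
strip_average <- function(field, geom, axis = c("y", "x"), center, width,
                          output = c("trace", "linescan")) {
  axis <- match.arg(axis); output <- match.arg(output)
  d <- if (axis == "y") geom$dy else geom$dx
  nmax <- if (axis == "y") geom$ny else geom$nx
  pos <- (seq_len(nmax) - 0.5) * d
  # half-open interval: a 1-um strip at dx = 0.1 covers exactly 10 rows
  idx <- which(pos >= center - width / 2 - 1e-9 &
                 pos < center + width / 2 - 1e-9)
  if (length(idx) == 0) stop("strip contains no nodes")
  v <- geom$v_i
  one <- function(m) {
    if (axis == "y") { mm <- m[, idx, drop = FALSE]; vv <- v[, idx, drop = FALSE] }
    else { mm <- m[idx, , drop = FALSE]; vv <- v[idx, , drop = FALSE] }
    if (output == "trace") sum(vv * mm) / sum(vv)
    else if (axis == "y") rowSums(vv * mm) / rowSums(vv)
    else colSums(vv * mm) / colSums(vv)
  }
  if (length(dim(field)) == 3) {
    nt <- dim(field)[3]
    res <- vapply(seq_len(nt), function(q) one(field[, , q]),
                  if (output == "trace") numeric(1)
                  else numeric(if (axis == "y") geom$nx else geom$ny))
    res
  } else one(field)
}

#' Detect calcium sparks in a field movie
#'
#' Frame-wise detection: nodes above the amplitude threshold are labelled
#' by 4-connected components; components with equivalent radius
#' `sqrt(area/pi)` at or above the radial threshold are candidate events;
#' candidates whose bounding regions overlap in consecutive frames (with up
#' to one missing frame tolerated) are merged into a single spark event.
#'
#' The default amplitude threshold is the robust baseline (median) plus two
#' median absolute deviations of the movie values, a criterion that adapts
#' to the resting fluctuation level.
#'
#' @param movie Array `nx x ny x nt` of cytosolic calcium (uM).
#' @param dx Grid spacing (um).
#' @param frame_times Frame times (ms), length `nt`.
#' @param amplitude_threshold Concentration level (uM); `NULL` = robust
#'   default.
#' @param radius_threshold Minimal equivalent radius (um), default 1.6.
#' @return Data frame: `t_start_ms`, `t_end_ms`, `x_um`, `y_um`
#'   (amplitude-weighted centroid at peak), `max_radius_um`,
#'   `peak_amplitude_uM`.
#' @export
detect_sparks <- function(movie, dx, frame_times,
                          amplitude_threshold = NULL,
                          radius_threshold = 1.6) {
  stopifnot(length(dim(movie)) == 3, radius_threshold > 0)
  nt <- dim(movie)[3]
  if (length(frame_times) != nt) stop("frame_times must match the movie")
  if (nt < 2) stop("movie must have at least 2 frames")
  if (is.null(amplitude_threshold))
    amplitude_threshold <- median(movie) + 2 * mad(movie)
  if (amplitude_threshold <= 0) stop("amplitude threshold must be positive")

  empty <- data.frame(t_start_ms = numeric(0), t_end_ms = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      max_radius_um = numeric(0),
                      peak_amplitude_uM = numeric(0))

  # per-frame candidate components
  cand <- vector("list", nt)
  for (q in seq_len(nt)) {
    fr <- movie[, , q]
    mask <- fr >= amplitude_threshold
    if (!any(mask)) { cand[q] <- list(NULL); next }
    lab <- .label4_cpp(mask)
    comps <- list()
    for (id in seq_len(max(lab))) {
      sel <- which(lab == id, arr.ind = TRUE)
      r_eq <- sqrt(nrow(sel) * dx * dx / pi)
      if (r_eq < radius_threshold) next
      w <- fr[sel]
      comps[[length(comps) + 1]] <- list(
        frame = q, r = r_eq, peak = max(w),
        x = sum(w * (sel[, 1] - 0.5)) / sum(w) * dx,
        y = sum(w * (sel[, 2] - 0.5)) / sum(w) * dx,
        bbox = c(range(sel[, 1]), range(sel[, 2])))
    }
    cand[[q]] <- comps
  }

  # link candidates across frames (spatial bbox overlap, <= 1 frame gap)
  events <- list()
  open <- list()  # active tracks: list(last_frame, bbox, comps)
  overlap <- function(a, b)
    a[1] <= b[2] && b[1] <= a[2] && a[3] <= b[4] && b[3] <= a[4]
  for (q in seq_len(nt)) {
    keep <- vapply(open, function(tr) q - tr$last_frame <= 2, logical(1))
    events <- c(events, lapply(open[!keep], function(tr) tr$comps))
    open <- open[keep]
    for (cp in if (is.null(cand[[q]])) list() else cand[[q]]) {
      hit <- 0L
      for (ii in seq_along(open)) {
        if (open[[ii]]$last_frame < q &&
            overlap(open[[ii]]$bbox, cp$bbox)) { hit <- ii; break }
      }
      if (hit > 0L) {
        open[[hit]]$comps <- c(open[[hit]]$comps, list(cp))
        open[[hit]]$last_frame <- q
        open[[hit]]$bbox <- c(min(open[[hit]]$bbox[1], cp$bbox[1]),
                              max(open[[hit]]$bbox[2], cp$bbox[2]),
                              min(open[[hit]]$bbox[3], cp$bbox[3]),
                              max(open[[hit]]$bbox[4], cp$bbox[4]))
      } else {
        open[[length(open) + 1]] <- list(last_frame = q, bbox = cp$bbox,
                                         comps = list(cp))
      }
    }
  }
  events <- c(events, lapply(open, function(tr) tr$comps))
  if (length(events) == 0) return(empty)

  rows <- lapply(events, function(cps) {
    frames <- vapply(cps, `[[`, numeric(1), "frame")
    peaks <- vapply(cps, `[[`, numeric(1), "peak")
    best <- which.max(peaks)
    data.frame(t_start_ms = frame_times[min(frames)],
               t_end_ms = frame_times[max(frames)],
               x_um = cps[[best]]$x, y_um = cps[[best]]$y,
               max_radius_um = max(vapply(cps, `[[`, numeric(1), "r")),
               peak_amplitude_uM = max(peaks))
  })
  do.call(rbind, rows)
}

#' Spark frequency
#'
#' Number of spark events (optionally restricted to a rectangular region by
#' centroid) per unit time.
#'
#' @param events Data frame from [detect_sparks()].
#' @param duration_ms Observation time (ms, > 0).
#' @param region Optional `c(x0, x1, y0, y1)` (um).
#' @param per_area_um2 Optional region area for a per-100-um^2 rate.
#' @return Events per second (or per second per 100 um^2).
#' @export
spark_frequency <- function(events, duration_ms, region = NULL,
                            per_area_um2 = NULL) {
  stopifnot(duration_ms > 0)
  n <- if (nrow(events) == 0) 0L else {
    if (is.null(region)) nrow(events) else
      sum(events$x_um >= region[1] & events$x_um <= region[2] &
            events$y_um >= region[3] & events$y_um <= region[4])
  }
  f <- n / (duration_ms / 1000)
  if (!is.null(per_area_um2)) f <- f / per_area_um2 * 100
  f
}

#' Track a propagating front and fit its speed
#'
#' Per frame, the front position is the farthest coordinate (from the
#' initiation side) at which the averaged profile exceeds the threshold;
#' the speed is the least-squares slope of position versus time over the
#' frames where the front advances monotonically.  A front that never
#' advances beyond its initial extent is flagged `stalled` with an
#' undefined speed.
#'
#' @param profiles Matrix (position x time) of transversally averaged
#'   concentration.
#' @param times Frame times (ms), strictly increasing.
#' @param dx Node spacing along the profile (um).
#' @param threshold Concentration threshold (uM).
#' @param from `"low"` (front advances towards larger coordinates) or
#'   `"high"`.
#' @return A `wave_trace` list: `times`, `front_positions` (um),
#'   `fitted_speed_um_s` (um/s, NA if stalled/undefined), `fit_residual`,
#'   `stalled`.
#' @export
track_front <- function(profiles, times, dx, threshold, from = c("low", "high")) {
  from <- match.arg(from)
  stopifnot(ncol(profiles) == length(times), all(diff(times) > 0))
  npos <- nrow(profiles)
  pos <- vapply(seq_along(times), function(q) {
    above <- which(profiles[, q] >= threshold)
    if (length(above) == 0) return(NA_real_)
    j <- if (from == "low") max(above) else min(above)
    if (from == "high") j <- npos + 1L - j
    (j - 0.5) * dx
  }, numeric(1))
  out <- list(times = times, front_positions = pos,
              fitted_speed_um_s = NA_real_, fit_residual = NA_real_,
              stalled = TRUE)
  class(out) <- "wave_trace"
  ok <- which(!is.na(pos))
  if (length(ok) < 3) return(out)
  # advancing segment: frames up to where the front reaches its maximum
  imax <- ok[which.max(pos[ok])]
  seg <- ok[ok <= imax]
  seg <- seg[pos[seg] > pos[seg[1]] | seq_along(seg) == 1]
  if (length(seg) < 3 || max(pos[seg]) - min(pos[seg]) < 2 * dx)
    return(out)  # never advanced: stalled
  fit <- lm(pos[seg] ~ times[seg])
  out$fitted_speed_um_s <- unname(coef(fit)[2]) * 1000  # um/ms -> um/s
  out$fit_residual <- sqrt(mean(stats::residuals(fit)^2))
  out$stalled <- FALSE
  out
}

#' @export
print.wave_trace <- function(x, ...) {
  if (x$stalled) cat("wave_trace: stalled (no propagating front)\n")
  else cat(sprintf("wave_trace: speed %.1f um/s (rms residual %.3f um, %d frames)\n",
                   x$fitted_speed_um_s, x$fit_residual, length(x$times)))
  invisible(x)
}

#' Per-beat transient features
#'
#' Splits a trace into beat windows and extracts, per beat, the peak, the
#' pre-stimulus (diastolic) minimum and the time to peak, averaged across
#' beats.
#'
#' @param trace Numeric trace (uM).
#' @param times Sample times (ms).
#' @param Ts Beat period (ms); the trace must span at least one full beat.
#' @return List: `peak`, `diastolic`, `time_to_peak_ms` (averages), and
#'   `per_beat` data frame.
#' @export
transient_features <- function(trace, times, Ts) {
  stopifnot(length(trace) == length(times))
  t0 <- times[1]
  beat <- floor((times - t0) / Ts)
  n_beats <- max(beat) + 1
  if (max(times) - t0 < Ts * 0.99) stop("trace spans less than one beat")
  rows <- lapply(seq_len(n_beats) - 1, function(b) {
    sel <- which(beat == b)
    if (length(sel) < 3) return(NULL)
    tr <- trace[sel]; tt <- times[sel]
    ip <- which.max(tr)
    # diastolic level: pre-stimulus minimum (the beat window opens at the
    # stimulus, so the first few samples carry the pre-stimulus level)
    pre <- min(tr[1:max(1, min(ip, ceiling(0.05 * length(tr))))])
    data.frame(beat = b + 1, peak = tr[ip], diastolic = pre,
               time_to_peak_ms = tt[ip] - tt[1])
  })
  per <- do.call(rbind, rows)
  list(peak = mean(per$peak), diastolic = mean(per$diastolic),
       time_to_peak_ms = mean(per$time_to_peak_ms), per_beat = per)
}
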