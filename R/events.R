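# Velocity-threshold (I-VT) event detection: angular sample velocity, fixation
# and saccade segmentation, blink/dropout detection and the net-gaze mask.

# Nominal inter-sample interval from timestamps (ms); 2 ms at 500 Hz.
sample_interval_ms <- function(t_ms) {
  if (length(t_ms) < 2) return(2)
  stats::median(diff(t_ms))
}

validate_stream <- function(stream) {
  need <- c("t_ms", "x_px", "y_px", "valid")
  if (!is.data.frame(stream) || !all(need %in% names(stream))) {
    stop("gaze stream needs columns t_ms, x_px, y_px, valid", call. = FALSE)
  }
  if (nrow(stream) > 1 && any(diff(stream$t_ms) <= 0)) {
    stop("gaze stream timestamps must be strictly increasing", call. = FALSE)
  }
  invisible(stream)
}

#' Angular gaze velocity per sample
#'
#' Central-difference speed: at interior sample i the angular distance between
#' positions i-1 and i+1 divided by the spanned time. Stream endpoints use
#' one-sided differences. A sample whose required neighbor is invalid (or
#' which is itself invalid) gets `NA`. No smoothing is applied unless
#' `smooth_window > 1`, in which case a centered moving average of that many
#' samples is run over the velocity trace (NA-preserving).
#'
#' @param stream data.frame with `t_ms`, `x_px`, `y_px`, `valid`.
#' @param screen A [screen_geometry()] object.
#' @param smooth_window Moving-average window in samples (0 or 1 = none).
#' @return Numeric vector of speeds in deg/s, one per sample.
#' @export
sample_velocity <- function(stream, screen, smooth_window = 0) {
  validate_stream(stream)
  n <- nrow(stream)
  if (n < 2) return(rep(NA_real_, n))
  dpp <- degrees_per_pixel(screen)
  xd <- stream$x_px * dpp[["horizontal"]]
  yd <- stream$y_px * dpp[["vertical"]]
  ok <- stream$valid > 0 & is.finite(xd) & is.finite(yd)
  t <- stream$t_ms
  v <- rep(NA_real_, n)
  dist_deg <- function(i, j) sqrt((xd[j] - xd[i])^2 + (yd[j] - yd[i])^2)
  idx <- which(ok)
  for (i in idx) {
    lo <- i - 1L; hi <- i + 1L
    if (i == 1L) lo <- i
    if (i == n) hi <- i
    if (lo == hi) next
    if (!ok[lo] || !ok[hi]) next
    v[i] <- dist_deg(lo, hi) / (t[hi] - t[lo]) * 1000
  }
  if (smooth_window > 1) {
    w <- as.integer(smooth_window)
    half <- w %/% 2L
    sm <- v
    for (i in seq_len(n)) {
      win <- v[max(1, i - half):min(n, i + half)]
      sm[i] <- if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
    }
    sm[is.na(v)] <- NA_real_
    v <- sm
  }
  v
}

# Per-sample classification underlying the I-VT segmentation:
#   "invalid"  valid == 0
#   "saccade"  speed > threshold
#   "fix"      speed <= threshold, or speed undefined on a valid sample
#              (single-sample valid runs, run edges next to dropouts)
classify_samples <- function(stream, screen, velocity_threshold, smooth_window) {
  v <- sample_velocity(stream, screen, smooth_window)
  cls <- rep("fix", nrow(stream))
  cls[!is.na(v) & v > velocity_threshold] <- "saccade"
  cls[stream$valid <= 0] <- "invalid"
  cls
}

run_bounds <- function(cls) {
  n <- length(cls)
  if (n == 0) {
    return(data.frame(cls = character(0), start = integer(0), end = integer(0)))
  }
  r <- rle(cls)
  end <- cumsum(r$lengths)
  data.frame(cls = r$values, start = c(1L, utils::head(end, -1) + 1L), end = end,
             stringsAsFactors = FALSE)
}

events_from_runs <- function(stream, runs, dt) {
  if (nrow(runs) == 0) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), x_px = numeric(0),
                      y_px = numeric(0), n_samples = integer(0)))
  }
  onset <- stream$t_ms[runs$start]
  offset <- stream$t_ms[runs$end] + dt
  data.frame(
    onset_ms = onset, offset_ms = offset, duration_ms = offset - onset,
    x_px = vapply(seq_len(nrow(runs)), function(k)
      mean(stream$x_px[runs$start[k]:runs$end[k]]), numeric(1)),
    y_px = vapply(seq_len(nrow(runs)), function(k)
      mean(stream$y_px[runs$start[k]:runs$end[k]]), numeric(1)),
    n_samples = runs$end - runs$start + 1L
  )
}

#' I-VT fixation and saccade detection
#'
#' Classifies every valid sample as saccade (angular speed above
#' `velocity_threshold`) or fixation candidate, groups consecutive samples of
#' one class into runs, and retains fixation candidates of at least
#' `min_fixation_ms` (boundary inclusive). Candidate runs shorter than the
#' minimum are returned separately as `discarded`; they count toward neither
#' fixation nor saccade time. Event intervals follow the convention
#' `[onset, last sample time + sample interval)`, so durations are whole
#' sample counts. No merging of fixations across brief saccades is performed.
#'
#' @param stream data.frame with `t_ms`, `x_px`, `y_px`, `valid`.
#' @param screen A [screen_geometry()] object.
#' @param velocity_threshold Peak angular speed separating saccade from
#'   fixation samples, deg/s.
#' @param min_fixation_ms Minimum retained fixation duration, ms.
#' @param smooth_window Optional velocity smoothing window in samples.
#' @return List with data.frames `fixations` (onset_ms, offset_ms,
#'   duration_ms, x_px, y_px centroid, n_samples), `saccades`, `discarded`.
#' @export
detect_fixations_ivt <- function(stream, screen, velocity_threshold = 40,
                                 min_fixation_ms = 80, smooth_window = 0) {
  validate_stream(stream)
  empty <- list(
    fixations = events_from_runs(stream, run_bounds(character(0)), 2),
    saccades = events_from_runs(stream, run_bounds(character(0)), 2),
    discarded = events_from_runs(stream, run_bounds(character(0)), 2))
  if (nrow(stream) == 0 || !any(stream$valid > 0)) return(empty)
  dt <- sample_interval_ms(stream$t_ms)
  cls <- classify_samples(stream, screen, velocity_threshold, smooth_window)
  runs <- run_bounds(cls)
  fix_runs <- runs[runs$cls == "fix", , drop = FALSE]
  sac_runs <- runs[runs$cls == "saccade", , drop = FALSE]
  fix_ev <- events_from_runs(stream, fix_runs, dt)
  keep <- fix_ev$duration_ms >= min_fixation_ms
  list(fixations = fix_ev[keep, , drop = FALSE],
       saccades = events_from_runs(stream, sac_runs, dt),
       discarded = fix_ev[!keep, , drop = FALSE])
}

#' Blink and dropout detection
#'
#' Maximal runs of invalid samples; runs of at least `min_blink_ms` are
#' labeled blinks, shorter ones dropouts. Both are excluded from net gaze.
#'
#' @param stream Gaze sample data.frame.
#' @param min_blink_ms Minimum invalid-run duration counted as a blink.
#' @return data.frame with `onset_ms`, `offset_ms`, `duration_ms`, `type`
#'   (`"blink"` or `"dropout"`).
#' @export
detect_blinks <- function(stream, min_blink_ms = 75) {
  validate_stream(stream)
  if (nrow(stream) == 0) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), type = character(0)))
  }
  dt <- sample_interval_ms(stream$t_ms)
  runs <- run_bounds(ifelse(stream$valid > 0, "valid", "invalid"))
  runs <- runs[runs$cls == "invalid", , drop = FALSE]
  ev <- events_from_runs(stream, runs, dt)
  ev$x_px <- NULL; ev$y_px <- NULL; ev$n_samples <- NULL
  ev$type <- ifelse(ev$duration_ms >= min_blink_ms, "blink", "dropout")
  ev
}

#' Net-gaze sample mask
#'
#' A sample counts toward net gaze iff it is valid and lies within a retained
#' fixation: saccades, blinks, dropouts and sub-minimum fixation candidates
#' are all excluded.
#'
#' @param stream Gaze sample data.frame.
#' @param fixations Retained fixations from [detect_fixations_ivt()] for the
#'   same stream.
#' @param blinks Optional blink table (kept for interface symmetry; invalid
#'   samples are excluded regardless).
#' @return Logical vector, one flag per sample.
#' @export
net_gaze_mask <- function(stream, fixations, blinks = NULL) {
  validate_stream(stream)
  n <- nrow(stream)
  mask <- rep(FALSE, n)
  if (n == 0 || nrow(fixations) == 0) return(mask)
  if (any(fixations$onset_ms < stream$t_ms[1]) ||
      any(fixations$offset_ms > stream$t_ms[n] + sample_interval_ms(stream$t_ms) + 1e-9)) {
    stop("fixation events extend beyond the stream they are matched to",
         call. = FALSE)
  }
  for (k in seq_len(nrow(fixations))) {
    mask <- mask | (stream$t_ms >= fixations$onset_ms[k] &
                      stream$t_ms < fixations$offset_ms[k])
  }
  mask & stream$valid > 0
}

#' ROI label for each fixation centroid
#'
#' @param fixations Fixation table from [detect_fixations_ivt()].
#' @param rois List of `roi` objects.
#' @return The fixation table with an added `roi` column.
#' @export
assign_fixation_rois <- function(fixations, rois) {
  fixations$roi <- assign_roi_points(fixations$x_px, fixations$y_px, rois)
  fixations
}
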