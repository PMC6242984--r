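# Per-trial eye-movement measures (first fixation, entry, net gaze duration,
# fixation counts, coverage) and their by-items aggregation.

# Indices of leading fixations whose centroid lies within center_radius_deg
# of the central fixation point: the fixation carried over from the cross.
leading_center_fixations <- function(fixations, center_px, center_radius_deg,
                                     screen) {
  if (nrow(fixations) == 0) return(integer(0))
  dpp <- mean(degrees_per_pixel(screen))
  d_deg <- sqrt((fixations$x_px - center_px[1])^2 +
                  (fixations$y_px - center_px[2])^2) * dpp
  out <- integer(0)
  for (k in seq_len(nrow(fixations))) {
    if (is.na(d_deg[k]) || d_deg[k] > center_radius_deg) break
    out <- c(out, k)
  }
  out
}

#' Region of the first fixation on the face
#'
#' Leading fixations whose centroid lies within `center_radius_deg` of the
#' central fixation point are the gaze carried over from the fixation cross
#' and are skipped; the ROI of the next fixation is returned. Later returns
#' to the screen center are ordinary nose fixations and are not skipped.
#'
#' @param fixations Time-ordered retained fixations (with or without `roi`).
#' @param rois List of `roi` objects.
#' @param center_px Pixel `c(x, y)` of the central fixation point.
#' @param center_radius_deg Radius of the carried-over-fixation exclusion
#'   zone, degrees.
#' @param screen A [screen_geometry()] object.
#' @return `"eyes"`, `"nose"`, `"mouth"`, `"other"`, or `"none"` when no
#'   fixation follows the carried-over one.
#' @export
first_fixation_roi <- function(fixations, rois, center_px,
                               center_radius_deg = 1.0, screen) {
  if (nrow(fixations) == 0) return("none")
  skip <- leading_center_fixations(fixations, center_px, center_radius_deg,
                                   screen)
  rest <- setdiff(seq_len(nrow(fixations)), skip)
  if (!length(rest)) return("none")
  k <- rest[1]
  assign_roi(fixations$x_px[k], fixations$y_px[k], rois)
}

#' Entry flags and entry times per region
#'
#' A region counts as entered when at least one retained, non-carried-over
#' fixation lands in it; the entry time is the onset of the earliest such
#' fixation.
#'
#' @inheritParams first_fixation_roi
#' @param exclude_initial_center Skip the carried-over central fixation(s).
#' @return List with logical `entered` and numeric `entry_time_ms` (NA when
#'   not entered), both named by ROI.
#' @export
entry_stats <- function(fixations, rois, center_px, center_radius_deg = 1.0,
                        screen, exclude_initial_center = TRUE) {
  labs <- roi_labels()
  entered <- stats::setNames(rep(FALSE, 3), labs)
  entry <- stats::setNames(rep(NA_real_, 3), labs)
  if (nrow(fixations) == 0) {
    return(list(entered = entered, entry_time_ms = entry))
  }
  keep <- seq_len(nrow(fixations))
  if (exclude_initial_center) {
    keep <- setdiff(keep, leading_center_fixations(
      fixations, center_px, center_radius_deg, screen))
  }
  if (length(keep)) {
    lab <- assign_roi_points(fixations$x_px[keep], fixations$y_px[keep], rois)
    for (r in labs) {
      hit <- keep[lab == r]
      if (length(hit)) {
        entered[r] <- TRUE
        entry[r] <- min(fixations$onset_ms[hit])
      }
    }
  }
  list(entered = entered, entry_time_ms = entry)
}

#' Net gaze duration per region
#'
#' Sums net-gaze sample time per region. By default each retained fixation's
#' whole net time is attributed to the ROI of its centroid (consistent with
#' fixation counts); with `attribution = "sample"` every masked sample is
#' attributed to the ROI of its own position.
#'
#' @param stream Gaze sample data.frame.
#' @param mask Net-gaze mask from [net_gaze_mask()].
#' @param fixations Retained fixations for the same stream.
#' @param rois List of `roi` objects.
#' @param attribution `"centroid"` (default) or `"sample"`.
#' @return Named numeric vector over `eyes`, `nose`, `mouth`, `other` (ms).
#' @export
gaze_durations <- function(stream, mask, fixations, rois,
                           attribution = c("centroid", "sample")) {
  attribution <- match.arg(attribution)
  labs <- roi_labels(with_other = TRUE)
  out <- stats::setNames(rep(0, 4), labs)
  if (!any(mask)) return(out)
  dt <- sample_interval_ms(stream$t_ms)
  if (attribution == "sample") {
    lab <- assign_roi_points(stream$x_px[mask], stream$y_px[mask], rois)
    tab <- table(lab)
    out[names(tab)] <- as.numeric(tab) * dt
    return(out)
  }
  if (!"roi" %in% names(fixations)) {
    fixations <- assign_fixation_rois(fixations, rois)
  }
  t <- stream$t_ms
  for (k in seq_len(nrow(fixations))) {
    in_fix <- mask & t >= fixations$onset_ms[k] & t < fixations$offset_ms[k]
    out[fixations$roi[k]] <- out[fixations$roi[k]] + sum(in_fix) * dt
  }
  out
}

#' Number of retained fixations per region
#'
#' Counts fixations (minimum-duration criterion already applied by the
#' detector, 80-ms boundary inclusive) by centroid ROI.
#'
#' @param fixations Retained fixations.
#' @param rois List of `roi` objects.
#' @return Named integer vector over `eyes`, `nose`, `mouth`, `other`.
#' @export
fixation_counts <- function(fixations, rois) {
  labs <- roi_labels(with_other = TRUE)
  out <- stats::setNames(rep(0L, 4), labs)
  if (nrow(fixations) == 0) return(out)
  if (!"roi" %in% names(fixations)) {
    fixations <- assign_fixation_rois(fixations, rois)
  }
  tab <- table(fixations$roi)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Fraction of net gaze inside the three regions
#'
#' @param gaze Named gaze-duration vector from [gaze_durations()].
#' @return Fraction in `[0, 1]`, or `NA` when total net gaze is zero.
#' @export
coverage <- function(gaze) {
  total <- sum(gaze)
  if (total <= 0) return(NA_real_)
  sum(gaze[roi_labels()]) / total
}

#' All per-trial measures for one gaze stream
#'
#' Runs event detection, the net-gaze mask and every attention measure for a
#' single trial, returning both the event tables and a one-row metrics frame.
#'
#' @param stream Gaze sample data.frame.
#' @param rois List of `roi` objects.
#' @param screen A [screen_geometry()] object.
#' @param center_px Central fixation point (defaults to the nose-ROI
#'   centroid).
#' @param velocity_threshold,min_fixation_ms,min_blink_ms,smooth_window
#'   Detection parameters; see [detect_fixations_ivt()], [detect_blinks()].
#' @param center_radius_deg Carried-over-fixation exclusion radius.
#' @param attribution Gaze-duration attribution mode.
#' @return List with `fixations`, `saccades`, `discarded`, `blinks`, `mask`
#'   and one-row data.frame `metrics`.
#' @export
analyze_trial <- function(stream, rois, screen, center_px = NULL,
                          velocity_threshold = 40, min_fixation_ms = 80,
                          min_blink_ms = 75, smooth_window = 0,
                          center_radius_deg = 1.0,
                          attribution = "centroid") {
  if (is.null(center_px)) {
    nose <- Filter(function(r) r$label == "nose", rois)
    center_px <- if (length(nose)) polygon_centroid(nose[[1]]) else c(0, 0)
  }
  ev <- detect_fixations_ivt(stream, screen, velocity_threshold,
                             min_fixation_ms, smooth_window)
  blinks <- detect_blinks(stream, min_blink_ms)
  fix <- assign_fixation_rois(ev$fixations, rois)
  mask <- net_gaze_mask(stream, fix)
  gaze <- gaze_durations(stream, mask, fix, rois, attribution)
  ent <- entry_stats(fix, rois, center_px, center_radius_deg, screen)
  counts <- fixation_counts(fix, rois)
  metrics <- data.frame(
    first_fix_roi = first_fixation_roi(fix, rois, center_px,
                                       center_radius_deg, screen),
    entered_eyes = ent$entered[["eyes"]],
    entered_nose = ent$entered[["nose"]],
    entered_mouth = ent$entered[["mouth"]],
    entry_eyes = ent$entry_time_ms[["eyes"]],
    entry_nose = ent$entry_time_ms[["nose"]],
    entry_mouth = ent$entry_time_ms[["mouth"]],
    gaze_eyes = gaze[["eyes"]], gaze_nose = gaze[["nose"]],
    gaze_mouth = gaze[["mouth"]], gaze_other = gaze[["other"]],
    nfix_eyes = counts[["eyes"]], nfix_nose = counts[["nose"]],
    nfix_mouth = counts[["mouth"]], nfix_other = counts[["other"]],
    coverage = coverage(gaze),
    net_ms = sum(mask) * sample_interval_ms(stream$t_ms),
    stringsAsFactors = FALSE)
  list(fixations = fix, saccades = ev$saccades, discarded = ev$discarded,
       blinks = blinks, mask = mask, metrics = metrics)
}

sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' By-items aggregation of trial metrics
#'
#' Averages the per-trial measures across participants for each stimulus:
#' first-fixation probabilities are shares among trials with a defined first
#' fixation (trials whose first fixation lands outside every region stay in
#' the denominator, so the three probabilities need not sum to 1); entry
#' probability is the share of trials entering the region; entry time is
#' averaged over entering trials only; gaze durations and fixation counts are
#' plain means with sample SDs.
#'
#' @param trial_metrics data.frame combining per-trial metrics rows with at
#'   least `stimulus_id`, `expression` and the columns produced by
#'   [analyze_trial()].
#' @return One row per stimulus (item norms).
#' @export
aggregate_by_items <- function(trial_metrics) {
  need <- c("stimulus_id", "expression", "first_fix_roi")
  if (!all(need %in% names(trial_metrics))) {
    stop("trial_metrics must include stimulus_id, expression and measures",
         call. = FALSE)
  }
  split_idx <- split(seq_len(nrow(trial_metrics)), trial_metrics$stimulus_id)
  rows <- lapply(names(split_idx), function(sid) {
    d <- trial_metrics[split_idx[[sid]], ]
    defined <- d$first_fix_roi != "none"
    n_def <- sum(defined)
    p_first <- vapply(roi_labels(), function(r)
      if (n_def) mean(d$first_fix_roi[defined] == r) else NA_real_,
      numeric(1))
    out <- data.frame(stimulus_id = sid, expression = d$expression[1],
                      n_trials = nrow(d), stringsAsFactors = FALSE)
    for (r in roi_labels()) {
      out[[paste0("p_first_", r)]] <- p_first[[r]]
      ent <- d[[paste0("entered_", r)]]
      out[[paste0("p_entry_", r)]] <- mean(ent)
      et <- d[[paste0("entry_", r)]][ent]
      out[[paste0("entry_time_", r)]] <- if (length(et)) mean(et) else NA_real_
      out[[paste0("entry_time_sd_", r)]] <- if (length(et)) sd0(et) else NA_real_
      out[[paste0("gaze_", r)]] <- mean(d[[paste0("gaze_", r)]])
      out[[paste0("gaze_sd_", r)]] <- sd0(d[[paste0("gaze_", r)]])
      out[[paste0("nfix_", r)]] <- mean(d[[paste0("nfix_", r)]])
      out[[paste0("nfix_sd_", r)]] <- sd0(d[[paste0("nfix_", r)]])
    }
    out$coverage <- mean(d$coverage, na.rm = TRUE)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
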