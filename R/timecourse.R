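# Time course of region gaze: 100-ms binning of net gaze and the threshold /
# amplitude of each expression's attentional advantage.

#' Bin net gaze into 100-ms proportions for one trial
#'
#' Splits the first `n_bins * bin_ms` milliseconds of the trial into
#' consecutive bins and computes, per region, the proportion of each bin
#' spent in net gaze on that region (denominator = bin length, so saccade
#' and blink time dilutes all regions equally). Samples beyond the last
#' complete bin -- the final 33 ms of a 1,033-ms trial -- are discarded.
#' Masked samples are attributed to the ROI of the owning fixation's
#' centroid (or their own position with `attribution = "sample"`).
#'
#' @param stream Gaze sample data.frame.
#' @param mask Net-gaze mask from [net_gaze_mask()].
#' @param fixations Retained fixations (with or without `roi`).
#' @param rois List of `roi` objects.
#' @param bin_ms Bin length (ms).
#' @param n_bins Number of complete bins required.
#' @param attribution `"centroid"` or `"sample"`.
#' @param trial_id Optional id used in error messages.
#' @return data.frame with columns `roi` (eyes, nose, mouth, other), `bin`
#'   (1..n_bins) and `proportion`.
#' @export
bin_gaze_proportions <- function(stream, mask, fixations, rois,
                                 bin_ms = 100, n_bins = 10,
                                 attribution = c("centroid", "sample"),
                                 trial_id = NULL) {
  attribution <- match.arg(attribution)
  validate_stream(stream)
  dt <- sample_interval_ms(stream$t_ms)
  span <- if (nrow(stream)) stream$t_ms[nrow(stream)] + dt else 0
  if (span < n_bins * bin_ms) {
    stop(sprintf("trial %stoo short for %d x %g-ms bins (spans %g ms)",
                 if (is.null(trial_id)) "" else paste0("'", trial_id, "' "),
                 n_bins, bin_ms, span), call. = FALSE)
  }
  labs <- roi_labels(with_other = TRUE)
  # per-sample ROI label for masked samples
  lab <- rep(NA_character_, nrow(stream))
  if (attribution == "sample") {
    lab[mask] <- assign_roi_points(stream$x_px[mask], stream$y_px[mask], rois)
  } else if (any(mask)) {
    if (!"roi" %in% names(fixations)) {
      fixations <- assign_fixation_rois(fixations, rois)
    }
    for (k in seq_len(nrow(fixations))) {
      sel <- mask & stream$t_ms >= fixations$onset_ms[k] &
        stream$t_ms < fixations$offset_ms[k]
      lab[sel] <- fixations$roi[k]
    }
  }
  bin <- floor(stream$t_ms / bin_ms) + 1L
  keep <- mask & !is.na(lab) & bin >= 1L & bin <= n_bins
  grid <- expand.grid(roi = labs, bin = seq_len(n_bins),
                      stringsAsFactors = FALSE)
  ms <- mapply(function(r, b) sum(keep & lab == r & bin == b) * dt,
               grid$roi, grid$bin)
  data.frame(roi = grid$roi, bin = grid$bin, proportion = ms / bin_ms,
             row.names = NULL)
}

#' By-items time-course table
#'
#' Averages per-trial binned proportions across participants for each
#' stimulus, giving one row per stimulus x region x bin.
#'
#' @param trial_bins data.frame stacking [bin_gaze_proportions()] outputs
#'   with added `stimulus_id` and `expression` columns.
#' @return data.frame `stimulus_id`, `expression`, `roi`, `bin`,
#'   `proportion`.
#' @export
timecourse_by_items <- function(trial_bins) {
  need <- c("stimulus_id", "expression", "roi", "bin", "proportion")
  if (!all(need %in% names(trial_bins))) {
    stop("trial_bins must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  agg <- stats::aggregate(
    proportion ~ stimulus_id + expression + roi + bin,
    data = trial_bins, FUN = mean)
  agg[order(agg$stimulus_id, agg$roi, agg$bin), , drop = FALSE]
}

#' Threshold and amplitude of an expression's attentional advantage
#'
#' For one region and target expression: in every bin a one-way by-items
#' ANOVA across expressions gates single-step Bonferroni pairwise contrasts
#' (pooled error term). The expression holds an advantage in a bin iff its
#' mean proportion exceeds, and differs significantly from, every expression
#' in `comparison_set`. The threshold is the earliest such bin; the
#' amplitude is the length of the maximal consecutive run of advantage bins
#' starting at the threshold. Later, disjoint advantage runs are reported in
#' `advantage_bins` but not merged into the amplitude.
#'
#' @param binned_items By-items table from [timecourse_by_items()].
#' @param expression Target expression.
#' @param roi Region to test.
#' @param comparison_set Expressions the target must beat (default: all
#'   others present in the data).
#' @param alpha Significance level.
#' @return List of class `advantage_profile`: `expression`, `roi`,
#'   `threshold_bin` (NA when no advantage), `amplitude_bins`,
#'   `advantage_bins`, `comparison_set`, and per-bin detail `bins`
#'   (data.frame with omnibus F/p and the advantage flag).
#' @export
advantage_profile <- function(binned_items, expression, roi,
                              comparison_set = NULL, alpha = 0.05) {
  d <- binned_items[binned_items$roi == roi, , drop = FALSE]
  exprs <- unique(d$expression)
  if (!expression %in% exprs) {
    stop("expression '", expression, "' absent from binned data",
         call. = FALSE)
  }
  if (is.null(comparison_set)) comparison_set <- setdiff(exprs, expression)
  comparison_set <- setdiff(comparison_set, expression)
  if (!length(comparison_set)) {
    stop("comparison_set must contain at least one other expression",
         call. = FALSE)
  }
  bins <- sort(unique(d$bin))
  detail <- data.frame(bin = bins, F = NA_real_, p = NA_real_,
                       advantage = FALSE)
  for (i in seq_along(bins)) {
    db <- d[d$bin == bins[i], , drop = FALSE]
    if (min(table(db$expression)) < 2) next
    a <- oneway_anova(db$proportion, db$expression)
    detail$F[i] <- a$F
    detail$p[i] <- a$p
    if (!is.na(a$p) && a$p < alpha) {
      ct <- bonferroni_pairwise(db$proportion, db$expression,
                                ms_error = a$ms_error,
                                df_error = a$df_error, alpha = alpha)
      beats <- vapply(comparison_set, function(cmp) {
        isTRUE(ct$means[[expression]] > ct$means[[cmp]]) &&
          isTRUE(ct$significant[expression, cmp])
      }, logical(1))
      detail$advantage[i] <- all(beats)
    }
  }
  adv <- detail$bin[detail$advantage]
  if (length(adv)) {
    thr <- adv[1]
    run <- 1L
    while (run < length(adv) && adv[run + 1L] == adv[run] + 1L) run <- run + 1L
    amp <- run
  } else {
    thr <- NA_integer_
    amp <- 0L
  }
  structure(list(expression = expression, roi = roi,
                 threshold_bin = thr, amplitude_bins = amp,
                 advantage_bins = adv, comparison_set = comparison_set,
                 alpha = alpha, bins = detail),
            class = "advantage_profile")
}

#' Advantage report over all expression x region pairs
#'
#' @param binned_items By-items table from [timecourse_by_items()].
#' @param alpha Significance level.
#' @return data.frame with one row per expression x region: threshold bin,
#'   amplitude and the comparison set beaten.
#' @export
advantage_report <- function(binned_items, alpha = 0.05) {
  exprs <- unique(binned_items$expression)
  rois_here <- intersect(roi_labels(), unique(binned_items$roi))
  rows <- list()
  for (r in rois_here) {
    for (e in exprs) {
      ap <- advantage_profile(binned_items, e, r, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        expression = e, roi = r, threshold_bin = ap$threshold_bin,
        amplitude_bins = ap$amplitude_bins,
        beaten = paste(ap$comparison_set, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
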