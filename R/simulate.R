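# Synthetic scanpath and categorization-response generator. Produces per-trial
# 500-Hz gaze streams with the statistical structure the analysis assumes:
# an initial fixation carried over from the central cross on the nose,
# alternating fixation plateaus and constant-velocity saccade ramps, optional
# blink dropouts, and multinomial categorization responses with per-expression
# reaction-time distributions.

#' Attention profile for one expression
#'
#' Dwell weights govern which region a new fixation targets; they may vary
#' over the trial by 100-ms segment. The first-target bias gives the landing
#' probabilities of the first saccade leaving the central fixation.
#'
#' @param expression Expression label.
#' @param dwell_weights Either a named nonnegative vector over
#'   `c("eyes","nose","mouth","other")` or a 4 x n_segments matrix with those
#'   rownames (one column per 100-ms segment).
#' @param first_target_bias Named probability vector over the same labels,
#'   summing to 1.
#' @param n_segments Number of 100-ms segments a vector weight is expanded to.
#' @return Object of class `attention_profile`.
#' @export
attention_profile <- function(expression, dwell_weights, first_target_bias,
                              n_segments = 10L) {
  labs <- roi_labels(with_other = TRUE)
  if (is.matrix(dwell_weights)) {
    w <- dwell_weights[labs, , drop = FALSE]
  } else {
    w <- matrix(dwell_weights[labs], nrow = 4, ncol = n_segments,
                dimnames = list(labs, NULL))
  }
  if (any(w < 0) || any(!is.finite(w))) {
    stop("dwell weights must be finite and nonnegative", call. = FALSE)
  }
  if (any(colSums(w) <= 0)) {
    stop("dwell weights must have positive sum in every segment",
         call. = FALSE)
  }
  b <- first_target_bias[labs]
  b[is.na(b)] <- 0
  if (abs(sum(b) - 1) > 1e-6) {
    stop("first_target_bias must sum to 1", call. = FALSE)
  }
  structure(list(expression = expression,
                 dwell_weights = sweep(w, 2, colSums(w), "/"),
                 first_target_bias = b / sum(b)),
            class = "attention_profile")
}

#' Default per-expression attention profiles
#'
#' Emulates the qualitative scanpath signature of each basic expression:
#' before `divergence_segment` all expressions share an eyes-leaning neutral
#' weighting (faces start neutral, so early gaze cannot differ by emotion);
#' from that segment on, weights become expression-specific -- mouth-heavy for
#' happiness, eyes-heavy for anger and sadness, nose/cheek-heavy for disgust,
#' and eyes/mouth-balanced for surprise and fear. About 3% of dwell weight
#' falls outside the three regions (forehead/chin). First-target biases favor
#' the eyes for every expression, least so for happiness where the mouth draws
#' a larger share of first saccades.
#'
#' @param divergence_segment First 100-ms segment (1-10) at which weights
#'   become expression-specific.
#' @return Named list of [attention_profile()] objects, one per expression.
#' @export
default_attention_profiles <- function(divergence_segment = 5L) {
  labs <- roi_labels(with_other = TRUE)
  early <- c(eyes = 0.45, nose = 0.33, mouth = 0.19, other = 0.03)
  late <- list(
    happiness = c(eyes = 0.26, nose = 0.27, mouth = 0.44, other = 0.03),
    surprise  = c(eyes = 0.42, nose = 0.26, mouth = 0.29, other = 0.03),
    anger     = c(eyes = 0.55, nose = 0.27, mouth = 0.15, other = 0.03),
    sadness   = c(eyes = 0.54, nose = 0.27, mouth = 0.16, other = 0.03),
    disgust   = c(eyes = 0.33, nose = 0.42, mouth = 0.22, other = 0.03),
    fear      = c(eyes = 0.43, nose = 0.25, mouth = 0.29, other = 0.03))
  bias <- list(
    happiness = c(eyes = 0.478, nose = 0.231, mouth = 0.236, other = 0.055),
    surprise  = c(eyes = 0.533, nose = 0.218, mouth = 0.189, other = 0.060),
    anger     = c(eyes = 0.548, nose = 0.229, mouth = 0.154, other = 0.069),
    sadness   = c(eyes = 0.542, nose = 0.240, mouth = 0.156, other = 0.062),
    disgust   = c(eyes = 0.516, nose = 0.245, mouth = 0.168, other = 0.071),
    fear      = c(eyes = 0.512, nose = 0.230, mouth = 0.193, other = 0.065))
  out <- lapply(expression_labels(), function(e) {
    w <- matrix(0, 4, 10, dimnames = list(labs, NULL))
    for (s in 1:10) {
      w[, s] <- if (s < divergence_segment) early[labs] else late[[e]][labs]
    }
    attention_profile(e, w, bias[[e]])
  })
  names(out) <- expression_labels()
  out
}

#' Simulation configuration
#'
#' Defaults mirror the recording conditions the pipeline targets: 500-Hz
#' sampling over a 1,033-ms clip, an initial gaze position on the nose carried
#' over from the 500-ms central fixation cross, log-normal fixation durations
#' with a median around 250 ms, 300 deg/s constant-velocity saccade ramps
#' (safely above the 40 deg/s detection threshold), and small within-fixation
#' positional noise whose per-sample increments are clipped so plateau
#' velocity stays well below threshold.
#'
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param trial_duration_ms Clip duration (ms).
#' @param fixation_meanlog,fixation_sdlog Log-normal fixation-duration
#'   parameters (log-ms).
#' @param initial_fixation_ms Mean residual duration of the carried-over
#'   central fixation (exponential with this mean, floored at 80 ms).
#' @param saccade_peak_velocity_deg_s Constant saccade speed (deg/s); must
#'   exceed 40.
#' @param blink_rate_per_trial Probability a trial contains one blink.
#' @param blink_duration_ms Length-2 range of blink durations (ms).
#' @param positional_noise_deg SD of per-sample noise increments (deg),
#'   clipped at 0.025 deg per axis.
#' @param min_saccade_amplitude_deg Smallest jump between successive fixation
#'   targets (deg); guarantees at least one above-threshold saccade sample.
#' @param center_start Optional pixel `c(x, y)` start position; defaults to
#'   the nose-region centroid.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate_hz = 500,
                              trial_duration_ms = 1033,
                              fixation_meanlog = log(250),
                              fixation_sdlog = 0.35,
                              initial_fixation_ms = 180,
                              saccade_peak_velocity_deg_s = 300,
                              blink_rate_per_trial = 0.1,
                              blink_duration_ms = c(75, 150),
                              positional_noise_deg = 0.01,
                              min_saccade_amplitude_deg = 0.5,
                              center_start = NULL) {
  if (saccade_peak_velocity_deg_s <= 40) {
    stop("saccade velocity must exceed the 40 deg/s detection threshold",
         call. = FALSE)
  }
  if (sampling_rate_hz <= 0 || trial_duration_ms <= 0) {
    stop("sampling rate and trial duration must be positive", call. = FALSE)
  }
  structure(list(
    sampling_rate_hz = sampling_rate_hz,
    trial_duration_ms = trial_duration_ms,
    fixation_meanlog = fixation_meanlog,
    fixation_sdlog = fixation_sdlog,
    initial_fixation_ms = initial_fixation_ms,
    saccade_peak_velocity_deg_s = saccade_peak_velocity_deg_s,
    blink_rate_per_trial = blink_rate_per_trial,
    blink_duration_ms = blink_duration_ms,
    positional_noise_deg = positional_noise_deg,
    min_saccade_amplitude_deg = min_saccade_amplitude_deg,
    center_start = center_start
  ), class = "simulation_config")
}

# Uniform point inside a polygon via rejection sampling from its bounding
# box, pulled 15% toward the centroid so positional noise cannot push the
# sample outside the region.
draw_point_in_roi <- function(poly) {
  cx <- mean(poly$x); cy <- mean(poly$y)
  for (i in 1:200) {
    px <- stats::runif(1, min(poly$x), max(poly$x))
    py <- stats::runif(1, min(poly$y), max(poly$y))
    if (point_in_polygon(px, py, poly)) {
      return(c(cx + 0.85 * (px - cx), cy + 0.85 * (py - cy)))
    }
  }
  c(cx, cy)
}

# A point in the uncovered forehead or chin strip of the face box.
draw_point_other <- function(rois, face_box) {
  top <- min(vapply(rois, function(r) min(r$y), numeric(1)))
  bottom <- max(vapply(rois, function(r) max(r$y), numeric(1)))
  x <- stats::runif(1, face_box[["x"]] + 0.25 * face_box[["width"]],
                    face_box[["x"]] + 0.75 * face_box[["width"]])
  if (stats::runif(1) < 0.5) {
    y <- stats::runif(1, face_box[["y"]] + 0.02 * face_box[["height"]],
                      max(top - 8, face_box[["y"]] + 0.03 * face_box[["height"]]))
  } else {
    y <- stats::runif(1, min(bottom + 8, face_box[["y"]] + 0.97 * face_box[["height"]]),
                      face_box[["y"]] + 0.98 * face_box[["height"]])
  }
  c(x, y)
}

#' Simulate one gaze stream
#'
#' Alternates fixation plateaus and constant-velocity saccade ramps. The
#' stream starts at `center_start` (gaze carried over from the fixation
#' cross); the first saccade target is drawn from the profile's first-target
#' bias, later targets from the segment-specific dwell weights at the time
#' the saccade is launched. Within plateaus, position is the target plus a
#' clipped random-walk noise whose central-difference velocity stays below
#' the 40 deg/s threshold; saccade ramps move at the configured constant
#' velocity, above it. With probability `blink_rate_per_trial` one run of
#' invalid samples (coordinates `NA`) is inserted. Identical seeds give
#' bitwise-identical streams.
#'
#' @param profile An [attention_profile()].
#' @param config A [simulation_config()].
#' @param rois List of `roi` objects.
#' @param screen A [screen_geometry()] object.
#' @param face_box Face bounding box (for "other" targets); defaults to the
#'   bounding box of the ROI set padded by 20%.
#' @param seed Optional integer seed.
#' @return data.frame with `t_ms`, `x_px`, `y_px`, `valid` (1/0).
#' @export
simulate_trial <- function(profile, config, rois, screen, face_box = NULL,
                           seed = NULL) {
  stopifnot(inherits(profile, "attention_profile"),
            inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(face_box)) {
    xs <- unlist(lapply(rois, `[[`, "x")); ys <- unlist(lapply(rois, `[[`, "y"))
    w <- diff(range(xs)); h <- diff(range(ys))
    face_box <- c(x = min(xs) - 0.1 * w, y = min(ys) - 0.25 * h,
                  width = 1.2 * w, height = 1.5 * h)
  }
  dpp <- degrees_per_pixel(screen)
  dpp_mean <- mean(dpp)
  dt <- 1000 / config$sampling_rate_hz
  n <- floor((config$trial_duration_ms - 1e-9) / dt) + 1L
  times <- (seq_len(n) - 1L) * dt
  labs_w <- rownames(profile$dwell_weights)
  n_seg <- ncol(profile$dwell_weights)

  roi_by_label <- list()
  for (r in rois) roi_by_label[[r$label]] <- r

  target_point <- function(lab) {
    if (lab == "other" || is.null(roi_by_label[[lab]])) {
      draw_point_other(rois, face_box)
    } else {
      draw_point_in_roi(roi_by_label[[lab]])
    }
  }
  center <- config$center_start
  if (is.null(center)) {
    center <- if (!is.null(roi_by_label$nose)) {
      polygon_centroid(roi_by_label$nose)
    } else {
      c(face_box[["x"]] + face_box[["width"]] / 2,
        face_box[["y"]] + face_box[["height"]] / 2)
    }
  }

  # times at which the dwell-weight schedule changes (e.g. the expression
  # becoming discriminable): an ongoing fixation is interrupted there and a
  # re-orienting saccade drawn under the new weights, so the programmed
  # divergence shows up in observed dwell at the programmed segment
  change_ms <- numeric(0)
  if (n_seg > 1) {
    for (s in 2:n_seg) {
      if (any(profile$dwell_weights[, s] != profile$dwell_weights[, s - 1])) {
        change_ms <- c(change_ms, (s - 1) * 100)
      }
    }
  }

  x <- numeric(n); y <- numeric(n)
  i <- 1L
  cur <- as.numeric(center)
  first_saccade <- TRUE
  # residual central fixation: gaze has already been on the cross 500 ms
  plateau_ms <- max(120, stats::rexp(1, 1 / config$initial_fixation_ms))

  fill_plateau <- function(i, target, k) {
    # clipped random-walk noise keeps within-plateau velocity < 40 deg/s
    sd_px <- config$positional_noise_deg / dpp_mean
    clip_px <- 0.025 / dpp_mean
    nx <- cumsum(pmin(pmax(stats::rnorm(k, 0, sd_px), -clip_px), clip_px))
    ny <- cumsum(pmin(pmax(stats::rnorm(k, 0, sd_px), -clip_px), clip_px))
    nx <- nx - mean(nx); ny <- ny - mean(ny)
    list(x = target[1] + nx, y = target[2] + ny)
  }

  while (i <= n) {
    k <- max(1L, round(plateau_ms / dt))
    k <- min(k, n - i + 1L)
    ahead <- change_ms[change_ms > times[i]]
    if (length(ahead)) {
      k_change <- floor((ahead[1] - times[i]) / dt)
      if (k_change >= 1L && k_change < k) k <- k_change
    }
    pl <- fill_plateau(i, cur, k)
    x[i:(i + k - 1L)] <- pl$x
    y[i:(i + k - 1L)] <- pl$y
    i <- i + k
    if (i > n) break
    # choose next target
    seg <- min(n_seg, floor(times[i] / 100) + 1L)
    prob <- if (first_saccade) profile$first_target_bias
            else profile$dwell_weights[, seg]
    first_saccade <- FALSE
    lab <- sample(labs_w, 1L, prob = prob)
    nxt <- target_point(lab)
    tries <- 0L
    while (sqrt(sum((nxt - cur)^2)) * dpp_mean <
             config$min_saccade_amplitude_deg && tries < 20L) {
      nxt <- target_point(lab)
      tries <- tries + 1L
    }
    if (sqrt(sum((nxt - cur)^2)) * dpp_mean < config$min_saccade_amplitude_deg) {
      # push radially away from current position to honor the minimum jump
      dir <- nxt - cur
      nrm <- sqrt(sum(dir^2))
      if (nrm < 1e-9) dir <- c(1, 0) else dir <- dir / nrm
      nxt <- cur + dir * config$min_saccade_amplitude_deg / dpp_mean
    }
    # constant-velocity ramp: one sample per v*dt degrees travelled
    dist_deg <- sqrt(sum((nxt - cur)^2)) * dpp_mean
    step_deg <- config$saccade_peak_velocity_deg_s * dt / 1000
    ks <- max(1L, floor(dist_deg / step_deg))
    ks <- min(ks, n - i + 1L)
    frac <- seq_len(ks) / (ks + 1L)
    x[i:(i + ks - 1L)] <- cur[1] + frac * (nxt[1] - cur[1])
    y[i:(i + ks - 1L)] <- cur[2] + frac * (nxt[2] - cur[2])
    i <- i + ks
    cur <- nxt
    plateau_ms <- stats::rlnorm(1, config$fixation_meanlog,
                                config$fixation_sdlog)
  }

  valid <- rep(1L, n)
  if (stats::runif(1) < config$blink_rate_per_trial) {
    len_ms <- stats::runif(1, config$blink_duration_ms[1],
                           config$blink_duration_ms[2])
    kb <- max(1L, round(len_ms / dt))
    start <- sample.int(max(1L, n - kb), 1L)
    valid[start:min(n, start + kb - 1L)] <- 0L
  }
  x[valid == 0L] <- NA_real_
  y[valid == 0L] <- NA_real_
  data.frame(t_ms = times, x_px = x, y_px = y, valid = valid)
}

#' Confusion model for categorization responses
#'
#' @param prob Row-stochastic 6 x 6 matrix (rows = stimulus expression,
#'   columns = response expression, dimnames required).
#' @param rt_location_ms,rt_scale_ms Named per-expression location and scale
#'   of the correct-response RT distribution (ms, measured from clip offset).
#' @return Object of class `confusion_model`.
#' @export
confusion_model <- function(prob, rt_location_ms, rt_scale_ms) {
  if (!is.matrix(prob) || nrow(prob) != ncol(prob) ||
      is.null(rownames(prob)) || is.null(colnames(prob))) {
    stop("prob must be a square matrix with dimnames", call. = FALSE)
  }
  if (any(prob < 0) || any(abs(rowSums(prob) - 1) > 1e-9)) {
    stop("prob rows must be nonnegative and sum to 1", call. = FALSE)
  }
  if (any(rt_location_ms[rownames(prob)] <= 0) ||
      any(rt_scale_ms[rownames(prob)] <= 0)) {
    stop("RT parameters must be positive for every expression", call. = FALSE)
  }
  structure(list(prob = prob,
                 rt_location_ms = rt_location_ms[rownames(prob)],
                 rt_scale_ms = rt_scale_ms[rownames(prob)]),
            class = "confusion_model")
}

#' Default confusion model from the packaged categorization norms
#'
#' Response probabilities and hit-RT parameters are taken from the packaged
#' norm tables ([load_categorization_norms()]); rows are renormalized to sum
#' exactly to 1 (the printed percentages carry rounding error).
#'
#' @return A [confusion_model()].
#' @export
default_confusion_model <- function() {
  norms <- load_categorization_norms()
  p <- norms$proportions / 100
  p <- sweep(p, 1, rowSums(p), "/")
  confusion_model(p, norms$hit_rt_ms, norms$hit_rt_sd)
}

#' Simulate one categorization response
#'
#' Response drawn from the expression's confusion-model row; RT drawn from a
#' log-normal with the configured median and coefficient of variation,
#' measured from clip offset.
#'
#' @param model A [confusion_model()].
#' @param expression Stimulus expression label.
#' @param seed Optional integer seed.
#' @return List with `response` (label) and `rt_ms`.
#' @export
simulate_response <- function(model, expression, seed = NULL) {
  stopifnot(inherits(model, "confusion_model"))
  if (!expression %in% rownames(model$prob)) {
    stop("no confusion-model row for expression '", expression, "'",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  resp <- sample(colnames(model$prob), 1L, prob = model$prob[expression, ])
  loc <- model$rt_location_ms[[expression]]
  cv <- model$rt_scale_ms[[expression]] / loc
  rt <- stats::rlnorm(1, meanlog = log(loc), sdlog = sqrt(log(1 + cv^2)))
  list(response = resp, rt_ms = rt)
}

# Deterministic per-trial seed below 2^31, stable under trial reordering.
derive_seed <- function(master, participant, trial) {
  (as.double(master) * 2654435761 + participant * 97561 + trial * 8191) %%
    2147483629
}

#' Simulate a full categorization experiment
#'
#' Every participant sees every registry entry exactly once, in an order
#' randomized per participant and partitioned into blocks of `block_size`
#' trials. Per-trial seeds are derived deterministically from the master
#' seed, participant and trial index, so the whole dataset is reproducible.
#'
#' @param n_participants Number of simulated observers.
#' @param registry Stimulus table from [stimulus_registry()].
#' @param profiles Named list of [attention_profile()]s covering every
#'   expression in the registry.
#' @param conf_model A [confusion_model()].
#' @param config A [simulation_config()].
#' @param rois,screen Geometry passed to [simulate_trial()].
#' @param seed Master seed (integer).
#' @param block_size Trials per block.
#' @return List with `streams` (named list of gaze data.frames, one per
#'   trial) and `trials` (metadata data.frame: trial_id, participant, block,
#'   trial_index, stimulus_id, model_id, expression, response, rt_ms,
#'   correct).
#' @export
simulate_experiment <- function(n_participants, registry, profiles,
                                conf_model, config, rois, screen,
                                seed = 1L, block_size = 40L) {
  missing_prof <- setdiff(unique(registry$expression), names(profiles))
  if (length(missing_prof)) {
    stop("no attention profile for expression(s): ",
         paste(missing_prof, collapse = ", "), call. = FALSE)
  }
  streams <- vector("list", n_participants * nrow(registry))
  ids <- character(length(streams))
  rows <- vector("list", length(streams))
  k <- 0L
  for (p in seq_len(n_participants)) {
    set.seed(as.integer(derive_seed(seed, p, 0L)))
    order_idx <- sample.int(nrow(registry))
    for (j in seq_along(order_idx)) {
      k <- k + 1L
      stim <- registry[order_idx[j], ]
      trial_seed <- derive_seed(seed, p, j)
      stream <- simulate_trial(profiles[[stim$expression]], config, rois,
                               screen, seed = trial_seed)
      resp <- simulate_response(conf_model, stim$expression)
      id <- sprintf("P%02d_T%03d", p, j)
      ids[k] <- id
      streams[[k]] <- stream
      rows[[k]] <- data.frame(
        trial_id = id, participant = p,
        block = ceiling(j / block_size), trial_index = j,
        stimulus_id = stim$stimulus_id, model_id = stim$model_id,
        expression = stim$expression, response = resp$response,
        rt_ms = resp$rt_ms,
        correct = as.integer(resp$response == stim$expression),
        stringsAsFactors = FALSE)
    }
  }
  names(streams) <- ids
  list(streams = streams, trials = do.call(rbind, rows))
}
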