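# Delimited-text gaze and trial formats, JSON run configuration, packaged
# categorization norms and the end-to-end pipeline.

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(",")
  if (grepl("\t", first)) "\t" else ","
}

#' Read a gaze sample file
#'
#' Comma- or tab-delimited (auto-detected) with header columns `trial_id`,
#' `t_ms`, `x_px`, `y_px`, `valid`. Invalid samples carry blank coordinates,
#' never sentinel values. Timestamps must be strictly increasing within each
#' trial.
#'
#' @param path File path.
#' @return Named list of per-trial gaze data.frames, in file order.
#' @export
read_gaze_file <- function(path) {
  if (!file.exists(path)) stop("gaze file not found: ", path, call. = FALSE)
  sep <- detect_delim(path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("trial_id", "t_ms", "x_px", "y_px", "valid")
  if (!all(need %in% names(d))) {
    stop("gaze file must have header columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d) == 0) return(stats::setNames(list(), character(0)))
  bad <- which(!is.finite(d$t_ms) | !d$valid %in% c(0, 1) |
                 (d$valid == 1 & (!is.finite(d$x_px) | !is.finite(d$y_px))))
  if (length(bad)) {
    stop("malformed gaze record at data line ", bad[1], call. = FALSE)
  }
  ids <- unique(d$trial_id)
  streams <- lapply(ids, function(id) {
    s <- d[d$trial_id == id, c("t_ms", "x_px", "y_px", "valid")]
    rownames(s) <- NULL
    if (nrow(s) > 1 && any(diff(s$t_ms) <= 0)) {
      stop("non-monotone timestamps in trial '", id, "'", call. = FALSE)
    }
    s
  })
  stats::setNames(streams, ids)
}

#' Write gaze streams to a delimited file
#'
#' @param streams Named list of gaze data.frames.
#' @param path Output path (written comma-delimited).
#' @export
write_gaze_file <- function(streams, path) {
  rows <- lapply(names(streams), function(id) {
    cbind(trial_id = id, streams[[id]])
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) {
    d <- data.frame(trial_id = character(0), t_ms = numeric(0),
                    x_px = numeric(0), y_px = numeric(0), valid = integer(0))
  }
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write trial metadata
#'
#' @param path File path.
#' @return data.frame of trial metadata.
#' @export
read_trials_file <- function(path) {
  if (!file.exists(path)) stop("trials file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = detect_delim(path),
                    stringsAsFactors = FALSE)
}

#' @rdname read_trials_file
#' @param trials data.frame to write (comma-delimited).
#' @export
write_trials_file <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Default run configuration
#'
#' Analysis defaults: 40 deg/s velocity threshold, 80-ms minimum fixation,
#' 75-ms blink criterion, no velocity smoothing, ten 100-ms bins, alpha
#' 0.05, 1-degree carried-over-fixation radius.
#'
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    screen = unclass(default_screen_geometry()),
    face_width_deg = 8.8, face_height_deg = 11.6,
    roi_layout = default_roi_layout(),
    velocity_threshold = 40, min_fixation_ms = 80, min_blink_ms = 75,
    smooth_window = 0, bin_ms = 100, n_bins = 10,
    center_radius_deg = 1.0, attribution = "centroid",
    alpha = 0.05, seed = 1L
  ), class = "run_config")
}

validate_run_config <- function(config) {
  pos <- c("velocity_threshold", "min_fixation_ms", "min_blink_ms",
           "bin_ms", "n_bins", "face_width_deg", "face_height_deg")
  for (p in pos) {
    if (is.null(config[[p]]) || !is.finite(config[[p]]) || config[[p]] <= 0) {
      stop("run config parameter '", p, "' must be positive", call. = FALSE)
    }
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!config$attribution %in% c("centroid", "sample")) {
    stop("attribution must be 'centroid' or 'sample'", call. = FALSE)
  }
  do.call(screen_geometry, config$screen)  # validates geometry
  invisible(config)
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config()
  for (nm in names(raw)) {
    if (nm == "roi_layout") {
      for (b in names(raw$roi_layout)) cfg$roi_layout[[b]] <- unlist(raw$roi_layout[[b]])
      names(cfg$roi_layout$eyes) <- names(cfg$roi_layout$nose) <-
        names(cfg$roi_layout$mouth) <- c("top", "bottom")
    } else if (nm == "screen") {
      cfg$screen <- as.list(unlist(raw$screen))
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config A `run_config` list.
#' @export
write_run_config <- function(config, path) {
  validate_run_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Geometry objects implied by a run config.
config_geometry <- function(config) {
  screen <- do.call(screen_geometry, config$screen)
  face_box <- face_box_for_angle(screen, config$face_width_deg,
                                 config$face_height_deg)
  rois <- build_default_rois(face_box, config$roi_layout)
  list(screen = screen, face_box = face_box, rois = rois)
}

#' Packaged categorization norm tables
#'
#' Loads the published mean confusion percentages, their SDs and the hit
#' reaction times for the six basic expressions from the package's plain-text
#' data files. An internal consistency check (matrix diagonal must equal the
#' hits column) guards against packaging corruption.
#'
#' @return List with `proportions` (6 x 6 matrix, %), `sd` (6 x 6, %),
#'   `hits` (%), `hits_sd`, `hit_rt_ms`, `hit_rt_sd` (named vectors).
#' @export
load_categorization_norms <- function() {
  dir <- system.file("extdata", package = "facegaze")
  mean_path <- file.path(dir, "categorization_norms_mean.csv")
  sd_path <- file.path(dir, "categorization_norms_sd.csv")
  rt_path <- file.path(dir, "categorization_hit_rt.csv")
  if (!file.exists(mean_path)) {
    stop("categorization norm fixtures missing from installation",
         call. = FALSE)
  }
  labs <- expression_labels()
  read_m <- function(p) {
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    m <- as.matrix(d[, labs])
    rownames(m) <- d$stimulus
    m[labs, labs]
  }
  m <- read_m(mean_path)
  s <- read_m(sd_path)
  rt <- utils::read.csv(rt_path, stringsAsFactors = FALSE)
  rownames(rt) <- rt$expression
  rt <- rt[labs, ]
  hits <- stats::setNames(diag(m), labs)
  if (any(abs(diag(m) - hits) > 1e-9) || any(m < 0) ||
      any(rt$rt_mean_ms <= 0)) {
    stop("categorization norms failed the packaging consistency check",
         call. = FALSE)
  }
  list(proportions = m, sd = s,
       hits = hits,
       hits_sd = stats::setNames(diag(s), labs),
       hit_rt_ms = stats::setNames(rt$rt_mean_ms, labs),
       hit_rt_sd = stats::setNames(rt$rt_sd_ms, labs))
}

#' Run the full gaze-analysis pipeline
#'
#' Reads (or accepts in memory) per-trial gaze streams and trial metadata,
#' runs event detection and all attention measures per trial, aggregates by
#' items, builds the by-items time-course table and advantage report, the
#' categorization tables, and by-items one-way ANOVAs with Bonferroni
#' contrasts and compact letter displays for each measure x region. All
#' stages are deterministic given inputs and configuration. When `out_dir`
#' is given, every table is written there as CSV together with a plain-text
#' log of parameters and counts.
#'
#' @param gaze Path to a gaze file or a named list of gaze data.frames.
#' @param trials Path to a trials file or a trial metadata data.frame
#'   (columns `trial_id`, `stimulus_id`, `expression`, and for
#'   categorization `response`, `rt_ms`).
#' @param config A `run_config` list; see [default_run_config()].
#' @param out_dir Optional output directory.
#' @return List of class `gaze_report`: `trial_metrics`, `item_norms`,
#'   `timecourse`, `advantage`, `confusion`, `hits`, `anova_tables`,
#'   `excluded`, `log`.
#' @export
run_pipeline <- function(gaze, trials, config = default_run_config(),
                         out_dir = NULL) {
  validate_run_config(config)
  log <- character(0)
  say <- function(...) {
    log <<- c(log, sprintf(...))
  }
  streams <- if (is.character(gaze)) read_gaze_file(gaze) else gaze
  trials <- if (is.character(trials)) read_trials_file(trials) else trials
  if (!all(c("trial_id", "stimulus_id", "expression") %in% names(trials))) {
    stop("stage trials-load failed: trials need trial_id, stimulus_id, expression",
         call. = FALSE)
  }
  geom <- config_geometry(config)
  say("parameters: velocity_threshold=%g deg/s, min_fixation_ms=%g, min_blink_ms=%g, bin_ms=%g x %d, alpha=%g",
      config$velocity_threshold, config$min_fixation_ms, config$min_blink_ms,
      config$bin_ms, config$n_bins, config$alpha)
  say("trials read: %d; gaze streams: %d", nrow(trials), length(streams))

  ids <- intersect(trials$trial_id, names(streams))
  excluded <- setdiff(trials$trial_id, ids)
  metrics_rows <- vector("list", length(ids))
  bin_rows <- vector("list", length(ids))
  n_fix_total <- 0L
  min_span <- config$n_bins * config$bin_ms
  center_px <- polygon_centroid(geom$rois$nose)
  for (k in seq_along(ids)) {
    id <- ids[k]
    stream <- streams[[id]]
    dt <- sample_interval_ms(stream$t_ms)
    span <- if (nrow(stream)) stream$t_ms[nrow(stream)] + dt else 0
    if (span < min_span) {
      excluded <- c(excluded, id)
      next
    }
    an <- analyze_trial(stream, geom$rois, geom$screen, center_px,
                        config$velocity_threshold, config$min_fixation_ms,
                        config$min_blink_ms, config$smooth_window,
                        config$center_radius_deg, config$attribution)
    n_fix_total <- n_fix_total + nrow(an$fixations)
    meta <- trials[trials$trial_id == id,
                   c("trial_id", "stimulus_id", "expression")]
    if ("participant" %in% names(trials)) {
      meta$participant <- trials$participant[trials$trial_id == id][1]
    }
    metrics_rows[[k]] <- cbind(meta, an$metrics)
    tb <- bin_gaze_proportions(stream, an$mask, an$fixations, geom$rois,
                               config$bin_ms, config$n_bins,
                               config$attribution, trial_id = id)
    bin_rows[[k]] <- cbind(stimulus_id = meta$stimulus_id[1],
                           expression = meta$expression[1], tb)
  }
  metrics_rows <- metrics_rows[!vapply(metrics_rows, is.null, logical(1))]
  bin_rows <- bin_rows[!vapply(bin_rows, is.null, logical(1))]
  if (!length(metrics_rows)) {
    stop("stage per-trial-analysis failed: no analyzable trials",
         call. = FALSE)
  }
  trial_metrics <- do.call(rbind, metrics_rows)
  say("trials analyzed: %d; excluded: %d; fixations detected: %d",
      nrow(trial_metrics), length(excluded), n_fix_total)

  item_norms <- aggregate_by_items(trial_metrics)
  binned <- timecourse_by_items(do.call(rbind, bin_rows))
  multi_expr <- length(unique(trial_metrics$expression)) >= 2
  enough <- all(table(item_norms$expression) >= 2)
  adv <- if (multi_expr && enough) {
    advantage_report(binned, alpha = config$alpha)
  } else NULL

  has_resp <- "response" %in% names(trials)
  confusion <- NULL; hits <- NULL
  if (has_resp) {
    resp <- trials[trials$trial_id %in% trial_metrics$trial_id, ]
    confusion <- confusion_matrix(resp)
    hits <- hits_and_rts(resp)
  }

  anova_tables <- NULL
  if (multi_expr && enough) {
    measures <- c("p_first", "p_entry", "gaze", "nfix")
    rows <- list()
    for (ms in measures) {
      for (r in roi_labels()) {
        col <- paste0(ms, "_", r)
        vals <- item_norms[[col]]
        keep <- !is.na(vals)
        if (sum(keep) < 4) next
        a <- oneway_anova(vals[keep], item_norms$expression[keep])
        ct <- bonferroni_pairwise(vals[keep], item_norms$expression[keep],
                                  a$ms_error, a$df_error, config$alpha)
        cld <- compact_letter_display(ct)
        means <- unlist(ct$means)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = ms, roi = r, expression = names(means),
          mean = unname(means), F = a$F, df_num = a$df_num,
          df_den = a$df_den, p = a$p, partial_eta_sq = a$partial_eta_sq,
          letters = unname(cld[names(means)]), stringsAsFactors = FALSE)
      }
    }
    anova_tables <- do.call(rbind, rows)
  }

  report <- structure(list(
    trial_metrics = trial_metrics, item_norms = item_norms,
    timecourse = binned, advantage = adv, confusion = confusion,
    hits = hits, anova_tables = anova_tables,
    excluded = excluded, log = log, config = config
  ), class = "gaze_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(trial_metrics,
                     file.path(out_dir, "trial_metrics.csv"), row.names = FALSE)
    utils::write.csv(item_norms,
                     file.path(out_dir, "item_norms.csv"), row.names = FALSE)
    utils::write.csv(binned,
                     file.path(out_dir, "timecourse_by_items.csv"),
                     row.names = FALSE)
    if (!is.null(adv)) {
      utils::write.csv(adv, file.path(out_dir, "advantage_report.csv"),
                       row.names = FALSE)
    }
    if (!is.null(confusion)) {
      utils::write.csv(as.data.frame(confusion$prop),
                       file.path(out_dir, "confusion_matrix.csv"))
      utils::write.csv(hits, file.path(out_dir, "hits_and_rts.csv"),
                       row.names = FALSE)
    }
    if (!is.null(anova_tables)) {
      utils::write.csv(anova_tables,
                       file.path(out_dir, "anova_letter_tables.csv"),
                       row.names = FALSE)
    }
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  report
}
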