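# Shared fixtures and independent oracles used across the suite. Oracles are
# written as plain per-sample / per-cell loops, independent of the package's
# vectorized implementations.

test_screen <- function() default_screen_geometry()

test_rois <- function(screen = test_screen()) {
  build_default_rois(face_box_for_angle(screen))
}

# Build a gaze stream from a position script: list of segments, each
# list(ms =, x =, y =) held constant, or list(ms =, from = c(x,y), to = c(x,y))
# ramped linearly. 2-ms sampling, all samples valid unless invalid_ms given.
script_stream <- function(..., dt = 2) {
  segs <- list(...)
  xs <- numeric(0); ys <- numeric(0)
  for (s in segs) {
    k <- round(s$ms / dt)
    if (!is.null(s$x)) {
      xs <- c(xs, rep(s$x, k)); ys <- c(ys, rep(s$y, k))
    } else {
      fr <- seq_len(k) / k
      xs <- c(xs, s$from[1] + fr * (s$to[1] - s$from[1]))
      ys <- c(ys, s$from[2] + fr * (s$to[2] - s$from[2]))
    }
  }
  data.frame(t_ms = (seq_along(xs) - 1) * dt, x_px = xs, y_px = ys,
             valid = 1L)
}

# Winding-angle point-in-polygon oracle (strict interior/exterior; callers
# avoid boundary points).
oracle_point_inside <- function(px, py, poly) {
  dx <- poly$x - px; dy <- poly$y - py
  n <- length(dx)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(dy[i], dx[i]); a2 <- atan2(dy[j], dx[j])
    da <- a2 - a1
    while (da > pi) da <- da - 2 * pi
    while (da < -pi) da <- da + 2 * pi
    total <- total + da
  }
  abs(total) > pi
}

# Per-sample angular speed oracle: explicit loop over samples.
oracle_velocity <- function(stream, screen) {
  dpp <- degrees_per_pixel(screen)
  n <- nrow(stream)
  v <- rep(NA_real_, n)
  ok <- stream$valid > 0
  for (i in seq_len(n)) {
    if (!ok[i]) next
    lo <- if (i == 1) i else i - 1
    hi <- if (i == n) i else i + 1
    if (lo == hi || !ok[lo] || !ok[hi]) next
    ddx <- (stream$x_px[hi] - stream$x_px[lo]) * dpp[["horizontal"]]
    ddy <- (stream$y_px[hi] - stream$y_px[lo]) * dpp[["vertical"]]
    v[i] <- sqrt(ddx^2 + ddy^2) / (stream$t_ms[hi] - stream$t_ms[lo]) * 1000
  }
  v
}

# Brute-force I-VT segmentation oracle: per-sample classification followed by
# a manual run scan (no rle), mirroring the detection contract.
oracle_segment <- function(stream, screen, threshold = 40, min_fix = 80) {
  n <- nrow(stream)
  dt <- if (n > 1) stats::median(diff(stream$t_ms)) else 2
  v <- oracle_velocity(stream, screen)
  cls <- character(n)
  for (i in seq_len(n)) {
    cls[i] <- if (stream$valid[i] <= 0) "invalid"
      else if (!is.na(v[i]) && v[i] > threshold) "saccade" else "fix"
  }
  fixations <- list(); saccades <- list(); discarded <- list()
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && cls[j + 1] == cls[i]) j <- j + 1
    onset <- stream$t_ms[i]; offset <- stream$t_ms[j] + dt
    ev <- data.frame(onset_ms = onset, offset_ms = offset,
                     duration_ms = offset - onset,
                     x_px = mean(stream$x_px[i:j]),
                     y_px = mean(stream$y_px[i:j]),
                     n_samples = j - i + 1)
    if (cls[i] == "fix") {
      if (ev$duration_ms >= min_fix) fixations[[length(fixations) + 1]] <- ev
      else discarded[[length(discarded) + 1]] <- ev
    } else if (cls[i] == "saccade") {
      saccades[[length(saccades) + 1]] <- ev
    }
    i <- j + 1
  }
  bind <- function(l) if (length(l)) do.call(rbind, l) else NULL
  list(fixations = bind(fixations), saccades = bind(saccades),
       discarded = bind(discarded))
}

# Explicit-loop one-way ANOVA sum-of-squares oracle.
oracle_oneway <- function(values, groups) {
  labs <- unique(groups)
  gm <- mean(values)
  ss_b <- 0; ss_e <- 0
  for (g in labs) {
    v <- values[groups == g]
    ss_b <- ss_b + length(v) * (mean(v) - gm)^2
    for (x in v) ss_e <- ss_e + (x - mean(v))^2
  }
  df_b <- length(labs) - 1
  df_e <- length(values) - length(labs)
  F <- (ss_b / df_b) / (ss_e / df_e)
  list(F = F, df_num = df_b, df_den = df_e,
       p = stats::pf(F, df_b, df_e, lower.tail = FALSE),
       partial_eta_sq = ss_b / (ss_b + ss_e))
}

# Explicit split-plot SS-decomposition oracle for a balanced design:
# items nested in `between`, crossed with `within`.
oracle_mixed <- function(d) {
  # d: data.frame(y, item, b, w)
  gm <- mean(d$y)
  items <- unique(d$item); bs <- unique(d$b); ws <- unique(d$w)
  n_w <- length(ws)
  item_mean <- sapply(items, function(it) mean(d$y[d$item == it]))
  names(item_mean) <- items
  item_b <- sapply(items, function(it) d$b[d$item == it][1])
  names(item_b) <- items
  b_mean <- sapply(bs, function(b) mean(d$y[d$b == b]))
  names(b_mean) <- bs
  w_mean <- sapply(ws, function(w) mean(d$y[d$w == w]))
  names(w_mean) <- ws
  ss_b <- 0
  for (b in bs) ss_b <- ss_b + sum(d$b == b) * (b_mean[[b]] - gm)^2
  ss_item_within_b <- 0
  for (it in items) {
    ss_item_within_b <- ss_item_within_b +
      n_w * (item_mean[[it]] - b_mean[[item_b[[it]]]])^2
  }
  ss_w <- 0
  for (w in ws) ss_w <- ss_w + sum(d$w == w) * (w_mean[[w]] - gm)^2
  ss_bw <- 0
  for (b in bs) {
    for (w in ws) {
      cell <- mean(d$y[d$b == b & d$w == w])
      ss_bw <- ss_bw + sum(d$b == b & d$w == w) *
        (cell - b_mean[[b]] - w_mean[[w]] + gm)^2
    }
  }
  ss_tot <- sum((d$y - gm)^2)
  ss_err_w <- ss_tot - ss_b - ss_item_within_b - ss_w - ss_bw
  df_b <- length(bs) - 1
  df_item <- length(items) - length(bs)
  df_w <- n_w - 1
  df_bw <- df_b * df_w
  df_err_w <- df_item * df_w
  list(
    between = list(F = (ss_b / df_b) / (ss_item_within_b / df_item),
                   pes = ss_b / (ss_b + ss_item_within_b)),
    within = list(F = (ss_w / df_w) / (ss_err_w / df_err_w),
                  pes = ss_w / (ss_w + ss_err_w)),
    interaction = list(F = (ss_bw / df_bw) / (ss_err_w / df_err_w),
                       pes = ss_bw / (ss_bw + ss_err_w)))
}

# Small simulated batch shared by several tests (built once per test run).
sim_batch <- local({
  cache <- NULL
  function(n = 60, expression = "happiness", seed0 = 500) {
    key <- paste(n, expression, seed0)
    if (!is.null(cache) && identical(attr(cache, "key"), key)) return(cache)
    screen <- test_screen(); rois <- test_rois(screen)
    prof <- default_attention_profiles()[[expression]]
    cfg <- simulation_config()
    out <- lapply(seq_len(n), function(i)
      simulate_trial(prof, cfg, rois, screen, seed = seed0 + i))
    attr(out, "key") <- key
    cache <<- out
    out
  }
})

# Exhaustive check of the letter-sharing-iff-non-significant property.
cld_property_holds <- function(cld, sig) {
  labs <- names(cld)
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i == j) next
      share <- length(intersect(strsplit(cld[[i]], "")[[1]],
                                strsplit(cld[[j]], "")[[1]])) > 0
      if (share == isTRUE(sig[labs[i], labs[j]])) return(FALSE)
    }
  }
  TRUE
}

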