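screen <- test_screen()
rois <- test_rois(screen)
center <- polygon_centroid(rois$nose)

fix_row <- function(onset, offset, x, y) {
  data.frame(onset_ms = onset, offset_ms = offset,
             duration_ms = offset - onset, x_px = x, y_px = y,
             n_samples = (offset - onset) / 2)
}

test_that("first fixation skips only the carried-over central fixation", {
  mouth_c <- polygon_centroid(rois$mouth)
  fx <- rbind(fix_row(0, 250, center[1], center[2]),
              fix_row(280, 500, mouth_c[1], mouth_c[2]))
  expect_equal(first_fixation_roi(fx, rois, center, 1.0, screen), "mouth")

  # only the center fixation in the trial -> none
  fx2 <- fix_row(0, 250, center[1], center[2])
  expect_equal(first_fixation_roi(fx2, rois, center, 1.0, screen), "none")

  # a nose landing beyond the 1-degree exclusion zone counts as a nose
  # first fixation (nose first-fixation probabilities can be nonzero)
  fx3 <- rbind(fix_row(0, 250, center[1], center[2]),
               fix_row(300, 450, center[1] + 60, center[2] + 40))
  expect_equal(first_fixation_roi(fx3, rois, center, 1.0, screen), "nose")

  expect_equal(first_fixation_roi(fx2[0, ], rois, center, 1.0, screen), "none")
})

test_that("entry flags and entry times per region", {
  mouth_c <- polygon_centroid(rois$mouth)
  fx <- rbind(fix_row(0, 250, center[1], center[2]),
              fix_row(320, 600, mouth_c[1], mouth_c[2]))
  es <- entry_stats(fx, rois, center, 1.0, screen)
  expect_true(es$entered[["mouth"]])
  expect_equal(es$entry_time_ms[["mouth"]], 320)
  expect_false(es$entered[["eyes"]])
  expect_true(is.na(es$entry_time_ms[["eyes"]]))
  # carried-over center fixation does not count as a nose entry
  expect_false(es$entered[["nose"]])
})

test_that("entry dominates first fixation on simulated batches", {
  streams <- sim_batch(60, "happiness", seed0 = 500)
  firsts <- character(0)
  entered <- matrix(FALSE, length(streams), 3,
                    dimnames = list(NULL, roi_labels()))
  for (i in seq_along(streams)) {
    an <- analyze_trial(streams[[i]], rois, screen)
    firsts <- c(firsts, an$metrics$first_fix_roi)
    entered[i, ] <- c(an$metrics$entered_eyes, an$metrics$entered_nose,
                      an$metrics$entered_mouth)
  }
  def <- firsts != "none"
  for (r in roi_labels()) {
    p_first <- mean(firsts[def] == r)
    p_entry <- mean(entered[def, r])
    expect_gte(p_entry, p_first)
  }
  # first-fixation shares over all labels sum to 1 among defined trials
  shares <- vapply(c(roi_labels(), "other"),
                   function(r) mean(firsts[def] == r), numeric(1))
  expect_equal(sum(shares), 1)
})

test_that("gaze durations, counts and coverage on constructed streams", {
  eyes_c <- polygon_centroid(rois$eyes)
  st <- script_stream(list(ms = 300, x = eyes_c[1], y = eyes_c[2]))
  ev <- detect_fixations_ivt(st, screen)
  mask <- net_gaze_mask(st, ev$fixations)
  g <- gaze_durations(st, mask, ev$fixations, rois)
  expect_equal(g[["eyes"]], 300)
  expect_equal(sum(g) - g[["eyes"]], 0)
  expect_equal(coverage(g), 1)

  # per-sample attribution agrees for a stream that never leaves the region
  gs <- gaze_durations(st, mask, ev$fixations, rois, attribution = "sample")
  expect_equal(gs, g)

  # half the net time on the forehead halves coverage
  top <- c(mean(rois$eyes$x), min(rois$eyes$y) - 40)
  st2 <- script_stream(
    list(ms = 300, x = eyes_c[1], y = eyes_c[2]),
    list(ms = 40, from = c(eyes_c[1], eyes_c[2]), to = top),
    list(ms = 300, x = top[1], y = top[2]))
  ev2 <- detect_fixations_ivt(st2, screen)
  mask2 <- net_gaze_mask(st2, ev2$fixations)
  g2 <- gaze_durations(st2, mask2, ev2$fixations, rois)
  expect_equal(coverage(g2), g2[["eyes"]] / (g2[["eyes"]] + g2[["other"]]))
  expect_equal(unname(g2[["eyes"]] / sum(g2)), 0.5, tolerance = 0.02)

  cnt <- fixation_counts(ev2$fixations, rois)
  expect_equal(cnt[["eyes"]], 1L)
  expect_equal(cnt[["other"]], 1L)
  expect_equal(fixation_counts(ev2$fixations[0, ], rois),
               c(eyes = 0L, nose = 0L, mouth = 0L, other = 0L))
  expect_true(is.na(coverage(c(eyes = 0, nose = 0, mouth = 0, other = 0))))
})

test_that("gaze time respects the 80-ms-per-fixation lower bound", {
  for (st in sim_batch(15, "anger", seed0 = 2600)) {
    an <- analyze_trial(st, rois, screen)
    cnt <- c(an$metrics$nfix_eyes, an$metrics$nfix_nose, an$metrics$nfix_mouth)
    gaze <- c(an$metrics$gaze_eyes, an$metrics$gaze_nose, an$metrics$gaze_mouth)
    expect_true(all(gaze >= 80 * cnt - 1e-9))
  }
})

test_that("conservation of gaze accounting through analyze_trial", {
  cfg <- simulation_config(blink_rate_per_trial = 0.4)
  prof <- default_attention_profiles()$surprise
  for (s in 1:10) {
    st <- simulate_trial(prof, cfg, rois, screen, seed = 2800 + s)
    an <- analyze_trial(st, rois, screen)
    g <- an$metrics
    roi_net <- g$gaze_eyes + g$gaze_nose + g$gaze_mouth + g$gaze_other
    sac <- sum(an$saccades$n_samples) * 2
    disc <- sum(an$discarded$n_samples) * 2
    inv <- sum(st$valid == 0) * 2
    expect_equal(roi_net + sac + disc + inv, nrow(st) * 2)
    expect_equal(roi_net, g$net_ms)
  }
})

test_that("by-items aggregation computes means, SDs and probabilities", {
  tm <- data.frame(
    stimulus_id = rep("S1", 2), expression = "anger", participant = 1:2,
    first_fix_roi = c("eyes", "mouth"),
    entered_eyes = c(TRUE, FALSE), entered_nose = c(FALSE, FALSE),
    entered_mouth = c(TRUE, TRUE),
    entry_eyes = c(150, NA), entry_nose = c(NA, NA),
    entry_mouth = c(300, 400),
    gaze_eyes = c(100, 200), gaze_nose = c(0, 0), gaze_mouth = c(300, 200),
    gaze_other = c(0, 0),
    nfix_eyes = c(1, 2), nfix_nose = c(0, 0), nfix_mouth = c(2, 1),
    nfix_other = c(0, 0), coverage = c(1, 1),
    stringsAsFactors = FALSE)
  it <- aggregate_by_items(tm)
  expect_equal(nrow(it), 1)
  expect_equal(it$gaze_eyes, 150)
  expect_equal(it$gaze_sd_eyes, sd(c(100, 200)))
  expect_equal(round(it$gaze_sd_eyes, 2), 70.71)
  expect_equal(it$p_first_eyes, 0.5)
  expect_equal(it$p_entry_eyes, 0.5)
  expect_equal(it$p_entry_mouth, 1)
  expect_equal(it$entry_time_mouth, 350)  # over entrants only
  expect_equal(it$entry_time_eyes, 150)
  # identical trials give zero SDs
  tm2 <- tm; tm2$gaze_eyes <- c(100, 100)
  expect_equal(aggregate_by_items(tm2)$gaze_sd_eyes, 0)
})
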