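screen <- test_screen()
rois <- test_rois(screen)

test_that("sample velocity: stationary, uniform-motion and oracle cases", {
  st <- script_stream(list(ms = 200, x = 500, y = 500))
  v <- sample_velocity(st, screen)
  expect_true(all(v == 0))

  # uniform motion of 0.08 deg per 2-ms sample = 40 deg/s
  dpp <- degrees_per_pixel(screen)
  step_px <- 0.08 / dpp[["horizontal"]]
  n <- 50
  st2 <- data.frame(t_ms = (0:(n - 1)) * 2,
                    x_px = (0:(n - 1)) * step_px, y_px = 100, valid = 1L)
  v2 <- sample_velocity(st2, screen)
  expect_equal(v2[2:(n - 1)], rep(40, n - 2), tolerance = 1e-9)

  # random streams match the per-sample oracle, including invalid gaps
  set.seed(5)
  for (rep in 1:20) {
    n <- 80
    st3 <- data.frame(t_ms = (0:(n - 1)) * 2,
                      x_px = cumsum(rnorm(n, 0, 4)) + 800,
                      y_px = cumsum(rnorm(n, 0, 4)) + 500,
                      valid = rbinom(n, 1, 0.9))
    st3$x_px[st3$valid == 0] <- NA
    st3$y_px[st3$valid == 0] <- NA
    expect_equal(sample_velocity(st3, screen), oracle_velocity(st3, screen),
                 tolerance = 1e-9)
  }
  expect_length(sample_velocity(st[0, ], screen), 0)
})

test_that("I-VT segments constructed streams as specified", {
  dpp <- mean(degrees_per_pixel(screen))
  jump <- 5 / dpp  # 5 degrees in pixels
  st <- script_stream(
    list(ms = 500, x = 800, y = 400),
    list(ms = 40, from = c(800, 400), to = c(800 + jump, 400)),
    list(ms = 460, x = 800 + jump, y = 400))
  ev <- detect_fixations_ivt(st, screen)
  expect_equal(nrow(ev$fixations), 2)
  expect_equal(nrow(ev$saccades), 1)
  expect_equal(nrow(ev$discarded), 0)
  expect_true(all(ev$fixations$duration_ms >= 80))

  # stationary 60-ms segment flanked by saccades is discarded
  st2 <- script_stream(
    list(ms = 200, x = 800, y = 400),
    list(ms = 40, from = c(800, 400), to = c(800 + jump, 400)),
    list(ms = 60, x = 800 + jump, y = 400),
    list(ms = 40, from = c(800 + jump, 400), to = c(800, 400)),
    list(ms = 200, x = 800, y = 400))
  ev2 <- detect_fixations_ivt(st2, screen)
  expect_equal(nrow(ev2$fixations), 2)
  expect_gt(nrow(ev2$discarded), 0)
  expect_true(all(ev2$discarded$duration_ms < 80))

  # empty and all-invalid streams yield empty event lists, not errors
  empty <- st[0, ]
  expect_equal(nrow(detect_fixations_ivt(empty, screen)$fixations), 0)
  allbad <- script_stream(list(ms = 100, x = 1, y = 1))
  allbad$valid <- 0L
  expect_equal(nrow(detect_fixations_ivt(allbad, screen)$fixations), 0)
})

test_that("I-VT segmentation equals the brute-force oracle on simulated streams", {
  streams <- sim_batch(40, "surprise", seed0 = 900)
  for (st in streams) {
    got <- detect_fixations_ivt(st, screen)
    want <- oracle_segment(st, screen)
    for (part in c("fixations", "saccades", "discarded")) {
      w <- want[[part]]
      g <- got[[part]]
      if (is.null(w)) {
        expect_equal(nrow(g), 0)
      } else {
        expect_equal(nrow(g), nrow(w))
        expect_equal(g$onset_ms, w$onset_ms)
        expect_equal(g$offset_ms, w$offset_ms)
        expect_equal(g$x_px, w$x_px, tolerance = 1e-9)
        expect_equal(g$y_px, w$y_px, tolerance = 1e-9)
      }
    }
  }
})

test_that("events never overlap and retained fixations respect the minimum duration", {
  for (st in sim_batch(20, "disgust", seed0 = 1200)) {
    ev <- detect_fixations_ivt(st, screen)
    all_ev <- rbind(ev$fixations[, 1:2], ev$saccades[, 1:2],
                    ev$discarded[, 1:2])
    all_ev <- all_ev[order(all_ev$onset_ms), ]
    if (nrow(all_ev) > 1) {
      expect_true(all(all_ev$onset_ms[-1] >= all_ev$offset_ms[-nrow(all_ev)] - 1e-9))
    }
    expect_true(all(ev$fixations$duration_ms >= 80))
  }
})

test_that("raising the velocity threshold never decreases fixation time", {
  for (st in sim_batch(10, "fear", seed0 = 1500)) {
    t20 <- sum(detect_fixations_ivt(st, screen, 20)$fixations$duration_ms)
    t40 <- sum(detect_fixations_ivt(st, screen, 40)$fixations$duration_ms)
    t80 <- sum(detect_fixations_ivt(st, screen, 80)$fixations$duration_ms)
    expect_lte(t20, t40 + 1e-9)
    expect_lte(t40, t80 + 1e-9)
  }
})

test_that("blink detection labels invalid runs by duration", {
  st <- script_stream(list(ms = 400, x = 800, y = 400))
  st$valid[51:100] <- 0L  # 100-ms invalid run
  st$x_px[st$valid == 0] <- NA; st$y_px[st$valid == 0] <- NA
  b <- detect_blinks(st)
  expect_equal(nrow(b), 1)
  expect_equal(b$type, "blink")
  expect_equal(b$duration_ms, 100)
  expect_equal(b$onset_ms, st$t_ms[51])

  st2 <- script_stream(list(ms = 400, x = 800, y = 400))
  st2$valid[51:55] <- 0L  # 10-ms dropout
  st2$x_px[st2$valid == 0] <- NA; st2$y_px[st2$valid == 0] <- NA
  b2 <- detect_blinks(st2)
  expect_equal(b2$type, "dropout")
  # excluded from net gaze regardless of label
  ev <- detect_fixations_ivt(st2, screen)
  mask <- net_gaze_mask(st2, ev$fixations)
  expect_true(all(!mask[st2$valid == 0]))

  expect_equal(nrow(detect_blinks(script_stream(list(ms = 100, x = 1, y = 1)))), 0)
})

test_that("net gaze mask and the time-conservation identity", {
  # single fixation: net gaze equals its duration
  st <- script_stream(list(ms = 300, x = 800, y = 400))
  ev <- detect_fixations_ivt(st, screen)
  mask <- net_gaze_mask(st, ev$fixations)
  expect_equal(sum(mask) * 2, 300)

  # conservation: fixation + discarded + saccade + invalid = total, exactly
  cfg <- simulation_config(blink_rate_per_trial = 0.5)
  prof <- default_attention_profiles()$happiness
  for (s in 1:25) {
    stm <- simulate_trial(prof, cfg, test_rois(screen), screen, seed = 4000 + s)
    evs <- detect_fixations_ivt(stm, screen)
    msk <- net_gaze_mask(stm, evs$fixations)
    n_fix <- sum(evs$fixations$n_samples)
    n_disc <- sum(evs$discarded$n_samples)
    n_sac <- sum(evs$saccades$n_samples)
    n_inv <- sum(stm$valid == 0)
    expect_equal(n_fix + n_disc + n_sac + n_inv, nrow(stm))
    expect_equal(sum(msk), n_fix)
  }

  # mismatched events are rejected
  bad <- ev$fixations
  bad$offset_ms <- bad$offset_ms + 1000
  expect_error(net_gaze_mask(st, bad), "beyond the stream")
})
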