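screen <- test_screen()
rois <- test_rois(screen)

test_that("binning splits net gaze into ten 100-ms proportions", {
  eyes_c <- polygon_centroid(rois$eyes)
  # eyes fixation spanning the whole 1,033-ms trial
  st <- script_stream(list(ms = 1034, x = eyes_c[1], y = eyes_c[2]))
  ev <- detect_fixations_ivt(st, screen)
  mask <- net_gaze_mask(st, ev$fixations)
  tb <- bin_gaze_proportions(st, mask, ev$fixations, rois)
  expect_equal(sort(unique(tb$bin)), 1:10)
  eyes_rows <- tb[tb$roi == "eyes", ]
  expect_equal(eyes_rows$proportion, rep(1, 10))
  expect_true(all(tb$proportion >= 0 & tb$proportion <= 1))
  # per bin, proportions over all labels sum to <= 1
  sums <- tapply(tb$proportion, tb$bin, sum)
  expect_true(all(sums <= 1 + 1e-9))
})

test_that("a fixation crossing a bin boundary is split proportionally", {
  mouth_c <- polygon_centroid(rois$mouth)
  n <- 600
  st <- data.frame(t_ms = (0:(n - 1)) * 2, x_px = unname(mouth_c[1]),
                   y_px = unname(mouth_c[2]), valid = 1L)
  fx <- data.frame(onset_ms = 50, offset_ms = 150, duration_ms = 100,
                   x_px = mouth_c[1], y_px = mouth_c[2], n_samples = 50)
  mask <- st$t_ms >= 50 & st$t_ms < 150
  tb <- bin_gaze_proportions(st, mask, fx, rois)
  expect_equal(tb$proportion[tb$roi == "mouth" & tb$bin == 1], 0.5)
  expect_equal(tb$proportion[tb$roi == "mouth" & tb$bin == 2], 0.5)
  expect_equal(sum(tb$proportion[tb$roi == "mouth"]), 1)
})

test_that("binned time equals net gaze within the first second (conservation)", {
  for (st in sim_batch(15, "fear", seed0 = 3200)) {
    ev <- detect_fixations_ivt(st, screen)
    mask <- net_gaze_mask(st, ev$fixations)
    tb <- bin_gaze_proportions(st, mask, ev$fixations, rois)
    binned_ms <- sum(tb$proportion) * 100
    expect_equal(binned_ms, sum(mask & st$t_ms < 1000) * 2)
  }
  # the final 33 ms are excluded: a sample at 1,010 ms contributes nothing
  eyes_c <- polygon_centroid(rois$eyes)
  st <- script_stream(list(ms = 1034, x = eyes_c[1], y = eyes_c[2]))
  ev <- detect_fixations_ivt(st, screen)
  mask <- net_gaze_mask(st, ev$fixations)
  late_only <- mask & st$t_ms >= 1000
  expect_gt(sum(late_only), 0)
  tb_all <- bin_gaze_proportions(st, mask, ev$fixations, rois)
  tb_trim <- bin_gaze_proportions(st, mask & st$t_ms < 1000, ev$fixations, rois)
  expect_equal(tb_all$proportion, tb_trim$proportion)
})

test_that("trials shorter than the binned window are rejected by name", {
  st <- script_stream(list(ms = 600, x = 800, y = 500))
  ev <- detect_fixations_ivt(st, screen)
  mask <- net_gaze_mask(st, ev$fixations)
  expect_error(
    bin_gaze_proportions(st, mask, ev$fixations, rois, trial_id = "T042"),
    "T042")
})

# Synthetic by-items table: `target` expression diverges upward from
# `diverge_bin` onward on the given roi; all expressions identical before.
make_binned_items <- function(n_items = 40, diverge_bin = 5, roi = "mouth",
                              target = "happiness", base = 0.20, high = 0.50,
                              sd = 0.05, seed = 42) {
  set.seed(seed)
  rows <- list()
  for (e in expression_labels()) {
    for (i in seq_len(n_items)) {
      for (b in 1:10) {
        mu <- if (e == target && b >= diverge_bin) high else base
        rows[[length(rows) + 1]] <- data.frame(
          stimulus_id = sprintf("%s_%02d", e, i), expression = e,
          roi = roi, bin = b,
          proportion = min(1, max(0, rnorm(1, mu, sd))))
      }
    }
  }
  do.call(rbind, rows)
}

test_that("advantage threshold and amplitude recover a programmed divergence", {
  bd <- make_binned_items(n_items = 40, diverge_bin = 5)
  ap <- advantage_profile(bd, "happiness", "mouth")
  expect_s3_class(ap, "advantage_profile")
  expect_equal(ap$threshold_bin, 5)
  expect_equal(ap$amplitude_bins, 6)
  expect_equal(ap$advantage_bins, 5:10)

  # oracle: per-bin pooled two-sample t-tests with Bonferroni over the 15
  # pairwise comparisons; the large programmed effect must be significant in
  # exactly bins 5..10
  others <- setdiff(expression_labels(), "happiness")
  for (b in 1:10) {
    db <- bd[bd$bin == b, ]
    sig_all <- all(vapply(others, function(o) {
      x <- db$proportion[db$expression == "happiness"]
      y <- db$proportion[db$expression == o]
      p <- t.test(x, y, var.equal = TRUE)$p.value * 15
      mean(x) > mean(y) && p < 0.05
    }, logical(1)))
    expect_equal(sig_all, b >= 5)
  }
})

test_that("no advantage when all expressions are exchangeable", {
  bd <- make_binned_items(n_items = 20, diverge_bin = 11)  # never diverges
  ap <- advantage_profile(bd, "happiness", "mouth")
  expect_true(is.na(ap$threshold_bin))
  expect_equal(ap$amplitude_bins, 0)
  expect_length(ap$advantage_bins, 0)
})

test_that("an isolated advantage bin yields amplitude 1", {
  bd <- make_binned_items(n_items = 30, diverge_bin = 7)
  bd$proportion[bd$expression == "happiness" & bd$bin >= 8] <- with(
    bd[bd$expression == "happiness" & bd$bin >= 8, ],
    pmin(1, pmax(0, rnorm(length(proportion), 0.20, 0.05))))
  ap <- advantage_profile(bd, "happiness", "mouth")
  expect_equal(ap$threshold_bin, 7)
  expect_equal(ap$amplitude_bins, 1)
})

test_that("shrinking the comparison set can only move the threshold earlier", {
  # surprise diverges at bin 4, happiness at bin 6, both above the rest
  bd <- make_binned_items(n_items = 30, diverge_bin = 6, seed = 9)
  sel <- bd$expression == "surprise" & bd$bin >= 4
  bd$proportion[sel] <- pmin(1, pmax(0, rnorm(sum(sel), 0.50, 0.05)))
  full <- advantage_profile(bd, "happiness", "mouth")
  partial <- advantage_profile(bd, "happiness", "mouth",
                               comparison_set = setdiff(
                                 expression_labels(),
                                 c("happiness", "surprise")))
  expect_true(is.na(full$threshold_bin) ||
                partial$threshold_bin <= full$threshold_bin)
  expect_false(is.na(partial$threshold_bin))
  expect_error(advantage_profile(bd, "happiness", "mouth",
                                 comparison_set = "happiness"),
               "comparison_set")
})
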