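# Image conditioning: background subtraction, segmentation, traces, Wiener
# filtering and Otsu-union masking.

test_that("background subtraction recovers the generator background", {
  # flat frame, no foreground -> all zeros
  flat <- structure(list(frames = array(7, c(1, 32, 32)), channel = "nadph",
                         condition_labels = "a", truth = NULL),
                    class = "frame_stack")
  out <- suppressWarnings(subtract_background(flat))
  expect_true(all(out$frames == 0))

  sc <- tiny_scene(15, seed = 21, background_level = 100)
  stk <- render_frames(sc, c("a", "b"), "nadph", challenged = c(FALSE, TRUE),
                       noise = FALSE)
  out <- subtract_background(stk)
  expect_equal(attr(out, "background_estimates"), c(100, 100), tolerance = 1e-6)

  # noisy time-course stacks: estimate within 100 +/- 1 over 10 replicates.
  # The below-percentile-of-max-projection selection is biased low for very
  # short stacks; over a 12-frame time course the bias is well under 1 AFU.
  ests <- vapply(1:10, function(i) {
    sc <- tiny_scene(15, seed = 100 + i, background_level = 100,
                     read_noise_sigma = 5, photon_gain = 0)
    stk <- render_frames(sc, sprintf("t%02d", 1:12), "nadph",
                         challenged = rep(FALSE, 12))
    mean(attr(subtract_background(stk), "background_estimates"))
  }, numeric(1))
  expect_true(all(abs(ests - 100) < 1))
})

test_that("segmentation finds well-separated spots with sub-pixel centroids", {
  sc <- tiny_scene(50, seed = 31, image_shape = c(192L, 192L))
  stk <- render_frames(sc, "a", "nadph", challenged = FALSE, noise = FALSE)
  stk <- subtract_background(stk)
  rois <- segment_mitochondria(stk$frames[1, , ])
  expect_equal(length(rois$pixels), 50)
  mt <- match_rois(rois, sc)
  expect_true(all(mt$dist < 0.5))
  # empty field
  expect_length(segment_mitochondria(matrix(0, 64, 64))$pixels, 0)
})

tiny_scene_snr <- function(seed) {
  # peak amplitude ~300 over read noise ~4 and shot noise: SNR >> 10
  build_scene(scene_config(image_shape = c(160L, 160L), n_mito = 40,
                           seed = seed, motility_amplitude = 0))
}

test_that("segmentation recall and precision reach 0.95 at high SNR", {
  scores <- vapply(1:10, function(i) {
    sc <- tiny_scene_snr(400 + i)
    stk <- render_frames(sc, "a", "nadph", challenged = FALSE)
    stk <- subtract_background(stk)
    rois <- segment_mitochondria(stk$frames[1, , ])
    unlist(detection_scores(rois, sc))
  }, numeric(2))
  expect_gte(mean(scores["recall", ]), 0.95)
  expect_gte(mean(scores["precision", ]), 0.95)
})

test_that("trace extraction is exact on constants and truthful on renders", {
  stk <- structure(list(frames = array(5, c(2, 16, 16)), channel = "nadph",
                        condition_labels = c("a", "b"), truth = NULL),
                   class = "frame_stack")
  lab <- matrix(0L, 16, 16); lab[3:5, 3:5] <- 1L; lab[10, 10] <- 2L
  rois <- structure(list(label_image = lab,
                         pixels = list(which(lab == 1L), which(lab == 2L)),
                         areas = c(9L, 1L),
                         centroids = data.frame(roi = 1:2, y = c(3, 9), x = c(3, 9))),
                    class = "roi_set")
  tr <- extract_traces(stk, rois)
  expect_true(all(tr == 5))
  # single-pixel ROI equals that pixel
  stk$frames[2, 10, 10] <- 42
  tr <- extract_traces(stk, rois)
  expect_equal(unname(tr[2, "b"]), 42)

  # noiseless render: trace ratios match truth within 1%
  sc <- tiny_scene(25, seed = 41)
  stk <- render_frames(sc, c("pre", "post"), "nadph",
                       challenged = c(FALSE, TRUE), noise = FALSE)
  stk <- subtract_background(stk)
  rois <- segment_mitochondria(stk$frames[1, , ])
  tr <- extract_traces(stk, rois)
  mt <- match_rois(rois, sc)
  truth_ratio <- 2^sc$mitochondria$nadph_log2_response[mt$nearest]
  expect_equal(unname(tr[, 2] / tr[, 1]), truth_ratio, tolerance = 0.01)
})

test_that("Wiener filtering reduces noise and preserves structure and mean", {
  const <- matrix(3.5, 32, 32)
  expect_equal(wiener_denoise(const), const)
  set.seed(5)
  noisy <- matrix(rnorm(64 * 64, 100, 10), 64, 64)
  out <- wiener_denoise(noisy)
  expect_lt(sd(out), 10)
  expect_equal(mean(out), mean(noisy), tolerance = 1e-3)
  expect_error(wiener_denoise(noisy, 4), "odd")
})

test_that("Otsu union mask keeps objects visible in either frame", {
  sc <- tiny_scene(20, seed = 51)
  stk <- render_frames(sc, c("a", "b"), "nadph", challenged = c(FALSE, FALSE),
                       noise = FALSE)
  f <- stk$frames[1, , ]
  # identical frames: union equals the single-frame mask
  single <- f > retquant:::otsu_threshold(f)
  expect_equal(otsu_union_mask(f, f), single)
  # a mitochondrion present only in `before` stays in the mask
  g <- f
  m <- sc$mitochondria
  yy <- round(m$y[1]) + 1; xx <- round(m$x[1]) + 1
  g[(yy - 5):(yy + 5), (xx - 5):(xx + 5)] <- sc$config$background_level
  u <- otsu_union_mask(f, g)
  expect_true(u[yy, xx])
  # noiseless scene: mask covers the spot cores (within 1 sigma of centers)
  cover <- vapply(seq_len(nrow(m)), function(i) {
    yy <- round(m$y[i]) + 1; xx <- round(m$x[i]) + 1
    mean(u[(yy - 1):(yy + 1), (xx - 1):(xx + 1)])
  }, numeric(1))
  expect_gte(mean(cover), 0.99)
  w <- capture_warnings(m0 <- otsu_union_mask(matrix(1, 8, 8), matrix(1, 8, 8)))
  expect_true(any(grepl("empty", w)))
  expect_false(any(m0))
})
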