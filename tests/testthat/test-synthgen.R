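# Synthetic generator: apportionment, determinism, rendering, noise model,
# motility and the plate simulator.

test_that("largest-remainder apportionment is exact and conserves totals", {
  expect_equal(unname(apportion_counts(c(fet_responder = 0.65, stalled = 0.30,
                                         ret = 0.05), 100)),
               c(65L, 30L, 5L))
  # the simulated-RET scenario: 4.2% of 1000
  expect_equal(unname(apportion_counts(c(a = 0.042, b = 0.958), 1000))[1], 42L)
  expect_equal(ceiling(0.064 * 500 - 1e-9), 32)
  set.seed(1)
  for (i in 1:20) {
    p <- runif(4); p <- p / sum(p)
    n <- sample(1:500, 1)
    expect_equal(sum(apportion_counts(p, n)), n)
  }
  expect_error(apportion_counts(c(0.6, 0.5), 10), "sum to 1")
})

test_that("identical config and seed reproduce scenes and frames bit-exactly", {
  cfg <- scene_config(n_mito = 40, seed = 123)
  s1 <- build_scene(cfg); s2 <- build_scene(cfg)
  expect_identical(s1, s2)
  f1 <- render_frames(s1, c("a", "b"), "nadph", challenged = c(FALSE, TRUE))
  f2 <- render_frames(s2, c("a", "b"), "nadph", challenged = c(FALSE, TRUE))
  expect_identical(f1$frames, f2$frames)
})

test_that("scene capacity and fraction validation fail loudly", {
  expect_error(build_scene(scene_config(image_shape = c(20L, 20L), n_mito = 20,
                                        seed = 1)),
               "capacity")
  expect_error(build_scene(scene_config(class_fractions = c(fet_responder = 0.5,
                                                            stalled = 0.4,
                                                            ret = 0, nonpolarizing = 0),
                                        seed = 1)),
               "sum to 1")
})

test_that("TMRM spot amplitudes follow the inverse Nernst readout", {
  cfg <- scene_config(image_shape = c(64L, 64L), n_mito = 1, seed = 2,
                      tmrm_potentials = list(a = c(mean = 0, sd = 0),
                                             b = c(mean = 61, sd = 0)))
  sc <- build_scene(cfg)
  stk <- render_frames(sc, c("a", "b"), channel = "tmrm", noise = FALSE)
  peak <- function(t) max(stk$frames[t, , ]) - cfg$background_level
  expect_equal(peak(2) / peak(1), 10, tolerance = 1e-10)
})

test_that("NAD(P)H challenge doubles the spot for a log2 response of 1", {
  cfg <- scene_config(image_shape = c(64L, 64L), n_mito = 1, seed = 3,
                      class_fractions = c(fet_responder = 1, stalled = 0,
                                          ret = 0, nonpolarizing = 0),
                      nadph_log2_response = list(fet_responder = c(mean = 1, sd = 0),
                                                 stalled = c(mean = 0, sd = 0),
                                                 ret = c(mean = -1, sd = 0),
                                                 nonpolarizing = c(mean = 0, sd = 0)))
  sc <- build_scene(cfg)
  stk <- render_frames(sc, c("pre", "post"), "nadph",
                       challenged = c(FALSE, TRUE), noise = FALSE)
  pk <- function(t) max(stk$frames[t, , ]) - cfg$background_level
  expect_equal(pk(2) / pk(1), 2, tolerance = 1e-10)
})

test_that("per-pixel noise variance matches read + scaled-Poisson model", {
  # flat field (no spots), 128x128 = 1.6e4 pixels
  cfg <- scene_config(image_shape = c(128L, 128L), n_mito = 1, seed = 4,
                      background_level = 200, read_noise_sigma = 5,
                      photon_gain = 2,
                      nadph_baseline_meanlog = log(1e-6), nadph_baseline_sdlog = 0)
  sc <- build_scene(cfg)
  stk <- render_frames(sc, "a", "nadph", challenged = FALSE)
  v <- var(as.vector(stk$frames[1, , ]))
  expect_equal(v, 5^2 + 2 * 200, tolerance = 0.1)
})

test_that("motility warps have the requested RMS and zero amplitude is identity", {
  sc <- tiny_scene(15, seed = 6)
  stk <- render_frames(sc, c("a", "b"), "nadph", challenged = c(FALSE, FALSE))
  expect_identical(apply_motility(stk, 0, 50), stk)
  warped <- apply_motility(stk, 2, 50, seed = 9)
  u <- warped$motility_fields[[2]]
  expect_equal(sqrt(mean(u$dy^2 + u$dx^2)), 2, tolerance = 0.1)
  expect_lt(cor(as.vector(stk$frames[2, , ]), as.vector(warped$frames[2, , ])), 1)
})

test_that("mask_fraction replaces the right number of mitochondria with background", {
  cfg <- scene_config(n_mito = 125, seed = 8, motility_amplitude = 0)
  stk <- render_frames(build_scene(cfg), c("a", "b"), "nadph",
                       challenged = c(FALSE, FALSE))
  expect_identical(mask_fraction(stk, 0), stk)
  out <- mask_fraction(stk, 0.064, seed = 3)
  expect_length(out$truth$masked_ids, ceiling(0.064 * 125 - 1e-9))  # 8
  m <- out$truth$mitochondria
  for (id in out$truth$masked_ids[1:3]) {
    yy <- round(m$y[id]) + 1; xx <- round(m$x[id]) + 1
    vals <- out$frames[2, (yy - 1):(yy + 1), (xx - 1):(xx + 1)]
    # masked core should sit at background, far below the original spot
    expect_lt(mean(vals), cfg$background_level + 5 * cfg$read_noise_sigma)
  }
  nomask <- stk$frames[2, , ]
  expect_error(mask_fraction(structure(list(frames = stk$frames, truth = NULL),
                                       class = "frame_stack"), 0.1),
               "ground truth")
})

test_that("plate simulator is exact in the noiseless limit", {
  wells <- data.frame(well = c("S1", "S2", "C1"),
                      role = c("sample", "sample", "calibration"),
                      condition = c("x", "ic50", "cal"),
                      true_h2o2_rate = c(10, NA, NA),
                      background_rate = c(0, 0, 0),
                      s1qel_concentration = c(NA, 150, NA))
  tr <- plate_truth(wells, calibration_spikes = c(100, 200),
                    spike_cycles = c(6, 12), calibration_slope = 3,
                    noise_sigma = 0)
  tab <- simulate_plate(tr)
  s1 <- tab[tab$well == "S1", ]
  expect_equal(unname(coef(lm(fluorescence_afu ~ I(seconds / 60), s1))[2]),
               3 * 10, tolerance = 1e-9)
  # 4PL midpoint at the IC50
  s2 <- tab[tab$well == "S2", ]
  r2 <- unname(coef(lm(fluorescence_afu ~ I(seconds / 60), s2))[2]) / 3
  expect_equal(r2, (100 + 20) / 2, tolerance = 1e-9)
  # calibration steps: 100 pmol at 3 AFU/pmol -> 300 AFU
  c1 <- tab[tab$well == "C1", ]
  expect_equal(c1$fluorescence_afu[6] - c1$fluorescence_afu[5], 300)
  expect_equal(c1$fluorescence_afu[12] - c1$fluorescence_afu[11], 600)
})

test_that("frame stacks survive a TIFF round trip within quantization", {
  sc <- tiny_scene(10, seed = 13)
  stk <- render_frames(sc, c("a", "b"), "nadph", challenged = c(FALSE, TRUE))
  path <- tempfile(fileext = ".tiff")
  write_frame_stack(stk, path)
  back <- read_frame_stack(path)
  expect_equal(back$condition_labels, stk$condition_labels)
  expect_equal(back$frames, stk$frames, tolerance = max(stk$frames) / 65535 * 2)
  unlink(c(path, paste0(path, ".json")))
})
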