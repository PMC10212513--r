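# Ground-truthed synthetic micrographs and plate-reader tables.
#
# The generator emulates the two imaging arms (isolated mitochondria on glass;
# punctate mitochondria inside cells) and the plate-reader resorufin assay, so
# every downstream stage can be exercised against known truth.

MITO_CLASSES <- c("fet_responder", "stalled", "ret", "nonpolarizing")

#' Scene configuration with study-condition defaults
#'
#' Returns the full parameter set describing one synthetic field of punctate
#' mitochondria. Defaults emulate the cell-arm conditions: a field of
#' diffraction-limited spots over a uniform background, with 74% of
#' mitochondria responding to the rotenone challenge by a mean 50% NAD(P)H
#' increase (log2-fold 0.585) and 26% stalled, additive Gaussian read noise
#' plus a scaled-Poisson shot term, and sub-pixel frame-to-frame motility.
#'
#' @param image_shape integer (rows, cols) of the field in pixels.
#' @param n_mito number of mitochondria to place.
#' @param class_fractions named fractions over
#'   `c("fet_responder", "stalled", "ret", "nonpolarizing")`; must sum to 1.
#' @param spot_sigma Gaussian spot sigma in pixels.
#' @param min_separation minimum center-to-center distance in pixels
#'   (default `4 * spot_sigma`).
#' @param background_level uniform background in arbitrary fluorescence
#'   units (AFU).
#' @param read_noise_sigma additive Gaussian read noise sigma (AFU).
#' @param photon_gain AFU per photon for the scaled-Poisson shot-noise term;
#'   0 disables it. Per-pixel variance is
#'   `read_noise_sigma^2 + photon_gain * mean`.
#' @param nadph_baseline_meanlog,nadph_baseline_sdlog log-normal parameters of
#'   per-mitochondrion NAD(P)H baseline peak amplitude (AFU).
#' @param nadph_log2_response named list per class of `c(mean, sd)` log2-fold
#'   NAD(P)H response to the challenge.
#' @param tmrm_brightness TMRM spot peak amplitude (AFU) at 0 mV relative
#'   potential.
#' @param tmrm_potentials named list per condition label of either a single
#'   `c(mean, sd)` pair (mV, applied to every class) or a named list per class
#'   of `c(mean, sd)`. `NULL` disables the TMRM channel.
#' @param motility_amplitude RMS displacement (px) of the smooth random warp
#'   applied between consecutive frames.
#' @param motility_correlation_length correlation length (px) of the warp
#'   field.
#' @param class_sampling `"largest_remainder"` (deterministic apportionment,
#'   so realized class counts are exact) or `"multinomial"` (each scene is an
#'   independent draw from the class distribution, as replicate fields of a
#'   real experiment are).
#' @param seed root seed; all randomness derives from named child streams.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(128L, 128L),
                         n_mito = 125L,
                         class_fractions = c(fet_responder = 0.74, stalled = 0.26,
                                             ret = 0, nonpolarizing = 0),
                         spot_sigma = 1.6,
                         min_separation = 4 * spot_sigma,
                         background_level = 15,
                         read_noise_sigma = 4,
                         photon_gain = 2,
                         nadph_baseline_meanlog = log(300),
                         nadph_baseline_sdlog = 0.25,
                         nadph_log2_response = list(
                           fet_responder = c(mean = log2(1.5), sd = 0.15),
                           stalled = c(mean = 0, sd = 0),
                           ret = c(mean = -0.8, sd = 0.2),
                           nonpolarizing = c(mean = 0, sd = 0)),
                         tmrm_brightness = 50,
                         tmrm_potentials = NULL,
                         motility_amplitude = 0.8,
                         motility_correlation_length = 24,
                         class_sampling = c("largest_remainder", "multinomial"),
                         seed = 1L) {
  class_sampling <- match.arg(class_sampling)
  cfg <- list(image_shape = as.integer(image_shape), n_mito = as.integer(n_mito),
              class_fractions = class_fractions, spot_sigma = spot_sigma,
              min_separation = min_separation, background_level = background_level,
              read_noise_sigma = read_noise_sigma, photon_gain = photon_gain,
              nadph_baseline_meanlog = nadph_baseline_meanlog,
              nadph_baseline_sdlog = nadph_baseline_sdlog,
              nadph_log2_response = nadph_log2_response,
              tmrm_brightness = tmrm_brightness, tmrm_potentials = tmrm_potentials,
              motility_amplitude = motility_amplitude,
              motility_correlation_length = motility_correlation_length,
              class_sampling = class_sampling,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

#' Deterministic largest-remainder apportionment of fractions over n
#'
#' @param fractions numeric vector summing to 1 (within 1e-9).
#' @param n total count to apportion.
#' @return integer vector of counts summing to `n`.
#' @export
apportion_counts <- function(fractions, n) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("class fractions must sum to 1 (got ", sum(fractions), ")")
  if (any(fractions < 0)) stop("class fractions must be non-negative")
  quota <- fractions * n
  base <- floor(quota + 1e-9)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- quota - base
    # ties broken by position, deterministically
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(fractions)
  counts
}

#' Build the ground truth of a synthetic field
#'
#' Places `n_mito` Gaussian spots by rejection sampling under a minimum
#' center-to-center separation, assigns responder classes by deterministic
#' largest-remainder apportionment of the class fractions, and draws
#' per-mitochondrion baselines, challenge responses and (optionally) relative
#' TMRM potentials.
#'
#' @param config a [scene_config()].
#' @return a list of class `scene_truth` with elements `config`,
#'   `mitochondria` (data frame: id, y, x in 0-based pixel-center coordinates,
#'   spot_sigma, class, nadph_baseline, nadph_log2_response) and
#'   `tmrm_potential` (mitochondria x condition matrix in mV, or NULL).
#' @export
build_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  fr <- config$class_fractions
  if (is.null(names(fr)) || !all(names(fr) %in% MITO_CLASSES))
    stop("class_fractions must be named with classes ",
         paste(MITO_CLASSES, collapse = ", "))
  counts <- if (identical(config$class_sampling, "multinomial")) {
    if (abs(sum(fr) - 1) > 1e-9)
      stop("class fractions must sum to 1 (got ", sum(fr), ")")
    cnt <- with_stream(config$seed, "classes",
                       as.vector(stats::rmultinom(1, config$n_mito, fr)))
    names(cnt) <- names(fr)
    cnt
  } else apportion_counts(fr, config$n_mito)
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  margin <- 3 * config$spot_sigma
  if (nr - 2 * margin <= 0 || nc - 2 * margin <= 0)
    stop("image too small for the spot size")

  pos <- with_stream(config$seed, "positions", {
    ys <- numeric(0); xs <- numeric(0)
    attempts <- 0L
    max_attempts <- 4000L * config$n_mito
    while (length(ys) < config$n_mito) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("capacity error: could not place ", config$n_mito,
             " mitochondria at min_separation ", config$min_separation)
      y <- runif(1, margin, nr - 1 - margin)
      x <- runif(1, margin, nc - 1 - margin)
      if (length(ys) == 0 ||
          min((ys - y)^2 + (xs - x)^2) >= config$min_separation^2) {
        ys <- c(ys, y); xs <- c(xs, x)
      }
    }
    cbind(ys, xs)
  })

  cls <- rep(names(counts), counts)
  baseline <- with_stream(config$seed, "baseline",
                          rlnorm(config$n_mito, config$nadph_baseline_meanlog,
                                 config$nadph_baseline_sdlog))
  resp <- with_stream(config$seed, "response", {
    out <- numeric(config$n_mito)
    for (k in names(counts)) {
      idx <- which(cls == k)
      pr <- config$nadph_log2_response[[k]]
      if (length(idx)) out[idx] <- rnorm(length(idx), pr[["mean"]], pr[["sd"]])
    }
    out
  })
  # enforce class sign contracts
  resp[cls == "fet_responder"] <- pmax(resp[cls == "fet_responder"], 0.05)
  resp[cls == "ret"] <- pmin(resp[cls == "ret"], -0.05)
  resp[cls %in% c("stalled", "nonpolarizing")] <- 0

  tmrm <- NULL
  if (!is.null(config$tmrm_potentials)) {
    conds <- names(config$tmrm_potentials)
    tmrm <- matrix(NA_real_, config$n_mito, length(conds),
                   dimnames = list(NULL, conds))
    tmrm[] <- with_stream(config$seed, "tmrm", {
      vals <- matrix(NA_real_, config$n_mito, length(conds))
      for (j in seq_along(conds)) {
        spec <- config$tmrm_potentials[[j]]
        if (is.list(spec)) {
          for (k in names(spec)) {
            idx <- which(cls == k)
            if (length(idx))
              vals[idx, j] <- rnorm(length(idx), spec[[k]][["mean"]], spec[[k]][["sd"]])
          }
        } else {
          vals[, j] <- rnorm(config$n_mito, spec[["mean"]], spec[["sd"]])
        }
      }
      vals
    })
  }

  mito <- data.frame(id = seq_len(config$n_mito),
                     y = pos[, 1], x = pos[, 2],
                     spot_sigma = config$spot_sigma,
                     class = cls,
                     nadph_baseline = baseline,
                     nadph_log2_response = resp,
                     stringsAsFactors = FALSE)
  structure(list(config = config, mitochondria = mito, tmrm_potential = tmrm,
                 class_counts = counts, masked_ids = integer(0)),
            class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("Synthetic scene:", nrow(x$mitochondria), "mitochondria on a",
      paste(x$config$image_shape, collapse = " x "), "field\n")
  print(x$class_counts)
  invisible(x)
}

## Render the noiseless signal image (no background) of a set of spots.
render_spots <- function(image_shape, y, x, sigma, amplitude) {
  nr <- image_shape[1]; nc <- image_shape[2]
  img <- matrix(0, nr, nc)
  w <- ceiling(4 * max(sigma))
  for (i in seq_along(y)) {
    # 0-based centers -> 1-based matrix indices
    cy <- y[i] + 1; cx <- x[i] + 1
    r0 <- max(1L, floor(cy - w)); r1 <- min(nr, ceiling(cy + w))
    c0 <- max(1L, floor(cx - w)); c1 <- min(nc, ceiling(cx + w))
    if (r0 > r1 || c0 > c1) next
    gy <- exp(-((r0:r1) - cy)^2 / (2 * sigma[i]^2))
    gx <- exp(-((c0:c1) - cx)^2 / (2 * sigma[i]^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amplitude[i] * outer(gy, gx)
  }
  img
}

add_noise <- function(mean_img, read_noise_sigma, photon_gain) {
  out <- mean_img
  if (photon_gain > 0)
    out <- photon_gain * matrix(rpois(length(mean_img), pmax(mean_img, 0) / photon_gain),
                                nrow(mean_img))
  if (read_noise_sigma > 0)
    out <- out + matrix(rnorm(length(mean_img), 0, read_noise_sigma), nrow(mean_img))
  out
}

#' Render a frame stack from a scene
#'
#' Each mitochondrion is an isotropic 2-D Gaussian spot. TMRM amplitudes scale
#' as `10^(potential / 61)` so the Nernst-slope readout recovers the assigned
#' relative potentials exactly in the noiseless limit; NAD(P)H amplitudes are
#' `baseline * 2^(log2_response)` in challenged frames. Background and noise
#' are added last; ground truth is carried on the stack.
#'
#' @param scene a [build_scene()] result.
#' @param conditions ordered condition labels. For the TMRM channel every
#'   label must be a column of the scene's potential matrix.
#' @param channel `"tmrm"` or `"nadph"`.
#' @param challenged logical vector along `conditions` (NAD(P)H channel):
#'   whether the challenge response applies in that frame. Defaults to all
#'   `FALSE`.
#' @param noise if `FALSE`, render noiseless frames (background still added).
#' @return a `frame_stack`: list with `frames` (T x rows x cols array),
#'   `channel`, `condition_labels`, `pixel_size_um`, and attached `truth`.
#' @export
render_frames <- function(scene, conditions, channel = c("nadph", "tmrm"),
                          challenged = NULL, noise = TRUE) {
  stopifnot(inherits(scene, "scene_truth"))
  channel <- match.arg(channel)
  cfg <- scene$config
  m <- scene$mitochondria
  if (channel == "tmrm") {
    if (is.null(scene$tmrm_potential))
      stop("scene has no TMRM potentials")
    missing <- setdiff(conditions, colnames(scene$tmrm_potential))
    if (length(missing))
      stop("conditions missing from tmrm_potential map: ",
           paste(missing, collapse = ", "))
  } else {
    if (is.null(challenged)) challenged <- rep(FALSE, length(conditions))
    if (length(challenged) != length(conditions))
      stop("challenged must match conditions in length")
  }
  nr <- cfg$image_shape[1]; nc <- cfg$image_shape[2]
  frames <- array(0, dim = c(length(conditions), nr, nc))
  for (t in seq_along(conditions)) {
    amp <- if (channel == "tmrm") {
      cfg$tmrm_brightness * 10^(scene$tmrm_potential[, conditions[t]] / 61)
    } else {
      m$nadph_baseline * 2^(m$nadph_log2_response * challenged[t])
    }
    sig <- render_spots(cfg$image_shape, m$y, m$x, m$spot_sigma, amp)
    mean_img <- sig + cfg$background_level
    frames[t, , ] <- if (noise) {
      with_stream(cfg$seed, paste0("noise:", channel, ":", t, ":", conditions[t]),
                  add_noise(mean_img, cfg$read_noise_sigma, cfg$photon_gain))
    } else mean_img
  }
  structure(list(frames = frames, channel = channel,
                 condition_labels = conditions,
                 pixel_size_um = 0.17,
                 truth = scene, motility_fields = NULL),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  cat("Frame stack (", x$channel, "): ", dim(x$frames)[1], " frame(s) of ",
      dim(x$frames)[2], " x ", dim(x$frames)[3], " px [",
      paste(x$condition_labels, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

## Smooth random displacement field with RMS displacement magnitude = amplitude.
random_displacement_field <- function(shape, amplitude, correlation_length) {
  uy <- gauss_blur_fft(matrix(rnorm(prod(shape)), shape[1], shape[2]),
                       correlation_length)
  ux <- gauss_blur_fft(matrix(rnorm(prod(shape)), shape[1], shape[2]),
                       correlation_length)
  rms <- sqrt(mean(uy^2 + ux^2))
  if (rms > 0) { uy <- uy * amplitude / rms; ux <- ux * amplitude / rms }
  list(dy = uy, dx = ux)
}

#' Apply smooth random motility to the post-baseline frames of a stack
#'
#' Frames after the first are warped by a smooth random displacement field
#' (pull semantics: output pixel samples the source at `pixel + displacement`)
#' whose RMS displacement magnitude equals `amplitude`. The true fields are
#' retained on the stack for registration-recovery tests.
#'
#' @param stack a `frame_stack`.
#' @param amplitude RMS displacement in px (0 = identity).
#' @param correlation_length correlation length of the field in px.
#' @param seed seed for the field draw (defaults to the scene seed).
#' @return the warped `frame_stack` with `motility_fields` attached.
#' @export
apply_motility <- function(stack, amplitude, correlation_length, seed = NULL) {
  stopifnot(inherits(stack, "frame_stack"), amplitude >= 0)
  if (amplitude == 0) return(stack)
  seed <- seed %||% stack$truth$config$seed
  nt <- dim(stack$frames)[1]
  shape <- dim(stack$frames)[2:3]
  fields <- vector("list", nt)
  Y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  X <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (t in seq_len(nt)[-1]) {
    f <- with_stream(seed, paste0("motility:", stack$channel, ":", t),
                     random_displacement_field(shape, amplitude, correlation_length))
    fields[[t]] <- f
    stack$frames[t, , ] <- bilinear_sample(stack$frames[t, , ], Y + f$dy, X + f$dx)
  }
  stack$motility_fields <- fields
  stack
}

#' Replace a random subset of mitochondria with background in one frame
#'
#' Emulates a simulated-RET control: a uniformly random subset of
#' `ceiling(fraction * N)` mitochondria has all pixels within `3 * spot_sigma`
#' of its center replaced by intensities sampled from the frame's own
#' off-mitochondrion background pixels. Masked ids are recorded on the truth.
#'
#' @param stack a `frame_stack` with attached truth.
#' @param fraction proportion of mitochondria to mask, in \[0, 1\].
#' @param seed seed for the subset draw (defaults to the scene seed).
#' @param frame index of the frame to modify (default: last).
#' @return the modified `frame_stack`; `stack$truth$masked_ids` lists the
#'   masked mitochondria.
#' @export
mask_fraction <- function(stack, fraction, seed = NULL,
                          frame = dim(stack$frames)[1]) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.null(stack$truth)) stop("stack has no attached ground truth")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (fraction == 0) return(stack)
  m <- stack$truth$mitochondria
  n_mask <- ceil_frac(fraction, nrow(m))
  seed <- seed %||% stack$truth$config$seed
  ids <- with_stream(seed, "mask_fraction", sample(m$id, n_mask))
  img <- stack$frames[frame, , ]
  nr <- nrow(img); nc <- ncol(img)
  Y <- matrix(seq_len(nr) - 1, nr, nc)
  X <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  # off-mitochondrion pool: farther than 4 sigma from every center
  bg_pool <- rep(TRUE, nr * nc)
  for (i in seq_len(nrow(m))) {
    d2 <- (Y - m$y[i])^2 + (X - m$x[i])^2
    bg_pool[d2 <= (4 * m$spot_sigma[i])^2] <- FALSE
  }
  pool_vals <- img[bg_pool]
  repl <- rep(FALSE, nr * nc)
  for (i in which(m$id %in% ids)) {
    d2 <- (Y - m$y[i])^2 + (X - m$x[i])^2
    repl[d2 <= (3 * m$spot_sigma[i])^2] <- TRUE
  }
  img[repl] <- with_stream(seed, "mask_fraction_bg",
                           sample(pool_vals, sum(repl), replace = TRUE))
  stack$frames[frame, , ] <- img
  stack$truth$masked_ids <- sort(ids)
  stack
}

#' Plate-reader ground truth
#'
#' Describes a synthetic resorufin-accumulation plate: per-well true hydrogen
#' peroxide release rates (optionally governed by a four-parameter logistic
#' curve over inhibitor concentration), cell-free background drift,
#' calibration wells with known H2O2 spike additions, cycle timing and noise.
#'
#' @param wells data frame with columns `well`, `role` (one of `sample`,
#'   `cell_free_background`, `calibration`, `vehicle`), `condition`,
#'   `true_h2o2_rate` (pmol/min; `NA` to derive from the 4PL curve),
#'   `background_rate` (AFU/min), `s1qel_concentration` (nM or `NA`).
#' @param calibration_spikes pmol amounts added stepwise to calibration wells.
#' @param spike_cycles cycle indices at which each spike lands.
#' @param calibration_slope AFU per pmol H2O2.
#' @param cycle_seconds,n_cycles cycle timing (defaults 80 s, 25 cycles).
#' @param noise_sigma additive Gaussian noise on each reading (AFU).
#' @param fourpl list `(top, bottom, ic50, hill)` governing rate (pmol/min)
#'   versus inhibitor concentration (nM).
#' @param baseline_afu fluorescence at time 0.
#' @param seed root seed.
#' @return list of class `plate_truth`.
#' @export
plate_truth <- function(wells, calibration_spikes = c(100, 100, 100),
                        spike_cycles = c(6, 12, 18),
                        calibration_slope = 3,
                        cycle_seconds = 80, n_cycles = 25L,
                        noise_sigma = 0, fourpl = list(top = 100, bottom = 20,
                                                       ic50 = 150, hill = 1.2),
                        baseline_afu = 500, seed = 1L) {
  stopifnot(is.data.frame(wells), n_cycles >= 19)
  if (fourpl$ic50 <= 0) stop("ic50 must be positive")
  if (any(wells$true_h2o2_rate < 0, na.rm = TRUE)) stop("rates must be >= 0")
  structure(list(wells = wells, calibration_spikes = calibration_spikes,
                 spike_cycles = spike_cycles, calibration_slope = calibration_slope,
                 cycle_seconds = cycle_seconds, n_cycles = as.integer(n_cycles),
                 noise_sigma = noise_sigma, fourpl = fourpl,
                 baseline_afu = baseline_afu, seed = as.integer(seed)),
            class = "plate_truth")
}

#' Evaluate a four-parameter logistic curve
#'
#' `bottom + (top - bottom) / (1 + (conc / ic50)^hill)`; at zero dose the
#' curve takes its `top` (hill > 0) or `bottom` (hill < 0) limit.
#'
#' @param conc concentrations (same units as `ic50`).
#' @param top,bottom,ic50,hill curve parameters.
#' @export
fourpl_curve <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Simulate a well-by-cycle plate-reader fluorescence table
#'
#' Sample and vehicle wells accumulate fluorescence linearly at
#' `calibration_slope * rate + background_rate`; calibration wells step by
#' `calibration_slope * spike` pmol at the configured cycles; Gaussian noise is
#' added to each reading.
#'
#' @param truth a [plate_truth()].
#' @return data frame: well, role, condition, s1qel_concentration, cycle,
#'   seconds, fluorescence_afu.
#' @export
simulate_plate <- function(truth) {
  stopifnot(inherits(truth, "plate_truth"))
  w <- truth$wells
  cyc <- seq_len(truth$n_cycles)
  secs <- (cyc - 1) * truth$cycle_seconds
  tmin <- secs / 60
  out <- vector("list", nrow(w))
  for (i in seq_len(nrow(w))) {
    role <- w$role[i]
    if (role == "calibration") {
      steps <- numeric(truth$n_cycles)
      for (j in seq_along(truth$calibration_spikes))
        steps[cyc >= truth$spike_cycles[j]] <- steps[cyc >= truth$spike_cycles[j]] +
          truth$calibration_spikes[j]
      trace <- truth$baseline_afu + truth$calibration_slope * steps
    } else {
      rate <- w$true_h2o2_rate[i]
      if (is.na(rate)) {
        conc <- w$s1qel_concentration[i]
        if (is.na(conc)) stop("well ", w$well[i], ": no rate and no concentration")
        rate <- fourpl_curve(conc, truth$fourpl$top, truth$fourpl$bottom,
                             truth$fourpl$ic50, truth$fourpl$hill)
      }
      bg <- if (is.null(w$background_rate)) 0 else w$background_rate[i]
      if (is.na(bg)) bg <- 0
      rate_eff <- if (role == "cell_free_background") 0 else rate
      trace <- truth$baseline_afu +
        (truth$calibration_slope * rate_eff + bg) * tmin
    }
    if (truth$noise_sigma > 0)
      trace <- trace + with_stream(truth$seed, paste0("well:", w$well[i]),
                                   rnorm(truth$n_cycles, 0, truth$noise_sigma))
    out[[i]] <- data.frame(well = w$well[i], role = role,
                           condition = w$condition[i] %||% NA,
                           s1qel_concentration = w$s1qel_concentration[i],
                           cycle = cyc, seconds = secs,
                           fluorescence_afu = trace,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a frame stack as multi-page 16-bit TIFF plus a truth sidecar
#'
#' @param stack a `frame_stack`.
#' @param path output TIFF path; truth is written to `<path>.json`.
#' @param max_afu full-scale intensity mapped to 65535.
#' @export
write_frame_stack <- function(stack, path, max_afu = NULL) {
  max_afu <- max_afu %||% max(stack$frames)
  pages <- lapply(seq_len(dim(stack$frames)[1]), function(t)
    pmin(pmax(stack$frames[t, , ] / max_afu, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channel = stack$channel, condition_labels = stack$condition_labels,
               pixel_size_um = stack$pixel_size_um, max_afu = max_afu)
  if (!is.null(stack$truth))
    meta$truth <- list(config = unclass(stack$truth$config),
                       mitochondria = stack$truth$mitochondria,
                       masked_ids = stack$truth$masked_ids)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(path)
}

#' Read a frame stack written by [write_frame_stack()]
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @export
read_frame_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]] * meta$max_afu
  structure(list(frames = frames, channel = meta$channel,
                 condition_labels = meta$condition_labels,
                 pixel_size_um = meta$pixel_size_um,
                 truth = NULL, motility_fields = NULL),
            class = "frame_stack")
}
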