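# End-to-end recovery experiments on synthetic data: the cell-arm
# reverse-transport fraction estimator and the glass-arm direction-call
# analysis, run against generator ground truth.

#' Simulate one cell-arm NAD(P)H frame pair
#'
#' Renders a baseline and a challenge frame for one synthetic cell field,
#' applies frame-to-frame motility, and (optionally) replaces a fraction of
#' mitochondria in the challenge frame with background (the simulated-RET
#' control). Mock pairs render the challenge frame without any response, so
#' the pair differs only by noise and motility.
#'
#' @param config a [scene_config()]; its seed identifies the cell.
#' @param treated if `FALSE`, a mock (vehicle) pair.
#' @param masked_fraction fraction of mitochondria masked to background in
#'   the challenge frame.
#' @return a `frame_stack` with 2 frames (baseline, challenge).
#' @export
simulate_cell_pair <- function(config, treated = TRUE, masked_fraction = 0) {
  scene <- build_scene(config)
  stack <- render_frames(scene, c("baseline", "challenge"), channel = "nadph",
                         challenged = c(FALSE, treated))
  if (config$motility_amplitude > 0)
    stack <- apply_motility(stack, config$motility_amplitude,
                            config$motility_correlation_length)
  if (masked_fraction > 0)
    stack <- mask_fraction(stack, masked_fraction)
  stack
}

#' Analyze one cell-arm frame pair to a masked log2-fold histogram
#'
#' The per-cell analysis chain: Wiener denoising, B-spline deformable
#' registration of the challenge frame onto the baseline with Pearson QC,
#' Otsu-union mitochondrial masking, modal intensity rescale, and pixelwise
#' log2-fold histogramming.
#'
#' @param stack a 2-frame `frame_stack` (baseline, challenge).
#' @param wiener_kernel_px Wiener window (odd px).
#' @param grid_spacing_px,levels registration controls.
#' @param qc_threshold Pearson acceptance threshold.
#' @param bin_width,eps histogram controls.
#' @param source,cell_id passed to the histogram.
#' @return a `logfold_histogram`, or `NULL` when registration fails QC
#'   (attribute `"pearson"` carries the correlation either way).
#' @export
analyze_cell_pair <- function(stack, wiener_kernel_px = 5,
                              grid_spacing_px = 16, levels = 3,
                              qc_threshold = 0.6, bin_width = 0.05, eps = 1,
                              source = "treated", cell_id = NULL) {
  before <- wiener_denoise(stack$frames[1, , ], wiener_kernel_px)
  after <- wiener_denoise(stack$frames[2, , ], wiener_kernel_px)
  reg <- register_deformable(before, after, grid_spacing_px = grid_spacing_px,
                             levels = levels, qc_threshold = qc_threshold)
  reg <- qc_registration(reg, qc_threshold)
  if (!reg$accepted) {
    out <- NULL
    attr(out, "pearson") <- reg$pearson_after
    return(out)
  }
  warped <- reg$warped_frame
  mask <- otsu_union_mask(before, warped)
  sc <- rescale_pair(before, warped, mask, bin_width = bin_width, eps = eps)
  h <- pixel_log2fold(sc$before, sc$after, mask, eps = eps,
                      bin_width = bin_width, source = source, cell_id = cell_id)
  attr(h, "pearson") <- reg$pearson_after
  h
}

#' Reverse-transport fraction recovery experiment (cell arm)
#'
#' Generates mock cells to calibrate the null spread of log2-fold pixel
#' changes, then treated cells (a responsive population with an optional
#' fraction of mitochondria masked to background in the challenge frame),
#' runs the full per-cell chain, fits the constrained two-component mixture
#' per cell, and pools the excess-pixel-count oxidised fractions.
#'
#' @param n_cells number of treated cells.
#' @param n_mock number of mock (vehicle) cells pooled for the null fit.
#' @param masked_fraction fraction of mitochondria masked to background.
#' @param seed root seed.
#' @param config base [scene_config()] (per-cell seeds are derived from
#'   `seed`).
#' @param k sigma multiple of the excess-count threshold.
#' @param bin_width histogram bin width.
#' @param treated if `FALSE`, the analyzed cells are themselves mock pairs
#'   (independent of the null-calibration set): the false-positive control,
#'   whose pooled estimate measures the method's null calibration.
#' @return list of class `ret_experiment`: `pooled`
#'   (a `ret_fraction_pooled`), `null` (the mock `null_fit`), `n_used`,
#'   `n_rejected`, `masked_fraction`.
#' @export
ret_fraction_experiment <- function(n_cells = 100, n_mock = 20,
                                    masked_fraction = 0.064, seed = 1,
                                    config = scene_config(), k = 2,
                                    bin_width = 0.05, treated = TRUE) {
  mock_vals <- vector("list", n_mock)
  for (i in seq_len(n_mock)) {
    cfg <- config
    cfg$seed <- stream_seed(seed, paste0("mockcell:", i))
    stk <- simulate_cell_pair(cfg, treated = FALSE)
    h <- analyze_cell_pair(stk, bin_width = bin_width, source = "mock",
                           cell_id = paste0("mock", i))
    if (!is.null(h)) mock_vals[[i]] <- h$values
  }
  mock_hist <- logfold_histogram(unlist(mock_vals), bin_width = bin_width,
                                 source = "mock")
  null <- fit_null(mock_hist)

  fracs <- numeric(0)
  n_rejected <- 0L
  for (i in seq_len(n_cells)) {
    cfg <- config
    cfg$seed <- stream_seed(seed, paste0("cell:", i))
    stk <- simulate_cell_pair(cfg, treated = treated,
                              masked_fraction = if (treated) masked_fraction else 0)
    h <- analyze_cell_pair(stk, bin_width = bin_width,
                           source = if (treated) "treated" else "mock",
                           cell_id = i)
    if (is.null(h)) { n_rejected <- n_rejected + 1L; next }
    fit <- fit_two_normals(h, null$sigma0)
    est <- excess_oxidised_fraction(h, fit, null, k = k)
    fracs <- c(fracs, est$fraction)
  }
  structure(list(pooled = pool_ret_fraction(fracs), null = null,
                 mock_hist = mock_hist, n_used = length(fracs),
                 n_rejected = n_rejected, masked_fraction = masked_fraction),
            class = "ret_experiment")
}

#' @export
print.ret_experiment <- function(x, ...) {
  cat(sprintf("Simulated-RET recovery: true masked fraction %.1f%%\n",
              100 * x$masked_fraction))
  print(x$pooled)
  cat(sprintf("  null: sigma0 = %.3f over %d mock pixels; %d cell(s) rejected by QC\n",
              x$null$sigma0, x$mock_hist$n_pixels, x$n_rejected))
  invisible(x)
}

#' Glass-arm configuration defaults
#'
#' Study conditions of the isolated-mitochondria (glass) arm: a larger field
#' of immobilised mitochondria with the forward/stalled/reverse class mix of
#' the rotenone-challenge experiment.
#'
#' @param n_mito mitochondria per field.
#' @param class_fractions class mix (defaults: 65% forward responders, 30.8%
#'   stalled, 4.2% reverse).
#' @param seed root seed.
#' @param ... overrides passed to [scene_config()].
#' @export
glass_config <- function(n_mito = 150L,
                         class_fractions = c(fet_responder = 0.65,
                                             stalled = 0.308, ret = 0.042,
                                             nonpolarizing = 0),
                         seed = 1L, ...) {
  scene_config(image_shape = c(256L, 256L), n_mito = n_mito,
               class_fractions = class_fractions,
               motility_amplitude = 0, class_sampling = "multinomial",
               seed = seed, ...)
}

#' Direction-call recovery experiment (glass arm)
#'
#' For each replicate field: render 3 baseline and 3 post-challenge NAD(P)H
#' frames, subtract background, segment single mitochondria on the first
#' baseline frame, extract traces, form population-normalized per-object
#' log2-fold changes, derive the call threshold from the scatter of the
#' repeated post-challenge determinations, and call each object
#' forward/stalled/reverse. Fractions are summarized as mean +/- SE across
#' fields.
#'
#' @param n_fields replicate fields.
#' @param seed root seed.
#' @param config base [glass_config()].
#' @param c_mult threshold multiple (default 2).
#' @return list of class `direction_experiment`: `calls`
#'   (a `direction_calls`), `truth` (generator fractions), `n_objects`.
#' @export
direction_experiment <- function(n_fields = 4, seed = 1,
                                 config = glass_config(), c_mult = 2) {
  delta_all <- numeric(0); reps_all <- integer(0)
  thr_all <- numeric(0)
  for (f in seq_len(n_fields)) {
    cfg <- config
    cfg$seed <- stream_seed(seed, paste0("field:", f))
    scene <- build_scene(cfg)
    conds <- c("pre1", "pre2", "pre3", "post1", "post2", "post3")
    stk <- render_frames(scene, conds, channel = "nadph",
                         challenged = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
    stk <- subtract_background(stk)
    rois <- segment_mitochondria(stk$frames[1, , ],
                                 log_sigma = cfg$spot_sigma)
    tr <- extract_traces(stk, rois)
    pre <- rowMeans(tr[, 1:3, drop = FALSE])
    post <- tr[, 4:6, drop = FALSE]
    popmean <- mean(pre)
    delta <- per_mito_dnadh(rowMeans(post) - pre, popmean)
    post_rep <- apply(post, 2, function(col) per_mito_dnadh(col - pre, popmean))
    # per-replicate threshold, as each field is analyzed as one experiment
    fcall <- classify_direction(delta, post_repeats = post_rep, c_mult = c_mult)
    delta_all <- c(delta_all, delta)
    reps_all <- c(reps_all, rep(f, length(delta)))
    thr_all <- c(thr_all, fcall$threshold)
  }
  thr_obj <- thr_all[reps_all]
  call_vec <- ifelse(delta_all > thr_obj, "fet",
                     ifelse(delta_all < -thr_obj, "ret", "stalled"))
  calls <- classify_direction(delta_all,
                              threshold = mean(thr_all),
                              replicate = reps_all)
  # overwrite with the per-field-threshold calls and refresh the summary
  calls$calls$call <- factor(call_vec, levels = levels(calls$calls$call))
  for (f in seq_len(n_fields)) {
    sub <- calls$calls$call[reps_all == f]
    calls$per_replicate[f, ] <- as.numeric(table(sub)[colnames(calls$per_replicate)]) /
      length(sub)
  }
  calls$fractions$mean <- colMeans(calls$per_replicate)
  calls$fractions$se <- apply(calls$per_replicate, 2, stats::sd) / sqrt(n_fields)
  calls$threshold <- thr_all
  fr <- config$class_fractions
  truth <- c(fet = unname(fr["fet_responder"]),
             stalled = unname(fr["stalled"] + fr["nonpolarizing"]),
             ret = unname(fr["ret"]))
  structure(list(calls = calls, truth = truth,
                 n_objects = length(delta_all), n_fields = n_fields),
            class = "direction_experiment")
}

#' @export
print.direction_experiment <- function(x, ...) {
  cat(sprintf("Direction-call recovery over %d field(s), %d objects\n",
              x$n_fields, x$n_objects))
  s <- x$calls$fractions
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s truth %5.1f%%  estimated %5.1f%%%s\n", s$call[i],
                100 * x$truth[[as.character(s$call[i])]], 100 * s$mean[i],
                if (is.na(s$se[i])) "" else sprintf(" +/- %.1f%%", 100 * s$se[i])))
  invisible(x)
}
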