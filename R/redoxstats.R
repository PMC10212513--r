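# Pixelwise and per-object NAD(P)H log2-fold analysis: mock-calibrated null
# fitting, constrained two-component mixture fitting, the excess-pixel-count
# estimator of the reverse-transport fraction, and per-object direction
# calls.

#' Histogram of log2-fold values at a fixed bin width
#'
#' @param values log2-fold values.
#' @param bin_width uniform bin width (default 0.05).
#' @param source `"mock"` or `"treated"`.
#' @param cell_id optional cell/field identifier.
#' @return a `logfold_histogram`: bin_edges, counts, n_pixels, values,
#'   source, cell_id.
#' @export
logfold_histogram <- function(values, bin_width = 0.05,
                              source = c("treated", "mock"), cell_id = NULL) {
  source <- match.arg(source)
  stopifnot(length(values) > 0, all(is.finite(values)))
  edges <- seq(floor(min(values) / bin_width) * bin_width,
               ceiling(max(values) / bin_width) * bin_width + bin_width,
               by = bin_width)
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                     length(edges) - 1)
  structure(list(bin_edges = edges, counts = counts, n_pixels = length(values),
                 values = values, source = source, cell_id = cell_id),
            class = "logfold_histogram")
}

#' @export
print.logfold_histogram <- function(x, ...) {
  cat("log2-fold histogram (", x$source, "): ", x$n_pixels, " pixels in ",
      length(x$counts), " bins of ", diff(x$bin_edges)[1], "\n", sep = "")
  invisible(x)
}

bin_centres <- function(hist) (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2

#' Pixelwise log2-fold change between a registered frame pair
#'
#' `log2((after + eps) / (before + eps))` over the masked pixels, binned at a
#' fixed width. The frames must be registered and on a common intensity scale
#' (see [rescale_pair()]).
#'
#' @param before,after frames (after typically warped onto before).
#' @param mask logical matrix of mitochondrial pixels.
#' @param eps intensity floor (AFU) guarding the ratio.
#' @param bin_width histogram bin width.
#' @param source,cell_id passed to [logfold_histogram()].
#' @return a `logfold_histogram`.
#' @export
pixel_log2fold <- function(before, after, mask, eps = 1, bin_width = 0.05,
                           source = "treated", cell_id = NULL) {
  stopifnot(all(dim(before) == dim(after)), all(dim(mask) == dim(before)))
  if (!any(mask)) stop("empty mask")
  b <- before[mask]; a <- after[mask]
  floor_frac <- mean(a <= 0 | b <= 0)
  if (floor_frac > 0.01)
    warning(sprintf("%.1f%% of masked pixels at the intensity floor", 100 * floor_frac))
  logfold_histogram(log2((pmax(a, 0) + eps) / (pmax(b, 0) + eps)),
                    bin_width = bin_width, source = source, cell_id = cell_id)
}

#' Per-cell delta-F/F0 between two frames
#'
#' `(mean_after - mean_before) / mean_before` over each labelled cell.
#'
#' @param before,after frames.
#' @param cell_mask integer label image (0 = background).
#' @return data frame: cell, mean_before, mean_after, dff0. Cells with zero
#'   baseline mean are excluded with a warning.
#' @export
cell_delta_f_over_f0 <- function(before, after, cell_mask) {
  stopifnot(all(dim(before) == dim(cell_mask)))
  ids <- setdiff(sort(unique(as.integer(cell_mask))), 0L)
  out <- data.frame(cell = ids, mean_before = NA_real_, mean_after = NA_real_,
                    dff0 = NA_real_)
  for (i in seq_along(ids)) {
    px <- cell_mask == ids[i]
    out$mean_before[i] <- mean(before[px])
    out$mean_after[i] <- mean(after[px])
  }
  zero <- out$mean_before == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero baseline mean excluded")
    out <- out[!zero, , drop = FALSE]
  }
  out$dff0 <- (out$mean_after - out$mean_before) / out$mean_before
  out
}

## Bin probabilities of one Gaussian over the histogram support, renormalized
## so the multinomial likelihood over observed bins is proper.
gauss_bin_probs <- function(edges, mu, sigma) {
  p <- diff(stats::pnorm(edges, mu, sigma))
  tot <- stats::pnorm(edges[length(edges)], mu, sigma) -
    stats::pnorm(edges[1], mu, sigma)
  if (tot <= 0) return(rep(1e-300, length(p)))
  p / tot
}

#' Single-Gaussian maximum-likelihood fit to a binned histogram
#'
#' Maximizes the multinomial log-likelihood of the bin counts under a normal
#' distribution truncated to the histogram support. Used to calibrate the
#' null (mock-pair) spread of log2-fold pixel changes. A small uniform
#' contamination term (`outlier_mass`) keeps isolated outlier pixels from
#' dominating the likelihood; it is a fitting device only and carries no
#' probability mass in [expected_counts()].
#'
#' @param hist a `logfold_histogram` with >= 100 pixels and more than one
#'   occupied bin.
#' @param outlier_mass uniform contamination weight in the fitted density.
#' @return a `null_fit`: mu0, sigma0, logLik, convergence.
#' @export
fit_null <- function(hist, outlier_mass = 1e-3) {
  stopifnot(inherits(hist, "logfold_histogram"))
  if (hist$n_pixels < 100) stop("need at least 100 pixels")
  if (sum(hist$counts > 0) < 2) stop("degenerate histogram: single occupied bin")
  ctr <- bin_centres(hist)
  w <- hist$counts / sum(hist$counts)
  mu_init <- sum(w * ctr)
  sd_init <- sqrt(max(sum(w * (ctr - mu_init)^2), 1e-8))
  nbin <- length(hist$counts)
  nll <- function(par) {
    p <- gauss_bin_probs(hist$bin_edges, par[1], exp(par[2]))
    p <- (1 - outlier_mass) * p + outlier_mass / nbin
    -sum(hist$counts * log(pmax(p, 1e-300)))
  }
  opt <- stats::optim(c(mu_init, log(sd_init)), nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(mu0 = opt$par[1], sigma0 = exp(opt$par[2]),
                 logLik = -opt$value, convergence = opt$convergence == 0),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("Null fit: mu0 = %.4f, sigma0 = %.4f (logLik %.1f)\n",
              x$mu0, x$sigma0, x$logLik))
  invisible(x)
}

#' @export
coef.null_fit <- function(object, ...) c(mu0 = object$mu0, sigma0 = object$sigma0)

#' @export
logLik.null_fit <- function(object, ...)
  structure(object$logLik, df = 2, class = "logLik")

#' Constrained two-component Gaussian mixture fit to a binned histogram
#'
#' Models the treated log2-fold distribution as a non-responder plus a
#' responder normal component, both with sigma fixed to the mock-calibrated
#' `sigma0`, maximizing the multinomial binned log-likelihood over the
#' responder weight and the two means under the identifiability constraint
#' `mu_resp >= mu_nonresp`. Deterministic multi-start optimization. As in
#' [fit_null()], a small uniform contamination term keeps isolated outlier
#' pixels (the very excess the downstream estimator measures) from dragging
#' a component away from the population structure.
#'
#' @param hist a `logfold_histogram` (>= 100 pixels).
#' @param sigma0 component sigma from the mock fit (> 0).
#' @param outlier_mass uniform contamination weight in the fitted density.
#' @return a `two_normal_fit`: w_nonresp, w_resp, mu_nonresp, mu_resp,
#'   sigma, logLik, convergence.
#' @export
fit_two_normals <- function(hist, sigma0, outlier_mass = 1e-3) {
  stopifnot(inherits(hist, "logfold_histogram"))
  if (!(sigma0 > 0)) stop("sigma0 must be positive")
  if (hist$n_pixels < 100) stop("need at least 100 pixels")
  ctr <- bin_centres(hist)
  w <- hist$counts / sum(hist$counts)
  m <- sum(w * ctr)
  nbin <- length(hist$counts)
  nll <- function(par) {
    wr <- stats::plogis(par[1])
    mu_n <- par[2]; mu_r <- par[2] + exp(par[3])
    p <- (1 - wr) * gauss_bin_probs(hist$bin_edges, mu_n, sigma0) +
      wr * gauss_bin_probs(hist$bin_edges, mu_r, sigma0)
    p <- (1 - outlier_mass) * p + outlier_mass / nbin
    -sum(hist$counts * log(pmax(p, 1e-300)))
  }
  starts <- expand.grid(w = c(0.25, 0.5, 0.75), delta = c(0.15, 0.4, 0.7))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    wr0 <- starts$w[i]; d0 <- starts$delta[i]
    par0 <- c(stats::qlogis(wr0), m - wr0 * d0, log(d0))
    opt <- tryCatch(stats::optim(par0, nll, method = "Nelder-Mead",
                                 control = list(maxit = 1000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("two-component fit failed from all starts")
  wr <- stats::plogis(best$par[1])
  fit <- structure(list(w_nonresp = 1 - wr, w_resp = wr,
                        mu_nonresp = best$par[2],
                        mu_resp = best$par[2] + exp(best$par[3]),
                        sigma = sigma0, logLik = -best$value,
                        convergence = best$convergence == 0,
                        bin_edges = hist$bin_edges),
                   class = "two_normal_fit")
  fit
}

#' @export
print.two_normal_fit <- function(x, ...) {
  cat(sprintf(paste0("Two-component fit (sigma fixed at %.4f):\n",
                     "  non-responders: w = %.3f at mu = %.4f\n",
                     "  responders:     w = %.3f at mu = %.4f  (logLik %.1f)\n"),
              x$sigma, x$w_nonresp, x$mu_nonresp, x$w_resp, x$mu_resp, x$logLik))
  invisible(x)
}

#' @export
coef.two_normal_fit <- function(object, ...)
  c(w_nonresp = object$w_nonresp, w_resp = object$w_resp,
    mu_nonresp = object$mu_nonresp, mu_resp = object$mu_resp,
    sigma = object$sigma)

#' @export
logLik.two_normal_fit <- function(object, ...)
  structure(object$logLik, df = 3, class = "logLik")

#' Expected bin counts of a histogram under a fitted model
#'
#' @param fit a `null_fit` or `two_normal_fit`.
#' @param hist the `logfold_histogram` the fit refers to.
#' @return expected counts per bin (same length as `hist$counts`).
#' @export
expected_counts <- function(fit, hist) {
  p <- if (inherits(fit, "two_normal_fit")) {
    fit$w_nonresp * gauss_bin_probs(hist$bin_edges, fit$mu_nonresp, fit$sigma) +
      fit$w_resp * gauss_bin_probs(hist$bin_edges, fit$mu_resp, fit$sigma)
  } else if (inherits(fit, "null_fit")) {
    gauss_bin_probs(hist$bin_edges, fit$mu0, fit$sigma0)
  } else stop("unsupported fit class")
  hist$n_pixels * p
}

#' Excess pixel count at significantly decreased intensities
#'
#' The reverse-transport subpopulation estimate: over bins whose centre lies
#' below `mu_nonresp - k * sigma0` (k = 2 by default; sigma0 from the mock
#' null), sums the excess of observed over model-expected counts, as a
#' fraction of all masked pixels. Reported as a pixel fraction of the
#' mitochondrial mask; equating it with a mitochondrion fraction assumes
#' equal mean mitochondrial area across classes.
#'
#' @param hist the treated `logfold_histogram`.
#' @param fit the [fit_two_normals()] result on the same binning.
#' @param null the mock [fit_null()] supplying sigma0.
#' @param k sigma multiple of the threshold (> 0).
#' @return list of class `ret_fraction`: fraction, threshold, n_pixels,
#'   cell_id.
#' @export
excess_oxidised_fraction <- function(hist, fit, null, k = 2) {
  stopifnot(inherits(hist, "logfold_histogram"), inherits(fit, "two_normal_fit"),
            inherits(null, "null_fit"))
  if (k <= 0) stop("k must be positive")
  if (!isTRUE(all.equal(fit$bin_edges, hist$bin_edges)))
    stop("fit and histogram binnings differ")
  thr <- fit$mu_nonresp - k * null$sigma0
  sel <- bin_centres(hist) < thr
  exp_counts <- expected_counts(fit, hist)
  fraction <- sum(pmax(hist$counts[sel] - exp_counts[sel], 0)) / hist$n_pixels
  structure(list(fraction = fraction, threshold = thr, k = k,
                 n_pixels = hist$n_pixels, cell_id = hist$cell_id),
            class = "ret_fraction")
}

#' @export
print.ret_fraction <- function(x, ...) {
  cat(sprintf("Excess oxidised pixel fraction: %.3f%% (below %.3f log2-fold)\n",
              100 * x$fraction, x$threshold))
  invisible(x)
}

#' Pool per-cell oxidised fractions into experiment-level estimates
#'
#' Unweighted mean +/- SE across cells within each experiment, then across
#' experiments.
#'
#' @param fractions numeric per-cell fractions (or a list of `ret_fraction`s).
#' @param experiment experiment id per cell (single experiment by default).
#' @return list of class `ret_fraction_pooled`: per_cell, per_experiment,
#'   pooled_mean, pooled_se.
#' @export
pool_ret_fraction <- function(fractions, experiment = NULL) {
  if (is.list(fractions) && inherits(fractions[[1]], "ret_fraction"))
    fractions <- vapply(fractions, `[[`, numeric(1), "fraction")
  if (is.null(experiment)) experiment <- rep(1L, length(fractions))
  exps <- unique(experiment)
  per_exp <- data.frame(experiment = exps, mean = NA_real_, se = NA_real_,
                        n_cells = NA_integer_)
  for (i in seq_along(exps)) {
    v <- fractions[experiment == exps[i]]
    per_exp$mean[i] <- mean(v)
    per_exp$se[i] <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    per_exp$n_cells[i] <- length(v)
  }
  pooled_mean <- mean(per_exp$mean)
  pooled_se <- if (nrow(per_exp) > 1)
    stats::sd(per_exp$mean) / sqrt(nrow(per_exp)) else per_exp$se[1]
  structure(list(per_cell = fractions, per_experiment = per_exp,
                 pooled_mean = pooled_mean, pooled_se = pooled_se),
            class = "ret_fraction_pooled")
}

#' @export
print.ret_fraction_pooled <- function(x, ...) {
  cat(sprintf("Pooled oxidised fraction: %.2f%% +/- %.2f%% (%d cell(s), %d experiment(s))\n",
              100 * x$pooled_mean, 100 * (x$pooled_se %||% NA), length(x$per_cell),
              nrow(x$per_experiment)))
  invisible(x)
}

#' Per-object direction calls (forward / reverse / stalled)
#'
#' Calls each object `fet` when its challenge-evoked log2-fold change exceeds
#' `+threshold`, `ret` below `-threshold`, otherwise `stalled`. When no
#' explicit threshold is given it is computed as `c_mult` times the average
#' per-object scatter (the unbiased standard deviation of a single
#' determination, i.e. the SD over the repeated post-challenge
#' determinations corrected for small-sample bias), which requires at least
#' two repeats.
#'
#' @param delta per-object log2-fold changes at the challenge.
#' @param threshold explicit log2-fold threshold (> 0), or `NULL` to derive
#'   it from `post_repeats`.
#' @param post_repeats objects x repeats matrix of per-object log2-fold
#'   values of the repeated post-challenge determinations.
#' @param c_mult threshold multiple of the average repeat scatter, in
#'   \[1, 2\] (default 2, the conservative end of the range: it holds the
#'   false-call rate on truly stalled objects below 1% per side when the
#'   challenge response is formed from equally many baseline and
#'   post-challenge determinations).
#' @param replicate optional replicate id per object for the fraction
#'   summary.
#' @return list of class `direction_calls`: `calls` (data frame: object,
#'   delta, call), `threshold`, and `fractions` (a per-replicate summary as
#'   in [classify_population()], over fet/ret/stalled).
#' @export
classify_direction <- function(delta, threshold = NULL, post_repeats = NULL,
                               c_mult = 2, replicate = NULL) {
  if (is.null(threshold)) {
    if (is.null(post_repeats) || ncol(post_repeats) < 2)
      stop("need >= 2 repeated determinations to derive the threshold; ",
           "supply an explicit threshold instead")
    n_rep <- ncol(post_repeats)
    # c4 unbiased-scale correction: E[SD] = c4(n) * sigma
    c4 <- sqrt(2 / (n_rep - 1)) * gamma(n_rep / 2) / gamma((n_rep - 1) / 2)
    threshold <- c_mult * mean(apply(post_repeats, 1, stats::sd)) / c4
  }
  if (!(threshold > 0)) stop("threshold must be positive")
  call <- ifelse(delta > threshold, "fet",
                 ifelse(delta < -threshold, "ret", "stalled"))
  calls <- data.frame(object = seq_along(delta), delta = delta,
                      call = factor(call, levels = c("fet", "stalled", "ret")))
  if (is.null(replicate)) replicate <- rep(1L, length(delta))
  reps <- unique(replicate)
  per <- matrix(NA_real_, length(reps), 3,
                dimnames = list(as.character(reps), c("fet", "stalled", "ret")))
  for (i in seq_along(reps)) {
    sub <- calls$call[replicate == reps[i]]
    per[i, ] <- as.numeric(table(sub)[colnames(per)]) / length(sub)
  }
  n <- nrow(per)
  summ <- data.frame(call = colnames(per), mean = colMeans(per),
                     se = if (n > 1) apply(per, 2, stats::sd) / sqrt(n) else NA_real_,
                     n = n, row.names = NULL)
  structure(list(calls = calls, threshold = threshold,
                 per_replicate = per, fractions = summ),
            class = "direction_calls")
}

#' @export
print.direction_calls <- function(x, ...) {
  cat(sprintf("Direction calls at |log2-fold| > %.3f:\n", x$threshold))
  s <- x$fractions
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %5.1f%%%s\n", s$call[i], 100 * s$mean[i],
                if (is.na(s$se[i])) "" else sprintf(" +/- %.1f%%", 100 * s$se[i])))
  invisible(x)
}

#' Population-normalized per-object log2-fold NAD(P)H change
#'
#' `log2(1 + delta_F / population_mean_pre)`: the intensity change is
#' normalized to the population mean baseline fluorescence (robust for dim
#' objects with near-zero own baseline), then converted to log2-fold so
#' symmetric intensity changes give symmetric distributions.
#'
#' @param delta_f per-object intensity changes (AFU).
#' @param population_mean_pre population mean baseline fluorescence (> 0).
#' @param floor lower clip for the fold ratio before the log (default 2^-10).
#' @return per-object log2-fold values.
#' @export
per_mito_dnadh <- function(delta_f, population_mean_pre, floor = 2^-10) {
  if (!(population_mean_pre > 0)) stop("population_mean_pre must be positive")
  v <- 1 + delta_f / population_mean_pre
  if (any(v <= floor)) {
    warning(sum(v <= floor), " object(s) clipped at the fold floor")
    v <- pmax(v, floor)
  }
  log2(v)
}
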