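# Plate/cuvette quantification: H2O2 calibration, rate extraction,
# percent-of-vehicle normalization, NAD(P)H percent-reduction scaling,
# four-parameter logistic dose-response fitting, and site-IQ attribution.

#' Calibrate resorufin fluorescence against known H2O2 additions
#'
#' Least-squares slope through the origin of fluorescence step responses
#' versus spiked pmol amounts (steps are differences, so the regression is
#' offset-free by construction; set `intercept = TRUE` for a free-intercept
#' variant).
#'
#' @param spike_amounts pmol H2O2 per spike (>= 2 spikes).
#' @param responses AFU step responses.
#' @param intercept fit a free intercept instead of through-origin.
#' @return list of class `h2o2_calibration`: slope (AFU/pmol), r_squared, n.
#' @export
calibrate_h2o2 <- function(spike_amounts, responses, intercept = FALSE) {
  if (length(spike_amounts) < 2) stop("need at least 2 calibration spikes")
  stopifnot(length(spike_amounts) == length(responses))
  ord <- order(spike_amounts)
  if (any(diff(responses[ord]) < 0))
    warning("non-monotone calibration responses")
  fit <- if (intercept) stats::lm(responses ~ spike_amounts)
         else stats::lm(responses ~ spike_amounts - 1)
  slope <- unname(stats::coef(fit)[["spike_amounts"]])
  if (slope <= 0) stop("calibration slope is not positive")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  structure(list(slope = slope, r_squared = 1 - ss_res / ss_tot,
                 n = length(responses), intercept = intercept),
            class = "h2o2_calibration")
}

#' @export
print.h2o2_calibration <- function(x, ...) {
  cat(sprintf("H2O2 calibration: %.4g AFU/pmol (R^2 = %.4f, n = %d)\n",
              x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Fluorescence accumulation rate over a cycle window
#'
#' Ordinary least-squares slope of fluorescence versus time over the
#' inclusive cycle window (default cycles 5-18, i.e. 14 points of a 25-cycle
#' recording), converted to AFU/min. Invariant to constant offsets.
#'
#' @param trace data frame with columns `cycle`, `seconds`,
#'   `fluorescence_afu` (one well).
#' @param cycle_window inclusive `(first, last)` cycle bounds.
#' @return list of class `rate_result`: slope (AFU/min), se, n_points,
#'   r_squared.
#' @export
fit_rate <- function(trace, cycle_window = c(5, 18)) {
  stopifnot(all(c("cycle", "seconds", "fluorescence_afu") %in% names(trace)))
  if (cycle_window[1] < min(trace$cycle) || cycle_window[2] > max(trace$cycle))
    stop("cycle window outside the recorded cycles")
  sub <- trace[trace$cycle >= cycle_window[1] & trace$cycle <= cycle_window[2], ]
  if (nrow(sub) < 3) stop("fewer than 3 points in the cycle window")
  tmin <- sub$seconds / 60
  fit <- stats::lm(sub$fluorescence_afu ~ tmin)
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 n_points = nrow(sub), r_squared = sm$r.squared),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("Rate: %.4g AFU/min (SE %.3g, %d points, R^2 %.4f)\n",
              x$slope, x$se, x$n_points, x$r_squared))
  invisible(x)
}

#' Express background-subtracted rates as percent of vehicle
#'
#' `100 * (sample - sample_background) / mean(vehicle - vehicle_background)`.
#'
#' @param sample_rates sample-well rates.
#' @param vehicle_rates vehicle-well rates.
#' @param sample_background matched cell-free background rate(s) for the
#'   sample wells (scalar or per-well).
#' @param vehicle_background matched background rate(s) for the vehicle wells.
#' @return percent-of-vehicle value per sample well.
#' @export
percent_vehicle <- function(sample_rates, vehicle_rates,
                            sample_background = 0, vehicle_background = 0) {
  veh <- mean(vehicle_rates - vehicle_background)
  if (veh <= 0) stop("vehicle mean rate is not positive after background subtraction")
  100 * (sample_rates - sample_background) / veh
}

#' Scale a fluorescence trace to percent NAD(P)H reduction
#'
#' `100 * (x - zero_ref) / (full_ref - zero_ref)`, where the references are
#' the no-substrate signal (0%) and the steady value after saturating
#' NAD-linked substrate (100%). Values may transiently leave \[0, 100\] and
#' are reported unclipped.
#'
#' @param trace AFU values.
#' @param zero_ref,full_ref reference intensities with `full_ref > zero_ref`.
#' @return percent-reduction values with the references as attributes.
#' @export
percent_reduction <- function(trace, zero_ref, full_ref) {
  if (!(full_ref > zero_ref)) stop("full_ref must exceed zero_ref")
  out <- 100 * (trace - zero_ref) / (full_ref - zero_ref)
  attr(out, "zero_ref") <- zero_ref
  attr(out, "full_ref") <- full_ref
  out
}

#' Four-parameter logistic (variable-slope) dose-response fit
#'
#' Fits `rate = bottom + (top - bottom) / (1 + (conc / ic50)^hill)` by
#' nonlinear least squares with a deterministic multi-start over the Hill
#' slope, reporting standard errors from the Jacobian. Zero-dose points are
#' handled exactly through the curve's limit. With
#' `subtract_residual = TRUE` the fitted bottom plateau (the residual rate at
#' saturating inhibitor) is subtracted and the curve refit with the bottom
#' fixed at zero, leaving only the site-specific signal before the IC50 is
#' read. IC50s are labelled nominal: they reflect added, not measured,
#' concentrations.
#'
#' @param concentrations inhibitor concentrations (>= 0; >= 5 values).
#' @param rates measured rates, same length.
#' @param subtract_residual subtract the fitted bottom plateau and refit.
#' @return a `four_pl_fit`: coefficients (top, bottom, ic50, hill), their
#'   standard errors, `residual_subtracted`, the data, and the underlying
#'   `nls` object.
#' @export
fit_4pl <- function(concentrations, rates, subtract_residual = FALSE) {
  stopifnot(length(concentrations) == length(rates))
  if (length(unique(concentrations)) < 5)
    stop("need at least 5 distinct concentrations spanning the transition")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  df <- data.frame(conc = concentrations, rate = rates)
  fit <- fit_4pl_nls(df, fix_bottom = FALSE)
  co <- fit$coefficients
  if (subtract_residual) {
    df2 <- data.frame(conc = concentrations, rate = rates - co[["bottom"]])
    fit <- fit_4pl_nls(df2, fix_bottom = TRUE)
    fit$residual_subtracted <- TRUE
    fit$subtracted_rate <- co[["bottom"]]
  }
  fit
}

fit_4pl_nls <- function(df, fix_bottom = FALSE) {
  pos <- df$conc > 0
  if (!any(pos)) stop("all concentrations are zero")
  top0 <- max(df$rate); bot0 <- min(df$rate)
  # starting ic50: concentration whose rate is nearest the half-height
  half <- (top0 + bot0) / 2
  ic0 <- df$conc[pos][which.min(abs(df$rate[pos] - half))]
  if (!is.finite(ic0) || ic0 <= 0) ic0 <- stats::median(df$conc[pos])
  best <- NULL
  for (h0 in c(0.5, 1, 2, -0.5, -1, -2)) {
    fit <- tryCatch(suppressWarnings({
      if (fix_bottom) {
        minpack.lm::nlsLM(rate ~ top / (1 + (conc / exp(lic50))^hill),
                          data = df,
                          start = list(top = top0 - bot0, lic50 = log(ic0), hill = h0),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(rate ~ bottom + (top - bottom) / (1 + (conc / exp(lic50))^hill),
                          data = df,
                          start = list(top = top0, bottom = bot0,
                                       lic50 = log(ic0), hill = h0),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }), error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("4PL fit failed from all starts; no plateau identifiable ",
         "(rate range ", paste(signif(range(df$rate), 4), collapse = " to "), ")")
  co <- stats::coef(best$fit)
  sm <- tryCatch(suppressWarnings(summary(best$fit)$coefficients), error = function(e) NULL)
  top <- if (fix_bottom) co[["top"]] else co[["top"]]
  bottom <- if (fix_bottom) 0 else co[["bottom"]]
  hill <- co[["hill"]]
  ic50 <- exp(co[["lic50"]])
  # orientation normalization: a 4PL is invariant under swapping the
  # plateaus and negating the Hill slope; report bottom <= top.
  if (bottom > top) { tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill }
  se <- rep(NA_real_, 4)
  names(se) <- c("top", "bottom", "ic50", "hill")
  if (!is.null(sm)) {
    if ("top" %in% rownames(sm)) se["top"] <- sm["top", 2]
    if ("bottom" %in% rownames(sm)) se["bottom"] <- sm["bottom", 2]
    if ("hill" %in% rownames(sm)) se["hill"] <- sm["hill", 2]
    if ("lic50" %in% rownames(sm)) se["ic50"] <- sm["lic50", 2] * ic50
  }
  structure(list(coefficients = c(top = unname(top), bottom = unname(bottom),
                                  ic50 = unname(ic50), hill = unname(hill)),
                 se = se, residual_subtracted = FALSE, subtracted_rate = 0,
                 rss = best$rss, data = df, nls = best$fit),
            class = "four_pl_fit")
}

#' @export
coef.four_pl_fit <- function(object, ...) object$coefficients

#' @export
print.four_pl_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(paste0("Four-parameter logistic fit%s:\n",
                     "  top %.4g, bottom %.4g, nominal IC50 %.4g, Hill %.3g\n"),
              if (x$residual_subtracted) " (residual rate subtracted)" else "",
              co["top"], co["bottom"], co["ic50"], co["hill"]))
  invisible(x)
}

#' @export
predict.four_pl_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc else newdata$conc %||% newdata
  co <- object$coefficients
  fourpl_curve(conc, co["top"], co["bottom"], co["ic50"], co["hill"])
}

#' Rate attributed to site IQ by saturating S1QEL suppression
#'
#' The difference between the total rate and the rate remaining with a
#' saturating S1QEL concentration, floored at 0 with a warning when negative.
#' Both rates must be background-subtracted and in the same units.
#'
#' @param total_rate,rate_with_saturating_s1qel rates in identical units.
#' @param units optional unit labels; a mismatch is an error.
#' @return the attributed rate(s).
#' @export
site_iq_rate <- function(total_rate, rate_with_saturating_s1qel,
                         units = NULL) {
  if (!is.null(units) && length(unique(units)) > 1)
    stop("unit mismatch between rates: ", paste(unique(units), collapse = " vs "))
  d <- total_rate - rate_with_saturating_s1qel
  if (any(d < 0)) {
    warning("negative site-IQ rate floored at 0")
    d <- pmax(d, 0)
  }
  d
}
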