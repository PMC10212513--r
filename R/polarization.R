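# Nernst-slope relative membrane potentials from single-mitochondrion TMRM
# traces, and rectangular response gating of the population.

#' Relative membrane potential from a TMRM intensity ratio
#'
#' TMRM distributes Nernstianly (one decade of matrix accumulation per 61 mV),
#' so the relative polarization between two conditions is
#' `61 * log10(f_num / f_den)` mV. The readout is additive over chained
#' ratios. Potentials are relative throughout: no absolute zero-mV
#' calibration is attempted.
#'
#' @param f_num,f_den background-subtracted TMRM intensities (AFU), > 0.
#' @param mito_id optional identifier(s) used in error messages.
#' @return relative potential(s) in mV.
#' @export
relative_polarization <- function(f_num, f_den, mito_id = NULL) {
  bad <- !(f_num > 0 & f_den > 0)
  if (any(bad)) {
    who <- if (!is.null(mito_id)) paste(" (mitochondrion ",
                                        paste(mito_id[bad], collapse = ", "), ")",
                                        sep = "") else ""
    stop("non-positive TMRM intensity", who)
  }
  61 * log10(f_num / f_den)
}

#' Normalize a fluorescence trace between frame background and its maximum
#'
#' `(x - background) / (max - background)`, clipped to \[0, 1\]. If the trace
#' maximum does not exceed the background the mitochondrion is flagged
#' nonresponsive and the trace is returned as zeros.
#'
#' @param trace AFU values over time.
#' @param frame_background background AFU.
#' @param trace_max maximal fluorescence over the whole time course
#'   (default `max(trace)`).
#' @return normalized trace; `attr(, "nonresponsive")` is TRUE when degenerate.
#' @export
normalize_trace <- function(trace, frame_background, trace_max = max(trace)) {
  if (trace_max <= frame_background) {
    out <- rep(0, length(trace))
    attr(out, "nonresponsive") <- TRUE
    return(out)
  }
  out <- pmin(pmax((trace - frame_background) / (trace_max - frame_background), 0), 1)
  attr(out, "nonresponsive") <- FALSE
  out
}

#' Rectangular gates in the (G+M vs succinate, G3P vs G+M) potential plane
#'
#' Two thresholds partition the plane into the four response classes:
#' mitochondria strongly polarized by glutamate+malate (x above `gm_mv`) with
#' an appreciable further G3P response (y above `g3p_mv`) are
#' `medium_medium`; strong G+M but weak G3P is `strong_gm_weak_g3p`; weak G+M
#' with a strong G3P response is the RET-candidate class `ret_like`; weak on
#' both axes is `nonresponsive`. The thresholds are explicitly a documented
#' convention, not a claim about the original gating.
#'
#' @param gm_mv threshold on the G+M-vs-succinate axis (mV, <= 0 scale).
#' @param g3p_mv threshold on the G3P-vs-G+M hyperpolarization axis (mV).
#' @return a `gate_set`.
#' @export
gate_set <- function(gm_mv = -30, g3p_mv = 20) {
  structure(list(gm_mv = gm_mv, g3p_mv = g3p_mv), class = "gate_set")
}

POLARIZATION_CLASSES <- c("medium_medium", "strong_gm_weak_g3p",
                          "ret_like", "nonresponsive")

#' Assign gate classes to polarization records
#'
#' @param records data frame with columns `pol_gm_vs_succ` and
#'   `pol_g3p_vs_gm` (mV).
#' @param gates a [gate_set()].
#' @return `records` with a `class` column (factor over the four classes).
#' @export
classify_gates <- function(records, gates = gate_set()) {
  stopifnot(inherits(gates, "gate_set"),
            all(c("pol_gm_vs_succ", "pol_g3p_vs_gm") %in% names(records)))
  strong_gm <- records$pol_gm_vs_succ > gates$gm_mv
  strong_g3p <- records$pol_g3p_vs_gm > gates$g3p_mv
  cls <- ifelse(strong_gm & strong_g3p, "medium_medium",
                ifelse(strong_gm & !strong_g3p, "strong_gm_weak_g3p",
                       ifelse(!strong_gm & strong_g3p, "ret_like",
                              "nonresponsive")))
  records$class <- factor(cls, levels = POLARIZATION_CLASSES)
  records
}

#' Class fractions with standard errors over experimental replicates
#'
#' Computes per-replicate class fractions (each summing to 1) and their mean
#' and standard error across replicates. With a single replicate the SE is
#' reported as `NA`.
#'
#' @param records data frame with the potential columns and a `replicate`
#'   column; classified with `gates` if no `class` column is present.
#' @param gates a [gate_set()].
#' @param replicate optional replicate vector overriding the column.
#' @return list of class `class_fractions` with `per_replicate` (replicate x
#'   class matrix) and `summary` (class, mean, se, n).
#' @export
classify_population <- function(records, gates = gate_set(), replicate = NULL) {
  if (!is.null(replicate)) records$replicate <- replicate
  if (is.null(records$replicate)) records$replicate <- 1L
  if (nrow(records) == 0) stop("no records")
  if (is.null(records$class)) records <- classify_gates(records, gates)
  reps <- unique(records$replicate)
  per <- matrix(NA_real_, length(reps), length(POLARIZATION_CLASSES),
                dimnames = list(as.character(reps), POLARIZATION_CLASSES))
  keep <- logical(length(reps))
  for (i in seq_along(reps)) {
    sub <- records$class[records$replicate == reps[i]]
    if (length(sub) == 0) {
      warning("replicate ", reps[i], " is empty and was excluded")
      next
    }
    keep[i] <- TRUE
    per[i, ] <- as.numeric(table(sub)[POLARIZATION_CLASSES]) / length(sub)
  }
  per <- per[keep, , drop = FALSE]
  n <- nrow(per)
  summ <- data.frame(class = POLARIZATION_CLASSES,
                     mean = colMeans(per),
                     se = if (n > 1) apply(per, 2, stats::sd) / sqrt(n)
                          else NA_real_,
                     n = n, row.names = NULL)
  structure(list(per_replicate = per, summary = summ),
            class = "class_fractions")
}

#' @export
print.class_fractions <- function(x, ...) {
  cat("Class fractions over", x$summary$n[1], "replicate(s):\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-20s %5.1f%%%s\n", s$class[i], 100 * s$mean[i],
                if (is.na(s$se[i])) "" else sprintf(" +/- %.1f%%", 100 * s$se[i])))
  invisible(x)
}

#' Per-mitochondrion polarization records from TMRM traces
#'
#' Builds the two gating axes from a trace matrix: polarization by
#' glutamate+malate referenced to succinate (how many mV less polarized than
#' with succinate; <= 0 means less polarized) and the hyperpolarization upon
#' G3P addition in the presence of G+M.
#'
#' @param traces K x T matrix of background-subtracted TMRM means with
#'   columns named for the conditions.
#' @param gm,g3p,succ condition labels of the three reference frames.
#' @return data frame of `PolarizationRecord`s: mito_id, the two potentials
#'   (mV), and the raw intensities.
#' @export
polarization_records <- function(traces, gm = "gm", g3p = "g3p", succ = "succ") {
  stopifnot(all(c(gm, g3p, succ) %in% colnames(traces)))
  ok <- traces[, gm] > 0 & traces[, g3p] > 0 & traces[, succ] > 0
  if (!all(ok)) warning(sum(!ok), " mitochondria with non-positive TMRM dropped")
  tr <- traces[ok, , drop = FALSE]
  data.frame(mito_id = which(ok),
             f_gm = tr[, gm], f_g3p = tr[, g3p], f_succ = tr[, succ],
             pol_gm_vs_succ = relative_polarization(tr[, gm], tr[, succ]),
             pol_g3p_vs_gm = relative_polarization(tr[, g3p], tr[, gm]))
}
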