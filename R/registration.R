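# Multi-resolution B-spline deformable registration with Pearson-correlation
# quality control. Mean-squared-difference metric on frames rescaled to
# [0, 1], rigid (translation) pre-alignment, analytic gradients with respect
# to the control grid, and an identity fallback so registration never
# degrades the Pearson correlation.

## Cubic B-spline kernel.
bspline3 <- function(t) {
  a <- abs(t)
  out <- numeric(length(t))
  i1 <- a < 1
  out[i1] <- (4 - 6 * a[i1]^2 + 3 * a[i1]^3) / 6
  i2 <- a >= 1 & a < 2
  out[i2] <- (2 - a[i2])^3 / 6
  out
}

## Basis matrix mapping control values at nodes j = -1..J+1 (node j sits at
## full-resolution pixel coordinate 1 + j*s) to displacements at the given
## full-resolution pixel coordinates.
bspline_basis <- function(coords_full, spacing, n_full) {
  J <- ceiling((n_full - 1) / spacing)
  js <- seq.int(-1L, J + 1L)
  t <- (coords_full - 1) / spacing
  B <- outer(t, js, function(tt, jj) bspline3(tt - jj))
  B
}

## Integer translation estimate via FFT cross-correlation; returns the pull
## displacement (dy, dx) maximizing the Pearson correlation of
## moving(y + dy, x + dx) with fixed.
estimate_translation <- function(fixed, moving, max_shift = 12L) {
  f <- fixed - mean(fixed); m <- moving - mean(moving)
  cc <- Re(stats::fft(stats::fft(m) * Conj(stats::fft(f)), inverse = TRUE))
  nr <- nrow(f); nc <- ncol(f)
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  cand <- c(wrap(idx[1] - 1, nr), wrap(idx[2] - 1, nc))
  cand <- pmax(pmin(cand, max_shift), -max_shift)
  shifts <- unique(list(cand, -cand, c(0, 0)))
  score <- function(s) {
    Y <- matrix(seq_len(nr), nr, nc); X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    w <- bilinear_sample(moving, Y + s[1], X + s[2])
    suppressWarnings(stats::cor(as.vector(w), as.vector(fixed)))
  }
  sc <- vapply(shifts, score, numeric(1))
  sc[is.na(sc)] <- -Inf
  shifts[[which.max(sc)]]
}

#' Deformable B-spline registration of a moving frame onto a fixed frame
#'
#' Minimizes the mean squared difference between the fixed frame and the
#' warped moving frame (both linearly rescaled to \[0, 1\]) over a cubic
#' B-spline displacement field, coarse-to-fine over an image pyramid, after a
#' translation pre-alignment. Displacements use pull semantics: the output
#' pixel at (y, x) samples the moving frame at (y + dy, x + dx). If the
#' optimized field fails to improve the Pearson correlation between the
#' frames, the identity field is returned instead, so `pearson_after >=
#' pearson_before` always holds.
#'
#' @param fixed,moving numeric matrices of identical shape, finite values.
#' @param grid_spacing_px control-point spacing in px (>= 8).
#' @param levels pyramid levels (3 = quarter, half, full resolution).
#' @param lambda ridge penalty on control-point displacements.
#' @param maxit optimizer iterations per level.
#' @param qc_threshold Pearson threshold for the `accepted` flag (see
#'   [qc_registration()]).
#' @return a `registration_result`: list with `displacement_field`
#'   (rows x cols x 2 array, dy then dx), `warped_frame` (moving warped onto
#'   fixed, original intensity scale), `pearson_before`, `pearson_after`,
#'   `accepted`.
#' @export
register_deformable <- function(fixed, moving, grid_spacing_px = 16,
                                levels = 3L, lambda = 1e-3, maxit = 40L,
                                qc_threshold = 0.6) {
  stopifnot(all(dim(fixed) == dim(moving)))
  if (grid_spacing_px < 8) stop("grid_spacing_px must be >= 8")
  if (any(!is.finite(fixed)) || any(!is.finite(moving)))
    stop("non-finite pixel values")
  nr <- nrow(fixed); nc <- ncol(fixed)
  rs <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(x * 0)
    (x - rng[1]) / diff(rng)
  }
  f0 <- rs(fixed); m0 <- rs(moving)

  shift <- estimate_translation(f0, m0)
  By_full <- bspline_basis(seq_len(nr), grid_spacing_px, nr)
  Bx_full <- bspline_basis(seq_len(nc), grid_spacing_px, nc)
  gy <- ncol(By_full); gx <- ncol(Bx_full)
  Py <- matrix(shift[1], gy, gx)
  Px <- matrix(shift[2], gy, gx)

  pyramid <- vector("list", levels)
  pyramid[[levels]] <- list(f = f0, m = m0, fac = 1)
  if (levels > 1) for (l in (levels - 1):1) {
    prev <- pyramid[[l + 1]]
    pyramid[[l]] <- list(f = downsample2(prev$f), m = downsample2(prev$m),
                         fac = prev$fac * 2)
  }

  np <- gy * gx
  for (l in seq_len(levels)) {
    lev <- pyramid[[l]]
    fac <- lev$fac
    nrl <- nrow(lev$f); ncl <- ncol(lev$f)
    if (nrl < 8 || ncl < 8) next
    coords_y <- (seq_len(nrl) - 0.5) * fac + 0.5
    coords_x <- (seq_len(ncl) - 0.5) * fac + 0.5
    By <- bspline_basis(coords_y, grid_spacing_px, nr)
    Bx <- bspline_basis(coords_x, grid_spacing_px, nc)
    Yc <- matrix(seq_len(nrl), nrl, ncl)
    Xc <- matrix(seq_len(ncl), nrl, ncl, byrow = TRUE)
    # image gradients of the moving frame at this level (per coarse px)
    gMy <- lev$m * 0; gMx <- lev$m * 0
    gMy[2:(nrl - 1), ] <- (lev$m[3:nrl, ] - lev$m[1:(nrl - 2), ]) / 2
    gMx[, 2:(ncl - 1)] <- (lev$m[, 3:ncl] - lev$m[, 1:(ncl - 2)]) / 2
    N <- nrl * ncl

    fn <- function(par) {
      Pym <- matrix(par[1:np], gy, gx); Pxm <- matrix(par[np + 1:np], gy, gx)
      uy <- By %*% Pym %*% t(Bx); ux <- By %*% Pxm %*% t(Bx)
      w <- bilinear_sample(lev$m, Yc + uy / fac, Xc + ux / fac)
      r <- w - lev$f
      mean(r^2) + lambda * mean(par^2)
    }
    gr <- function(par) {
      Pym <- matrix(par[1:np], gy, gx); Pxm <- matrix(par[np + 1:np], gy, gx)
      uy <- By %*% Pym %*% t(Bx); ux <- By %*% Pxm %*% t(Bx)
      ys <- Yc + uy / fac; xs <- Xc + ux / fac
      w <- bilinear_sample(lev$m, ys, xs)
      r <- w - lev$f
      wy <- bilinear_sample(gMy, ys, xs) / fac
      wx <- bilinear_sample(gMx, ys, xs) / fac
      gPy <- (2 / N) * t(By) %*% (r * wy) %*% Bx
      gPx <- (2 / N) * t(By) %*% (r * wx) %*% Bx
      c(as.vector(gPy), as.vector(gPx)) + 2 * lambda * par / (2 * np)
    }
    res <- stats::optim(c(as.vector(Py), as.vector(Px)), fn, gr,
                        method = "L-BFGS-B", control = list(maxit = maxit))
    Py <- matrix(res$par[1:np], gy, gx)
    Px <- matrix(res$par[np + 1:np], gy, gx)
  }

  uy <- By_full %*% Py %*% t(Bx_full)
  ux <- By_full %*% Px %*% t(Bx_full)
  Y <- matrix(seq_len(nr), nr, nc); X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  warped <- bilinear_sample(moving, Y + uy, X + ux)
  pearson_before <- stats::cor(as.vector(fixed), as.vector(moving))
  pearson_after <- stats::cor(as.vector(fixed), as.vector(warped))
  if (is.na(pearson_after) || pearson_after < pearson_before) {
    uy <- uy * 0; ux <- ux * 0
    warped <- moving
    pearson_after <- pearson_before
  }
  field <- array(c(uy, ux), dim = c(nr, nc, 2))
  structure(list(displacement_field = field, warped_frame = warped,
                 pearson_before = pearson_before, pearson_after = pearson_after,
                 accepted = pearson_after >= qc_threshold),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("Deformable registration: r %.3f -> %.3f (%s)\n",
              x$pearson_before, x$pearson_after,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Quality-control decision on a registration result
#'
#' Accepts the registration when the post-registration Pearson
#' cross-correlation is at least `threshold` (the boundary value itself is
#' kept; only values strictly below the threshold are discarded).
#'
#' @param result a `registration_result`.
#' @param threshold Pearson r cutoff (default 0.6).
#' @return the result with its `accepted` flag set; rejects emit a message.
#' @export
qc_registration <- function(result, threshold = 0.6) {
  stopifnot(inherits(result, "registration_result"))
  result$accepted <- result$pearson_after >= threshold
  if (!result$accepted)
    message(sprintf("registration rejected: r = %.3f < %.2f",
                    result$pearson_after, threshold))
  result
}
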