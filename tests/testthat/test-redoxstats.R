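# Pixelwise log2-fold analysis, binned ML fits, the excess-count estimator
# and direction calls.

test_that("pixelwise log2-fold is exact on scaled frames", {
  b <- matrix(100, 16, 16); m <- matrix(TRUE, 16, 16)
  h0 <- pixel_log2fold(b, b, m, eps = 0)
  expect_true(all(abs(h0$values) < 1e-12))
  h1 <- pixel_log2fold(b, 2 * b, m, eps = 0)
  expect_true(all(abs(h1$values - 1) < 1e-12))
  expect_error(pixel_log2fold(b, b, m & FALSE), "empty mask")
})

test_that("mock pairs give a log2-fold histogram centred at zero", {
  cfg <- scene_config(seed = 901)
  stk <- simulate_cell_pair(cfg, treated = FALSE)
  h <- analyze_cell_pair(stk, source = "mock")
  se <- sd(h$values) / sqrt(length(h$values))
  # modal rescale centres the distribution; mean within 2 SE of 0 would be
  # exact for a symmetric null, allow the bin-width scale instead
  expect_lt(abs(mean(h$values)), 0.05)
  # and the calibrated spread is in the plausible range for this microscope
  expect_gt(sd(h$values), 0.1)
  expect_lt(sd(h$values), 0.3)
})

test_that("per-cell delta-F/F0 matches imposed global changes", {
  b <- matrix(200, 32, 32)
  lab <- matrix(0L, 32, 32); lab[1:10, 1:10] <- 1L; lab[20:30, 20:30] <- 2L
  expect_equal(cell_delta_f_over_f0(b, b, lab)$dff0, c(0, 0))
  expect_equal(cell_delta_f_over_f0(b, 1.5 * b, lab)$dff0, c(0.5, 0.5))
  # FCCP-like global 50% decrease
  expect_equal(cell_delta_f_over_f0(b, 0.5 * b, lab)$dff0, c(-0.5, -0.5))
  bad <- b; bad[1:10, 1:10] <- 0
  expect_warning(cell_delta_f_over_f0(bad, b, lab), "zero baseline")
})

test_that("binned null fit recovers Gaussian parameters and matches the
          unbinned oracle", {
  set.seed(7)
  x <- rnorm(1e5, 0, 0.2)
  h <- logfold_histogram(x, bin_width = 0.05, source = "mock")
  fit <- fit_null(h)
  expect_equal(fit$mu0, 0, tolerance = 0.005)
  expect_equal(fit$sigma0, 0.2, tolerance = 0.025)
  # oracle: direct MLE on the unbinned sample
  expect_lt(abs(fit$mu0 - mean(x)), 0.05 / 10)
  # fine binning localizes a shifted constant at its bin centre
  y <- rnorm(2000, 0.37, 0.001)
  hf <- logfold_histogram(y, bin_width = 0.01, source = "mock")
  fitf <- fit_null(hf)
  expect_equal(fitf$mu0, 0.37, tolerance = 0.005)
  expect_error(fit_null(logfold_histogram(rep(0.5, 200), bin_width = 0.05)),
               "single occupied bin|degenerate")
})

test_that("binned ML agrees with a brute-force lattice search", {
  set.seed(11)
  x <- rnorm(2000, 0.1, 0.15)
  h <- logfold_histogram(x, bin_width = 0.05, source = "mock")
  fit <- fit_null(h)
  mus <- seq(-0.1, 0.3, by = 0.01)
  sds <- seq(0.05, 0.4, by = 0.01)
  ll <- function(mu, s) {
    p <- retquant:::gauss_bin_probs(h$bin_edges, mu, s)
    p <- (1 - 1e-3) * p + 1e-3 / length(p)
    sum(h$counts * log(pmax(p, 1e-300)))
  }
  grid <- outer(mus, sds, Vectorize(ll))
  best <- which(grid == max(grid), arr.ind = TRUE)[1, ]
  expect_lt(abs(fit$mu0 - mus[best[1]]), 0.011)
  expect_lt(abs(fit$sigma0 - sds[best[2]]), 0.011)
})

test_that("the constrained mixture recovers a 0.26/0.74 split at log2(1.5)", {
  set.seed(13)
  n <- 1e5
  lab <- runif(n) < 0.74
  x <- ifelse(lab, rnorm(n, log2(1.5), 0.2), rnorm(n, 0, 0.2))
  h <- logfold_histogram(x, bin_width = 0.05)
  fit <- fit_two_normals(h, sigma0 = 0.2)
  expect_equal(fit$w_resp, 0.74, tolerance = 0.02 / 0.74)
  expect_equal(fit$mu_resp, log2(1.5), tolerance = 0.02 / log2(1.5))
  expect_equal(fit$w_nonresp + fit$w_resp, 1)
})

test_that("the mixture degenerates gracefully on single-Gaussian data and is
          dominated by a free-sigma fit", {
  set.seed(19)
  x <- rnorm(2e4, 0, 0.2)
  h <- logfold_histogram(x, bin_width = 0.05)
  null <- fit_null(h)
  fit <- fit_two_normals(h, sigma0 = 0.2)
  # one component vanishes or the means coincide
  expect_true(fit$w_resp < 0.05 || fit$w_nonresp < 0.05 ||
                abs(fit$mu_resp - fit$mu_nonresp) < 0.05)
  expect_gte(fit$mu_resp, fit$mu_nonresp)
  # fitted density matches the single fit closely where it matters
  e1 <- expected_counts(null, h); e2 <- expected_counts(fit, h)
  expect_lt(max(abs(e1 - e2)) / h$n_pixels, 0.01)
  # nested models: fixing sigma cannot beat fitting it freely
  free_nll <- function(par) {
    p <- retquant:::gauss_bin_probs(h$bin_edges, par[1], exp(par[2]))
    w <- plogis(par[3])
    p2 <- retquant:::gauss_bin_probs(h$bin_edges, par[4], exp(par[2]))
    pm <- (1 - w) * p + w * p2
    pm <- (1 - 1e-3) * pm + 1e-3 / length(pm)
    -sum(h$counts * log(pmax(pm, 1e-300)))
  }
  opt <- optim(c(0, log(0.25), 0, 0.1), free_nll,
               control = list(maxit = 2000, reltol = 1e-12))
  expect_lte(fit$logLik, -opt$value + 1e-3)
})

test_that("excess count is zero when the data equal the fitted model", {
  edges <- seq(-1, 1, by = 0.05)
  fit <- structure(list(w_nonresp = 0.3, w_resp = 0.7, mu_nonresp = 0,
                        mu_resp = 0.5, sigma = 0.1, bin_edges = edges),
                   class = "two_normal_fit")
  null <- structure(list(mu0 = 0, sigma0 = 0.1), class = "null_fit")
  p <- 0.3 * retquant:::gauss_bin_probs(edges, 0, 0.1) +
    0.7 * retquant:::gauss_bin_probs(edges, 0.5, 0.1)
  h <- structure(list(bin_edges = edges, counts = 1e4 * p, n_pixels = 1e4,
                      source = "treated", cell_id = 1),
                 class = "logfold_histogram")
  est <- excess_oxidised_fraction(h, fit, null, k = 2)
  expect_equal(est$fraction, 0, tolerance = 1e-12)
  expect_error(excess_oxidised_fraction(h, fit, null, k = 0), "positive")
})

test_that("direction calls follow the threshold contract", {
  dc <- classify_direction(c(0, 0.5, -0.5), threshold = 0.1)
  expect_equal(as.character(dc$calls$call), c("stalled", "fet", "ret"))
  expect_error(classify_direction(1:3), "repeated determinations")
  # bulk-trace variant: steady post-challenge value below baseline is a
  # reverse-transport signature (monotone NADH decay after the challenge)
  trace <- 100 * exp(-seq(0, 2, length.out = 20))
  delta <- log2(trace[20] / trace[1])
  bulk <- classify_direction(delta, threshold = 0.1)
  expect_equal(as.character(bulk$calls$call), "ret")
})

test_that("population-normalized changes stay finite for dim objects", {
  expect_equal(per_mito_dnadh(0, 100), 0)
  expect_equal(per_mito_dnadh(100, 100), 1)
  set.seed(23)
  dim_deltas <- rnorm(1000, -20, 30)  # near-zero baselines, noisy changes
  out <- suppressWarnings(per_mito_dnadh(dim_deltas, 100))
  expect_true(all(is.finite(out)))
  expect_error(per_mito_dnadh(1, 0), "positive")
})

test_that("a global uncoupler-like oxidation is called in at least 85% of objects", {
  # positive control: every mitochondrion oxidises (NAD(P)H falls), as after
  # a protonophore; the per-object call must flag the bulk of them
  cfg <- glass_config(n_mito = 120,
                      class_fractions = c(fet_responder = 0, stalled = 0,
                                          ret = 1, nonpolarizing = 0),
                      seed = 3)
  ex <- direction_experiment(n_fields = 2, seed = 3, config = cfg)
  ret_frac <- ex$calls$fractions$mean[ex$calls$fractions$call == "ret"]
  expect_gte(ret_frac, 0.85)
})

test_that("pooling averages within then across experiments", {
  pl <- pool_ret_fraction(c(0.01, 0.02, 0.03, 0.05), experiment = c(1, 1, 2, 2))
  expect_equal(pl$per_experiment$mean, c(0.015, 0.04))
  expect_equal(pl$pooled_mean, mean(c(0.015, 0.04)))
})
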