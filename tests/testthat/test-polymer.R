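test_that("rigid-rod conversion counts every started nucleotide", {
  est <- rigid_contour_nt(c(5, 9))
  expect_identical(est$L_nt, c(9L, 16L))
  expect_identical(rigid_contour_nt(0.59)$L_nt, 1L)
  expect_identical(rigid_contour_nt(0.59, polymer_params(rounding = "floor"))$L_nt, 1L)
  expect_error(rigid_contour_nt(0), "positive")
  # ceil bracket invariant: nt * rise >= d > (nt - 1) * rise
  set.seed(1)
  d <- runif(50, 0.2, 30)
  nt <- rigid_contour_nt(d)$L_nt
  expect_true(all(nt * 0.59 >= d - 1e-9))
  expect_true(all((nt - 1) * 0.59 < d + 1e-9))
})

test_that("the WLC radial density is normalised, supported on [0, L)", {
  grid <- list(c(10, 1), c(20, 2.1), c(30, 5), c(15, 50))
  for (g in grid) {
    L <- g[1]; lp <- g[2]
    I <- stats::integrate(function(r) wlc_pdf(r, L, lp), 0, L,
                          rel.tol = 1e-9, subdivisions = 500L)$value
    expect_lt(abs(I - 1), 1e-6)
    r <- seq(-1, L + 1, length.out = 101)
    p <- wlc_pdf(r, L, lp)
    expect_true(all(p >= 0))
    expect_true(all(p[r <= 0 | r >= L] == 0))
  }
  expect_error(wlc_pdf(1, -2, 2.1), "L")
  expect_error(wlc_pdf(1, 10, 0), "lp")
})

test_that("the density reproduces the rod and Gaussian-coil limits", {
  # stiff chain: mode approaches the contour length
  L <- 9; lp <- 100 * L
  mode <- optimize(function(r) wlc_pdf(r, L, lp), c(0.5 * L, L * (1 - 1e-9)),
                   maximum = TRUE, tol = 1e-10)$maximum
  expect_lt(abs(mode / L - 1), 0.01)
  # floppy chain: rms of the density approaches sqrt(2 lp L)
  lp <- 2.1; L <- 100 * lp
  rms_num <- sqrt(stats::integrate(function(r) r^2 * wlc_pdf(r, L, lp),
                                   0, L, rel.tol = 1e-9)$value)
  expect_lt(abs(rms_num / sqrt(2 * lp * L) - 1), 0.05)
})

test_that("the closed-form rms matches independent quadrature and chain simulation", {
  # rod limit of the moment formula
  lp <- 2.1; L <- lp / 100
  expect_lt(abs(wlc_rms(L, lp) / L - 1), 0.01)
  # direct value at 100 nt of ssRNA
  expect_equal(wlc_rms(59, 2.1), 15.46, tolerance = 1e-3)
  # tangent-correlation double quadrature oracle
  for (g in list(c(59, 2.1), c(10, 5), c(21.4, 2.1))) {
    expect_equal(wlc_rms(g[1], g[2]), kp_rms_quadrature(g[1], g[2]),
                 tolerance = 1e-7)
  }
  # discretised-chain Monte Carlo oracle
  set.seed(21)
  expect_lt(abs(chain_mc_rms(59, 2.1, n_chain = 4000L) / wlc_rms(59, 2.1) - 1),
            0.03)
  # monotone in both arguments, always below the contour length
  L <- seq(2, 60, by = 2)
  expect_true(all(diff(wlc_rms(L, 2.1)) > 0))
  expect_true(all(wlc_rms(L, 2.1) < L))
  lp <- seq(0.5, 30, by = 0.5)
  expect_true(all(diff(wlc_rms(20, lp)) > 0))
})

test_that("contour-length inversion agrees with brute-force search and round trips", {
  for (d in c(5, 9, 12)) {
    for (lp in c(1, 2.1, 5)) {
      est <- invert_contour_length(d, lp)
      expect_lt(abs(est$L_nm - grid_invert_rms(d, lp)), 0.011)
      expect_equal(wlc_rms(est$L_nm, lp), d, tolerance = 1e-9)
    }
  }
  # round trip on a grid: invert(rms(L)) == L
  for (L in c(8, 21.4, 40)) {
    expect_equal(invert_contour_length(wlc_rms(L, 2.1), 2.1)$L_nm, L,
                 tolerance = 1e-6)
  }
  # quoted working point: d = 9 nm at lp = 2.1 gives a ~21.4 nm loop
  est <- invert_contour_length(9, 2.1)
  expect_equal(est$L_nm, 21.4, tolerance = 1e-2)
  expect_identical(.subset2(est, "L_nt"),
                   as.integer(ceiling(est$L_nm / 0.59 - 1e-9)))
  # near-rigid persistence length reduces to the rigid model
  rigid <- invert_contour_length(9, 1e6)
  expect_equal(rigid$L_nm, 9, tolerance = 1e-4)
  expect_identical(rigid$L_nt, 16L)
})

test_that("mean and mode statistics also invert consistently", {
  for (stat in c("mean", "mode")) {
    p <- polymer_params(match_statistic = stat)
    est <- invert_contour_length(9, 2.1, p)
    # the chosen statistic of the solved chain equals the input distance
    recovered <- fretends:::.wlc_statistic(est$L_nm, 2.1, stat)
    expect_equal(recovered, 9, tolerance = 1e-6)
    # matching a more central statistic needs at least the rigid length
    expect_gt(est$L_nm, 9)
  }
})

test_that("predicted histograms collapse to shot noise for rigid chains", {
  h <- predict_fret_histogram(9, 900, 8.5, mean_total_photons = 100,
                              n_draws = 2e4L, seed = 3L)
  shot <- sigma_to_fwhm(shot_noise_sigma(h$mean_E, 100))
  expect_lt(abs(h$fwhm / shot - 1), 0.1)
})

test_that("predicted width falls monotonically with rising persistence length", {
  # L chosen so even the floppiest chain spans the responsive distance range
  w <- vapply(c(1, 2.1, 5, 20), function(lp) {
    predict_width(45, lp, 8.5, 100)$sigma
  }, numeric(1))
  expect_true(all(diff(w) < 0))
  # and the Monte-Carlo histogram agrees with quadrature on the rigid side
  w_mc <- vapply(c(5, 20), function(lp) {
    predict_fret_histogram(21.4, lp, 8.5, 100, n_draws = 3e4L,
                           seed = 6L)$sample_sd
  }, numeric(1))
  w_q <- vapply(c(5, 20), function(lp) predict_width(21.4, lp, 8.5, 100)$sigma,
                numeric(1))
  expect_equal(w_mc, w_q, tolerance = 0.05)
})

test_that("with unlimited photons only the conformational width remains", {
  pw <- predict_width(12, 20, 8.5, mean_total_photons = 1e7)
  expect_equal(pw$sigma, pw$conformational_sigma, tolerance = 1e-3)
  h <- predict_fret_histogram(12, 20, 8.5, mean_total_photons = 1e5,
                              n_draws = 4e4L, seed = 2L)
  expect_equal(h$sample_sd, predict_width(12, 20, 8.5, 1e5)$conformational_sigma,
               tolerance = 0.05)
})

test_that("persistence-length inference recovers the generative rigidity", {
  h <- predict_fret_histogram(12, 5, 8.5, 100, n_draws = 2e4L, seed = 7L)
  lp_hat <- infer_persistence_length(h$fwhm, h$mean_E, 12, 8.5, 100, seed = 11L)
  expect_lt(abs(lp_hat / 5 - 1), 0.15)
})

test_that("inference flags shot-noise-limited and impossible widths", {
  shot <- sigma_to_fwhm(shot_noise_sigma(0.45, 100))
  expect_warning(
    lp <- infer_persistence_length(shot * 1.0000001, 0.45, 9, 8.5, 100, seed = 5L),
    "lower bound")
  expect_true(isTRUE(attr(lp, "lower_bound")))
  expect_error(
    infer_persistence_length(shot * 0.5, 0.45, 9, 8.5, 100),
    "below the shot-noise limit")
})
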