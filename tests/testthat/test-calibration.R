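test_that("ruler separations follow the 0.34 nm/bp rise, with optional linker", {
  expect_equal(ruler_separation(45), 15.3)
  expect_equal(ruler_separation(10), 3.4)
  g <- ruler_geometry(include_linker_in_abscissa = TRUE)
  expect_equal(ruler_separation(10, g), 4.9)
  expect_error(ruler_separation(0), "positive")
  expect_error(ruler_separation(-3), "positive")
})

test_that("the Forster relation has the right limits and is monotone", {
  expect_equal(efficiency_from_distance(8.5, 8.5), 0.5)
  expect_equal(efficiency_from_distance(0, 8.5), 1)
  expect_equal(efficiency_from_distance(6.5, 8.5),
               1 / (1 + (6.5 / 8.5)^6))
  expect_equal(efficiency_from_distance(6.5, 8.5), 0.8333, tolerance = 1e-3)
  R <- seq(0.5, 25, by = 0.25)
  expect_true(all(diff(efficiency_from_distance(R, 8.5)) < 0))
})

test_that("distance inversion is exact and propagates both error sources", {
  inv <- distance_from_efficiency(0.5, 0, 8.5)
  expect_equal(inv$R_nm, 8.5)
  inv2 <- distance_from_efficiency(0.2, 0, 8.5)
  expect_equal(inv2$R_nm, 8.5 * 4^(1 / 6), tolerance = 1e-12)
  # round trip over a grid, 1e-9 relative
  R <- seq(2, 20, by = 0.5)
  back <- distance_from_efficiency(efficiency_from_distance(R, 8.5), 0, 8.5)$R_nm
  expect_equal(back, R, tolerance = 1e-9)
  # monotone decreasing in E
  E <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(distance_from_efficiency(E, 0, 8.5)$R_nm) < 0))
  expect_error(distance_from_efficiency(1, 0, 8.5), "inside")
  expect_error(distance_from_efficiency(0, 0, 8.5), "inside")
  # sigma grows with both sigma_E and the calibration uncertainty
  pts <- data.frame(R_nm = ruler_separation(ruler_lengths_bp),
                    E = efficiency_from_distance(
                      ruler_separation(ruler_lengths_bp), 8.5),
                    sigma_E = 0.02)
  fit <- fit_calibration(pts)
  s0 <- distance_from_efficiency(0.4, 0.00, fit)$sigma_R_nm
  s1 <- distance_from_efficiency(0.4, 0.02, fit)$sigma_R_nm
  expect_gt(s1, s0)
  expect_gt(s0, 0)  # calibration term alone already contributes
})

test_that("noise-free ruler data recovers the generative radius to 1e-6", {
  for (r_true in c(6, 8.5, 12)) {
    R <- ruler_separation(ruler_lengths_bp)
    pts <- data.frame(R_nm = R, E = efficiency_from_distance(R, r_true))
    fit <- fit_calibration(pts)
    expect_lt(abs(fit$r_eff / r_true - 1), 1e-6)
    # noise-free residuals vanish to solver tolerance
    expect_lt(max(abs(pts$E - predict(fit, R))), 1e-7)
  }
})

test_that("a single half-transfer point determines the radius exactly, with a warning", {
  expect_warning(
    fit <- fit_calibration(data.frame(R_nm = 8.5, E = 0.5),
                           ruler_geometry(linker_rel_uncertainty = 0)),
    "fewer than 3")
  expect_equal(unname(coef(fit)), 8.5, tolerance = 1e-6)
})

test_that("degenerate calibration inputs are rejected", {
  expect_error(fit_calibration(data.frame(R_nm = c(8, 8, 8),
                                          E = c(0.4, 0.5, 0.6))),
               "identical")
})

test_that("linker uncertainty never shrinks the calibration error", {
  R <- ruler_separation(ruler_lengths_bp)
  pts <- data.frame(R_nm = R, E = efficiency_from_distance(R, 8.5),
                    sigma_E = 0.02)
  sig <- vapply(c(0, 0.1, 0.3), function(u) {
    fit_calibration(pts, ruler_geometry(linker_rel_uncertainty = u))$sigma_r_eff
  }, numeric(1))
  expect_true(all(diff(sig) >= 0))
})
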