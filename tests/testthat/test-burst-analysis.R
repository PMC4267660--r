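test_that("burst selection keeps exactly the bins above threshold, in order", {
  tr <- make_trace(donor = c(1, 2, 30, 2, 35), acceptor = c(1, 1, 20, 2, 25))
  expect_identical(select_bursts(tr, threshold = 10), c(3L, 5L))
  # strict inequality: all-zero trace selects nothing even at threshold 0
  z <- make_trace(rep(0, 5), rep(0, 5))
  expect_identical(select_bursts(z, threshold = 0), integer(0))
  # idempotent and monotone in the threshold
  tr2 <- simulate_trace(sim_config(trace_length = 5000L, seed = 2L))
  b1 <- select_bursts(tr2, 10)
  expect_identical(b1, sort(b1))
  expect_true(all(select_bursts(tr2, 20) %in% b1))
})

test_that("false-positive rate of the threshold matches the Poisson tail", {
  mu <- 4  # 2 + 2 background, no bursts at all
  thr <- mu + 5 * sqrt(mu)
  tr <- simulate_trace(sim_config(trace_length = 2e5L,
                                  background_rate_donor = 2,
                                  background_rate_acceptor = 2,
                                  burst_rate = 0, seed = 8L))
  frac <- length(select_bursts(tr, thr)) / length(tr$donor)
  p_tail <- stats::ppois(floor(thr), mu, lower.tail = FALSE)
  expect_lt(abs(frac - p_tail), 3 * sqrt(p_tail * (1 - p_tail) / 2e5))
})

test_that("efficiencies are background-subtracted, unclamped, with the drop rule", {
  tr <- make_trace(donor = c(10, 40, 3), acceptor = c(30, 0, 5),
                   bg_donor = 0, bg_acceptor = 0)
  eff <- compute_efficiencies(tr, 1:2)
  expect_equal(eff$E, c(0.75, 0))
  # backgrounds (4, 4): raw (I_A=5, I_D=3) -> (1, -1), sum 0 -> dropped
  tr2 <- make_trace(donor = c(3), acceptor = c(5), bg_donor = 4, bg_acceptor = 4)
  expect_message(eff2 <- compute_efficiencies(tr2, 1L), "dropped 1")
  expect_identical(nrow(eff2), 0L)
  expect_error(compute_efficiencies(tr, 7L), "out of range")
})

test_that("Gaussian histogram fit recovers the moments of Gaussian samples", {
  set.seed(42)
  x <- rnorm(1e5, 0.6, 0.05)
  h <- fit_histogram(x)
  se_mean <- 0.05 / sqrt(1e5)
  expect_lt(abs(h$mean_E - 0.6), max(3 * se_mean, 3 * sqrt(h$cov["mu", "mu"])))
  expect_lt(abs(h$sigma_E / sd(x) - 1), 0.05)
  expect_equal(h$fwhm, 2 * sqrt(2 * log(2)) * h$sigma_E)
  expect_equal(sum(h$counts), h$n_in_range)
})

test_that("degenerate or under-sized histogram inputs fail explicitly", {
  expect_error(fit_histogram(rep(0.5, 200)), "identical")
  expect_error(fit_histogram(runif(10)), "10")
})

test_that("shot-noise width follows the binomial partitioning law", {
  expect_equal(shot_noise_sigma(0.5, 100), 0.05)
  expect_equal(sigma_to_fwhm(shot_noise_sigma(0.5, 100)),
               2 * sqrt(2 * log(2)) * 0.05)
  expect_error(shot_noise_sigma(0, 100), "inside")
  expect_error(shot_noise_sigma(1.2, 100), "inside")
  expect_error(shot_noise_sigma(0.5, 0), "positive")
})

test_that("width excess is the plain ratio and grows with linker jitter", {
  expect_equal(width_excess(0.15, 0.10), 1.5)
  expect_equal(width_excess(0.2, 0.2), 1.0)
  sig <- vapply(c(0, 0.3, 0.6, 1.0), function(s) {
    model <- if (s == 0) distance_fixed(8.5) else distance_linker(8.5, s)
    tr <- simulate_trace(sim_config(trace_length = 6e4L,
                                    distance_model = model,
                                    burst_brightness = 100, seed = 11L))
    eff <- suppressMessages(compute_efficiencies(tr, select_bursts(tr)))
    fit_histogram(eff)$sigma_E
  }, numeric(1))
  expect_true(all(diff(sig) > 0))          # monotone broadening
  shot <- shot_noise_sigma(0.5, 100)
  expect_true(all(sig[-1] > shot))         # observed >= shot-noise width
})
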