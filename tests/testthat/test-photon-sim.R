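test_that("burst photons land entirely in one channel at the transfer limits", {
  cfg1 <- sim_config(trace_length = 5000L, background_rate_donor = 0,
                     background_rate_acceptor = 0, burst_rate = 20,
                     distance_model = distance_fixed(0), seed = 1L)
  tr1 <- simulate_trace(cfg1)
  expect_true(all(tr1$donor == 0L))
  expect_gt(sum(tr1$acceptor), 0L)

  cfg0 <- sim_config(trace_length = 5000L, background_rate_donor = 0,
                     background_rate_acceptor = 0, burst_rate = 20,
                     distance_model = distance_fixed(Inf), seed = 1L)
  tr0 <- simulate_trace(cfg0)
  expect_true(all(tr0$acceptor == 0L))
  expect_gt(sum(tr0$donor), 0L)
})

test_that("burst-bin occupancy follows the configured Poisson rate", {
  counts <- vapply(1:20, function(s) {
    tr <- simulate_trace(sim_config(trace_length = 1e5L, burst_rate = 5,
                                    seed = s))
    length(tr$truth$burst_bins)
  }, numeric(1))
  # expected 500 bursts per trace; mean of 20 seeds within 3 sd of the mean
  expect_lt(abs(mean(counts) - 500), 3 * sqrt(500 / 20))
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.75)  # Poisson-like dispersion
})

test_that("a fixed seed reproduces every simulator output bit-exactly", {
  cfg <- sim_config(trace_length = 2000L, seed = 99L,
                    distance_model = distance_wlc(21, 2.1, sigma_link = 0.4))
  expect_identical(simulate_trace(cfg), simulate_trace(cfg))
  expect_identical(simulate_calibration_dataset(seed = 7L),
                   simulate_calibration_dataset(seed = 7L))
  expect_identical(simulate_rna_dataset(seed = 7L),
                   simulate_rna_dataset(seed = 7L))
})

test_that("mean burst efficiency converges to the Forster value (binomial law)", {
  r <- 9.5; r_eff <- 8.5
  E_true <- 1 / (1 + (r / r_eff)^6)
  tr <- simulate_trace(sim_config(trace_length = 4e4L,
                                  background_rate_donor = 0,
                                  background_rate_acceptor = 0,
                                  burst_rate = 10, burst_brightness = 100,
                                  distance_model = distance_fixed(r),
                                  r_eff = r_eff, seed = 3L))
  eff <- compute_efficiencies(tr, select_bursts(tr, threshold = 10))
  N_tot <- sum(eff$I_A + eff$I_D)
  se <- sqrt(E_true * (1 - E_true) / N_tot)
  expect_lt(abs(mean(eff$E) - E_true), 3.5 * se)
})

test_that("channel sums scale linearly with trace length", {
  # per-bin expected total: 2 background + (5/1000)*100 burst photons = 2.5;
  # per-bin variance: 2 (Poisson bg) + p*E[N^2] - (p*E[N])^2 ~ 52.3 with
  # p = 0.005 and N ~ Poisson(100)
  mu_bin <- 2.5
  var_bin <- 2 + 0.005 * (100 + 100^2) - 0.5^2
  means <- vapply(c(1e4L, 4e4L), function(n) {
    tr <- simulate_trace(sim_config(trace_length = n, seed = 10L + n))
    (sum(tr$donor) + sum(tr$acceptor)) / n
  }, numeric(1))
  expect_lt(abs(means[1] - mu_bin), 3 * sqrt(var_bin / 1e4))
  expect_lt(abs(means[2] - mu_bin), 3 * sqrt(var_bin / 4e4))
})

test_that("calibration datasets lie exactly on the Forster curve when noise-free", {
  d <- simulate_calibration_dataset(r_eff = 8.5, noise_sd_E = 0, seed = 1L)
  expect_equal(d$E, 1 / (1 + (d$R_nm / 8.5)^6), tolerance = 1e-12)
  expect_equal(d$R_nm[d$bp == 45], 15.3)
  dn <- simulate_calibration_dataset(noise_sd_E = 0.3, seed = 5L)
  expect_true(all(dn$E > 0 & dn$E < 1))  # truncation to (0, 1)
})

test_that("RNA datasets follow the configured linear trend", {
  d <- simulate_rna_dataset(a = 6.8, b = 7.2e-4, lengths_nt = 1000,
                            scatter_sd = 0, seed = 1L)
  expect_equal(d$distance_nm, 7.52)
  flat <- simulate_rna_dataset(a = 6.8, b = 0, scatter_sd = 0, seed = 1L)
  expect_true(all(flat$distance_nm == 6.8))

  # empirical scatter about the line matches scatter_sd
  res <- unlist(lapply(1:2000, function(s) {
    d <- simulate_rna_dataset(scatter_sd = 1.2, seed = s)
    d$distance_nm - (6.8 + 7.2e-4 * d$length_nt)
  }))
  expect_equal(sd(res), 1.2, tolerance = 0.03)
})

test_that("invalid simulator configurations are rejected with the field named", {
  expect_error(sim_config(background_rate_donor = -1), "background_rate_donor")
  expect_error(sim_config(burst_rate = -2), "burst_rate")
  expect_error(sim_config(bin_width = 0), "bin_width")
  expect_error(simulate_rna_dataset(lengths_nt = integer(0)), "empty")
  expect_error(simulate_calibration_dataset(noise_sd_E = -0.1), "noise_sd_E")
  expect_error(distance_linker(8, -1), "sigma_link")
})
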