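#' Select single-molecule burst bins from a photon trace
#'
#' A bin is a burst candidate when its raw donor + acceptor count is
#' strictly greater than the threshold. Raw (not background-subtracted)
#' totals are compared, and the default threshold is
#' \eqn{\mu_{bg} + 5\sqrt{\mu_{bg}}} with \eqn{\mu_{bg}} the total mean
#' background per bin.
#'
#' @param trace a \code{"photon_trace"}.
#' @param threshold counts per bin (>= 0); \code{NULL} uses the default rule.
#' @return Integer vector of selected bin indices (1-based, ascending).
#' @export
select_bursts <- function(trace, threshold = NULL) {
  stopifnot(inherits(trace, "photon_trace"))
  if (is.null(threshold)) {
    mu <- trace$background_rate_donor + trace$background_rate_acceptor
    threshold <- mu + 5 * sqrt(mu)
  }
  check_nonneg(threshold, "threshold")
  which(trace$donor + trace$acceptor > threshold)
}

#' Per-bin FRET efficiencies of selected bursts
#'
#' Subtracts the known mean background rate of each channel from the raw
#' counts (expected-value subtraction, not per-bin estimation) and computes
#' \eqn{E_i = I_A^i / (I_A^i + I_D^i)}. Bins whose background-subtracted
#' total is <= 0 are dropped (reported via \code{message}). Efficiencies are
#' not clamped to [0, 1], so background leakage stays visible in the
#' histogram tails.
#'
#' @param trace a \code{"photon_trace"}.
#' @param burst_bins bin indices, e.g. from [select_bursts()].
#' @return data.frame with columns \code{bin}, \code{I_D}, \code{I_A},
#'   \code{E} (one row per retained burst).
#' @export
compute_efficiencies <- function(trace, burst_bins) {
  stopifnot(inherits(trace, "photon_trace"))
  n <- length(trace$donor)
  if (length(burst_bins) == 0L) {
    return(data.frame(bin = integer(0), I_D = numeric(0),
                      I_A = numeric(0), E = numeric(0)))
  }
  if (any(burst_bins < 1L) || any(burst_bins > n)) {
    stop("burst bin index out of range", call. = FALSE)
  }
  I_D <- trace$donor[burst_bins] - trace$background_rate_donor
  I_A <- trace$acceptor[burst_bins] - trace$background_rate_acceptor
  keep <- (I_A + I_D) > 0
  if (any(!keep)) {
    message(sprintf("compute_efficiencies: dropped %d of %d bins with non-positive total counts",
                    sum(!keep), length(keep)))
  }
  data.frame(bin = as.integer(burst_bins[keep]),
             I_D = I_D[keep], I_A = I_A[keep],
             E = I_A[keep] / (I_A[keep] + I_D[keep]))
}

#' Fit a Gaussian to a FRET efficiency histogram
#'
#' Histograms the per-burst efficiencies (default 40 bins over [-0.1, 1.1])
#' and fits \eqn{A \exp(-(x - \mu)^2 / 2\sigma^2)} to the bin counts by
#' least squares, as smFRET histograms are conventionally summarised. The
#' sample mean and sd are also kept for comparison with the binned fit.
#'
#' @param samples numeric vector of efficiencies, or a data.frame from
#'   [compute_efficiencies()] (its \code{E} column is used).
#' @param n_bins number of histogram bins.
#' @param range histogram support, \code{c(lo, hi)}.
#' @param min_samples minimum number of efficiencies required.
#' @return Object of class \code{"fret_histogram"}: \code{breaks},
#'   \code{counts}, \code{mids}, \code{mean_E}, \code{sigma_E},
#'   \code{amplitude}, \code{fwhm}, fit covariance \code{cov}, sample
#'   moments \code{sample_mean}/\code{sample_sd}, and \code{n}.
#' @export
fit_histogram <- function(samples, n_bins = 40L, range = c(-0.1, 1.1),
                          min_samples = 50L) {
  if (is.data.frame(samples)) samples <- samples$E
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < min_samples) {
    stop(sprintf("only %d efficiency samples; at least %d required for a histogram fit",
                 n, min_samples), call. = FALSE)
  }
  if (stats::sd(samples) == 0) {
    stop("degenerate histogram: all efficiency samples identical", call. = FALSE)
  }
  breaks <- seq(range[1], range[2], length.out = n_bins + 1L)
  inside <- samples >= range[1] & samples <= range[2]
  h <- graphics::hist(samples[inside], breaks = breaks, plot = FALSE)
  mids <- h$mids
  counts <- h$counts

  start <- list(mu = mean(samples), sigma = max(stats::sd(samples), 1e-3),
                A = max(counts))
  fit <- tryCatch(
    minpack.lm::nlsLM(counts ~ A * exp(-(mids - mu)^2 / (2 * sigma^2)),
                      start = start,
                      lower = c(mu = range[1], sigma = 1e-6, A = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian histogram fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  structure(
    list(breaks = breaks, counts = counts, mids = mids,
         mean_E = unname(cf["mu"]), sigma_E = abs(unname(cf["sigma"])),
         amplitude = unname(cf["A"]),
         fwhm = sigma_to_fwhm(abs(unname(cf["sigma"]))),
         cov = stats::vcov(fit),
         sample_mean = mean(samples), sample_sd = stats::sd(samples),
         n = n, n_in_range = sum(inside)),
    class = "fret_histogram"
  )
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("FRET efficiency histogram: %d samples in %d bins\n",
              x$n, length(x$counts)))
  cat(sprintf("  Gaussian fit: mean E = %.4f, sigma = %.4f, FWHM = %.4f\n",
              x$mean_E, x$sigma_E, x$fwhm))
  cat(sprintf("  sample moments: mean = %.4f, sd = %.4f\n",
              x$sample_mean, x$sample_sd))
  if (x$mean_E < 0 || x$mean_E > 1) {
    cat("  note: fitted mean lies outside [0, 1]\n")
  }
  invisible(x)
}

#' @export
plot.fret_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$counts, type = "h", lwd = 3, col = "grey60",
                 xlab = "FRET efficiency E", ylab = "bursts", ...)
  xx <- seq(min(x$breaks), max(x$breaks), length.out = 400)
  graphics::lines(xx, x$amplitude * exp(-(xx - x$mean_E)^2 / (2 * x$sigma_E^2)),
                  col = "black", lwd = 2)
  invisible(x)
}

#' Shot-noise (binomial partitioning) width of a FRET histogram
#'
#' The minimum histogram width attainable from photon statistics alone:
#' partitioning N photons with probability E gives
#' \eqn{\sigma_E = \sqrt{E(1-E)/N}}.
#'
#' @param mean_E mean efficiency, strictly in (0, 1).
#' @param mean_total_photons mean total photons per burst, > 0.
#' @return Standard deviation of E at the shot-noise limit.
#' @seealso [sigma_to_fwhm()] to express it as a FWHM, [width_excess()].
#' @export
shot_noise_sigma <- function(mean_E, mean_total_photons) {
  if (!is.numeric(mean_E) || any(mean_E <= 0) || any(mean_E >= 1)) {
    stop("'mean_E' must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(mean_total_photons <= 0)) {
    stop("'mean_total_photons' must be positive", call. = FALSE)
  }
  sqrt(mean_E * (1 - mean_E) / mean_total_photons)
}

#' Ratio of an observed histogram width to the shot-noise width
#'
#' @param observed_fwhm fitted histogram FWHM (> 0).
#' @param shot_noise_fwhm shot-noise-limited FWHM (> 0), e.g.
#'   \code{sigma_to_fwhm(shot_noise_sigma(E, N))}.
#' @return The dimensionless width excess; 1 means shot-noise limited,
#'   values above 1 indicate extra broadening (linker motion, chain
#'   fluctuation).
#' @export
width_excess <- function(observed_fwhm, shot_noise_fwhm) {
  check_pos(observed_fwhm, "observed_fwhm")
  check_pos(shot_noise_fwhm, "shot_noise_fwhm")
  observed_fwhm / shot_noise_fwhm
}
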