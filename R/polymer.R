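#' Polymer parameters for contour-length conversion
#'
#' @param rise_per_nt contour length per nucleotide of ssRNA, nm (0.59).
#' @param lp persistence length, nm (2.1 for ssRNA at 5 mM MgCl2).
#' @param rounding convention used to turn a contour length in nm into a
#'   whole nucleotide count. \code{"ceil"} (default) counts every started
#'   nucleotide; \code{"floor"} and \code{"nearest"} are available because
#'   no single convention reproduces all published endpoint pairs.
#' @param match_statistic which feature of the worm-like-chain end-to-end
#'   distribution is matched to a measured distance when inverting for the
#'   contour length: \code{"rms"} (default, closed form), \code{"mean"} or
#'   \code{"mode"} (numerical).
#' @return Object of class \code{"polymer_params"}.
#' @export
polymer_params <- function(rise_per_nt = 0.59, lp = 2.1,
                           rounding = c("ceil", "floor", "nearest"),
                           match_statistic = c("rms", "mean", "mode")) {
  check_pos(rise_per_nt, "rise_per_nt")
  check_pos(lp, "lp")
  structure(
    list(rise_per_nt = rise_per_nt, lp = lp,
         rounding = match.arg(rounding),
         match_statistic = match.arg(match_statistic)),
    class = "polymer_params"
  )
}

# nm -> whole nucleotides under a rounding convention; the 1e-9 guard keeps
# exact multiples of the rise from being bumped by floating-point noise
.round_nt <- function(x, convention) {
  nt <- switch(convention,
    ceil = ceiling(x - 1e-9),
    floor = floor(x + 1e-9),
    nearest = round(x)
  )
  as.integer(pmax(nt, 1L))
}

.new_contour <- function(L_nm, params, model, statistic = NA_character_) {
  structure(
    list(L_nm = L_nm,
         L_nt = .round_nt(L_nm / params$rise_per_nt, params$rounding),
         model = model, statistic = statistic, params = params),
    class = "contour_estimate"
  )
}

#' @export
print.contour_estimate <- function(x, ...) {
  extra <- if (x$model == "wlc") {
    sprintf(" (lp = %g nm, matched %s)", x$params$lp, x$statistic)
  } else ""
  cat(sprintf("Exterior-loop contour estimate [%s%s]:\n", x$model, extra))
  for (i in seq_along(x$L_nm)) {
    cat(sprintf("  L = %.4g nm  ->  %d nt (%s, %g nm/nt)\n",
                x$L_nm[i], x$L_nt[i], x$params$rounding, x$params$rise_per_nt))
  }
  invisible(x)
}

#' Rigid-rod contour length for an end-to-end distance
#'
#' Under a rigid chain the contour length equals the end-to-end distance;
#' the nucleotide count is \code{d / rise_per_nt} rounded per the
#' convention in \code{params} (default ceiling).
#'
#' @param d end-to-end distance(s), nm (> 0).
#' @param params a [polymer_params()].
#' @return A \code{"contour_estimate"} with \code{L_nm = d} and integer
#'   \code{L_nt}.
#' @examples
#' rigid_contour_nt(c(5, 9))  # 9 and 16 nt
#' @export
rigid_contour_nt <- function(d, params = polymer_params()) {
  stopifnot(inherits(params, "polymer_params"))
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop("'d' must be positive", call. = FALSE)
  }
  .new_contour(d, params, model = "rigid")
}

# unnormalised log radial density of the mean-field semiflexible chain:
#   P(r) proportional to r^2 (1-(r/L)^2)^(-9/2) exp(-3L / (4 lp (1-(r/L)^2)))
# and of the Gaussian chain: r^2 exp(-3 r^2 / (4 lp L))
.wlc_logg <- function(r, L, lp, chain_model) {
  x2 <- (r / L)^2
  if (chain_model == "gaussian") {
    2 * log(r) - 3 * r^2 / (4 * lp * L)
  } else {
    u <- 1 - x2
    2 * log(r) - 4.5 * log(u) - 3 * L / (4 * lp * u)
  }
}

# composite evaluation grid on (0, L), log-dense near r = L so that the
# near-rod spike (lp >> L) is resolved
.wlc_grid <- function(L) {
  u <- c(10^seq(-13, -1.02, length.out = 700),
         seq(0.1, 1 - 1e-9, length.out = 1500))
  rev(L * sqrt(1 - u))
}

# normalisation constant of exp(.wlc_logg) on (0, L)
.wlc_norm <- function(L, lp, chain_model) {
  f <- function(r) exp(.wlc_logg(r, L, lp, chain_model))
  val <- tryCatch(
    stats::integrate(f, 0, L, rel.tol = 1e-11, subdivisions = 1000L)$value,
    error = function(e) NA_real_
  )
  if (!is.finite(val) || val <= 0) {
    g <- .wlc_grid(L)
    y <- f(g)
    val <- sum(diff(g) * (y[-1] + y[-length(y)]) / 2)
  }
  val
}

#' Radial end-to-end density of a semiflexible chain
#'
#' The mean-field interpolation density
#' \deqn{P(r) \propto r^2 (1-(r/L)^2)^{-9/2}
#'       \exp\!\left(-\frac{3L}{4 l_p (1-(r/L)^2)}\right)}
#' normalised numerically so that \eqn{\int_0^L P(r)\,dr = 1}. It reproduces
#' the rigid-rod limit (mass concentrating at \eqn{r = L} for
#' \eqn{l_p \gg L}) and the Gaussian-coil limit (for \eqn{L \gg l_p} it
#' approaches \eqn{r^2 e^{-3r^2/(4 l_p L)}}, also available directly via
#' \code{chain_model = "gaussian"}).
#'
#' @param r evaluation distance(s), nm; density is 0 outside [0, L).
#' @param L contour length, nm (> 0).
#' @param lp persistence length, nm (> 0).
#' @param chain_model \code{"meanfield"} (default) or \code{"gaussian"}.
#' @return Probability density value(s), 1/nm.
#' @export
wlc_pdf <- function(r, L, lp, chain_model = c("meanfield", "gaussian")) {
  chain_model <- match.arg(chain_model)
  check_pos(L, "L")
  check_pos(lp, "lp")
  if (!is.numeric(r) || any(is.na(r))) stop("'r' must be numeric", call. = FALSE)
  norm <- .wlc_norm(L, lp, chain_model)
  out <- numeric(length(r))
  ok <- r > 0 & r < L
  out[ok] <- exp(.wlc_logg(r[ok], L, lp, chain_model)) / norm
  out
}

#' Root-mean-square end-to-end distance of a worm-like chain
#'
#' Closed-form second moment of the continuous worm-like chain,
#' \deqn{\langle R^2 \rangle = 2 l_p L - 2 l_p^2 (1 - e^{-L/l_p}),}
#' returning its square root. Approaches \eqn{L} for \eqn{L \ll l_p}
#' (rigid rod) and \eqn{\sqrt{2 l_p L}} for \eqn{L \gg l_p} (Gaussian coil).
#'
#' @param L contour length(s), nm (> 0).
#' @param lp persistence length, nm (> 0).
#' @return RMS end-to-end distance(s), nm (always < L).
#' @export
wlc_rms <- function(L, lp) {
  if (any(L <= 0) || any(lp <= 0)) stop("'L' and 'lp' must be positive", call. = FALSE)
  sqrt(2 * lp * L - 2 * lp^2 * (1 - exp(-L / lp)))
}

# moment / mode of the normalised wlc density
.wlc_statistic <- function(L, lp, statistic, chain_model = "meanfield") {
  if (statistic == "rms") return(wlc_rms(L, lp))
  norm <- .wlc_norm(L, lp, chain_model)
  if (statistic == "mean") {
    f <- function(r) r * exp(.wlc_logg(r, L, lp, chain_model)) / norm
    return(stats::integrate(f, 0, L, rel.tol = 1e-10,
                            subdivisions = 1000L)$value)
  }
  # mode: maximise the smooth log density
  stats::optimize(function(r) .wlc_logg(r, L, lp, chain_model),
                  c(L * 1e-8, L * (1 - 1e-10)), maximum = TRUE,
                  tol = 1e-11 * L)$maximum
}

#' Draw end-to-end distances from the worm-like-chain density
#'
#' Inverse-CDF sampling on a composite grid dense near \eqn{r = L}, so the
#' near-rigid regime is handled as well as the coil regime.
#'
#' @param n number of draws.
#' @param L,lp contour and persistence length, nm.
#' @param chain_model \code{"meanfield"} or \code{"gaussian"}.
#' @return Numeric vector of distances in (0, L).
#' @export
wlc_sample <- function(n, L, lp, chain_model = c("meanfield", "gaussian")) {
  chain_model <- match.arg(chain_model)
  check_pos(L, "L")
  check_pos(lp, "lp")
  if (n == 0L) return(numeric(0))
  g <- .wlc_grid(L)
  y <- exp(.wlc_logg(g, L, lp, chain_model))
  cdf <- c(0, cumsum(diff(g) * (y[-1] + y[-length(y)]) / 2))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  stats::approx(cdf[keep], g[keep], xout = stats::runif(n),
                rule = 2)$y
}

#' Invert a measured end-to-end distance to a contour length
#'
#' Solves for the contour length \eqn{L} at which the chosen feature of the
#' worm-like-chain end-to-end distribution (\code{match_statistic} in
#' \code{params}: rms, mean or mode) equals the measured distance
#' \code{d}, by root bracketing and bisection; the rms statistic uses the
#' closed form [wlc_rms()], mean and mode use quadrature/optimisation of
#' [wlc_pdf()].
#'
#' @param d measured end-to-end distance, nm (> 0, scalar).
#' @param lp persistence length, nm; defaults to \code{params$lp}.
#' @param params a [polymer_params()].
#' @param chain_model passed to the density for mean/mode statistics.
#' @return A \code{"contour_estimate"} with the solved \code{L_nm} and the
#'   rounded nucleotide count \code{L_nt}.
#' @examples
#' invert_contour_length(9, lp = 2.1)   # ~21.4 nm contour
#' @export
invert_contour_length <- function(d, lp = NULL, params = polymer_params(),
                                  chain_model = "meanfield") {
  stopifnot(inherits(params, "polymer_params"))
  check_pos(d, "d")
  if (is.null(lp)) lp <- params$lp
  check_pos(lp, "lp")
  statistic <- params$match_statistic
  stat_fun <- function(L) .wlc_statistic(L, lp, statistic, chain_model)

  # statistic(L) < L for all L, and it is increasing in L, so L = d is a
  # lower bracket; double upward until the statistic exceeds d
  lo <- d
  if (stat_fun(lo) >= d) lo <- d / 2           # defensive; should not trigger
  hi <- max(2 * d, d^2 / lp)
  it <- 0L
  while (stat_fun(hi) < d) {
    hi <- hi * 2
    it <- it + 1L
    if (it > 60L) {
      stop(sprintf("cannot bracket a contour length whose %s reaches %g nm (lp = %g nm)",
                   statistic, d, lp), call. = FALSE)
    }
  }
  root <- stats::uniroot(function(L) stat_fun(L) - d, c(lo, hi),
                         tol = 1e-10 * max(d, 1))
  .new_contour(root$root, list(rise_per_nt = params$rise_per_nt, lp = lp,
                               rounding = params$rounding),
               model = "wlc", statistic = statistic)
}

#' Monte-Carlo FRET histogram predicted from chain fluctuations
#'
#' Draws per-burst end-to-end distances from the worm-like-chain density,
#' converts them to efficiencies through the calibration, partitions a
#' photon budget binomially, and fits the resulting histogram exactly as
#' [fit_histogram()] does for measured traces. Used to compare predicted
#' conformational broadening against observed histogram widths.
#'
#' @param L,lp contour and persistence length, nm.
#' @param model a [fit_calibration()] fit or bare effective Forster radius.
#' @param mean_total_photons photons per burst (binomially partitioned).
#' @param n_draws number of simulated bursts.
#' @param sigma_link optional per-axis linker jitter, nm.
#' @param seed integer seed or \code{NULL}.
#' @param n_bins,range histogram settings as in [fit_histogram()].
#' @param chain_model \code{"meanfield"} or \code{"gaussian"}.
#' @return A \code{"fret_histogram"}; its \code{predicted} element records
#'   the generative parameters.
#' @export
predict_fret_histogram <- function(L, lp, model, mean_total_photons = 100,
                                   n_draws = 5000L, sigma_link = 0,
                                   seed = NULL, n_bins = 40L,
                                   range = c(-0.1, 1.1),
                                   chain_model = "meanfield") {
  r_eff <- .r_eff(model)
  check_pos(mean_total_photons, "mean_total_photons")
  check_nonneg(sigma_link, "sigma_link")
  N <- max(1L, as.integer(round(mean_total_photons)))
  with_seed(seed, {
    r <- wlc_sample(n_draws, L, lp, chain_model)
    if (sigma_link > 0) {
      r <- sqrt((r + stats::rnorm(n_draws, 0, sigma_link))^2 +
                  stats::rnorm(n_draws, 0, sigma_link)^2 +
                  stats::rnorm(n_draws, 0, sigma_link)^2)
    }
    E <- 1 / (1 + (r / r_eff)^6)
    E_obs <- stats::rbinom(n_draws, N, E) / N
    h <- fit_histogram(E_obs, n_bins = n_bins, range = range)
    h$predicted <- list(L = L, lp = lp, r_eff = r_eff, N = N,
                        sigma_link = sigma_link, chain_model = chain_model)
    h
  })
}

#' Deterministic FRET histogram width from chain fluctuations
#'
#' Quadrature companion of [predict_fret_histogram()]: the variance of the
#' per-burst efficiency decomposes exactly into a shot-noise term and a
#' conformational term,
#' \deqn{Var(E_{obs}) = \mathrm{E}[E(r)(1-E(r))]/N + Var(E(r)),}
#' with \eqn{r} distributed per the worm-like-chain density. Both terms are
#' computed by quadrature, so the result is smooth and Monte-Carlo free.
#'
#' @param L,lp contour and persistence length, nm.
#' @param model calibration fit or bare effective Forster radius, nm.
#' @param mean_total_photons photons per burst.
#' @param chain_model density variant.
#' @return List with \code{sigma} (total sd of E), \code{fwhm},
#'   \code{mean_E}, \code{shot_sigma} and \code{conformational_sigma}.
#' @export
predict_width <- function(L, lp, model, mean_total_photons = 100,
                          chain_model = "meanfield") {
  r_eff <- .r_eff(model)
  check_pos(L, "L")
  check_pos(lp, "lp")
  check_pos(mean_total_photons, "mean_total_photons")
  out <- .predicted_sigma_E(L, lp, r_eff, mean_total_photons, chain_model)
  out$fwhm <- sigma_to_fwhm(out$sigma)
  out[c("sigma", "fwhm", "mean_E", "shot_sigma", "conformational_sigma")]
}

# deterministic width prediction: Var(E_obs) = E[E(1-E)]/N + Var(E(r))
# under r ~ wlc density (quadrature)
.predicted_sigma_E <- function(L, lp, r_eff, N, chain_model = "meanfield") {
  norm <- .wlc_norm(L, lp, chain_model)
  pdf <- function(r) exp(.wlc_logg(r, L, lp, chain_model)) / norm
  Eof <- function(r) 1 / (1 + (r / r_eff)^6)
  m1 <- stats::integrate(function(r) Eof(r) * pdf(r), 0, L,
                         rel.tol = 1e-10, subdivisions = 1000L)$value
  m2 <- stats::integrate(function(r) Eof(r)^2 * pdf(r), 0, L,
                         rel.tol = 1e-10, subdivisions = 1000L)$value
  shot <- stats::integrate(function(r) Eof(r) * (1 - Eof(r)) * pdf(r), 0, L,
                           rel.tol = 1e-10, subdivisions = 1000L)$value / N
  list(sigma = sqrt(shot + max(m2 - m1^2, 0)), mean_E = m1,
       conformational_sigma = sqrt(max(m2 - m1^2, 0)),
       shot_sigma = sqrt(shot))
}

#' Infer the effective persistence length from an observed histogram width
#'
#' Solves for the persistence length at which the predicted FRET histogram
#' width equals the observed one. The prediction uses the same statistic as
#' the observation — a Gaussian fit to a binned Monte-Carlo histogram
#' ([predict_fret_histogram()]) — with common random numbers across
#' persistence lengths, so the predicted width is a smooth function of
#' \code{lp}. The width is not globally monotone in \code{lp} (a collapsed
#' coil also gives a narrow, high-E histogram), so the solve is restricted
#' to the rigid-side branch, from the width maximum down towards the rigid
#' (shot-noise) limit: a narrower histogram there means a more rigid chain.
#'
#' @param observed_fwhm observed histogram FWHM (must be at least the
#'   shot-noise FWHM at \code{mean_E} and \code{mean_total_photons}).
#' @param mean_E observed mean efficiency in (0, 1).
#' @param L exterior-loop contour length, nm.
#' @param model calibration fit or bare effective Forster radius, nm.
#' @param mean_total_photons mean photons per burst.
#' @param bracket search interval for lp, nm.
#' @param n_draws Monte-Carlo draws per width evaluation.
#' @param seed seed of the common random numbers.
#' @param chain_model density variant.
#' @return The inferred persistence length in nm. If the observed width is
#'   indistinguishable from (or below) even the most rigid prediction in
#'   the bracket, the upper bracket is returned with a warning and
#'   attribute \code{lower_bound = TRUE}: the chain is effectively rigid
#'   and only a lower bound on its rigidity is identified.
#' @export
infer_persistence_length <- function(observed_fwhm, mean_E, L, model,
                                     mean_total_photons = 100,
                                     bracket = c(0.2, 500),
                                     n_draws = 20000L, seed = 1L,
                                     chain_model = "meanfield") {
  r_eff <- .r_eff(model)
  check_pos(observed_fwhm, "observed_fwhm")
  check_pos(L, "L")
  N <- mean_total_photons
  shot_fwhm <- sigma_to_fwhm(shot_noise_sigma(mean_E, N))
  if (observed_fwhm < shot_fwhm * (1 - 1e-9)) {
    stop(sprintf("observed FWHM (%.4g) is below the shot-noise limit (%.4g): inconsistent input",
                 observed_fwhm, shot_fwhm), call. = FALSE)
  }
  pred <- function(lp) {
    predict_fret_histogram(L, lp, r_eff, mean_total_photons,
                           n_draws = n_draws, seed = seed,
                           chain_model = chain_model)$fwhm
  }
  # locate the floppy-side width maximum on a log grid, then solve on the
  # decreasing branch towards the rigid limit
  lp_grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 25L))
  w_grid <- vapply(lp_grid, function(lp) {
    tryCatch(pred(lp), error = function(e) NA_real_)  # degenerate histograms
  }, numeric(1))
  if (all(is.na(w_grid))) {
    stop("width prediction failed over the whole lp bracket", call. = FALSE)
  }
  i_max <- which.max(w_grid)
  if (observed_fwhm > w_grid[i_max] * (1 + 1e-9)) {
    stop(sprintf("observed FWHM (%.4g) exceeds the widest prediction (%.4g at lp = %.3g nm): no bracket",
                 observed_fwhm, w_grid[i_max], lp_grid[i_max]), call. = FALSE)
  }
  if (observed_fwhm <= w_grid[length(w_grid)]) {
    warning("observed width is at or below the most rigid prediction in the bracket; ",
            "returning the upper bracket as a lower bound on rigidity")
    return(structure(bracket[2], lower_bound = TRUE))
  }
  stats::uniroot(function(lp) pred(lp) - observed_fwhm,
                 c(lp_grid[i_max], bracket[2]), tol = 1e-4)$root
}
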