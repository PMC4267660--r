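#' Distance models for the trace simulator
#'
#' The generative inter-dye distance of a diffusing molecule, drawn once per
#' burst:
#' \describe{
#'   \item{\code{distance_fixed(r)}}{a rigid species at distance \code{r} nm.}
#'   \item{\code{distance_linker(r, sigma_link)}}{a rigid species whose dyes
#'     jitter by an isotropic 3-D Gaussian displacement of per-axis standard
#'     deviation \code{sigma_link} nm (fluorophore-linker motion); the
#'     realised distance is the modulus of the displaced separation vector,
#'     i.e. the jitter adds to \code{r} in quadrature.}
#'   \item{\code{distance_wlc(L, lp, sigma_link)}}{a semiflexible chain of
#'     contour length \code{L} nm and persistence length \code{lp} nm whose
#'     end-to-end distance is drawn from the worm-like-chain radial density
#'     ([wlc_pdf()]), with optional linker jitter on top.}
#' }
#'
#' @param r fixed inter-dye distance, nm (>= 0; \code{Inf} allowed as the
#'   zero-transfer limit).
#' @param sigma_link per-axis linker jitter, nm (>= 0).
#' @param L,lp chain contour and persistence length, nm.
#' @return A distance-model object used by [sim_config()].
#' @name distance_models
NULL

#' @rdname distance_models
#' @export
distance_fixed <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0) {
    stop("'r' must be a single non-negative number", call. = FALSE)
  }
  structure(list(type = "fixed", r = r), class = "fret_distance_model")
}

#' @rdname distance_models
#' @export
distance_linker <- function(r, sigma_link) {
  m <- distance_fixed(r)
  check_nonneg(sigma_link, "sigma_link")
  m$type <- "linker"
  m$sigma_link <- sigma_link
  m
}

#' @rdname distance_models
#' @export
distance_wlc <- function(L, lp, sigma_link = 0) {
  check_pos(L, "L")
  check_pos(lp, "lp")
  check_nonneg(sigma_link, "sigma_link")
  structure(list(type = "wlc", L = L, lp = lp, sigma_link = sigma_link),
            class = "fret_distance_model")
}

# draw n per-burst distances from a distance model
.draw_distances <- function(model, n) {
  if (n == 0L) return(numeric(0))
  r <- switch(model$type,
    fixed = rep(model$r, n),
    linker = rep(model$r, n),
    wlc = wlc_sample(n, model$L, model$lp),
    stop("unknown distance model type: ", model$type, call. = FALSE)
  )
  s <- model$sigma_link
  if (!is.null(s) && s > 0) {
    r <- sqrt((r + stats::rnorm(n, 0, s))^2 +
                stats::rnorm(n, 0, s)^2 + stats::rnorm(n, 0, s)^2)
  }
  r
}

#' Configuration of the photon-trace simulator
#'
#' @param bin_width bin width in seconds (acquisition default 1 ms).
#' @param trace_length number of bins.
#' @param background_rate_donor,background_rate_acceptor mean background
#'   counts per bin in each channel.
#' @param burst_rate expected number of single-molecule bursts per 1000 bins
#'   (a proxy for the ~90 pM occupancy of the confocal volume; each burst
#'   occupies a single bin).
#' @param burst_brightness mean total burst photons per burst bin; realised
#'   counts are Poisson.
#' @param distance_model a [distance_models] object giving the generative
#'   inter-dye distance.
#' @param r_eff effective Forster radius, nm; the detection factor gamma is
#'   fixed at 1 and absorbed here.
#' @param sample_id,condition metadata labels carried on the trace
#'   (condition conventionally "TM" or "TE").
#' @param seed integer seed; a fixed seed makes the simulated trace
#'   bit-reproducible. \code{NULL} uses the current RNG stream.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(bin_width = 1e-3,
                       trace_length = 20000L,
                       background_rate_donor = 1,
                       background_rate_acceptor = 1,
                       burst_rate = 5,
                       burst_brightness = 100,
                       distance_model = distance_fixed(8.5),
                       r_eff = 8.5,
                       sample_id = "sim",
                       condition = "TM",
                       seed = NULL) {
  check_pos(bin_width, "bin_width")
  check_nonneg(trace_length, "trace_length")
  check_nonneg(background_rate_donor, "background_rate_donor")
  check_nonneg(background_rate_acceptor, "background_rate_acceptor")
  check_nonneg(burst_rate, "burst_rate")
  check_nonneg(burst_brightness, "burst_brightness")
  check_pos(r_eff, "r_eff")
  stopifnot(inherits(distance_model, "fret_distance_model"))
  structure(
    list(bin_width = bin_width, trace_length = as.integer(trace_length),
         background_rate_donor = background_rate_donor,
         background_rate_acceptor = background_rate_acceptor,
         burst_rate = burst_rate, burst_brightness = burst_brightness,
         distance_model = distance_model, r_eff = r_eff,
         sample_id = sample_id, condition = condition, seed = seed),
    class = "sim_config"
  )
}

#' Simulate a binned two-channel photon trace
#'
#' Every bin receives Poisson background in each channel. A bin hosts a
#' single-molecule burst with probability \code{burst_rate/1000}; a burst
#' contributes \eqn{N \sim Poisson(burst\_brightness)} photons, partitioned
#' into the acceptor channel as \eqn{Binomial(N, E(r))} with
#' \eqn{E(r) = 1/(1 + (r/r_{eff})^6)} and \eqn{r} drawn per burst from the
#' configured distance model.
#'
#' @param config a [sim_config()].
#' @return An object of class \code{"photon_trace"}: integer vectors
#'   \code{donor} and \code{acceptor}, the bin width, the (known) background
#'   rates, \code{metadata}, and a \code{truth} list (burst bin indices,
#'   per-burst distances and photon counts) for validation work.
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$trace_length
    donor <- stats::rpois(n, config$background_rate_donor)
    acceptor <- stats::rpois(n, config$background_rate_acceptor)
    is_burst <- stats::runif(n) < config$burst_rate / 1000
    idx <- which(is_burst)
    r <- .draw_distances(config$distance_model, length(idx))
    E <- 1 / (1 + (r / config$r_eff)^6)
    E[r == 0] <- 1                      # contact limit
    N <- stats::rpois(length(idx), config$burst_brightness)
    acc_burst <- stats::rbinom(length(idx), N, E)
    donor[idx] <- donor[idx] + (N - acc_burst)
    acceptor[idx] <- acceptor[idx] + acc_burst
    structure(
      list(donor = as.integer(donor), acceptor = as.integer(acceptor),
           bin_width = config$bin_width,
           background_rate_donor = config$background_rate_donor,
           background_rate_acceptor = config$background_rate_acceptor,
           metadata = list(sample_id = config$sample_id,
                           condition = config$condition),
           truth = list(burst_bins = idx, r = r, N = N)),
      class = "photon_trace"
    )
  })
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("Photon trace '%s' (%s): %d bins of %g ms\n",
              x$metadata$sample_id, x$metadata$condition,
              length(x$donor), x$bin_width * 1e3))
  cat(sprintf("  background rates (donor, acceptor): %g, %g counts/bin\n",
              x$background_rate_donor, x$background_rate_acceptor))
  cat(sprintf("  total counts: donor %d, acceptor %d\n",
              sum(x$donor), sum(x$acceptor)))
  invisible(x)
}

#' Simulate a dsDNA-ruler calibration dataset
#'
#' One (separation, mean efficiency, sd) triple per ruler: separations from
#' [ruler_separation()], efficiencies as the Forster value at the given
#' \code{r_eff} plus truncated Gaussian noise.
#'
#' @param r_eff generative effective Forster radius, nm.
#' @param ruler_bp ruler lengths in bp (default the ten standard rulers).
#' @param noise_sd_E standard deviation of the efficiency noise (>= 0);
#'   draws are truncated to (0, 1) by resampling.
#' @param geometry a [ruler_geometry()].
#' @param seed integer seed or \code{NULL}.
#' @return data.frame with columns \code{bp}, \code{R_nm}, \code{E},
#'   \code{sigma_E} (the generative \code{noise_sd_E}).
#' @export
simulate_calibration_dataset <- function(r_eff = 8.5,
                                         ruler_bp = ruler_lengths_bp,
                                         noise_sd_E = 0.03,
                                         geometry = ruler_geometry(),
                                         seed = NULL) {
  check_pos(r_eff, "r_eff")
  check_nonneg(noise_sd_E, "noise_sd_E")
  R <- ruler_separation(ruler_bp, geometry)
  E0 <- 1 / (1 + (R / r_eff)^6)
  with_seed(seed, {
    E <- E0
    if (noise_sd_E > 0) {
      E <- E0 + stats::rnorm(length(E0), 0, noise_sd_E)
      bad <- which(E <= 0 | E >= 1)
      while (length(bad) > 0) {          # truncate to (0, 1) by resampling
        E[bad] <- E0[bad] + stats::rnorm(length(bad), 0, noise_sd_E)
        bad <- which(E <= 0 | E >= 1)
      }
    }
    data.frame(bp = ruler_bp, R_nm = R, E = E,
               sigma_E = rep(noise_sd_E, length(R)))
  })
}

#' Simulate a set of RNA inter-dye distance measurements
#'
#' Draws one fluorophore-separation measurement per RNA length from a linear
#' length trend plus Gaussian scatter:
#' \eqn{d_i = a + b \cdot length_i + N(0, scatter\_sd)}, floored at a small
#' positive value.
#'
#' @param a intercept of the trend, nm.
#' @param b slope of the trend, nm per nt.
#' @param lengths_nt RNA lengths in nt (default the eleven reference
#'   lengths, [rna_lengths_nt]).
#' @param scatter_sd between-molecule scatter about the trend, nm
#'   (default 1.2).
#' @param condition buffer label stored with every measurement.
#' @param sigma_nm per-measurement reported uncertainty; defaults to
#'   \code{scatter_sd} so that trend fits can weight points consistently
#'   with the generative model.
#' @param floor_nm lower floor for drawn distances, nm.
#' @param seed integer seed or \code{NULL}.
#' @return data.frame with columns \code{sample_id}, \code{length_nt},
#'   \code{condition}, \code{distance_nm}, \code{sigma_nm},
#'   \code{cistron_class}.
#' @export
simulate_rna_dataset <- function(a = 6.8, b = 7.2e-4,
                                 lengths_nt = rna_lengths_nt,
                                 scatter_sd = 1.2,
                                 condition = "TM",
                                 sigma_nm = scatter_sd,
                                 floor_nm = 0.1,
                                 seed = NULL) {
  if (length(lengths_nt) == 0L) stop("'lengths_nt' is empty", call. = FALSE)
  if (any(lengths_nt <= 0)) stop("'lengths_nt' must be positive", call. = FALSE)
  check_nonneg(scatter_sd, "scatter_sd")
  ids <- names(lengths_nt)
  if (is.null(ids)) ids <- sprintf("rna%02d", seq_along(lengths_nt))
  classes <- rna_cistron_class[match(ids, names(rna_cistron_class))]
  classes[is.na(classes)] <- "mono"
  with_seed(seed, {
    d <- a + b * lengths_nt + stats::rnorm(length(lengths_nt), 0, scatter_sd)
    d <- pmax(d, floor_nm)
    data.frame(sample_id = ids,
               length_nt = as.integer(lengths_nt),
               condition = condition,
               distance_nm = as.numeric(d),
               sigma_nm = rep_len(sigma_nm, length(lengths_nt)),
               cistron_class = as.character(classes),
               row.names = NULL)
  })
}
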