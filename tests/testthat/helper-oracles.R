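# Shared helpers: hand-built traces and independent polymer oracles.

# construct a photon_trace directly from count vectors
make_trace <- function(donor, acceptor, bg_donor = 0, bg_acceptor = 0,
                       bin_width = 1e-3) {
  structure(
    list(donor = as.integer(donor), acceptor = as.integer(acceptor),
         bin_width = bin_width,
         background_rate_donor = bg_donor,
         background_rate_acceptor = bg_acceptor,
         metadata = list(sample_id = "manual", condition = "TE"),
         truth = NULL),
    class = "photon_trace"
  )
}

# independent <R^2> of the continuous worm-like chain by double quadrature
# of the tangent correlation <t(s).t(t)> = exp(-|s-t|/lp):
#   <R^2> = 2 int_0^L int_0^s exp(-(s-t)/lp) dt ds
kp_rms_quadrature <- function(L, lp) {
  inner <- function(s) lp * (1 - exp(-s / lp))
  sqrt(2 * stats::integrate(Vectorize(inner), 0, L, rel.tol = 1e-10)$value)
}

# Monte-Carlo rms of a discretised semiflexible chain: n_seg bonds of length
# b, successive bond angles drawn from p(cos t) ~ exp(kappa cos t), random
# azimuth. kappa is chosen so the bond correlation matches the continuous
# chain exactly: <cos t> = coth(kappa) - 1/kappa = exp(-b/lp); for stiff
# bonds coth(kappa) ~ 1, giving kappa = 1 / (1 - exp(-b/lp))
chain_mc_rms <- function(L, lp, n_chain = 2000L, n_seg = 200L) {
  b <- L / n_seg
  kappa <- 1 / (1 - exp(-b / lp))
  # current bond direction per chain
  ex <- rep(0, n_chain); ey <- rep(0, n_chain); ez <- rep(1, n_chain)
  x <- y <- z <- rep(0, n_chain)
  for (i in seq_len(n_seg)) {
    x <- x + b * ex; y <- y + b * ey; z <- z + b * ez
    # inverse-CDF draw of cos(theta) from exp(kappa * c) on [-1, 1]
    u <- stats::runif(n_chain)
    ct <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
    st <- sqrt(pmax(1 - ct^2, 0))
    phi <- stats::runif(n_chain, 0, 2 * pi)
    # rotate a vector at polar angle theta, azimuth phi about (ex, ey, ez)
    # build an orthonormal frame around the current direction
    small <- abs(ez) > 0.99
    ax <- ifelse(small, 1, 0); ay <- ifelse(small, 0, -ez); az <- ifelse(small, 0, ey)
    nrm <- sqrt(ax^2 + ay^2 + az^2)
    # u1 = normalize(a x e)
    u1x <- (ay * ez - az * ey); u1y <- (az * ex - ax * ez); u1z <- (ax * ey - ay * ex)
    n1 <- sqrt(u1x^2 + u1y^2 + u1z^2)
    u1x <- u1x / n1; u1y <- u1y / n1; u1z <- u1z / n1
    # u2 = e x u1
    u2x <- ey * u1z - ez * u1y; u2y <- ez * u1x - ex * u1z; u2z <- ex * u1y - ey * u1x
    ex2 <- ct * ex + st * (cos(phi) * u1x + sin(phi) * u2x)
    ey2 <- ct * ey + st * (cos(phi) * u1y + sin(phi) * u2y)
    ez2 <- ct * ez + st * (cos(phi) * u1z + sin(phi) * u2z)
    nn <- sqrt(ex2^2 + ey2^2 + ez2^2)
    ex <- ex2 / nn; ey <- ey2 / nn; ez <- ez2 / nn
  }
  # add final bond end
  sqrt(mean(x^2 + y^2 + z^2))
}

# brute-force grid inversion: contour length whose WLC rms is closest to d
grid_invert_rms <- function(d, lp, resolution = 0.01) {
  grid <- seq(d, max(4 * d, d^2 / lp + 4 * d), by = resolution)
  grid[which.min(abs(wlc_rms(grid, lp) - d))]
}
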