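#' Geometry of the dsDNA calibration rulers
#'
#' Bundles the constants that turn a ruler length in base pairs into an
#' inter-dye separation in nm, together with the dye-linker geometry used in
#' uncertainty propagation.
#'
#' @param rise_per_bp helical rise of B-form dsDNA, nm per base pair.
#' @param include_linker_in_abscissa if \code{TRUE}, add \code{linker_total}
#'   to every ruler separation. The calibration abscissa is the separation of
#'   the fluorophores; whether the dye linkers are counted in it is a
#'   convention, so it is a switch (default \code{FALSE}).
#' @param linker_total total effective length of the two opposed dye linkers,
#'   nm.
#' @param linker_rel_uncertainty relative uncertainty of the linker length
#'   (dimensionless, in [0, 1)); folded into the calibration fit as an
#'   abscissa error.
#' @return An object of class \code{"ruler_geometry"}.
#' @seealso [ruler_separation()], [fit_calibration()]
#' @export
ruler_geometry <- function(rise_per_bp = 0.34,
                           include_linker_in_abscissa = FALSE,
                           linker_total = 1.5,
                           linker_rel_uncertainty = 0.10) {
  check_pos(rise_per_bp, "rise_per_bp")
  check_nonneg(linker_total, "linker_total")
  if (!is.numeric(linker_rel_uncertainty) || linker_rel_uncertainty < 0 ||
      linker_rel_uncertainty >= 1) {
    stop("'linker_rel_uncertainty' must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(rise_per_bp = rise_per_bp,
         include_linker_in_abscissa = isTRUE(include_linker_in_abscissa),
         linker_total = linker_total,
         linker_rel_uncertainty = linker_rel_uncertainty),
    class = "ruler_geometry"
  )
}

#' Inter-dye separation of a dsDNA ruler
#'
#' @param bp ruler length in base pairs (vectorised, each > 0).
#' @param geometry a [ruler_geometry()].
#' @return Separation(s) in nm: \code{bp * rise_per_bp}, plus
#'   \code{linker_total} when the geometry includes the linker in the
#'   abscissa.
#' @examples
#' ruler_separation(45)  # 15.3 nm
#' @export
ruler_separation <- function(bp, geometry = ruler_geometry()) {
  stopifnot(inherits(geometry, "ruler_geometry"))
  if (!is.numeric(bp) || any(!is.finite(bp)) || any(bp <= 0)) {
    stop("'bp' must be positive", call. = FALSE)
  }
  sep <- bp * geometry$rise_per_bp
  if (geometry$include_linker_in_abscissa) sep <- sep + geometry$linker_total
  sep
}

# r_eff extractor: accepts a fitted calibration or a bare number
.r_eff <- function(model) {
  if (inherits(model, "fret_calibration")) return(model$r_eff)
  if (is.numeric(model) && length(model) == 1L && model > 0) return(model)
  stop("'model' must be a 'fret_calibration' object or a positive number",
       call. = FALSE)
}

#' Forster efficiency at a given inter-dye distance
#'
#' Evaluates \eqn{E = 1 / (1 + (R/R_{eff})^6)}, the effective Forster
#' relation in which the detection factor gamma is absorbed into
#' \eqn{R_{eff}}.
#'
#' @param R inter-dye distance(s), nm (>= 0; \code{Inf} gives E = 0).
#' @param model a fitted [fit_calibration()] object or a bare effective
#'   Forster radius in nm.
#' @return Transfer efficiency in [0, 1], strictly decreasing in \code{R}.
#' @export
efficiency_from_distance <- function(R, model) {
  r_eff <- .r_eff(model)
  if (!is.numeric(R) || any(is.na(R)) || any(R < 0)) {
    stop("'R' must be non-negative", call. = FALSE)
  }
  1 / (1 + (R / r_eff)^6)
}

#' Invert a FRET efficiency to an inter-dye distance
#'
#' Inverts the effective Forster relation,
#' \eqn{R = R_{eff} (1/E - 1)^{1/6}}, and propagates the efficiency
#' uncertainty and the calibration uncertainty of \eqn{R_{eff}} to first
#' order, added in quadrature.
#'
#' @param E mean FRET efficiency, strictly inside (0, 1). Vectorised.
#' @param sigma_E standard error of \code{E} (same length or scalar).
#' @param model a [fit_calibration()] fit or a bare \eqn{R_{eff}} in nm (in
#'   the latter case the calibration term of the error is zero).
#' @return A data.frame with columns \code{R_nm} and \code{sigma_R_nm}.
#' @export
distance_from_efficiency <- function(E, sigma_E = 0, model) {
  r_eff <- .r_eff(model)
  sigma_r_eff <- if (inherits(model, "fret_calibration")) model$sigma_r_eff else 0
  if (!is.numeric(E) || any(!is.finite(E)) || any(E <= 0) || any(E >= 1)) {
    stop("cannot invert: 'E' must lie strictly inside (0, 1)", call. = FALSE)
  }
  check_nonneg(min(sigma_E), "sigma_E")
  u <- 1 / E - 1
  R <- r_eff * u^(1 / 6)
  # dR/dE = -(r_eff/6) u^(-5/6) / E^2 ; dR/dr_eff = R / r_eff
  dR_dE <- (r_eff / 6) * u^(-5 / 6) / E^2
  sigma_R <- sqrt((dR_dE * sigma_E)^2 + (R / r_eff * sigma_r_eff)^2)
  data.frame(R_nm = R, sigma_R_nm = sigma_R)
}

#' Fit the effective Forster radius to dsDNA ruler data
#'
#' Weighted nonlinear least squares of measured mean efficiencies against
#' ruler separations under \eqn{E^{-1} = 1 + (R/R_{eff})^6}, with the single
#' free parameter \eqn{R_{eff}}. The ordinate weight of each point is its
#' effective variance \eqn{\sigma_{eff}^2 = \sigma_E^2 + (dE/dR)^2 \sigma_R^2},
#' which folds the dye-linker abscissa uncertainty
#' (\code{linker_rel_uncertainty * linker_total} nm per point) into the fit.
#' \eqn{R_0} and the detection factor gamma are not separately identifiable
#' from (R, E) data and are deliberately not parameters.
#'
#' @param points data.frame with columns \code{R_nm}, \code{E} and optionally
#'   \code{sigma_E} (per-point efficiency standard deviations; omitted or all
#'   zero means an unweighted fit).
#' @param geometry a [ruler_geometry()]; supplies the linker abscissa error.
#' @return An object of class \code{"fret_calibration"} with elements
#'   \code{r_eff}, \code{sigma_r_eff}, \code{points}, \code{geometry},
#'   \code{chisq} and \code{df}.
#' @examples
#' R <- ruler_separation(ruler_lengths_bp)
#' pts <- data.frame(R_nm = R, E = efficiency_from_distance(R, 8.5))
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points, geometry = ruler_geometry()) {
  stopifnot(is.data.frame(points), all(c("R_nm", "E") %in% names(points)))
  stopifnot(inherits(geometry, "ruler_geometry"))
  R <- points$R_nm
  E <- points$E
  n <- length(R)
  if (n < 1L) stop("no calibration points", call. = FALSE)
  if (any(!is.finite(R)) || any(R <= 0)) stop("'R_nm' must be positive", call. = FALSE)
  if (n > 1L && length(unique(R)) == 1L) {
    stop("all ruler separations identical: R_eff is not constrained", call. = FALSE)
  }
  if (n < 3L) {
    warning("fewer than 3 calibration points: R_eff is poorly constrained")
  }
  if (n >= 3L && (all(E < 0.5) || all(E > 0.5))) {
    warning("calibration points do not span the half-transfer point (E = 0.5); ",
            "R_eff is extrapolated")
  }
  sigma_E <- if ("sigma_E" %in% names(points)) points$sigma_E else rep(0, n)
  sigma_E <- rep_len(sigma_E, n)
  if (any(sigma_E < 0)) stop("'sigma_E' must be non-negative", call. = FALSE)
  sigma_R <- geometry$linker_rel_uncertainty * geometry$linker_total

  model_E <- function(r) 1 / (1 + (R / r)^6)
  dE_dR <- function(r) {
    x <- (R / r)^6
    -6 * x / R / (1 + x)^2
  }
  weighted <- any(sigma_E > 0) || sigma_R > 0
  obj <- function(r) {
    res <- E - model_E(r)
    if (!weighted) return(sum(res^2))
    v <- sigma_E^2 + (dE_dR(r) * sigma_R)^2
    v[v <= 0] <- min(v[v > 0], 1e-12)  # guard pure-zero variances
    sum(res^2 / v)
  }
  lo <- max(min(R) / 50, 1e-3)
  hi <- max(R) * 20
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-10)
  r_hat <- opt$minimum
  if (r_hat <= lo * 1.01 || r_hat >= hi * 0.99) {
    stop(sprintf("calibration fit did not converge inside (%g, %g) nm; minimum at %g",
                 lo, hi, r_hat), call. = FALSE)
  }
  chisq <- opt$objective

  # 1-sigma from the curvature of the objective at the minimum:
  # var(r_eff) = 2 / chisq''(r_hat) for a chi-square objective; for the
  # unweighted fit the residual variance s^2 rescales it.
  h <- max(1e-4 * r_hat, 1e-6)
  d2 <- (obj(r_hat + h) - 2 * chisq + obj(r_hat - h)) / h^2
  sigma_r <- if (d2 > 0) {
    if (weighted) sqrt(2 / d2)
    else if (n > 1L) sqrt(2 * chisq / max(n - 1L, 1L) / d2)
    else 0
  } else NA_real_
  if (!weighted && chisq < 1e-20) sigma_r <- 0  # noise-free input

  pts <- data.frame(R_nm = R, E = E, sigma_E = sigma_E)
  structure(
    list(r_eff = r_hat, sigma_r_eff = sigma_r, points = pts,
         geometry = geometry, chisq = chisq, df = n - 1L,
         weighted = weighted),
    class = "fret_calibration"
  )
}

#' @export
print.fret_calibration <- function(x, ...) {
  cat("Effective Forster radius calibration (E^-1 = 1 + (R/R_eff)^6)\n")
  cat(sprintf("  R_eff = %.3g +/- %.2g nm  (%d ruler points, %s fit)\n",
              x$r_eff, x$sigma_r_eff, nrow(x$points),
              if (x$weighted) "weighted" else "unweighted"))
  cat(sprintf("  chi-square = %.4g on %d df\n", x$chisq, x$df))
  invisible(x)
}

#' @export
coef.fret_calibration <- function(object, ...) {
  c(r_eff = object$r_eff)
}

#' @export
summary.fret_calibration <- function(object, ...) {
  out <- object
  out$residuals <- object$points$E -
    efficiency_from_distance(object$points$R_nm, object)
  class(out) <- c("summary.fret_calibration", class(object))
  out
}

#' @export
print.summary.fret_calibration <- function(x, ...) {
  print.fret_calibration(x, ...)
  cat("  residuals (E):\n")
  print(stats::setNames(signif(x$residuals, 3),
                        sprintf("%.3g nm", x$points$R_nm)))
  invisible(x)
}

#' @export
predict.fret_calibration <- function(object, R, ...) {
  efficiency_from_distance(R, object)
}
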