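# Internal helpers shared across modules.

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Convert a Gaussian standard deviation to a full width at half maximum
#'
#' @param sigma standard deviation (any unit).
#' @return FWHM in the same unit, \code{2*sqrt(2*log(2)) * sigma}.
#' @export
sigma_to_fwhm <- function(sigma) FWHM_FACTOR * sigma

#' @rdname sigma_to_fwhm
#' @param fwhm full width at half maximum.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_FACTOR

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with the offending field named, for config validation
check_nonneg <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value < 0) {
    stop(sprintf("'%s' must be a single non-negative number (got %s)",
                 field, deparse(value)), call. = FALSE)
  }
  invisible(value)
}

check_pos <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0) {
    stop(sprintf("'%s' must be a single positive number (got %s)",
                 field, deparse(value)), call. = FALSE)
  }
  invisible(value)
}
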