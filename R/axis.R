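#' Canonical fingerprint-region wavenumber grid
#'
#' The instrument configuration emulated throughout this package covers the
#' biological fingerprint region at a spectral resolution of about one pixel
#' per 3.8 cm^-1. The canonical grid places 316 uniformly spaced channels
#' starting at 600 cm^-1 (600 + 315 * 3.8 = 1797 cm^-1).
#'
#' @param n Number of channels.
#' @param from First wavenumber (cm^-1).
#' @param by Channel spacing (cm^-1).
#' @return Numeric vector of wavenumbers (cm^-1), strictly increasing.
#' @examples
#' head(raman_axis())
#' @export
raman_axis <- function(n = 316L, from = 600, by = 3.8) {
  stopifnot(n >= 2, by > 0)
  axis <- from + (seq_len(n) - 1L) * by
  validate_wavenumbers(axis)
  axis
}

# Reject axes that are non-finite, decreasing, out of the fingerprint
# range, or not uniformly spaced (1e-9 relative tolerance on the step).
validate_wavenumbers <- function(w, arg = "wavenumber") {
  if (length(w) < 2 || anyNA(w) || any(!is.finite(w))) {
    abort(sprintf("`%s` must contain at least 2 finite values.", arg),
          class = "ramancell_axis_error")
  }
  d <- diff(w)
  if (any(d <= 0)) {
    abort(sprintf("`%s` must be strictly increasing.", arg),
          class = "ramancell_axis_error")
  }
  if (min(w) < 600 - 1e-6 || max(w) > 1800 + 1e-6) {
    abort(sprintf("`%s` must lie within the fingerprint region [600, 1800] cm^-1.", arg),
          class = "ramancell_axis_error")
  }
  step <- d[1]
  if (any(abs(d - step) > 1e-9 * max(abs(step), 1))) {
    abort(sprintf("`%s` must be uniformly spaced (relative tolerance 1e-9).", arg),
          class = "ramancell_axis_error")
  }
  invisible(w)
}

axis_step <- function(w) (w[length(w)] - w[1]) / (length(w) - 1)

# Channel column names are the wavenumbers printed with one decimal.
axis_colnames <- function(w) sprintf("%.1f", w)
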