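#' Channel-wise group mean and standard deviation
#'
#' The mean +/- SD profile of one class, as plotted for group comparisons
#' of preprocessed spectra. The SD is the population SD (divide by n), so
#' a class of identical spectra has SD exactly zero.
#'
#' @param x A [raman_spectra] tibble (normally preprocessed).
#' @param class_label `"pediatric"` or `"adult"`.
#' @return A `raman_profile` tibble with columns `wavenumber`, `mean`,
#'   `sd`, and attributes `n` and `class_label`.
#' @export
class_profile <- function(x, class_label = c("pediatric", "adult")) {
  class_label <- match.arg(class_label)
  x <- as_raman_spectra(x)
  m <- intensity_matrix(x[x$class_label == class_label, ])
  if (nrow(m) == 0) {
    abort(sprintf("No spectra with class_label '%s'.", class_label),
          class = "ramancell_empty_class_error")
  }
  mu <- unname(colMeans(m))
  sdv <- unname(sqrt(colMeans(sweep(m, 2, mu)^2)))
  out <- tibble(wavenumber = wavenumbers(x), mean = mu, sd = sdv)
  attr(out, "n") <- nrow(m)
  attr(out, "class_label") <- class_label
  class(out) <- c("raman_profile", class(out))
  out
}

#' Subtraction spectrum between two group profiles
#'
#' @param a,b `raman_profile` tibbles on the same axis.
#' @return Tibble with `wavenumber` and `difference` (= `a$mean - b$mean`).
#' @export
profile_difference <- function(a, b) {
  if (length(a$wavenumber) != length(b$wavenumber) ||
      any(abs(a$wavenumber - b$wavenumber) > 1e-9)) {
    abort("Profiles are on different wavenumber axes.",
          class = "ramancell_axis_error")
  }
  tibble(wavenumber = a$wavenumber, difference = a$mean - b$mean)
}

#' Savitzky-Golay negative second derivative
#'
#' Estimates -d2y/dw2 by Savitzky-Golay convolution (default window 9,
#' polynomial order 3) in physical units (per cm^-2, i.e. scaled by the
#' squared channel step). Peak maxima of a spectrum become sharp maxima of
#' its negative second derivative, which is how overlapping bands are
#' localized. Edge channels are handled by the off-centre polynomial fits
#' of the same window, so the operator remains exact for polynomials up to
#' the fitted order everywhere.
#'
#' @param y Numeric signal sampled on a uniform axis.
#' @param wavenumber Optional axis; only its (uniform) step is used.
#' @param window Odd SG window length (default 9).
#' @param degree Polynomial order (default 3; must be < `window`).
#' @return Numeric vector, same length as `y`.
#' @examples
#' w <- raman_axis()
#' d2 <- neg_second_derivative(w^2, w)  # constant -2
#' @export
neg_second_derivative <- function(y, wavenumber = NULL, window = 9L,
                                  degree = 3L) {
  window <- as.integer(window)
  degree <- as.integer(degree)
  if (window %% 2 != 1 || degree >= window || degree < 2) {
    abort("Need an odd `window` and 2 <= degree < window.",
          class = "ramancell_sg_error")
  }
  if (length(y) < window) {
    abort("Signal shorter than the SG window.", class = "ramancell_sg_error")
  }
  step <- if (is.null(wavenumber)) 1 else {
    validate_wavenumbers(wavenumber)
    axis_step(wavenumber)
  }
  -signal::sgolayfilt(y, p = degree, n = window, m = 2, ts = step)
}

#' Detect peaks in a negative-second-derivative trace
#'
#' Local maxima with topographic prominence of at least `prominence_frac`
#' times the global maximum are reported; positions are refined by
#' three-point parabolic interpolation around the discrete maximum.
#'
#' @param d2 Numeric trace (typically from [neg_second_derivative()]).
#' @param wavenumber Matching axis.
#' @param prominence_frac Minimum prominence as a fraction of `max(d2)`
#'   (default 0.05).
#' @return A `raman_peaks` tibble with columns `position` (cm^-1) and
#'   `height`, sorted by position; empty when the trace has no positive
#'   local maxima.
#' @export
detect_peaks <- function(d2, wavenumber = seq_along(d2),
                         prominence_frac = 0.05) {
  stopifnot(length(d2) == length(wavenumber), prominence_frac >= 0)
  if (any(!is.finite(d2))) abort("`d2` must be finite.")
  n <- length(d2)
  if (n < 3 || max(d2) <= 0) return(peaks_tibble())
  is_max <- which(d2[2:(n - 1)] > d2[1:(n - 2)] & d2[2:(n - 1)] >= d2[3:n]) + 1L
  is_max <- is_max[d2[is_max] > 0]
  if (!length(is_max)) return(peaks_tibble())
  thr <- prominence_frac * max(d2)
  keep <- vapply(is_max, function(i) prominence_at(d2, i) >= thr, logical(1))
  is_max <- is_max[keep]
  if (!length(is_max)) return(peaks_tibble())
  step <- (wavenumber[n] - wavenumber[1]) / (n - 1)
  refined <- lapply(is_max, function(i) {
    if (i <= 1L || i >= n) {
      return(c(wavenumber[i], d2[i]))
    }
    denom <- d2[i - 1] - 2 * d2[i] + d2[i + 1]
    if (denom >= 0) return(c(wavenumber[i], d2[i]))
    delta <- 0.5 * (d2[i - 1] - d2[i + 1]) / denom
    delta <- max(min(delta, 0.5), -0.5)
    c(wavenumber[i] + delta * step,
      d2[i] - 0.25 * (d2[i - 1] - d2[i + 1]) * delta)
  })
  out <- tibble(position = vapply(refined, `[`, numeric(1), 1),
                height = vapply(refined, `[`, numeric(1), 2))
  out <- out[order(out$position), ]
  class(out) <- c("raman_peaks", class(tibble()))
  out
}

peaks_tibble <- function() {
  out <- tibble(position = numeric(), height = numeric())
  class(out) <- c("raman_peaks", class(tibble()))
  out
}

# Topographic prominence of the local maximum at index i: height above the
# highest of the two key saddles, where each saddle is the minimum between
# the peak and the nearest strictly higher point (or the series end).
prominence_at <- function(y, i) {
  h <- y[i]
  left_min <- h
  j <- i - 1L
  while (j >= 1L && y[j] <= h) {
    left_min <- min(left_min, y[j])
    j <- j - 1L
  }
  if (j < 1L) left_min <- min(left_min, min(y[seq_len(i)]))
  right_min <- h
  j <- i + 1L
  while (j <= length(y) && y[j] <= h) {
    right_min <- min(right_min, y[j])
    j <- j + 1L
  }
  if (j > length(y)) right_min <- min(right_min, min(y[i:length(y)]))
  h - max(left_min, right_min)
}

#' Assign detected peaks to literature bands
#'
#' Each peak is matched to the nearest band-table position; the assignment
#' is kept only when the distance is at most `tolerance` (about one
#' spectral pixel by default). Ties are broken toward the lower band
#' position; one band may serve several peaks.
#'
#' @param peaks A `raman_peaks` tibble from [detect_peaks()].
#' @param bands A band table from [band_assignments()].
#' @param tolerance Maximum assignment distance in cm^-1 (default 4).
#' @return The peaks tibble with columns `band`, `allocation` and
#'   `distance` added (`NA` where unassigned).
#' @examples
#' pk <- tibble::tibble(position = c(1001.3, 900), height = c(1, 1))
#' assign_bands(pk)
#' @export
assign_bands <- function(peaks, bands = band_assignments(), tolerance = 4) {
  stopifnot(tolerance >= 0, nrow(bands) >= 1)
  res <- lapply(peaks$position, function(p) {
    d <- abs(bands$position - p)
    k <- which.min(d)  # which.min takes the first, i.e. the lower position
    if (d[k] <= tolerance) {
      list(band = bands$position[k], allocation = bands$allocation[k],
           distance = d[k])
    } else {
      list(band = NA_real_, allocation = NA_character_, distance = NA_real_)
    }
  })
  peaks$band <- vapply(res, `[[`, numeric(1), "band")
  peaks$allocation <- vapply(res, `[[`, character(1), "allocation")
  peaks$distance <- vapply(res, `[[`, numeric(1), "distance")
  peaks
}
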