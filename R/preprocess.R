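#' Preprocessing configuration
#'
#' @param spike_z_threshold Modified z-score threshold on first differences
#'   above which a channel is treated as a cosmic-ray spike (default 6).
#' @param spike_window Odd window width (channels) whose non-flagged
#'   members supply the replacement median (default 5).
#' @param fluorescence_reject_ratio Reject a spectrum when the rubber-band
#'   baseline accounts for more than this fraction of its total intensity
#'   (strict inequality; default 0.90).
#' @param normalize_region Optional `c(lo, hi)` wavenumber interval over
#'   which the Euclidean norm is computed; default the full axis.
#' @return A `raman_preprocess_config` list.
#' @export
preprocess_config <- function(spike_z_threshold = 6,
                              spike_window = 5L,
                              fluorescence_reject_ratio = 0.90,
                              normalize_region = NULL) {
  stopifnot(spike_z_threshold > 0, spike_window >= 3, spike_window %% 2 == 1,
            fluorescence_reject_ratio > 0, fluorescence_reject_ratio <= 1)
  if (!is.null(normalize_region)) {
    stopifnot(length(normalize_region) == 2,
              normalize_region[1] < normalize_region[2])
  }
  structure(list(spike_z_threshold = spike_z_threshold,
                 spike_window = as.integer(spike_window),
                 fluorescence_reject_ratio = fluorescence_reject_ratio,
                 normalize_region = normalize_region),
            class = "raman_preprocess_config")
}

# Whitaker-Hayes style despiking of a single trace: modified z-scores of
# the first-difference series; a channel is a spike candidate only when
# both adjacent differences are extreme (single-pixel events), so genuine
# sharp Raman bands, which rise over several channels, are left alone.
despike_signal <- function(y, z_threshold = 6, window = 5L) {
  n <- length(y)
  if (n < window) abort("Need at least `window` channels to despike.")
  d <- diff(y)
  med <- median(d)
  madv <- median(abs(d - med))
  z <- if (madv > 0) {
    0.6745 * (d - med) / madv
  } else {
    ifelse(abs(d - med) > 0, Inf, 0)
  }
  az <- abs(z)
  # az[i-1] tests the step into channel i, az[i] the step out of it.
  left <- c(Inf, az)        # step into channel i (Inf at the first channel)
  right <- c(az, Inf)       # step out of channel i (Inf at the last)
  score <- pmin(left, right)
  flagged <- which(score > z_threshold)
  out <- y
  if (length(flagged)) {
    half <- (window - 1L) %/% 2L
    for (i in flagged) {
      k <- half
      repeat {
        nb <- setdiff(max(1L, i - k):min(n, i + k), flagged)
        if (length(nb)) break
        k <- k + 1L
      }
      out[i] <- median(y[nb])
    }
  }
  list(intensity = out, flagged = flagged)
}

#' Remove cosmic-ray spikes from a spectra table
#'
#' Channels whose first differences are extreme on both sides (modified
#' z-score above the threshold) are replaced by the median of the
#' non-flagged channels in the surrounding window. Spectra with at least
#' one replaced channel gain the qc flag `"despiked"`. The operation is
#' idempotent.
#'
#' @param x A [raman_spectra] tibble.
#' @param config A [preprocess_config()].
#' @return The despiked spectra table.
#' @export
despike_spectra <- function(x, config = preprocess_config()) {
  x <- as_raman_spectra(x)
  m <- intensity_matrix(x)
  hit <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    r <- despike_signal(m[i, ], config$spike_z_threshold, config$spike_window)
    if (length(r$flagged)) {
      m[i, ] <- r$intensity
      hit[i] <- TRUE
    }
  }
  x <- set_intensities(x, m)
  x$qc_flags <- add_qc_flag(x$qc_flags, "despiked",
                            which(hit & !has_qc_flag(x$qc_flags, "despiked")))
  x
}

#' Rubber-band baseline of a single spectrum
#'
#' Estimates the broad fluorescence background as the lower convex hull of
#' the points (wavenumber, intensity), anchored at both endpoints and
#' linearly interpolated between hull vertices, and subtracts it. The
#' corrected trace is zero at every hull vertex and non-negative
#' everywhere; the baseline is piecewise linear and convex.
#'
#' @param intensity Numeric intensity vector (>= 3 finite values).
#' @param wavenumber Matching wavenumber vector.
#' @return List with `baseline`, `corrected` and the hull vertex indices
#'   `hull`.
#' @examples
#' w <- raman_axis(64, 600, 3.8)
#' y <- 5 + 0.01 * w + exp(-((w - 700) / 10)^2)
#' r <- rubberband_baseline(y, w)
#' range(r$corrected)
#' @export
rubberband_baseline <- function(intensity, wavenumber = seq_along(intensity)) {
  n <- length(intensity)
  if (n < 3) abort("Need at least 3 channels for a rubber-band baseline.",
                   class = "ramancell_baseline_error")
  if (length(wavenumber) != n) abort("Axis/intensity length mismatch.")
  if (any(!is.finite(intensity)) || any(!is.finite(wavenumber))) {
    abort("Intensities and wavenumbers must be finite.",
          class = "ramancell_baseline_error")
  }
  hull <- lower_hull_indices(wavenumber, intensity)
  baseline <- approx(wavenumber[hull], intensity[hull], xout = wavenumber,
                     ties = "ordered")$y
  list(baseline = baseline, corrected = intensity - baseline, hull = hull)
}

# Andrew monotone-chain lower hull over points with strictly increasing x.
# Collinear interior points are dropped, keeping the earliest channels as
# vertices; both endpoints are always vertices.
lower_hull_indices <- function(x, y) {
  n <- length(x)
  h <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      a <- h[top - 1L]
      b <- h[top]
      cr <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cr <= 0) top <- top - 1L else break
    }
    top <- top + 1L
    h[top] <- i
  }
  h[seq_len(top)]
}

#' Subtract rubber-band baselines across a spectra table
#'
#' @param x A [raman_spectra] tibble.
#' @return `x` with baseline-corrected intensities; the per-spectrum
#'   baseline matrix and the baseline-to-total intensity ratio are
#'   attached as attributes `"baseline"` and `"baseline_ratio"`.
#' @export
correct_baseline <- function(x) {
  x <- as_raman_spectra(x)
  w <- wavenumbers(x)
  m <- intensity_matrix(x)
  bl <- m
  for (i in seq_len(nrow(m))) {
    bl[i, ] <- rubberband_baseline(m[i, ], w)$baseline
  }
  tot <- rowSums(m)
  ratio <- ifelse(tot > 0, rowSums(bl) / tot, NA_real_)
  out <- set_intensities(x, m - bl)
  attr(out, "baseline") <- bl
  attr(out, "baseline_ratio") <- ratio
  out
}

#' Vector-normalize spectra to unit Euclidean norm
#'
#' @param x A [raman_spectra] tibble.
#' @param region Optional `c(lo, hi)` wavenumber interval over which the
#'   norm is computed (the whole spectrum is rescaled either way).
#' @return The normalized spectra table.
#' @export
normalize_spectra <- function(x, region = NULL) {
  x <- as_raman_spectra(x)
  w <- wavenumbers(x)
  sel <- if (is.null(region)) rep(TRUE, length(w)) else
    w >= region[1] & w <= region[2]
  if (!any(sel)) abort("`region` contains no channels.")
  m <- intensity_matrix(x)
  nrm <- sqrt(rowSums(m[, sel, drop = FALSE]^2))
  if (any(nrm <= 0)) {
    abort("Degenerate spectrum: zero norm over the normalization region.",
          class = "ramancell_degenerate_error")
  }
  set_intensities(x, m / nrm)
}

#' Full spectral preprocessing pipeline
#'
#' Applies, in this fixed order: cosmic-ray despiking, rubber-band
#' baseline subtraction, rejection of fluorescence-dominated or degenerate
#' spectra, and vector normalization. Despiking precedes the baseline
#' because a spike would be taken up into the convex hull; baseline
#' removal precedes normalization so the norm reflects Raman signal, not
#' fluorescence.
#'
#' @param x A [raman_spectra] tibble.
#' @param config A [preprocess_config()].
#' @return The surviving spectra, baseline-corrected and unit-norm, with
#'   updated `qc_flags`. The full audit trail (one row per input spectrum:
#'   flags, baseline ratio, kept or not) is attached as attribute `"qc"`
#'   and retrievable with [qc_log()].
#' @examples
#' cohort <- simulate_cohort(synthetic_config(per_line_counts =
#'   c("SF188-like" = 12, "adult-1" = 12)), seed = 1)
#' pre <- preprocess_spectra(cohort$spectra)
#' qc_log(pre)
#' @export
preprocess_spectra <- function(x, config = preprocess_config()) {
  x <- as_raman_spectra(x)
  if (nrow(x) == 0) abort("No spectra to preprocess.")
  x <- despike_spectra(x, config)
  x <- correct_baseline(x)
  ratio <- attr(x, "baseline_ratio")
  degenerate <- is.na(ratio)
  fluorescent <- !degenerate & ratio > config$fluorescence_reject_ratio
  x$qc_flags <- add_qc_flag(x$qc_flags, "degenerate", which(degenerate))
  x$qc_flags <- add_qc_flag(x$qc_flags, "fluorescence", which(fluorescent))
  # A spectrum whose corrected trace has zero norm cannot be normalized.
  m <- intensity_matrix(x)
  w <- wavenumbers(x)
  sel <- if (is.null(config$normalize_region)) rep(TRUE, length(w)) else
    w >= config$normalize_region[1] & w <= config$normalize_region[2]
  zero_norm <- sqrt(rowSums(m[, sel, drop = FALSE]^2)) <= 0
  x$qc_flags <- add_qc_flag(x$qc_flags, "degenerate",
                            which(zero_norm & !degenerate))
  drop_row <- degenerate | fluorescent | zero_norm
  qc <- tibble(spectrum_id = x$spectrum_id,
               qc_flags = x$qc_flags,
               baseline_ratio = ratio,
               kept = !drop_row)
  keep <- x[!drop_row, ]
  if (nrow(keep) == 0) {
    abort("All spectra were rejected during preprocessing.",
          class = "ramancell_degenerate_error")
  }
  out <- normalize_spectra(as_raman_spectra(keep), config$normalize_region)
  attr(out, "qc") <- qc
  out
}

#' Quality-control audit of a preprocessed spectra table
#' @param x Output of [preprocess_spectra()].
#' @return Tibble with one row per input spectrum: `spectrum_id`,
#'   `qc_flags`, `baseline_ratio`, `kept`.
#' @export
qc_log <- function(x) {
  qc <- attr(x, "qc")
  if (is.null(qc)) abort("`x` carries no qc audit; run preprocess_spectra().")
  qc
}
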