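# Shared fixtures and independent oracles, all built in code.

# A small cohort configuration that keeps the default physics but shrinks
# the study size for fast tests.
tiny_config <- function(ped = 36, adults = c(18, 18, 18), ...) {
  counts <- c("SF188-like" = ped,
              setNames(adults, paste0("adult-", seq_along(adults))))
  synthetic_config(per_line_counts = counts, ...)
}

# A noise- and artifact-free configuration: hierarchy and composition
# variation off, no baseline, no spikes.
clean_config <- function(..., peaks = synthetic_peak_library()) {
  synthetic_config(peaks = peaks,
                   baseline_amplitude = 0, baseline_cv = 0,
                   sigma_line = 0, sigma_cell = 0, sigma_point = 0,
                   sigma_composition_family = 0, sigma_composition_band = 0,
                   noise_sigma = 0, cosmic_ray_prob = 0, ...)
}

# Single-band peak library (plus optional second band) used to isolate
# class-factor arithmetic from band-overlap effects.
single_band_library <- function(centers, effect_delta = 0.15) {
  full <- synthetic_peak_library(effect_delta, envelope_amplitude = 0)
  full[full$center %in% centers, ]
}

# O(n^2) brute-force lower convex hull: the baseline at each channel is
# the highest line through two sample points that stays below all points.
brute_force_lower_hull <- function(x, y) {
  n <- length(x)
  best <- rep(-Inf, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sl <- (y[j] - y[i]) / (x[j] - x[i])
      ln <- y[i] + sl * (x - x[i])
      if (all(ln <= y + 1e-9)) best <- pmax(best, ln)
    }
  }
  best
}

# Modified z-scores of the first-difference series (despiking oracle).
modified_zscores <- function(y) {
  d <- diff(y)
  med <- stats::median(d)
  madv <- stats::median(abs(d - med))
  if (madv == 0) return(ifelse(abs(d - med) > 0, Inf, 0))
  0.6745 * (d - med) / madv
}

# Metadata-only spectra table (flat dummy intensities) for split tests:
# `cells` whole cells of `points` spectra per class.
meta_only_spectra <- function(cells_per_class = 10, points = 3) {
  rows <- list()
  for (cl in c("pediatric", "adult")) {
    ln <- if (cl == "pediatric") "SF188-like" else "adult-1"
    for (ce in seq_len(cells_per_class)) {
      for (p in seq_len(points)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          spectrum_id = sprintf("%s_c%03d_p%d", ln, ce, p),
          cell_line = ln, cell_id = sprintf("c%03d", ce),
          point_index = p, class_label = cl)
      }
    }
  }
  meta <- dplyr::bind_rows(rows)
  m <- matrix(rep(c(1, 2), each = nrow(meta)), nrow = nrow(meta))
  raman_spectra(meta, m, c(600, 603.8))
}

# Two well-separated Gaussian clouds in `d` dimensions with cell-group
# metadata (for CV / MLP tests).
separable_scores <- function(n_per_class = 100, d = 4, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
               matrix(rnorm(n_per_class * d, mean = sep / sqrt(d)), ncol = d))
    y <- rep(c("adult", "pediatric"), each = n_per_class)
    cell <- paste0(rep(c("a", "p"), each = n_per_class), "_c",
                   rep(seq_len(ceiling(n_per_class / 2)), each = 2,
                       length.out = n_per_class))
    meta <- tibble::tibble(cell_line = substr(cell, 1, 1), cell_id = cell,
                           class_label = y)
    list(x = x, y = y, meta = meta)
  })
}
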