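#' Peak library for the synthetic cohort generator
#'
#' Returns the spectral components the simulator superposes. The 35
#' fingerprint bands of [band_assignments()] are modelled as Lorentzian
#' lines (FWHM 12 cm^-1) in three amplitude tiers so that the strong
#' phenylalanine (1001), CH2 deformation (1445) and amide I (1657) bands
#' dominate the spectrum. A small set of very broad Lorentzian components
#' (FWHM 180 cm^-1) emulates the unresolved biomolecular background that
#' fills the region between resolved bands in real cell spectra; without
#' it, between-band channels would carry nothing but detector noise, which
#' real spectra do not show.
#'
#' Class contrast: bands elevated in the pediatric phenotype carry
#' `pediatric_factor = 1 + effect_delta` (nucleic-acid backbone 621/672,
#' tryptophan 751, phenylalanine 781/1001, deoxyribose 1125, lipid CH2
#' 1301/1445, amide I 1657, ester carbonyl 1745); bands elevated in the
#' adult group carry `adult_factor = 1 + effect_delta` (cholesterol 719,
#' collagen 1338, NADH 1512, cytochrome 1582). All other components are
#' class-neutral.
#'
#' @param effect_delta Fractional class-specific amplitude contrast.
#' @param envelope_amplitude Amplitude of the broad background components
#'   (0 disables them).
#' @return Tibble with columns `center`, `base_amplitude`, `fwhm`,
#'   `family`, `component`, `pediatric_factor`, `adult_factor`.
#' @export
synthetic_peak_library <- function(effect_delta = 0.15,
                                   envelope_amplitude = 0.8) {
  stopifnot(effect_delta >= 0, envelope_amplitude >= 0)
  bands <- band_assignments()
  tier1 <- c(1001, 1445, 1657)
  tier2 <- c(781, 1301, 1582, 1065)
  ped_up <- pediatric_elevated_bands()
  adu_up <- adult_elevated_bands()
  pk <- tibble(
    center = bands$position,
    base_amplitude = ifelse(bands$position %in% tier1, 1.0,
                     ifelse(bands$position %in% tier2, 0.6, 0.35)),
    fwhm = 12,
    family = bands$reference_note,
    component = "band",
    pediatric_factor = ifelse(bands$position %in% ped_up, 1 + effect_delta, 1),
    adult_factor = ifelse(bands$position %in% adu_up, 1 + effect_delta, 1)
  )
  if (envelope_amplitude > 0) {
    centers <- seq(650, 1750, by = 157)
    env <- tibble(
      center = centers,
      base_amplitude = envelope_amplitude,
      fwhm = 180,
      family = rep(c("protein", "lipid", "nucleic_acid", "carbohydrate"),
                   length.out = length(centers)),
      component = "envelope",
      pediatric_factor = 1,
      adult_factor = 1
    )
    pk <- dplyr::bind_rows(pk, env)
  }
  pk
}

#' Band sets carrying the class contrast
#'
#' Wavenumbers (cm^-1) of the fingerprint bands simulated with elevated
#' intensity in the pediatric phenotype, respectively in the adult lines.
#' @return Numeric vector of band positions.
#' @export
pediatric_elevated_bands <- function() {
  c(621, 672, 751, 781, 1001, 1125, 1301, 1445, 1657, 1745)
}

#' @rdname pediatric_elevated_bands
#' @export
adult_elevated_bands <- function() {
  c(719, 1338, 1512, 1582)
}

#' Configuration of the synthetic Raman cohort
#'
#' Parameterizes a simulated study: six neurosphere cell lines (one
#' pediatric, five adult), three measurement points per cell, 1,382
#' spectra in total of which 364 are pediatric. Each spectrum is a sum of
#' Lorentzian components whose amplitudes carry (i) joint brightness
#' multipliers drawn once per line, per cell and per spectrum, and (ii)
#' per-spectrum composition variability, drawn per biochemical family
#' (nucleic acid, protein, lipid, carbohydrate, cofactor) and per
#' component, so measurements differ in relative composition and not just
#' overall signal strength; plus a broad exponentially decaying
#' fluorescence baseline with per-spectrum log-normal amplitude variation,
#' additive Gaussian detector noise, and rare single-pixel cosmic-ray
#' spikes.
#'
#' @param axis Wavenumber grid (default [raman_axis()]).
#' @param peaks Peak library, see [synthetic_peak_library()].
#' @param effect_delta Class amplitude contrast on the elevated band sets
#'   (fraction; default 0.15).
#' @param baseline_amplitude Fluorescence baseline height at 600 cm^-1 in
#'   units of the maximum band amplitude (default 2.0).
#' @param baseline_tau Exponential decay constant of the baseline (cm^-1).
#' @param baseline_cv Log-scale SD of the per-spectrum baseline amplitude.
#' @param sigma_line,sigma_cell,sigma_point Log-scale SDs of the joint
#'   (all-component) brightness multipliers drawn once per line, once per
#'   cell and once per spectrum: overall signal-strength variation from
#'   biomass, focus and optical coupling. Adult lines draw independent
#'   line effects, emulating their greater heterogeneity. Being common to
#'   all components, these multipliers are removed by vector
#'   normalization, as overall brightness should be.
#' @param sigma_composition_family,sigma_composition_band Log-scale SDs of
#'   the per-spectrum composition variability that survives normalization:
#'   a multiplier drawn per biochemical family (relative nucleic acid /
#'   protein / lipid / carbohydrate / cofactor content at the probed spot)
#'   and an independent per-component idiosyncrasy. These draws carry no
#'   line or cell signature, so with `effect_delta = 0` the two classes
#'   are statistically identical after normalization.
#' @param noise_sigma Detector noise SD; default 1% of the maximum of the
#'   clean class-mean signal.
#' @param cosmic_ray_prob Probability that a spectrum carries one
#'   single-pixel spike.
#' @param cosmic_ray_gain Range of the spike height in units of the
#'   spectrum's clean maximum.
#' @param per_line_counts Named integer vector, spectra per cell line.
#' @param pediatric_lines Names of the pediatric line(s).
#' @param points_per_cell Measurement points per cell (spectra per cell).
#' @param seed Default RNG seed used by [simulate_cohort()].
#' @return A `raman_sim_config` list.
#' @examples
#' cfg <- synthetic_config()
#' sum(cfg$per_line_counts)  # 1382
#' @export
synthetic_config <- function(axis = raman_axis(),
                             peaks = synthetic_peak_library(effect_delta),
                             effect_delta = 0.15,
                             baseline_amplitude = 2.0,
                             baseline_tau = 700,
                             baseline_cv = 0.20,
                             sigma_line = 0.10,
                             sigma_cell = 0.05,
                             sigma_point = 0.03,
                             sigma_composition_family = 0.18,
                             sigma_composition_band = 0.06,
                             noise_sigma = NULL,
                             cosmic_ray_prob = 0.02,
                             cosmic_ray_gain = c(5, 20),
                             per_line_counts = c("SF188-like" = 364,
                                                 "adult-1" = 204,
                                                 "adult-2" = 204,
                                                 "adult-3" = 204,
                                                 "adult-4" = 203,
                                                 "adult-5" = 203),
                             pediatric_lines = "SF188-like",
                             points_per_cell = 3L,
                             seed = 1L) {
  validate_wavenumbers(axis)
  stopifnot(effect_delta >= 0, baseline_amplitude >= 0, baseline_tau > 0,
            baseline_cv >= 0, sigma_line >= 0, sigma_cell >= 0,
            sigma_point >= 0, sigma_composition_family >= 0,
            sigma_composition_band >= 0,
            cosmic_ray_prob >= 0, cosmic_ray_prob <= 1,
            length(cosmic_ray_gain) == 2, all(cosmic_ray_gain > 0),
            points_per_cell >= 1)
  if (is.null(names(per_line_counts)) || any(!nzchar(names(per_line_counts)))) {
    abort("`per_line_counts` must be a named vector.")
  }
  if (any(per_line_counts < 1)) {
    abort("Every cell line needs at least 1 spectrum.")
  }
  if (!all(pediatric_lines %in% names(per_line_counts))) {
    abort("`pediatric_lines` must name entries of `per_line_counts`.")
  }
  if (!all(peaks$center >= min(axis) & peaks$center <= max(axis) + 50)) {
    abort("Peak centers must lie within (or just above) the axis range.")
  }
  stopifnot(all(peaks$base_amplitude >= 0), all(peaks$fwhm > 0),
            all(peaks$pediatric_factor > 0), all(peaks$adult_factor > 0))
  cfg <- list(axis = axis, peaks = peaks, effect_delta = effect_delta,
              baseline_amplitude = baseline_amplitude,
              baseline_tau = baseline_tau, baseline_cv = baseline_cv,
              sigma_line = sigma_line, sigma_cell = sigma_cell,
              sigma_point = sigma_point,
              sigma_composition_family = sigma_composition_family,
              sigma_composition_band = sigma_composition_band,
              noise_sigma = noise_sigma,
              cosmic_ray_prob = cosmic_ray_prob,
              cosmic_ray_gain = sort(cosmic_ray_gain),
              per_line_counts = per_line_counts,
              pediatric_lines = pediatric_lines,
              points_per_cell = as.integer(points_per_cell),
              seed = as.integer(seed))
  if (is.null(cfg$noise_sigma)) {
    cmax <- max(clean_class_signal(cfg, "pediatric")$intensity,
                clean_class_signal(cfg, "adult")$intensity)
    cfg$noise_sigma <- 0.01 * cmax
  }
  stopifnot(cfg$noise_sigma >= 0)
  class(cfg) <- "raman_sim_config"
  cfg
}

# Lorentzian line shapes evaluated on the axis, one row per component.
lorentzian_basis <- function(centers, fwhm, axis) {
  hw <- fwhm / 2
  t(vapply(seq_along(centers),
           function(k) 1 / (1 + ((axis - centers[k]) / hw[k])^2),
           numeric(length(axis))))
}

#' Noise-free class-mean signal of the simulator
#'
#' The deterministic superposition of all peak-library components with the
#' class-specific amplitude factors applied and all hierarchy multipliers
#' at unity — the signal a cohort mean converges to (before baseline,
#' noise and artifacts). Useful as an oracle for the stochastic generator.
#'
#' @param config A [synthetic_config()].
#' @param class_label `"pediatric"` or `"adult"`.
#' @return Tibble with columns `wavenumber`, `intensity`.
#' @export
clean_class_signal <- function(config, class_label = c("pediatric", "adult")) {
  class_label <- match.arg(class_label)
  pk <- config$peaks
  fac <- if (class_label == "pediatric") pk$pediatric_factor else pk$adult_factor
  L <- lorentzian_basis(pk$center, pk$fwhm, config$axis)
  tibble(wavenumber = config$axis,
         intensity = drop((pk$base_amplitude * fac) %*% L))
}

#' Simulate a cohort of single-cell Raman spectra
#'
#' Draws a full synthetic study deterministically from `seed`: line-,
#' cell- and point-level per-family amplitude multipliers, per-spectrum
#' baseline amplitudes, detector noise and cosmic-ray spikes, then emits
#' `intensity = clean + baseline + noise + spike` per channel. The
#' returned ground truth stores each additive component exactly, so every
#' downstream stage can be checked against what was injected.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `raman_cohort` list with elements `spectra` (a
#'   [raman_spectra] tibble) and `truth` (list with matrices `clean`,
#'   `baseline`, `noise`, spike table `spikes`, and the drawn
#'   `multipliers`).
#' @examples
#' cohort <- simulate_cohort(synthetic_config(), seed = 1)
#' nrow(cohort$spectra)  # 1382
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "raman_sim_config"))
  counts <- config$per_line_counts
  lines <- names(counts)
  ppc <- config$points_per_cell
  meta <- dplyr::bind_rows(lapply(lines, function(ln) {
    n <- counts[[ln]]
    n_cells <- ceiling(n / ppc)
    cell <- rep(seq_len(n_cells), each = ppc)[seq_len(n)]
    point <- rep(seq_len(ppc), times = n_cells)[seq_len(n)]
    tibble(cell_line = ln,
           cell_id = sprintf("%s_c%03d", ln, cell),
           point_index = as.integer(point),
           class_label = ifelse(ln %in% config$pediatric_lines,
                                "pediatric", "adult"))
  }))
  meta$spectrum_id <- sprintf("spec_%04d", seq_len(nrow(meta)))
  meta$qc_flags <- ""
  n_spec <- nrow(meta)
  pk <- config$peaks
  fam <- sort(unique(pk$family))
  fam_idx <- match(pk$family, fam)
  cells <- unique(meta$cell_id)
  axis <- config$axis

  draws <- withr::with_seed(seed, {
    list(
      line = setNames(rnorm(length(lines), 0, config$sigma_line), lines),
      cell = setNames(rnorm(length(cells), 0, config$sigma_cell), cells),
      point = rnorm(n_spec, 0, config$sigma_point),
      comp_family = matrix(rnorm(n_spec * length(fam), 0,
                                 config$sigma_composition_family),
                           nrow = n_spec, dimnames = list(NULL, fam)),
      comp_band = matrix(rnorm(n_spec * nrow(pk), 0,
                               config$sigma_composition_band),
                         nrow = n_spec),
      baseline_factor = exp(rnorm(n_spec, 0, config$baseline_cv)),
      noise = matrix(rnorm(n_spec * length(axis), 0, config$noise_sigma),
                     nrow = n_spec),
      spike_hit = runif(n_spec) < config$cosmic_ray_prob,
      spike_channel = sample.int(length(axis), n_spec, replace = TRUE),
      spike_gain = runif(n_spec, config$cosmic_ray_gain[1],
                         config$cosmic_ray_gain[2])
    )
  })

  brightness <- draws$line[meta$cell_line] + draws$cell[meta$cell_id] +
    draws$point
  mult <- exp(brightness +                               # n_spec x n_peak
              draws$comp_family[, fam_idx, drop = FALSE] + draws$comp_band)
  fac <- ifelse(meta$class_label == "pediatric", 1, 0) %o% pk$pediatric_factor +
    ifelse(meta$class_label == "adult", 1, 0) %o% pk$adult_factor
  amps <- sweep(mult * fac, 2, pk$base_amplitude, `*`)
  L <- lorentzian_basis(pk$center, pk$fwhm, axis)
  clean <- amps %*% L
  shape <- exp(-(axis - min(axis)) / config$baseline_tau)
  baseline <- (config$baseline_amplitude * draws$baseline_factor) %o% shape
  intens <- clean + baseline + draws$noise
  spikes <- tibble(spectrum_id = meta$spectrum_id[draws$spike_hit],
                   channel = draws$spike_channel[draws$spike_hit],
                   height = draws$spike_gain[draws$spike_hit] *
                     apply(clean[draws$spike_hit, , drop = FALSE], 1, max))
  if (nrow(spikes)) {
    idx <- cbind(match(spikes$spectrum_id, meta$spectrum_id), spikes$channel)
    intens[idx] <- intens[idx] + spikes$height
  }
  spectra <- raman_spectra(meta, intens, axis)
  structure(list(
    spectra = spectra,
    truth = list(clean = clean, baseline = baseline, noise = draws$noise,
                 spikes = spikes,
                 multipliers = list(line = exp(draws$line),
                                    cell = exp(draws$cell),
                                    point = exp(draws$point),
                                    composition_family = exp(draws$comp_family),
                                    composition_band = exp(draws$comp_band),
                                    amplitudes = amps,
                                    baseline_factor = draws$baseline_factor),
                 seed = seed)
  ), class = "raman_cohort")
}

#' Simulate a single spectrum with fixed hierarchy effects
#'
#' One draw of the generative model with the line- and cell-level
#' log-multipliers supplied instead of sampled; point-level variation,
#' baseline, noise and spikes follow the configuration. Mostly useful for
#' focused tests of the signal model.
#'
#' @param class_label `"pediatric"` or `"adult"`.
#' @param config A [synthetic_config()].
#' @param line_effect,cell_effect Log-scale joint brightness effects to
#'   impose instead of drawing them.
#' @param seed RNG seed.
#' @return A `raman_cohort` with a single spectrum.
#' @export
simulate_spectrum <- function(class_label, config, line_effect = 0,
                              cell_effect = 0, seed = config$seed) {
  stopifnot(class_label %in% class_levels())
  ln <- if (class_label == "pediatric") config$pediatric_lines[1] else "adult-x"
  cfg1 <- config
  cfg1$per_line_counts <- setNames(1L, ln)
  cfg1$pediatric_lines <- if (class_label == "pediatric") ln else character(0)
  cfg1$sigma_line <- 0
  cfg1$sigma_cell <- 0
  out <- simulate_cohort(cfg1, seed = seed)
  gain <- exp(line_effect + cell_effect)
  if (gain != 1) {
    clean_new <- out$truth$clean[1, ] * gain
    delta <- clean_new - out$truth$clean[1, ]
    out$truth$clean[1, ] <- clean_new
    out$truth$multipliers$line[] <- exp(line_effect)
    out$truth$multipliers$cell[] <- exp(cell_effect)
    m <- intensity_matrix(out$spectra)
    out$spectra <- set_intensities(out$spectra, m + rbind(delta))
  }
  out
}
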