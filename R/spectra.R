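#' Build a spectra table from an intensity matrix and metadata
#'
#' A spectra table is a wide tibble with one row per spectrum: the metadata
#' columns `spectrum_id`, `cell_line`, `cell_id`, `point_index`,
#' `class_label`, `qc_flags`, followed by one numeric column per wavenumber
#' channel, named by the wavenumber printed with one decimal (e.g. `"600.0"`).
#' All user-facing verbs in the package take and return this shape, so it
#' composes with dplyr and the pipe.
#'
#' @param meta Data frame with the metadata columns (`qc_flags` optional; a
#'   semicolon-separated string of quality-control flags, `""` when clean).
#' @param intensities Numeric matrix, one row per spectrum, one column per
#'   channel.
#' @param wavenumber Numeric axis (cm^-1), one entry per matrix column.
#' @return A `raman_spectra` tibble.
#' @examples
#' m <- matrix(rnorm(2 * 316)^2, nrow = 2)
#' meta <- tibble::tibble(
#'   spectrum_id = c("s1", "s2"), cell_line = "L1", cell_id = "c1",
#'   point_index = c(1L, 2L), class_label = "adult"
#' )
#' raman_spectra(meta, m, raman_axis())
#' @export
raman_spectra <- function(meta, intensities, wavenumber) {
  validate_wavenumbers(wavenumber)
  intensities <- as.matrix(intensities)
  if (nrow(meta) != nrow(intensities)) {
    abort("`meta` and `intensities` must describe the same spectra.")
  }
  if (ncol(intensities) != length(wavenumber)) {
    abort("`intensities` must have one column per wavenumber channel.")
  }
  meta <- as_tibble(meta)
  if (!"qc_flags" %in% names(meta)) meta$qc_flags <- ""
  colnames(intensities) <- axis_colnames(wavenumber)
  out <- dplyr::bind_cols(meta[meta_cols()[meta_cols() %in% names(meta)]],
                          as_tibble(intensities))
  as_raman_spectra(out)
}

#' Validate a wide data frame of spectra
#'
#' Checks the invariants of the spectra-table contract: required metadata
#' columns, unique spectrum ids, a strictly increasing uniform wavenumber
#' axis, finite intensities, point indices in 1..3, recognised class labels,
#' and one class label per cell line.
#'
#' @param x A data frame in wide spectra layout.
#' @return `x` as a validated `raman_spectra` tibble.
#' @export
as_raman_spectra <- function(x) {
  x <- as_tibble(x)
  if (!"qc_flags" %in% names(x)) x$qc_flags <- ""
  need <- setdiff(meta_cols(), "qc_flags")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("Missing metadata column(s): ", paste(missing, collapse = ", ")),
          class = "ramancell_meta_error")
  }
  chan <- spectra_channel_cols(x)
  if (length(chan) < 2) {
    abort("A spectra table needs at least 2 wavenumber channels.",
          class = "ramancell_axis_error")
  }
  w <- as.numeric(chan)
  validate_wavenumbers(w)
  if (anyDuplicated(x$spectrum_id)) {
    abort("Duplicate `spectrum_id`.", class = "ramancell_meta_error")
  }
  if (anyNA(x$class_label) || !all(x$class_label %in% class_levels())) {
    abort("`class_label` must be 'pediatric' or 'adult' for every spectrum.",
          class = "ramancell_meta_error")
  }
  if (anyNA(x$point_index) || !all(x$point_index %in% 1:3)) {
    abort("`point_index` must be 1, 2 or 3.", class = "ramancell_meta_error")
  }
  by_line <- tapply(x$class_label, x$cell_line, function(z) length(unique(z)))
  if (any(by_line > 1)) {
    abort("`class_label` must be constant within a cell line.",
          class = "ramancell_meta_error")
  }
  m <- as.matrix(x[chan])
  if (!all(is.finite(m))) {
    abort("Intensities must be finite.", class = "ramancell_intensity_error")
  }
  x$point_index <- as.integer(x$point_index)
  x$qc_flags <- ifelse(is.na(x$qc_flags), "", as.character(x$qc_flags))
  x <- x[c(meta_cols(), chan)]
  class(x) <- c("raman_spectra", class(as_tibble(tibble())))
  x
}

# Channel columns are those whose names parse as plain numbers.
spectra_channel_cols <- function(x) {
  nm <- names(x)
  nm[grepl("^[0-9]+(\\.[0-9]+)?$", nm)]
}

#' Wavenumber axis of a spectra table
#' @param x A `raman_spectra` tibble.
#' @return Numeric vector of wavenumbers (cm^-1).
#' @export
wavenumbers <- function(x) {
  as.numeric(spectra_channel_cols(x))
}

#' Intensity matrix of a spectra table
#' @param x A `raman_spectra` tibble.
#' @return Numeric matrix (spectra in rows, channels in columns) with
#'   `spectrum_id` row names.
#' @export
intensity_matrix <- function(x) {
  m <- as.matrix(x[spectra_channel_cols(x)])
  rownames(m) <- x$spectrum_id
  m
}

#' Metadata of a spectra table
#' @param x A `raman_spectra` tibble.
#' @return Tibble of the metadata columns only.
#' @export
spectra_meta <- function(x) {
  as_tibble(x)[intersect(meta_cols(), names(x))]
}

# Replace the intensity block, preserving metadata and axis.
set_intensities <- function(x, m) {
  chan <- spectra_channel_cols(x)
  stopifnot(ncol(m) == length(chan), nrow(m) == nrow(x))
  x[chan] <- as_tibble(`colnames<-`(m, chan))
  x
}

add_qc_flag <- function(flags, flag, which) {
  sep <- ifelse(nzchar(flags[which]), ";", "")
  flags[which] <- paste0(flags[which], sep, flag)
  flags
}

has_qc_flag <- function(flags, flag) {
  vapply(strsplit(flags, ";", fixed = TRUE), function(f) flag %in% f,
         logical(1))
}

#' @export
print.raman_spectra <- function(x, ...) {
  w <- wavenumbers(x)
  cat(sprintf("# Raman spectra: %d spectra x %d channels (%.1f-%.1f cm^-1, step %.3g)\n",
              nrow(x), length(w), min(w), max(w), axis_step(w)))
  cc <- table(x$class_label)
  cat("# Classes:", paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n")
  print(as_tibble(x), ...)
  invisible(x)
}
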