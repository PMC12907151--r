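#' Read a spectra table from delimited text
#'
#' Two layouts are supported. `"wide"` has one row per spectrum: the
#' metadata columns (`spectrum_id`, `cell_line`, `cell_id`, `point_index`,
#' `class_label`, optionally `qc_flags`) followed by one numeric column per
#' wavenumber. `"long"` has columns `spectrum_id`, `wavenumber`,
#' `intensity` plus the metadata columns repeated on every row.
#'
#' In long form, spectra recorded on a different but overlapping axis are
#' linearly interpolated onto the first spectrum's axis and flagged
#' `"resampled"` in `qc_flags`; channels outside the shared support are
#' dropped for all spectra (no extrapolation).
#'
#' @param path Path to a CSV file (UTF-8, `.` decimal separator).
#' @param format `"wide"` or `"long"`.
#' @return A validated [raman_spectra] tibble.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "ramancell_io_error")
  }
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      abort(sprintf("Failed to read '%s': %s", path, conditionMessage(e)),
            class = "ramancell_io_error")
    }
  )
  if (format == "wide") {
    chan <- spectra_channel_cols(df)
    if (nrow(df) == 0 && length(chan) >= 2) {
      return(empty_spectra(as.numeric(chan)))
    }
    return(as_raman_spectra(df))
  }
  long_to_wide(df)
}

# Assemble a wide table from long records, resampling mismatched axes
# onto the first spectrum's grid.
long_to_wide <- function(df) {
  need <- c("spectrum_id", "wavenumber", "intensity", "cell_line",
            "cell_id", "point_index", "class_label")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(paste0("Long format needs column(s): ", paste(missing, collapse = ", ")),
          class = "ramancell_io_error")
  }
  if (!"qc_flags" %in% names(df)) df$qc_flags <- ""
  ids <- unique(df$spectrum_id)
  if (nrow(df) == 0) abort("Empty long-format file.", class = "ramancell_io_error")
  recs <- split(df, factor(df$spectrum_id, levels = ids))
  for (r in recs) {
    if (anyDuplicated(r$wavenumber)) {
      abort("Duplicate wavenumber within a spectrum_id.",
            class = "ramancell_meta_error")
    }
    if (is.unsorted(r$wavenumber, strictly = TRUE)) {
      abort("Non-monotone wavenumber axis.", class = "ramancell_axis_error")
    }
  }
  ref <- recs[[1]]$wavenumber
  validate_wavenumbers(ref)
  # Trim the reference grid to the support shared by every spectrum.
  lo <- max(vapply(recs, function(r) min(r$wavenumber), numeric(1)))
  hi <- min(vapply(recs, function(r) max(r$wavenumber), numeric(1)))
  keep <- ref >= lo - 1e-9 & ref <= hi + 1e-9
  if (sum(keep) < 2) {
    abort("Spectra share fewer than 2 wavenumber channels.",
          class = "ramancell_axis_error")
  }
  ref <- ref[keep]
  rows <- lapply(recs, function(r) {
    same <- length(r$wavenumber) >= length(ref) &&
      all(vapply(ref, function(w) any(abs(r$wavenumber - w) < 1e-9), logical(1)))
    if (same) {
      idx <- vapply(ref, function(w) which.min(abs(r$wavenumber - w)), integer(1))
      list(y = r$intensity[idx], resampled = FALSE)
    } else {
      list(y = approx(r$wavenumber, r$intensity, xout = ref)$y, resampled = TRUE)
    }
  })
  meta <- df[!duplicated(df$spectrum_id),
             c("spectrum_id", "cell_line", "cell_id", "point_index",
               "class_label", "qc_flags")]
  meta$qc_flags <- ifelse(is.na(meta$qc_flags), "", meta$qc_flags)
  res <- vapply(rows, `[[`, logical(1), "resampled")
  meta$qc_flags <- add_qc_flag(meta$qc_flags, "resampled", which(res))
  m <- do.call(rbind, lapply(rows, `[[`, "y"))
  raman_spectra(meta, m, ref)
}

empty_spectra <- function(wavenumber) {
  meta <- tibble(spectrum_id = character(), cell_line = character(),
                 cell_id = character(), point_index = integer(),
                 class_label = character(), qc_flags = character())
  out <- dplyr::bind_cols(meta, as_tibble(matrix(numeric(0), nrow = 0,
                          ncol = length(wavenumber),
                          dimnames = list(NULL, axis_colnames(wavenumber)))))
  class(out) <- c("raman_spectra", class(tibble()))
  out
}

#' Write a spectra table to delimited text
#'
#' Writing then reading back reproduces intensities to better than 1e-9
#' relative error (readr prints shortest round-trippable decimals) and
#' metadata exactly.
#'
#' @param x A [raman_spectra] tibble.
#' @param path Output CSV path.
#' @param format `"wide"` or `"long"`.
#' @return `x`, invisibly.
#' @export
write_spectra <- function(x, path, format = c("wide", "long")) {
  format <- match.arg(format)
  x <- as_raman_spectra_or_empty(x)
  out <- if (format == "wide") {
    as_tibble(x)
  } else {
    w <- wavenumbers(x)
    long <- tidyr::pivot_longer(as_tibble(x),
                                cols = dplyr::all_of(spectra_channel_cols(x)),
                                names_to = "wavenumber",
                                values_to = "intensity")
    long$wavenumber <- as.numeric(long$wavenumber)
    long[c("spectrum_id", "wavenumber", "intensity", "cell_line", "cell_id",
           "point_index", "class_label", "qc_flags")]
  }
  tryCatch(
    readr::write_csv(out, path, progress = FALSE),
    error = function(e) {
      abort(sprintf("Failed to write '%s': %s", path, conditionMessage(e)),
            class = "ramancell_io_error")
    }
  )
  invisible(x)
}

as_raman_spectra_or_empty <- function(x) {
  if (nrow(x) == 0) return(x)
  as_raman_spectra(x)
}

#' Literature Raman band assignments
#'
#' Loads a band-assignment lookup: peak position (cm^-1) versus the
#' biochemical allocation reported in the Raman literature. The packaged
#' default is the 35-band fingerprint-region table used throughout the
#' package, spanning 621 to 1745 cm^-1 (phosphate backbone and base
#' vibrations of nucleic acids, aromatic amino acids, amide I-III protein
#' bands, CH2/CH3 lipid modes, cytochrome and NADH bands, and the
#' triglyceride ester carbonyl). These allocations are literature-based
#' look-ups, not biologically verified assignments.
#'
#' @param path Optional path to a CSV with columns `position`,
#'   `allocation` and optionally `reference_note`. Defaults to the
#'   packaged table.
#' @return Tibble with columns `position` (cm^-1, strictly increasing),
#'   `allocation`, `reference_note`.
#' @examples
#' band_assignments()
#' @export
band_assignments <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "band_assignments.csv",
                        package = "ramancell", mustWork = TRUE)
  }
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "ramancell_io_error")
  }
  tab <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      abort(sprintf("Failed to read '%s': %s", path, conditionMessage(e)),
            class = "ramancell_io_error")
    }
  )
  if (nrow(tab) == 0 || !all(c("position", "allocation") %in% names(tab))) {
    abort("A band table needs at least one row with columns `position`, `allocation`.",
          class = "ramancell_bandtable_error")
  }
  if (!"reference_note" %in% names(tab)) tab$reference_note <- NA_character_
  if (is.unsorted(tab$position, strictly = TRUE)) {
    abort("Band positions must be strictly increasing.",
          class = "ramancell_bandtable_error")
  }
  if (min(tab$position) < 600 || max(tab$position) > 1800) {
    abort("Band positions must lie within [600, 1800] cm^-1.",
          class = "ramancell_bandtable_error")
  }
  as_tibble(tab[c("position", "allocation", "reference_note")])
}
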