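test_that("axis validation accepts the canonical grid and rejects bad axes", {
  w <- raman_axis()
  expect_length(w, 316)
  expect_equal(w[1], 600)
  expect_equal(w[316], 1797)
  expect_error(raman_axis(10, from = 500), class = "ramancell_axis_error")
  m <- matrix(1, 1, 3)
  meta <- tibble::tibble(spectrum_id = "s", cell_line = "L", cell_id = "c",
                         point_index = 1L, class_label = "adult")
  expect_error(raman_spectra(meta, m, c(700, 650, 720)),
               class = "ramancell_axis_error")
  expect_error(raman_spectra(meta, m, c(600, NA, 700)),
               class = "ramancell_axis_error")
  expect_error(raman_spectra(meta, m, c(600, 610, 630)),  # non-uniform
               class = "ramancell_axis_error")
})

test_that("metadata invariants are enforced", {
  co <- simulate_cohort(tiny_config(ped = 6, adults = 6), seed = 1)
  x <- co$spectra
  bad <- x
  bad$spectrum_id[2] <- bad$spectrum_id[1]
  expect_error(as_raman_spectra(bad), class = "ramancell_meta_error")
  bad <- x
  bad$class_label[1] <- NA
  expect_error(as_raman_spectra(bad), class = "ramancell_meta_error")
  bad <- x
  bad$point_index[1] <- 4L
  expect_error(as_raman_spectra(bad), class = "ramancell_meta_error")
  bad <- x  # one line, two class labels
  bad$class_label[bad$cell_line == "adult-1"][1] <- "pediatric"
  expect_error(as_raman_spectra(bad), class = "ramancell_meta_error")
})

test_that("write/read round-trips intensities and metadata in both formats", {
  co <- simulate_cohort(tiny_config(ped = 6, adults = c(3, 3)), seed = 3)
  x <- co$spectra
  x$qc_flags[1] <- "despiked"
  for (fmt in c("wide", "long")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_spectra(x, path, format = fmt)
    back <- read_spectra(path, format = fmt)
    expect_equal(spectra_meta(back), spectra_meta(x))
    rel <- abs(intensity_matrix(back) - intensity_matrix(x)) /
      pmax(abs(intensity_matrix(x)), 1e-12)
    expect_lt(max(rel), 1e-9)
    expect_equal(wavenumbers(back), wavenumbers(x))
  }
})

test_that("an empty table round-trips as a header-only file", {
  x <- simulate_cohort(tiny_config(ped = 3, adults = 3), seed = 1)$spectra
  empty <- x[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(empty, path, format = "wide")
  back <- read_spectra(path, format = "wide")
  expect_equal(nrow(back), 0)
  expect_equal(wavenumbers(back), wavenumbers(x))
})

test_that("mismatched long-format axes are interpolated onto the first grid", {
  ref <- raman_axis(21, 600, 3.8)
  other <- 600 + (0:20) * 3.9
  f <- function(w) 2 + 0.01 * w + sin(w / 40)
  long <- dplyr::bind_rows(
    tibble::tibble(spectrum_id = "s1", wavenumber = ref, intensity = f(ref)),
    tibble::tibble(spectrum_id = "s2", wavenumber = other,
                   intensity = f(other))
  )
  long$cell_line <- "L1"
  long$cell_id <- ifelse(long$spectrum_id == "s1", "c1", "c2")
  long$point_index <- 1L
  long$class_label <- "adult"
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(long, path)
  ds <- read_spectra(path, format = "long")
  expect_equal(nrow(ds), 2)
  expect_false(grepl("resampled", ds$qc_flags[ds$spectrum_id == "s1"]))
  expect_true(grepl("resampled", ds$qc_flags[ds$spectrum_id == "s2"]))
  # direct linear-interpolation oracle at hand-picked channels
  m <- intensity_matrix(ds)
  for (k in c(2, 5, 9, 14, 20)) {
    w <- ref[k]
    i <- findInterval(w, other)
    frac <- (w - other[i]) / (other[i + 1] - other[i])
    oracle <- f(other[i]) * (1 - frac) + f(other[i + 1]) * frac
    expect_equal(unname(m["s2", k]), oracle, tolerance = 1e-12)
  }
})

test_that("long files with duplicate records or bad axes are rejected", {
  base <- tibble::tibble(spectrum_id = "s1",
                         wavenumber = c(600, 603.8, 603.8),
                         intensity = 1, cell_line = "L", cell_id = "c",
                         point_index = 1L, class_label = "adult")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(base, path)
  expect_error(read_spectra(path, format = "long"),
               class = "ramancell_meta_error")
  base$wavenumber <- c(610, 605, 600)
  readr::write_csv(base, path)
  expect_error(read_spectra(path, format = "long"),
               class = "ramancell_axis_error")
  expect_error(read_spectra(file.path(tempdir(), "nope.csv")),
               class = "ramancell_io_error")
})

test_that("the packaged band table matches the fingerprint literature table", {
  tab <- band_assignments()
  expect_equal(nrow(tab), 35)
  expect_true(all(diff(tab$position) > 0))
  expect_equal(min(tab$position), 621)
  expect_equal(max(tab$position), 1745)
  expect_equal(tab$allocation[tab$position == 1001], "Phenylalanine")
  expect_equal(tab$allocation[tab$position == 1745],
               "Ester C=O Stretching (Triglycerides in lipids)")
})

test_that("malformed band tables are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("position,allocation", path)
  expect_error(band_assignments(path), class = "ramancell_bandtable_error")
  readr::write_csv(tibble::tibble(position = c(700, 650),
                                  allocation = c("a", "b")), path)
  expect_error(band_assignments(path), class = "ramancell_bandtable_error")
  readr::write_csv(tibble::tibble(position = c(500, 650),
                                  allocation = c("a", "b")), path)
  expect_error(band_assignments(path), class = "ramancell_bandtable_error")
})
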