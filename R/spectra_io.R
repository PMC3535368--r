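#' Write a spectrum as a two-column CSV
#'
#' Format: a comment line `# time_min=<t>` followed by a `ppm,intensity`
#' header and the data.
#'
#' @param spectrum An [nmr_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "nmr_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# time_min=%.17g", spectrum$time_min), con)
  writeLines("ppm,intensity", con)
  writeLines(sprintf("%.17g,%.17g", spectrum$ppm, spectrum$intensity), con)
  invisible(path)
}

#' Read a spectrum CSV written by [write_spectrum()]
#'
#' @param path File path.
#' @return An [nmr_spectrum()].
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  t_min <- NA_real_
  if (grepl("^#\\s*time_min=", first)) {
    t_min <- as.numeric(sub("^#\\s*time_min=", "", first))
  }
  df <- read.csv(path, comment.char = "#")
  if (!all(c("ppm", "intensity") %in% names(df))) {
    stop("spectrum file must have columns ppm,intensity")
  }
  nmr_spectrum(df$ppm, df$intensity, t_min)
}

#' Write a spectra series (one CSV per spectrum plus a manifest)
#'
#' @param experiment An `"nmr_experiment"` (or a bare list of
#'   [nmr_spectrum()] objects).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the per-spectrum CSVs.
#' @return Path of the manifest CSV (`manifest.csv`, columns
#'   `file,time_min`), invisibly.
#' @export
write_spectra_series <- function(experiment, dir, prefix = "spectrum") {
  spectra <- if (inherits(experiment, "nmr_experiment")) {
    experiment$spectra
  } else {
    experiment
  }
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, logical(1), "nmr_spectrum")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.csv", prefix, seq_along(spectra))
  for (i in seq_along(spectra)) {
    write_spectrum(spectra[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(
    file = files,
    time_min = vapply(spectra, `[[`, numeric(1), "time_min"))
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a spectra series from its manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by
#'   [write_spectra_series()].
#' @return List of [nmr_spectrum()], ordered by acquisition time.
#' @export
read_spectra_series <- function(manifest_path) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("file", "time_min") %in% names(manifest))) {
    stop("manifest must have columns file,time_min")
  }
  manifest <- manifest[order(manifest$time_min), , drop = FALSE]
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    s <- read_spectrum(file.path(base, manifest$file[i]))
    s$time_min <- manifest$time_min[i]
    s
  })
}

#' Write a peak table as CSV
#'
#' Columns: `label,shift_ppm,fwhm_ppm,species_tag,response`.
#'
#' @param peaks A `"peak_table"` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  need <- c("label", "shift_ppm", "fwhm_ppm", "species_tag", "response")
  stopifnot(is.data.frame(peaks), all(need %in% names(peaks)))
  write.csv(peaks[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak table CSV written by [write_peak_table()]
#'
#' @param path File path.
#' @return A `"peak_table"` data frame.
#' @export
read_peak_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "shift_ppm", "fwhm_ppm", "species_tag", "response")
  if (!all(need %in% names(df))) {
    stop("peak table misses column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  structure(df, class = c("peak_table", "data.frame"))
}
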