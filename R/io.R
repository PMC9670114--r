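## Plain-text interchange: recordings as CSV (rows = channels, header =
## channel names transposed below; metadata in a JSON sidecar), spectra and
## Z-score matrices as CSV, RGB renders as PNG.

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a recording to CSV with a JSON metadata sidecar
#'
#' The CSV holds one row per channel (first column the channel name); the
#' sidecar (same path with `.json`) stores `fs`, `reference` and the subject
#' metadata (age, sex, group).
#'
#' @param rec An `eeg_recording`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- data.frame(channel = rec$channel_names, rec$data, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(fs = rec$fs, reference = rec$reference,
               subject_id = rec$profile$subject_id, age = rec$profile$age,
               sex = rec$profile$sex, group = rec$profile$group,
               noise_level = rec$profile$noise_level)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording_csv()]
#'
#' @param path CSV file path (sidecar expected alongside).
#' @return An `eeg_recording`.
#' @export
read_recording_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  data <- as.matrix(df[, -1, drop = FALSE])
  dimnames(data) <- list(df$channel, NULL)
  data <- data[match(CHANNELS_1020, df$channel), , drop = FALSE]
  prof <- subject_profile(meta$subject_id, meta$age, meta$sex,
                          group = if (meta$group %in% c("healthy", "SCD", "MCI", "ADD"))
                            meta$group else "healthy",
                          noise_level = meta$noise_level)
  structure(list(data = data, fs = meta$fs, channel_names = CHANNELS_1020,
                 reference = meta$reference, profile = prof),
            class = "eeg_recording")
}

#' Write a channels-by-bins matrix (relative power or Z-scores) to CSV
#'
#' @param x A `relative_power` or `zscore_matrix`.
#' @param path CSV file path; a JSON sidecar stores age/sex metadata.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  stopifnot(inherits(x, "relative_power") || inherits(x, "zscore_matrix"))
  df <- data.frame(channel = x$channel_names, x$values, check.names = FALSE)
  colnames(df) <- c("channel", format(x$freqs, nsmall = 2))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(age = x$age, sex = x$sex,
                            kind = class(x)[1]),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Z-score matrix written by [write_spectrum_csv()]
#'
#' @param path CSV file path.
#' @return A `zscore_matrix` (or `relative_power`, per the sidecar `kind`).
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$channel
  structure(list(values = values, freqs = bin_freqs(),
                 channel_names = df$channel,
                 age = meta$age, sex = meta$sex),
            class = meta$kind)
}

#' Write an RGB render to PNG
#'
#' @param img A `feature_image`.
#' @param path PNG file path.
#' @param clip Colormap saturation passed to [render_rgb()].
#' @return `path`, invisibly.
#' @export
write_feature_png <- function(img, path, clip = 1.96) {
  png::writePNG(render_rgb(img, clip), path)
  invisible(path)
}
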