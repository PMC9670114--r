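## Preprocessing: common average reference, zero-phase bandpass, epoching and
## amplitude-based bad-epoch rejection.

#' Re-reference a recording to the common average
#'
#' Subtracts the instantaneous mean across the 19 channels from every channel,
#' so that at each sample the channel mean is zero. Idempotent.
#'
#' @param rec An `eeg_recording`.
#' @return The re-referenced `eeg_recording` with `reference = "common-average"`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$data) == 19L)
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  rec$reference <- "common-average"
  rec
}

#' Zero-phase bandpass filter
#'
#' Forward-backward (zero-phase) 4th-order Butterworth bandpass over the band
#' of interest, default 1-45.5 Hz. The two-pass magnitude response keeps a
#' 10 Hz tone essentially untouched while suppressing DC drift and
#' line-frequency content far below 10% amplitude.
#'
#' @param rec An `eeg_recording`.
#' @param lo,hi Band edges in Hz, `lo < hi < fs/2`.
#' @param order Butterworth prototype order (default 4).
#' @return Filtered `eeg_recording` (same length and channel count).
#' @export
bandpass_filter <- function(rec, lo = 1, hi = 45.5, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(lo < hi)) stop("`lo` must be below `hi`", call. = FALSE)
  if (hi >= nyq) stop("`hi` must be below the Nyquist frequency ", nyq, " Hz",
                      call. = FALSE)
  bf <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  ## demean per channel first: keeps the forward-backward passes free of the
  ## large DC edge transient a constant offset would otherwise inject
  rec$data <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x - mean(x))))
  rownames(rec$data) <- rec$channel_names
  rec
}

#' Cut a recording into fixed-length epochs
#'
#' Contiguous windows of `epoch_length_s` seconds with optional fractional
#' overlap; a trailing partial window is discarded.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_length_s Epoch length in seconds (default 4 s, matching the
#'   0.25 Hz spectral resolution of the analysis grid).
#' @param overlap_frac Fractional overlap between consecutive epochs in
#'   `[0, 1)`.
#' @return An `epoched_eeg`: list with `data` (n_epochs x 19 x samples array),
#'   `fs`, `epoch_length_s`, `kept_indices`, `channel_names` and `profile`.
#' @export
make_epochs <- function(rec, epoch_length_s = 4, overlap_frac = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("`overlap_frac` must lie in [0, 1)", call. = FALSE)
  }
  len <- round(epoch_length_s * rec$fs)
  n <- ncol(rec$data)
  if (n < len) stop("recording shorter than one epoch", call. = FALSE)
  step <- max(1L, round(len * (1 - overlap_frac)))
  starts <- seq.int(1L, n - len + 1L, by = step)
  data <- array(0, dim = c(length(starts), 19L, len))
  for (i in seq_along(starts)) {
    data[i, , ] <- rec$data[, starts[i]:(starts[i] + len - 1L)]
  }
  structure(
    list(data = data, fs = rec$fs, epoch_length_s = epoch_length_s,
         kept_indices = seq_along(starts), channel_names = rec$channel_names,
         profile = rec$profile),
    class = "epoched_eeg"
  )
}

#' Reject artifact-contaminated epochs
#'
#' Drops every epoch containing a sample whose absolute amplitude exceeds
#' `amp_threshold_uV` on any channel and, when `flat_sd_uV > 0`, flatlined
#' epochs (any channel with SD below `flat_sd_uV`). Surviving epochs keep
#' their original order and indices.
#'
#' @param ep An `epoched_eeg`.
#' @param amp_threshold_uV Absolute amplitude threshold in uV (default 100).
#' @param flat_sd_uV Flatline threshold: minimum per-channel SD in uV; 0
#'   (default) disables the check so that a silent-but-clean epoch is kept.
#' @return The pruned `epoched_eeg`; `attr(, "n_rejected")` counts removals.
#' @export
reject_bad_epochs <- function(ep, amp_threshold_uV = 100, flat_sd_uV = 0) {
  stopifnot(inherits(ep, "epoched_eeg"))
  if (amp_threshold_uV <= 0) stop("`amp_threshold_uV` must be > 0", call. = FALSE)
  n_ep <- dim(ep$data)[1]
  keep <- vapply(seq_len(n_ep), function(i) {
    seg <- ep$data[i, , , drop = TRUE]
    if (max(abs(seg)) > amp_threshold_uV) return(FALSE)
    if (flat_sd_uV > 0 && any(apply(seg, 1L, stats::sd) < flat_sd_uV)) return(FALSE)
    TRUE
  }, logical(1))
  if (!any(keep)) {
    stop("all ", n_ep, " epochs rejected (threshold ", amp_threshold_uV,
         " uV); recording unusable", call. = FALSE)
  }
  n_rej <- sum(!keep)
  if (n_rej > 0) message(n_rej, " of ", n_ep, " epochs rejected")
  ep$data <- ep$data[keep, , , drop = FALSE]
  ep$kept_indices <- ep$kept_indices[keep]
  attr(ep, "n_rejected") <- n_rej
  ep
}
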