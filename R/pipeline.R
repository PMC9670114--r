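## End-to-end convenience wrappers: recording -> relative power -> Z-scores ->
## feature image, with a hook point where an ICA-based artifact-removal step
## can be plugged in between re-referencing and spectral analysis.

#' Relative power spectrum of a raw recording
#'
#' Runs the standard preprocessing contract (common average reference, an
#' optional artifact-removal hook, 1-45.5 Hz zero-phase bandpass, 4 s
#' epoching, amplitude-based epoch rejection) and returns the 19 x 176
#' relative power spectrum.
#'
#' @param rec An `eeg_recording`.
#' @param lo,hi Bandpass edges in Hz.
#' @param epoch_length_s Epoch length (4 s for the 0.25 Hz grid).
#' @param amp_threshold_uV Bad-epoch amplitude threshold.
#' @param artifact_hook Optional `function(eeg_recording) -> eeg_recording`
#'   applied after re-referencing (e.g. an ICA component-removal step); the
#'   default is a no-op.
#' @return A `relative_power`.
#' @export
rp_from_recording <- function(rec, lo = 1, hi = 45.5, epoch_length_s = 4,
                              amp_threshold_uV = 100, artifact_hook = NULL) {
  rec <- common_average_reference(rec)
  if (!is.null(artifact_hook)) rec <- artifact_hook(rec)
  rec <- bandpass_filter(rec, lo, hi)
  ep <- make_epochs(rec, epoch_length_s)
  ep <- suppressMessages(reject_bad_epochs(ep, amp_threshold_uV))
  epoch_relative_power(ep)
}

#' Feature image of a recording, standardized against a normative database
#'
#' @param rec An `eeg_recording`.
#' @param db A `normative_db`.
#' @param variant `"nearest"`, `"bicubic"`, `"weightmap"` or `"rescaled"`.
#' @param ... Passed to [rp_from_recording()].
#' @return A `feature_image`.
#' @export
feature_image_from_recording <- function(rec, db,
                                         variant = c("weightmap", "nearest",
                                                     "bicubic", "rescaled"),
                                         ...) {
  variant <- match.arg(variant)
  rp <- rp_from_recording(rec, ...)
  fm <- assemble_feature_matrix(zscore(rp, db))
  switch(variant,
         nearest  = nearest_upscale(fm),
         bicubic  = bicubic_upscale(fm),
         weightmap = apply_weight_map(bicubic_upscale(fm)),
         rescaled = rescale_bands(fm))
}

#' Build a normative database from a synthetic cohort
#'
#' @param cohort Output of [generate_cohort()].
#' @param ... Passed to [build_normdb()].
#' @return A `normative_db`.
#' @export
normdb_from_cohort <- function(cohort, ...) {
  rps <- lapply(cohort, function(s) rp_from_recording(s$recording))
  suppressMessages(build_normdb(rps, ...))
}

#' Wrap a CNN model as a LIME-compatible prediction function
#'
#' @param model A `cnn_model`.
#' @param downsample Block-average factor matching the one used at training.
#' @return `function(list of RGB arrays) -> n x 2 probability matrix`.
#' @export
cnn_predict_fn <- function(model, downsample = 8L) {
  function(images) {
    predict_cnn(model, lapply(images, downsample_rgb, factor = downsample))
  }
}
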