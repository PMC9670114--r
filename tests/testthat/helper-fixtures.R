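## Shared fixtures and independent oracles, all built in code.

zero_gains <- function() {
  stats::setNames(rep(0, 8), band_scheme()$band)
}

## Wrap a plain 19 x n matrix as a recording (for oracle-driven tests).
rec_from_matrix <- function(data, fs = 250, age = 30, sex = "male") {
  structure(
    list(data = data, fs = fs,
         channel_names = c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz", "T3",
                           "T4", "C3", "C4", "Cz", "T5", "T6", "P3", "P4",
                           "Pz", "O1", "O2"),
         reference = "linked-ear",
         profile = subject_profile("fix", age, sex)),
    class = "eeg_recording"
  )
}

## Wrap a 19 x 176 matrix as a Z-score matrix object.
z_from_matrix <- function(values, age = 30, sex = "male") {
  chs <- c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz", "T3", "T4", "C3",
           "C4", "Cz", "T5", "T6", "P3", "P4", "Pz", "O1", "O2")
  rownames(values) <- chs
  structure(list(values = values, freqs = bin_freqs(), channel_names = chs,
                 age = age, sex = sex),
            class = "zscore_matrix")
}

## Independent oracle: separable 1-D cubic convolution (Catmull-Rom spline,
## kernel parameter -1/2), applied row-then-column on a 4 x 4 patch.
keys_interp_1d <- function(p, x) {
  0.5 * (2 * p[2] + (-p[1] + p[3]) * x +
           (2 * p[1] - 5 * p[2] + 4 * p[3] - p[4]) * x^2 +
           (-p[1] + 3 * p[2] - 3 * p[3] + p[4]) * x^3)
}

keys_interp_patch <- function(patch, x, y) {
  rows <- vapply(1:4, function(m) keys_interp_1d(patch[m, ], y), numeric(1))
  keys_interp_1d(rows, x)
}

## Direct periodogram band power oracle: raw squared DFT magnitudes summed
## over [lo, hi), no windowing, whole recording in one block.
direct_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  spec <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  sum(spec[freqs >= lo & freqs < hi])
}

direct_relative_band_power <- function(x, fs, lo, hi, total_lo = 1, total_hi = 45) {
  direct_band_power(x, fs, lo, hi) / direct_band_power(x, fs, total_lo, total_hi)
}

## Bicubic feature image of a random Z-score matrix, with known geometry.
demo_image <- function(weightmap = FALSE, seed = 70) {
  set.seed(seed)
  img <- bicubic_upscale(assemble_feature_matrix(
    z_from_matrix(matrix(stats::rnorm(19 * 176), 19))))
  if (weightmap) img <- apply_weight_map(img)
  img
}

## Tiny image dataset of two trivially separable classes: class ADD has the
## top half bright red, class NADD the bottom half bright blue.
two_blob_dataset <- function(n_per_class = 12, h = 16, seed = 42) {
  items <- withr::with_seed(seed, {
    lapply(seq_len(2 * n_per_class), function(i) {
      lab <- if (i <= n_per_class) "ADD" else "NADD"
      x <- array(stats::runif(h * h * 3, 0.4, 0.6), c(h, h, 3))
      if (lab == "ADD") x[seq_len(h / 2), , 1] <- 1 else x[(h / 2 + 1):h, , 3] <- 1
      list(x = x, label = lab, subject_id = sprintf("b%02d", i))
    })
  })
  structure(list(items = items, variant = "synthetic", classes = c("ADD", "NADD")),
            class = "image_dataset")
}
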