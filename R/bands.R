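#' @keywords internal
"_PACKAGE"

## Fixed 10-20 montage order used throughout the package. Every matrix with a
## channel dimension uses exactly this order.
CHANNELS_1020 <- c(
  "Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz", "T3", "T4",
  "C3", "C4", "Cz", "T5", "T6", "P3", "P4", "Pz", "O1", "O2"
)

## Posterior channels carrying the eyes-closed alpha dominance.
POSTERIOR_CHANNELS <- c("O1", "O2", "P3", "P4", "Pz", "T5", "T6")

#' The eight-band frequency scheme
#'
#' Contiguous, non-overlapping, half-open bands `[lo, hi)` covering 1-45 Hz:
#' delta (1-4), theta (4-8), alpha1 (8-10), alpha2 (10-12), beta1 (12-15),
#' beta2 (15-20), beta3 (20-30) and gamma (30-45). On the 0.25 Hz analysis
#' grid the bands contain 12, 16, 8, 8, 12, 20, 40 and 60 bins (176 total).
#'
#' @return A data frame with columns `band`, `lo`, `hi` and `n_bins`.
#' @export
#' @examples
#' band_scheme()
band_scheme <- function() {
  bands <- data.frame(
    band = c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2", "beta3", "gamma"),
    lo   = c(1, 4, 8, 10, 12, 15, 20, 30),
    hi   = c(4, 8, 10, 12, 15, 20, 30, 45),
    stringsAsFactors = FALSE
  )
  bands$n_bins <- as.integer((bands$hi - bands$lo) / 0.25)
  bands
}

#' Frequency bins of the relative-power spectrum
#'
#' Lower edges of the 176 half-open 0.25 Hz bins spanning `[1, 45)` Hz.
#'
#' @return Numeric vector of length 176 (1.00, 1.25, ..., 44.75).
#' @export
bin_freqs <- function() seq(1, 45 - 0.25, by = 0.25)

#' Map frequencies to band names
#'
#' @param freqs Frequencies in Hz (bin lower edges).
#' @return Character vector of band names; NA outside `[1, 45)`.
#' @export
band_of <- function(freqs) {
  scheme <- band_scheme()
  idx <- findInterval(freqs, c(scheme$lo, 45))
  out <- rep(NA_character_, length(freqs))
  ok <- idx >= 1 & idx <= nrow(scheme) & freqs >= 1 & freqs < 45
  out[ok] <- scheme$band[idx[ok]]
  out
}

#' Hemispheric channel layout of the feature matrix
#'
#' Eleven rows per hemisphere, anterior to posterior; the midline channels
#' Fz, Cz and Pz belong to both sides so that each hemisphere column block
#' carries a complete front-to-back strip.
#'
#' @return List with `left_rows` and `right_rows`, each 11 channel names.
#' @export
#' @examples
#' channel_layout()
channel_layout <- function() {
  list(
    left_rows  = c("Fp1", "F7", "F3", "Fz", "T3", "C3", "Cz", "T5", "P3", "Pz", "O1"),
    right_rows = c("Fp2", "F8", "F4", "Fz", "T4", "C4", "Cz", "T6", "P4", "Pz", "O2")
  )
}

## Run `fn` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards, so generators are deterministic without side
## effects on the session.
with_seed <- function(seed, fn) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}
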