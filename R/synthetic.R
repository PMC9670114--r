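## Synthetic resting-state EEG: band-limited oscillators over a 1/f background.
##
## Each channel is a sum over the eight bands of three amplitude-modulated
## sinusoids at random in-band frequencies, plus spectrally shaped (1/f) noise.
## Posterior channels receive an alpha boost, emulating the eyes-closed
## posterior alpha dominance that resting-state QEEG relies on.

## Default healthy oscillator amplitudes (uV, per-sinusoid scale). Alpha is the
## dominant rhythm before the posterior boost; high-frequency bands are weak.
HEALTHY_GAINS <- c(
  delta = 4, theta = 3, alpha1 = 8, alpha2 = 6,
  beta1 = 2.5, beta2 = 2, beta3 = 1.5, gamma = 1
)

## Multiplicative ADD spectral signature: slowing (delta/theta up) with
## attenuated alpha; beta/gamma unchanged.
ADD_MULTIPLIERS <- c(
  delta = 1.8, theta = 1.8, alpha1 = 0.5, alpha2 = 0.5,
  beta1 = 1, beta2 = 1, beta3 = 1, gamma = 1
)

#' Create a subject profile for the synthetic EEG generator
#'
#' @param subject_id Identifier string.
#' @param age Age in years, within 4.5-81.
#' @param sex `"male"` or `"female"`.
#' @param group One of `"healthy"`, `"SCD"`, `"MCI"`, `"ADD"`.
#' @param band_gains Named nonnegative amplitudes (uV) for the eight bands of
#'   [band_scheme()]. Defaults to the healthy profile.
#' @param noise_level RMS amplitude (uV) of the 1/f background, `>= 0`.
#' @return A `subject_profile` list.
#' @export
#' @examples
#' subject_profile("s1", age = 70, sex = "female")
subject_profile <- function(subject_id, age, sex = c("male", "female"),
                            group = c("healthy", "SCD", "MCI", "ADD"),
                            band_gains = HEALTHY_GAINS, noise_level = 5) {
  sex <- match.arg(sex)
  group <- match.arg(group)
  stopifnot(length(age) == 1L, is.finite(age))
  if (age < 4.5 || age > 81) {
    stop("`age` must lie within 4.5-81 years", call. = FALSE)
  }
  if (noise_level < 0) stop("`noise_level` must be >= 0", call. = FALSE)
  scheme <- band_scheme()
  if (!setequal(names(band_gains), scheme$band)) {
    stop("`band_gains` names must be exactly the band scheme bands: ",
         paste(scheme$band, collapse = ", "), call. = FALSE)
  }
  if (any(band_gains < 0)) stop("`band_gains` must be nonnegative", call. = FALSE)
  structure(
    list(
      subject_id = as.character(subject_id), age = age, sex = sex, group = group,
      band_gains = band_gains[scheme$band], noise_level = noise_level
    ),
    class = "subject_profile"
  )
}

#' ADD-like subject profile
#'
#' Applies the dementia spectral signature (elevated delta/theta, attenuated
#' alpha) to the healthy gains. `separation` interpolates between the healthy
#' profile (0) and the full signature (1); values above 1 exaggerate it.
#'
#' @inheritParams subject_profile
#' @param separation Nonnegative scale of the ADD spectral shift.
#' @return A `subject_profile`.
#' @export
add_profile <- function(subject_id, age, sex = c("male", "female"),
                        separation = 1, noise_level = 5) {
  stopifnot(separation >= 0)
  mult <- 1 + separation * (ADD_MULTIPLIERS - 1)
  subject_profile(subject_id, age, sex, group = "ADD",
                  band_gains = HEALTHY_GAINS * mult[names(HEALTHY_GAINS)],
                  noise_level = noise_level)
}

## 1/f-shaped noise (power ~ 1/f^exponent), scaled to the requested RMS.
pink_noise <- function(n, fs, rms, exponent = 1) {
  if (rms == 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- c(0, 1 / freq[-1]^(exponent / 2))
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * rms / stats::sd(x)
}

## One channel: per band, `n_osc` sinusoids at uniform in-band frequencies with
## random phase, amplitude-modulated by a slow raised-cosine (Hann-like)
## envelope with a random period of a few seconds.
synth_channel <- function(t, fs, gains, alpha_boost, noise_level, n_osc = 3) {
  scheme <- band_scheme()
  n <- length(t)
  n_band <- nrow(scheme)
  g <- as.numeric(gains[scheme$band])
  g[scheme$band %in% c("alpha1", "alpha2")] <-
    g[scheme$band %in% c("alpha1", "alpha2")] * alpha_boost
  total <- n_osc * n_band
  freqs <- stats::runif(total, rep(scheme$lo, each = n_osc),
                        rep(scheme$hi, each = n_osc))
  phases <- stats::runif(total, 0, 2 * pi)
  ## one slow Hann-like raised-cosine envelope per band (period 2-6 s),
  ## shared by that band's oscillators
  env_period <- stats::runif(n_band, 2, 6)
  env_phase <- stats::runif(n_band, 0, 2 * pi)
  amps <- rep(g, each = n_osc) / n_osc
  carrier <- sin(outer(t, 2 * pi * freqs) +
                   matrix(phases, n, total, byrow = TRUE))
  env <- 0.5 * (1 - cos(outer(t, 2 * pi / env_period) +
                          matrix(env_phase, n, n_band, byrow = TRUE)))
  env <- env[, rep(seq_len(n_band), each = n_osc), drop = FALSE]
  as.numeric((carrier * env) %*% amps) + pink_noise(n, fs, noise_level)
}

#' Generate a synthetic 19-channel EEG recording
#'
#' @param profile A [subject_profile()].
#' @param duration_s Recording length in seconds (> 0). Default 120 s, the
#'   short end of the typical 2-3 minute continuous eyes-closed resting
#'   acquisition.
#' @param fs Sampling rate in Hz, `>= 100`. Default 250 Hz.
#' @param seed Integer seed; output is bit-identical for a fixed seed.
#' @param alpha_boost Posterior alpha amplitude factor applied to O1, O2, P3,
#'   P4, Pz, T5, T6 (default 2).
#' @param amplitude_cap Hard bound (uV) applied symmetrically to the signal.
#' @return An `eeg_recording`: list with `data` (19 x samples matrix, uV),
#'   `fs`, `channel_names`, `reference` and `profile`.
#' @export
#' @examples
#' rec <- generate_recording(subject_profile("s1", 30, "male"),
#'                           duration_s = 8, fs = 250, seed = 1)
#' dim(rec$data)
generate_recording <- function(profile, duration_s = 120, fs = 250, seed = 1,
                               alpha_boost = 2, amplitude_cap = 500) {
  stopifnot(inherits(profile, "subject_profile"))
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  if (fs < 100) stop("`fs` must be >= 100 Hz", call. = FALSE)
  if (fs <= 2 * 45.5) stop("`fs` must exceed twice the 45.5 Hz band edge", call. = FALSE)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  data <- with_seed(seed, function() {
    m <- matrix(0, nrow = 19L, ncol = n)
    for (ch in seq_along(CHANNELS_1020)) {
      boost <- if (CHANNELS_1020[ch] %in% POSTERIOR_CHANNELS) alpha_boost else 1
      m[ch, ] <- synth_channel(t, fs, profile$band_gains, boost, profile$noise_level)
    }
    m
  })
  data <- pmin(pmax(data, -amplitude_cap), amplitude_cap)
  rownames(data) <- CHANNELS_1020
  structure(
    list(data = data, fs = fs, channel_names = CHANNELS_1020,
         reference = "linked-ear", profile = profile),
    class = "eeg_recording"
  )
}

#' Generate a synthetic healthy normative cohort
#'
#' Ages are uniform over `age_range`, sexes balanced (or drawn at the given
#' ratio), and each subject's band gains receive mild lognormal jitter so the
#' cohort has realistic between-subject spectral variability.
#'
#' @param n Number of subjects, `>= 1`.
#' @param age_range Numeric `(lo, hi)` in years, within 4.5-81.
#' @param seed Integer seed.
#' @param male_frac Fraction of males. Default 0.5 gives alternating sexes
#'   with counts differing by at most one; e.g. `553 / 1289` reproduces a
#'   553:736 male:female cohort shape.
#' @param duration_s,fs Passed to [generate_recording()].
#' @param gain_jitter_sd SD of the lognormal per-subject gain jitter.
#' @param map Optional `function(recording, profile)` applied to each subject
#'   as it is generated; when supplied the recording is released immediately
#'   and the mapped values are returned instead (keeps memory flat for large
#'   cohorts).
#' @return List of `n` elements, each `list(recording, profile)` (or the
#'   `map` results).
#' @export
generate_cohort <- function(n, age_range = c(4.5, 81), seed = 1, male_frac = 0.5,
                            duration_s = 120, fs = 250, gain_jitter_sd = 0.1,
                            map = NULL) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (length(age_range) != 2L || age_range[2] <= age_range[1]) {
    stop("`age_range` must be an increasing (lo, hi) pair", call. = FALSE)
  }
  meta <- with_seed(seed, function() {
    ages <- stats::runif(n, age_range[1], age_range[2])
    n_male <- round(n * male_frac)
    sexes <- rep(c("male", "female"), length.out = n)
    if (male_frac != 0.5) {
      sexes <- c(rep("male", n_male), rep("female", n - n_male))
    }
    jitter <- matrix(exp(stats::rnorm(n * 8, 0, gain_jitter_sd)), nrow = n)
    list(ages = ages, sexes = sexes, jitter = jitter,
         seeds = sample.int(.Machine$integer.max, n))
  })
  lapply(seq_len(n), function(i) {
    gains <- HEALTHY_GAINS * meta$jitter[i, ]
    prof <- subject_profile(sprintf("norm%04d", i), age = meta$ages[i],
                            sex = meta$sexes[i], group = "healthy",
                            band_gains = gains)
    rec <- generate_recording(prof, duration_s, fs, seed = meta$seeds[i])
    if (is.null(map)) list(recording = rec, profile = prof) else map(rec, prof)
  })
}

#' Generate a labeled synthetic ADD / NADD dataset
#'
#' @param n_add,n_nadd Class sizes, `>= 1`; any imbalance (e.g. 137:628) is
#'   supported.
#' @param separation Nonnegative scale of the ADD spectral shift; 0 makes the
#'   two groups exchangeable.
#' @param seed Integer seed.
#' @param age_range Ages (years); defaults to 60-81, the recruitment range of
#'   dementia cohorts.
#' @param duration_s,fs Passed to [generate_recording()].
#' @param gain_jitter_sd SD of the lognormal per-subject gain jitter.
#' @param map Optional `function(recording, profile, label)` applied per
#'   subject as generated (memory-flat streaming, as in [generate_cohort()]).
#' @return List of `list(recording, profile, label)` with labels
#'   `"ADD"` / `"NADD"` (or the `map` results).
#' @export
generate_labeled_dataset <- function(n_add, n_nadd, separation = 1, seed = 1,
                                     age_range = c(60, 81), duration_s = 120,
                                     fs = 250, gain_jitter_sd = 0.1,
                                     map = NULL) {
  if (n_add < 1 || n_nadd < 1) stop("both class sizes must be >= 1", call. = FALSE)
  if (separation < 0) stop("`separation` must be >= 0", call. = FALSE)
  n <- n_add + n_nadd
  labels <- c(rep("ADD", n_add), rep("NADD", n_nadd))
  mult <- 1 + separation * (ADD_MULTIPLIERS - 1)
  meta <- with_seed(seed, function() {
    list(ages = stats::runif(n, age_range[1], age_range[2]),
         sexes = rep(c("male", "female"), length.out = n),
         jitter = matrix(exp(stats::rnorm(n * 8, 0, gain_jitter_sd)), nrow = n),
         seeds = sample.int(.Machine$integer.max, n))
  })
  lapply(seq_len(n), function(i) {
    gains <- HEALTHY_GAINS * meta$jitter[i, ]
    if (labels[i] == "ADD") gains <- gains * mult[names(HEALTHY_GAINS)]
    prof <- subject_profile(sprintf("sub%04d", i), age = meta$ages[i],
                            sex = meta$sexes[i],
                            group = if (labels[i] == "ADD") "ADD" else "healthy",
                            band_gains = gains)
    rec <- generate_recording(prof, duration_s, fs, seed = meta$seeds[i])
    if (is.null(map)) list(recording = rec, profile = prof, label = labels[i])
    else map(rec, prof, labels[i])
  })
}
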