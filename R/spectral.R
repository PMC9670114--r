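## Relative power spectra on the 0.25 Hz grid, eight-band aggregation, the
## age/sex-stratified normative database, and Z-score standardization.

#' Relative power spectrum of an epoched recording
#'
#' Per epoch and channel the squared-magnitude FFT is computed (Bartlett-style
#' averaging across epochs, rectangular window by default), accumulated onto
#' the half-open 0.25 Hz bins spanning `[1, 45)` Hz, and each channel row is
#' normalized by its total so that rows sum to one. A 4 s epoch makes the DFT
#' resolution exactly 0.25 Hz, the grid the 176-bin spectrum is defined on.
#'
#' @param ep An `epoched_eeg` with `epoch_length_s = 4`.
#' @param window `"rect"` (default) or `"hann"`.
#' @return A `relative_power`: list with `values` (19 x 176, rows sum to 1),
#'   `freqs` (bin lower edges), `channel_names`, `age`, `sex`.
#' @export
epoch_relative_power <- function(ep, window = c("rect", "hann")) {
  stopifnot(inherits(ep, "epoched_eeg"))
  window <- match.arg(window)
  len <- dim(ep$data)[3]
  df <- ep$fs / len
  if (abs(df - 0.25) > 1e-12) {
    stop("epoch length x sampling rate must give 0.25 Hz resolution ",
         "(4 s epochs); got ", signif(df, 4), " Hz", call. = FALSE)
  }
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(len) - 1) / len)
  } else rep(1, len)
  ## On the enforced 0.25 Hz grid each DFT frequency >= 1 Hz and < 45 Hz falls
  ## on a distinct bin lower edge, so accumulation is a one-to-one gather.
  freqs_fft <- (seq_len(len) - 1) * df
  sel <- which(freqs_fft >= 1 & freqs_fft < 45)
  lower <- bin_freqs()
  stopifnot(length(sel) == 176L)
  n_ep <- dim(ep$data)[1]
  acc <- matrix(0, nrow = 19L, ncol = 176L)
  for (i in seq_len(n_ep)) {
    seg <- ep$data[i, , , drop = TRUE] * rep(w, each = 19L)
    spec <- Mod(stats::mvfft(t(seg)))^2   # len x 19
    acc <- acc + t(spec[sel, , drop = FALSE])
  }
  tot <- rowSums(acc)
  if (any(tot <= 0)) stop("zero total power on at least one channel", call. = FALSE)
  values <- acc / tot
  dimnames(values) <- list(ep$channel_names, format(lower, nsmall = 2))
  age <- if (!is.null(ep$profile)) ep$profile$age else NA_real_
  sex <- if (!is.null(ep$profile)) ep$profile$sex else NA_character_
  structure(
    list(values = values, freqs = lower, channel_names = ep$channel_names,
         age = age, sex = sex),
    class = "relative_power"
  )
}

#' Aggregate a relative-power spectrum into the eight bands
#'
#' @param rp A `relative_power`.
#' @param scheme Band scheme data frame (default [band_scheme()]).
#' @return 19 x 8 matrix of band powers; rows still sum to 1.
#' @export
band_aggregate <- function(rp, scheme = band_scheme()) {
  stopifnot(inherits(rp, "relative_power"))
  idx <- findInterval(rp$freqs, c(scheme$lo, max(scheme$hi)))
  out <- t(apply(rp$values, 1L, function(row) {
    as.numeric(rowsum(row, idx, reorder = TRUE))
  }))
  colnames(out) <- scheme$band
  rownames(out) <- rp$channel_names
  out
}

#' Build an age/sex-stratified normative database
#'
#' Stratifies a healthy cohort's relative-power spectra by sex and age band
#' and stores the per-stratum mean and SD of every channel x bin cell
#' (optionally of log10 power). Strata with fewer than `min_n` subjects, or
#' with any zero-SD cell, are flagged unusable.
#'
#' @param cohort_rp List of `relative_power` objects carrying `age` and `sex`.
#' @param age_band_width Width of the age bands in years (default 5).
#' @param min_n Minimum subjects per usable stratum (default 20).
#' @param transform `"identity"` (default) or `"log10"`.
#' @param age_range Overall age span covered by the bands (default 4.5-81).
#' @return A `normative_db`: list of strata keyed `"<sex>_<lo>-<hi>"`, each
#'   with `mean`, `sd` (19 x 176), `n`, `usable`, plus `age_band_edges` and
#'   `transform`.
#' @export
build_normdb <- function(cohort_rp, age_band_width = 5, min_n = 20,
                         transform = c("identity", "log10"),
                         age_range = c(4.5, 81)) {
  transform <- match.arg(transform)
  stopifnot(length(cohort_rp) >= 1)
  edges <- seq(age_range[1], age_range[2] + age_band_width, by = age_band_width)
  tfun <- if (transform == "log10") function(x) log10(pmax(x, 1e-12)) else identity
  ages <- vapply(cohort_rp, function(r) r$age, numeric(1))
  sexes <- vapply(cohort_rp, function(r) r$sex, character(1))
  if (anyNA(ages) || anyNA(sexes)) {
    stop("every cohort member needs age and sex metadata", call. = FALSE)
  }
  band_idx <- findInterval(ages, edges, rightmost.closed = TRUE)
  strata <- list()
  for (sx in c("male", "female")) {
    for (b in sort(unique(band_idx[sexes == sx]))) {
      members <- which(sexes == sx & band_idx == b)
      arr <- vapply(cohort_rp[members], function(r) tfun(r$values),
                    matrix(0, 19L, 176L))
      mu <- apply(arr, c(1, 2), mean)
      sdv <- if (length(members) > 1) apply(arr, c(1, 2), stats::sd) else
        matrix(0, 19L, 176L)
      usable <- length(members) >= min_n && all(sdv > 0)
      if (!usable) {
        message("stratum ", sx, " ", edges[b], "-", edges[b + 1],
                " flagged unusable (n = ", length(members),
                if (any(sdv <= 0)) ", zero-SD cells present" else "", ")")
      }
      key <- sprintf("%s_%g-%g", sx, edges[b], edges[b + 1])
      strata[[key]] <- list(mean = mu, sd = sdv, n = length(members),
                            usable = usable, sex = sx,
                            age_lo = edges[b], age_hi = edges[b + 1])
    }
  }
  if (!any(vapply(strata, `[[`, logical(1), "usable"))) {
    stop("no usable stratum: every stratum is below min_n = ", min_n,
         " or degenerate", call. = FALSE)
  }
  structure(list(strata = strata, age_band_edges = edges, transform = transform),
            class = "normative_db")
}

find_stratum <- function(db, age, sex) {
  top <- max(db$age_band_edges)
  hit <- Filter(function(s) {
    s$sex == sex &&
      ((age >= s$age_lo && age < s$age_hi) || (age == s$age_hi && s$age_hi == top))
  }, db$strata)
  if (length(hit) == 0) {
    stop("no normative stratum for (", sex, ", age ", age, ")", call. = FALSE)
  }
  hit[[1]]
}

#' Standardize a spectrum against the normative database
#'
#' Returns cellwise Z-scores `(t(x) - mean) / sd` for the subject's
#' (sex, age band) stratum, where `t` is the database transform. This yields
#' 176 Z-score values at each of the 19 electrode locations.
#'
#' @param rp A `relative_power`.
#' @param db A `normative_db`.
#' @param age,sex Subject metadata; default taken from `rp`.
#' @return A `zscore_matrix`: list with `values` (19 x 176), `freqs`,
#'   `channel_names`, `age`, `sex`.
#' @export
zscore <- function(rp, db, age = rp$age, sex = rp$sex) {
  stopifnot(inherits(rp, "relative_power"), inherits(db, "normative_db"))
  st <- find_stratum(db, age, sex)
  if (!st$usable) {
    stop("stratum (", sex, ", ", st$age_lo, "-", st$age_hi,
         ") is flagged unusable (n = ", st$n, ")", call. = FALSE)
  }
  tfun <- if (db$transform == "log10") function(x) log10(pmax(x, 1e-12)) else identity
  z <- (tfun(rp$values) - st$mean) / st$sd
  if (!all(is.finite(z))) stop("non-finite Z-scores produced", call. = FALSE)
  structure(
    list(values = z, freqs = rp$freqs, channel_names = rp$channel_names,
         age = age, sex = sex),
    class = "zscore_matrix"
  )
}
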