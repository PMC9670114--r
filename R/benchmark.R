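## Reproducible end-to-end synthetic benchmark: normative cohort -> NormDB,
## labeled ADD/NADD recordings -> standardized feature images -> compact CNN
## -> held-out metrics, with optional band-level surrogate explanations of the
## test images. This is the pipeline the package's validation rests on.

new_image_dataset <- function(items, variant) {
  labels <- vapply(items, `[[`, character(1), "label")
  structure(list(items = items, variant = variant,
                 classes = c("ADD", "NADD")[c("ADD", "NADD") %in% labels]),
            class = "image_dataset")
}

#' Run the synthetic end-to-end classification benchmark
#'
#' Builds a normative database from `n_normative` synthetic healthy subjects
#' (ages 60-81, one age stratum per sex), generates `n_add + n_nadd` labeled
#' recordings, converts each to an age/sex-standardized feature image of the
#' chosen variant, trains a compact CNN on a stratified 9:1 split and
#' evaluates it on the held-out test images. All randomness derives from
#' `seed`.
#'
#' @param n_normative Normative cohort size (default 200).
#' @param n_add,n_nadd Labeled class sizes (default 100 each).
#' @param separation ADD spectral shift scale (default 1; 0 gives
#'   exchangeable groups, the no-leakage control).
#' @param seed Integer master seed.
#' @param variant Feature-image variant (default `"weightmap"`).
#' @param arch CNN architecture (default `"resnet_s"`).
#' @param test_frac Held-out fraction (default 0.1).
#' @param downsample Block-average factor for the CNN input rasters.
#' @param hyper Training hyperparameter overrides (see [train_cnn()]).
#' @param db Optional prebuilt `normative_db`; when supplied the cohort stage
#'   is skipped.
#' @param keep_test_images Keep the full-resolution test `feature_image`s
#'   (needed for explanation); default `TRUE`.
#' @return List with `db`, `model`, `metrics` (an `eval_metrics`), `split`,
#'   `test_images` (full-resolution, with labels), `variant`, and the
#'   per-stage seeds.
#' @export
run_synthetic_benchmark <- function(n_normative = 200, n_add = 100,
                                    n_nadd = 100, separation = 1, seed = 1,
                                    variant = "weightmap", arch = "resnet_s",
                                    test_frac = 0.1, downsample = 8L,
                                    hyper = list(), db = NULL,
                                    keep_test_images = TRUE) {
  seeds <- as.integer(seed) + 1:4
  if (is.null(db)) {
    ## stream: recording -> relative power, one subject in memory at a time
    rps <- generate_cohort(n_normative, age_range = c(60, 81), seed = seeds[1],
                           map = function(rec, prof) rp_from_recording(rec))
    db <- suppressMessages(
      build_normdb(rps, age_band_width = 21, min_n = 20,
                   age_range = c(60, 81)))
    rm(rps)
  }
  ## stream: recording -> feature image -> downsampled RGB raster
  mapped <- generate_labeled_dataset(
    n_add, n_nadd, separation = separation, seed = seeds[2],
    map = function(rec, prof, label) {
      img <- feature_image_from_recording(rec, db, variant = variant)
      list(item = list(x = downsample_rgb(render_rgb(img), downsample),
                       label = label, subject_id = prof$subject_id),
           image = if (keep_test_images) img else NULL)
    })
  items <- lapply(mapped, `[[`, "item")
  imgs <- lapply(mapped, `[[`, "image")
  rm(mapped)
  ds <- new_image_dataset(items, variant)
  split <- stratified_split(ds, test_frac = test_frac, seed = seeds[3])
  test_ids <- vapply(split$test$items, `[[`, character(1), "subject_id")
  all_ids <- vapply(items, `[[`, character(1), "subject_id")
  test_images <- if (keep_test_images) {
    lapply(match(test_ids, all_ids), function(i)
      list(image = imgs[[i]], label = items[[i]]$label))
  } else NULL
  rm(imgs)
  ## benchmark-sized training defaults: the synthetic separation is learned
  ## within ~10 epochs by a narrow network, so the benchmark trains a width-6
  ## model for up to 15 epochs (both overridable through `hyper`)
  hyper <- utils::modifyList(list(width = 6L, epochs = 15L), hyper)
  model <- train_cnn(split$train, arch = arch, hyper = hyper, seed = seeds[4])
  metrics <- evaluate(model, split$test)
  list(db = db, model = model, metrics = metrics, split = split,
       test_images = test_images, variant = variant, downsample = downsample,
       seeds = seeds)
}

#' Explain benchmark test images and tally their leading bands
#'
#' Runs the band-aligned surrogate explainer over the benchmark's held-out
#' feature images (explaining each image's true class) and reports, per
#' image, the top-ranked band.
#'
#' @param bench Output of [run_synthetic_benchmark()] (with test images kept).
#' @param n_samples,K,seed Passed to [lime_explain()].
#' @param rows_per_block Segment block height (default: quarter image).
#' @return List with `explanations`, `seg`, `top_bands` (character vector,
#'   one per test image) and the `criteria_summary`.
#' @export
explain_benchmark <- function(bench, n_samples = 150L, K = 6L, seed = 1,
                              rows_per_block = NULL) {
  stopifnot(!is.null(bench$test_images))
  pf <- cnn_predict_fn(bench$model, bench$downsample)
  seg <- segment_feature_image(bench$test_images[[1]]$image, rows_per_block)
  expls <- lapply(seq_along(bench$test_images), function(i) {
    ti <- bench$test_images[[i]]
    lime_explain(pf, ti$image, seg, n_samples = n_samples, K = K,
                 explained_class = ti$label, seed = seed + i)
  })
  list(explanations = expls, seg = seg,
       top_bands = vapply(expls, top_band, character(1), seg = seg),
       summary = summarize_criteria(expls, seg))
}
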