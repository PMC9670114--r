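## Planted linear predictor: probability of ADD rises with the visible color
## content (darkness relative to the white background) of one chosen segment,
## so switching the segment on increases the ADD probability.
planted_predict_fn <- function(seg, target_id, gain = 12) {
  idx <- which(seg$labels == target_id)
  npix <- prod(dim(seg$labels))
  function(images) {
    p <- vapply(images, function(x) {
      dark <- mean(1 - x[c(idx, idx + npix, idx + 2 * npix)])
      1 / (1 + exp(-gain * (dark - 0.1)))
    }, numeric(1))
    cbind(ADD = p, NADD = 1 - p)
  }
}

test_that("segmentation census: 8 bands x 2 sides x 4 row blocks = 64 segments", {
  img <- demo_image()
  seg <- segment_feature_image(img, rows_per_block = 88)
  expect_identical(seg$n_segments, 64L)
  expect_identical(sort(unique(as.integer(seg$labels))), 1:64)
  expect_true(all(seg$labels >= 1))   # no masked pixels on the plain variant
  expect_identical(length(unique(as.integer(seg$labels))), 64L)
  ## every segment is a contiguous rectangle
  for (id in c(1, 30, 64)) {
    hit <- which(seg$labels == id, arr.ind = TRUE)
    expect_identical(nrow(hit),
                     length(unique(hit[, 1])) * length(unique(hit[, 2])))
    expect_true(all(diff(sort(unique(hit[, 1]))) == 1))
    expect_true(all(diff(sort(unique(hit[, 2]))) == 1))
  }
})

test_that("segmentation collapses to one block per band-side column", {
  img <- demo_image()
  seg <- segment_feature_image(img, rows_per_block = nrow(img$values))
  expect_identical(seg$n_segments, 16L)
  expect_identical(as.integer(table(seg$segment_meta$band)), rep(2L, 8))
})

test_that("weight-map images exclude masked beta3/gamma pixels from segments", {
  img <- demo_image(weightmap = TRUE)
  seg <- segment_feature_image(img, rows_per_block = 88)
  expect_identical(seg$n_segments, 48L)   # 6 bands x 2 sides x 4 blocks
  expect_false(any(c("beta3", "gamma") %in% seg$segment_meta$band))
  expect_true(all(seg$labels[img$mask] == 0L))
})

test_that("the surrogate recovers a planted linear predictor's segment", {
  img <- demo_image()
  seg <- segment_feature_image(img, rows_per_block = 88)
  pf <- planted_predict_fn(seg, target_id = 17L)
  expl <- lime_explain(pf, img, seg, n_samples = 150, K = 5, seed = 71)
  expect_identical(which.max(expl$segment_weights), 17L)
  expect_lte(sum(expl$segment_weights != 0), 5L)
  expect_gte(expl$fidelity_loss, 0)
  ## determinism and cross-seed stability of the top segment
  expl_b <- lime_explain(pf, img, seg, n_samples = 150, K = 5, seed = 71)
  expect_identical(expl$segment_weights, expl_b$segment_weights)
  expl_c <- lime_explain(pf, img, seg, n_samples = 150, K = 5, seed = 72)
  expect_identical(which.max(expl_c$segment_weights), 17L)
})

test_that("a constant predictor yields near-zero weights and fidelity loss", {
  img <- demo_image()
  seg <- segment_feature_image(img, rows_per_block = 88)
  const_fn <- function(images) {
    cbind(ADD = rep(0.6, length(images)), NADD = rep(0.4, length(images)))
  }
  expl <- lime_explain(const_fn, img, seg, n_samples = 100, K = 4, seed = 73)
  expect_lt(max(abs(expl$segment_weights)), 1e-9)
  expect_lt(expl$fidelity_loss, 1e-12)
})

test_that("malformed prediction functions are rejected", {
  img <- demo_image()
  seg <- segment_feature_image(img, rows_per_block = 176)
  bad_fn <- function(images) {
    cbind(ADD = rep(2, length(images)), NADD = rep(-1, length(images)))
  }
  expect_error(lime_explain(bad_fn, img, seg, n_samples = 60, seed = 74),
               "probabilities")
})

test_that("top-N masks are nested, cover the planted rectangle, and background-free", {
  img <- demo_image()
  seg <- segment_feature_image(img, rows_per_block = 88)
  pf <- planted_predict_fn(seg, target_id = 9L)
  expl <- lime_explain(pf, img, seg, n_samples = 150, K = 5, seed = 75)
  m1 <- top_n_mask(expl, seg, 1)
  m3 <- top_n_mask(expl, seg, 3)
  mall <- top_n_mask(expl, seg, seg$n_segments)
  expect_true(all(m1[seg$labels == 9L]))
  expect_identical(sum(m1), sum(seg$labels == 9L))   # exactly that rectangle
  expect_true(all(m3[m1]))                           # mask(1) inside mask(3)
  expect_true(all(mall[seg$labels > 0L]))            # full cover of active pixels
  expect_false(any(mall[seg$labels == 0L]))
})

test_that("weight ranking recovers a multi-segment linear model (Spearman)", {
  img <- demo_image()
  seg <- segment_feature_image(img, rows_per_block = 88)
  true_ids <- c(5L, 21L, 40L, 55L)
  true_coef <- c(8, 6, 4, 2)
  npix <- prod(dim(seg$labels))
  ## normalize each segment's darkness by its unperturbed value so the
  ## planted on/off coefficients are exactly true_coef
  seg_dark <- function(x, id) {
    idx <- which(seg$labels == id)
    mean(1 - x[c(idx, idx + npix, idx + 2 * npix)])
  }
  d0 <- vapply(true_ids, function(id) seg_dark(render_rgb(img), id), numeric(1))
  pfn <- function(images) {
    p <- vapply(images, function(x) {
      on <- vapply(seq_along(true_ids), function(j)
        seg_dark(x, true_ids[j]) / d0[j], numeric(1))
      1 / (1 + exp(-(sum(true_coef * on) - 10)))
    }, numeric(1))
    cbind(ADD = p, NADD = 1 - p)
  }
  expl <- lime_explain(pfn, img, seg, n_samples = 1000, K = 4, seed = 76)
  got <- expl$segment_weights[true_ids]
  expect_true(all(got > 0))
  expect_gte(cor(rank(got), rank(true_coef), method = "spearman"), 0.9)
  expect_setequal(which(expl$segment_weights != 0), as.integer(true_ids))
})

test_that("criteria summary aggregates and ranks bands per class", {
  img <- demo_image()
  seg <- segment_feature_image(img, rows_per_block = 88)
  ## plant the predictor on a delta-band segment for the ADD class
  delta_id <- seg$segment_meta$id[seg$segment_meta$band == "delta"][1]
  pf <- planted_predict_fn(seg, delta_id)
  e1 <- lime_explain(pf, img, seg, n_samples = 150, K = 3, seed = 77)
  summ <- summarize_criteria(list(e1), seg)
  expect_identical(summ$ADD$table$band[1], "delta")
  expect_match(summ$ADD$criterion, "delta")
  expect_identical(top_band(e1, seg), "delta")
  ## single explanation: summary importance equals its own band aggregation
  expect_equal(summ$ADD$table$importance[1],
               mean(abs(e1$segment_weights[
                 seg$segment_meta$id[seg$segment_meta$band == "delta"]])))
})
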