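test_that("feature matrix assembly places channels and bins correctly", {
  z <- z_from_matrix(matrix(0, 19, 176))
  fm0 <- assemble_feature_matrix(z)
  expect_identical(dim(fm0$values), c(11L, 352L))
  expect_true(all(fm0$values == 0))
  ## single nonzero cell: O1 at the 10.0 Hz bin -> exactly one nonzero entry
  vals <- matrix(0, 19, 176)
  vals[18, which(bin_freqs() == 10)] <- 5   # channel O1, bin [10, 10.25)
  fm <- assemble_feature_matrix(z_from_matrix(vals))
  nz <- which(fm$values != 0, arr.ind = TRUE)
  expect_identical(nrow(nz), 1L)
  expect_identical(unname(nz[1, "row"]),
                   match("O1", channel_layout()$left_rows))
  expect_identical(unname(nz[1, "col"]), which(bin_freqs() == 10))
  expect_identical(fm$values[nz], 5)
})

test_that("midline channels are duplicated across sides", {
  set.seed(31)
  z <- z_from_matrix(matrix(rnorm(19 * 176), 19))
  fm <- assemble_feature_matrix(z)
  lay <- channel_layout()
  for (m in c("Fz", "Cz", "Pz")) {
    lrow <- match(m, lay$left_rows)
    rrow <- match(m, lay$right_rows)
    expect_identical(fm$values[lrow, 1:176], fm$values[rrow, 177:352])
  }
  expect_identical(fm$column_side, rep(c("left", "right"), each = 176L))
  expect_equal(fm$column_freqs[1:176], bin_freqs())
  expect_equal(fm$column_freqs[177:352], bin_freqs())
})

test_that("mirrored right half reverses the right block's frequency axis", {
  set.seed(32)
  z <- z_from_matrix(matrix(rnorm(19 * 176), 19))
  fm <- assemble_feature_matrix(z, mirror_right = TRUE)
  plain <- assemble_feature_matrix(z)
  expect_identical(fm$values[, 177:352], plain$values[, 352:177])
})

test_that("nearest upscaling is exact 32x row replication with no new values", {
  set.seed(33)
  z <- z_from_matrix(matrix(rnorm(19 * 176), 19))
  fm <- assemble_feature_matrix(z)
  img <- nearest_upscale(fm)
  expect_identical(dim(img$values), c(352L, 352L))
  for (i in c(1, 100, 352)) {
    expect_identical(img$values[i, ], fm$values[floor((i - 1) * 11 / 352) + 1, ])
  }
  expect_setequal(unique(as.numeric(img$values)), unique(as.numeric(fm$values)))
  const <- fm; const$values[] <- 2.5
  expect_true(all(nearest_upscale(const)$values == 2.5))
})

test_that("bicubic coefficients: constant and bilinear fields are exact", {
  bp <- bicubic_coefficients(matrix(7, 4, 4))
  expect_equal(bp$coefficients[1, 1], 7, tolerance = 1e-12)
  expect_equal(sum(abs(bp$coefficients[-1])), 0, tolerance = 1e-12)
  ## f(x, y) = x + y sampled on the integer grid
  patch <- outer(-1:2, -1:2, `+`)
  bp2 <- bicubic_coefficients(patch)
  for (pt in list(c(0.3, 0.8), c(0.5, 0.5), c(0.99, 0.01))) {
    expect_equal(bicubic_eval(bp2, pt[1], pt[2]), sum(pt), tolerance = 1e-12)
  }
})

test_that("bicubic surface reproduces corner values exactly on random patches", {
  set.seed(34)
  for (r in 1:20) {
    patch <- matrix(rnorm(16), 4)
    bp <- bicubic_coefficients(patch)
    expect_equal(bicubic_eval(bp, 0, 0), patch[2, 2], tolerance = 1e-10)
    expect_equal(bicubic_eval(bp, 1, 0), patch[3, 2], tolerance = 1e-10)
    expect_equal(bicubic_eval(bp, 0, 1), patch[2, 3], tolerance = 1e-10)
    expect_equal(bicubic_eval(bp, 1, 1), patch[3, 3], tolerance = 1e-10)
  }
  expect_error(bicubic_coefficients(matrix(c(NA, rnorm(15)), 4)), "finite")
})

test_that("bicubic matches the separable cubic-convolution oracle", {
  set.seed(35)
  for (r in 1:100) {
    patch <- matrix(rnorm(16), 4)
    bp <- bicubic_coefficients(patch)
    x <- runif(1); y <- runif(1)
    expect_equal(bicubic_eval(bp, x, y), keys_interp_patch(patch, x, y),
                 tolerance = 1e-9)
    expect_equal(bicubic_eval(bp, 0.5, 0.5),
                 keys_interp_patch(patch, 0.5, 0.5), tolerance = 1e-9)
  }
})

test_that("bicubic upscaling: size, constancy, node recovery, overshoot bound", {
  set.seed(36)
  z <- z_from_matrix(matrix(rnorm(19 * 176), 19))
  fm <- assemble_feature_matrix(z)
  img <- bicubic_upscale(fm)
  expect_identical(dim(img$values), c(352L, 352L))
  ## x-axis is identity: first and last rows coincide with source rows
  expect_equal(img$values[1, ], fm$values[1, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(img$values[352, ], fm$values[11, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  const <- fm; const$values[] <- -1.5
  expect_equal(max(abs(bicubic_upscale(const)$values + 1.5)), 0,
               tolerance = 1e-9)
  ## monotone column gradient: overshoot bounded by 12.5% of the local step
  mono <- fm
  mono$values <- matrix(rep(c(0, 1, 3, 6, 10, 15, 21, 28, 36, 45, 55), 352), 11)
  out <- bicubic_upscale(mono)$values
  step <- max(diff(c(0, 1, 3, 6, 10, 15, 21, 28, 36, 45, 55)))
  expect_gt(min(out), 0 - 0.125 * step)
  expect_lt(max(out), 55 + 0.125 * step)
})

test_that("interpolant values at source nodes are recoverable from the images", {
  set.seed(37)
  z <- z_from_matrix(matrix(rnorm(19 * 176), 19))
  fm <- assemble_feature_matrix(z)
  near <- nearest_upscale(fm)
  for (r in c(1, 6, 11)) {
    expect_identical(near$values[(r - 1) * 32 + 1, ], fm$values[r, ])
  }
  ## bicubic: evaluate the patch interpolant at interior node coordinates
  pad <- fm$values[c(1, 1:11, 11), c(1, 1:352, 352)]
  for (node in list(c(5, 40), c(2, 351), c(10, 2))) {
    r <- node[1]; cl <- node[2]
    bp <- bicubic_coefficients(pad[r:(r + 3), cl:(cl + 3)])
    expect_equal(bicubic_eval(bp, 0, 0), unname(fm$values[r, cl]), tolerance = 1e-10)
  }
  ## and from a rendered image whose rows land exactly on source nodes
  img351 <- bicubic_upscale(fm, out_h = 351, out_w = 352)
  for (r in c(2, 5, 9)) {
    expect_equal(img351$values[35 * (r - 1) + 1, ], fm$values[r, ],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("weight map masks exactly the beta3/gamma columns at 20 Hz", {
  set.seed(38)
  z <- z_from_matrix(matrix(rnorm(19 * 176), 19))
  fm <- assemble_feature_matrix(z)
  img <- bicubic_upscale(fm)
  wm <- apply_weight_map(img, cutoff_hz = 20)
  masked_cols <- which(apply(wm$mask, 2, all))
  ## oracle: enumerate bin edges >= 20 Hz: 100 bins per side
  expect_identical(length(masked_cols), 200L)
  expect_setequal(unique(wm$region_map$col_band[masked_cols]),
                  c("beta3", "gamma"))
  expect_setequal(setdiff(unique(wm$region_map$col_band), c("beta3", "gamma")),
                  unique(wm$region_map$col_band[-masked_cols]))
  ## unmasked values bitwise unchanged; variant updated
  expect_identical(wm$values, img$values)
  expect_identical(wm$variant, "weightmap")
  ## cutoff at 45 masks nothing
  expect_false(any(apply_weight_map(img, cutoff_hz = 45)$mask))
  expect_error(apply_weight_map(img, cutoff_hz = 0.5), "cutoff")
})

test_that("band rescaling hits the published geometry", {
  set.seed(39)
  z <- z_from_matrix(matrix(rnorm(19 * 176), 19))
  fm <- assemble_feature_matrix(z)
  img <- rescale_bands(fm)
  expect_identical(dim(img$values), c(240L, 240L))
  expect_identical(attr(img, "intermediate_dim"), c(152L, 152L))
  ## 12 regions of 20 columns each, bands ordered delta..beta2, left then right
  expect_identical(img$region_map$col_band,
                   rep(rep(c("delta", "theta", "alpha1", "alpha2", "beta1",
                             "beta2"), each = 20), 2))
  expect_identical(img$region_map$col_side, rep(c("left", "right"), each = 120))
  const <- fm; const$values[] <- 0.7
  expect_equal(max(abs(rescale_bands(const)$values - 0.7)), 0, tolerance = 1e-9)
})

test_that("RGB rendering: midpoint white, saturation, masked black", {
  img <- structure(
    list(values = matrix(c(0, 10, -10, 1.96, -1.96, 3), 1),
         mask = matrix(c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE), 1),
         variant = "bicubic",
         region_map = list(col_freq = rep(2, 6), col_side = rep("left", 6),
                           col_band = rep("delta", 6))),
    class = "feature_image")
  rgb <- render_rgb(img, clip = 1.96)
  expect_equal(rgb[1, 1, ], c(1, 1, 1))            # z = 0 -> white midpoint
  expect_equal(rgb[1, 2, ], rgb[1, 4, ])           # z = 10 saturates at 1.96
  expect_equal(rgb[1, 3, ], rgb[1, 5, ])           # z = -10 saturates at -1.96
  expect_equal(rgb[1, 2, ], c(1, 0, 0))            # hot end is red
  expect_equal(rgb[1, 3, ], c(0, 0, 1))            # cold end is blue
  expect_equal(rgb[1, 6, ], c(0, 0, 0))            # masked -> black despite z = 3
})

test_that("midline rows carry identical values on left and right halves", {
  set.seed(40)
  z <- z_from_matrix(matrix(rnorm(19 * 176), 19))
  fm <- assemble_feature_matrix(z)
  lay <- channel_layout()
  near <- nearest_upscale(fm)
  bic <- bicubic_upscale(fm, out_h = 351, out_w = 352)  # rows hit source nodes
  for (m in c("Fz", "Cz", "Pz")) {
    lrow <- match(m, lay$left_rows); rrow <- match(m, lay$right_rows)
    expect_identical(fm$values[lrow, 1:176], fm$values[rrow, 177:352])
    ## nearest: every replicated row of the block
    rows <- (lrow - 1) * 32 + 1:32
    expect_identical(near$values[rows, 1:176], near$values[rows, 177:352])
    ## bicubic: at the source-node row
    ni <- 35 * (lrow - 1) + 1
    expect_equal(bic$values[ni, 1:176], bic$values[ni, 177:352],
                 tolerance = 1e-9)
  }
})
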