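## The rectangular QEEG feature matrix and its image renderings.
##
## The 19-channel Z-score spectrum is split into left and right hemispheric
## strips (midline channels in both), stacked anterior-to-posterior, and laid
## out as an 11 x 352 matrix: columns 1-176 are the left side, 177-352 the
## right side, each ascending 1.00 -> 44.75 Hz in 0.25 Hz bins. The matrix is
## rendered as four image variants: nearest (exact 32x row replication),
## bicubic (third-degree polynomial surface per cell), weight map (beta3 and
## gamma regions masked out) and rescaled (bands 1-20 Hz resized to equal
## widths).

#' Assemble the 11 x 352 feature matrix from a Z-score matrix
#'
#' @param z A `zscore_matrix` (19 x 176).
#' @param layout Channel layout from [channel_layout()].
#' @param mirror_right If `TRUE`, the right-side block runs with descending
#'   frequency (mirrored about the matrix midline) instead of ascending.
#' @return A `feature_matrix`: list with `values` (11 x 352), `column_freqs`,
#'   `column_side`, `layout`, `mirror_right`, and subject metadata.
#' @export
assemble_feature_matrix <- function(z, layout = channel_layout(),
                                    mirror_right = FALSE) {
  stopifnot(inherits(z, "zscore_matrix"))
  if (!all(dim(z$values) == c(19L, 176L))) {
    stop("Z-score matrix must be 19 x 176", call. = FALSE)
  }
  miss <- setdiff(c(layout$left_rows, layout$right_rows), z$channel_names)
  if (length(miss)) {
    stop("unknown channel name(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  rows <- function(chs) z$values[match(chs, z$channel_names), , drop = FALSE]
  left <- rows(layout$left_rows)
  right <- rows(layout$right_rows)
  rfreqs <- z$freqs
  if (mirror_right) {
    right <- right[, rev(seq_len(ncol(right))), drop = FALSE]
    rfreqs <- rev(rfreqs)
  }
  structure(
    list(values = cbind(left, right),
         column_freqs = c(z$freqs, rfreqs),
         column_side = rep(c("left", "right"), each = 176L),
         layout = layout, mirror_right = mirror_right,
         age = z$age, sex = z$sex),
    class = "feature_matrix"
  )
}

new_feature_image <- function(values, variant, region_map, mask = NULL) {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  structure(
    list(values = values, mask = mask, variant = variant, region_map = region_map),
    class = "feature_image"
  )
}

region_map_from_fm <- function(fm, out_w) {
  ## nearest source column for every output column (x is identity when
  ## out_w == ncol, the default for the 352- and 152-wide images)
  src <- pmin(pmax(round((seq_len(out_w) - 1) * (ncol(fm$values) - 1) /
                           max(out_w - 1, 1)) + 1, 1), ncol(fm$values))
  list(col_freq = fm$column_freqs[src],
       col_side = fm$column_side[src],
       col_band = band_of(fm$column_freqs[src]))
}

#' Nearest-interpolation feature image
#'
#' Stretches the feature matrix in the y-direction by exact integer row
#' replication (352 / 11 = 32) to a square 352 x 352 image with hard edges
#' between consecutive rows.
#'
#' @param fm A `feature_matrix`.
#' @return A `feature_image` with `variant = "nearest"`.
#' @export
nearest_upscale <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"),
            all(dim(fm$values) == c(11L, 352L)))
  values <- fm$values[rep(seq_len(11L), each = 32L), , drop = FALSE]
  new_feature_image(values, "nearest", region_map_from_fm(fm, 352L))
}

## --- bicubic interpolation ---------------------------------------------------
##
## p(x, y) = sum_{i=0}^{3} sum_{j=0}^{3} a_ij x^i y^j on the unit cell, the 16
## coefficients solved from the cell's corner values and corner derivative
## estimates (central finite differences over the 4 x 4 neighborhood).

## 16 x 16 system: row blocks are p, p_x, p_y, p_xy at the four corners;
## unknown vector is a_ij with k = i + 1 + 4 j (column-major 4 x 4).
bicubic_system <- function() {
  corners <- cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  C <- matrix(0, 16L, 16L)
  row <- 0L
  for (deriv in c("p", "px", "py", "pxy")) {
    for (cn in seq_len(4L)) {
      row <- row + 1L
      x <- corners[cn, 1]; y <- corners[cn, 2]
      for (i in 0:3) for (j in 0:3) {
        k <- i + 1L + 4L * j
        C[row, k] <- switch(deriv,
          p   = x^i * y^j,
          px  = if (i > 0) i * x^(i - 1) * y^j else 0,
          py  = if (j > 0) j * x^i * y^(j - 1) else 0,
          pxy = if (i > 0 && j > 0) i * j * x^(i - 1) * y^(j - 1) else 0)
      }
    }
  }
  ## B maps vec(patch) (4 x 4, column-major, patch[m, n] = f(m - 2, n - 2))
  ## to the 16 constraint values via the finite-difference stencils.
  B <- matrix(0, 16L, 16L)
  pidx <- function(m, n) m + 4L * (n - 1L)
  row <- 0L
  for (deriv in c("p", "px", "py", "pxy")) {
    for (cn in seq_len(4L)) {
      row <- row + 1L
      m <- corners[cn, 1] + 2L; n <- corners[cn, 2] + 2L
      switch(deriv,
        p   = { B[row, pidx(m, n)] <- 1 },
        px  = { B[row, pidx(m + 1L, n)] <- 0.5; B[row, pidx(m - 1L, n)] <- -0.5 },
        py  = { B[row, pidx(m, n + 1L)] <- 0.5; B[row, pidx(m, n - 1L)] <- -0.5 },
        pxy = {
          B[row, pidx(m + 1L, n + 1L)] <- 0.25
          B[row, pidx(m - 1L, n + 1L)] <- -0.25
          B[row, pidx(m + 1L, n - 1L)] <- -0.25
          B[row, pidx(m - 1L, n - 1L)] <- 0.25
        })
    }
  }
  list(patch_to_coef = solve(C) %*% B)
}

.bicubic_cache <- new.env(parent = emptyenv())

patch_to_coef_matrix <- function() {
  if (is.null(.bicubic_cache$W)) .bicubic_cache$W <- bicubic_system()$patch_to_coef
  .bicubic_cache$W
}

#' Bicubic coefficients of one interpolation cell
#'
#' Solves the 16 coefficients `a_00`-`a_33` of the third-degree surface
#' `p(x, y) = sum a_ij x^i y^j` over the unit cell between the central four
#' points of a 4 x 4 neighborhood. Corner derivatives are estimated by central
#' finite differences; the surface reproduces the four corner values exactly.
#'
#' @param patch 4 x 4 numeric matrix; `patch[m, n] = f(m - 2, n - 2)` with the
#'   unit cell spanned by `patch[2:3, 2:3]`.
#' @return A `bicubic_patch`: list with `coefficients` (4 x 4, `[i+1, j+1]`
#'   holding `a_ij`) and the corner values.
#' @export
bicubic_coefficients <- function(patch) {
  patch <- as.matrix(patch)
  if (!all(dim(patch) == c(4L, 4L)) || !all(is.finite(patch))) {
    stop("`patch` must be a finite 4 x 4 matrix", call. = FALSE)
  }
  a <- matrix(patch_to_coef_matrix() %*% as.numeric(patch), 4L, 4L)
  structure(list(coefficients = a, corners = patch[2:3, 2:3]),
            class = "bicubic_patch")
}

#' Evaluate a bicubic patch
#'
#' @param bp A `bicubic_patch`.
#' @param x,y Coordinates in the unit cell (vectors recycled together).
#' @return `p(x, y)`.
#' @export
bicubic_eval <- function(bp, x, y) {
  stopifnot(inherits(bp, "bicubic_patch"))
  out <- 0
  for (i in 0:3) for (j in 0:3) {
    out <- out + bp$coefficients[i + 1L, j + 1L] * x^i * y^j
  }
  out
}

## Bicubic resize of a plain matrix with align-corners sampling: output pixel
## (i, j) is evaluated at source coordinates ((i-1)(h-1)/(H-1), (j-1)(w-1)/(W-1)),
## so source nodes are reproduced exactly wherever an output pixel lands on
## them. Border cells use edge replication for missing neighbors.
resize_bicubic <- function(mat, out_h, out_w) {
  h <- nrow(mat); w <- ncol(mat)
  if (h == 1L) mat <- rbind(mat, mat)
  if (w == 1L) mat <- cbind(mat, mat)
  h <- nrow(mat); w <- ncol(mat)
  P <- mat[c(1L, seq_len(h), h), c(1L, seq_len(w), w), drop = FALSE]  # edge pad
  W16 <- patch_to_coef_matrix()
  ## per-cell coefficient planes: A[[k]] is (h-1) x (w-1)
  A <- vector("list", 16L)
  for (k in seq_len(16L)) A[[k]] <- matrix(0, h - 1L, w - 1L)
  for (m in 1:4) for (n in 1:4) {
    Gp <- P[(seq_len(h - 1L)) + m - 1L, (seq_len(w - 1L)) + n - 1L, drop = FALSE]
    p <- m + 4L * (n - 1L)
    for (k in seq_len(16L)) {
      wk <- W16[k, p]
      if (wk != 0) A[[k]] <- A[[k]] + wk * Gp
    }
  }
  xs <- if (out_h == 1L) 0 else (seq_len(out_h) - 1) * (h - 1) / (out_h - 1)
  ys <- if (out_w == 1L) 0 else (seq_len(out_w) - 1) * (w - 1) / (out_w - 1)
  rcell <- pmin(pmax(floor(xs) + 1L, 1L), h - 1L)
  ccell <- pmin(pmax(floor(ys) + 1L, 1L), w - 1L)
  xf <- xs - (rcell - 1L)
  yf <- ys - (ccell - 1L)
  L <- outer(rcell, (ccell - 1L) * (h - 1L), "+")  # linear cell index
  out <- matrix(0, out_h, out_w)
  for (i in 0:3) for (j in 0:3) {
    k <- i + 1L + 4L * j
    out <- out + matrix(A[[k]][L], out_h, out_w) * outer(xf^i, yf^j)
  }
  out
}

#' Bicubic-interpolated feature image
#'
#' Upscales the feature matrix to `out_h` x `out_w` (default 352 x 352) by
#' evaluating the per-cell third-degree surface of [bicubic_coefficients()]
#' at every output pixel, giving smooth transitions between rows.
#'
#' @param fm A `feature_matrix`.
#' @param out_h,out_w Output size in pixels (each at least the input size).
#' @return A `feature_image` with `variant = "bicubic"`.
#' @export
bicubic_upscale <- function(fm, out_h = 352L, out_w = 352L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (out_h < nrow(fm$values) || out_w < ncol(fm$values)) {
    stop("output size must not shrink the feature matrix", call. = FALSE)
  }
  values <- resize_bicubic(fm$values, out_h, out_w)
  new_feature_image(values, "bicubic", region_map_from_fm(fm, out_w))
}

#' Mask high-frequency image regions (weight map)
#'
#' Marks every pixel whose represented frequency is at or above `cutoff_hz`
#' as inactive. Masked pixels render black and carry no Z information for the
#' classifier; the default 20 Hz cutoff masks exactly the beta3 and gamma
#' band regions. Unmasked values are untouched.
#'
#' @param img A `feature_image` whose `region_map` carries frequency labels.
#' @param cutoff_hz Cutoff frequency in Hz, within (1, 45].
#' @return The masked `feature_image`, `variant = "weightmap"`.
#' @export
apply_weight_map <- function(img, cutoff_hz = 20) {
  stopifnot(inherits(img, "feature_image"))
  if (cutoff_hz <= 1 || cutoff_hz > 45) {
    stop("`cutoff_hz` must lie in (1, 45]", call. = FALSE)
  }
  freq <- img$region_map$col_freq
  if (is.null(freq) || anyNA(freq)) {
    stop("image carries no per-column frequency labels", call. = FALSE)
  }
  cols <- which(freq >= cutoff_hz)
  img$mask[, cols] <- TRUE
  img$variant <- "weightmap"
  img
}

#' Band-rescaled feature image
#'
#' Drops the beta3/gamma columns (frequency >= 20 Hz), bicubic-upscales the
#' remaining 11 x 152 matrix to a 152 x 152 image, then resizes each of the
#' 12 band regions (six bands x two sides, pre-rescale widths 12, 16, 8, 8,
#' 12, 20 pixels per side) to a uniform 20 x 240 and concatenates them into a
#' 240 x 240 image, so every band occupies equal image area.
#'
#' @param fm A `feature_matrix`.
#' @return A `feature_image` with `variant = "rescaled"` (240 x 240);
#'   `attr(, "intermediate_dim")` records the 152 x 152 intermediate.
#' @export
rescale_bands <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"), all(dim(fm$values) == c(11L, 352L)))
  keep <- fm$column_freqs < 20
  sub <- fm$values[, keep, drop = FALSE]              # 11 x 152
  side <- fm$column_side[keep]
  band <- band_of(fm$column_freqs[keep])
  mid <- resize_bicubic(sub, 152L, 152L)              # x is identity: col k = bin k
  scheme <- band_scheme()[band_scheme()$lo < 20, ]
  out_cols <- vector("list", 12L)
  col_band <- character(0); col_side <- character(0)
  i <- 0L
  for (sd in c("left", "right")) {
    for (b in scheme$band) {
      i <- i + 1L
      cols <- which(side == sd & band == b)
      region <- mid[, cols, drop = FALSE]
      out_cols[[i]] <- resize_bicubic(region, 240L, 20L)
      col_band <- c(col_band, rep(b, 20L))
      col_side <- c(col_side, rep(sd, 20L))
    }
  }
  values <- do.call(cbind, out_cols)
  img <- new_feature_image(values, "rescaled",
                           list(col_freq = rep(NA_real_, 240L),
                                col_side = col_side, col_band = col_band))
  attr(img, "intermediate_dim") <- dim(mid)
  img
}

#' Render a feature image to RGB
#'
#' Symmetric diverging blue-white-red colormap over `[-clip, clip]` Z-scores,
#' saturating at the ends; masked pixels are rendered pure black regardless
#' of their Z value.
#'
#' @param img A `feature_image`.
#' @param clip Positive saturation Z-score (default 1.96).
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
render_rgb <- function(img, clip = 1.96) {
  stopifnot(inherits(img, "feature_image"), clip > 0)
  z <- pmin(pmax(img$values, -clip), clip)
  t <- (z + clip) / (2 * clip)
  r <- pmin(2 * t, 1)
  g <- 1 - abs(2 * t - 1)
  b <- pmin(2 * (1 - t), 1)
  r[img$mask] <- 0; g[img$mask] <- 0; b[img$mask] <- 0
  array(c(r, g, b), dim = c(nrow(z), ncol(z), 3L))
}
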