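## Band-aligned local surrogate explanations.
##
## The explainer perturbs a feature image by switching rectangular segments
## (band x side x row-block) off to a background value, weights perturbed
## samples by proximity to the original image, and fits a sparse weighted
## linear surrogate to the classifier's probabilities. Because segments are
## aligned to the band regions of the image, surrogate weights aggregate
## directly into band-level classification criteria.

#' Segment a feature image into band-aligned rectangles
#'
#' Columns are grouped by their (band, side) region; rows are cut into equal
#' blocks of `rows_per_block` pixels. Masked (weight-map) pixels fall into an
#' inert background segment with id 0.
#'
#' @param img A `feature_image` with a region map.
#' @param rows_per_block Block height in pixels; default one quarter of the
#'   image height (four row blocks).
#' @return A `segment_map`: list with `labels` (H x W integer, 0 =
#'   background), `segment_meta` (data frame id/band/side/block) and
#'   `n_segments`.
#' @export
segment_feature_image <- function(img, rows_per_block = NULL) {
  stopifnot(inherits(img, "feature_image"))
  H <- nrow(img$values); W <- ncol(img$values)
  if (is.null(rows_per_block)) rows_per_block <- H %/% 4L
  stopifnot(rows_per_block >= 1)
  band <- img$region_map$col_band
  side <- img$region_map$col_side
  key <- paste(side, band, sep = ".")
  groups <- unique(key)
  n_blocks <- ceiling(H / rows_per_block)
  labels <- matrix(0L, H, W)
  meta <- data.frame(id = integer(0), band = character(0), side = character(0),
                     block = integer(0), stringsAsFactors = FALSE)
  id <- 0L
  for (g in groups) {
    cols <- which(key == g)
    for (blk in seq_len(n_blocks)) {
      rows <- ((blk - 1L) * rows_per_block + 1L):min(blk * rows_per_block, H)
      id <- id + 1L
      labels[rows, cols] <- id
      meta <- rbind(meta, data.frame(
        id = id, band = band[cols[1]], side = side[cols[1]], block = blk,
        stringsAsFactors = FALSE))
    }
  }
  labels[img$mask] <- 0L
  present <- sort(unique(labels[labels > 0L]))
  meta <- meta[meta$id %in% present, , drop = FALSE]
  relabel <- integer(id)
  relabel[present] <- seq_along(present)
  labels[labels > 0L] <- relabel[labels[labels > 0L]]
  meta$id <- relabel[meta$id]
  rownames(meta) <- NULL
  structure(list(labels = labels, segment_meta = meta,
                 n_segments = nrow(meta)),
            class = "segment_map")
}

## Weighted forward selection of at most K features, then weighted least
## squares on the selected set (the l0 complexity budget of the surrogate).
forward_select_wls <- function(X, y, w, K) {
  n_feat <- ncol(X)
  selected <- integer(0)
  remaining <- seq_len(n_feat)
  sw <- sqrt(w)
  fit_rss <- function(cols) {
    M <- cbind(1, X[, cols, drop = FALSE])
    fit <- stats::lm.wfit(M, y, w)
    sum(w * fit$residuals^2)
  }
  for (step in seq_len(min(K, n_feat))) {
    rss <- vapply(remaining, function(j) fit_rss(c(selected, j)), numeric(1))
    best <- remaining[which.min(rss)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  M <- cbind(1, X[, selected, drop = FALSE])
  fit <- stats::lm.wfit(M, y, w)
  coefs <- fit$coefficients[-1]
  coefs[is.na(coefs)] <- 0
  list(selected = selected, coefs = coefs,
       loss = sum(w * fit$residuals^2))
}

#' Explain a prediction with a band-aligned local linear surrogate
#'
#' Draws random binary on/off vectors over the active segments, renders each
#' perturbed image (off segments replaced by the variant's background: the
#' colormap midpoint for plain variants, black for weight-map images),
#' queries the classifier, weights samples by an exponential kernel on the
#' Hamming distance to the unperturbed image, and fits a sparse weighted
#' linear surrogate (forward selection to at most `K` features, then weighted
#' least squares). The recorded fidelity loss is the surrogate's weighted
#' squared error against the classifier; the complexity is the selected
#' feature count.
#'
#' @param predict_fn Function taking a list of RGB arrays and returning an
#'   n x 2 matrix of class probabilities with columns `ADD`, `NADD`.
#' @param img A `feature_image`.
#' @param seg A `segment_map` from [segment_feature_image()].
#' @param n_samples Number of perturbed samples (>= 50).
#' @param kernel_width Proximity kernel width; default `0.25 * sqrt(n_segments)`.
#' @param K Maximum surrogate features (complexity budget).
#' @param explained_class `"ADD"` (default) or `"NADD"`.
#' @param clip Colormap saturation for rendering.
#' @param seed Integer seed; explanations are deterministic given the seed.
#' @return A `lime_explanation`: `segment_weights` (length `n_segments`,
#'   zero off the selected set), `fidelity_loss`, `complexity`,
#'   `kernel_width`, `n_samples`, `seed`, `explained_class`.
#' @export
lime_explain <- function(predict_fn, img, seg, n_samples = 200L,
                         kernel_width = NULL, K = 8L,
                         explained_class = c("ADD", "NADD"),
                         clip = 1.96, seed = 1) {
  explained_class <- match.arg(explained_class)
  stopifnot(inherits(img, "feature_image"), inherits(seg, "segment_map"),
            n_samples >= 50, K >= 1)
  n_seg <- seg$n_segments
  if (is.null(kernel_width)) kernel_width <- 0.25 * sqrt(n_seg)
  base <- render_rgb(img, clip)
  bg <- if (img$variant == "weightmap") 0 else 1   # black vs colormap midpoint
  pix <- lapply(seq_len(n_seg), function(id) which(seg$labels == id))
  npix <- prod(dim(seg$labels))
  with_seed(seed, function() {
    Z <- matrix(stats::rbinom(n_samples * n_seg, 1L, 0.5), n_samples, n_seg)
    Z[1, ] <- 1L
    ## build and score perturbed rasters in chunks to bound peak memory
    probs <- do.call(rbind, lapply(split(seq_len(n_samples),
                                         ceiling(seq_len(n_samples) / 25)),
                                   function(chunk) {
      imgs <- lapply(chunk, function(s) {
        x <- base
        off <- which(Z[s, ] == 0L)
        if (length(off)) {
          idx <- unlist(pix[off], use.names = FALSE)
          x[idx] <- bg; x[idx + npix] <- bg; x[idx + 2L * npix] <- bg
        }
        x
      })
      predict_fn(imgs)
    }))
    if (!is.matrix(probs) || nrow(probs) != n_samples ||
        any(!is.finite(probs)) || any(probs < -1e-9 | probs > 1 + 1e-9) ||
        any(abs(rowSums(probs) - 1) > 1e-6)) {
      stop("`predict_fn` must return an n x k matrix of class probabilities",
           call. = FALSE)
    }
    y <- probs[, explained_class]
    ## proximity: normalized Hamming distance (fraction of segments toggled
    ## off) under an exponential kernel
    d <- rowSums(Z == 0L) / n_seg
    w <- exp(-d^2 / kernel_width^2)
    fit <- forward_select_wls(Z, y, w, K)
    weights <- numeric(n_seg)
    weights[fit$selected] <- fit$coefs
    structure(
      list(segment_weights = weights, fidelity_loss = fit$loss,
           complexity = length(fit$selected), kernel_width = kernel_width,
           n_samples = n_samples, seed = seed,
           explained_class = explained_class),
      class = "lime_explanation"
    )
  })
}

#' Pixel mask of the top-N most important segments
#'
#' @param expl A `lime_explanation`.
#' @param seg The matching `segment_map`.
#' @param N Number of segments, `1 <= N <= n_segments`.
#' @return H x W logical mask: union of the N segments with the largest
#'   weights for the explained class; nested for increasing N.
#' @export
top_n_mask <- function(expl, seg, N) {
  stopifnot(inherits(expl, "lime_explanation"), inherits(seg, "segment_map"),
            N >= 1, N <= seg$n_segments)
  top <- order(expl$segment_weights, decreasing = TRUE)[seq_len(N)]
  matrix(seg$labels %in% top, nrow(seg$labels), ncol(seg$labels))
}

## Aggregate one explanation's segment weights to band level.
band_importance <- function(expl, seg) {
  meta <- seg$segment_meta
  sp <- split(expl$segment_weights[meta$id], meta$band)
  data.frame(band = names(sp),
             mean_abs = vapply(sp, function(v) mean(abs(v)), numeric(1)),
             mean_signed = vapply(sp, mean, numeric(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Band-level classification criteria across explanations
#'
#' Aggregates the surrogate weights of many explanations to band level: the
#' mean absolute importance ranks the bands, and the sign consensus (mean
#' sign of nonzero weights, in `[-1, 1]`) indicates whether each band's
#' visible power pushes toward or away from the explained class.
#'
#' @param expls List of `lime_explanation`s (any mix of explained classes).
#' @param seg The shared `segment_map`.
#' @return A `criteria_summary`: per class a data frame (band, importance,
#'   consensus, ranked by descending importance) and a one-line textual
#'   criterion naming the leading bands.
#' @export
summarize_criteria <- function(expls, seg) {
  stopifnot(length(expls) >= 1, inherits(seg, "segment_map"))
  meta <- seg$segment_meta
  classes <- unique(vapply(expls, `[[`, character(1), "explained_class"))
  per_class <- lapply(classes, function(cl) {
    ee <- Filter(function(e) e$explained_class == cl, expls)
    W <- do.call(rbind, lapply(ee, `[[`, "segment_weights"))
    tabs <- lapply(unique(meta$band), function(b) {
      wb <- W[, meta$id[meta$band == b], drop = FALSE]
      nz <- wb[wb != 0]
      data.frame(band = b,
                 importance = mean(abs(wb)),
                 consensus = if (length(nz)) mean(sign(nz)) else 0,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tabs)
    tab <- tab[order(-tab$importance), , drop = FALSE]
    rownames(tab) <- NULL
    lead <- tab[seq_len(min(2L, nrow(tab))), , drop = FALSE]
    phr <- vapply(seq_len(nrow(lead)), function(i) {
      sprintf("%s power of %s", if (lead$consensus[i] >= 0) "high" else "low",
              lead$band[i])
    }, character(1))
    list(table = tab,
         criterion = sprintf("%s classification criteria: %s.", cl,
                             paste(phr, collapse = ", ")))
  })
  names(per_class) <- classes
  structure(per_class, class = "criteria_summary")
}

#' Top-ranked band of one explanation
#'
#' @param expl A `lime_explanation`.
#' @param seg The matching `segment_map`.
#' @return The band name with the largest mean absolute surrogate weight.
#' @export
top_band <- function(expl, seg) {
  bi <- band_importance(expl, seg)
  bi$band[which.max(bi$mean_abs)]
}
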