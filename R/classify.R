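## Dataset assembly, stratified splitting, CNN training/evaluation with the
## standard confusion-matrix metrics (ADD positive), and the KDE-intersection
## score cutoff baseline.

## Block-average an H x W x C array by an integer factor in both directions.
downsample_rgb <- function(a, factor) {
  if (factor == 1L) return(a)
  d <- dim(a)
  H2 <- d[1] %/% factor; W2 <- d[2] %/% factor
  a <- a[seq_len(H2 * factor), seq_len(W2 * factor), , drop = FALSE]
  m <- colMeans(array(a, c(factor, H2, W2 * factor * d[3])))   # over row blocks
  m <- array(m, c(H2, factor, W2 * d[3]))
  m <- colMeans(aperm(m, c(2, 1, 3)))                           # over col blocks
  array(m, c(H2, W2, d[3]))
}

#' Assemble an image dataset for classification
#'
#' @param items List of `list(image = feature_image, label, subject_id)`.
#' @param clip Colormap saturation passed to [render_rgb()].
#' @param downsample Integer block-average factor applied to the RGB rasters
#'   before training (default 8: a 352 x 352 image becomes 44 x 44).
#' @return An `image_dataset`: list with `items` (each holding `x`, an RGB
#'   array, `label`, `subject_id`), `variant`, `classes`.
#' @export
image_dataset <- function(items, clip = 1.96, downsample = 8L) {
  stopifnot(length(items) >= 1)
  variant <- items[[1]]$image$variant
  out <- lapply(seq_along(items), function(i) {
    it <- items[[i]]
    stopifnot(inherits(it$image, "feature_image"))
    list(x = downsample_rgb(render_rgb(it$image, clip), downsample),
         label = it$label,
         subject_id = if (is.null(it$subject_id)) as.character(i) else it$subject_id)
  })
  labels <- vapply(out, `[[`, character(1), "label")
  structure(list(items = out, variant = variant,
                 classes = c("ADD", "NADD")[c("ADD", "NADD") %in% labels]),
            class = "image_dataset")
}

#' Stratified train/test split
#'
#' Draws `test_frac` of each class (rounded per class) into the test set, so
#' class proportions are preserved to within rounding; e.g. a 137:628 dataset
#' at 10% yields a 14 + 63 test set.
#'
#' @param ds An `image_dataset`.
#' @param test_frac Test fraction in (0, 1), default 0.1 (the 9:1 split).
#' @param seed Integer seed; the split is reproducible.
#' @return List with `train` and `test` (`image_dataset`s, disjoint).
#' @export
stratified_split <- function(ds, test_frac = 0.1, seed = 1) {
  stopifnot(inherits(ds, "image_dataset"), test_frac > 0, test_frac < 1)
  labels <- vapply(ds$items, `[[`, character(1), "label")
  test_idx <- with_seed(seed, function() {
    unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      n_test <- round(length(idx) * test_frac)
      if (n_test < 1 || n_test >= length(idx)) {
        stop("class ", cl, " too small for a ", test_frac, " split", call. = FALSE)
      }
      sample(idx, n_test)
    }))
  })
  mk <- function(idx) {
    d <- ds; d$items <- ds$items[idx]; d
  }
  list(train = mk(setdiff(seq_along(labels), test_idx)), test = mk(sort(test_idx)))
}

dataset_xy <- function(ds) {
  list(x = lapply(ds$items, `[[`, "x"),
       y = match(vapply(ds$items, `[[`, character(1), "label"), c("ADD", "NADD")))
}

## One Adam step over flat parameter lists.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a compact CNN on a feature-image dataset
#'
#' Trains one of three downscaled network analogs from scratch (no pretrained
#' weights): `alexnet_s` (five convolutions, one 5x5 kernel), `vgg_s` (3x3
#' kernels throughout) or `resnet_s` (residual blocks, see
#' [residual_block_forward()]). Softmax cross-entropy loss, Adam optimizer,
#' optional early stopping on a held-out validation fraction of the training
#' set. Deterministic for a fixed seed.
#'
#' @param train An `image_dataset`.
#' @param arch `"resnet_s"` (default), `"vgg_s"` or `"alexnet_s"`.
#' @param hyper Named list overriding defaults: `lr` (3e-3), `batch` (16),
#'   `epochs` (30), `val_frac` (0.1), `patience` (5), `width` (8),
#'   `class_weights` (FALSE: inverse-frequency weighting off).
#' @param seed Integer seed for weight init, shuffling and the val split.
#' @return A `cnn_model`: list with `layers`, `arch`, `classes`, `loss_log`.
#' @export
train_cnn <- function(train, arch = c("resnet_s", "vgg_s", "alexnet_s"),
                      hyper = list(), seed = 1) {
  arch <- match.arg(arch)
  stopifnot(inherits(train, "image_dataset"))
  hp <- utils::modifyList(
    list(lr = 3e-3, batch = 16L, epochs = 30L, val_frac = 0.1, patience = 5L,
         width = 8L, class_weights = FALSE),
    hyper
  )
  xy <- dataset_xy(train)
  if (length(unique(xy$y)) < 2L) stop("training set needs both classes", call. = FALSE)
  cw <- c(1, 1)
  if (isTRUE(hp$class_weights)) {
    tab <- tabulate(xy$y, 2L)
    cw <- sum(tab) / (2 * tab)
  }
  with_seed(seed, function() {
    n <- length(xy$x)
    n_val <- if (hp$val_frac > 0) max(2L, round(n * hp$val_frac)) else 0L
    val_idx <- if (n_val > 0) {
      unlist(lapply(1:2, function(cl) {
        idx <- which(xy$y == cl)
        sample(idx, max(1L, round(length(idx) * hp$val_frac)))
      }))
    } else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    layers <- build_arch(arch, in_channels = dim(xy$x[[1]])[3],
                         n_classes = 2L, width = hp$width)
    params <- collect_params(layers)
    state <- list(t = 0L,
                  m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    loss_log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                           val_loss = numeric(0))
    best <- list(loss = Inf, params = params, since = 0L)
    eval_loss <- function(idx) {
      if (!length(idx)) return(NA_real_)
      ls <- vapply(idx, function(i) {
        p <- softmax(net_forward(layers, xy$x[[i]], keep_cache = FALSE)$out)
        -log(max(p[xy$y[i]], 1e-12))
      }, numeric(1))
      mean(ls)
    }
    for (ep in seq_len(hp$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / hp$batch))) {
        gsum <- NULL
        for (i in bs) {
          fw <- net_forward(layers, xy$x[[i]])
          p <- softmax(fw$out)
          ep_loss <- ep_loss + cw[xy$y[i]] * -log(max(p[xy$y[i]], 1e-12))
          dz <- p
          dz[xy$y[i]] <- dz[xy$y[i]] - 1
          dz <- dz * cw[xy$y[i]]
          g <- grads_as_params(layers, net_backward(layers, fw$caches, dz))
          gsum <- if (is.null(gsum)) g else Map(`+`, gsum, g)
        }
        gsum <- lapply(gsum, function(g) g / length(bs))
        upd <- adam_step(params, gsum, state, hp$lr)
        params <- upd$params; state <- upd$state
        layers <- set_params(layers, params)
      }
      vl <- eval_loss(val_idx)
      loss_log <- rbind(loss_log, data.frame(
        epoch = ep, train_loss = ep_loss / length(tr_idx), val_loss = vl))
      if (!is.finite(ep_loss)) stop("training diverged (non-finite loss)", call. = FALSE)
      if (n_val > 0) {
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, params = params, since = 0L)
        } else {
          best$since <- best$since + 1L
          if (best$since >= hp$patience) break
        }
      }
    }
    if (n_val > 0 && is.finite(best$loss)) layers <- set_params(layers, best$params)
    structure(list(layers = layers, arch = arch, classes = c("ADD", "NADD"),
                   loss_log = loss_log, hyper = hp),
              class = "cnn_model")
  })
}

#' Predict class probabilities for images
#'
#' @param model A `cnn_model`.
#' @param images List of H x W x C arrays (or an `image_dataset`).
#' @return Matrix (n x 2) of class probabilities, columns ADD, NADD.
#' @export
predict_cnn <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  if (inherits(images, "image_dataset")) images <- lapply(images$items, `[[`, "x")
  probs <- t(vapply(images, function(x) {
    softmax(net_forward(model$layers, x, keep_cache = FALSE)$out)
  }, numeric(2)))
  colnames(probs) <- model$classes
  probs
}

#' Classification metrics from a confusion matrix
#'
#' With ADD as the positive class: accuracy `(TP+TN)/(TP+TN+FP+FN)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, reported as
#' percentages rounded to one decimal.
#'
#' @param tp,fn,fp,tn Confusion-matrix counts.
#' @return An `eval_metrics` list with `confusion` and the three percentages.
#' @export
#' @examples
#' eval_metrics(tp = 14, fn = 0, fp = 2, tn = 61)  # 97.4 / 100.0 / 96.8
eval_metrics <- function(tp, fn, fp, tn) {
  stopifnot(all(c(tp, fn, fp, tn) >= 0), tp + fn + fp + tn > 0)
  pct <- function(x) round(100 * x, 1)
  structure(
    list(confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
         accuracy = pct((tp + tn) / (tp + fn + fp + tn)),
         sensitivity = pct(tp / (tp + fn)),
         specificity = pct(tn / (tn + fp))),
    class = "eval_metrics"
  )
}

#' Evaluate a model on a test dataset
#'
#' @param model A `cnn_model`.
#' @param test An `image_dataset`.
#' @return An `eval_metrics` (ADD positive).
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(test, "image_dataset"), length(test$items) >= 1)
  probs <- predict_cnn(model, test)
  pred <- model$classes[max.col(probs, ties.method = "first")]
  truth <- vapply(test$items, `[[`, character(1), "label")
  eval_metrics(tp = sum(pred == "ADD" & truth == "ADD"),
               fn = sum(pred == "NADD" & truth == "ADD"),
               fp = sum(pred == "ADD" & truth == "NADD"),
               tn = sum(pred == "NADD" & truth == "NADD"))
}

#' Score cutoff at the intersection of two kernel density estimates
#'
#' Fits Gaussian-kernel density estimates to the positive (e.g. ADD) and
#' negative group scores and returns the score where the two densities cross
#' between their modes. The induced rule classifies `score <= cutoff` as the
#' positive class (low scores indicate impairment, as with MMSE).
#'
#' @param scores_pos,scores_neg Nonempty numeric score vectors; the positive
#'   group is expected at lower scores.
#' @param bandwidth Kernel bandwidth; `NULL` (default) uses `stats::bw.nrd0`.
#' @param n_grid Grid resolution for the crossing search.
#' @return The cutoff score (length-1 numeric).
#' @export
kde_cutoff <- function(scores_pos, scores_neg, bandwidth = NULL, n_grid = 2048L) {
  stopifnot(length(scores_pos) >= 1, length(scores_neg) >= 1)
  rng <- range(c(scores_pos, scores_neg))
  pad <- diff(rng) * 0.2 + 1e-9
  args <- list(from = rng[1] - pad, to = rng[2] + pad, n = n_grid)
  if (!is.null(bandwidth)) {
    stopifnot(bandwidth > 0)
    args$bw <- bandwidth
  }
  d_pos <- do.call(stats::density, c(list(scores_pos), args))
  d_neg <- do.call(stats::density, c(list(scores_neg), args))
  grid <- d_pos$x
  diffc <- d_pos$y - d_neg$y
  m_pos <- grid[which.max(d_pos$y)]
  m_neg <- grid[which.max(d_neg$y)]
  between <- which(grid >= min(m_pos, m_neg) & grid <= max(m_pos, m_neg))
  if (length(between) < 2L || max(abs(diffc[between])) < 1e-12) {
    stop("no unique density intersection between the group modes", call. = FALSE)
  }
  sgn <- sign(diffc[between])
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(cross)) {
    stop("no density intersection between the group modes", call. = FALSE)
  }
  ## if several crossings exist, take the one where the densities are largest
  height <- pmin(d_pos$y[between][cross], d_neg$y[between][cross])
  k <- between[cross[which.max(height)]]
  x0 <- grid[k]; x1 <- grid[k + 1]
  y0 <- diffc[k]; y1 <- diffc[k + 1]
  x0 - y0 * (x1 - x0) / (y1 - y0)
}
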