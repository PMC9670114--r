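## Compact convolutional networks trained from scratch.
##
## A small, self-contained CNN engine (im2col convolutions, ReLU, residual
## blocks, max/avg pooling, global average pooling, dense head, softmax
## cross-entropy, Adam) sized for feature-image classification on one CPU.
## Images are H x W x C arrays; batches are lists of such arrays.

## --- im2col / col2im --------------------------------------------------------

pad_hw <- function(a, p) {
  d <- dim(a)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- a
  out
}

## (H*W) x (k*k*C) matrix; column block order: kernel offset (di, dj) fastest
## over dj, then di, channels outermost within each offset.
im2col <- function(a, k) {
  d <- dim(a); H <- d[1]; W <- d[2]; C <- d[3]
  p <- (k - 1L) %/% 2L
  ap <- pad_hw(a, p)
  cols <- matrix(0, H * W, k * k * C)
  blk <- 0L
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    sl <- ap[di + seq_len(H) - 1L, dj + seq_len(W) - 1L, , drop = FALSE]
    cols[, blk * C + seq_len(C)] <- matrix(sl, H * W, C)
    blk <- blk + 1L
  }
  cols
}

col2im <- function(cols, H, W, C, k) {
  p <- (k - 1L) %/% 2L
  acc <- array(0, c(H + 2L * p, W + 2L * p, C))
  blk <- 0L
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    sl <- array(cols[, blk * C + seq_len(C)], c(H, W, C))
    acc[di + seq_len(H) - 1L, dj + seq_len(W) - 1L, ] <-
      acc[di + seq_len(H) - 1L, dj + seq_len(W) - 1L, , drop = FALSE] + sl
    blk <- blk + 1L
  }
  acc[p + seq_len(H), p + seq_len(W), , drop = FALSE]
}

## --- layer forward / backward -----------------------------------------------

conv_fwd <- function(a, W, b, k) {
  d <- dim(a)
  X <- im2col(a, k)
  out <- X %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(d[1], d[2], ncol(W))), X = X, in_dim = d)
}

conv_bwd <- function(cache, dout, W, k) {
  d <- cache$in_dim
  D <- matrix(dout, d[1] * d[2], ncol(W))
  list(dW = crossprod(cache$X, D),
       db = colSums(D),
       da = col2im(D %*% t(W), d[1], d[2], d[3], k))
}

pool_fwd <- function(a, type = "max") {
  d <- dim(a)
  H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
  ii <- seq_len(2L * H2); jj <- seq_len(2L * W2)
  s <- list(
    a[ii[c(TRUE, FALSE)], jj[c(TRUE, FALSE)], , drop = FALSE],
    a[ii[c(FALSE, TRUE)], jj[c(TRUE, FALSE)], , drop = FALSE],
    a[ii[c(TRUE, FALSE)], jj[c(FALSE, TRUE)], , drop = FALSE],
    a[ii[c(FALSE, TRUE)], jj[c(FALSE, TRUE)], , drop = FALSE]
  )
  if (type == "avg") {
    out <- (s[[1]] + s[[2]] + s[[3]] + s[[4]]) / 4
    return(list(out = out, in_dim = d, type = type))
  }
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  ## first-max tie-break: the earliest slot attaining the max gets the gradient
  arg <- array(1L, dim(out))
  for (q in 4:1) arg[s[[q]] == out] <- q
  list(out = out, in_dim = d, type = type, arg = arg)
}

pool_bwd <- function(cache, dout) {
  d <- cache$in_dim
  da <- array(0, d)
  H2 <- dim(dout)[1]; W2 <- dim(dout)[2]
  ri <- list(seq_len(H2) * 2L - 1L, seq_len(H2) * 2L,
             seq_len(H2) * 2L - 1L, seq_len(H2) * 2L)
  cj <- list(seq_len(W2) * 2L - 1L, seq_len(W2) * 2L - 1L,
             seq_len(W2) * 2L, seq_len(W2) * 2L)
  if (cache$type == "avg") {
    for (q in 1:4) {
      da[ri[[q]], cj[[q]], ] <- da[ri[[q]], cj[[q]], , drop = FALSE] + dout / 4
    }
    return(da)
  }
  for (q in 1:4) {
    g <- dout * (cache$arg == q)
    da[ri[[q]], cj[[q]], ] <- da[ri[[q]], cj[[q]], , drop = FALSE] + g
  }
  da
}

#' Residual block forward pass
#'
#' Computes `ReLU(conv2(ReLU(conv1(x))) + x)`: the input passes through the
#' first convolution and ReLU, then the second convolution; that output
#' `f(x)` is added to the original input and the sum passes through a final
#' ReLU. Both convolutions are same-padded with channel count preserved so
#' the skip connection is shape-compatible.
#'
#' @param x H x W x C input array.
#' @param conv1,conv2 Weight sets: lists with `W` ((k*k*C) x C matrix), `b`
#'   (length C), `k` (kernel size).
#' @return H x W x C output array.
#' @export
#' @examples
#' C <- 2L
#' w0 <- list(W = matrix(0, 9 * C, C), b = rep(0, C), k = 3L)
#' x <- array(rnorm(32), c(4, 4, C))
#' all.equal(residual_block_forward(x, w0, w0), pmax(x, 0))
residual_block_forward <- function(x, conv1, conv2) {
  d <- dim(x)
  for (cv in list(conv1, conv2)) {
    if (ncol(cv$W) != d[3] || nrow(cv$W) != cv$k^2 * d[3]) {
      stop("residual block convolutions must preserve the channel count",
           call. = FALSE)
    }
  }
  h <- conv_fwd(x, conv1$W, conv1$b, conv1$k)$out
  h <- pmax(h, 0)
  fx <- conv_fwd(h, conv2$W, conv2$b, conv2$k)$out
  pmax(fx + x, 0)
}

## --- architectures ----------------------------------------------------------

he_init <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))

make_conv <- function(cin, cout, k) {
  list(type = "conv", k = k,
       W = matrix(he_init(k * k * cin, k * k * cin * cout), k * k * cin, cout),
       b = rep(0, cout))
}

make_res <- function(c, k = 3L) {
  list(type = "res",
       conv1 = make_conv(c, c, k), conv2 = make_conv(c, c, k))
}

make_dense <- function(cin, cout) {
  list(type = "dense",
       W = matrix(he_init(cin, cin * cout) / sqrt(2), cin, cout),
       b = rep(0, cout))
}

## Compact analogs: a 5-convolution AlexNet-like stack, a 3x3-kernel VGG-like
## stack, and a residual-block ResNet-like stack, each ending in global
## average pooling and a dense softmax head.
build_arch <- function(arch, in_channels, n_classes, width = 8L) {
  w <- as.integer(width)
  layers <- switch(arch,
    alexnet_s = list(
      make_conv(in_channels, w, 5L), list(type = "relu"), list(type = "pool"),
      make_conv(w, 2L * w, 3L), list(type = "relu"), list(type = "pool"),
      make_conv(2L * w, 2L * w, 3L), list(type = "relu"),
      make_conv(2L * w, 2L * w, 3L), list(type = "relu"),
      make_conv(2L * w, w, 3L), list(type = "relu"), list(type = "pool"),
      list(type = "gap"), make_dense(w, n_classes)
    ),
    vgg_s = list(
      make_conv(in_channels, w, 3L), list(type = "relu"),
      make_conv(w, w, 3L), list(type = "relu"), list(type = "pool"),
      make_conv(w, 2L * w, 3L), list(type = "relu"),
      make_conv(2L * w, 2L * w, 3L), list(type = "relu"), list(type = "pool"),
      list(type = "gap"), make_dense(2L * w, n_classes)
    ),
    resnet_s = list(
      make_conv(in_channels, w, 3L), list(type = "relu"),
      make_res(w), list(type = "pool"),
      make_conv(w, 2L * w, 3L), list(type = "relu"),
      make_res(2L * w), list(type = "pool"),
      list(type = "gap"), make_dense(2L * w, n_classes)
    ),
    stop("unknown architecture: ", arch, call. = FALSE)
  )
  layers
}

## --- forward / backward through a layer stack -------------------------------

net_forward <- function(layers, x, keep_cache = TRUE) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type == "conv") {
      cf <- conv_fwd(x, l$W, l$b, l$k)
      if (keep_cache) caches[[li]] <- cf
      x <- cf$out
    } else if (l$type == "relu") {
      if (keep_cache) caches[[li]] <- list(mask = x > 0)
      x <- pmax(x, 0)
    } else if (l$type == "pool") {
      pf <- pool_fwd(x, "max")
      if (keep_cache) caches[[li]] <- pf
      x <- pf$out
    } else if (l$type == "res") {
      c1 <- conv_fwd(x, l$conv1$W, l$conv1$b, l$conv1$k)
      h <- pmax(c1$out, 0)
      c2 <- conv_fwd(h, l$conv2$W, l$conv2$b, l$conv2$k)
      s <- c2$out + x
      if (keep_cache) {
        caches[[li]] <- list(c1 = c1, relu1 = c1$out > 0, c2 = c2, sum_mask = s > 0)
      }
      x <- pmax(s, 0)
    } else if (l$type == "gap") {
      d <- dim(x)
      if (keep_cache) caches[[li]] <- list(in_dim = d)
      x <- apply(x, 3L, mean)
    } else if (l$type == "dense") {
      if (keep_cache) caches[[li]] <- list(xin = x)
      x <- as.numeric(crossprod(l$W, x) + l$b)
    }
  }
  list(out = x, caches = caches)
}

net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]; cc <- caches[[li]]
    if (l$type == "conv") {
      g <- conv_bwd(cc, dout, l$W, l$k)
      grads[[li]] <- list(dW = g$dW, db = g$db)
      dout <- g$da
    } else if (l$type == "relu") {
      dout <- dout * cc$mask
    } else if (l$type == "pool") {
      dout <- pool_bwd(cc, dout)
    } else if (l$type == "res") {
      ds <- dout * cc$sum_mask
      g2 <- conv_bwd(cc$c2, ds, l$conv2$W, l$conv2$k)
      dh <- g2$da * cc$relu1
      g1 <- conv_bwd(cc$c1, dh, l$conv1$W, l$conv1$k)
      grads[[li]] <- list(conv1 = list(dW = g1$dW, db = g1$db),
                          conv2 = list(dW = g2$dW, db = g2$db))
      dout <- g1$da + ds
    } else if (l$type == "gap") {
      d <- cc$in_dim
      dout <- array(rep(dout / (d[1] * d[2]), each = d[1] * d[2]), d)
    } else if (l$type == "dense") {
      grads[[li]] <- list(dW = outer(cc$xin, dout), db = dout)
      dout <- as.numeric(l$W %*% dout)
    }
  }
  grads
}

## --- parameter bookkeeping (flat list of numeric arrays) --------------------

collect_params <- function(layers) {
  out <- list()
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type == "conv" || l$type == "dense") {
      out[[paste0(li, ".W")]] <- l$W
      out[[paste0(li, ".b")]] <- l$b
    } else if (l$type == "res") {
      out[[paste0(li, ".c1.W")]] <- l$conv1$W
      out[[paste0(li, ".c1.b")]] <- l$conv1$b
      out[[paste0(li, ".c2.W")]] <- l$conv2$W
      out[[paste0(li, ".c2.b")]] <- l$conv2$b
    }
  }
  out
}

set_params <- function(layers, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    li <- as.integer(parts[1])
    if (length(parts) == 2L) {
      layers[[li]][[parts[2]]] <- params[[nm]]
    } else {
      slot <- if (parts[2] == "c1") "conv1" else "conv2"
      layers[[li]][[slot]][[parts[3]]] <- params[[nm]]
    }
  }
  layers
}

grads_as_params <- function(layers, grads) {
  out <- list()
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    if (!is.null(g$dW)) {
      out[[paste0(li, ".W")]] <- g$dW
      out[[paste0(li, ".b")]] <- g$db
    } else {
      out[[paste0(li, ".c1.W")]] <- g$conv1$dW
      out[[paste0(li, ".c1.b")]] <- g$conv1$db
      out[[paste0(li, ".c2.W")]] <- g$conv2$dW
      out[[paste0(li, ".c2.b")]] <- g$conv2$db
    }
  }
  out
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}
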