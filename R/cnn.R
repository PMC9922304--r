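# Small convolutional network: 3x(conv 3x3 same -> ReLU -> maxpool 2x2),
# global average pooling, linear head, softmax cross-entropy, SGD+momentum
# with L2 weight decay. Implemented with im2col so every convolution is one
# BLAS matrix product; fully deterministic given a seed. The GAP head makes
# class-activation maps exact (the logit is a weighted spatial mean of the
# final activation channels).

#' Training configuration for the desk-scale CNN
#'
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param l2 L2 regularization (weight decay) on convolution and dense weights.
#' @param filters Integer vector of length 3: channels of the conv blocks.
#' @param input_size Optional `c(p, q)`; images of a different spatial size
#'   are bilinearly resized to this contract before entering the network
#'   (`NULL` uses the native frame).
#' @param seed Integer seed for initialization and batch shuffling.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(epochs = 30L, batch_size = 16L, lr = 0.05,
                       momentum = 0.9, l2 = 1e-4,
                       filters = c(8L, 16L, 32L), input_size = NULL,
                       seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, momentum >= 0,
            momentum < 1, l2 >= 0, length(filters) == 3L)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, momentum = momentum, l2 = l2,
                 filters = as.integer(filters),
                 input_size = if (!is.null(input_size)) as.integer(rep(input_size, length.out = 2L)),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# ---- low-level ops ---------------------------------------------------------

pad_batch <- function(X) {
  d <- dim(X)
  Xp <- array(0, c(d[1L] + 2L, d[2L] + 2L, d[3L], d[4L]))
  Xp[2:(d[1L] + 1L), 2:(d[2L] + 1L), , ] <- X
  Xp
}

# flat padded-array indices of every 3x3xC patch; rows = output positions
# (column-major over the p x q frame), cols = patch entries
make_conv_idx <- function(p, q, C) {
  pp <- p + 2L
  qq <- q + 2L
  ij <- expand.grid(i = seq_len(p), j = seq_len(q))
  base <- ij$i + (ij$j - 1L) * pp
  off <- expand.grid(di = 0:2, dj = 0:2, ch = seq_len(C) - 1L)
  idx <- outer(base, off$di + off$dj * pp + off$ch * (pp * qq), `+`)
  storage.mode(idx) <- "integer"
  idx
}

# im2col over a batch: X (p,q,C,n) -> (pq*n x 9C) patch matrix
im2col_batch <- function(X, idx) {
  d <- dim(X)
  Xp <- as.vector(pad_batch(X))
  padlen <- (d[1L] + 2L) * (d[2L] + 2L) * d[3L]
  cols <- matrix(0, nrow(idx) * d[4L], ncol(idx))
  for (bi in seq_len(d[4L])) {
    cols[(bi - 1L) * nrow(idx) + seq_len(nrow(idx)), ] <- Xp[idx + (bi - 1L) * padlen]
  }
  cols
}

# X: (p,q,C,n) -> list(A: relu output (pq*n x F), cols, pre); `cols` may be
# supplied precomputed (the input-layer patches never change across epochs)
conv_forward <- function(X, W, b, idx, cols = NULL) {
  cols <- cols %||% im2col_batch(X, idx)
  pre <- cols %*% W
  pre <- pre + rep(b, each = nrow(pre))
  A <- pre
  A[A < 0] <- 0
  list(A = A, cols = cols, pre = pre)
}

# dOut: (pq*n x F) gradient at the conv PRE-activation; returns grads and,
# when need_dx, gradient wrt the (unpadded) input as (p,q,C,n)
conv_backward <- function(dOut, cache, W, idx, in_dim, need_dx = TRUE) {
  dW <- crossprod(cache$cols, dOut)
  db <- colSums(dOut)
  dX <- NULL
  if (need_dx) {
    n <- in_dim[4L]
    pp <- in_dim[1L] + 2L
    qq <- in_dim[2L] + 2L
    padlen <- pp * qq * in_dim[3L]
    dcols <- dOut %*% t(W)
    dXp <- numeric(padlen * n)
    img_off <- rep((seq_len(n) - 1L) * padlen, each = nrow(idx))
    for (m in seq_len(ncol(idx))) {
      pos <- rep(idx[, m], n) + img_off
      dXp[pos] <- dXp[pos] + dcols[, m]
    }
    dXp <- array(dXp, c(pp, qq, in_dim[3L], n))
    dX <- dXp[2:(in_dim[1L] + 1L), 2:(in_dim[2L] + 1L), , , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

# matrix (pq*n x F) -> array (p,q,F,n)
to_array <- function(A, p, q, n) {
  aperm(array(A, c(p, q, n, ncol(A))), c(1L, 2L, 4L, 3L))
}

# array (p,q,F,n) -> matrix (pq*n x F)
to_matrix <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
}

maxpool_forward <- function(A) {
  d <- dim(A)
  h <- (d[1L] %/% 2L) * 2L
  w <- (d[2L] %/% 2L) * 2L
  i1 <- seq(1L, h, by = 2L); j1 <- seq(1L, w, by = 2L)
  s1 <- A[i1, j1, , , drop = FALSE]
  s2 <- A[i1 + 1L, j1, , , drop = FALSE]
  s3 <- A[i1, j1 + 1L, , , drop = FALSE]
  s4 <- A[i1 + 1L, j1 + 1L, , , drop = FALSE]
  m <- pmax(s1, s2, s3, s4)
  # first-max tie rule, stored as masks reused by the backward pass
  m1 <- s1 == m
  m2 <- (s2 == m) & !m1
  m3 <- (s3 == m) & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(out = m, masks = list(m1, m2, m3, m4), in_dim = d)
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$in_dim
  h <- (d[1L] %/% 2L) * 2L
  w <- (d[2L] %/% 2L) * 2L
  i1 <- seq(1L, h, by = 2L); j1 <- seq(1L, w, by = 2L)
  dA <- array(0, d)
  dA[i1, j1, , ] <- dOut * cache$masks[[1L]]
  dA[i1 + 1L, j1, , ] <- dA[i1 + 1L, j1, , , drop = FALSE] + dOut * cache$masks[[2L]]
  dA[i1, j1 + 1L, , ] <- dA[i1, j1 + 1L, , , drop = FALSE] + dOut * cache$masks[[3L]]
  dA[i1 + 1L, j1 + 1L, , ] <- dA[i1 + 1L, j1 + 1L, , , drop = FALSE] + dOut * cache$masks[[4L]]
  dA
}

gap_forward <- function(A) {
  d <- dim(A)
  cm <- colMeans(matrix(A, d[1L] * d[2L], d[3L] * d[4L]))
  t(matrix(cm, d[3L], d[4L]))  # n x F
}

softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

#' Bilinear resize of a matrix or multi-channel array
#'
#' Align-corners bilinear interpolation: source and target corner pixels
#' coincide, interior values are interpolated on the regular grid.
#'
#' @param x Matrix (p x q) or array (p x q x C).
#' @param out_h,out_w Target size.
#' @return Resized matrix/array.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  if (length(dim(x)) == 3L) {
    out <- array(0, c(out_h, out_w, dim(x)[3L]))
    for (ch in seq_len(dim(x)[3L])) out[, , ch] <- bilinear_resize(x[, , ch], out_h, out_w)
    return(out)
  }
  p <- nrow(x); q <- ncol(x)
  ri <- if (out_h == 1L) rep(1, out_h) else seq(1, p, length.out = out_h)
  ci <- if (out_w == 1L) rep(1, out_w) else seq(1, q, length.out = out_w)
  r0 <- pmin(floor(ri), p - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(ci), q - 1L); c0 <- pmax(c0, 1L)
  fr <- ri - r0
  fc <- ci - c0
  if (p == 1L) { r0 <- rep(1L, out_h); fr <- rep(0, out_h) }
  if (q == 1L) { c0 <- rep(1L, out_w); fc <- rep(0, out_w) }
  r1 <- pmin(r0 + 1L, p)
  c1 <- pmin(c0 + 1L, q)
  a <- x[r0, c0, drop = FALSE]; b <- x[r1, c0, drop = FALSE]
  cc <- x[r0, c1, drop = FALSE]; d <- x[r1, c1, drop = FALSE]
  wr <- matrix(fr, out_h, out_w)
  wc <- matrix(fc, out_h, out_w, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + cc * (1 - wr) * wc + d * wr * wc
}

resize_batch <- function(X, size) {
  d <- dim(X)
  if (d[1L] == size[1L] && d[2L] == size[2L]) return(X)
  out <- array(0, c(size[1L], size[2L], d[3L], d[4L]))
  for (j in seq_len(d[4L])) out[, , , j] <- bilinear_resize(X[, , , j, drop = TRUE], size[1L], size[2L])
  if (d[3L] == 1L) dim(out) <- c(size[1L], size[2L], 1L, d[4L])
  out
}

# ---- model -----------------------------------------------------------------

cnn_init <- function(C, n_classes, filters, seed) {
  set.seed(seed)
  he <- function(fan_in, n_out) {
    matrix(rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
  }
  list(
    W1 = he(9L * C, filters[1L]), b1 = numeric(filters[1L]),
    W2 = he(9L * filters[1L], filters[2L]), b2 = numeric(filters[2L]),
    W3 = he(9L * filters[2L], filters[3L]), b3 = numeric(filters[3L]),
    Wd = he(filters[3L], n_classes) / sqrt(2), bd = numeric(n_classes)
  )
}

# forward pass; X (p,q,C,n); returns probs, feats and (optionally) caches.
# cols1: precomputed input-layer im2col (training-set cache)
cnn_forward <- function(params, X, keep = FALSE, cols1 = NULL) {
  d <- dim(X)
  idx1 <- make_conv_idx(d[1L], d[2L], d[3L])
  c1 <- conv_forward(X, params$W1, params$b1, idx1, cols = cols1)
  A1 <- to_array(c1$A, d[1L], d[2L], d[4L])
  p1 <- maxpool_forward(A1)
  d1 <- dim(p1$out)
  idx2 <- make_conv_idx(d1[1L], d1[2L], d1[3L])
  c2 <- conv_forward(p1$out, params$W2, params$b2, idx2)
  A2 <- to_array(c2$A, d1[1L], d1[2L], d1[4L])
  p2 <- maxpool_forward(A2)
  d2 <- dim(p2$out)
  idx3 <- make_conv_idx(d2[1L], d2[2L], d2[3L])
  c3 <- conv_forward(p2$out, params$W3, params$b3, idx3)
  A3 <- to_array(c3$A, d2[1L], d2[2L], d2[4L])
  p3 <- maxpool_forward(A3)
  feats <- gap_forward(p3$out)
  logits <- feats %*% params$Wd + rep(params$bd, each = nrow(feats))
  probs <- softmax(logits)
  out <- list(probs = probs, feats = feats, logits = logits, last_relu = A3)
  if (keep) {
    out$cache <- list(X = X, idx1 = idx1, c1 = c1, A1dim = dim(A1), p1 = p1,
                      idx2 = idx2, c2 = c2, A2dim = dim(A2), p2 = p2,
                      idx3 = idx3, c3 = c3, A3dim = dim(A3), p3 = p3)
  }
  out
}

cnn_backward <- function(params, fwd, y_onehot, l2) {
  ch <- fwd$cache
  nb <- nrow(fwd$probs)
  dlogits <- (fwd$probs - y_onehot) / nb
  grads <- list(
    Wd = crossprod(fwd$feats, dlogits) + l2 * params$Wd,
    bd = colSums(dlogits)
  )
  dfeats <- dlogits %*% t(params$Wd)  # n x F3
  dpool3 <- dim(ch$p3$out)
  hw3 <- dpool3[1L] * dpool3[2L]
  dP3 <- array(0, dpool3)
  # each spatial cell of the GAP input receives dfeat / (h*w)
  dP3[] <- aperm(array(rep(t(dfeats) / hw3, each = hw3),
                       c(dpool3[1L], dpool3[2L], dpool3[3L], dpool3[4L])), c(1L, 2L, 3L, 4L))
  dA3 <- maxpool_backward(dP3, ch$p3)
  dPre3 <- to_matrix(dA3) * (ch$c3$pre > 0)
  in3 <- dim(ch$p2$out)
  g3 <- conv_backward(dPre3, ch$c3, params$W3, ch$idx3, in3, need_dx = TRUE)
  grads$W3 <- g3$dW + l2 * params$W3
  grads$b3 <- g3$db
  dA2 <- maxpool_backward(g3$dX, ch$p2)
  dPre2 <- to_matrix(dA2) * (ch$c2$pre > 0)
  in2 <- dim(ch$p1$out)
  g2 <- conv_backward(dPre2, ch$c2, params$W2, ch$idx2, in2, need_dx = TRUE)
  grads$W2 <- g2$dW + l2 * params$W2
  grads$b2 <- g2$db
  dA1 <- maxpool_backward(g2$dX, ch$p1)
  dPre1 <- to_matrix(dA1) * (ch$c1$pre > 0)
  g1 <- conv_backward(dPre1, ch$c1, params$W1, ch$idx1, dim(ch$X), need_dx = FALSE)
  grads$W1 <- g1$dW + l2 * params$W1
  grads$b1 <- g1$db
  grads
}

cnn_fit <- function(X, y, config, X_val = NULL, y_val = NULL) {
  d <- dim(X)
  classes <- levels(y)
  n_classes <- length(classes)
  params <- cnn_init(d[3L], n_classes, config$filters, config$seed)
  vel <- lapply(params, function(p) p * 0)
  yi <- as.integer(y)
  onehot <- diag(n_classes)[yi, , drop = FALSE]
  n <- d[4L]
  history <- vector("list", config$epochs)
  # the input-layer patch matrix is invariant across epochs: build it once
  pq <- d[1L] * d[2L]
  cols1_all <- im2col_batch(X, make_conv_idx(d[1L], d[2L], d[3L]))
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    correct <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[, , , bi, drop = FALSE]
      rows <- rep((bi - 1L) * pq, each = pq) + seq_len(pq)
      fwd <- cnn_forward(params, Xb, keep = TRUE,
                         cols1 = cols1_all[rows, , drop = FALSE])
      pb <- fwd$probs
      losses <- c(losses, -mean(log(pmax(pb[cbind(seq_along(bi), yi[bi])], 1e-12))))
      correct <- correct + sum(max.col(pb, ties.method = "first") == yi[bi])
      grads <- cnn_backward(params, fwd, onehot[bi, , drop = FALSE], config$l2)
      for (nm in names(params)) {
        vel[[nm]] <- config$momentum * vel[[nm]] - config$lr * grads[[nm]]
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
    }
    h <- list(epoch = ep, loss = mean(losses), accuracy = correct / n)
    if (!is.null(X_val)) {
      pv <- cnn_forward(params, X_val)$probs
      yv <- as.integer(y_val)
      h$val_loss <- -mean(log(pmax(pv[cbind(seq_len(nrow(pv)), yv)], 1e-12)))
      h$val_accuracy <- mean(max.col(pv, ties.method = "first") == yv)
    }
    history[[ep]] <- h
  }
  list(params = params, classes = classes,
       history = dplyr::bind_rows(lapply(history, as_tibble)))
}
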