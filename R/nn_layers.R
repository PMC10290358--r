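# Internal neural-network primitives. Batches are arrays of dimension
# (H, W, C, N). Convolutions are same-padding, stride 1, realised as an
# im2col gather followed by one matrix product; the gather indices are
# injective per kernel offset, so the backward scatter accumulates
# column-by-column without collisions. All operations are plain double
# arithmetic with no threading assumptions, so runs are bit-reproducible.

# Memoised across calls: training revisits the same (dims, kernel) a few
# thousand times per run.
.im2col_cache <- new.env(parent = emptyenv())

# Linear gather indices of all k x k x C patches of a zero-padded batch.
# Returns list(idx = (H*W*N) x (k*k*C) integer matrix into the padded array,
# padded dims). Row order: output row fastest, then column, then sample.
im2col_indices <- function(h, w, c, n, k) {
  key <- paste(h, w, c, n, k, sep = "x")
  cached <- .im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  res <- im2col_indices_build(h, w, c, n, k)
  .im2col_cache[[key]] <- res
  res
}

im2col_indices_build <- function(h, w, c, n, k) {
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  offs <- expand.grid(di = 0:(k - 1L), dj = 0:(k - 1L), cc = 0:(c - 1L))
  off <- offs$di + offs$dj * hp + offs$cc * (hp * wp)
  starts <- as.vector(outer(0:(h - 1L), (0:(w - 1L)) * hp, "+")) + 1L
  base <- outer(starts, off, "+")
  idx <- base[rep(seq_len(h * w), n), , drop = FALSE] +
    rep((0:(n - 1L)) * (hp * wp * c), each = h * w)
  list(idx = idx, pad = p, hp = hp, wp = wp)
}

pad_batch <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L] + 2L * p, d[2L] + 2L * p, d[3L], d[4L]))
  xp[p + seq_len(d[1L]), p + seq_len(d[2L]), , ] <- x
  xp
}

conv_forward <- function(x, w, b) {
  d <- dim(x)                               # H, W, C, N
  k <- as.integer(sqrt(nrow(w) / d[3L]))
  ii <- im2col_indices(d[1L], d[2L], d[3L], d[4L], k)
  xp <- pad_batch(x, ii$pad)
  m <- matrix(xp[as.vector(ii$idx)], nrow = nrow(ii$idx))
  out <- m %*% w
  out <- sweep(out, 2L, b, "+")
  f <- ncol(w)
  out <- array(out, c(d[1L], d[2L], d[4L], f))
  list(out = aperm(out, c(1L, 2L, 4L, 3L)),
       cache = list(m = m, ii = ii, dims = d, k = k, w = w))
}

conv_backward <- function(dout, cache) {
  d <- cache$dims
  f <- ncol(cache$w)
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), ncol = f)
  dw <- crossprod(cache$m, dmat)
  db <- colSums(dmat)
  dcol <- tcrossprod(dmat, cache$w)
  ii <- cache$ii
  dxp <- array(0, c(ii$hp, ii$wp, d[3L], d[4L]))
  for (j in seq_len(ncol(ii$idx))) {
    v <- ii$idx[, j]
    dxp[v] <- dxp[v] + dcol[, j]
  }
  p <- ii$pad
  dx <- dxp[p + seq_len(d[1L]), p + seq_len(d[2L]), , , drop = FALSE]
  list(dx = dx, dw = dw, db = db)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_backward <- function(dout, cache) dout * cache

# Pooling with square window s and stride s (H, W divisible by s).
pool_forward <- function(x, s, type) {
  d <- dim(x)
  ri <- seq.int(1L, d[1L], by = s); ci <- seq.int(1L, d[2L], by = s)
  cols <- vector("list", s * s)
  kk <- 0L
  for (b in 0:(s - 1L)) for (a in 0:(s - 1L)) {
    kk <- kk + 1L
    cols[[kk]] <- as.vector(x[ri + a, ci + b, , , drop = FALSE])
  }
  m <- do.call(cbind, cols)
  od <- c(d[1L] %/% s, d[2L] %/% s, d[3L], d[4L])
  if (type == "max") {
    amax <- max.col(m, ties.method = "first")
    out <- array(m[cbind(seq_len(nrow(m)), amax)], od)
    list(out = out, cache = list(amax = amax, dims = d, s = s, type = type))
  } else {
    out <- array(rowMeans(m), od)
    list(out = out, cache = list(dims = d, s = s, type = type))
  }
}

pool_backward <- function(dout, cache) {
  d <- cache$dims; s <- cache$s
  ri <- seq.int(1L, d[1L], by = s); ci <- seq.int(1L, d[2L], by = s)
  dv <- as.vector(dout)
  dx <- array(0, d)
  od <- c(d[1L] %/% s, d[2L] %/% s, d[3L], d[4L])
  kk <- 0L
  for (b in 0:(s - 1L)) for (a in 0:(s - 1L)) {
    kk <- kk + 1L
    g <- if (cache$type == "max") dv * (cache$amax == kk) else dv / (s * s)
    dx[ri + a, ci + b, , ] <- dx[ri + a, ci + b, , ] + array(g, od)
  }
  dx
}

# Row-wise softmax with max subtraction.
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
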