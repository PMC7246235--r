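# Internal layer primitives for the generator/discriminator.
#
# Feature maps are 3D arrays (H, W, C). A convolution parameter object is
#   list(meta = list(k, pad, stride, cin, cout), w, b)
# with w a (k*k*cin) x cout matrix, row index ki + k*kj + k*k*ci (0-based),
# matching the C++ im2col layout. Everything is deterministic given the
# R RNG state.

.asCube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

.makeConv <- function(cin, cout, k = 3L, stride = 1L, pad = 1L,
                      gain = sqrt(2)) {
  sd <- gain / sqrt(k * k * cin)
  list(meta = list(k = k, pad = pad, stride = stride, cin = cin, cout = cout),
       w = matrix(rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout),
       b = numeric(cout))
}

.convFwd <- function(p, x) {
  cpp_conv2d_fwd(x, p$w, p$b, p$meta$k, p$meta$pad, p$meta$stride)
}

.convBwd <- function(p, x, gy) {
  cpp_conv2d_bwd(x, p$w, gy, p$meta$k, p$meta$pad, p$meta$stride)
}

# instance normalization: per-channel standardisation over the spatial
# grid with learnable scale/shift; stabilises short training schedules
.inormFwd <- function(p, x, eps = 1e-5) {
  d <- dim(x); N <- d[1] * d[2]
  y <- x
  stats <- matrix(0, d[3], 2)
  for (c in seq_len(d[3])) {
    m <- mean(x[, , c])
    v <- sum((x[, , c] - m)^2) / N
    stats[c, ] <- c(m, sqrt(v + eps))
    y[, , c] <- p$g[c] * (x[, , c] - m) / stats[c, 2] + p$b[c]
  }
  list(y = y, stats = stats)
}

.inormBwd <- function(p, x, stats, gy) {
  d <- dim(x); N <- d[1] * d[2]
  gx <- x; gg <- numeric(d[3]); gb <- numeric(d[3])
  for (c in seq_len(d[3])) {
    sd <- stats[c, 2]
    xhat <- (x[, , c] - stats[c, 1]) / sd
    gyc <- gy[, , c]
    gg[c] <- sum(gyc * xhat)
    gb[c] <- sum(gyc)
    dxhat <- gyc * p$g[c]
    gx[, , c] <- (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) / sd
  }
  list(gx = gx, gg = gg, gb = gb)
}

.makeInorm <- function(ch) {
  list(meta = list(ch = ch), g = rep(1, ch), b = numeric(ch))
}

.lreluFwd <- function(x, alpha = 0.2) {
  ifelse(x > 0, x, alpha * x)
}

.lreluBwd <- function(x, gy, alpha = 0.2) {
  gy * ifelse(x > 0, 1, alpha)
}

.concatC <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
}

.splitC <- function(g, c1) {
  list(g[, , seq_len(c1), drop = FALSE],
       g[, , c1 + seq_len(dim(g)[3] - c1), drop = FALSE])
}

# ---- structure-walking helpers (skip "meta" entries) ----------------------

.isMeta <- function(nms, i) !is.null(nms) && identical(nms[i], "meta")

.zeroLike <- function(p) {
  if (is.list(p)) {
    nms <- names(p)
    out <- vector("list", length(p))
    for (i in seq_along(p))
      out[[i]] <- if (.isMeta(nms, i)) p[[i]] else .zeroLike(p[[i]])
    names(out) <- nms
    out
  } else p * 0
}

.addGrads <- function(a, b) {
  if (is.list(a)) {
    nms <- names(a)
    out <- vector("list", length(a))
    for (i in seq_along(a))
      out[[i]] <- if (.isMeta(nms, i)) a[[i]] else .addGrads(a[[i]], b[[i]])
    names(out) <- nms
    out
  } else a + b
}

.scaleGrads <- function(a, s) {
  if (is.list(a)) {
    nms <- names(a)
    out <- vector("list", length(a))
    for (i in seq_along(a))
      out[[i]] <- if (.isMeta(nms, i)) a[[i]] else .scaleGrads(a[[i]], s)
    names(out) <- nms
    out
  } else a * s
}

# ---- Adam -----------------------------------------------------------------

.adamInit <- function(params) {
  list(m = .zeroLike(params), v = .zeroLike(params), t = 0L)
}

.adamWalk <- function(p, g, m, v, lr, b1, b2, eps, bc1, bc2) {
  if (is.list(p)) {
    nms <- names(p)
    for (i in seq_along(p)) {
      if (.isMeta(nms, i)) next
      r <- .adamWalk(p[[i]], g[[i]], m[[i]], v[[i]],
                     lr, b1, b2, eps, bc1, bc2)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
    list(p = p, m = m, v = v)
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
}

.adamStep <- function(params, grads, state, lr, b1 = 0.5, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  r <- .adamWalk(params, grads, state$m, state$v, lr, b1, b2, eps, bc1, bc2)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
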