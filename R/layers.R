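# Neural-network primitives with paired forward/backward implementations.
# Every forward returns its output plus the cache the analytic backward needs;
# gradients are verified against finite differences in the test suite.
# Token sequences are plain L x d matrices (row i = sequence position i-1).

.broadcast_row <- function(x, v) x * matrix(v, nrow(x), length(v), byrow = TRUE)
.add_row <- function(x, v) x + matrix(v, nrow(x), length(v), byrow = TRUE)

# cyclic roll: row i of the result is row ((i-1+s) mod L)+1 of x
.roll_rows <- function(x, s) {
  L <- nrow(x)
  s <- ((s %% L) + L) %% L
  if (s == 0) return(x)
  x[c((s + 1):L, 1:s), , drop = FALSE]
}

.linear_fwd <- function(x, W, b) .add_row(x %*% W, b)
.linear_bwd <- function(x, W, dy) {
  list(dx = dy %*% t(W), dW = crossprod(x, dy), db = colSums(dy))
}

.gelu_fwd <- function(x) x * stats::pnorm(x)
.gelu_bwd <- function(x, dy) dy * (stats::pnorm(x) + x * stats::dnorm(x))

.ln_fwd <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * invstd
  list(y = .add_row(.broadcast_row(xhat, g), b), xhat = xhat, invstd = invstd)
}
.ln_bwd <- function(cache, g, dy) {
  xhat <- cache$xhat
  dxhat <- .broadcast_row(dy, g)
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

.softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# ---- windowed multi-head self-attention ------------------------------------

# p: list(Wq, Wk, Wv, Wo, bq, bk, bv, bo); wmap: window_map; shift in positions
.attn_fwd <- function(x, p, wmap, heads, shift, keep_attention = FALSE) {
  d <- ncol(x)
  dh <- d %/% heads
  xs <- .roll_rows(x, shift)
  Q <- .linear_fwd(xs, p$Wq, p$bq)
  K <- .linear_fwd(xs, p$Wk, p$bk)
  V <- .linear_fwd(xs, p$Wv, p$bv)
  L <- nrow(x)
  ws <- wmap$window_size
  nw <- L %/% ws
  O <- matrix(0, L, d)
  A_cache <- vector("list", nw)
  scale <- 1 / sqrt(dh)
  for (w in seq_len(nw)) {
    idx <- ((w - 1L) * ws + 1L):(w * ws)
    Aw <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[idx, cols, drop = FALSE],
                      K[idx, cols, drop = FALSE]) * scale
      A <- .softmax_rows(S)
      O[idx, cols] <- A %*% V[idx, cols, drop = FALSE]
      Aw[[h]] <- A
    }
    A_cache[[w]] <- Aw
  }
  ys <- .linear_fwd(O, p$Wo, p$bo)
  y <- .roll_rows(ys, -shift)
  out <- list(y = y, xs = xs, Q = Q, K = K, V = V, O = O, A = A_cache,
              heads = heads, shift = shift, ws = ws)
  if (keep_attention) out$attention <- A_cache
  out
}

.attn_bwd <- function(cache, p, dy) {
  heads <- cache$heads
  ws <- cache$ws
  d <- ncol(dy)
  dh <- d %/% heads
  scale <- 1 / sqrt(dh)
  dys <- .roll_rows(dy, cache$shift)
  lo <- .linear_bwd(cache$O, p$Wo, dys)
  dO <- lo$dx
  L <- nrow(dy)
  nw <- L %/% ws
  dQ <- matrix(0, L, d); dK <- matrix(0, L, d); dV <- matrix(0, L, d)
  for (w in seq_len(nw)) {
    idx <- ((w - 1L) * ws + 1L):(w * ws)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[w]][[h]]
      dOw <- dO[idx, cols, drop = FALSE]
      Vw <- cache$V[idx, cols, drop = FALSE]
      dA <- tcrossprod(dOw, Vw)
      dS <- A * (dA - rowSums(dA * A)) * scale
      dQ[idx, cols] <- dS %*% cache$K[idx, cols, drop = FALSE]
      dK[idx, cols] <- crossprod(dS, cache$Q[idx, cols, drop = FALSE])
      dV[idx, cols] <- crossprod(A, dOw)
    }
  }
  lq <- .linear_bwd(cache$xs, p$Wq, dQ)
  lk <- .linear_bwd(cache$xs, p$Wk, dK)
  lv <- .linear_bwd(cache$xs, p$Wv, dV)
  dxs <- lq$dx + lk$dx + lv$dx
  list(dx = .roll_rows(dxs, -cache$shift),
       grads = list(Wq = lq$dW, Wk = lk$dW, Wv = lv$dW, Wo = lo$dW,
                    bq = lq$db, bk = lk$db, bv = lv$db, bo = lo$db))
}

# ---- feed-forward network ---------------------------------------------------

.ffn_fwd <- function(x, p) {
  h_pre <- .linear_fwd(x, p$W1, p$b1)
  h <- .gelu_fwd(h_pre)
  list(y = .linear_fwd(h, p$W2, p$b2), h_pre = h_pre, h = h)
}
.ffn_bwd <- function(cache, p, x, dy) {
  l2 <- .linear_bwd(cache$h, p$W2, dy)
  dh_pre <- .gelu_bwd(cache$h_pre, l2$dx)
  l1 <- .linear_bwd(x, p$W1, dh_pre)
  list(dx = l1$dx,
       grads = list(W1 = l1$dW, b1 = l1$db, W2 = l2$dW, b2 = l2$db))
}

# ---- local-MHSA block -------------------------------------------------------
# pre-norm sub-steps with residuals:
#   LN -> W-MHSA -> +x ; LN -> FFN -> +x ; LN -> SW-MHSA -> +x ; LN -> FFN -> +x
# The shifted pass cyclically rolls the sequence by `wmap$shift` positions, so
# a fraction of every window's patches attends jointly with the neighbouring
# window's patches.

.block_fwd <- function(x, p, wmap, heads, keep_attention = FALSE) {
  c1 <- .ln_fwd(x, p$ln1$g, p$ln1$b)
  a1 <- .attn_fwd(c1$y, p$attn1, wmap, heads, 0L, keep_attention)
  x1 <- x + a1$y
  c2 <- .ln_fwd(x1, p$ln2$g, p$ln2$b)
  f1 <- .ffn_fwd(c2$y, p$ffn1)
  x2 <- x1 + f1$y
  c3 <- .ln_fwd(x2, p$ln3$g, p$ln3$b)
  a2 <- .attn_fwd(c3$y, p$attn2, wmap, heads, wmap$shift, keep_attention)
  x3 <- x2 + a2$y
  c4 <- .ln_fwd(x3, p$ln4$g, p$ln4$b)
  f2 <- .ffn_fwd(c4$y, p$ffn2)
  list(y = x3 + f2$y,
       cache = list(c1 = c1, a1 = a1, x1 = x1, c2 = c2, f1 = f1, x2 = x2,
                    c3 = c3, a2 = a2, x3 = x3, c4 = c4, f2 = f2))
}

.block_bwd <- function(cache, p, x, dy) {
  g <- list()
  b4 <- .ffn_bwd(cache$f2, p$ffn2, cache$c4$y, dy)
  l4 <- .ln_bwd(cache$c4, p$ln4$g, b4$dx)
  dx3 <- dy + l4$dx
  g$ffn2 <- b4$grads; g$ln4 <- list(g = l4$dg, b = l4$db)
  b3 <- .attn_bwd(cache$a2, p$attn2, dx3)
  l3 <- .ln_bwd(cache$c3, p$ln3$g, b3$dx)
  dx2 <- dx3 + l3$dx
  g$attn2 <- b3$grads; g$ln3 <- list(g = l3$dg, b = l3$db)
  b2 <- .ffn_bwd(cache$f1, p$ffn1, cache$c2$y, dx2)
  l2 <- .ln_bwd(cache$c2, p$ln2$g, b2$dx)
  dx1 <- dx2 + l2$dx
  g$ffn1 <- b2$grads; g$ln2 <- list(g = l2$dg, b = l2$db)
  b1 <- .attn_bwd(cache$a1, p$attn1, dx1)
  l1 <- .ln_bwd(cache$c1, p$ln1$g, b1$dx)
  dx <- dx1 + l1$dx
  g$attn1 <- b1$grads; g$ln1 <- list(g = l1$dg, b = l1$db)
  # return grads in the canonical parameter order so structures stay congruent
  g <- g[c("ln1", "attn1", "ln2", "ffn1", "ln3", "attn2", "ln4", "ffn2")]
  list(dx = dx, grads = g)
}

# ---- patch merging / partition ---------------------------------------------

# 4-to-1 merge along the canonical face hierarchy: output row f is the
# concatenation of input rows 4f..4f+3 (0-based), i.e. the children of face f
.merge_fwd <- function(x) {
  L <- nrow(x)
  if (L %% 4L != 0L) stop("sequence length must be divisible by 4 to merge")
  cbind(x[seq(1, L, 4), , drop = FALSE], x[seq(2, L, 4), , drop = FALSE],
        x[seq(3, L, 4), , drop = FALSE], x[seq(4, L, 4), , drop = FALSE])
}
.merge_bwd <- function(dy, d_in) {
  Lc <- nrow(dy)
  dx <- matrix(0, 4L * Lc, d_in)
  for (j in 1:4)
    dx[seq(j, 4L * Lc, 4), ] <- dy[, ((j - 1L) * d_in + 1L):(j * d_in),
                                   drop = FALSE]
  dx
}

# inverse 1-to-4 partition used by the decoder: each parent token is copied to
# its 4 children and concatenated with the skip token there
.partition_up_fwd <- function(x, skip) {
  if (nrow(skip) != 4L * nrow(x))
    stop("skip sequence must be 4x the length of the upsampled sequence")
  parent <- x[rep(seq_len(nrow(x)), each = 4L), , drop = FALSE]
  cbind(parent, skip)
}
.partition_up_bwd <- function(dy, d_parent) {
  dparent_rep <- dy[, seq_len(d_parent), drop = FALSE]
  L <- nrow(dy) %/% 4L
  dx <- dparent_rep[seq(1, nrow(dy), 4), , drop = FALSE] +
    dparent_rep[seq(2, nrow(dy), 4), , drop = FALSE] +
    dparent_rep[seq(3, nrow(dy), 4), , drop = FALSE] +
    dparent_rep[seq(4, nrow(dy), 4), , drop = FALSE]
  dskip <- dy[, -seq_len(d_parent), drop = FALSE]
  list(dx = dx, dskip = dskip)
}
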