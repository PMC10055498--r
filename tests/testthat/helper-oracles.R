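# Shared fixtures and independent oracles used across the suite.

# unique undirected edge count by direct enumeration
count_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nrow(unique(e))
}

# independent point-in-spherical-triangle test (same-side signed volumes)
point_in_spherical_triangle <- function(p, a, b, c, tol = 1e-9) {
  det3 <- function(x, y, z) {
    x[1] * (y[2] * z[3] - y[3] * z[2]) -
      x[2] * (y[1] * z[3] - y[3] * z[1]) +
      x[3] * (y[1] * z[2] - y[2] * z[1])
  }
  det3(a, b, p) >= -tol && det3(b, c, p) >= -tol && det3(c, a, p) >= -tol
}

# brute-force masked global attention: full L x L attention with -Inf outside
# the allowed blocks; reference for the windowed implementation
masked_attention_oracle <- function(x, p, window_of, heads) {
  L <- nrow(x)
  d <- ncol(x)
  dh <- d %/% heads
  addb <- function(m, b) m + matrix(b, nrow(m), length(b), byrow = TRUE)
  Q <- addb(x %*% p$Wq, p$bq)
  K <- addb(x %*% p$Wk, p$bk)
  V <- addb(x %*% p$Wv, p$bv)
  mask <- outer(window_of, window_of, `==`)
  O <- matrix(0, L, d)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    S[!mask] <- -Inf
    A <- exp(S - apply(S, 1, max))
    A <- A / rowSums(A)
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  addb(O %*% p$Wo, p$bo)
}

# tiny model configurations reused across tests
tiny_reg_config <- function(input_order = 2) {
  mssit_config("regression", input_order = input_order, channels = 2,
               base_dim = 4, depths = c(1, 1), heads = c(2, 2), mlp_ratio = 2)
}

random_signal <- function(order, channels = 2, seed = 1) {
  set.seed(seed)
  n <- 10 * 4^order + 2
  surface_signal(matrix(stats::rnorm(n * channels), n, channels),
                 mesh_order = order)
}

# smooth deterministic test field exercised by resampling tests
smooth_field <- function(mesh, channels = 2) {
  v <- mesh$vertices
  vals <- cbind(v[, 3], sin(2 * v[, 1]) * cos(v[, 2]))[, seq_len(channels),
                                                       drop = FALSE]
  surface_signal(vals, mesh_order = mesh$order)
}
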