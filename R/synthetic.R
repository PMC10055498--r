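# Seeded generators for spherical datasets with known structure. Signals are
# mixtures of rotated zonal spherical harmonics (Legendre polynomials of a
# dot product with a random axis, degree <= 8), which are smooth, cheap, and
# resolution independent, standing in for cortical metric maps such as sulcal
# depth or curvature. Every generator is a pure function of its spec, seed
# included.

#' Specification of a synthetic spherical dataset
#'
#' @param task `"regression"` or `"segmentation"`.
#' @param n_subjects Number of subjects, `>= 1`.
#' @param mesh_order Icosphere order of the generated signals, in `2..6`.
#' @param n_channels Channels per subject (4 emulates the usual quartet of
#'   cortical metrics).
#' @param n_regions Regions for segmentation (default 31, the size of a
#'   typical cortical parcellation atlas).
#' @param noise_sd Per-vertex Gaussian noise standard deviation, against
#'   signal components of unit scale.
#' @param seed Integer seed.
#' @param target_range Regression target range; the default 26-45 mimics
#'   postmenstrual age in weeks so downstream defaults (e.g. 1-week sampler
#'   bins) transfer.
#' @param target_dist `"skewed"` (a two-component mixture emulating the
#'   term/preterm imbalance of neonatal cohorts) or `"uniform"`.
#' @param jitter_deg Per-subject rotational jitter for segmentation, degrees.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(task = c("regression", "segmentation"),
                           n_subjects = 50, mesh_order = 6, n_channels = 4,
                           n_regions = 31, noise_sd = 0.1, seed = 0,
                           target_range = c(26, 45),
                           target_dist = c("skewed", "uniform"),
                           jitter_deg = 3) {
  task <- match.arg(task)
  target_dist <- match.arg(target_dist)
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  if (mesh_order < 2 || mesh_order > 6) stop("`mesh_order` must be in 2..6")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  n_vertices <- 10 * 4^mesh_order + 2
  if (task == "segmentation" && n_regions > n_vertices)
    stop("`n_regions` exceeds the vertex count")
  out <- list(task = task, n_subjects = as.integer(n_subjects),
              mesh_order = as.integer(mesh_order),
              n_channels = as.integer(n_channels),
              n_regions = as.integer(n_regions), noise_sd = noise_sd,
              seed = as.integer(seed), target_range = target_range,
              target_dist = target_dist, jitter_deg = jitter_deg)
  class(out) <- "synthetic_spec"
  out
}

# Legendre polynomial P_l(x) by the three-term recurrence
.legendre <- function(l, x) {
  if (l == 0) return(rep(1, length(x)))
  if (l == 1) return(x)
  pm2 <- rep(1, length(x)); pm1 <- x
  for (k in 2:l) {
    pk <- ((2 * k - 1) * x * pm1 - (k - 1) * pm2) / k
    pm2 <- pm1; pm1 <- pk
  }
  pm1
}

# a smooth random field: mixture of n_terms rotated zonal harmonics, degrees
# 1..max_degree, axes and coefficients drawn from the current RNG
.random_smooth_field <- function(vertices, n_terms = 6, max_degree = 8) {
  n <- nrow(vertices)
  out <- numeric(n)
  for (j in seq_len(n_terms)) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    l <- sample(1:max_degree, 1)
    a <- stats::rnorm(1) / sqrt(n_terms)
    out <- out + a * .legendre(l, as.vector(vertices %*% u))
  }
  out
}

.draw_targets <- function(spec) {
  a <- spec$target_range[1]; b <- spec$target_range[2]
  if (spec$target_dist == "uniform") return(stats::runif(spec$n_subjects, a, b))
  # term-dominated mixture: most subjects near the top of the range
  comp <- stats::runif(spec$n_subjects) < 0.8
  t <- ifelse(comp, stats::rnorm(spec$n_subjects, a + 0.75 * (b - a), 0.1 * (b - a)),
              stats::rnorm(spec$n_subjects, a + 0.25 * (b - a), 0.12 * (b - a)))
  pmin(pmax(t, a), b)
}

#' Generate a synthetic regression dataset
#'
#' Each subject gets a scalar target `t` and `n_channels` smooth spherical
#' fields of the form `base_c + g(t) * effect_c + noise`, where `base_c` and
#' `effect_c` are fixed (per-channel) harmonic mixtures shared across subjects
#' and `g(t)` rescales the target linearly to `[0, 1]` — so every channel
#' depends deterministically and monotonically on the target. The first
#' channel's effect field includes a `1 + z` term, making the channel-1 mean
#' over the polar cap a strictly monotone function of `t`.
#'
#' @param spec A [synthetic_spec()] with `task = "regression"`.
#' @param out_dir Output directory (created if needed).
#' @return Path of the written manifest CSV (`manifest.csv` in `out_dir`),
#'   with attribute `"targets"`.
#' @export
make_regression_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$task != "regression") stop("`spec$task` must be regression")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  mesh <- build_icosphere(spec$mesh_order)
  v <- mesh$vertices
  targets <- .draw_targets(spec)
  base_fields <- lapply(seq_len(spec$n_channels), function(c_)
    .random_smooth_field(v))
  effect_fields <- lapply(seq_len(spec$n_channels), function(c_)
    .random_smooth_field(v))
  effect_fields[[1]] <- effect_fields[[1]] + 1 + v[, 3]
  g <- (targets - spec$target_range[1]) / diff(spec$target_range)
  rows <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    vals <- vapply(seq_len(spec$n_channels), function(c_)
      base_fields[[c_]] + g[i] * effect_fields[[c_]] +
        stats::rnorm(nrow(v), 0, spec$noise_sd), numeric(nrow(v)))
    sid <- sprintf("sub-%03d", i)
    path <- file.path(out_dir, paste0(sid, ".shape.gii"))
    write_metric(surface_signal(vals, paste0("channel", seq_len(spec$n_channels)),
                                spec$mesh_order), path)
    rows[[i]] <- data.frame(subject_id = sid, metric_path = basename(path),
                            target = targets[i])
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  structure(mpath, targets = targets)
}

#' Geodesic-region reference parcellation
#'
#' Labels every vertex with its nearest (great-circle) seed point. Seeds are
#' spread with a Fibonacci lattice plus a small seeded jitter, so all regions
#' are non-empty for any sensible `n_regions`/`mesh_order` pairing.
#'
#' @param mesh An icosphere.
#' @param n_regions Number of seed points.
#' @return List with `labels` (0-based region per vertex) and `seeds`
#'   (`n_regions x 3`).
#' @export
geodesic_parcellation <- function(mesh, n_regions) {
  i <- seq_len(n_regions) - 0.5
  phi <- acos(1 - 2 * i / n_regions)
  theta <- pi * (1 + sqrt(5)) * i
  seeds <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  jit <- matrix(stats::rnorm(3 * n_regions, 0, 0.02), n_regions, 3)
  seeds <- seeds + jit
  seeds <- seeds / sqrt(rowSums(seeds^2))
  labels <- max.col(mesh$vertices %*% t(seeds), ties.method = "first") - 1L
  list(labels = labels, seeds = seeds)
}

#' Generate a synthetic parcellation dataset
#'
#' A fixed reference parcellation (nearest-seed geodesic regions) is shared
#' across subjects. Per subject, channels carry region-dependent mean levels
#' plus smooth within-region variation and noise, and a small random rotation
#' (jitter) is applied consistently to channels and labels — so the labels are
#' recoverable from the channels but subjects are not identical.
#'
#' @param spec A [synthetic_spec()] with `task = "segmentation"`.
#' @param out_dir Output directory.
#' @return Path of the written manifest CSV.
#' @export
make_parcellation_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$task != "segmentation") stop("`spec$task` must be segmentation")
  if (spec$n_regions < 2) stop("`n_regions` must be >= 2")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  mesh <- build_icosphere(spec$mesh_order)
  v <- mesh$vertices
  parc <- geodesic_parcellation(mesh, spec$n_regions)
  ref_labels <- label_map(parc$labels)
  # distinct per-region channel signatures
  levels_ <- matrix(stats::runif(spec$n_regions * spec$n_channels, -1, 1),
                    spec$n_regions, spec$n_channels)
  smooth <- vapply(seq_len(spec$n_channels), function(c_)
    .random_smooth_field(v), numeric(nrow(v)))
  rows <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    base_vals <- levels_[parc$labels + 1L, , drop = FALSE] + 0.2 * smooth
    sig <- surface_signal(base_vals, paste0("channel", seq_len(spec$n_channels)),
                          spec$mesh_order)
    lab <- ref_labels
    if (spec$jitter_deg > 0) {
      R <- rotation_matrix(stats::runif(3, -spec$jitter_deg, spec$jitter_deg))
      res <- .apply_rotation(sig, mesh, R, lab)
      sig <- res$signal
      lab <- res$labels
    }
    vals <- sig$values + matrix(stats::rnorm(length(sig$values), 0, spec$noise_sd),
                                nrow(sig$values))
    sid <- sprintf("sub-%03d", i)
    mpath_i <- file.path(out_dir, paste0(sid, ".shape.gii"))
    lpath_i <- file.path(out_dir, paste0(sid, ".label.gii"))
    write_metric(surface_signal(vals, sig$channel_names, spec$mesh_order), mpath_i)
    write_labels(lab, lpath_i)
    rows[[i]] <- data.frame(subject_id = sid, metric_path = basename(mpath_i),
                            label_path = basename(lpath_i))
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  mpath
}

#' Generate a synthetic native-resolution sphere mesh and metric
#'
#' Builds a jittered latitude/longitude (UV) sphere — a closed triangulated
#' 2-manifold with non-icosahedral connectivity — together with a smooth
#' harmonic metric, for exercising resampling from native meshes onto the
#' icosphere hierarchy.
#'
#' @param spec A [synthetic_spec()]; `mesh_order` controls the resolution
#'   (roughly matching the vertex count of that icosphere order).
#' @param out_dir Optional output directory; when given, writes
#'   `native.surf.gii` and `native.shape.gii`.
#' @return List with `mesh` (vertices + 0-based faces) and `signal`.
#' @export
make_native_mesh <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  n_target <- 10 * 4^spec$mesh_order + 2
  n_theta <- max(4L, round(sqrt(n_target / 2)))
  n_phi <- 2L * n_theta
  # rings exclude the poles; poles are added as single vertices
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  theta <- seq(0, pi, length.out = n_theta + 2L)[-c(1L, n_theta + 2L)]
  ring <- as.matrix(expand.grid(phi = phi, theta = theta))
  v <- cbind(sin(ring[, "theta"]) * cos(ring[, "phi"]),
             sin(ring[, "theta"]) * sin(ring[, "phi"]),
             cos(ring[, "theta"]))
  # small tangential jitter so the mesh is irregular but stays embedded;
  # scaled by sin(theta) because ring spacing shrinks towards the poles
  jit <- matrix(stats::rnorm(nrow(v) * 3), nrow(v), 3) *
    (0.06 * sin(ring[, "theta"]) * 2 * pi / n_phi)
  jit <- jit - v * rowSums(jit * v)
  v <- v + jit
  v <- v / sqrt(rowSums(v^2))
  np <- nrow(v)
  v <- rbind(c(0, 0, 1), v, c(0, 0, -1))       # row 1 = north, last = south
  idx <- function(i, j) 1L + (j - 1L) * n_phi + ((i - 1L) %% n_phi) + 1L
  faces <- list()
  for (i in seq_len(n_phi)) {                   # north cap (CCW from outside)
    faces[[length(faces) + 1L]] <- c(1L, idx(i, 1L), idx(i + 1L, 1L))
  }
  for (j in seq_len(n_theta - 1L)) {            # quad band split in two
    for (i in seq_len(n_phi)) {
      a <- idx(i, j); b <- idx(i + 1L, j); c_ <- idx(i, j + 1L); d <- idx(i + 1L, j + 1L)
      faces[[length(faces) + 1L]] <- c(a, c_, b)
      faces[[length(faces) + 1L]] <- c(b, c_, d)
    }
  }
  south <- np + 2L
  for (i in seq_len(n_phi)) {                   # south cap
    faces[[length(faces) + 1L]] <- c(south, idx(i + 1L, n_theta), idx(i, n_theta))
  }
  f <- do.call(rbind, faces) - 1L
  storage.mode(f) <- "integer"
  mesh <- list(vertices = v, faces = f)
  if (!all(.face_signed_det(mesh) > 0))
    stop("internal error: native mesh has inverted faces")
  metric <- .random_smooth_field(v, n_terms = 4, max_degree = 4)
  signal <- surface_signal(cbind(metric), "metric", "native")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_surface(mesh, file.path(out_dir, "native.surf.gii"))
    write_metric(signal, file.path(out_dir, "native.shape.gii"))
  }
  list(mesh = mesh, signal = signal)
}
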