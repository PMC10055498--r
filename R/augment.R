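# Surface data augmentation: random rotations and coarse-grid elastic warps.
# Both act by pulling the signal back through a deterministic geometric
# transform with barycentric resampling; label maps use the same transform
# with nearest-corner assignment so channels and labels stay consistent.

#' Augmentation configuration
#'
#' Defaults follow the training recipe used throughout the package: an
#' augmentation is applied with probability 0.8 and, when applied, is a random
#' rotation or an elastic warp with equal probability. Rotations draw one angle
#' per axis uniformly from `[-max_rotation_deg, +max_rotation_deg]` (30 degrees
#' for regression tasks, 15 for segmentation). Elastic warps displace the
#' vertices of a coarse order-2 icosphere tangentially by at most
#' `warp_max_fraction` (default 1/8) of each vertex's mean neighbour distance —
#' a bound small enough to keep the induced ico-mesh deformation
#' diffeomorphic — and interpolate the displacement field to the signal's
#' resolution.
#'
#' @param apply_probability Probability any augmentation is applied.
#' @param rotation_share Probability the applied augmentation is a rotation.
#' @param max_rotation_deg Per-axis rotation range, degrees.
#' @param warp_grid_order Icosphere order of the warp control grid.
#' @param warp_max_fraction Maximum displacement as a fraction of the mean
#'   neighbour distance, in `[0, 1)`.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(apply_probability = 0.8, rotation_share = 0.5,
                                max_rotation_deg = 30, warp_grid_order = 2,
                                warp_max_fraction = 1 / 8) {
  if (apply_probability < 0 || apply_probability > 1)
    stop("`apply_probability` must be in [0, 1]")
  if (rotation_share < 0 || rotation_share > 1)
    stop("`rotation_share` must be in [0, 1]")
  if (max_rotation_deg < 0) stop("`max_rotation_deg` must be >= 0")
  if (warp_max_fraction < 0 || warp_max_fraction >= 1)
    stop("`warp_max_fraction` must be in [0, 1)")
  out <- list(apply_probability = apply_probability,
              rotation_share = rotation_share,
              max_rotation_deg = max_rotation_deg,
              warp_grid_order = as.integer(warp_grid_order),
              warp_max_fraction = warp_max_fraction)
  class(out) <- "augmentation_config"
  out
}

#' Rotation matrix from per-axis Euler angles
#'
#' Rotations are composed in fixed x-then-y-then-z order.
#'
#' @param angles_deg Length-3 vector of rotation angles about x, y, z, degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# rotate a signal (and optionally labels) by a fixed matrix: the value at
# vertex v of the output is the input sampled at R^{-1} v
.apply_rotation <- function(signal, mesh, R, labels = NULL) {
  target <- mesh$vertices %*% R      # rows are (R^-1 v)^T since R^-1 = R^T
  out <- barycentric_resample(signal, mesh, target,
                              target_order = signal$mesh_order)
  if (is.null(labels)) return(list(signal = out, labels = NULL))
  list(signal = out,
       labels = resample_labels(labels, mesh, target))
}

#' Randomly rotate a surface signal
#'
#' Draws one angle per axis uniformly from `[-max_deg, +max_deg]` (composed
#' x-then-y-then-z) and pulls the signal back through the rotation with
#' barycentric resampling. `max_deg = 0` returns the input exactly.
#'
#' @param signal A [surface_signal()] on `mesh`.
#' @param mesh The icosphere the signal lives on.
#' @param max_deg Per-axis rotation range in degrees.
#' @param labels Optional [label_map()] transformed consistently
#'   (nearest-corner assignment).
#' @return If `labels` is `NULL`, the rotated [surface_signal()]; otherwise a
#'   list with elements `signal` and `labels`.
#' @export
random_rotation <- function(signal, mesh, max_deg, labels = NULL) {
  if (max_deg == 0) {
    return(if (is.null(labels)) signal else list(signal = signal, labels = labels))
  }
  angles <- stats::runif(3, -max_deg, max_deg)
  res <- .apply_rotation(signal, mesh, rotation_matrix(angles), labels)
  if (is.null(labels)) res$signal else res
}

# mean great-circle distance from each vertex to its mesh neighbours
.mean_neighbour_distance <- function(mesh) {
  f <- mesh$faces + 1L
  # each undirected edge appears once per direction across the oriented faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  d <- acos(pmin(1, pmax(-1, rowSums(mesh$vertices[e[, 1], , drop = FALSE] *
                                       mesh$vertices[e[, 2], , drop = FALSE]))))
  as.vector(tapply(d, factor(e[, 1], levels = seq_len(nrow(mesh$vertices))),
                   mean))
}

# draw the tangential control-point displacements for an elastic warp:
# returns |V_grid| x 3 matrix with per-vertex norm <= max_fraction * mean
# neighbour distance (chord displacement of the reprojected vertex is smaller)
.warp_field <- function(grid_mesh, max_fraction) {
  v <- grid_mesh$vertices
  n <- nrow(v)
  nb <- .mean_neighbour_distance(grid_mesh)
  raw <- matrix(stats::rnorm(3 * n), n, 3)
  tang <- raw - v * rowSums(raw * v)            # project out the radial part
  nrm <- sqrt(rowSums(tang^2))
  nrm[nrm < 1e-12] <- 1
  mag <- stats::runif(n, 0, max_fraction) * nb
  tang / nrm * mag
}

# warped positions of arbitrary unit directions under a control-grid field
.warp_points <- function(points, grid_mesh, disp) {
  field <- surface_signal(disp, c("dx", "dy", "dz"), grid_mesh$order)
  d <- barycentric_resample(field, grid_mesh, points)$values
  w <- points + d
  w / sqrt(rowSums(w^2))
}

#' Elastic warp of a surface signal
#'
#' Displaces the vertices of a coarse control icosphere (order
#' `config$warp_grid_order`) by random tangential vectors bounded by
#' `config$warp_max_fraction` of the local neighbour distance, interpolates the
#' displacement field barycentrically to the signal's resolution, and resamples
#' the signal through the warped coordinates. A zero bound is the identity.
#'
#' @inheritParams random_rotation
#' @param config An [augmentation_config()].
#' @return As [random_rotation()].
#' @export
elastic_warp <- function(signal, mesh, config, labels = NULL) {
  if (mesh$order <= config$warp_grid_order)
    stop("the signal mesh must be finer than the warp control grid")
  if (config$warp_max_fraction == 0) {
    return(if (is.null(labels)) signal else list(signal = signal, labels = labels))
  }
  grid_mesh <- build_icosphere(config$warp_grid_order)
  disp <- .warp_field(grid_mesh, config$warp_max_fraction)
  target <- .warp_points(mesh$vertices, grid_mesh, disp)
  out <- barycentric_resample(signal, mesh, target,
                              target_order = signal$mesh_order)
  if (is.null(labels)) return(out)
  list(signal = out, labels = resample_labels(labels, mesh, target))
}

#' Apply one random surface augmentation
#'
#' With probability `config$apply_probability` applies exactly one transform —
#' a random rotation with probability `config$rotation_share`, otherwise an
#' elastic warp — and returns the input unchanged the rest of the time.
#' Randomness comes from R's global RNG; seed it for reproducibility.
#'
#' @param signal A [surface_signal()] on a canonical icosphere.
#' @param config An [augmentation_config()].
#' @param labels Optional [label_map()] transformed consistently.
#' @return A list with `signal`, `labels` (possibly `NULL`), `applied`
#'   (logical) and `kind` (`"rotation"`, `"warp"` or `"none"`).
#' @export
augment <- function(signal, config, labels = NULL) {
  stopifnot(inherits(config, "augmentation_config"))
  if (stats::runif(1) >= config$apply_probability)
    return(list(signal = signal, labels = labels, applied = FALSE, kind = "none"))
  mesh <- build_icosphere(signal$mesh_order)
  if (stats::runif(1) < config$rotation_share) {
    res <- random_rotation(signal, mesh, config$max_rotation_deg, labels)
    if (is.null(labels)) res <- list(signal = res, labels = NULL)
    c(res, list(applied = TRUE, kind = "rotation"))
  } else {
    res <- elastic_warp(signal, mesh, config, labels)
    if (is.null(labels)) res <- list(signal = res, labels = NULL)
    c(res, list(applied = TRUE, kind = "warp"))
  }
}
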