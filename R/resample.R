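# Barycentric resampling of spherical signals. A signal on a closed
# triangulated sphere is evaluated at arbitrary unit directions by locating
# the face hit by the ray from the origin and interpolating the three corner
# values with the barycentric weights of the radial projection onto the face
# plane. Exact for constants (weights sum to one) and the identity when the
# target points coincide with source vertices.

# barycentric weights of directions p within faces (0-based ids) of mesh;
# returns list(corners = n x 3 vertex ids (0-based), weights = n x 3)
.bary_weights <- function(mesh, face_ids, p) {
  v <- mesh$vertices
  tri <- mesh$faces[face_ids + 1L, , drop = FALSE] + 1L
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  c_ <- v[tri[, 3], , drop = FALSE]
  w1 <- rowSums(p * .cross_rows(b, c_))
  w2 <- rowSums(p * .cross_rows(c_, a))
  w3 <- rowSums(p * .cross_rows(a, b))
  s <- w1 + w2 + w3
  bad <- which(abs(s) < 1e-12)
  if (length(bad) > 0)
    stop(sprintf("degenerate source face hit during resampling (face id %d)",
                 face_ids[bad[1]]))
  w <- cbind(w1, w2, w3) / s
  # clamp tiny negatives from edge hits so outputs stay convex combinations
  w[w < 0] <- 0
  w <- w / rowSums(w)
  list(corners = tri - 1L, weights = w)
}

# face containing each direction for an arbitrary closed sphere mesh:
# exhaustive max-min-edge-determinant scan (vectorised over points per face)
.locate_faces_generic <- function(mesh, p) {
  v <- mesh$vertices
  f <- mesh$faces + 1L
  n <- nrow(p)
  best <- rep.int(-Inf, n)
  cur <- integer(n)
  for (fi in seq_len(nrow(f))) {
    a <- matrix(v[f[fi, 1], ], n, 3, byrow = TRUE)
    b <- matrix(v[f[fi, 2], ], n, 3, byrow = TRUE)
    c_ <- matrix(v[f[fi, 3], ], n, 3, byrow = TRUE)
    d <- .min_edge_det(p, a, b, c_)
    upd <- d > best
    best[upd] <- d[upd]
    cur[upd] <- fi - 1L
  }
  cur
}

.is_canonical_icosphere <- function(mesh) {
  if (!inherits(mesh, "icosphere") || is.null(mesh$order)) return(FALSE)
  ref <- build_icosphere(mesh$order)
  nrow(mesh$vertices) == nrow(ref$vertices) &&
    max(abs(mesh$vertices - ref$vertices)) < 1e-9
}

# interpolation operator from a source mesh onto target directions
.resample_operator <- function(source_mesh, target_points) {
  p <- target_points / sqrt(rowSums(target_points^2))
  fids <- if (.is_canonical_icosphere(source_mesh))
    locate_faces(p, source_mesh$order)
  else .locate_faces_generic(source_mesh, p)
  .bary_weights(source_mesh, fids, p)
}

#' Barycentric resampling of a surface signal
#'
#' Interpolates `signal` (living on the vertices of `source_mesh`) at arbitrary
#' unit directions. Canonical icospheres use fast hierarchical face lookup;
#' any other closed triangulated sphere falls back to an exhaustive scan.
#'
#' @param signal A [surface_signal()] with one row per `source_mesh` vertex.
#' @param source_mesh Mesh list with `vertices`/`faces` (0-based).
#' @param target_points `n x 3` matrix of directions (normalised internally).
#' @param target_order Mesh order recorded on the output signal (defaults to
#'   `"native"`).
#' @return A [surface_signal()] with `n` rows.
#' @export
barycentric_resample <- function(signal, source_mesh, target_points,
                                 target_order = "native") {
  stopifnot(inherits(signal, "surface_signal"))
  if (nrow(signal$values) != nrow(source_mesh$vertices))
    stop(sprintf("signal has %d rows but the source mesh has %d vertices",
                 nrow(signal$values), nrow(source_mesh$vertices)))
  op <- .resample_operator(source_mesh, target_points)
  vals <- .apply_operator(op, signal$values)
  surface_signal(vals, signal$channel_names, mesh_order = target_order)
}

.apply_operator <- function(op, values) {
  w <- op$weights
  idx <- op$corners + 1L
  values[idx[, 1], , drop = FALSE] * w[, 1] +
    values[idx[, 2], , drop = FALSE] * w[, 2] +
    values[idx[, 3], , drop = FALSE] * w[, 3]
}

# categorical signals: take the corner with the largest barycentric weight
.apply_operator_labels <- function(op, labels) {
  pick <- max.col(op$weights, ties.method = "first")
  corner <- op$corners[cbind(seq_len(nrow(op$corners)), pick)]
  labels[corner + 1L]
}

#' Resample a label map between spherical meshes
#'
#' Labels are categorical, so each target vertex takes the label of the source
#' face corner with the largest barycentric weight (nearest corner). Target
#' points coinciding with source vertices keep their label exactly.
#'
#' @param map A [label_map()] on the vertices of `source_mesh`.
#' @param source_mesh Mesh list.
#' @param target_points `n x 3` matrix of directions.
#' @return A [label_map()] of length `n` with the same label table.
#' @export
resample_labels <- function(map, source_mesh, target_points) {
  stopifnot(inherits(map, "label_map"))
  op <- .resample_operator(source_mesh, target_points)
  label_map(.apply_operator_labels(op, map$labels), map$label_table)
}
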