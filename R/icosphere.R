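# Nested icosahedral tessellations of the unit sphere, with the canonical
# vertex/face ordering that the rest of the architecture relies on:
#   - subdivision appends edge-midpoint vertices after all existing vertices,
#     so the order-(k-1) vertices are a prefix of the order-k vertices;
#   - the four children of face f are stored at indices 4f..4f+3, so windows
#     are contiguous runs and patch merging is a stride-4 regrouping.
# Face and vertex ids are 0-based throughout the index-map API (matching
# GIFTI array semantics); R matrices are indexed with the usual +1 internally.

#' Construct a subdivided icosphere
#'
#' Builds the order-`k` icosahedral tessellation of the unit sphere by `k`
#' rounds of 4-to-1 face subdivision of a fixed base icosahedron (poles on the
#' z-axis), projecting every new vertex back onto the sphere. The construction
#' is deterministic: repeated calls return identical meshes.
#'
#' The mesh satisfies `|V| = 10 * 4^k + 2`, `|F| = 20 * 4^k`, and the vertices
#' of the order-`(k-1)` mesh are a prefix (same index, same coordinates) of the
#' order-`k` vertices.
#'
#' @param order Integer subdivision level, `>= 0`.
#' @return An object of class `icosphere`: a list with `order`, `vertices`
#'   (`|V| x 3` matrix of unit vectors), `faces` (`|F| x 3` integer matrix of
#'   0-based vertex ids, outward oriented), and `face_mids` (`|F| x 3` matrix
#'   giving, for each face of the *previous* order, the 0-based indices of its
#'   three edge midpoints in this mesh; `NULL` for order 0).
#' @export
build_icosphere <- function(order) {
  if (length(order) != 1L || is.na(order) || order != as.integer(order) || order < 0)
    stop("`order` must be a single non-negative integer")
  order <- as.integer(order)
  cached <- .ico_cache_get(order)
  if (!is.null(cached)) return(cached)
  mesh <- .base_icosahedron()
  if (order > 0) {
    for (k in seq_len(order)) {
      prev <- .ico_cache_get(k - 1L)
      if (is.null(prev)) prev <- mesh
      mesh <- .subdivide_icosphere(prev)
      .ico_cache_set(k, mesh)
    }
  } else {
    .ico_cache_set(0L, mesh)
  }
  .ico_cache_get(order)
}

# memoised meshes: orders are rebuilt constantly by resampling and tests
.ico_env <- new.env(parent = emptyenv())
.ico_cache_get <- function(order) {
  key <- as.character(order)
  if (exists(key, envir = .ico_env, inherits = FALSE)) get(key, envir = .ico_env) else NULL
}
.ico_cache_set <- function(order, mesh) {
  assign(as.character(order), mesh, envir = .ico_env)
  invisible(NULL)
}

.base_icosahedron <- function() {
  # canonical orientation: two vertices on the +/- z poles, two 5-rings between
  z <- 1 / sqrt(5)
  r <- 2 / sqrt(5)
  ang1 <- 2 * pi * (0:4) / 5
  ang2 <- ang1 + pi / 5
  v <- rbind(
    c(0, 0, 1),
    cbind(r * cos(ang1), r * sin(ang1), z),
    cbind(r * cos(ang2), r * sin(ang2), -z),
    c(0, 0, -1)
  )
  nxt <- c(2:5, 1)
  f <- matrix(0L, 20, 3)
  for (i in 1:5) {
    a <- i; b <- nxt[i]                      # ring-1 ids 1..5 -> rows 2..6
    c1 <- 5 + i; c2 <- 5 + nxt[i]            # ring-2 ids 6..10 -> rows 7..11
    f[i, ]      <- c(0L, a, b)               # top cap
    f[5 + i, ]  <- c(a, c1, b)               # upper band
    f[10 + i, ] <- c(b, c1, c2)              # lower band
    f[15 + i, ] <- c(11L, c2, c1)            # bottom cap
  }
  storage.mode(f) <- "integer"
  mesh <- list(order = 0L, vertices = v, faces = f, face_mids = NULL)
  class(mesh) <- "icosphere"
  stopifnot(all(.face_signed_det(mesh) > 0))
  mesh
}

# one 4-to-1 subdivision round; midpoints are deduplicated via a sorted
# vertex-pair key so shared vertices are created exactly once (nesting)
.subdivide_icosphere <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nf <- nrow(f)
  mid_env <- new.env(parent = emptyenv(), size = 4L * nf)
  new_pts <- vector("list", 3L * nf)
  n_new <- 0L
  nv0 <- nrow(v)
  midpoint <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    id <- mid_env[[key]]
    if (!is.null(id)) return(id)
    p <- v[i + 1L, ] + v[j + 1L, ]
    p <- p / sqrt(sum(p * p))
    n_new <<- n_new + 1L
    new_pts[[n_new]] <<- p
    id <- nv0 + n_new - 1L
    mid_env[[key]] <- id
    id
  }
  child_f <- matrix(0L, 4L * nf, 3L)
  face_mids <- matrix(0L, nf, 3L)
  for (fi in seq_len(nf)) {
    a <- f[fi, 1L]; b <- f[fi, 2L]; c <- f[fi, 3L]
    mab <- midpoint(a, b); mbc <- midpoint(b, c); mca <- midpoint(c, a)
    base <- 4L * (fi - 1L)
    child_f[base + 1L, ] <- c(a, mab, mca)
    child_f[base + 2L, ] <- c(b, mbc, mab)
    child_f[base + 3L, ] <- c(c, mca, mbc)
    child_f[base + 4L, ] <- c(mab, mbc, mca)
    face_mids[fi, ] <- c(mab, mbc, mca)
  }
  storage.mode(child_f) <- "integer"
  storage.mode(face_mids) <- "integer"
  out <- list(
    order = mesh$order + 1L,
    vertices = rbind(v, do.call(rbind, new_pts[seq_len(n_new)])),
    faces = child_f,
    face_mids = face_mids
  )
  class(out) <- "icosphere"
  out
}

#' @export
print.icosphere <- function(x, ...) {
  cat(sprintf("icosphere of order %d: %d vertices, %d faces\n",
              x$order, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Children of a face under icosphere subdivision
#'
#' Under the canonical nesting convention the four order-`(order+1)` faces that
#' tile face `face_id` of the order-`order` mesh are `4*face_id .. 4*face_id+3`.
#'
#' @param face_id 0-based face id(s) at level `order`.
#' @param order Subdivision order of the parent mesh.
#' @return Integer matrix with one row per input id and 4 columns of 0-based
#'   child face ids (a plain vector for a single id).
#' @export
face_children <- function(face_id, order) {
  nf <- 20L * 4L^order
  if (any(face_id < 0 | face_id >= nf | face_id != floor(face_id)))
    stop(sprintf("`face_id` must be an integer in [0, %d)", nf))
  out <- outer(as.integer(4 * face_id), 0:3, `+`)
  if (length(face_id) == 1L) as.integer(out[1L, ]) else out
}

#' Patch partition of a fine icosphere by the next-coarser one
#'
#' Each face of the coarse mesh covers a patch of 6 fine-mesh vertices: its 3
#' corners plus the 3 edge midpoints created by subdivision. Patches tile the
#' fine vertex set (boundary vertices are shared between neighbouring patches
#' but every fine face belongs to exactly one patch).
#'
#' @param fine Icosphere of order `k`.
#' @param coarse Icosphere of order `k - 1`.
#' @return An object of class `patch_partition`: list with `fine_order`,
#'   `coarse_order`, and `patch_vertex_ids`, a `|F_coarse| x 6` integer matrix
#'   of 0-based fine-mesh vertex ids ordered corners then midpoints (midpoint
#'   `i` opposite corner `i`).
#' @export
build_patch_partition <- function(fine, coarse) {
  stopifnot(inherits(fine, "icosphere"), inherits(coarse, "icosphere"))
  if (fine$order != coarse$order + 1L)
    stop(sprintf("`fine` order (%d) must be `coarse` order (%d) + 1",
                 fine$order, coarse$order))
  # the fine mesh of the canonical hierarchy records its parents' midpoints
  sub <- if (!is.null(fine$face_mids) && nrow(fine$face_mids) == nrow(coarse$faces))
    fine else .subdivide_icosphere(coarse)
  corners <- coarse$faces
  mids <- sub$face_mids                     # columns: mab, mbc, mca
  # opposite-corner order: corner a <-> mbc, b <-> mca, c <-> mab
  ids <- cbind(corners, mids[, c(2L, 3L, 1L), drop = FALSE])
  storage.mode(ids) <- "integer"
  out <- list(fine_order = fine$order, coarse_order = coarse$order,
              patch_vertex_ids = ids)
  class(out) <- "patch_partition"
  out
}

#' Window map for one encoder level
#'
#' At level `l` the token sequence is indexed by the faces of the icosphere of
#' order `input_order - l`, and attention windows are the faces of the mesh
#' `window_depth` further subdivision levels down (64 patches per window for
#' the default depth of 3). When that coarser mesh does not exist the level
#' uses a single global window — for a 6th-order input this happens exactly at
#' level 4, where attention is global over the 320 positions of the order-2
#' grid. Under the canonical face ordering each window is a contiguous run of
#' positions, so the assignment is pure index arithmetic.
#'
#' @param level Encoder level in `1..4`.
#' @param shift_fraction Fraction of the window size the shifted-attention pass
#'   rolls the sequence by (default 0.5, i.e. half a window).
#' @param input_order Order of the input icosphere (default 6).
#' @param window_depth How many subdivision levels below the sequence grid the
#'   window grid sits (default 3, i.e. 4^3 = 64 patches per window).
#' @return An object of class `window_map`: list with `level`, `grid_order`,
#'   `seq_len`, `window_size`, `n_windows`, `window_of` (length-`seq_len`
#'   integer vector of 0-based window ids for positions `0..seq_len-1`), and
#'   `shift` (`round(shift_fraction * window_size)` positions).
#' @export
build_window_map <- function(level, shift_fraction = 0.5, input_order = 6,
                             window_depth = 3) {
  if (length(level) != 1L || is.na(level) || level != as.integer(level) ||
      level < 1L || level > 4L)
    stop("`level` must be an integer in 1..4")
  if (shift_fraction < 0 || shift_fraction >= 1)
    stop("`shift_fraction` must be in [0, 1)")
  g <- input_order - level
  if (g < 0) stop("`level` exceeds the input order")
  seq_len_ <- as.integer(20 * 4^g)
  wo <- g - window_depth
  if (wo < 0L) {
    ws <- seq_len_                      # global attention window
  } else {
    ws <- as.integer(4L^window_depth)
  }
  positions <- 0:(seq_len_ - 1L)
  out <- list(
    level = as.integer(level),
    grid_order = as.integer(g),
    seq_len = seq_len_,
    window_size = as.integer(ws),
    n_windows = as.integer(seq_len_ %/% ws),
    window_of = as.integer(positions %/% ws),
    shift = as.integer(round(shift_fraction * ws))
  )
  class(out) <- "window_map"
  out
}

# ---- geometric helpers ------------------------------------------------------

# row-wise cross product of two n x 3 matrices
.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# signed triple product det[a; b; c] per face: positive = outward orientation
.face_signed_det <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces + 1L
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  rowSums(a * .cross_rows(b, c_))
}

#' Face centroids projected to the sphere
#' @param mesh An `icosphere` (or any mesh list with `vertices`/`faces`).
#' @return `|F| x 3` matrix of unit vectors.
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces + 1L
  c_ <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  c_ / sqrt(rowSums(c_^2))
}

# for points p and triangles (a, b, c): the minimum of the three signed dets
# det[a,b,p], det[b,c,p], det[c,a,p]; >= 0 (up to tol) iff p lies inside the
# spherical triangle of an outward-oriented face
.min_edge_det <- function(p, a, b, c) {
  pmin(rowSums(.cross_rows(a, b) * p),
       pmin(rowSums(.cross_rows(b, c) * p),
            rowSums(.cross_rows(c, a) * p)))
}

#' Locate the icosphere face containing each query direction
#'
#' Hierarchical descent through the nested face hierarchy: the containing base
#' face is found among the 20 order-0 faces, then refined through the 4
#' children per level. Ties on edges resolve to the face with the largest
#' minimum edge determinant, making the result deterministic.
#'
#' @param points `n x 3` matrix of (non-zero) direction vectors.
#' @param order Icosphere order to locate within.
#' @return Integer vector of 0-based face ids at level `order`.
#' @export
locate_faces <- function(points, order) {
  p <- points / sqrt(rowSums(points^2))
  n <- nrow(p)
  base <- build_icosphere(0L)
  best <- rep.int(-Inf, n)
  cur <- integer(n)
  v0 <- base$vertices
  for (fi in 0:19) {
    tri <- base$faces[fi + 1L, ] + 1L
    a <- matrix(v0[tri[1], ], n, 3, byrow = TRUE)
    b <- matrix(v0[tri[2], ], n, 3, byrow = TRUE)
    c_ <- matrix(v0[tri[3], ], n, 3, byrow = TRUE)
    d <- .min_edge_det(p, a, b, c_)
    upd <- d > best
    best[upd] <- d[upd]
    cur[upd] <- fi
  }
  if (order == 0L) return(cur)
  for (k in seq_len(order)) {
    mesh <- build_icosphere(k)
    v <- mesh$vertices
    best <- rep.int(-Inf, n)
    nxt <- integer(n)
    for (j in 0:3) {
      fid <- 4L * cur + j
      tri <- mesh$faces[fid + 1L, , drop = FALSE] + 1L
      d <- .min_edge_det(p, v[tri[, 1], , drop = FALSE],
                         v[tri[, 2], , drop = FALSE],
                         v[tri[, 3], , drop = FALSE])
      upd <- d > best
      best[upd] <- d[upd]
      nxt[upd] <- fid[upd]
    }
    cur <- nxt
  }
  cur
}

#' Export index tables for inspection
#'
#' Writes `patch_vertex_ids` of a [build_patch_partition()] result or the
#' `window_of` vector of a [build_window_map()] result as plain CSV.
#'
#' @param x A `patch_partition` or `window_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(x, path) {
  if (inherits(x, "patch_partition")) {
    df <- as.data.frame(x$patch_vertex_ids)
    names(df) <- c("corner1", "corner2", "corner3", "mid1", "mid2", "mid3")
    df <- cbind(patch = seq_len(nrow(df)) - 1L, df)
  } else if (inherits(x, "window_map")) {
    df <- data.frame(position = seq_len(x$seq_len) - 1L, window = x$window_of)
  } else stop("`x` must be a patch_partition or window_map")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
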