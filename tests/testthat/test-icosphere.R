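test_that("icosphere counts, unit vertices, orientation and Euler characteristic", {
  for (k in 0:4) {
    m <- build_icosphere(k)
    nv <- nrow(m$vertices)
    nf <- nrow(m$faces)
    ne <- count_edges(m)
    expect_identical(nv, as.integer(10 * 4^k + 2))
    expect_identical(nf, as.integer(20 * 4^k))
    expect_identical(ne, as.integer(30 * 4^k))
    expect_identical(nv - ne + nf, 2L)
    expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 1)), 1e-9)
    expect_true(all(mssit:::.face_signed_det(m) > 0))
  }
  expect_identical(nrow(build_icosphere(5)$vertices), 10242L)
  expect_identical(nrow(build_icosphere(5)$faces), 20480L)
  expect_identical(nrow(build_icosphere(6)$vertices), 40962L)
  expect_error(build_icosphere(-1), "non-negative")
})

test_that("subdivision is deterministic and nests vertex prefixes", {
  a <- build_icosphere(3)
  b <- mssit:::.subdivide_icosphere(
    mssit:::.subdivide_icosphere(
      mssit:::.subdivide_icosphere(mssit:::.base_icosahedron())))
  expect_equal(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  for (k in 1:5) {
    fine <- build_icosphere(k)
    coarse <- build_icosphere(k - 1)
    expect_lt(max(abs(fine$vertices[seq_len(nrow(coarse$vertices)), ] -
                        coarse$vertices)), 1e-9)
  }
})

test_that("face_children follows the 4f..4f+3 convention and children lie inside parents", {
  expect_identical(face_children(0, 3), c(0L, 1L, 2L, 3L))
  expect_identical(face_children(7, 2), c(28L, 29L, 30L, 31L))
  expect_error(face_children(20, 0), "face_id")
  expect_error(face_children(-1, 2), "face_id")
  # geometric containment of child centroids in the parent spherical triangle
  for (k in c(1, 4)) {
    parent <- build_icosphere(k - 1)
    child <- build_icosphere(k)
    cents <- face_centroids(child)
    v <- parent$vertices
    for (fi in seq_len(nrow(parent$faces))) {
      tri <- parent$faces[fi, ] + 1
      for (cf in face_children(fi - 1, k - 1)) {
        expect_true(point_in_spherical_triangle(
          cents[cf + 1, ], v[tri[1], ], v[tri[2], ], v[tri[3], ]))
      }
    }
  }
})

test_that("patch partition has 6 ordered vertices per coarse face and tiles the fine mesh", {
  fine <- build_icosphere(1)
  coarse <- build_icosphere(0)
  pp <- build_patch_partition(fine, coarse)
  expect_identical(dim(pp$patch_vertex_ids), c(20L, 6L))
  expect_identical(sort(unique(as.vector(pp$patch_vertex_ids))), 0:41)
  # corners are the coarse face vertices themselves
  expect_identical(pp$patch_vertex_ids[, 1:3], coarse$faces)
  expect_error(build_patch_partition(build_icosphere(2), coarse), "order")

  # geometric containment: all 6 patch vertices lie on/in the coarse triangle
  fine5 <- build_icosphere(5)
  coarse4 <- build_icosphere(4)
  pp5 <- build_patch_partition(fine5, coarse4)
  v <- coarse4$vertices
  vf <- fine5$vertices
  ok <- TRUE
  for (fi in seq_len(nrow(coarse4$faces))) {
    tri <- coarse4$faces[fi, ] + 1
    for (vid in pp5$patch_vertex_ids[fi, ]) {
      ok <- ok && point_in_spherical_triangle(
        vf[vid + 1, ], v[tri[1], ], v[tri[2], ], v[tri[3], ], tol = 1e-7)
    }
  }
  expect_true(ok)
})

test_that("window maps partition positions into contiguous windows with the right sizes", {
  wm1 <- build_window_map(1)
  expect_identical(wm1$seq_len, 20480L)
  expect_identical(wm1$window_size, 64L)
  expect_identical(wm1$n_windows, 320L)
  expect_identical(wm1$shift, 32L)
  expect_identical(tabulate(wm1$window_of + 1L), rep(64L, 320L))
  wm4 <- build_window_map(4)
  expect_identical(wm4$seq_len, 320L)
  expect_identical(wm4$window_size, 320L)
  expect_identical(wm4$n_windows, 1L)
  expect_error(build_window_map(0), "level")
  expect_error(build_window_map(5), "level")
  expect_error(build_window_map(1, shift_fraction = 1), "shift_fraction")
})

test_that("index-arithmetic window assignment matches geometric centroid containment", {
  # sequence positions at level 2 are order-4 faces; their window is the
  # order-1 face containing the patch centroid
  wm <- build_window_map(2)
  cents <- face_centroids(build_icosphere(4))
  geom <- locate_faces(cents, 1)
  expect_identical(wm$window_of, geom)
})

test_that("merge-then-window grouping equals direct coarse-window grouping", {
  # grouping level-l positions by children of level-(l+1) positions, then by
  # the level-(l+1) windows, must equal grouping level-l positions directly by
  # the level-(l+1) window's faces three orders down
  wm_next <- build_window_map(3)
  wm_cur <- build_window_map(2)
  parent_of <- (seq_len(wm_cur$seq_len) - 1L) %/% 4L
  via_merge <- wm_next$window_of[parent_of + 1L]
  # direct geometric route: order-4 centroids located on the order-0 window grid
  direct <- locate_faces(face_centroids(build_icosphere(4)), 0)
  expect_identical(via_merge, direct)
})

test_that("index tables export as CSV", {
  pp <- build_patch_partition(build_icosphere(1), build_icosphere(0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_index_table(pp, path)
  df <- read.csv(path)
  expect_identical(nrow(df), 20L)
  expect_identical(df$corner1, pp$patch_vertex_ids[, 1])
})
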