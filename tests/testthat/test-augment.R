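test_that("zero-magnitude transforms are exact identities", {
  m3 <- build_icosphere(3)
  sig <- smooth_field(m3)
  expect_identical(random_rotation(sig, m3, 0)$values, sig$values)
  cfg0 <- augmentation_config(warp_max_fraction = 0)
  expect_identical(elastic_warp(sig, m3, cfg0)$values, sig$values)
  cfg_off <- augmentation_config(apply_probability = 0)
  set.seed(1)
  for (i in 1:20) {
    out <- augment(sig, cfg_off)
    expect_false(out$applied)
    expect_identical(out$signal$values, sig$values)
  }
})

test_that("constant fields are invariant under any rotation", {
  m3 <- build_icosphere(3)
  const <- surface_signal(matrix(4.2, 642, 1), mesh_order = 3)
  set.seed(2)
  out <- random_rotation(const, m3, 30)
  expect_lt(max(abs(out$values - 4.2)), 1e-12)
})

test_that("rotating by R then R^-1 deviates less than the two interpolation steps combined", {
  m4 <- build_icosphere(4)
  sig <- smooth_field(m4)
  R <- rotation_matrix(c(17, -23, 9))
  fwd <- mssit:::.apply_rotation(sig, m4, R)$signal
  back <- mssit:::.apply_rotation(fwd, m4, t(R))$signal
  # one-step interpolation errors measured against the analytic rotated field
  exact_fwd <- smooth_field(list(vertices = m4$vertices %*% R, order = 4))
  e1 <- max(abs(fwd$values - exact_fwd$values))
  # bound: ||back - sig|| <= e1 (carried) + e2 (second interpolation step)
  exact_fwd_sig <- surface_signal(exact_fwd$values, sig$channel_names, 4)
  e2 <- max(abs(mssit:::.apply_rotation(exact_fwd_sig, m4, t(R))$signal$values -
                  sig$values))
  expect_lt(max(abs(back$values - sig$values)), e1 + e2 + 1e-12)
  expect_gt(e1, 0)
})

test_that("warp control displacements respect the 1/8 neighbour-distance bound", {
  grid <- build_icosphere(2)
  nb <- mssit:::.mean_neighbour_distance(grid)
  set.seed(4)
  for (i in 1:1000) {
    d <- mssit:::.warp_field(grid, 1 / 8)
    expect_true(all(sqrt(rowSums(d^2)) <= nb / 8 + 1e-12))
    # displacements are tangential before reprojection
    expect_lt(max(abs(rowSums(d * grid$vertices))), 1e-9)
  }
})

test_that("elastic warps never invert faces of the warped mesh", {
  grid <- build_icosphere(2)
  set.seed(5)
  for (ord in c(4L, 6L)) {
    m <- build_icosphere(ord)
    n_draws <- if (ord == 6L) 2 else 20
    for (i in seq_len(n_draws)) {
      disp <- mssit:::.warp_field(grid, 1 / 8)
      warped <- mssit:::.warp_points(m$vertices, grid, disp)
      expect_true(all(mssit:::.face_signed_det(
        list(vertices = warped, faces = m$faces)) > 0))
    }
  }
})

test_that("augmentation application and rotation/warp frequencies match the recipe", {
  sig <- random_signal(2, channels = 1, seed = 6)
  cfg <- augmentation_config(warp_grid_order = 0, max_rotation_deg = 10)
  n <- 10000
  set.seed(7)
  kinds <- character(n)
  for (i in seq_len(n)) kinds[i] <- augment(sig, cfg)$kind
  p_applied <- mean(kinds != "none")
  se_a <- sqrt(0.8 * 0.2 / n)
  expect_lt(abs(p_applied - 0.8), 3 * se_a)
  p_rot <- mean(kinds == "rotation") / p_applied
  se_r <- sqrt(0.5 * 0.5 / sum(kinds != "none"))
  expect_lt(abs(p_rot - 0.5), 3 * se_r)
})

test_that("augmentation is deterministic under a fixed seed and label-consistent", {
  sig <- random_signal(3, channels = 2, seed = 8)
  m3 <- build_icosphere(3)
  set.seed(123)
  labs <- label_map(sample(0:4, 642, TRUE))
  cfg <- augmentation_config(apply_probability = 1)
  set.seed(99); a <- augment(sig, cfg, labels = labs)
  set.seed(99); b <- augment(sig, cfg, labels = labs)
  expect_identical(a$signal$values, b$signal$values)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$kind, b$kind)
  # identity transform leaves labels untouched
  expect_identical(resample_labels(labs, m3, m3$vertices)$labels, labs$labels)
})
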