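test_that("tokenisation flattens patches channel-by-channel in canonical order", {
  sig <- random_signal(2, channels = 3, seed = 1)
  pp <- build_patch_partition(build_icosphere(2), build_icosphere(1))
  X <- tokenize(sig, pp)
  expect_identical(dim(X), c(80L, 18L))
  # independent gather oracle
  set.seed(2)
  for (i in sample(80, 10)) {
    expected <- as.vector(sapply(1:3, function(ch)
      sig$values[pp$patch_vertex_ids[i, ] + 1, ch]))
    expect_equal(X[i, ], expected, ignore_attr = TRUE)
  }
  const <- surface_signal(matrix(1.5, 162, 2), mesh_order = 2)
  Xc <- tokenize(const, pp)
  expect_true(all(Xc == 1.5))
  expect_error(tokenize(random_signal(3), pp), "rows")
})

test_that("patch merging concatenates the 4 children of each coarse face", {
  set.seed(3)
  x <- matrix(rnorm(80 * 5), 80, 5)
  y <- mssit:::.merge_fwd(x)
  expect_identical(dim(y), c(20L, 20L))
  for (f in c(0L, 7L, 19L)) {
    kids <- face_children(f, 1)
    expect_equal(y[f + 1, ], c(x[kids[1] + 1, ], x[kids[2] + 1, ],
                               x[kids[3] + 1, ], x[kids[4] + 1, ]),
                 ignore_attr = TRUE)
  }
  const <- matrix(2, 80, 3)
  expect_true(all(mssit:::.merge_fwd(const) == 2))
  expect_error(mssit:::.merge_fwd(matrix(0, 81, 2)), "divisible")
})

test_that("partition-up copies parents to children and merge/partition round-trips constants", {
  x <- matrix(1:10, 5, 2)
  skip0 <- matrix(0, 20, 3)
  up <- mssit:::.partition_up_fwd(x, skip0)
  expect_identical(dim(up), c(20L, 5L))
  expect_equal(up[, 1:2], x[rep(1:5, each = 4), ], ignore_attr = TRUE)
  # identity projection on the parent block makes partition_up(merge) = id
  const <- matrix(3, 20, 2)
  merged <- mssit:::.merge_fwd(const)
  up2 <- mssit:::.partition_up_fwd(merged[, 1:2, drop = FALSE],
                                   matrix(0, 20, 1))
  expect_equal(up2[, 1:2], const, ignore_attr = TRUE)
  expect_error(mssit:::.partition_up_fwd(x, matrix(0, 19, 1)), "4x")
})

test_that("windowed attention equals brute-force masked global attention (incl. shifts)", {
  # scaled model: ico3-input sequence (320 positions) with order-0 windows of 16
  wm <- build_window_map(1, shift_fraction = 0.5, input_order = 3,
                         window_depth = 2)
  expect_identical(wm$window_size, 16L)
  set.seed(4)
  d <- 8
  x <- matrix(rnorm(wm$seq_len * d), wm$seq_len, d)
  p <- mssit:::.init_attn(d)
  got <- mssit:::.attn_fwd(x, p, wm, heads = 2, shift = 0L)$y
  want <- masked_attention_oracle(x, p, wm$window_of, heads = 2)
  expect_lt(max(abs(got - want)), 1e-10)
  # shifted pass: roll, mask on rolled windows, unroll
  got_s <- mssit:::.attn_fwd(x, p, wm, heads = 2, shift = wm$shift)$y
  xs <- mssit:::.roll_rows(x, wm$shift)
  want_s <- mssit:::.roll_rows(
    masked_attention_oracle(xs, p, wm$window_of, heads = 2), -wm$shift)
  expect_lt(max(abs(got_s - want_s)), 1e-10)
})

test_that("zero shift makes the shifted sub-step identical to the windowed one", {
  wm <- build_window_map(2, shift_fraction = 0, input_order = 3,
                         window_depth = 2)
  expect_identical(wm$shift, 0L)
  set.seed(5)
  x <- matrix(rnorm(wm$seq_len * 8), wm$seq_len, 8)
  p <- mssit:::.init_attn(8)
  a <- mssit:::.attn_fwd(x, p, wm, heads = 2, shift = 0L)$y
  b <- mssit:::.attn_fwd(x, p, wm, heads = 2, shift = wm$shift)$y
  expect_identical(a, b)
})

test_that("unshifted attention is strictly local: perturbations stay in their window", {
  wm <- build_window_map(1, input_order = 3, window_depth = 2)
  set.seed(6)
  d <- 8
  x <- matrix(rnorm(wm$seq_len * d), wm$seq_len, d)
  p <- mssit:::.init_attn(d)
  base <- mssit:::.attn_fwd(x, p, wm, heads = 2, shift = 0L)$y
  x2 <- x
  x2[3, ] <- x2[3, ] + 5          # position 2 (0-based) lives in window 0
  pert <- mssit:::.attn_fwd(x2, p, wm, heads = 2, shift = 0L)$y
  other <- wm$window_of != 0L
  expect_identical(pert[other, ], base[other, ])
  expect_gt(max(abs(pert[!other, ] - base[!other, ])), 0)
})

test_that("attention cost follows the windowed complexity contract", {
  # score-matrix entries per head at each level: n_windows * ws^2 = seq_len * ws
  for (cfg in list(c(1, 3, 3), c(2, 3, 2), c(1, 4, 3))) {
    level <- cfg[1]; input_order <- cfg[2]; wd <- cfg[3]
    wm <- build_window_map(level, input_order = input_order, window_depth = wd)
    set.seed(7)
    x <- matrix(rnorm(wm$seq_len * 4), wm$seq_len, 4)
    p <- mssit:::.init_attn(4)
    out <- mssit:::.attn_fwd(x, p, wm, heads = 1, shift = 0L)
    entries <- sum(vapply(out$A, function(w) length(w[[1]]), numeric(1)))
    expect_identical(entries, as.numeric(wm$seq_len) * wm$window_size)
    if (wm$n_windows > 1)
      expect_lt(entries, as.numeric(wm$seq_len)^2)
  }
})

test_that("local-MHSA blocks and the full encoder preserve sequence shapes", {
  cfg <- mssit_config("regression", input_order = 4, channels = 2,
                      base_dim = 8, depths = c(1, 1, 1, 1),
                      heads = c(2, 2, 2, 2), mlp_ratio = 2)
  params <- init_mssit_params(cfg, seed = 1)
  geo <- mssit:::.config_geometry(cfg)
  sig <- random_signal(4, channels = 2, seed = 8)
  X0 <- tokenize(sig, geo$partition)
  enc <- mssit:::.encoder_fwd(params, X0, cfg, geo)
  expect_identical(vapply(enc$skips, nrow, integer(1)),
                   c(1280L, 320L, 80L, 20L))
  expect_identical(vapply(enc$skips, ncol, integer(1)),
                   c(8L, 16L, 32L, 64L))
  # block input/output shapes are equal at every level
  for (l in 1:4) {
    blk <- mssit:::.block_fwd(enc$lev_cache[[l]]$blocks[[1]]$x_in,
                              params$levels[[l]]$blocks[[1]],
                              geo$wmaps[[l]], cfg$heads[l])
    expect_identical(dim(blk$y),
                     dim(enc$lev_cache[[l]]$blocks[[1]]$x_in))
  }
})

test_that("regression forward yields num_outputs values, deterministically", {
  cfg <- tiny_reg_config()
  params <- init_mssit_params(cfg, seed = 2)
  sig <- random_signal(2, channels = 2, seed = 9)
  out1 <- forward_regression(sig, cfg, params)
  out2 <- forward_regression(sig, cfg, params)
  expect_length(out1, 1L)
  expect_identical(out1, out2)
  att <- forward_regression(sig, cfg, params, keep_attention = TRUE)
  expect_identical(length(attr(att, "attention")), 2L)
})

test_that("segmentation forward covers all vertices with softmax rows summing to 1", {
  cfg <- mssit_config("segmentation", input_order = 3, channels = 2,
                      base_dim = 8, depths = c(1, 1), heads = c(2, 2),
                      mlp_ratio = 2, num_classes = 5,
                      decoder_depths = c(0))
  params <- init_mssit_params(cfg, seed = 3)
  sig <- random_signal(3, channels = 2, seed = 10)
  logits <- forward_segmentation(sig, cfg, params)
  expect_identical(dim(logits), c(642L, 5L))
  probs <- softmax_rows(logits)
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
  expect_error(mssit_config("segmentation", num_classes = 1), "num_classes")
})

test_that("analytic gradients match finite differences on both task heads", {
  eps <- 1e-5
  flat <- function(p) unlist(p, use.names = FALSE)
  # regression head
  cfg <- tiny_reg_config()
  params <- init_mssit_params(cfg, seed = 4)
  geo <- mssit:::.config_geometry(cfg)
  sig <- random_signal(2, channels = 2, seed = 11)
  target <- c(0.7)
  loss_r <- function(p) {
    fw <- mssit:::.forward_reg_full(sig, cfg, p, geo)
    mean((fw$pred - target)^2)
  }
  fw <- mssit:::.forward_reg_full(sig, cfg, params, geo)
  gr <- mssit:::.backward_reg_full(cfg, geo, params, fw,
                                   2 * (fw$pred - target))
  gv <- flat(mssit:::.match_structure(params, gr))
  pv <- flat(params)
  set.seed(12)
  idx <- sample(length(pv), 50)
  num <- vapply(idx, function(i) {
    p1 <- pv; p2 <- pv
    p1[i] <- p1[i] + eps; p2[i] <- p2[i] - eps
    (loss_r(utils::relist(p1, params)) - loss_r(utils::relist(p2, params))) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - gv[idx])), 1e-6)

  # segmentation with a decoder block and Dice+CE loss
  cfgS <- mssit_config("segmentation", input_order = 2, channels = 2,
                       base_dim = 4, depths = c(1, 1), heads = c(2, 2),
                       mlp_ratio = 2, num_classes = 3, decoder_depths = c(1))
  pS <- init_mssit_params(cfgS, seed = 5)
  geoS <- mssit:::.config_geometry(cfgS)
  set.seed(13)
  labels <- sample(0:2, 162, TRUE)
  loss_s <- function(p) {
    fw <- mssit:::.forward_seg_full(sig, cfgS, p, geoS)
    as.numeric(dice_ce_loss(fw$logits, labels))
  }
  fwS <- mssit:::.forward_seg_full(sig, cfgS, pS, geoS)
  lS <- dice_ce_loss(fwS$logits, labels)
  grS <- mssit:::.backward_seg_full(cfgS, geoS, pS, fwS, attr(lS, "gradient"))
  gvS <- flat(mssit:::.match_structure(pS, grS))
  pvS <- flat(pS)
  set.seed(14)
  idxS <- sample(length(pvS), 50)
  numS <- vapply(idxS, function(i) {
    p1 <- pvS; p2 <- pvS
    p1[i] <- p1[i] + eps; p2[i] <- p2[i] - eps
    (loss_s(utils::relist(p1, pS)) - loss_s(utils::relist(p2, pS))) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(numS - gvS[idxS])), 1e-6)
})
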