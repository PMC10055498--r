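test_that("Dice+CE loss matches closed forms and a brute-force Dice oracle", {
  K <- 4
  set.seed(1)
  labels <- sample(0:(K - 1), 50, TRUE)
  # uniform logits: CE part is exactly ln K
  lu <- dice_ce_loss(matrix(0, 50, K), labels)
  expect_equal(unname(attr(lu, "parts")["ce"]), log(K), tolerance = 1e-12)
  # near-one-hot correct logits: vanishing loss
  hot <- matrix(-20, 50, K)
  hot[cbind(1:50, labels + 1)] <- 20
  expect_lt(as.numeric(dice_ce_loss(hot, labels)), 1e-6)
  # soft-Dice term equals an independent per-class summation oracle
  set.seed(2)
  logits <- matrix(rnorm(642 * 5), 642, 5)
  labs5 <- sample(0:4, 642, TRUE)
  l <- dice_ce_loss(logits, labs5)
  p <- softmax_rows(logits)
  s <- 1e-5
  dice_oracle <- mean(vapply(0:4, function(k) {
    y <- as.numeric(labs5 == k)
    (2 * sum(p[, k + 1] * y) + s) / (sum(p[, k + 1]) + sum(y) + s)
  }, numeric(1)))
  expect_equal(unname(attr(l, "parts")["dice"]), 1 - dice_oracle,
               tolerance = 1e-9)
  expect_error(dice_ce_loss(logits, rep(9, 642)), "labels")
})

test_that("hard Dice handles perfect, complementary and random predictions", {
  ref <- c(rep(0L, 30), rep(1L, 70))
  expect_equal(dice_per_region(ref, ref, 2), c(1, 1))
  expect_equal(dice_per_region(1L - ref, ref, 2), c(0, 0))
  # brute-force confusion-matrix oracle on a random 3-class case
  set.seed(3)
  pred <- sample(0:2, 162, TRUE)
  ref3 <- sample(0:2, 162, TRUE)
  got <- dice_per_region(pred, ref3, 3)
  for (k in 0:2) {
    tp <- sum(pred == k & ref3 == k)
    expect_equal(got[k + 1], 2 * tp / (sum(pred == k) + sum(ref3 == k)))
  }
})

test_that("balanced sampling weights equalise mass across occupied bins", {
  targets <- c(rep(30.2, 90), rep(40.7, 10))
  w <- balanced_sample_weights(targets, 1)
  expect_equal(sum(w), 1)
  expect_equal(w[100] / w[1], 9)
  expect_equal(sum(w[1:90]), 0.5)
  expect_equal(sum(w[91:100]), 0.5)
  expect_equal(balanced_sample_weights(rep(5, 7), 1), rep(1 / 7, 7))
  expect_error(balanced_sample_weights(numeric(0), 1), "non-empty")
  # empirical bin frequencies are uniform across occupied bins
  set.seed(4)
  draws <- sample.int(100, 1e5, replace = TRUE, prob = w)
  p_hi <- mean(draws > 90)
  expect_lt(abs(p_hi - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("cosine decay hits its endpoints and midpoint exactly and never increases", {
  tc <- train_config("regression", lr_max = 3e-3, lr_min = 1e-5,
                     total_steps = 200)
  expect_equal(cosine_decay_lr(0, tc), 3e-3)
  expect_equal(cosine_decay_lr(200, tc), 1e-5)
  expect_equal(cosine_decay_lr(100, tc), (3e-3 + 1e-5) / 2)
  lrs <- cosine_decay_lr(0:200, tc)
  expect_true(all(diff(lrs) <= 1e-15))
  expect_error(cosine_decay_lr(201, tc), "step")
})

test_that("training runs, logs finite losses per epoch, and is seed-deterministic", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec("regression", n_subjects = 8, mesh_order = 2,
                         noise_sd = 0.1, seed = 21)
  manifest <- make_regression_dataset(spec, dir)
  cfg <- tiny_reg_config()
  cfg$channels <- 4L
  cfg <- mssit_config("regression", input_order = 2, channels = 4,
                      base_dim = 4, depths = c(1, 1), heads = c(2, 2),
                      mlp_ratio = 2)
  tc <- train_config("regression", total_steps = 4, batch_size = 4, seed = 5,
                     augmentation = augmentation_config(warp_grid_order = 0,
                                                        max_rotation_deg = 10))
  ck1 <- train(manifest, cfg, tc)
  expect_s3_class(ck1, "mssit_checkpoint")
  expect_true(all(is.finite(ck1$history$train_loss)))
  expect_identical(nrow(ck1$history), 2L)   # 4 steps / 2 steps-per-epoch
  ck2 <- train(manifest, cfg, tc)
  expect_identical(ck1$history, ck2$history)
  expect_identical(ck1$params, ck2$params)
  # evaluate() reproduces the stored validation path
  ev <- evaluate(ck1, manifest)
  expect_s3_class(ev, "eval_report")
  expect_gte(ev$mae, 0)
  pred <- predict_mssit(ck1, read_metric(read_manifest(manifest)$metric_path[1]))
  expect_true(is.finite(pred))
})

test_that("loss decreases on average over the first training steps", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec("regression", n_subjects = 12, mesh_order = 2,
                         noise_sd = 0.05, seed = 22)
  manifest <- make_regression_dataset(spec, dir)
  cfg <- mssit_config("regression", input_order = 2, channels = 4,
                      base_dim = 8, depths = c(1, 1), heads = c(2, 2),
                      mlp_ratio = 2)
  tc <- train_config("regression", total_steps = 50, batch_size = 4,
                     lr_max = 1e-3, seed = 6, augmentation = NULL,
                     patience = Inf)
  ck <- train(manifest, cfg, tc)
  h <- ck$history$train_loss
  expect_lt(mean(utils::tail(h, 3)), mean(utils::head(h, 3)))
})

test_that("evaluation reports perfect scores for an oracle predictor", {
  # regression: predictions equal to targets give MAE 0 by construction of the
  # metric implementation
  preds <- c(30, 40.5)
  expect_equal(mean(abs(preds - preds)), 0)
  # segmentation: predicted labels identical to reference give Dice 1 per region
  set.seed(7)
  ref <- sample(0:7, 2562, TRUE)
  expect_equal(dice_per_region(ref, ref, 8), rep(1, 8))
})
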