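test_that("dataset splitting follows the floor-remainder rule", {
  s <- split_dataset(10, c(8, 1, 1), seed = 1)
  expect_equal(lengths(s), c(train = 8L, val = 1L, test = 1L))

  s2 <- split_dataset(2176, c(8, 1, 1), seed = 1)
  expect_equal(lengths(s2), c(train = 1742L, val = 217L, test = 217L))

  # disjoint and exhaustive
  expect_equal(sort(unlist(s2)), 1:2176, ignore_attr = TRUE)

  expect_identical(split_dataset(50, seed = 9), split_dataset(50, seed = 9))
  expect_false(identical(split_dataset(50, seed = 9), split_dataset(50, seed = 10)))
  expect_error(split_dataset(2), "at least 3")
})

test_that("weighted cross-entropy matches closed forms", {
  # logits strongly favouring the true class saturate to ~0 loss
  y <- random_mask(8, 8, seed = 1)
  lg <- array(0, c(8, 8, 2))
  lg[, , 1] <- 50 * (y == 0)
  lg[, , 2] <- 50 * (y == 1)
  expect_lt(weighted_ce_loss(lg, y), 1e-3)

  # uniform logits, half the pixels each class, weights (1, 1.5): 1.25 log 2
  yh <- matrix(rep(0:1, each = 32), 8, 8)
  lu <- array(0, c(8, 8, 2))
  expect_equal(weighted_ce_loss(lu, yh, c(1, 1.5)), 1.25 * log(2))

  # linear in the class weights
  set.seed(2)
  lr <- array(rnorm(128), c(8, 8, 2))
  expect_equal(weighted_ce_loss(lr, yh, c(2, 3)),
               2 * weighted_ce_loss(lr, yh, c(1, 1.5)))

  # invariant under a joint pixel permutation
  perm <- sample(64)
  lp <- array(0, c(8, 8, 2))
  lp[, , 1] <- matrix(as.vector(lr[, , 1])[perm], 8, 8)
  lp[, , 2] <- matrix(as.vector(lr[, , 2])[perm], 8, 8)
  yp <- matrix(as.vector(yh)[perm], 8, 8)
  expect_equal(weighted_ce_loss(lp, yp), weighted_ce_loss(lr, yh))

  expect_error(weighted_ce_loss(lu, matrix(3L, 8, 8)), "labels")
})

test_that("gradient clipping bounds the global norm", {
  oct <- asNamespace("octdamage")
  set.seed(3)
  grads <- list(a = array(rnorm(100, sd = 5), c(10, 10)), b = rnorm(20, sd = 5))
  cl <- oct$clip_gradients(grads, 1.0)
  post <- sqrt(sum(vapply(cl$grads, function(g) sum(g * g), numeric(1))))
  expect_lte(post, 1.0 + 1e-6)
  # direction preserved
  expect_equal(cl$grads$a / post, grads$a / cl$norm, tolerance = 1e-12)

  small <- list(a = c(0.1, 0.1))
  expect_identical(oct$clip_gradients(small, 1.0)$grads, small)
})

test_that("the cosine schedule cycles with the configured period", {
  oct <- asNamespace("octdamage")
  expect_equal(oct$cosine_lr(1e-4, 1, 50), 1e-4)
  expect_equal(oct$cosine_lr(1e-4, 51, 50), 1e-4)  # restart
  expect_lt(oct$cosine_lr(1e-4, 50, 50), 1e-5)
  mid <- oct$cosine_lr(1e-4, 26, 50)
  expect_equal(mid, 1e-4 * 0.5 * (1 + cos(pi * 0.5)))
})

test_that("training bookkeeping: one history record per epoch, deterministic", {
  pairs <- lapply(1:4, function(i) tiny_phantom(seed = i))
  data <- list(images = lapply(pairs, function(p) p$images$slices[[1]]),
               masks = lapply(pairs, function(p) p$truth$slices[[1]]))
  tc <- train_config(epochs = 1, batch_size = 2, split_ratios = c(2, 1, 1),
                     seed = 3)
  m <- build_unet("unet", base_width = 4, depth = 2, seed = 1)
  fit <- train_segmenter(m, data, tc)
  expect_equal(nrow(fit$history), 1)
  expect_true(all(c("epoch", "train_loss", "val_dice", "val_miou",
                    "val_mpa", "val_accuracy") %in% names(fit$history)))

  fit2 <- train_segmenter(m, data, tc)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history, fit2$history)
})

test_that("a tiny phantom set is learnable in a few epochs", {
  pairs <- lapply(1:8, function(i) tiny_phantom(seed = i, h = 16, w = 16))
  data <- list(images = lapply(pairs, function(p) p$images$slices[[1]]),
               masks = lapply(pairs, function(p) p$truth$slices[[1]]))
  tc <- train_config(epochs = 25, lr = 1e-3, lr_period = 25,
                     split_ratios = c(6, 1, 1), seed = 1)
  m <- build_unet("unet", base_width = 8, depth = 2, seed = 2)
  fit <- train_segmenter(m, data, tc)
  expect_gt(max(fit$history$val_dice), 0.5)
  expect_error(train_segmenter(m, list(images = list(), masks = list()), tc),
               "nonempty")
})

test_that("evaluate_segmenter pools per-image confusions", {
  pairs <- lapply(1:3, function(i) tiny_phantom(seed = i))
  m <- build_unet("unet", base_width = 4, depth = 2, seed = 1)
  images <- lapply(pairs, function(p) p$images$slices[[1]])
  masks <- lapply(pairs, function(p) p$truth$slices[[1]])
  ev <- evaluate_segmenter(m, images, masks)
  expect_s3_class(ev$pooled, "metrics_report")
  expect_equal(nrow(ev$per_image), 3)
  pooled_oracle <- metrics_report(ev$predictions, masks)
  expect_equal(ev$pooled$dice, pooled_oracle$dice)

  # perfect predictions give the perfect report
  ev2 <- metrics_report(masks, masks)
  expect_equal(c(ev2$dice, ev2$miou, ev2$mpa, ev2$accuracy), c(1, 100, 100, 100))
})
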