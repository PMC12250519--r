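test_that("confusion counts pixels by (true, predicted) label", {
  truth <- matrix(c(1L, 0L, 1L, 0L), 2, 2)   # rows: [1,1] / [0,0]
  pred <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  cm <- confusion(pred, truth)
  expect_equal(unclass(cm), matrix(c(1, 1, 1, 1), 2, 2,
                                   dimnames = list(true = 0:1, pred = 0:1)),
               ignore_attr = "class")

  m <- random_mask(8, 8, seed = 3)
  cmd <- confusion(m, m)
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)

  allfn <- confusion(matrix(0L, 4, 4), matrix(1L, 4, 4))
  expect_equal(as.vector(unclass(allfn)), c(0, 16, 0, 0))

  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)), "mismatch")
  expect_error(confusion(matrix(2L, 2, 2), matrix(0L, 2, 2)), "labels")
})

test_that("dice matches its set-cardinality definition and edge cases", {
  m <- random_mask(6, 6, seed = 4)
  expect_equal(dice(confusion(m, m)), 1)

  a <- matrix(0L, 4, 4); a[1:2, ] <- 1L
  b <- matrix(0L, 4, 4); b[3:4, ] <- 1L
  expect_equal(dice(confusion(a, b)), 0)

  # TP = 3, FP = 1, FN = 2 built from explicit pixel sets
  pred <- matrix(0L, 2, 4); pred[1, 1:4] <- 1L          # X = 4 pixels
  truth <- matrix(0L, 2, 4); truth[1, 1:3] <- 1L; truth[2, 1:2] <- 1L
  cm <- confusion(pred, truth)
  expect_equal(c(cm[2, 2], cm[1, 2], cm[2, 1]), c(3, 1, 2))
  expect_equal(dice(cm), 6 / 9)

  # both regions empty: perfect agreement on absence
  expect_equal(dice(confusion(matrix(0L, 3, 3), matrix(0L, 3, 3))), 1)
})

test_that("accuracy, mPA and mIoU match constructed confusion matrices", {
  m <- random_mask(5, 5, seed = 5)
  cm_perfect <- confusion(m, m)
  expect_equal(accuracy(cm_perfect), 100)
  expect_equal(mpa(cm_perfect), 100)
  expect_equal(miou(cm_perfect), 100)

  balanced <- structure(matrix(c(1, 1, 1, 1), 2, 2),
                        class = c("confusion_matrix", "matrix"))
  expect_equal(accuracy(balanced), 50)

  tp90 <- structure(matrix(c(5, 2, 3, 90), 2, 2),
                    class = c("confusion_matrix", "matrix"))
  expect_equal(accuracy(tp90), 95)

  # per-class recalls 1.0 and 0.5 -> mPA 75%
  rec <- structure(matrix(c(10, 5, 0, 5), 2, 2),
                   class = c("confusion_matrix", "matrix"))
  expect_equal(mpa(rec), 75)

  # class IoUs 0.5 and 0.5 -> mIoU 50%
  half <- structure(matrix(c(2, 1, 1, 2), 2, 2),
                    class = c("confusion_matrix", "matrix"))
  expect_equal(miou(half), 50)

  # complement prediction with both classes present
  comp <- confusion(1L - m, m)
  expect_equal(miou(comp), 0)

  # class 1 absent from truth: mPA reduces to class-0 recall
  t0 <- matrix(0L, 4, 4)
  p <- matrix(0L, 4, 4); p[1, 1] <- 1L
  expect_equal(mpa(confusion(p, t0)), 100 * 15 / 16)
})

test_that("all four metrics equal brute-force pixel-set oracles", {
  set.seed(42)
  for (i in 1:100) {
    pred <- random_mask(32, 32, p = runif(1, 0.05, 0.9), seed = 1000 + i)
    truth <- random_mask(32, 32, p = runif(1, 0.05, 0.9), seed = 2000 + i)
    cm <- confusion(pred, truth)
    o <- oracle_metrics(pred, truth)
    expect_equal(dice(cm), o$dice, tolerance = 1e-12)
    expect_equal(accuracy(cm), o$accuracy, tolerance = 1e-12)
    expect_equal(mpa(cm), o$mpa, tolerance = 1e-12)
    expect_equal(miou(cm), o$miou, tolerance = 1e-12)
    # algebraic identity: Dice = 2 IoU1 / (1 + IoU1) for the foreground class
    iou1 <- cm[2, 2] / (cm[2, 2] + cm[1, 2] + cm[2, 1])
    expect_equal(dice(cm), 2 * iou1 / (1 + iou1), tolerance = 1e-12)
    expect_true(mpa(cm) >= 0 && mpa(cm) <= 100)
    expect_true(miou(cm) >= 0 && miou(cm) <= 100)
  }
})

test_that("symmetric metrics are invariant under joint relabeling", {
  pred <- random_mask(16, 16, seed = 11)
  truth <- random_mask(16, 16, seed = 12)
  cm <- confusion(pred, truth)
  cm_swap <- confusion(1L - pred, 1L - truth)
  expect_equal(accuracy(cm), accuracy(cm_swap))
  expect_equal(mpa(cm), mpa(cm_swap))
  expect_equal(miou(cm), miou(cm_swap))
})

test_that("metrics_report pools confusion matrices across images", {
  preds <- lapply(1:4, function(i) random_mask(8, 8, seed = 30 + i))
  truths <- lapply(1:4, function(i) random_mask(8, 8, seed = 40 + i))
  rep <- metrics_report(preds, truths)
  pooled <- Reduce(`+`, Map(function(p, t) unclass(confusion(p, t)),
                            preds, truths))
  expect_equal(unclass(rep$confusion), pooled, ignore_attr = TRUE)
  expect_equal(rep$accuracy, 100 * sum(diag(pooled)) / sum(pooled))
})
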