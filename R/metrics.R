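# Segmentation evaluation: confusion-matrix substrate and the four standard
# metrics (Dice, accuracy, mean pixel accuracy, mean IoU).
#
# The confusion matrix p(i, j) counts pixels with true label i and predicted
# label j, i and j in 0..k. For the binary (k = 1) case TP = p(1,1),
# TN = p(0,0), FP = p(0,1), FN = p(1,0).

#' Pixel confusion matrix
#'
#' @param pred,truth Integer label matrices of equal dimensions with values
#'   in `0..k`.
#' @param k Maximum label (default 1).
#' @return `(k+1) x (k+1)` integer matrix of class `"confusion_matrix"`;
#'   rows index the true label, columns the predicted label.
#' @export
confusion <- function(pred, truth, k = 1L) {
  if (!identical(dim(pred), dim(truth)))
    stop("confusion: dimension mismatch (",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), ")")
  if (any(pred < 0L | pred > k) || any(truth < 0L | truth > k))
    stop("labels outside 0..", k)
  n <- k + 1L
  counts <- tabulate(as.integer(truth) * n + as.integer(pred) + 1L, nbins = n * n)
  m <- matrix(counts, n, n, byrow = TRUE,
              dimnames = list(true = 0:k, pred = 0:k))
  structure(m, class = c("confusion_matrix", "matrix"))
}

# Sum a list of confusion matrices (pooled evaluation).
pool_confusions <- function(cms) {
  out <- Reduce(`+`, cms)
  structure(out, class = c("confusion_matrix", "matrix"))
}

as_cm <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop("expected a confusion matrix")
  unclass(cm)
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`, the overlap `2|X∩Y| / (|X| + |Y|)` between the
#' predicted and true foreground regions; 1 means complete overlap, 0 none.
#' When both regions are empty the coefficient is defined as 1 (perfect
#' agreement on absence).
#'
#' @param cm A binary [confusion()] matrix.
#' @return Value in `[0, 1]`.
#' @export
dice <- function(cm) {
  m <- as_cm(cm)
  if (nrow(m) != 2L) stop("dice is defined for the binary confusion matrix")
  tp <- m[2, 2]; fp <- m[1, 2]; fn <- m[2, 1]
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

#' Overall pixel accuracy
#'
#' `100 (TP + TN) / (TP + FP + FN + TN)`: the percentage of pixels whose
#' class is predicted correctly.
#'
#' @param cm A [confusion()] matrix with at least one counted pixel.
#' @return Percentage in `[0, 100]`.
#' @export
accuracy <- function(cm) {
  m <- as_cm(cm)
  if (sum(m) == 0) stop("empty confusion matrix")
  100 * sum(diag(m)) / sum(m)
}

#' Mean pixel accuracy (mPA)
#'
#' Mean over classes of the per-class recall `p(i,i) / sum_j p(i,j)`.
#' Classes absent from the truth are skipped and the divisor renormalized.
#'
#' @param cm A [confusion()] matrix.
#' @return Percentage in `[0, 100]`.
#' @export
mpa <- function(cm) {
  m <- as_cm(cm)
  rs <- rowSums(m)
  present <- rs > 0
  if (!any(present)) stop("no class present in truth")
  100 * mean(diag(m)[present] / rs[present])
}

#' Mean intersection over union (mIoU)
#'
#' Mean over classes of `p(i,i) / (sum_j p(i,j) + sum_j p(j,i) - p(i,i))`.
#' Classes absent from the truth are skipped and the divisor renormalized.
#'
#' @param cm A [confusion()] matrix.
#' @return Percentage in `[0, 100]`.
#' @export
miou <- function(cm) {
  m <- as_cm(cm)
  rs <- rowSums(m); cs <- colSums(m)
  present <- rs > 0
  if (!any(present)) stop("no class present in truth")
  iou <- diag(m)[present] / (rs[present] + cs[present] - diag(m)[present])
  100 * mean(iou)
}

#' Full metrics report from masks or a confusion matrix
#'
#' Computes Dice (fraction) plus mIoU, mPA and accuracy (percent) — the
#' standard report for damage-segmentation evaluation.
#'
#' @param pred Predicted mask, list of masks, [mask_stack()], or a
#'   [confusion()] matrix (then `truth` is ignored).
#' @param truth Ground-truth mask(s) aligned with `pred`.
#' @param k Maximum label.
#' @return Object of class `"metrics_report"`: list with `dice`, `miou`,
#'   `mpa`, `accuracy` and the pooled `confusion` matrix.
#' @export
metrics_report <- function(pred, truth = NULL, k = 1L) {
  cm <- if (inherits(pred, "confusion_matrix")) pred
  else {
    pl <- if (inherits(pred, "mask_stack")) pred$slices else if (is.list(pred)) pred else list(pred)
    tl <- if (inherits(truth, "mask_stack")) truth$slices else if (is.list(truth)) truth else list(truth)
    if (length(pl) != length(tl)) stop("pred and truth counts differ")
    pool_confusions(Map(function(p, tr) confusion(p, tr, k), pl, tl))
  }
  structure(list(dice = dice(cm), miou = miou(cm), mpa = mpa(cm),
                 accuracy = accuracy(cm), confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Dice %.4f | mIoU %.4g%% | mPA %.4g%% | accuracy %.4g%%\n",
              x$dice, x$miou, x$mpa, x$accuracy))
  invisible(x)
}
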