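# Training protocol: dataset splitting, weighted cross-entropy loss, Adam
# optimization with gradient clipping and a cyclic cosine learning-rate
# schedule, and the pooled evaluation harness.

#' Training configuration
#'
#' Defaults reproduce the damage-segmentation protocol: Adam at an initial
#' learning rate of 1e-4 with weight decay 1e-4 cycling over a 50-epoch
#' period, 200 epochs at batch size 4, weighted cross-entropy with weight
#' 1.5 on the damage class and 1.0 on the background, gradient clipping at a
#' maximum norm of 1.0, and an 8:1:1 train/validation/test split.
#'
#' @param lr Initial learning rate.
#' @param weight_decay L2 weight-decay factor applied by the optimizer.
#' @param lr_period Epochs per cosine learning-rate cycle.
#' @param epochs Training epochs.
#' @param batch_size Images per optimization step.
#' @param class_weights Per-class loss weights `(background, damage)`.
#' @param grad_clip_max_norm Global gradient-norm clip.
#' @param split_ratios Train/validation/test proportions.
#' @param seed Seed for shuffling and batching.
#' @return Object of class `"train_config"`.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, lr_period = 50L,
                         epochs = 200L, batch_size = 4L,
                         class_weights = c(background = 1.0, damage = 1.5),
                         grad_clip_max_norm = 1.0,
                         split_ratios = c(8, 1, 1), seed = 1L) {
  if (any(class_weights <= 0)) stop("class_weights must be positive")
  if (length(split_ratios) != 3L || any(split_ratios < 0))
    stop("split_ratios must be three nonnegative numbers")
  structure(list(lr = lr, weight_decay = weight_decay,
                 lr_period = as.integer(lr_period),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 class_weights = class_weights,
                 grad_clip_max_norm = grad_clip_max_norm,
                 split_ratios = split_ratios, seed = as.integer(seed)),
            class = "train_config")
}

#' Split a dataset into train / validation / test
#'
#' Disjoint, exhaustive, seeded random split. Validation and test receive
#' `floor(n * r)` items each, the remainder goes to training (so 10 items at
#' 8:1:1 give 8/1/1 and 2176 give 1742/217/217).
#'
#' @param n Number of items, or a list of items (then indices into it are
#'   returned all the same).
#' @param ratios Length-3 proportions, normalized internally.
#' @param seed Permutation seed.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, ratios = c(8, 1, 1), seed = 1L) {
  if (is.list(n)) n <- length(n)
  if (!is_count(n) || n < 3) stop("need at least 3 items to split")
  r <- ratios / sum(ratios)
  n_val <- floor(n * r[2])
  n_test <- floor(n * r[3])
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n - n_val - n_test)]),
       val = sort(perm[n - n_val - n_test + seq_len(n_val)]),
       test = sort(perm[n - n_test + seq_len(n_test)]))
}

#' Weighted cross-entropy loss
#'
#' Mean over pixels of `-w[y] * log softmax(logits)[y]`, the class-weighted
#' cross-entropy used to counter background/damage imbalance.
#'
#' @param logits Array `(H, W, K)` or `(H, W, K, N)` of class scores.
#' @param mask Integer labels `(H, W)` or `(H, W, N)` in `0..K-1`.
#' @param class_weights Positive per-class weights, default `c(1, 1.5)`.
#' @return Nonnegative scalar.
#' @export
weighted_ce_loss <- function(logits, mask, class_weights = c(1.0, 1.5)) {
  if (any(class_weights <= 0)) stop("class_weights must be positive")
  if (length(dim(logits)) == 3L) logits <- array(logits, c(dim(logits), 1L))
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  dm <- dim(logits)
  if (!identical(dim(mask), dm[c(1, 2, 4)]))
    stop("mask dimensions do not match logits")
  tp <- tape_new()
  ad_wce(tp, ad_leaf(tp, logits), mask, class_weights)$value
}

# Adam with decoupled behaviour matching the classical L2 formulation:
# the weight-decay term is added to the gradient before the moment updates.
adam_state <- function(params) {
  list(m = lapply(params, function(p) 0 * p),
       v = lapply(params, function(p) 0 * p),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t
  b2t <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / b1t) / (sqrt(st$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = st)
}

# Scale all gradients so the global L2 norm is at most max_norm.
clip_gradients <- function(grads, max_norm) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (is.finite(gn) && gn > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  list(grads = grads, norm = gn)
}

# Cyclic cosine learning rate: lr/2 * (1 + cos(pi * t/T)) within each cycle.
cosine_lr <- function(lr0, epoch, period) {
  t <- (epoch - 1L) %% period
  lr0 * 0.5 * (1 + cos(pi * t / period))
}

batch_arrays <- function(images, masks, idx) {
  d <- dim(images[[idx[1]]])
  x <- array(0, c(d[1], d[2], 1L, length(idx)))
  y <- array(0L, c(d[1], d[2], length(idx)))
  for (j in seq_along(idx)) {
    x[, , 1, j] <- images[[idx[j]]]
    y[, , j] <- masks[[idx[j]]]
  }
  list(x = x, y = y)
}

#' Train a UNet segmenter
#'
#' Optimizes the model with Adam (learning rate on a cyclic cosine schedule,
#' constant weight decay), weighted cross-entropy loss and global
#' gradient-norm clipping. Validation metrics are computed each epoch from a
#' pooled confusion matrix; the parameters achieving the best validation
#' Dice are restored at the end.
#'
#' @param model An untrained or previously trained `"oct_unet"`.
#' @param data List with `images` (list of H x W matrices in `[0, 1]`) and
#'   `masks` (list of integer label matrices).
#' @param cfg A [train_config()].
#' @param split Optional [split_dataset()] result; computed from
#'   `cfg$split_ratios` and `cfg$seed` when missing.
#' @param verbose Print per-epoch progress (default `FALSE`).
#' @return The fitted `"oct_unet"` with a `history` data frame (one row per
#'   epoch: training loss, validation Dice/mIoU/mPA/accuracy, learning rate).
#' @export
train_segmenter <- function(model, data, cfg = train_config(), split = NULL,
                            verbose = FALSE) {
  stopifnot(inherits(model, "oct_unet"), inherits(cfg, "train_config"))
  images <- data$images
  masks <- data$masks
  if (length(images) != length(masks) || !length(images))
    stop("data must hold matched, nonempty image and mask lists")
  split <- split %||% split_dataset(length(images), cfg$split_ratios, cfg$seed)
  if (!length(split$train)) stop("empty training set")

  # Work on a private copy of the batch-norm state so the input model object
  # is left untouched and repeated runs are reproducible.
  bn_new <- new.env(parent = emptyenv())
  for (nm in ls(model$bn)) bn_new[[nm]] <- model$bn[[nm]]
  model$bn <- bn_new

  params <- model$params
  opt <- adam_state(params)
  best <- list(dice = -Inf, params = params,
               bn = as.list(model$bn))
  hist <- vector("list", cfg$epochs)
  rng <- child_seed(cfg$seed, 1L)

  for (epoch in seq_len(cfg$epochs)) {
    lr_e <- cosine_lr(cfg$lr, epoch, cfg$lr_period)
    ord <- split$train[with_seed((rng + epoch) %% 2147483647,
                                 sample.int(length(split$train)))]
    losses <- numeric(0)
    for (s in seq(1L, length(ord), by = cfg$batch_size)) {
      idx <- ord[s:min(length(ord), s + cfg$batch_size - 1L)]
      ba <- batch_arrays(images, masks, idx)
      model$params <- params
      fw <- unet_fwd(model, ba$x, training = TRUE)
      loss <- ad_wce(fw$tape, fw$logits, ba$y, cfg$class_weights)
      if (!is.finite(loss$value))
        stop("non-finite loss at epoch ", epoch, " (batch starting ", s,
             "); inspect inputs and learning rate")
      ad_backward(fw$tape, loss)
      grads <- lapply(fw$leaves,
                      function(l) if (is.null(l$grad)) 0 * l$value else l$grad)
      cl <- clip_gradients(grads, cfg$grad_clip_max_norm)
      up <- adam_step(params, cl$grads, opt, lr_e, cfg$weight_decay)
      params <- up$params
      opt <- up$state
      losses <- c(losses, loss$value)
    }
    model$params <- params
    vm <- eval_masks(model, images, masks, split$val)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr_e,
                                train_loss = mean(losses),
                                val_dice = vm$dice, val_miou = vm$miou,
                                val_mpa = vm$mpa, val_accuracy = vm$accuracy)
    if (!is.na(vm$dice) && vm$dice > best$dice)
      best <- list(dice = vm$dice, params = params, bn = as.list(model$bn))
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  val Dice %.4f",
                      epoch, lr_e, mean(losses), vm$dice))
  }
  model$params <- best$params
  for (nm in names(best$bn)) model$bn[[nm]] <- best$bn[[nm]]
  model$history <- do.call(rbind, hist)
  model$split <- split
  model$trained <- TRUE
  model
}

# Pooled metrics of model predictions over the indexed subset.
eval_masks <- function(model, images, masks, idx) {
  if (!length(idx)) return(list(dice = NA_real_, miou = NA_real_,
                                mpa = NA_real_, accuracy = NA_real_))
  preds <- vector("list", length(idx))
  for (s in seq(1L, length(idx), by = 4L)) {
    jj <- s:min(length(idx), s + 3L)
    d <- dim(images[[idx[jj[1]]]])
    xa <- array(0, c(d, length(jj)))
    for (j in seq_along(jj)) xa[, , j] <- images[[idx[jj[j]]]]
    lab <- predict.oct_unet(model, xa, type = "mask")
    for (j in seq_along(jj))
      preds[[jj[j]]] <- matrix(as.integer(lab[, , j]), d[1], d[2])
  }
  rep <- metrics_report(preds, masks[idx], k = model$cfg$num_classes - 1L)
  list(dice = rep$dice, miou = rep$miou, mpa = rep$mpa, accuracy = rep$accuracy)
}

#' Evaluate a segmenter on labelled images
#'
#' Predicts every image and aggregates the four metrics both from the pooled
#' confusion matrix (primary) and as per-image means.
#'
#' @param model A trained `"oct_unet"`.
#' @param images List of H x W matrices (or an [image_stack()]).
#' @param masks List of ground-truth masks (or a [mask_stack()]).
#' @return List with `pooled` (a [metrics_report()]) and `per_image` (a data
#'   frame of per-image metrics plus their means).
#' @export
evaluate_segmenter <- function(model, images, masks) {
  if (inherits(images, "image_stack")) images <- images$slices
  if (inherits(masks, "mask_stack")) masks <- masks$slices
  if (!length(images) || length(images) != length(masks))
    stop("need matched nonempty images and masks")
  k <- model$cfg$num_classes - 1L
  preds <- lapply(images, function(im) predict.oct_unet(model, im, type = "mask"))
  pooled <- metrics_report(preds, masks, k = k)
  per <- do.call(rbind, Map(function(p, tr) {
    cm <- confusion(p, tr, k)
    data.frame(dice = dice(cm), miou = miou(cm), mpa = mpa(cm),
               accuracy = accuracy(cm))
  }, preds, masks))
  list(pooled = pooled, per_image = per, predictions = preds)
}
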