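# UNet segmenter with attention in the decoder ("up-sampling") path.
#
# Encoder: double 3x3 conv (+ batch norm + ReLU) and 2x2 max pooling per
# level. Decoder: 2x2 transposed-convolution upsampling, skip concatenation,
# double conv, then the configured attention block applied to the stage's
# fused features. A 1x1 convolution maps the first-level width to class
# logits. Four variants: plain UNet and the tandem/parallel/nested
# SimAM + PSA attention topologies.

#' Build a UNet segmenter
#'
#' Constructs an untrained segmentation model with seeded He-normal weight
#' initialization. The `variant` shorthand selects the attention topology
#' inserted in the decoder: `"unet"` (none), `"tandem"` (PSA after SimAM),
#' `"parallel"` (fused SimAM and PSA), `"nested"` (SimAM inside each PSA
#' branch), or `"simam"`/`"psa"` alone.
#'
#' @param variant Model variant; ignored when `attention` is supplied.
#' @param in_channels Input image channels (default 1, grayscale B-scans).
#' @param num_classes Output classes (default 2: background / damage).
#' @param base_width Channels at the first encoder level (default 64).
#' @param depth Number of encoder levels including the bottleneck (default 5,
#'   i.e. widths 64 to 1024); inputs must have H and W divisible by
#'   `2^(depth-1)`.
#' @param attention An [attention_config()]; overrides `variant`.
#' @param attention_levels Decoder levels (1 = highest resolution) that carry
#'   the attention block; default all.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `"oct_unet"`.
#' @examples
#' m <- build_unet("parallel", base_width = 16, depth = 3, seed = 1)
#' print(m)
#' @export
build_unet <- function(variant = c("unet", "tandem", "parallel", "nested",
                                   "simam", "psa"),
                       in_channels = 1L, num_classes = 2L,
                       base_width = 64L, depth = 5L,
                       attention = NULL, attention_levels = NULL,
                       seed = 1L) {
  variant <- match.arg(variant)
  if (is.null(attention)) {
    mode <- if (variant == "unet") "none" else variant
    attention <- attention_config(mode)
  }
  stopifnot(inherits(attention, "attention_config"), depth >= 2, base_width >= 1)
  widths <- base_width * 2^(0:(depth - 1))
  attention_levels <- as.integer(attention_levels %||% seq_len(depth - 1))
  if (any(attention_levels < 1L | attention_levels > depth - 1L))
    stop("attention_levels must lie in 1..", depth - 1)

  # Validate channel divisibility at every attention insertion site now,
  # before any training.
  if (attention$mode %in% c("psa", "tandem", "parallel", "nested")) {
    for (l in attention_levels) {
      C <- widths[l]
      if (C %% attention$psa_branches != 0L)
        stop("decoder level ", l, ": C = ", C, " not divisible by S = ",
             attention$psa_branches)
    }
  }

  params <- with_seed(seed, init_unet_params(in_channels, num_classes,
                                             widths, attention,
                                             attention_levels))
  bn <- new.env(parent = emptyenv())
  for (nm in names(params)) {
    if (grepl("\\.bn[12]\\.g$", nm)) {
      key <- sub("\\.g$", "", nm)
      bn[[key]] <- list(rm = numeric(length(params[[nm]])),
                        rv = rep(1, length(params[[nm]])))
    }
  }
  structure(list(cfg = list(variant = variant, in_channels = as.integer(in_channels),
                            num_classes = as.integer(num_classes),
                            base_width = as.integer(base_width),
                            depth = as.integer(depth),
                            attention = attention,
                            attention_levels = attention_levels,
                            seed = as.integer(seed)),
                 params = params, bn = bn, history = NULL, trained = FALSE),
            class = "oct_unet")
}

conv_init <- function(kh, kw, cin, cout, gain = sqrt(2)) {
  array(stats::rnorm(kh * kw * cin * cout, sd = gain / sqrt(kh * kw * cin)),
        c(kh, kw, cin, cout))
}

init_unet_params <- function(in_channels, num_classes, widths, attention,
                             attention_levels) {
  depth <- length(widths)
  p <- list()
  dbl <- function(prefix, cin, cout) {
    p[[paste0(prefix, ".c1.w")]] <<- conv_init(3, 3, cin, cout)
    p[[paste0(prefix, ".c1.b")]] <<- numeric(cout)
    p[[paste0(prefix, ".bn1.g")]] <<- rep(1, cout)
    p[[paste0(prefix, ".bn1.be")]] <<- numeric(cout)
    p[[paste0(prefix, ".c2.w")]] <<- conv_init(3, 3, cout, cout)
    p[[paste0(prefix, ".c2.b")]] <<- numeric(cout)
    p[[paste0(prefix, ".bn2.g")]] <<- rep(1, cout)
    p[[paste0(prefix, ".bn2.be")]] <<- numeric(cout)
  }
  cin <- in_channels
  for (l in seq_len(depth)) {
    dbl(sprintf("enc%d", l), cin, widths[l])
    cin <- widths[l]
  }
  for (l in rev(seq_len(depth - 1))) {
    p[[sprintf("dec%d.up.w", l)]] <- array(
      stats::rnorm(2 * 2 * widths[l] * widths[l + 1],
                   sd = sqrt(2) / sqrt(widths[l + 1])),
      c(2, 2, widths[l], widths[l + 1]))
    p[[sprintf("dec%d.up.b", l)]] <- numeric(widths[l])
    dbl(sprintf("dec%d", l), 2 * widths[l], widths[l])
    if (attention$mode %in% c("psa", "tandem", "parallel", "nested") &&
        l %in% attention_levels) {
      ap <- psa_init(widths[l], attention)
      names(ap) <- paste0(sprintf("dec%d.att.", l), names(ap))
      p <- c(p, ap)
    }
  }
  p[["head.w"]] <- conv_init(1, 1, widths[1], num_classes, gain = 1)
  p[["head.b"]] <- numeric(num_classes)
  p
}

# Batch normalization on the tape. In training mode the batch statistics are
# used and the running estimates updated in place; in eval mode the stored
# running statistics are applied as constants.
bn_fwd <- function(tp, x, leaves, key, bn_env, training, momentum = 0.1,
                   eps = 1e-5) {
  g <- leaves[[paste0(key, ".g")]]
  be <- leaves[[paste0(key, ".be")]]
  st <- bn_env[[key]]
  if (training) {
    mu <- ad_cmean(tp, x)
    xc <- ad_add_chan(tp, x, ad_mulc(tp, mu, -1))
    v <- ad_cmean(tp, ad_mul(tp, xc, xc))
    bn_env[[key]] <- list(rm = (1 - momentum) * st$rm + momentum * mu$value,
                          rv = (1 - momentum) * st$rv + momentum * v$value)
    xh <- ad_mul_chan(tp, xc, ad_rsqrt(tp, v, eps))
  } else {
    xc <- ad_add_chan(tp, x, ad_leaf(tp, -st$rm))
    xh <- ad_mul_chan(tp, xc, ad_leaf(tp, 1 / sqrt(st$rv + eps)))
  }
  ad_add_chan(tp, ad_mul_chan(tp, xh, g), be)
}

double_conv_fwd <- function(tp, x, leaves, prefix, bn_env, training) {
  h <- ad_conv2d(tp, x, leaves[[paste0(prefix, ".c1.w")]],
                 leaves[[paste0(prefix, ".c1.b")]], pad = 1L)
  h <- ad_relu(tp, bn_fwd(tp, h, leaves, paste0(prefix, ".bn1"), bn_env, training))
  h <- ad_conv2d(tp, h, leaves[[paste0(prefix, ".c2.w")]],
                 leaves[[paste0(prefix, ".c2.b")]], pad = 1L)
  ad_relu(tp, bn_fwd(tp, h, leaves, paste0(prefix, ".bn2"), bn_env, training))
}

# Full forward pass. x: (H, W, Cin, N). Returns tape, logits node, and the
# name -> leaf-node map for gradient collection.
unet_fwd <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  dm <- dim(x)
  div <- 2^(cfg$depth - 1)
  if (dm[1] %% div != 0L || dm[2] %% div != 0L)
    stop("input ", dm[1], "x", dm[2], " not divisible by 2^(depth-1) = ", div,
         "; run preprocess_geometry() first")
  tp <- tape_new()
  leaves <- lapply(model$params, function(p) ad_leaf(tp, p))
  att <- cfg$attention
  att_leaves <- function(l) {
    pre <- sprintf("dec%d.att.", l)
    sel <- leaves[startsWith(names(leaves), pre)]
    names(sel) <- substring(names(sel), nchar(pre) + 1L)
    sel
  }
  h <- ad_leaf(tp, x)
  skips <- vector("list", cfg$depth - 1L)
  for (l in seq_len(cfg$depth)) {
    h <- double_conv_fwd(tp, h, leaves, sprintf("enc%d", l), model$bn, training)
    if (l < cfg$depth) {
      skips[[l]] <- h
      h <- ad_maxpool2(tp, h)
    }
  }
  for (l in rev(seq_len(cfg$depth - 1L))) {
    h <- ad_convt2(tp, h, leaves[[sprintf("dec%d.up.w", l)]],
                   leaves[[sprintf("dec%d.up.b", l)]])
    h <- ad_concat_chan(tp, list(skips[[l]], h))
    h <- double_conv_fwd(tp, h, leaves, sprintf("dec%d", l), model$bn, training)
    if (att$mode != "none" && l %in% cfg$attention_levels)
      h <- attention_fwd(tp, h, att, att_leaves(l))
  }
  logits <- ad_conv2d(tp, h, leaves[["head.w"]], leaves[["head.b"]], pad = 0L)
  list(tape = tp, logits = logits, leaves = leaves)
}

#' Number of learnable parameters
#' @param model An `"oct_unet"`.
#' @return Integer parameter count (batch-norm scale/shift included).
#' @export
n_params <- function(model) sum(lengths(model$params))

#' @export
print.oct_unet <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<oct_unet> variant=%s depth=%d base_width=%d classes=%d\n",
              cfg$variant, cfg$depth, cfg$base_width, cfg$num_classes))
  cat(sprintf("  parameters: %s  attention: %s%s\n",
              format(n_params(x), big.mark = ","), cfg$attention$mode,
              if (cfg$attention$mode == "none") ""
              else paste0(" @ decoder level(s) ",
                          paste(cfg$attention_levels, collapse = ","))))
  if (!is.null(x$history))
    cat(sprintf("  trained: %d epoch(s), best val Dice %.4f\n",
                nrow(x$history), max(x$history$val_dice)))
  invisible(x)
}

#' @export
summary.oct_unet <- function(object, ...) {
  widths <- object$cfg$base_width * 2^(0:(object$cfg$depth - 1))
  grp <- sub("\\..*$", "", names(object$params))
  tab <- vapply(split(lengths(object$params), grp), sum, numeric(1))
  cat("UNet level widths:", paste(widths, collapse = " -> "), "\n")
  cat("Parameters by stage:\n")
  for (nm in names(tab)) cat(sprintf("  %-10s %10d\n", nm, tab[[nm]]))
  cat(sprintf("  %-10s %10d\n", "total", sum(tab)))
  invisible(tab)
}

#' @export
coef.oct_unet <- function(object, ...) object$params

#' Training-history curves
#'
#' Plots the per-epoch training loss and validation Dice of a trained
#' segmenter.
#'
#' @param x A trained `"oct_unet"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.oct_unet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  graphics::plot(h$epoch, h$val_dice, type = "l", xlab = "epoch",
                 ylab = "validation Dice", ylim = c(0, 1), ...)
  invisible(x)
}

#' Segment images with a UNet model
#'
#' Runs the model in inference mode (batch-norm running statistics, argmax
#' over class logits). For stacks, slices are processed in batches and, when
#' a slice carries geometry metadata from [preprocess_geometry()], the
#' predicted mask is mapped back to native scan geometry.
#'
#' @param object An `"oct_unet"`.
#' @param newdata A numeric H x W matrix, an (H, W, N) array, or an
#'   [image_stack()].
#' @param type `"mask"` (integer labels, default), `"prob"` (class-1
#'   probability), or `"logits"`.
#' @param batch_size Slices per forward pass for stacks (default 4).
#' @param ... Unused.
#' @return A mask/probability matrix, a [mask_stack()] for stack input, or a
#'   logits array.
#' @export
predict.oct_unet <- function(object, newdata, type = c("mask", "prob", "logits"),
                             batch_size = 4L, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "image_stack"))
    return(predict_stack(object, newdata, type = type, batch_size = batch_size))
  one <- is.matrix(newdata)
  x <- if (one) array(newdata, c(dim(newdata), 1L, 1L))
       else array(newdata, c(dim(newdata)[1:2], 1L, dim(newdata)[3]))
  fw <- unet_fwd(object, x, training = FALSE)
  lv <- fw$logits$value
  out <- switch(type,
    logits = lv,
    prob = softmax_probs(lv)[, , 2, , drop = FALSE],
    mask = {
      K <- dim(lv)[3]
      am <- lv[, , 1, , drop = FALSE]
      lab <- array(0L, dim(lv)[c(1, 2, 4)])
      for (k in seq_len(K - 1)) {
        sl <- lv[, , k + 1, , drop = FALSE]
        upd <- sl > am
        lab[upd] <- k
        am[upd] <- sl[upd]
      }
      lab
    })
  if (one) {
    if (type == "mask") matrix(out[, , 1], dim(x)[1], dim(x)[2])
    else if (type == "prob") matrix(out[, , 1, 1], dim(x)[1], dim(x)[2])
    else out[, , , 1]
  } else out
}

#' Segment an image stack
#'
#' @inheritParams predict.oct_unet
#' @param stack An [image_stack()] whose slices are already at the model
#'   input size.
#' @return A [mask_stack()] in acquisition order, restored to native
#'   geometry where the slices carry geometry metadata.
#' @export
predict_stack <- function(object, stack, type = "mask", batch_size = 4L) {
  stopifnot(inherits(stack, "image_stack"))
  m <- length(stack$slices)
  if (m == 0L) return(mask_stack(list()))
  masks <- vector("list", m)
  for (s in seq(1L, m, by = batch_size)) {
    idx <- s:min(m, s + batch_size - 1L)
    d <- dim(stack$slices[[idx[1]]])
    xa <- array(0, c(d[1], d[2], length(idx)))
    for (j in seq_along(idx)) xa[, , j] <- stack$slices[[idx[j]]]
    lab <- predict.oct_unet(object, xa, type = "mask")
    for (j in seq_along(idx)) {
      mk <- matrix(as.integer(lab[, , j]), d[1], d[2])
      geom <- attr(stack$slices[[idx[j]]], "geometry")
      if (!is.null(geom)) mk <- restore_geometry(mk, geom)
      masks[[idx[j]]] <- mk
    }
  }
  mask_stack(masks, k = object$cfg$num_classes - 1L)
}
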