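# Minimal reverse-mode automatic differentiation over R arrays.
#
# A tape records nodes in creation order; since every operand must already be
# on the tape, the reverse of creation order is a valid topological order for
# backpropagation. Nodes are environments holding `value`, an accumulated
# `grad`, and a `back` closure that pushes the node's gradient to its inputs.
# Feature maps are (H, W, C, N) arrays; channel descriptors are (C, N)
# matrices; per-channel parameters are plain vectors.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$k <- 0L
  t
}

nd <- function(tape, value, back = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$back <- back
  k <- tape$k + 1L
  if (k > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[k]] <- n
  tape$k <- k
  n
}

ad_leaf <- function(tape, value) nd(tape, value)

acc_grad <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

# Run backpropagation from a scalar loss node.
ad_backward <- function(tape, loss) {
  for (i in seq_len(tape$k)) tape$nodes[[i]]$grad <- NULL
  loss$grad <- 1
  for (i in rev(seq_len(tape$k))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$back)) n$back(n$grad)
  }
  invisible(NULL)
}

## ---- elementwise ----

ad_add <- function(tp, a, b) {
  stopifnot(identical(dim(a$value), dim(b$value)) || length(a$value) == length(b$value))
  nd(tp, a$value + b$value, function(g) { acc_grad(a, g); acc_grad(b, g) })
}

ad_sub <- function(tp, a, b) {
  nd(tp, a$value - b$value, function(g) { acc_grad(a, g); acc_grad(b, -g) })
}

ad_mul <- function(tp, a, b) {
  av <- a$value; bv <- b$value
  nd(tp, av * bv, function(g) { acc_grad(a, g * bv); acc_grad(b, g * av) })
}

ad_addc <- function(tp, a, k) nd(tp, a$value + k, function(g) acc_grad(a, g))

ad_mulc <- function(tp, a, k) nd(tp, a$value * k, function(g) acc_grad(a, g * k))

ad_relu <- function(tp, a) {
  m <- a$value > 0
  nd(tp, a$value * m, function(g) acc_grad(a, g * m))
}

ad_sigmoid <- function(tp, a) {
  s <- 1 / (1 + exp(-a$value))
  nd(tp, s, function(g) acc_grad(a, g * s * (1 - s)))
}

ad_exp <- function(tp, a) {
  e <- exp(a$value)
  nd(tp, e, function(g) acc_grad(a, g * e))
}

ad_recip <- function(tp, a) {
  v <- a$value
  nd(tp, 1 / v, function(g) acc_grad(a, -g / (v * v)))
}

# 1/sqrt(x + eps), used by batch normalization.
ad_rsqrt <- function(tp, a, eps) {
  v <- a$value + eps
  r <- 1 / sqrt(v)
  nd(tp, r, function(g) acc_grad(a, -0.5 * g * r / v))
}

## ---- reductions and broadcasts ----

# Broadcast a length-C vector over (H, W, C, N). Single rep() call and an
# in-place dim<- keep allocations down on the training hot path.
bc_chan <- function(v, dm) {
  x <- rep(v, times = dm[4], each = dm[1] * dm[2])
  dim(x) <- dm
  x
}

# Broadcast a (C, N) matrix over (H, W, C, N).
bc_cn <- function(m, dm) {
  x <- rep(as.vector(m), each = dm[1] * dm[2])
  dim(x) <- dm
  x
}

chan_sum <- function(x) {
  dm <- dim(x)
  s <- .colSums(x, m = dm[1] * dm[2], n = dm[3] * dm[4])
  dim(s) <- c(dm[3], dm[4])
  .rowSums(s, m = dm[3], n = dm[4])
}

cn_sum <- function(x) {
  dm <- dim(x)
  s <- .colSums(x, m = dm[1] * dm[2], n = dm[3] * dm[4])
  dim(s) <- c(dm[3], dm[4])
  s
}

# Mean over H, W and N per channel -> length-C vector (batch-norm statistic).
ad_cmean <- function(tp, x) {
  dm <- dim(x$value)
  nf <- dm[1] * dm[2] * dm[4]
  nd(tp, chan_sum(x$value) / nf,
     function(g) acc_grad(x, bc_chan(g, dm) / nf))
}

# Mean over H and W per channel and sample -> (C, N) matrix.
ad_smean <- function(tp, x) {
  dm <- dim(x$value)
  nf <- dm[1] * dm[2]
  nd(tp, cn_sum(x$value) / nf,
     function(g) acc_grad(x, bc_cn(g, dm) / nf))
}

ad_add_chan <- function(tp, x, v) {
  dm <- dim(x$value)
  nd(tp, x$value + bc_chan(v$value, dm),
     function(g) { acc_grad(x, g); acc_grad(v, chan_sum(g)) })
}

ad_mul_chan <- function(tp, x, v) {
  dm <- dim(x$value)
  xv <- x$value; vb <- bc_chan(v$value, dm)
  nd(tp, xv * vb,
     function(g) { acc_grad(x, g * vb); acc_grad(v, chan_sum(g * xv)) })
}

ad_add_cn <- function(tp, x, m) {
  dm <- dim(x$value)
  nd(tp, x$value + bc_cn(m$value, dm),
     function(g) { acc_grad(x, g); acc_grad(m, cn_sum(g)) })
}

ad_mul_cn <- function(tp, x, m) {
  dm <- dim(x$value)
  xv <- x$value; mb <- bc_cn(m$value, dm)
  nd(tp, xv * mb,
     function(g) { acc_grad(x, g * mb); acc_grad(m, cn_sum(g * xv)) })
}

## ---- small dense algebra on (C, N) descriptors ----

# W (p x q) times m (q x N).
ad_matmul <- function(tp, W, m) {
  Wv <- W$value; mv <- m$value
  nd(tp, Wv %*% mv,
     function(g) { acc_grad(W, g %*% t(mv)); acc_grad(m, crossprod(Wv, g)) })
}

# Add a length-p bias to every column of a (p x N) matrix.
ad_add_col <- function(tp, m, b) {
  nd(tp, m$value + b$value,
     function(g) { acc_grad(m, g); acc_grad(b, rowSums(g)) })
}

## ---- structural ops ----

ad_slice_chan <- function(tp, x, cs) {
  dm <- dim(x$value)
  nd(tp, x$value[, , cs, , drop = FALSE],
     function(g) {
       dx <- array(0, dm)
       dx[, , cs, ] <- g
       acc_grad(x, dx)
     })
}

ad_concat_chan <- function(tp, parts) {
  dms <- lapply(parts, function(p) dim(p$value))
  cs <- vapply(dms, function(d) d[3], numeric(1))
  dm <- dms[[1]]; dm[3] <- sum(cs)
  v <- array(0, dm)
  at <- 0L
  for (i in seq_along(parts)) {
    v[, , at + seq_len(cs[i]), ] <- parts[[i]]$value
    at <- at + cs[i]
  }
  nd(tp, v, function(g) {
    at <- 0L
    for (i in seq_along(parts)) {
      acc_grad(parts[[i]], g[, , at + seq_len(cs[i]), , drop = FALSE])
      at <- at + cs[i]
    }
  })
}

## ---- compiled layers ----

ad_conv2d <- function(tp, x, w, b, pad, groups = 1L) {
  xv <- x$value; wv <- w$value
  y <- cpp_conv2d_fwd(xv, wv, b$value, as.integer(pad), as.integer(groups))
  nd(tp, y, function(g) {
    gr <- cpp_conv2d_bwd(xv, wv, g, as.integer(pad), as.integer(groups))
    acc_grad(x, gr$dx); acc_grad(w, gr$dw); acc_grad(b, gr$db)
  })
}

ad_convt2 <- function(tp, x, w, b) {
  xv <- x$value; wv <- w$value
  y <- cpp_convt2_fwd(xv, wv, b$value)
  nd(tp, y, function(g) {
    gr <- cpp_convt2_bwd(xv, wv, g)
    acc_grad(x, gr$dx); acc_grad(w, gr$dw); acc_grad(b, gr$db)
  })
}

ad_maxpool2 <- function(tp, x) {
  fw <- cpp_maxpool2_fwd(x$value)
  xd <- dim(x$value)
  nd(tp, fw$y, function(g)
    acc_grad(x, cpp_maxpool2_bwd(fw$idx, g, as.integer(xd))))
}

## ---- loss ----

# Weighted cross-entropy over pixels: mean of -w[y] * log softmax(logits)[y].
# logits: (H, W, K, N); labels: (H, W, N) integer array with values 0..K-1.
# Works on a flat (pixel x class) matrix so no R-level per-pixel loops occur.
ad_wce <- function(tp, logits, labels, class_weights) {
  lv <- logits$value
  dm <- dim(lv)
  K <- dm[3]
  y <- as.integer(labels)
  if (any(y < 0L | y >= K)) stop("mask labels outside 0..", K - 1)
  m <- matrix(aperm(lv, c(1, 2, 4, 3)), ncol = K)  # rows: pixels of all samples
  mx <- m[, 1]
  for (k in seq_len(K - 1)) mx <- pmax(mx, m[, k + 1])
  ex <- exp(m - mx)
  p <- ex / rowSums(ex)
  npix <- nrow(m)
  ii <- cbind(seq_len(npix), y + 1L)
  wpix <- class_weights[y + 1L]
  loss <- -sum(wpix * log(p[ii])) / npix
  nd(tp, loss, function(g) {
    dl <- p
    dl[ii] <- dl[ii] - 1
    dl <- dl * (wpix * (g / npix))
    acc_grad(logits, aperm(array(dl, c(dm[1], dm[2], dm[4], K)), c(1, 2, 4, 3)))
  })
}

# Softmax class probabilities from a logits array, same flat formulation.
softmax_probs <- function(lv) {
  dm <- dim(lv)
  K <- dm[3]
  m <- matrix(aperm(lv, c(1, 2, 4, 3)), ncol = K)
  mx <- m[, 1]
  for (k in seq_len(K - 1)) mx <- pmax(mx, m[, k + 1])
  ex <- exp(m - mx)
  p <- ex / rowSums(ex)
  aperm(array(p, c(dm[1], dm[2], dm[4], K)), c(1, 2, 4, 3))
}
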