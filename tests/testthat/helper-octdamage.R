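# Shared fixtures: tiny seeded phantoms and random masks built in code.

tiny_phantom <- function(seed = 1L, h = 16L, w = 16L) {
  generate_phantom(phantom_spec(height = h, width = w, surface_depth = 4L,
                                surface_band = 2L,
                                lesion_center = c(1, 10, 8),
                                lesion_radii = c(0, 3, 4),
                                seed = seed))
}

random_mask <- function(h, w, p = 0.3, seed = 1L) {
  set.seed(seed)
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# Scalar-loop bilinear resize with half-pixel centres: the reference the
# vectorized implementation is checked against.
resize_bilinear_ref <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    sr <- min(max((i - 0.5) * H / h - 0.5, 0), H - 1)
    sc <- min(max((j - 0.5) * W / w - 0.5, 0), W - 1)
    r0 <- floor(sr); c0 <- floor(sc)
    r1 <- min(r0 + 1, H - 1); c1 <- min(c0 + 1, W - 1)
    fr <- sr - r0; fc <- sc - c0
    out[i, j] <- m[r0 + 1, c0 + 1] * (1 - fr) * (1 - fc) +
      m[r0 + 1, c1 + 1] * (1 - fr) * fc +
      m[r1 + 1, c0 + 1] * fr * (1 - fc) +
      m[r1 + 1, c1 + 1] * fr * fc
  }
  out
}

# Brute-force set-based metric oracles, written independently of the
# confusion-matrix implementation.
oracle_metrics <- function(pred, truth) {
  X <- which(pred == 1L)
  Y <- which(truth == 1L)
  inter <- length(intersect(X, Y))
  d <- if (length(X) + length(Y) == 0) 1 else 2 * inter / (length(X) + length(Y))
  acc <- 100 * mean(pred == truth)
  pa <- iou <- numeric(0)
  for (cl in 0:1) {
    t_cl <- which(truth == cl)
    if (!length(t_cl)) next
    p_cl <- which(pred == cl)
    pa <- c(pa, length(intersect(t_cl, p_cl)) / length(t_cl))
    iou <- c(iou, length(intersect(t_cl, p_cl)) / length(union(t_cl, p_cl)))
  }
  list(dice = d, accuracy = acc, mpa = 100 * mean(pa), miou = 100 * mean(iou))
}
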