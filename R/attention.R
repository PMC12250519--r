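#' Attention configuration
#'
#' Settings for the SimAM (parameter-free energy attention) and PSA (pyramid
#' squeeze attention) operators and for the three ways of combining them
#' inside the segmentation network.
#'
#' @param mode One of `"none"`, `"simam"`, `"psa"`, `"tandem"`, `"parallel"`,
#'   `"nested"`. `"tandem"` applies SimAM then PSA in series; `"parallel"`
#'   fuses the two branch outputs; `"nested"` applies SimAM to each PSA
#'   branch's multi-scale features before the squeeze/softmax stage.
#' @param simam_lambda Positive energy regularizer of the SimAM weight
#'   (dimensionless, default `1e-4`).
#' @param psa_branches Number of multi-scale branches S the channels are
#'   split into (default 4).
#' @param psa_kernel_sizes Odd convolution kernel size per branch
#'   (default `c(3, 5, 7, 9)`).
#' @param psa_groups Requested convolution group count per branch (default
#'   `c(1, 4, 8, 16)`); at a given insertion site the effective group count is
#'   the largest divisor of the branch width not exceeding the request.
#' @param se_reduction Bottleneck reduction of the per-branch squeeze
#'   (channel descriptor) stage (default 4); must divide the branch width.
#' @param parallel_fusion `"mean"` (default) or `"sum"` fusion of the SimAM
#'   and PSA outputs in parallel mode.
#' @return An object of class `"attention_config"`.
#' @export
attention_config <- function(mode = c("none", "simam", "psa", "tandem",
                                      "parallel", "nested"),
                             simam_lambda = 1e-4,
                             psa_branches = 4L,
                             psa_kernel_sizes = c(3L, 5L, 7L, 9L),
                             psa_groups = c(1L, 4L, 8L, 16L),
                             se_reduction = 4L,
                             parallel_fusion = c("mean", "sum")) {
  mode <- match.arg(mode)
  parallel_fusion <- match.arg(parallel_fusion)
  if (simam_lambda <= 0) stop("simam_lambda must be > 0")
  psa_branches <- as.integer(psa_branches)
  if (psa_branches < 1L) stop("psa_branches must be >= 1")
  psa_kernel_sizes <- as.integer(psa_kernel_sizes)
  psa_groups <- as.integer(psa_groups)
  if (length(psa_kernel_sizes) != psa_branches)
    stop("psa_kernel_sizes must have length psa_branches")
  if (length(psa_groups) != psa_branches)
    stop("psa_groups must have length psa_branches")
  if (any(psa_kernel_sizes %% 2L == 0L)) stop("psa_kernel_sizes must be odd")
  structure(list(mode = mode, simam_lambda = simam_lambda,
                 psa_branches = psa_branches,
                 psa_kernel_sizes = psa_kernel_sizes,
                 psa_groups = psa_groups,
                 se_reduction = as.integer(se_reduction),
                 parallel_fusion = parallel_fusion),
            class = "attention_config")
}

# Largest divisor of n that does not exceed g.
effective_groups <- function(n, g) {
  d <- which(n %% seq_len(n) == 0)
  max(d[d <= max(1L, g)])
}

## ---- SimAM ----

# Energy-based per-neuron attention on the tape. For each channel and sample,
# with spatial mean mu and population variance s2, the inverse-energy score is
# a = ((x - mu)^2 + 2 s2 + 2 lambda) / (4 (s2 + lambda)) and the output is
# x * sigmoid(a). No learnable parameters.
simam_fwd <- function(tp, x, lambda) {
  mu <- ad_smean(tp, x)
  xc <- ad_add_cn(tp, x, ad_mulc(tp, mu, -1))
  sq <- ad_mul(tp, xc, xc)
  s2 <- ad_smean(tp, sq)
  num <- ad_add_cn(tp, sq, ad_mulc(tp, ad_addc(tp, s2, lambda), 2))
  invden <- ad_recip(tp, ad_mulc(tp, ad_addc(tp, s2, lambda), 4))
  a <- ad_mul_cn(tp, num, invden)
  w <- ad_sigmoid(tp, a)
  list(out = ad_mul(tp, x, w), weights = w$value)
}

#' SimAM parameter-free attention
#'
#' Re-weights a feature map by the sigmoid of an inverse-energy score that
#' measures how much each activation stands out from its channel's spatial
#' statistics. Adds no learnable parameters and preserves shape.
#'
#' @param x Numeric 3-d array indexed channel x height x width.
#' @param lambda Positive regularizer of the energy denominator.
#' @return Array of the same shape as `x`.
#' @examples
#' x <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
#' y <- simam(x)
#' stopifnot(dim(y) == dim(x))
#' @export
simam <- function(x, lambda = 1e-4) {
  chw_unwrap(simam_chw(x, lambda)$out)
}

#' SimAM attention weights
#'
#' The multiplicative weights `sigmoid(a)` that [simam()] applies; all lie
#' strictly in (0, 1).
#'
#' @inheritParams simam
#' @return Array of the same shape as `x` holding the weights.
#' @export
simam_weights <- function(x, lambda = 1e-4) {
  chw_unwrap(simam_chw(x, lambda)$weights)
}

simam_chw <- function(x, lambda) {
  if (lambda <= 0) stop("lambda must be > 0")
  xa <- chw_wrap(x)
  if (dim(xa)[1] * dim(xa)[2] < 2) stop("SimAM needs at least 2 pixels per channel")
  tp <- tape_new()
  r <- simam_fwd(tp, ad_leaf(tp, xa), lambda)
  list(out = r$out$value, weights = r$weights)
}

# (C, H, W) user convention -> internal (H, W, C, 1).
chw_wrap <- function(x) {
  if (length(dim(x)) != 3) stop("feature map must be a 3-d array (C, H, W)")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  d <- dim(x)
  array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1))
}

chw_unwrap <- function(x) {
  d <- dim(x)
  aperm(array(x, d[1:3]), c(3, 1, 2))
}

## ---- PSA ----

# Initialize PSA parameters for `channels` input channels. Returns a flat
# named list; names are stable so optimizers can address them.
psa_init <- function(channels, cfg, gain = sqrt(2)) {
  S <- cfg$psa_branches
  if (channels %% S != 0L)
    stop("PSA: channel count ", channels, " not divisible by branches S = ", S)
  cb <- channels %/% S
  if (cb %% cfg$se_reduction != 0L && cb > 1L)
    stop("PSA: branch width ", cb, " not divisible by se_reduction = ",
         cfg$se_reduction)
  cr <- max(1L, cb %/% cfg$se_reduction)
  p <- list()
  for (i in seq_len(S)) {
    k <- cfg$psa_kernel_sizes[i]
    g <- effective_groups(cb, cfg$psa_groups[i])
    fan <- k * k * (cb %/% g)
    p[[sprintf("br%d.w", i)]] <- array(stats::rnorm(k * k * (cb %/% g) * cb,
                                                    sd = gain / sqrt(fan)),
                                       c(k, k, cb %/% g, cb))
    p[[sprintf("br%d.b", i)]] <- numeric(cb)
    p[[sprintf("br%d.fc1w", i)]] <- matrix(stats::rnorm(cr * cb, sd = gain / sqrt(cb)), cr, cb)
    p[[sprintf("br%d.fc1b", i)]] <- numeric(cr)
    p[[sprintf("br%d.fc2w", i)]] <- matrix(stats::rnorm(cb * cr, sd = gain / sqrt(cr)), cb, cr)
    p[[sprintf("br%d.fc2b", i)]] <- numeric(cb)
  }
  p
}

# PSA forward on the tape. `params` maps names from psa_init to leaf nodes.
# Returns the output node plus the softmax branch weights (cb x S x N).
psa_fwd <- function(tp, x, params, cfg, nested = FALSE) {
  dmx <- dim(x$value)
  C <- dmx[3]; N <- dmx[4]
  S <- cfg$psa_branches
  if (C %% S != 0L)
    stop("PSA: channel count ", C, " not divisible by branches S = ", S)
  cb <- C %/% S
  feats <- vector("list", S)
  descr <- vector("list", S)
  for (i in seq_len(S)) {
    k <- cfg$psa_kernel_sizes[i]
    g <- effective_groups(cb, cfg$psa_groups[i])
    xi <- ad_slice_chan(tp, x, (i - 1L) * cb + seq_len(cb))
    fi <- ad_conv2d(tp, xi, params[[sprintf("br%d.w", i)]],
                    params[[sprintf("br%d.b", i)]],
                    pad = (k - 1L) %/% 2L, groups = g)
    if (nested) fi <- simam_fwd(tp, fi, cfg$simam_lambda)$out
    d <- ad_smean(tp, fi)                              # (cb, N) squeeze
    z <- ad_relu(tp, ad_add_col(tp, ad_matmul(tp, params[[sprintf("br%d.fc1w", i)]], d),
                                params[[sprintf("br%d.fc1b", i)]]))
    s <- ad_sigmoid(tp, ad_add_col(tp, ad_matmul(tp, params[[sprintf("br%d.fc2w", i)]], z),
                                   params[[sprintf("br%d.fc2b", i)]]))
    feats[[i]] <- fi
    descr[[i]] <- s
  }
  # Softmax across branches at every (channel-slot, sample) position.
  es <- lapply(descr, function(s) ad_exp(tp, s))
  Z <- es[[1]]
  if (S > 1L) for (i in 2:S) Z <- ad_add(tp, Z, es[[i]])
  iZ <- ad_recip(tp, Z)
  wts <- array(0, c(cb, S, N))
  outs <- vector("list", S)
  for (i in seq_len(S)) {
    wi <- ad_mul(tp, es[[i]], iZ)
    wts[, i, ] <- wi$value
    outs[[i]] <- ad_mul_cn(tp, feats[[i]], wi)
  }
  out <- if (S == 1L) outs[[1]] else ad_concat_chan(tp, outs)
  list(out = out, weights = wts)
}

#' Construct a standalone attention block
#'
#' Builds the parameters of an attention operator for a given channel count so
#' it can be applied to feature maps outside the network (unit testing,
#' diagnostics). SimAM has no parameters; PSA branch convolutions and squeeze
#' bottlenecks are initialized from a seeded He-scaled normal.
#'
#' @param channels Number of input channels the block accepts.
#' @param config An [attention_config()].
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `"attention_block"` with elements `channels`,
#'   `config` and `params` (a flat named list of arrays).
#' @export
attention_block <- function(channels, config = attention_config("parallel"),
                            seed = 1L) {
  stopifnot(inherits(config, "attention_config"))
  params <- list()
  if (config$mode %in% c("psa", "tandem", "parallel", "nested"))
    params <- with_seed(seed, psa_init(channels, config))
  structure(list(channels = as.integer(channels), config = config,
                 params = params),
            class = "attention_block")
}

#' @export
print.attention_block <- function(x, ...) {
  cat(sprintf("<attention_block> mode=%s channels=%d params=%d\n",
              x$config$mode, x$channels,
              sum(lengths(x$params))))
  invisible(x)
}

#' Number of learnable parameters of an attention block
#' @param block An [attention_block()].
#' @return Integer count.
#' @export
attention_param_count <- function(block) sum(lengths(block$params))

# Shared forward used both standalone and inside the network.
attention_fwd <- function(tp, x, cfg, params) {
  switch(cfg$mode,
    none = x,
    simam = simam_fwd(tp, x, cfg$simam_lambda)$out,
    psa = psa_fwd(tp, x, params, cfg)$out,
    tandem = psa_fwd(tp, simam_fwd(tp, x, cfg$simam_lambda)$out, params, cfg)$out,
    parallel = {
      a <- simam_fwd(tp, x, cfg$simam_lambda)$out
      b <- psa_fwd(tp, x, params, cfg)$out
      s <- ad_add(tp, a, b)
      if (cfg$parallel_fusion == "mean") ad_mulc(tp, s, 0.5) else s
    },
    nested = psa_fwd(tp, x, params, cfg, nested = TRUE)$out,
    stop("unknown attention mode: ", cfg$mode)
  )
}

#' Apply an attention block to a feature map
#'
#' Runs the configured operator (`simam`, `psa`, or one of the combined
#' topologies `tandem` = PSA after SimAM, `parallel` = fused SimAM and PSA
#' branches, `nested` = PSA with SimAM inside each branch) on a single
#' feature map. All modes preserve shape.
#'
#' @param x Numeric 3-d array indexed channel x height x width; the channel
#'   count must equal `block$channels` when PSA participates.
#' @param block An [attention_block()].
#' @return Array of the same shape as `x`.
#' @export
apply_attention <- function(x, block) {
  stopifnot(inherits(block, "attention_block"))
  xa <- chw_wrap(x)
  tp <- tape_new()
  params <- lapply(block$params, function(p) ad_leaf(tp, p))
  out <- attention_fwd(tp, ad_leaf(tp, xa), block$config, params)
  chw_unwrap(out$value)
}

#' PSA branch softmax weights
#'
#' The softmax-normalized squeeze descriptors with which PSA scales its
#' branches; for every channel slot they are nonnegative and sum to one
#' across branches.
#'
#' @inheritParams apply_attention
#' @return Matrix (branch width x branches).
#' @export
psa_softmax_weights <- function(x, block) {
  stopifnot(inherits(block, "attention_block"))
  xa <- chw_wrap(x)
  tp <- tape_new()
  params <- lapply(block$params, function(p) ad_leaf(tp, p))
  cfg <- block$config
  r <- psa_fwd(tp, ad_leaf(tp, xa), params, cfg,
               nested = identical(cfg$mode, "nested"))
  w <- r$weights
  matrix(w[, , 1], dim(w)[1], dim(w)[2])
}
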