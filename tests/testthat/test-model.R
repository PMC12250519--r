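# Closed-form plain-UNet parameter count, written independently of the
# builder: double conv (+ batch norm) per level, transposed-conv upsampling,
# skip-concatenated decoder double convs, 1x1 head.
unet_param_formula <- function(in_ch, classes, base, depth) {
  w <- base * 2^(0:(depth - 1))
  dbl <- function(cin, cout) 9 * cin * cout + cout + 2 * cout +
    9 * cout * cout + cout + 2 * cout
  total <- dbl(in_ch, w[1])
  for (l in 2:depth) total <- total + dbl(w[l - 1], w[l])
  for (l in seq_len(depth - 1)) {
    total <- total + 4 * w[l + 1] * w[l] + w[l] +  # transposed conv
      dbl(2 * w[l], w[l])
  }
  total + w[1] * classes + classes
}

test_that("plain UNet parameter count matches the closed form", {
  for (cfg in list(c(8, 3), c(4, 2), c(16, 4))) {
    m <- build_unet("unet", base_width = cfg[1], depth = cfg[2], seed = 1)
    expect_equal(n_params(m), unet_param_formula(1, 2, cfg[1], cfg[2]))
  }
})

test_that("attention variants change the count only by the PSA blocks", {
  base <- n_params(build_unet("unet", base_width = 16, depth = 3, seed = 1))
  att <- attention_config("parallel")
  widths <- 16 * 2^(0:1)  # decoder levels 1 and 2
  psa_extra <- sum(vapply(widths, function(C)
    attention_param_count(attention_block(C, att)), numeric(1)))

  for (v in c("tandem", "parallel", "nested")) {
    m <- build_unet(v, base_width = 16, depth = 3, seed = 1)
    expect_equal(n_params(m), base + psa_extra)
  }
  # simam alone adds nothing
  expect_equal(n_params(build_unet("simam", base_width = 16, depth = 3)), base)
})

test_that("forward pass is shape-preserving for all four variants", {
  x <- matrix(runif(32 * 32), 32, 32)
  for (v in c("unet", "tandem", "parallel", "nested")) {
    m <- build_unet(v, base_width = 16, depth = 2, seed = 2)
    lg <- predict(m, x, type = "logits")
    expect_equal(dim(lg), c(32, 32, 2))
    mk <- predict(m, x, type = "mask")
    expect_equal(dim(mk), c(32, 32))
    expect_true(all(mk %in% 0:1))
    # mask is the argmax of the logits
    expect_equal(mk, matrix(as.integer(lg[, , 2] > lg[, , 1]), 32, 32))
  }
})

test_that("a depth-5 encoder runs end to end on a divisible input", {
  m <- build_unet("unet", base_width = 4, depth = 5, seed = 3)
  mk <- predict(m, matrix(runif(32 * 32), 32, 32))
  expect_equal(dim(mk), c(32, 32))
})

test_that("configuration errors surface before any training", {
  expect_error(build_unet("parallel", base_width = 10, depth = 3), "divisible")
  m <- build_unet("unet", base_width = 8, depth = 3)
  expect_error(predict(m, matrix(0.5, 30, 30)), "preprocess_geometry")
})

test_that("seeded initialization gives reproducible predictions", {
  x <- matrix(runif(16 * 16), 16, 16)
  m1 <- build_unet("parallel", base_width = 16, depth = 2, seed = 7)
  m2 <- build_unet("parallel", base_width = 16, depth = 2, seed = 7)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("stack prediction preserves order, geometry and the empty case", {
  m <- build_unet("unet", base_width = 4, depth = 2, seed = 4)
  sl <- matrix(runif(16 * 16), 16, 16)
  st <- image_stack(list(sl, sl, sl))
  mk <- predict_stack(m, st)
  expect_length(mk$slices, 3)
  expect_identical(mk$slices[[1]], mk$slices[[3]])

  expect_length(predict_stack(m, image_stack(list()))$slices, 0)

  # slices carrying preprocessing metadata come back in native geometry
  nat <- matrix(runif(30 * 26), 30, 26)
  pre <- preprocess_geometry(nat, resize_to = c(28, 24), pad_to = c(32, 32))
  mk2 <- predict_stack(m, image_stack(list(pre)))
  expect_equal(dim(mk2$slices[[1]]), c(30, 26))
})

test_that("whole-network gradients agree with finite differences", {
  oct <- asNamespace("octdamage")
  set.seed(5)
  m <- build_unet("parallel", base_width = 4, depth = 2, seed = 6,
                  attention = attention_config("parallel", psa_branches = 2L,
                                               psa_kernel_sizes = c(3L, 5L),
                                               psa_groups = c(1L, 2L),
                                               se_reduction = 2L))
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- array(sample(0:1, 8 * 8 * 2, TRUE), c(8, 8, 2))
  lossfn <- function(params) {
    m2 <- m
    m2$params <- params
    bn <- new.env()
    for (nm in ls(m$bn)) bn[[nm]] <- m$bn[[nm]]
    m2$bn <- bn
    fw <- oct$unet_fwd(m2, x, training = TRUE)
    list(loss = oct$ad_wce(fw$tape, fw$logits, y, c(1, 1.5)), fw = fw)
  }
  r <- lossfn(m$params)
  oct$ad_backward(r$fw$tape, r$loss)
  grads <- lapply(r$fw$leaves,
                  function(l) if (is.null(l$grad)) 0 * l$value else l$grad)
  eps <- 1e-5
  set.seed(8)
  for (nm in sample(names(m$params), 12)) {
    i <- sample(length(m$params[[nm]]), 1)
    pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (lossfn(pp)$loss$value - lossfn(pm)$loss$value) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})
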