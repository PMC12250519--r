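# Reading/writing B-scan images, stacks and label masks, plus the geometric
# preprocessing (resize + zero-pad) applied before segmentation.
#
# In memory a B-scan is a numeric H x W matrix with intensities in [0, 1]
# (8/16-bit files are normalized on read); a mask is an integer H x W matrix
# with labels {0, 1} (stored on disk as {0, 255}).

#' Ordered stack of co-registered B-scans
#'
#' @param slices List of numeric H x W matrices with finite intensities; all
#'   slices must share dimensions. Order is acquisition order.
#' @return Object of class `"image_stack"`.
#' @export
image_stack <- function(slices) {
  stopifnot(is.list(slices))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (!is.matrix(s) || !is.numeric(s)) stop("slice ", i, " is not a numeric matrix")
    if (!all(is.finite(s))) stop("slice ", i, " contains non-finite intensities")
    if (!identical(dim(s), dim(slices[[1]])))
      stop("slice ", i, " dimensions differ from slice 1")
  }
  structure(list(slices = slices), class = "image_stack")
}

#' Ordered stack of segmentation masks
#'
#' @param slices List of integer H x W matrices with labels in `0..k`.
#' @param k Maximum label (default 1: background/damage).
#' @return Object of class `"mask_stack"`.
#' @export
mask_stack <- function(slices, k = 1L) {
  stopifnot(is.list(slices))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (!is.matrix(s)) stop("mask ", i, " is not a matrix")
    if (any(s != as.integer(s)) || any(s < 0L) || any(s > k))
      stop("mask ", i, " has labels outside 0..", k)
    if (!identical(dim(s), dim(slices[[1]])))
      stop("mask ", i, " dimensions differ from mask 1")
  }
  structure(list(slices = lapply(slices, function(s)
    matrix(as.integer(s), nrow(s), ncol(s))), k = as.integer(k)),
    class = "mask_stack")
}

#' @export
length.image_stack <- function(x) length(x$slices)

#' @export
length.mask_stack <- function(x) length(x$slices)

#' @export
print.image_stack <- function(x, ...) {
  d <- if (length(x$slices)) dim(x$slices[[1]]) else c(0, 0)
  cat(sprintf("<image_stack> %d slice(s) of %d x %d\n", length(x$slices), d[1], d[2]))
  invisible(x)
}

#' @export
print.mask_stack <- function(x, ...) {
  d <- if (length(x$slices)) dim(x$slices[[1]]) else c(0, 0)
  cat(sprintf("<mask_stack> %d slice(s) of %d x %d, labels 0..%d\n",
              length(x$slices), d[1], d[2], x$k))
  invisible(x)
}

# Order filenames by their trailing numeric index (b_2 before b_10); files
# without digits sort last; ties broken lexicographically.
numeric_file_order <- function(files) {
  base <- sub("\\.[^.]*$", "", basename(files))
  num <- suppressWarnings(as.numeric(sub(".*?(\\d+)$", "\\1", base)))
  num[!grepl("\\d+$", base)] <- NA
  order(is.na(num), num, files)
}

read_gray <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path, all = TRUE)
         else if (ext == "png") list(png::readPNG(path))
         else stop("unsupported image format: ", path)
  lapply(img, function(m) {
    if (length(dim(m)) == 3) m <- m[, , 1]  # first channel of multi-channel input
    m
  })
}

#' Read a B-scan image stack
#'
#' Reads either a directory of grayscale PNG/TIFF slices (ordered by their
#' trailing numeric filename index, ascending) or a single multi-page TIFF
#' (page order preserved). Intensities are normalized to `[0, 1]`.
#'
#' @param path Directory of image files, or one multi-page TIFF file.
#' @param pattern Filename regular expression used when `path` is a directory.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, pattern = "\\.(png|tif|tiff)$") {
  if (!file.exists(path)) stop("path not found: ", path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = pattern, ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("no image files under ", path)
    files <- files[numeric_file_order(files)]
    slices <- unlist(lapply(files, read_gray), recursive = FALSE)
    d1 <- dim(slices[[1]])
    for (i in seq_along(slices))
      if (!identical(dim(slices[[i]]), d1))
        stop("dimension mismatch: ", files[min(i, length(files))],
             " is ", paste(dim(slices[[i]]), collapse = "x"),
             ", expected ", paste(d1, collapse = "x"))
    image_stack(slices)
  } else {
    image_stack(read_gray(path))
  }
}

#' Write a mask stack to disk
#'
#' Writes one 8-bit grayscale PNG per slice (`slice_###.png`, label 1 stored
#' as 255) into a directory, or a single multi-page TIFF when `path` ends in
#' `.tif`/`.tiff`. Reading the result back reproduces the labels exactly.
#'
#' @param masks A [mask_stack()]; must be nonempty.
#' @param path Output directory or `.tif`/`.tiff` file path.
#' @return Invisibly, the written file path(s).
#' @export
write_mask_stack <- function(masks, path) {
  stopifnot(inherits(masks, "mask_stack"))
  if (!length(masks$slices)) stop("mask stack is empty")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    ok <- tiff::writeTIFF(lapply(masks$slices, function(m) m / max(1L, masks$k)),
                          path, bits.per.sample = 8L)
    if (!ok) stop("could not write ", path)
    invisible(path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- file.path(path, sprintf("slice_%03d.png", seq_along(masks$slices)))
    for (i in seq_along(files))
      png::writePNG(masks$slices[[i]] / max(1L, masks$k), files[i])
    invisible(files)
  }
}

#' Read a mask stack written by [write_mask_stack()]
#'
#' @param path Directory of mask PNGs or a multi-page TIFF.
#' @param k Maximum label encoded in the file (default 1).
#' @return A [mask_stack()].
#' @export
read_mask_stack <- function(path, k = 1L) {
  st <- read_image_stack(path)
  mask_stack(lapply(st$slices, function(m)
    matrix(as.integer(round(m * k)), nrow(m), ncol(m))), k = k)
}

## ---- resampling ----

# Separable bilinear resize with half-pixel-centre coordinate mapping (the
# convention used by OpenCV, whose resize the preprocessing mirrors).
resize_bilinear <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  if (h == H && w == W) return(m)
  sr <- pmin(pmax((seq_len(h) - 0.5) * H / h - 0.5, 0), H - 1)
  sc <- pmin(pmax((seq_len(w) - 0.5) * W / w - 0.5, 0), W - 1)
  r0 <- floor(sr); c0 <- floor(sc)
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- sr - r0; fc <- sc - c0
  m00 <- m[r0 + 1, c0 + 1, drop = FALSE]; m01 <- m[r0 + 1, c1 + 1, drop = FALSE]
  m10 <- m[r1 + 1, c0 + 1, drop = FALSE]; m11 <- m[r1 + 1, c1 + 1, drop = FALSE]
  m00 * outer(1 - fr, 1 - fc) + m01 * outer(1 - fr, fc) +
    m10 * outer(fr, 1 - fc) + m11 * outer(fr, fc)
}

resize_nearest <- function(m, h, w) {
  H <- nrow(m); W <- ncol(m)
  if (h == H && w == W) return(m)
  ri <- pmin(pmax(floor((seq_len(h) - 0.5) * H / h), 0), H - 1) + 1
  ci <- pmin(pmax(floor((seq_len(w) - 0.5) * W / w), 0), W - 1) + 1
  m[ri, ci, drop = FALSE]
}

## ---- geometric preprocessing ----

#' Resize and zero-pad a B-scan to the network input size
#'
#' Resizes the image to `resize_to` (bilinear for intensity images, nearest
#' neighbour for label masks so labels stay integer) and centres it in a
#' zero-padded `pad_to` frame. The applied geometry (original size, scale
#' factors, pad offsets) is recorded in the `"geometry"` attribute so
#' [restore_geometry()] can map network-size masks back onto native scan
#' pixels for volumetry.
#'
#' @param image Numeric matrix (B-scan) or integer matrix (mask); also accepts
#'   an [image_stack()]/[mask_stack()], processing every slice.
#' @param resize_to Target (rows, cols) of the content, default `c(460, 460)`.
#' @param pad_to Padded output (rows, cols), default `c(512, 512)`; must be
#'   at least `resize_to` componentwise.
#' @param interp `"bilinear"` or `"nearest"`; masks force `"nearest"`.
#' @return Matrix of size `pad_to` with a `"geometry"` attribute, or a stack
#'   thereof.
#' @export
preprocess_geometry <- function(image, resize_to = c(460L, 460L),
                                pad_to = c(512L, 512L),
                                interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (any(pad_to < resize_to))
    stop("pad_to must be at least resize_to componentwise")
  if (inherits(image, "image_stack"))
    return(image_stack(lapply(image$slices, preprocess_geometry,
                              resize_to = resize_to, pad_to = pad_to,
                              interp = interp)))
  if (inherits(image, "mask_stack"))
    return(structure(list(slices = lapply(image$slices, preprocess_geometry,
                                          resize_to = resize_to, pad_to = pad_to,
                                          interp = "nearest"),
                          k = image$k), class = "mask_stack"))
  is_mask <- is.integer(image)
  if (is_mask) interp <- "nearest"
  rs <- if (interp == "bilinear") resize_bilinear(image, resize_to[1], resize_to[2])
        else resize_nearest(image, resize_to[1], resize_to[2])
  off <- (pad_to - resize_to) %/% 2L
  out <- matrix(if (is_mask) 0L else 0, pad_to[1], pad_to[2])
  out[off[1] + seq_len(resize_to[1]), off[2] + seq_len(resize_to[2])] <-
    if (is_mask) matrix(as.integer(rs), nrow(rs), ncol(rs)) else rs
  attr(out, "geometry") <- list(orig = dim(image), resize_to = resize_to,
                                pad_to = pad_to, offset = off)
  out
}

#' Map a network-size mask or image back to native scan geometry
#'
#' Inverts [preprocess_geometry()]: crops the centred content out of the
#' padded frame and resizes it back to the original dimensions (nearest
#' neighbour for integer masks, bilinear otherwise). Voxel spacings are
#' defined on native pixels, so volumetry requires masks in this geometry.
#'
#' @param x Matrix produced at `pad_to` size, or a mask/image stack.
#' @param geometry Geometry record; defaults to `attr(x, "geometry")`.
#' @return Matrix of the original size (or a stack thereof).
#' @export
restore_geometry <- function(x, geometry = NULL) {
  if (inherits(x, "mask_stack"))
    return(mask_stack(lapply(x$slices, restore_geometry, geometry = geometry),
                      k = x$k))
  if (inherits(x, "image_stack"))
    return(image_stack(lapply(x$slices, restore_geometry, geometry = geometry)))
  g <- geometry %||% attr(x, "geometry")
  if (is.null(g)) stop("no geometry metadata; pass `geometry` explicitly")
  cont <- x[g$offset[1] + seq_len(g$resize_to[1]),
            g$offset[2] + seq_len(g$resize_to[2]), drop = FALSE]
  if (is.integer(x)) {
    r <- resize_nearest(cont, g$orig[1], g$orig[2])
    matrix(as.integer(r), nrow(r), ncol(r))
  } else {
    resize_bilinear(cont, g$orig[1], g$orig[2])
  }
}
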