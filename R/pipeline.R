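# End-to-end driver: denoise -> preprocess -> train (or load) -> segment ->
# evaluate -> volumetry, with every stage's outputs written to a run
# directory together with a machine-readable manifest.

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Any subset of fields can be
#' overridden; the remainder keep the defaults shown by [dump_defaults()].
#'
#' @param input Either `list(type = "phantom", n = 40)` (the standard
#'   phantom benchmark) or `list(type = "files", images = <dir>, masks =
#'   <dir or NULL>)`.
#' @param denoise `list(enabled = TRUE, ...)` with [bm3d_config()] fields.
#' @param preprocess `list(enabled = FALSE, resize_to, pad_to)`; enable for
#'   native-geometry scans that need the network input size.
#' @param model `list(variant, base_width, depth)` for [build_unet()].
#' @param train [train_config()] fields plus `enabled`; when `model_path` is
#'   set training is skipped and the checkpoint loaded instead.
#' @param geometry [voxel_geometry()] spacings `dx`, `dy`, `dz`.
#' @param seed Master seed for the run.
#' @param out_dir Run directory (created if missing).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = list(type = "phantom", n = 40L),
                            denoise = list(enabled = TRUE),
                            preprocess = list(enabled = FALSE,
                                              resize_to = c(460L, 460L),
                                              pad_to = c(512L, 512L)),
                            model = list(variant = "parallel",
                                         base_width = 16L, depth = 3L),
                            train = list(enabled = TRUE, epochs = 30L,
                                         lr = 3e-4, lr_period = 30L),
                            geometry = list(dx = 10, dy = 22, dz = 50),
                            seed = 1L,
                            out_dir = tempfile("octdamage_run_")) {
  structure(list(input = input, denoise = denoise, preprocess = preprocess,
                 model = model, train = train, geometry = geometry,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Print every pipeline default as YAML
#' @return The YAML string, invisibly; also printed.
#' @export
dump_defaults <- function() {
  y <- yaml::as.yaml(unclass(pipeline_config(out_dir = "runs/latest")))
  cat(y)
  invisible(y)
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat sections mirror the [pipeline_config()] arguments; missing fields
#' keep their defaults.
#'
#' @param path YAML file.
#' @return A `"pipeline_config"`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- unclass(pipeline_config())
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      utils::modifyList(base[[nm]], user[[nm]]) else user[[nm]]
  }
  structure(base, class = "pipeline_config")
}

#' Save / load a trained segmenter
#'
#' Checkpoints embed the full model configuration, parameters and
#' batch-norm state.
#'
#' @param model An `"oct_unet"`.
#' @param path Checkpoint file path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "oct_unet"))
  obj <- model
  obj$bn <- as.list(model$bn)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  bn <- new.env(parent = emptyenv())
  for (nm in names(obj$bn)) bn[[nm]] <- obj$bn[[nm]]
  obj$bn <- bn
  class(obj) <- "oct_unet"
  obj
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full damage-analysis pipeline
#'
#' Executes denoise, optional geometric preprocessing, training (or
#' checkpoint loading), stack segmentation, evaluation (when ground truth is
#' present) and voxel volumetry, writing `report.csv`, `volumes.csv`,
#' `history.csv`, predicted masks and a `manifest.json` into the run
#' directory. With a fixed `seed` the whole run is reproducible.
#'
#' @param cfg A [pipeline_config()].
#' @return List with the trained `model`, the evaluation `report`, the
#'   `volumes` table and the `out_dir`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)

  ## ---- input ----
  if (identical(cfg$input$type, "phantom")) {
    n <- cfg$input$n %||% 40L
    pipeline_log("input", "generating %d phantom pairs (seed %d)", n, cfg$seed)
    pairs <- phantom_benchmark(n, seed = cfg$seed)
    images <- lapply(pairs, function(p) p$images$slices[[1]])
    masks <- lapply(pairs, function(p) p$truth$slices[[1]])
  } else {
    pipeline_log("input", "reading stacks from %s", cfg$input$images)
    st <- read_image_stack(cfg$input$images)
    images <- st$slices
    masks <- if (!is.null(cfg$input$masks))
      read_mask_stack(cfg$input$masks)$slices else NULL
  }

  ## ---- denoise ----
  if (isTRUE(cfg$denoise$enabled)) {
    bc <- do.call(bm3d_config,
                  cfg$denoise[setdiff(names(cfg$denoise), "enabled")])
    pipeline_log("denoise", "BM3D %dx%d window %d thr %.2g iters %d on %d image(s)",
                 bc$block_size, bc$block_size, bc$search_window,
                 bc$hard_threshold_coeff, bc$iterations, length(images))
    images <- lapply(images, bm3d_denoise, cfg = bc)
  }

  ## ---- preprocess ----
  if (isTRUE(cfg$preprocess$enabled)) {
    pipeline_log("preprocess", "resize to %s, pad to %s",
                 paste(cfg$preprocess$resize_to, collapse = "x"),
                 paste(cfg$preprocess$pad_to, collapse = "x"))
    images <- lapply(images, preprocess_geometry,
                     resize_to = cfg$preprocess$resize_to,
                     pad_to = cfg$preprocess$pad_to)
    if (!is.null(masks))
      masks <- lapply(masks, preprocess_geometry,
                      resize_to = cfg$preprocess$resize_to,
                      pad_to = cfg$preprocess$pad_to)
  }

  ## ---- model ----
  model <- build_unet(cfg$model$variant %||% "parallel",
                      base_width = cfg$model$base_width %||% 16L,
                      depth = cfg$model$depth %||% 3L,
                      seed = child_seed(cfg$seed, 3L))
  split <- NULL
  if (!is.null(cfg$train$model_path)) {
    pipeline_log("train", "loading checkpoint %s", cfg$train$model_path)
    model <- load_model(cfg$train$model_path)
  } else if (isTRUE(cfg$train$enabled %||% TRUE)) {
    if (is.null(masks)) stop("training requires ground-truth masks")
    tc_args <- cfg$train[setdiff(names(cfg$train), c("enabled", "model_path"))]
    tc_args$seed <- tc_args$seed %||% child_seed(cfg$seed, 4L)
    tc <- do.call(train_config, tc_args)
    pipeline_log("train", "%s variant, %d epochs, batch %d",
                 model$cfg$variant, tc$epochs, tc$batch_size)
    model <- train_segmenter(model, list(images = images, masks = masks), tc)
    split <- model$split
    utils::write.csv(model$history, file.path(cfg$out_dir, "history.csv"),
                     row.names = FALSE)
    save_model(model, file.path(cfg$out_dir, "model.rds"))
    outputs <- c(outputs, "history.csv", "model.rds")
  }

  ## ---- segment ----
  eval_idx <- if (!is.null(split)) split$test else seq_along(images)
  pipeline_log("segment", "predicting %d image(s)", length(eval_idx))
  preds <- lapply(images[eval_idx],
                  function(im) predict(model, im, type = "mask"))
  pred_stack <- mask_stack(lapply(seq_along(preds), function(i) {
    geom <- attr(images[[eval_idx[i]]], "geometry")
    if (!is.null(geom)) restore_geometry(preds[[i]], geom) else preds[[i]]
  }))
  write_mask_stack(pred_stack, file.path(cfg$out_dir, "masks"))
  outputs <- c(outputs, "masks/")

  ## ---- evaluate ----
  report <- NULL
  if (!is.null(masks)) {
    ev <- metrics_report(preds, masks[eval_idx])
    report <- data.frame(dice = ev$dice, miou = ev$miou, mpa = ev$mpa,
                         accuracy = ev$accuracy)
    utils::write.csv(report, file.path(cfg$out_dir, "report.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "report.csv")
    pipeline_log("evaluate", "Dice %.4f mIoU %.4g mPA %.4g acc %.4g",
                 ev$dice, ev$miou, ev$mpa, ev$accuracy)
  } else {
    pipeline_log("evaluate", "no ground truth; stage skipped")
  }

  ## ---- volumetry ----
  geom <- voxel_geometry(cfg$geometry$dx, cfg$geometry$dy, cfg$geometry$dz)
  doses <- c(25.0, 31.1, 36.5, 41.2)
  tps <- c(0, 1, 3, 7, 14)
  vols <- lapply(seq_along(pred_stack$slices), function(i) {
    damage_volume(list(pred_stack$slices[[i]]), geom,
                  meta = list(dose = doses[(i - 1) %% length(doses) + 1],
                              timepoint = tps[((i - 1) %/% length(doses)) %% length(tps) + 1],
                              item = eval_idx[i]))
  })
  per_item <- data.frame(item = vapply(vols, function(v) v$meta$item, numeric(1)),
                         pixels = vapply(vols, function(v) sum(v$per_slice_counts), numeric(1)),
                         volume_um3 = vapply(vols, function(v) v$V, numeric(1)))
  utils::write.csv(per_item, file.path(cfg$out_dir, "volumes.csv"),
                   row.names = FALSE)
  outputs <- c(outputs, "volumes.csv")
  healing <- tryCatch(healing_table(vols), error = function(e) NULL)
  if (!is.null(healing)) {
    utils::write.csv(healing, file.path(cfg$out_dir, "healing.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "healing.csv")
  }
  pipeline_log("volume", "total damage volume %.4g um^3 over %d item(s)",
               sum(per_item$volume_um3), nrow(per_item))

  ## ---- manifest ----
  cfg_path <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path)
  manifest <- list(config = "config.yaml",
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   seed = cfg$seed,
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(model = model, report = report, volumes = per_item,
                 healing = healing, out_dir = cfg$out_dir))
}
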