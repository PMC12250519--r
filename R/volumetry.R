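# Voxel-based damage-volume quantification: V = V_P * sum_k F(s_k), where
# F(s_k) counts damage-labelled pixels in slice k and V_P is the physical
# volume of one voxel (native B-scan pixel extruded by the slice spacing).

#' Voxel geometry
#'
#' Physical spacings of one voxel. The defaults follow the imaging geometry
#' of the dorsal-skin scans: 10 um lateral (width axis), 22 um axial
#' (height/depth axis), 50 um between slices, giving a per-voxel volume of
#' 11,000 um^3.
#'
#' @param dx Lateral spacing in micrometres (mask column axis).
#' @param dy Axial spacing in micrometres (mask row axis).
#' @param dz Inter-slice spacing in micrometres.
#' @return Object of class `"voxel_geometry"` with the per-voxel volume
#'   `v_p = dx * dy * dz` (um^3).
#' @export
voxel_geometry <- function(dx = 10, dy = 22, dz = 50) {
  if (any(c(dx, dy, dz) <= 0)) stop("spacings must be positive")
  structure(list(dx = dx, dy = dy, dz = dz, v_p = dx * dy * dz),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("<voxel_geometry> %g x %g x %g um, V_P = %g um^3\n",
              x$dx, x$dy, x$dz, x$v_p))
  invisible(x)
}

#' Count damage pixels in a binary mask
#'
#' `F(s_k)`: the number of pixels labelled 1 in one B-scan's mask.
#'
#' @param mask Integer matrix with labels in `{0, 1}`.
#' @return Nonnegative integer count.
#' @export
damage_pixel_count <- function(mask) {
  if (any(!mask %in% c(0L, 1L)))
    stop("mask is not binary (labels other than 0/1 present)")
  sum(mask == 1L)
}

#' Damage volume of a mask stack
#'
#' Accumulates the damage-pixel counts over all slices and multiplies by the
#' per-voxel volume. Masks must be in native scan geometry (use
#' [restore_geometry()] on network-size masks first, since the voxel
#' spacings are defined on native pixels).
#'
#' @param masks A [mask_stack()] or list of binary masks; must be nonempty.
#' @param geom A [voxel_geometry()].
#' @param meta Optional named list carried through (e.g. `dose`,
#'   `timepoint`).
#' @return Object of class `"damage_volume"`: total volume `V` (um^3),
#'   `per_slice_counts`, `geometry`, `meta`.
#' @export
damage_volume <- function(masks, geom = voxel_geometry(), meta = NULL) {
  slices <- if (inherits(masks, "mask_stack")) masks$slices else masks
  if (!length(slices)) stop("empty mask stack")
  stopifnot(inherits(geom, "voxel_geometry"))
  counts <- vapply(slices, damage_pixel_count, numeric(1))
  structure(list(V = geom$v_p * sum(counts), per_slice_counts = counts,
                 geometry = geom, meta = meta),
            class = "damage_volume")
}

#' @export
print.damage_volume <- function(x, ...) {
  cat(sprintf("<damage_volume> V = %.4g um^3 over %d slice(s), V_P = %g um^3\n",
              x$V, length(x$per_slice_counts), x$geometry$v_p))
  invisible(x)
}

#' Healing table across dose / recovery-time groups
#'
#' Collates damage volumes into one row per (dose, timepoint) pair, sorted
#' by dose then timepoint, with the relative change `V(t) / V(t0)` against
#' the earliest timepoint of each dose group.
#'
#' @param results List of [damage_volume()] objects whose `meta` carries
#'   `dose` (J/cm^2) and a numeric `timepoint`.
#' @return Data frame with columns `dose`, `timepoint`, `volume_um3`,
#'   `relative_change`.
#' @export
healing_table <- function(results) {
  if (!length(results)) stop("no results")
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "damage_volume"))
    if (is.null(r$meta$dose) || is.null(r$meta$timepoint))
      stop("every result needs meta$dose and meta$timepoint")
    data.frame(dose = r$meta$dose, timepoint = r$meta$timepoint,
               volume_um3 = r$V)
  })
  tab <- do.call(rbind, rows)
  key <- paste(tab$dose, tab$timepoint, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate (dose, timepoint) keys: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  tab <- tab[order(tab$dose, tab$timepoint), , drop = FALSE]
  tab$relative_change <- stats::ave(tab$volume_um3, tab$dose,
                                    FUN = function(v) v / v[1])
  rownames(tab) <- NULL
  tab
}
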