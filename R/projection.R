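# Maximum-intensity projections.
#
# Views are fixed, 90 degrees apart:
#   coronal  = project along AP (internal axis 2) -> image axes (LR, IS)
#   sagittal = project along LR (internal axis 1) -> image axes (AP, IS)
# Image axis 1 (x) is the horizontal anatomical axis, image axis 2 (y) is IS.

mip_view_axis <- function(view) {
  switch(view, coronal = 2L, sagittal = 1L,
         stop2("unknown view '", view, "': use 'coronal' or 'sagittal'"))
}

new_mip <- function(data, pixel_spacing, view, class) {
  structure(list(data = data, pixel_spacing = as.numeric(pixel_spacing),
                 view = view),
            class = class)
}

#' @export
print.mip_image <- function(x, ...) {
  cat("mip_image [", x$view, "]: ", paste(dim(x$data), collapse = " x "),
      " px @ ", paste(signif(x$pixel_spacing, 4), collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.mip_mask <- function(x, ...) {
  cat("mip_mask [", x$view, "]: ", paste(dim(x$data), collapse = " x "),
      " px @ ", paste(signif(x$pixel_spacing, 4), collapse = " x "), " mm; ",
      sum(x$data), " lesion px\n", sep = "")
  invisible(x)
}

# per-ray max along one axis of a 3D array, vectorized over slices
project_max <- function(arr, axis) {
  n <- dim(arr)[axis]
  out <- switch(axis, arr[1, , ], arr[, 1, ], arr[, , 1])
  for (s in seq_len(n)[-1L]) {
    out <- pmax(out, switch(axis, arr[s, , ], arr[, s, ], arr[, , s]))
  }
  out
}

#' Maximum-intensity projection of a PET volume
#'
#' Each output pixel is the maximum intensity observed along the ray normal to
#' the projection plane: along the anterior-posterior axis for the coronal
#' view, along the left-right axis for the sagittal view. Pixel spacing is
#' inherited unchanged from the two retained volume axes (no resampling).
#'
#' @param volume A [pet_volume()].
#' @param view `"coronal"` or `"sagittal"`.
#' @return A `mip_image`: 2D grid with `pixel_spacing` (mm) and `view`.
#' @export
mip_project <- function(volume, view = c("coronal", "sagittal")) {
  stopifnot(inherits(volume, "pet_volume"))
  view <- match.arg(view)
  axis <- mip_view_axis(view)
  keep <- setdiff(1:3, axis)
  new_mip(project_max(volume$data, axis), volume$spacing[keep], view, "mip_image")
}

#' Project a 3D lesion mask to a 2D MIP mask
#'
#' A pixel is 1 iff any voxel along its ray is 1 (the maximum of a binary ray
#' is a logical OR). This projects the lesion regions themselves; it is not a
#' re-thresholding of the projected intensities.
#'
#' @param mask A [lesion_mask()].
#' @param view `"coronal"` or `"sagittal"`.
#' @return A `mip_mask`.
#' @export
mip_project_mask <- function(mask, view = c("coronal", "sagittal")) {
  stopifnot(inherits(mask, "lesion_mask"))
  view <- match.arg(view)
  axis <- mip_view_axis(view)
  keep <- setdiff(1:3, axis)
  out <- project_max(mask$data, axis)
  new_mip(matrix(as.integer(out), nrow = nrow(out)), mask$spacing[keep],
          view, "mip_mask")
}

#' Bundle coronal and sagittal projections of a volume/mask pair
#'
#' @param volume A [pet_volume()].
#' @param mask The aligned [lesion_mask()], or `NULL` for image-only pairs.
#' @return A `mip_pair`: list with `coronal` and `sagittal`, each holding
#'   `image` ([mip_project()]) and `mask` ([mip_project_mask()] or `NULL`).
#' @export
make_mip_pair <- function(volume, mask = NULL) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "lesion_mask"))
    if (!identical(dim(mask$data), dim(volume$data))) {
      stop2("mask shape does not match volume shape")
    }
    if (any(abs(mask$spacing - volume$spacing) > 1e-3)) {
      stop2("mask spacing does not match volume spacing")
    }
  }
  one_view <- function(view) {
    list(image = mip_project(volume, view),
         mask = if (is.null(mask)) NULL else mip_project_mask(mask, view))
  }
  structure(list(coronal = one_view("coronal"), sagittal = one_view("sagittal")),
            class = "mip_pair")
}

#' @export
print.mip_pair <- function(x, ...) {
  cat("mip_pair:\n  ")
  print(x$coronal$image)
  cat("  ")
  print(x$sagittal$image)
  invisible(x)
}

#' Export a MIP view with optional mask overlay as a PNG (QC figure)
#'
#' @param mip A `mip_image`.
#' @param path Output PNG path.
#' @param mask Optional `mip_mask` drawn as a contoured overlay.
#' @return `path`, invisibly.
#' @export
export_mip_png <- function(mip, path, mask = NULL) {
  stopifnot(inherits(mip, "mip_image"))
  d <- mip$data
  grDevices::png(path, width = nrow(d) * 4, height = ncol(d) * 4)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  # display with IS (image y) pointing up
  graphics::image(seq_len(nrow(d)), seq_len(ncol(d)), d,
                  col = grDevices::gray.colors(256, start = 1, end = 0),
                  useRaster = TRUE, axes = FALSE, xlab = "", ylab = "")
  if (!is.null(mask) && sum(mask$data) > 0) {
    graphics::contour(seq_len(nrow(d)), seq_len(ncol(d)), mask$data,
                      levels = 0.5, add = TRUE, drawlabels = FALSE,
                      col = "red", lwd = 2)
  }
  invisible(path)
}
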