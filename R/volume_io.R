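#' Construct a whole-body PET volume
#'
#' A `pet_volume` is a 3D grid of non-negative uptake values (arbitrary,
#' SUV-like units) with physical voxel spacing in mm. Axes follow a fixed
#' internal anatomical convention: axis 1 runs left-to-right (LR), axis 2
#' posterior-to-anterior (AP), axis 3 inferior-to-superior (IS). All
#' downstream view semantics (coronal = projection along AP, sagittal =
#' projection along LR) refer to this convention.
#'
#' @param data 3D numeric array of non-negative, finite intensities.
#' @param spacing Numeric length-3 vector, voxel spacing in mm along
#'   (LR, AP, IS). All components must be > 0.
#' @param orientation Direction string of the source file (for provenance),
#'   default `"RAS"`.
#' @return An object of class `pet_volume` with elements `data`, `spacing`
#'   (mm) and `orientation`.
#' @seealso [read_volume()], [mip_project()], [generate_phantom()]
#' @export
pet_volume <- function(data, spacing, orientation = "RAS") {
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "pet_volume data must be a 3D array")
  assert_that(all(dim(data) >= 2L), "grid must have >= 2 planes along every axis")
  assert_that(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
              "spacing must be 3 positive finite values (mm)")
  assert_that(all(is.finite(data)), "intensities must all be finite")
  assert_that(min(data) >= 0, "intensities must be non-negative")
  structure(list(data = data, spacing = as.numeric(spacing),
                 orientation = orientation),
            class = "pet_volume")
}

#' Construct a binary 3D lesion mask
#'
#' A `lesion_mask` is a binary grid aligned voxel-for-voxel with a companion
#' [pet_volume()]; its 26-connected components are the individual lesions.
#'
#' @param data 3D array with values in \{0, 1\}.
#' @param spacing Voxel spacing in mm along (LR, AP, IS).
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, spacing) {
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "lesion_mask data must be a 3D array")
  assert_that(length(spacing) == 3L && all(is.finite(spacing)) && all(spacing > 0),
              "spacing must be 3 positive finite values (mm)")
  u <- unique(as.vector(data))
  assert_that(all(u %in% c(0, 1)), "mask values must be exactly {0, 1}")
  structure(list(data = array(as.integer(data), dim = dim(data)),
                 spacing = as.numeric(spacing)),
            class = "lesion_mask")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("pet_volume:", paste(dim(x$data), collapse = " x "),
      "voxels @", paste(signif(x$spacing, 4), collapse = " x "), "mm (LR, AP, IS)\n")
  cat("  intensity range:", signif(min(x$data), 4), "-", signif(max(x$data), 4), "\n")
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("lesion_mask:", paste(dim(x$data), collapse = " x "),
      "voxels @", paste(signif(x$spacing, 4), collapse = " x "), "mm;",
      sum(x$data), "lesion voxels\n")
  invisible(x)
}

#' Read a 3D PET volume from a NIfTI-1 file
#'
#' The volume is reoriented to the internal (LR, AP, IS) axis convention by
#' decomposing the header affine (sform preferred, then qform, then pixdim).
#' Only axis-aligned orientations are supported; oblique affines raise an
#' error rather than being silently resampled. The original on-disk
#' orientation is recorded in the returned object.
#'
#' @param path Path to a `.nii` or `.nii.gz` file with a 3D payload.
#' @return A [pet_volume()].
#' @export
read_volume <- function(path) {
  nii <- read_nifti(path)
  if (!all(is.finite(nii$data))) stop2("volume contains non-finite voxels: ", path)
  if (min(nii$data) < 0) {
    # PET uptake is non-negative by construction; clamp tiny numeric negatives
    if (min(nii$data) < -1e-6 * max(abs(nii$data))) {
      stop2("volume contains negative intensities: ", path)
    }
    nii$data[nii$data < 0] <- 0
  }
  pet_volume(nii$data, nii$spacing, orientation = nii$orientation)
}

#' Read a binary lesion mask aligned to a reference volume
#'
#' Values are binarized at 0.5 (so \{0, 255\}-coded masks are accepted, with a
#' warning). Shape or spacing disagreement with the reference beyond 1e-3 mm
#' is an error: masks are never resampled.
#'
#' @param path Path to a NIfTI-1 mask file.
#' @param reference The companion [pet_volume()].
#' @return A [lesion_mask()].
#' @export
read_mask <- function(path, reference) {
  stopifnot(inherits(reference, "pet_volume"))
  nii <- read_nifti(path)
  if (!identical(dim(nii$data), dim(reference$data))) {
    stop2("mask shape (", paste(dim(nii$data), collapse = "x"),
          ") does not match reference volume (",
          paste(dim(reference$data), collapse = "x"), ")")
  }
  if (any(abs(nii$spacing - reference$spacing) > 1e-3)) {
    stop2("mask spacing (", paste(signif(nii$spacing, 6), collapse = ", "),
          " mm) does not match reference (",
          paste(signif(reference$spacing, 6), collapse = ", "), " mm)")
  }
  vals <- unique(as.vector(nii$data))
  if (!all(vals %in% c(0, 1))) {
    lo <- vals[vals <= 0.5]; hi <- vals[vals > 0.5]
    if (any(abs(lo) > 1e-6) || length(unique(hi)) > 1L) {
      stop2("mask values are not binarizable to {0,1}: found ",
            paste(signif(utils::head(sort(vals), 5), 4), collapse = ", "))
    }
    warning("mask values ", paste(sort(vals), collapse = "/"),
            " binarized at 0.5 to {0,1}", call. = FALSE)
  }
  lesion_mask(array(as.integer(nii$data > 0.5), dim = dim(nii$data)),
              reference$spacing)
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' Intensities are stored as float32 (round-trip accurate to 1e-6 relative),
#' masks as uint8 (bit-exact round-trip). The canonical RAS orientation is
#' written; `orientation` allows writing deliberately flipped files, e.g. for
#' orientation-handling tests.
#'
#' @param x A [pet_volume()] or [lesion_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param orientation Direction string for the stored axis order, default
#'   `"RAS"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, orientation = "RAS") {
  if (inherits(x, "pet_volume")) {
    write_nifti(x$data, x$spacing, path, datatype = "float32",
                orientation = orientation)
  } else if (inherits(x, "lesion_mask")) {
    write_nifti(x$data, x$spacing, path, datatype = "uint8",
                orientation = orientation)
  } else {
    stop2("write_volume expects a pet_volume or lesion_mask")
  }
  invisible(path)
}
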