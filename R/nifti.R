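# Minimal NIfTI-1 (.nii / .nii.gz) reader and writer.
#
# Only what whole-body PET volumes and binary lesion masks need: 3D payloads,
# scalar datatypes, scl_slope/scl_inter rescaling, and axis-aligned sform /
# qform orientation. Oblique affines are rejected rather than resampled.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti_header <- function(con) {
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop2("not a NIfTI-1 file: header shorter than 348 bytes")
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop2("not a NIfTI-1 file: sizeof_hdr is not 348")
  }
  rb <- function(off, what, n, size, signed = TRUE) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what,
            n = n, size = size, signed = signed, endian = endian)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop2("not a NIfTI-1 file: bad magic '", magic, "'")
  list(
    endian = endian,
    dim = rb(40L, "integer", 8L, 2L),
    datatype = rb(70L, "integer", 1L, 2L),
    bitpix = rb(72L, "integer", 1L, 2L),
    pixdim = rb(76L, "numeric", 8L, 4L),
    vox_offset = rb(108L, "numeric", 1L, 4L),
    scl_slope = rb(112L, "numeric", 1L, 4L),
    scl_inter = rb(116L, "numeric", 1L, 4L),
    qform_code = rb(252L, "integer", 1L, 2L),
    sform_code = rb(254L, "integer", 1L, 2L),
    quatern = rb(256L, "numeric", 3L, 4L),
    qoffset = rb(268L, "numeric", 3L, 4L),
    srow = rbind(rb(280L, "numeric", 4L, 4L),
                 rb(296L, "numeric", 4L, 4L),
                 rb(312L, "numeric", 4L, 4L)),
    magic = magic
  )
}

# 3x3 spatial affine (voxel index -> world mm, RAS+ world axes) from the header
nifti_affine <- function(hdr) {
  if (hdr$sform_code > 0L) {
    return(hdr$srow[, 1:3, drop = FALSE])
  }
  if (hdr$qform_code > 0L) {
    b <- hdr$quatern[1]; c <- hdr$quatern[2]; d <- hdr$quatern[3]
    a2 <- 1 - b * b - c * c - d * d
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a * a + b * b - c * c - d * d, 2 * (b * c - a * d),           2 * (b * d + a * c),
      2 * (b * c + a * d),           a * a + c * c - b * b - d * d, 2 * (c * d - a * b),
      2 * (b * d - a * c),           2 * (c * d + a * b),           a * a + d * d - b * b - c * c
    ), nrow = 3, byrow = TRUE)
    qfac <- if (hdr$pixdim[1] < 0) -1 else 1
    sp <- abs(hdr$pixdim[2:4])
    R %*% diag(c(sp[1], sp[2], sp[3] * qfac))
  } else {
    diag(abs(hdr$pixdim[2:4]))
  }
}

# decompose an axis-aligned affine into (permutation, sign, spacing);
# world axis w is carried by data axis perm[w] with direction sgn[w]
orientation_from_affine <- function(A) {
  perm <- integer(3)
  sgn <- numeric(3)
  spacing <- numeric(3)
  for (w in 1:3) {
    d <- which.max(abs(A[w, ]))
    perm[w] <- d
    sgn[w] <- sign(A[w, d])
    spacing[w] <- abs(A[w, d])
    off <- abs(A[w, -d])
    if (any(off > 1e-3 * max(abs(A[w, d]), 1e-12))) {
      stop2("oblique NIfTI affine (srow/quatern): only axis-aligned orientations are supported")
    }
  }
  if (length(unique(perm)) != 3L) stop2("degenerate NIfTI affine: axes are not a permutation")
  list(perm = perm, sgn = sgn, spacing = spacing)
}

# orientation string such as "RAS", "LPS": direction of increasing data index
orientation_string <- function(orient) {
  lab <- matrix(c("L", "R", "P", "A", "I", "S"), nrow = 2)
  out <- character(3)
  for (d in 1:3) {
    w <- which(orient$perm == d)
    out[d] <- lab[if (orient$sgn[w] > 0) 2 else 1, w]
  }
  paste0(out, collapse = "")
}

# reorder/flip a 3D array so axes run (LR+, PA+ -> A, IS+) i.e. internal RAS
reorient_to_ras <- function(arr, orient) {
  arr <- aperm(arr, orient$perm)
  for (w in 1:3) {
    if (orient$sgn[w] < 0) {
      idx <- rev(seq_len(dim(arr)[w]))
      arr <- switch(w,
                    arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
    }
  }
  arr
}

read_nifti <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- read_nifti_header(con)
  ndim <- hdr$dim[1]
  if (ndim != 3L) {
    stop2("expected a 3D payload, but header dim[0] = ", ndim,
          " (grid ", paste(hdr$dim[2:(1 + max(ndim, 1))], collapse = "x"), ")")
  }
  dims <- hdr$dim[2:4]
  if (any(dims < 2L)) stop2("grid must have >= 2 planes along every axis, got ",
                            paste(dims, collapse = "x"))
  dt <- NIFTI_DT[[as.character(hdr$datatype)]]
  if (is.null(dt)) stop2("unsupported NIfTI datatype code: ", hdr$datatype)
  # skip extension bytes between header end and vox_offset (no seek on gz)
  skip <- as.integer(round(hdr$vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = hdr$endian)
  if (length(vals) < n) stop2("truncated NIfTI data payload")
  vals <- as.numeric(vals)
  if (is.finite(hdr$scl_slope) && hdr$scl_slope != 0 &&
      !(hdr$scl_slope == 1 && hdr$scl_inter == 0)) {
    vals <- vals * hdr$scl_slope + hdr$scl_inter
  }
  arr <- array(vals, dim = dims)
  A <- nifti_affine(hdr)
  orient <- orientation_from_affine(A)
  if (any(orient$spacing <= 0)) {
    stop2("zero or negative voxel spacing in header field pixdim/srow: ",
          paste(signif(orient$spacing, 6), collapse = ", "))
  }
  list(
    data = reorient_to_ras(arr, orient),
    spacing = orient$spacing,          # mm along internal (LR, AP, IS)
    orientation = orientation_string(orient)
  )
}

# datatype: "float32" for intensities, "uint8" for masks.
# orientation: direction labels of increasing data index, e.g. "RAS", "LPS";
# data is assumed to be in internal RAS order and is flipped/permuted to match.
write_nifti <- function(data, spacing, path, datatype = c("float32", "uint8"),
                        orientation = "RAS") {
  datatype <- match.arg(datatype)
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L)
  codes <- c(L = -1, R = 1, P = -2, A = 2, I = -3, S = 3)
  oc <- codes[strsplit(orientation, "")[[1]]]
  if (length(oc) != 3L || anyNA(oc) || !setequal(abs(oc), 1:3)) {
    stop2("invalid orientation string: ", orientation)
  }
  # build the stored array: stored axis d carries world axis abs(oc[d])
  perm <- abs(oc)
  arr <- aperm(data, perm)           # stored axis d = internal axis perm[d]
  sp_stored <- spacing[perm]
  for (d in 1:3) {
    if (oc[d] < 0) {
      idx <- rev(seq_len(dim(arr)[d]))
      arr <- switch(d,
                    arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
    }
  }
  srow <- matrix(0, 3, 4)
  for (d in 1:3) srow[perm[d], d] <- sign(oc[d]) * sp_stored[d]
  # anchor the first stored voxel so world coordinates match internal RAS
  for (w in 1:3) {
    d <- which(perm == w)
    if (oc[d] < 0) srow[w, 4] <- (dim(arr)[d] - 1L) * sp_stored[d] * 1  # flipped axis starts at max
  }
  dt_code <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wB <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wB(348L, 4L)                                  # sizeof_hdr
  wB(raw(36L), 1L)                              # data_type..dim_info
  wB(as.integer(c(3L, dim(arr), 1L, 1L, 1L, 1L)), 2L)  # dim
  wB(numeric(3), 4L)                            # intent_p1..p3
  wB(c(0L, dt_code, bitpix, 0L), 2L)            # intent_code, datatype, bitpix, slice_start
  wB(as.numeric(c(1, sp_stored, 1, 1, 1, 1)), 4L)      # pixdim (qfac = 1)
  wB(352, 4L)                                   # vox_offset
  wB(c(1, 0), 4L)                               # scl_slope, scl_inter
  wB(0L, 2L); wB(raw(2L), 1L)                   # slice_end, slice_code, xyzt_units
  wB(numeric(4), 4L)                            # cal_max..toffset
  wB(c(0L, 0L), 4L)                             # glmax, glmin
  wB(raw(104L), 1L)                             # descrip + aux_file
  wB(c(0L, 1L), 2L)                             # qform_code = 0, sform_code = 1
  wB(numeric(6), 4L)                            # quatern + qoffset
  wB(as.numeric(t(srow)), 4L)                   # srow_x, srow_y, srow_z
  wB(raw(16L), 1L)                              # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); wB(raw(1L), 1L)  # magic
  wB(raw(4L), 1L)                               # header extension flag
  if (datatype == "float32") {
    wB(as.numeric(arr), 4L)
  } else {
    writeBin(as.integer(round(arr)), con, size = 1L, endian = "little")
  }
  invisible(path)
}
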