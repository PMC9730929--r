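# 3D reference biomarkers and their 2D MIP surrogates.
#
# Units: all geometry is carried internally in mm; reported values are
# TMTV in cm^3, Dmax in cm, sTMTV in cm^2, sDmax in cm.

#' Total metabolic tumor volume (TMTV, cm^3)
#'
#' Volume of all lesion voxels: voxel count times the physical voxel volume
#' `sx * sy * sz`.
#'
#' @param mask A [lesion_mask()].
#' @return TMTV in cm^3 (0 for an empty mask).
#' @export
compute_tmtv <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$data) * prod(mask$spacing) / 1000
}

#' Label individual lesions in a 3D mask
#'
#' Lesions are the 26-connected components of the binary mask (voxels sharing
#' a face, edge or corner are connected). Centroids are means of member voxel
#' centers in physical mm.
#'
#' @param mask A [lesion_mask()].
#' @return A list with `labels` (integer array, 0 = background), `n_lesions`,
#'   `centroids_mm` (n x 3 matrix, mm) and `volumes_cm3` (per-lesion volume).
#' @export
label_lesions <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  cc <- label_components(mask$data)
  vol_vox <- if (cc$n > 0) as.vector(table(cc$labels[cc$labels > 0])) else numeric(0)
  list(labels = cc$labels,
       n_lesions = cc$n,
       centroids_mm = component_centroids(cc$labels, cc$n, mask$spacing),
       volumes_cm3 = vol_vox * prod(mask$spacing) / 1000)
}

#' Lesion dissemination Dmax (cm)
#'
#' The largest Euclidean distance between any two lesion centroids, in cm.
#' Patients with fewer than two lesions have no defined dissemination: the
#' value is 0 and the result is flagged (`defined = FALSE`); exclusion of
#' such patients is left to the analysis level.
#'
#' @param mask A [lesion_mask()].
#' @return A list with `dmax_cm`, `n_lesions` and `defined`.
#' @export
compute_dmax <- function(mask) {
  lab <- label_lesions(mask)
  if (lab$n_lesions < 2L) {
    return(list(dmax_cm = 0, n_lesions = lab$n_lesions, defined = FALSE))
  }
  dmax_mm <- max(stats::dist(lab$centroids_mm))
  list(dmax_cm = dmax_mm / 10, n_lesions = lab$n_lesions, defined = TRUE)
}

#' Surrogate tumor burden sTMTV (cm^2)
#'
#' Per view, the number of lesion pixels in the MIP mask multiplied by the
#' pixel area `u * v`; the total is the sum of the coronal and sagittal
#' components.
#'
#' @param pair A `mip_pair` from [make_mip_pair()] (masks required), or a
#'   list with `coronal`/`sagittal` elements holding `mask`.
#' @return A list with `stmtv_cm2`, `coronal_cm2`, `sagittal_cm2`.
#' @export
compute_stmtv <- function(pair) {
  one <- function(mk) sum(mk$data) * prod(mk$pixel_spacing) / 100
  cor <- one(pair$coronal$mask)
  sag <- one(pair$sagittal$mask)
  list(stmtv_cm2 = cor + sag, coronal_cm2 = cor, sagittal_cm2 = sag)
}

#' Column and row profiles of a MIP mask
#'
#' The x profile is the per-column pixel sum (one entry per position along the
#' horizontal image axis), the y profile the per-row sum (one entry per
#' position along the inferior-superior axis). Both profiles sum to the mask
#' pixel count.
#'
#' @param mask A `mip_mask`.
#' @return A list with `x_profile`, `y_profile`, `x_spacing_mm`,
#'   `y_spacing_mm`.
#' @export
mask_profiles <- function(mask) {
  stopifnot(inherits(mask, "mip_mask"))
  list(x_profile = rowSums(mask$data),
       y_profile = colSums(mask$data),
       x_spacing_mm = mask$pixel_spacing[1],
       y_spacing_mm = mask$pixel_spacing[2])
}

#' Robust 2%-98% percentile span of a mask profile (mm)
#'
#' Percentile positions are defined on the cumulative mass function of the
#' profile: with `F(k)` the fraction of total mass in bins `1..k`, `q(p)` is
#' the smallest bin index with `F(k) >= p`. The span is
#' `(q(hi) - q(lo)) * spacing` mm. The discrete left-continuous convention
#' (no interpolation) makes degenerate cases exact: a single occupied bin has
#' span 0, an empty profile has span 0. The trimmed 2%/98% percentiles make
#' the span robust to outlying pixels.
#'
#' @param profile Non-negative numeric vector of per-bin pixel counts.
#' @param spacing Bin width in mm.
#' @param lo,hi Percentile bounds as fractions (defaults 0.02 and 0.98).
#' @return Span in mm.
#' @export
percentile_span <- function(profile, spacing, lo = 0.02, hi = 0.98) {
  assert_that(all(profile >= 0), "profile entries must be non-negative")
  total <- sum(profile)
  if (total == 0) return(0)
  F <- cumsum(profile) / total
  q_lo <- which(F >= lo)[1]
  q_hi <- which(F >= hi)[1]
  (q_hi - q_lo) * spacing
}

#' Surrogate dissemination sDmax (cm)
#'
#' Per view, the sum of the x- and y-profile percentile spans,
#' `(x98 - x2) + (y98 - y2)`; the total is the sum of the coronal and
#' sagittal view components, reported in cm.
#'
#' @param pair A `mip_pair` with masks.
#' @param lo,hi Percentile bounds passed to [percentile_span()].
#' @return A list with `sdmax_cm`, `coronal_cm`, `sagittal_cm`, and per-view
#'   `x_span_mm` / `y_span_mm`.
#' @export
compute_sdmax <- function(pair, lo = 0.02, hi = 0.98) {
  one <- function(mk) {
    pr <- mask_profiles(mk)
    x <- percentile_span(pr$x_profile, pr$x_spacing_mm, lo, hi)
    y <- percentile_span(pr$y_profile, pr$y_spacing_mm, lo, hi)
    list(span_cm = (x + y) / 10, x_span_mm = x, y_span_mm = y)
  }
  cor <- one(pair$coronal$mask)
  sag <- one(pair$sagittal$mask)
  list(sdmax_cm = cor$span_cm + sag$span_cm,
       coronal_cm = cor$span_cm, sagittal_cm = sag$span_cm,
       coronal_x_span_mm = cor$x_span_mm, coronal_y_span_mm = cor$y_span_mm,
       sagittal_x_span_mm = sag$x_span_mm, sagittal_y_span_mm = sag$y_span_mm)
}

#' Compute all four biomarkers for one volume/mask pair
#'
#' @param volume A [pet_volume()].
#' @param mask The aligned [lesion_mask()].
#' @param patient_id Identifier carried into the output row.
#' @return A one-row `data.frame` with columns `patient_id`, `tmtv_cm3`,
#'   `dmax_cm`, `stmtv_cm2`, `sdmax_cm`, per-view components, `n_lesions`
#'   and `flag_single_lesion`.
#' @export
biomarker_record <- function(volume, mask, patient_id = NA_character_) {
  pair <- make_mip_pair(volume, mask)
  biomarker_record_from_masks(mask, pair, patient_id)
}

# same, but from a 3D mask plus already-projected (possibly predicted) masks
biomarker_record_from_masks <- function(mask, pair, patient_id = NA_character_) {
  tm <- compute_tmtv(mask)
  dm <- compute_dmax(mask)
  st <- compute_stmtv(pair)
  sd <- compute_sdmax(pair)
  data.frame(
    patient_id = as.character(patient_id),
    tmtv_cm3 = tm,
    dmax_cm = dm$dmax_cm,
    stmtv_cm2 = st$stmtv_cm2,
    sdmax_cm = sd$sdmax_cm,
    stmtv_coronal_cm2 = st$coronal_cm2,
    stmtv_sagittal_cm2 = st$sagittal_cm2,
    sdmax_coronal_cm = sd$coronal_cm,
    sdmax_sagittal_cm = sd$sagittal_cm,
    n_lesions = dm$n_lesions,
    flag_single_lesion = !dm$defined,
    stringsAsFactors = FALSE
  )
}

#' Biomarker table for a cohort
#'
#' @param cases A list of cases, each a list with elements `volume`, `mask`
#'   and optionally `patient_id` (e.g. from [generate_cohort()]).
#' @return A `data.frame` with one [biomarker_record()] row per case.
#' @export
biomarker_table <- function(cases) {
  assert_that(length(cases) >= 1L, "biomarker_table needs at least one case")
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    biomarker_record(cs$volume, cs$mask, cs$patient_id %||% sprintf("case%03d", i))
  })
  do.call(rbind, rows)
}

#' Descriptive statistics of biomarker columns
#'
#' Mean, SD, minimum, quartiles, median and maximum per biomarker column
#' (the layout of a cohort descriptive-statistics table). Quartiles use the
#' default sample-quantile definition (type 7).
#'
#' @param tab A biomarker `data.frame` from [biomarker_table()].
#' @param columns Columns to summarize; defaults to the four biomarkers.
#' @return A `data.frame` with one row per column.
#' @export
biomarker_summary <- function(tab,
                              columns = c("tmtv_cm3", "dmax_cm",
                                          "stmtv_cm2", "sdmax_cm")) {
  rows <- lapply(columns, function(cn) {
    x <- tab[[cn]]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(biomarker = cn, mean = mean(x), sd = stats::sd(x), min = min(x),
               q1 = q[1], median = q[2], q3 = q[3], max = max(x))
  })
  do.call(rbind, rows)
}
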