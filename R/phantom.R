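# Synthetic whole-body FDG-PET phantoms.
#
# The phantom is a stated world, not a tuned fixture: a warm body envelope
# (trunk column plus head), hot physiologic organs (brain, heart, bladder
# analogues) that are deliberately NOT part of the lesion mask, multiple
# ellipsoidal lesions of varying uptake, and additive Gaussian noise
# truncated at zero. Defaults approximate an SUV-like scale: background 1,
# lesions 4-9, brain/bladder hotter than most lesions.

#' Specify a synthetic whole-body PET phantom
#'
#' All geometry is physical (mm): centers and radii of organs and lesions are
#' given in the volume's mm coordinate frame, where voxel `i` along an axis
#' sits at `(i - 1) * spacing`.
#'
#' @param grid_shape Integer 3-vector, voxels along (LR, AP, IS). Default
#'   `c(64, 48, 128)`, a scaled-down whole-body matrix.
#' @param spacing Voxel spacing in mm, default 4 mm isotropic (typical PET).
#' @param body_uptake Mean background uptake inside the body envelope
#'   (arbitrary SUV-like units), default 1.
#' @param organ_specs List of physiologic hot regions, each
#'   `list(center, radii, uptake)` in mm; `NULL` (default) places brain,
#'   heart and bladder analogues; `list()` disables organs.
#' @param lesion_specs List of lesions, each `list(center, radii, uptake)`
#'   (mm; ellipsoid semi-axes).
#' @param noise_sigma SD of the additive Gaussian noise (truncated at zero),
#'   default 0.15 (15% of background).
#' @param seed Integer seed; a fixed seed gives byte-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 48L, 128L),
                         spacing = c(4, 4, 4),
                         body_uptake = 1,
                         organ_specs = NULL,
                         lesion_specs = list(),
                         noise_sigma = 0.15,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  extent <- (grid_shape - 1L) * spacing
  if (is.null(organ_specs)) organ_specs <- default_organs(extent)
  for (ls in lesion_specs) {
    assert_that(ls$uptake > body_uptake, "lesion uptake must exceed body uptake")
  }
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 body_uptake = body_uptake, organ_specs = organ_specs,
                 lesion_specs = lesion_specs, noise_sigma = noise_sigma,
                 seed = as.integer(seed), extent = extent),
            class = "phantom_spec")
}

# brain / heart / bladder analogues, scaled to the body extent (mm)
default_organs <- function(extent) {
  cx <- extent[1] / 2; cy <- extent[2] / 2; Lz <- extent[3]
  list(
    list(name = "brain", center = c(cx, cy, 0.92 * Lz),
         radii = c(0.14 * extent[1], 0.18 * extent[2], 0.055 * Lz), uptake = 7),
    list(name = "heart", center = c(cx - 0.08 * extent[1], cy, 0.62 * Lz),
         radii = c(22, 22, 22), uptake = 5),
    list(name = "bladder", center = c(cx, cy, 0.16 * Lz),
         radii = c(16, 16, 16), uptake = 8)
  )
}

# binary array of voxels whose centers lie inside the ellipsoid (mm geometry)
voxelize_ellipsoid <- function(grid_shape, spacing, center, radii) {
  idx <- lapply(1:3, function(d) {
    lo <- max(1L, floor((center[d] - radii[d]) / spacing[d]) + 1L)
    hi <- min(grid_shape[d], ceiling((center[d] + radii[d]) / spacing[d]) + 1L)
    if (lo > hi) integer(0) else lo:hi
  })
  out <- array(0L, grid_shape)
  if (any(lengths(idx) == 0L)) return(out)
  u <- lapply(1:3, function(d) (((idx[[d]] - 1) * spacing[d]) - center[d]) / radii[d])
  inside <- outer(outer(u[[1]]^2, u[[2]]^2, `+`), u[[3]]^2, `+`) <= 1
  out[idx[[1]], idx[[2]], idx[[3]]] <- as.integer(inside)
  out
}

# body envelope: elliptical trunk column plus head ellipsoid (logical array)
body_envelope <- function(grid_shape, spacing, extent) {
  x <- ((seq_len(grid_shape[1]) - 1) * spacing[1] - extent[1] / 2) / (0.45 * extent[1])
  y <- ((seq_len(grid_shape[2]) - 1) * spacing[2] - extent[2] / 2) / (0.42 * extent[2])
  z <- (seq_len(grid_shape[3]) - 1) * spacing[3]
  trunk_xy <- outer(x^2, y^2, `+`) <= 1
  trunk <- outer(trunk_xy, z <= 0.84 * extent[3])
  head <- voxelize_ellipsoid(grid_shape, spacing,
                             c(extent[1] / 2, extent[2] / 2, 0.92 * extent[3]),
                             c(0.2 * extent[1], 0.26 * extent[2], 0.075 * extent[3]))
  trunk | (head > 0)
}

#' Generate a synthetic phantom case
#'
#' Builds the intensity volume (body + organs + lesions, additive noise
#' truncated at zero), the binary lesion mask covering exactly the voxelized
#' lesion ellipsoids (a voxel belongs to a lesion iff its center is inside
#' the ellipsoid), and analytic ground truth. Physiologic organs are hot in
#' the image but excluded from the mask; voxels where a lesion and an organ
#' overlap are resolved lesion-wins (logged via `message`).
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `phantom_case` with `volume` ([pet_volume()]),
#'   `mask` ([lesion_mask()]) and `truth` (analytic per-lesion volumes
#'   `4/3*pi*abc` in cm^3, centroids in mm, the analytic maximum pairwise
#'   center distance `dmax_cm`, and `organ_mask`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; sp <- spec$spacing
  for (ls in spec$lesion_specs) {
    if (any(ls$center - ls$radii < 0) || any(ls$center + ls$radii > spec$extent)) {
      stop2("lesion at (", paste(round(ls$center), collapse = ", "),
            ") mm extends outside the grid")
    }
  }
  body <- body_envelope(gs, sp, spec$extent)
  img <- array(0, gs)
  img[body] <- spec$body_uptake
  organ_mask <- array(0L, gs)
  for (og in spec$organ_specs) {
    vox <- voxelize_ellipsoid(gs, sp, og$center, og$radii)
    organ_mask[vox > 0] <- 1L
    img[vox > 0] <- pmax(img[vox > 0], og$uptake)
  }
  mask <- array(0L, gs)
  for (ls in spec$lesion_specs) {
    vox <- voxelize_ellipsoid(gs, sp, ls$center, ls$radii)
    mask[vox > 0] <- 1L
    img[vox > 0] <- pmax(img[vox > 0], ls$uptake)
  }
  n_overlap <- sum(mask & organ_mask)
  if (n_overlap > 0) {
    message("phantom: ", n_overlap,
            " voxels overlap between lesions and physiologic organs (lesion wins)")
    organ_mask[mask > 0] <- 0L
  }
  if (spec$noise_sigma > 0) {
    set.seed(spec$seed)
    img <- pmax(img + stats::rnorm(length(img), 0, spec$noise_sigma), 0)
    img <- array(img, gs)
  }
  centers <- do.call(rbind, lapply(spec$lesion_specs, function(l) l$center))
  truth <- list(
    n_lesions = length(spec$lesion_specs),
    volumes_cm3 = vapply(spec$lesion_specs,
                         function(l) 4 / 3 * pi * prod(l$radii) / 1000, numeric(1)),
    centers_mm = centers,
    dmax_cm = if (length(spec$lesion_specs) >= 2)
      max(stats::dist(centers)) / 10 else 0,
    organ_mask = organ_mask
  )
  structure(list(volume = pet_volume(img, sp),
                 mask = lesion_mask(mask, sp),
                 truth = truth, spec = spec),
            class = "phantom_case")
}

# default per-case sampler: lesion count 1..10, spheroid radii 6-22 mm,
# uptake 4-9, centers inside the trunk; true TMTV spans > 1 order of magnitude
default_spec_sampler <- function(i, seed, grid_shape = c(64L, 48L, 128L),
                                 spacing = c(4, 4, 4), noise_sigma = 0.15,
                                 n_lesions = NULL) {
  set.seed(child_seed(seed, i))
  extent <- (as.integer(grid_shape) - 1L) * spacing
  n <- if (is.null(n_lesions)) sample(1:10, 1) else n_lesions
  lesions <- vector("list", n)
  for (j in seq_len(n)) {
    r0 <- stats::runif(1, 6, 22)
    radii <- r0 * stats::runif(3, 0.7, 1)
    center <- c(stats::runif(1, 0.28, 0.72) * extent[1],
                stats::runif(1, 0.3, 0.7) * extent[2],
                stats::runif(1, 0.08, 0.8) * extent[3])
    center <- pmin(pmax(center, radii + spacing), extent - radii - spacing)
    lesions[[j]] <- list(center = center, radii = radii,
                         uptake = stats::runif(1, 4, 9))
  }
  phantom_spec(grid_shape = grid_shape, spacing = spacing,
               lesion_specs = lesions, noise_sigma = noise_sigma,
               seed = child_seed(seed, 100000 + i))
}

#' Generate a reproducible phantom cohort
#'
#' Cases vary in lesion number (1-10), size and spread, so that true TMTV
#' spans at least an order of magnitude across a cohort of moderate size,
#' enabling correlation studies between 3D and surrogate biomarkers.
#'
#' @param n Number of cases (>= 1).
#' @param seed Integer seed; the cohort is reproducible given `seed`.
#' @param spec_sampler Optional `function(i, seed)` returning a
#'   [phantom_spec()] for case `i`; the default sampler is described above.
#' @return A list of `phantom_case` objects, each with a `patient_id` field.
#' @export
generate_cohort <- function(n, seed = 1L, spec_sampler = NULL) {
  assert_that(is_count(n), "n must be a positive integer")
  sampler <- spec_sampler %||% default_spec_sampler
  lapply(seq_len(n), function(i) {
    cs <- generate_phantom(sampler(i, seed))
    cs$patient_id <- sprintf("P%03d", i)
    cs
  })
}

#' Specify a survival simulation
#'
#' Event times are exponential with hazard `h0 * exp(sum(beta * x))`;
#' censoring is independent uniform on `(0, horizon]`, applied to each
#' subject with probability `censoring_rate`.
#'
#' @param baseline_hazard Baseline hazard `h0` in events per month.
#' @param log_hr_per_unit Named numeric vector of log hazard ratios; names
#'   must match covariate column names passed to [simulate_survival()].
#' @param censoring_rate Probability in `[0, 1)` that a subject is at risk of
#'   uniform censoring.
#' @param horizon_months Upper bound (months) of the uniform censoring
#'   window.
#' @param seed Integer seed.
#' @return A `survival_sim_spec` list.
#' @export
survival_sim_spec <- function(baseline_hazard = 0.01,
                              log_hr_per_unit = c(),
                              censoring_rate = 0.2,
                              horizon_months = 60,
                              seed = 1L) {
  assert_that(baseline_hazard > 0, "baseline_hazard must be > 0")
  assert_that(censoring_rate >= 0 && censoring_rate < 1,
              "censoring_rate must be in [0, 1)")
  structure(list(baseline_hazard = baseline_hazard,
                 log_hr_per_unit = log_hr_per_unit,
                 censoring_rate = censoring_rate,
                 horizon_months = horizon_months, seed = as.integer(seed)),
            class = "survival_sim_spec")
}

#' Simulate survival outcomes linked to biomarker values
#'
#' Draws exponential event times with per-subject hazard
#' `h0 * exp(sum(beta * x))` over the covariate columns named in the spec's
#' `log_hr_per_unit`, then applies independent uniform censoring on
#' `(0, horizon]` to the fraction `censoring_rate` of subjects. With
#' `censoring_rate = 0` every record is an event.
#'
#' @param biomarkers A `data.frame` with a `patient_id` column and the
#'   covariate columns named in `spec$log_hr_per_unit` (finite values).
#' @param spec A [survival_sim_spec()].
#' @return A `data.frame` with `patient_id`, `time_months`, `event` and the
#'   covariates used.
#' @export
simulate_survival <- function(biomarkers, spec) {
  stopifnot(inherits(spec, "survival_sim_spec"))
  n <- nrow(biomarkers)
  beta <- spec$log_hr_per_unit
  lp <- numeric(n)
  for (nm in names(beta)) {
    x <- biomarkers[[nm]]
    assert_that(!is.null(x) && all(is.finite(x)),
                paste0("covariate '", nm, "' missing or non-finite"))
    lp <- lp + beta[[nm]] * x
  }
  set.seed(spec$seed)
  t_event <- stats::rexp(n, rate = spec$baseline_hazard * exp(lp))
  censored_at <- rep(Inf, n)
  if (spec$censoring_rate > 0) {
    at_risk <- stats::runif(n) < spec$censoring_rate
    censored_at[at_risk] <- stats::runif(sum(at_risk), 0, spec$horizon_months)
  }
  time <- pmin(t_event, censored_at)
  data.frame(patient_id = biomarkers$patient_id %||% seq_len(n),
             time_months = time,
             event = as.integer(t_event <= censored_at),
             stringsAsFactors = FALSE)
}

#' Write a phantom case to disk (NIfTI pair + ground-truth JSON)
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @param id Basename for the files.
#' @return Invisibly, the paths written.
#' @export
write_phantom_case <- function(case, dir, id = case$patient_id %||% "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_vol <- file.path(dir, paste0(id, "_pet.nii.gz"))
  p_mask <- file.path(dir, paste0(id, "_mask.nii.gz"))
  p_json <- file.path(dir, paste0(id, "_truth.json"))
  write_volume(case$volume, p_vol)
  write_volume(case$mask, p_mask)
  truth <- case$truth[c("n_lesions", "volumes_cm3", "dmax_cm")]
  truth$centers_mm <- case$truth$centers_mm
  jsonlite::write_json(truth, p_json, digits = NA, auto_unbox = TRUE)
  invisible(c(volume = p_vol, mask = p_mask, truth = p_json))
}
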