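test_that("TMTV is voxel count times voxel volume", {
  a <- array(0L, c(10, 10, 10))
  a[sample(1000, 100)] <- 1L
  expect_equal(compute_tmtv(lesion_mask(a, c(4, 4, 4))), 6.4)  # 100 * 64 mm^3
  expect_equal(compute_tmtv(lesion_mask(array(0L, c(4, 4, 4)), c(1, 1, 1))), 0)
})

test_that("lesion labeling follows 26-connectivity and matches a union-find oracle", {
  # two voxels sharing only a corner: one component
  a <- array(0L, c(4, 4, 4))
  a[1, 1, 1] <- 1L; a[2, 2, 2] <- 1L
  expect_equal(label_lesions(lesion_mask(a, c(1, 1, 1)))$n_lesions, 1)
  # separated by a zero gap: two components
  b <- array(0L, c(5, 4, 4))
  b[1, 1, 1] <- 1L; b[3, 1, 1] <- 1L
  expect_equal(label_lesions(lesion_mask(b, c(1, 1, 1)))$n_lesions, 2)
  # random masks against the O(V^2) union-find oracle
  for (rep in 1:12) {
    m <- random_lesion_mask(c(6, 6, 6), 0.15, seed = 400 + rep)
    expect_equal(label_lesions(m)$n_lesions, oracle_n_components(m$data),
                 label = paste("rep", rep))
  }
})

test_that("Dmax is the max pairwise centroid distance (3-4-5 case exact)", {
  a <- array(0L, c(50, 50, 50))
  a[1, 1, 1] <- 1L         # centroid (0, 0, 0) mm
  a[31, 41, 1] <- 1L       # centroid (30, 40, 0) mm at 1 mm spacing
  d <- compute_dmax(lesion_mask(a, c(1, 1, 1)))
  expect_equal(d$dmax_cm, 5)
  expect_true(d$defined)

  single <- array(0L, c(5, 5, 5)); single[2:3, 2:3, 2:3] <- 1L
  ds <- compute_dmax(lesion_mask(single, c(1, 1, 1)))
  expect_equal(ds$dmax_cm, 0)
  expect_false(ds$defined)

  # multi-lesion random phantoms vs exhaustive pair enumeration
  for (rep in 1:8) {
    cs <- easy_phantom(500 + rep, n_lesions = 5)
    lab <- label_lesions(cs$mask)
    cen <- lab$centroids_mm
    best <- 0
    for (i in seq_len(nrow(cen) - 1)) for (j in (i + 1):nrow(cen)) {
      best <- max(best, sqrt(sum((cen[i, ] - cen[j, ])^2)))
    }
    expect_equal(compute_dmax(cs$mask)$dmax_cm, best / 10)
  }
})

test_that("sTMTV is pixel count times pixel area, summed over views", {
  mk <- function(n_px, dims, spacing, view) {
    d <- matrix(0L, dims[1], dims[2]); d[seq_len(n_px)] <- 1L
    petmip:::new_mip(d, spacing, view, "mip_mask")
  }
  pair <- list(coronal = list(mask = mk(10, c(12, 12), c(4, 4), "coronal")),
               sagittal = list(mask = mk(6, c(12, 12), c(4, 4), "sagittal")))
  st <- compute_stmtv(pair)
  expect_equal(st$stmtv_cm2, 2.56)      # 16 px * 16 mm^2
  expect_equal(st$coronal_cm2, 1.6)
  expect_equal(st$sagittal_cm2, 0.96)
  empty <- list(coronal = list(mask = mk(0, c(4, 4), c(4, 4), "coronal")),
                sagittal = list(mask = mk(0, c(4, 4), c(4, 4), "sagittal")))
  expect_equal(compute_stmtv(empty)$stmtv_cm2, 0)
})

test_that("mask profiles are row/column sums and total the pixel count", {
  d <- matrix(0L, 3, 3); d[, 2] <- 1L     # one full image row (y = 2)
  mk <- petmip:::new_mip(d, c(1, 1), "coronal", "mip_mask")
  pr <- mask_profiles(mk)
  expect_equal(pr$x_profile, c(1, 1, 1))
  expect_equal(sort(pr$y_profile), c(0, 0, 3))
  set.seed(6)
  for (rep in 1:10) {
    d <- matrix(as.integer(stats::runif(8 * 11) > 0.6), 8, 11)
    mk <- petmip:::new_mip(d, c(2, 3), "coronal", "mip_mask")
    pr <- mask_profiles(mk)
    xo <- sapply(1:8, function(i) sum(d[i, ]))
    yo <- sapply(1:11, function(j) sum(d[, j]))
    expect_equal(pr$x_profile, xo)
    expect_equal(pr$y_profile, yo)
    expect_equal(sum(pr$x_profile), sum(d))
    expect_equal(sum(pr$y_profile), sum(d))
  }
})

test_that("percentile_span worked examples and random-profile oracle", {
  expect_equal(percentile_span(c(0, 0, 5, 0), 3), 0)              # single bin
  expect_equal(percentile_span(rep(1, 100), 4), 96 * 4)           # uniform
  p2 <- numeric(11); p2[1] <- 1; p2[11] <- 1
  expect_equal(percentile_span(p2, 1), 10)                        # two bins
  expect_equal(percentile_span(numeric(5), 2), 0)                 # empty
  expect_error(percentile_span(c(1, -1, 2), 1), "non-negative")
  set.seed(13)
  for (rep in 1:50) {
    pr <- stats::rpois(sample(5:40, 1), lambda = stats::runif(1, 0.1, 3))
    sp <- stats::runif(1, 0.5, 5)
    expect_equal(percentile_span(pr, sp), oracle_span(pr, sp))
  }
})

test_that("sDmax sums per-view x and y spans and is translation invariant", {
  mk <- function(d, view) petmip:::new_mip(d, c(1, 1), view, "mip_mask")
  single <- matrix(0L, 20, 20); single[5, 5] <- 1L
  pair1 <- list(coronal = list(mask = mk(single, "coronal")),
                sagittal = list(mask = mk(single, "sagittal")))
  expect_equal(compute_sdmax(pair1)$sdmax_cm, 0)

  two <- matrix(0L, 120, 20); two[10, 7] <- 1L; two[110, 7] <- 1L  # 100 mm apart
  pair2 <- list(coronal = list(mask = mk(two, "coronal")),
                sagittal = list(mask = mk(two, "sagittal")))
  sd2 <- compute_sdmax(pair2)
  expect_equal(sd2$coronal_cm, 10)
  expect_equal(sd2$sdmax_cm, 20)

  shifted <- matrix(0L, 120, 20); shifted[15, 12] <- 1L; shifted[115, 12] <- 1L
  pair3 <- list(coronal = list(mask = mk(shifted, "coronal")),
                sagittal = list(mask = mk(shifted, "sagittal")))
  expect_equal(compute_sdmax(pair3)$sdmax_cm, sd2$sdmax_cm)
})

test_that("exact scaling laws under spacing changes", {
  cs <- easy_phantom(21, n_lesions = 4)
  mask1 <- cs$mask
  mask2 <- lesion_mask(mask1$data, mask1$spacing * 2)
  vol1 <- cs$volume
  vol2 <- pet_volume(vol1$data, vol1$spacing * 2)
  expect_equal(compute_tmtv(mask2), 8 * compute_tmtv(mask1))
  expect_equal(compute_dmax(mask2)$dmax_cm, 2 * compute_dmax(mask1)$dmax_cm)
  p1 <- make_mip_pair(vol1, mask1)
  p2 <- make_mip_pair(vol2, mask2)
  expect_equal(compute_stmtv(p2)$stmtv_cm2, 4 * compute_stmtv(p1)$stmtv_cm2)
  expect_equal(compute_sdmax(p2)$sdmax_cm, 2 * compute_sdmax(p1)$sdmax_cm)
})

test_that("geometric bounds and dilation monotonicity hold", {
  for (rep in 1:5) {
    cs <- easy_phantom(700 + rep)
    pair <- make_mip_pair(cs$volume, cs$mask)
    # span bound per view
    for (v in c("coronal", "sagittal")) {
      mkd <- pair[[v]]$mask
      bound <- (nrow(mkd$data) - 1) * mkd$pixel_spacing[1] +
        (ncol(mkd$data) - 1) * mkd$pixel_spacing[2]
      sd <- compute_sdmax(pair)[[paste0(v, "_cm")]]
      expect_lte(sd * 10, bound)
    }
    # Dmax bounded by the 3D bounding-box diagonal
    vox <- which(cs$mask$data == 1, arr.ind = TRUE)
    if (nrow(vox) > 0) {
      ext <- (apply(vox, 2, max) - apply(vox, 2, min)) * cs$mask$spacing
      expect_lte(compute_dmax(cs$mask)$dmax_cm, sqrt(sum(ext^2)) / 10 + 1e-9)
    }
    # adding voxels never decreases TMTV / sTMTV
    grown <- cs$mask$data
    set.seed(rep)
    grown[sample(length(grown), 500)] <- 1L
    gm <- lesion_mask(grown, cs$mask$spacing)
    expect_gte(compute_tmtv(gm), compute_tmtv(cs$mask))
    gp <- make_mip_pair(cs$volume, gm)
    expect_gte(compute_stmtv(gp)$stmtv_cm2, compute_stmtv(pair)$stmtv_cm2)
  }
})

test_that("biomarker_table and summary behave on a small cohort", {
  cases <- small_cohort(3, seed = 31)
  tab <- biomarker_table(cases)
  expect_equal(nrow(tab), 3)
  num_cols <- vapply(tab, is.numeric, logical(1))
  expect_true(all(is.finite(as.matrix(tab[, num_cols]))))
  expect_true(all(tab$stmtv_cm2 ==
                    tab$stmtv_coronal_cm2 + tab$stmtv_sagittal_cm2))

  sm <- biomarker_summary(data.frame(tmtv_cm3 = c(1, 2, 3), dmax_cm = c(1, 2, 3),
                                     stmtv_cm2 = c(1, 2, 3), sdmax_cm = c(1, 2, 3)))
  expect_true(all(sm$median == 2))

  # quartiles match the sorted type-7 interpolation definition on n = 11
  set.seed(77)
  x <- stats::rnorm(11)
  s <- sort(x)
  sm2 <- biomarker_summary(data.frame(tmtv_cm3 = x), columns = "tmtv_cm3")
  expect_equal(sm2$q1, s[3] + 0.5 * (s[4] - s[3]))   # h = (11-1)*0.25 + 1 = 3.5
  expect_equal(sm2$median, s[6])
  expect_equal(sm2$q3, s[8] + 0.5 * (s[9] - s[8]))
})
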