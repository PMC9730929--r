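# Pluggable 2D MIP lesion segmenters and the patientwise cross-validation
# harness. Coronal and sagittal MIPs are independent samples; splits are
# always by patient so that no patient's views straddle train/validation.

#' Configuration for the trainable MIP segmenter
#'
#' @param grid Fixed model grid (horizontal x vertical pixels); inputs are
#'   fitted in with an aspect-preserving resize + pad. Must be divisible
#'   by 4 (two pooling levels).
#' @param channels Encoder channel widths at the three resolution levels.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Gradient-accumulation batch size.
#' @param cutoff Probability binarization cutoff in (0, 1), default 0.5.
#' @param clip_pct Intensity normalization percentile (clip then scale to
#'   `[0,1]`), default 0.999.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(grid = c(48L, 96L), channels = c(8L, 16L, 32L),
                       lr = 3e-3, epochs = 10L, batch_size = 1L,
                       cutoff = 0.5, clip_pct = 0.999, seed = 0L) {
  assert_that(all(grid %% 4L == 0L), "grid must be divisible by 4")
  assert_that(cutoff > 0 && cutoff < 1, "cutoff must be in (0, 1)")
  structure(list(grid = as.integer(grid), channels = as.integer(channels),
                 in_channels = 3L, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), cutoff = cutoff,
                 clip_pct = clip_pct, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Deterministic threshold baseline segmenter
#'
#' Pixels at or above `threshold` times a robust intensity maximum (the
#' 99.5th percentile) are lesion candidates. Candidate pixels inside a
#' configured physiologic-region template (brain/heart/bladder analogues)
#' are then removed, mimicking the expert step of discarding physiologic
#' uptake; removal is pixelwise so that a lesion whose candidate component
#' touches an organ is not discarded with it. The segmenter is pure and
#' deterministic.
#'
#' @param mip A `mip_image`.
#' @param threshold Relative cutoff in (0, 1), default 0.5.
#' @param organ_mask Optional binary matrix (same shape) marking physiologic
#'   regions; see [organ_mip_mask()].
#' @param min_px Drop residual candidate components smaller than this many
#'   pixels (default 1 = keep everything).
#' @param robust_pct Percentile defining the robust maximum, default 0.995.
#' @return A `mip_mask`.
#' @export
baseline_segment <- function(mip, threshold = 0.5, organ_mask = NULL,
                             min_px = 1L, robust_pct = 0.995) {
  stopifnot(inherits(mip, "mip_image"))
  assert_that(length(mip$data) > 0 && any(is.finite(mip$data)),
              "empty MIP image")
  ref <- stats::quantile(mip$data, robust_pct, names = FALSE)
  cand <- mip$data >= threshold * ref & mip$data > min(mip$data)
  if (ref <= 0 || stats::sd(mip$data) == 0) {
    cand[] <- FALSE       # constant image: nothing exceeds a relative cutoff
  }
  cand <- matrix(as.integer(cand), nrow = nrow(mip$data))
  if (!is.null(organ_mask)) {
    stopifnot(all(dim(organ_mask) == dim(cand)))
    cand[organ_mask > 0] <- 0L
  }
  if (min_px > 1L && any(cand > 0)) {
    cc <- label_components(cand)
    for (l in seq_len(cc$n)) {
      px <- cc$labels == l
      if (sum(px) < min_px) cand[px] <- 0L
    }
  }
  new_mip(cand, mip$pixel_spacing, mip$view, "mip_mask")
}

#' Project a phantom's physiologic-organ template to a MIP view
#'
#' @param case A `phantom_case` from [generate_phantom()].
#' @param view `"coronal"` or `"sagittal"`.
#' @return Binary matrix usable as `organ_mask` in [baseline_segment()].
#' @export
organ_mip_mask <- function(case, view = c("coronal", "sagittal")) {
  view <- match.arg(view)
  om <- lesion_mask(case$truth$organ_mask, case$mask$spacing)
  mip_project_mask(om, view)$data
}

#' Patientwise k-fold split
#'
#' Patients (never single views) are randomly assigned to `k` folds of size
#' within one of each other; both views of a patient always share a fold.
#'
#' @param patient_ids Character vector of unique patient identifiers.
#' @param k Number of folds, default 5.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A `training_split`: data.frame with `patient_id` and `fold`.
#' @export
make_split <- function(patient_ids, k = 5L, seed = 0L) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  assert_that(n >= k, paste0("need at least k = ", k, " patients, got ", n))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  structure(data.frame(patient_id = patient_ids, fold = fold,
                       stringsAsFactors = FALSE),
            class = c("training_split", "data.frame"))
}

#' Build a MIP training set from phantom cases
#'
#' Each phantom contributes two independent samples (coronal and sagittal),
#' tagged with the patient id so that [make_split()] keeps views together.
#'
#' @param cases List of `phantom_case` objects (with `patient_id`).
#' @return List of samples `list(patient_id, image, mask)`.
#' @export
mip_training_set <- function(cases) {
  out <- list()
  for (cs in cases) {
    pair <- make_mip_pair(cs$volume, cs$mask)
    pid <- cs$patient_id %||% "case"
    out[[length(out) + 1L]] <- list(patient_id = pid,
                                    image = pair$coronal$image,
                                    mask = pair$coronal$mask)
    out[[length(out) + 1L]] <- list(patient_id = pid,
                                    image = pair$sagittal$image,
                                    mask = pair$sagittal$mask)
  }
  out
}

prepare_sample <- function(sample, config) {
  tg <- to_model_grid(normalize_mip(sample$image$data, config$clip_pct),
                      config$grid, "bilinear")
  mg <- to_model_grid(sample$mask$data, config$grid, "nearest")
  list(x = cnn_input(tg$m, config$grid), t = mg$m)
}

# single-model trainer on prepared samples (list of list(x, t))
fit_cnn <- function(prep, config, trace = FALSE) {
  params <- cnn_init_params(config)
  caches <- cnn_caches(config)
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n <- length(prep)
  for (epoch in seq_len(config$epochs)) {
    set.seed(child_seed(config$seed, epoch))
    ord <- sample(n)
    acc <- NULL; acc_n <- 0L
    ep_loss <- 0
    for (s in ord) {
      fwd <- cnn_forward(prep[[s]]$x, params, caches, keep = TRUE)
      lg <- seg_loss_grad(fwd$p, prep[[s]]$t)
      ep_loss <- ep_loss + lg$loss
      grads <- cnn_backward(lg$dz, params, caches, fwd$cache)
      if (is.null(acc)) {
        acc <- grads
      } else {
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + grads[[nm]]
      }
      acc_n <- acc_n + 1L
      if (acc_n == config$batch_size || s == ord[length(ord)]) {
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / acc_n
        st <- adam_step(params, acc, state, config$lr)
        params <- st$params; state <- st$state
        acc <- NULL; acc_n <- 0L
      }
    }
    if (trace) message(sprintf("epoch %d: mean loss %.4f", epoch, ep_loss / n))
  }
  structure(list(params = params, config = config, trained = TRUE),
            class = "mip_cnn")
}

#' Train the MIP segmenter with patientwise k-fold cross-validation
#'
#' One model is trained per fold on the remaining folds' samples (coronal and
#' sagittal views of a patient are independent training samples) and
#' evaluated on the held-out fold (mean per-sample Dice). A fold whose
#' training data contains no lesion pixels is skipped with a warning.
#'
#' @param samples List of samples `list(patient_id, image, mask)`, e.g. from
#'   [mip_training_set()].
#' @param split A `training_split` from [make_split()].
#' @param config A [cnn_config()].
#' @return A `mip_cnn_cv`: list with `models` (one `mip_cnn` per fold),
#'   `metrics` (data.frame fold / n_train / n_val / val_dice), `split`,
#'   `config`.
#' @export
train_cnn <- function(samples, split, config = cnn_config()) {
  stopifnot(inherits(split, "training_split"))
  pids <- vapply(samples, function(s) s$patient_id, character(1))
  assert_that(length(unique(pids)) >= 10L,
              "training requires at least 10 patients")
  assert_that(all(pids %in% split$patient_id),
              "every sample's patient must appear in the split")
  prep <- lapply(samples, prepare_sample, config = config)
  folds <- sort(unique(split$fold))
  models <- vector("list", length(folds))
  metrics <- data.frame()
  for (f in folds) {
    val_pat <- split$patient_id[split$fold == f]
    tr_idx <- which(!pids %in% val_pat)
    va_idx <- which(pids %in% val_pat)
    if (sum(vapply(prep[tr_idx], function(s) sum(s$t), numeric(1))) == 0) {
      warning("fold ", f, " skipped: no lesion pixels in training data",
              call. = FALSE)
      next
    }
    cfg <- config
    cfg$seed <- child_seed(config$seed, 1000 + f)
    model <- fit_cnn(prep[tr_idx], cfg)
    caches <- cnn_caches(cfg)
    dices <- vapply(va_idx, function(i) {
      p <- cnn_forward(prep[[i]]$x, model$params, caches, keep = FALSE)$p
      pred <- p >= cfg$cutoff
      t <- prep[[i]]$t > 0
      if (!any(t) && !any(pred)) return(1)
      2 * sum(pred & t) / (sum(pred) + sum(t))
    }, numeric(1))
    models[[f]] <- model
    metrics <- rbind(metrics, data.frame(fold = f, n_train = length(tr_idx),
                                         n_val = length(va_idx),
                                         val_dice = mean(dices)))
  }
  structure(list(models = models, metrics = metrics, split = split,
                 config = config),
            class = "mip_cnn_cv")
}

#' @export
print.mip_cnn_cv <- function(x, ...) {
  cat("mip_cnn_cv:", nrow(x$metrics), "trained folds; mean validation Dice",
      round(mean(x$metrics$val_dice), 3), "\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Segment a MIP image with a trained model
#'
#' The image is normalized, fitted to the model grid, passed through the
#' network, and the probability map is mapped back to the native grid by the
#' inverse transform and binarized at the configured cutoff. Output shape
#' equals input shape.
#'
#' @param object A `mip_cnn` (from [train_cnn()]'s `models`) or a
#'   `mip_cnn_cv` (its first trained fold model is used).
#' @param mip A `mip_image`.
#' @param cutoff Optional override of the binarization cutoff.
#' @param ... Unused.
#' @return A `mip_mask`.
#' @export
predict.mip_cnn <- function(object, mip, cutoff = NULL, ...) {
  assert_that(isTRUE(object$trained), "model has not been trained")
  stopifnot(inherits(mip, "mip_image"))
  cfg <- object$config
  cutoff <- cutoff %||% cfg$cutoff
  if (max(mip$data) <= 0) {   # no signal anywhere: trivially empty
    return(new_mip(matrix(0L, nrow(mip$data), ncol(mip$data)),
                   mip$pixel_spacing, mip$view, "mip_mask"))
  }
  tg <- to_model_grid(normalize_mip(mip$data, cfg$clip_pct), cfg$grid, "bilinear")
  x <- cnn_input(tg$m, cfg$grid)
  p <- cnn_forward(x, object$params, cnn_caches(cfg), keep = FALSE)$p
  native <- from_model_grid(p, tg$meta)
  out <- matrix(as.integer(native >= cutoff), nrow(mip$data), ncol(mip$data))
  new_mip(out, mip$pixel_spacing, mip$view, "mip_mask")
}

#' @rdname predict.mip_cnn
#' @export
predict.mip_cnn_cv <- function(object, mip, cutoff = NULL, ...) {
  idx <- which(!vapply(object$models, is.null, logical(1)))[1]
  assert_that(length(idx) == 1 && !is.na(idx), "no trained fold model available")
  predict(object$models[[idx]], mip, cutoff = cutoff, ...)
}
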