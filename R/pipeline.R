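# End-to-end orchestration: phantom cohort -> projections -> (reference |
# baseline | cnn) masks -> biomarkers -> simulated survival -> risk
# stratification and survival statistics. All stage seeds derive from one
# run seed and are recorded in the manifest; patients without a defined
# dissemination (fewer than 2 lesions) are excluded from the survival
# analysis with a logged reason.

#' Configure an end-to-end pipeline run
#'
#' @param n_patients Cohort size for phantom generation.
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it and records it in the run manifest.
#' @param mode Mask source for the surrogate biomarkers:
#'   `"reference"` (project the ground-truth 3D masks), `"baseline"`
#'   (threshold segmenter with organ templates), or `"cnn"` (out-of-fold
#'   predictions from patientwise cross-validation).
#' @param out_dir Output directory; `NULL` computes in memory only.
#' @param cutoff_method Cutoff rule for risk stratification
#'   (see [select_cutoff()]), default `"median"`.
#' @param horizon_months Horizon for the time-dependent AUC.
#' @param survival_spec A [survival_sim_spec()] or `NULL` for the default
#'   (hazard increasing with log TMTV and with Dmax).
#' @param cnn A [cnn_config()] used when `mode = "cnn"`.
#' @param n_boot Bootstrap resamples for the Cox CI.
#' @param qc_png Write per-patient MIP overlay PNGs, default FALSE.
#' @return A `run_config` list.
#' @export
run_config <- function(n_patients = 20L, seed = 1L,
                       mode = c("reference", "baseline", "cnn"),
                       out_dir = NULL, cutoff_method = "median",
                       horizon_months = 48, survival_spec = NULL,
                       cnn = cnn_config(), n_boot = 200L, qc_png = FALSE) {
  mode <- match.arg(mode)
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 mode = mode, out_dir = out_dir, cutoff_method = cutoff_method,
                 horizon_months = horizon_months,
                 survival_spec = survival_spec, cnn = cnn,
                 n_boot = as.integer(n_boot), qc_png = isTRUE(qc_png)),
            class = "run_config")
}

default_survival_spec <- function(seed) {
  survival_sim_spec(baseline_hazard = 0.004,
                    log_hr_per_unit = c(log_tmtv = 0.6, dmax_cm = 0.05),
                    censoring_rate = 0.2, horizon_months = 60,
                    seed = child_seed(seed, 7))
}

# masks for the chosen mode, as a list of mip_pair-like structures
pipeline_masks <- function(cases, config) {
  ref_pairs <- lapply(cases, function(cs) make_mip_pair(cs$volume, cs$mask))
  if (config$mode == "reference") return(ref_pairs)
  if (config$mode == "baseline") {
    return(lapply(seq_along(cases), function(i) {
      cs <- cases[[i]]
      pr <- ref_pairs[[i]]
      list(coronal = list(
             image = pr$coronal$image,
             mask = baseline_segment(pr$coronal$image,
                                     organ_mask = organ_mip_mask(cs, "coronal"))),
           sagittal = list(
             image = pr$sagittal$image,
             mask = baseline_segment(pr$sagittal$image,
                                     organ_mask = organ_mip_mask(cs, "sagittal"))))
    }))
  }
  # cnn: patientwise k-fold CV, out-of-fold predictions for every patient
  samples <- mip_training_set(cases)
  pids <- vapply(cases, function(cs) cs$patient_id, character(1))
  split <- make_split(pids, k = 5L, seed = child_seed(config$seed, 11))
  cv <- train_cnn(samples, split, config$cnn)
  lapply(seq_along(cases), function(i) {
    fold <- split$fold[split$patient_id == pids[i]]
    model <- cv$models[[fold]]
    if (is.null(model)) model <- cv$models[[which(!vapply(cv$models, is.null,
                                                          logical(1)))[1]]]
    pr <- ref_pairs[[i]]
    list(coronal = list(image = pr$coronal$image,
                        mask = predict(model, pr$coronal$image)),
         sagittal = list(image = pr$sagittal$image,
                         mask = predict(model, pr$sagittal$image)))
  })
}

#' Run the end-to-end pipeline
#'
#' Generates (or accepts) a phantom cohort, computes the 3D biomarkers from
#' the reference masks and the surrogate biomarkers from the configured mask
#' source, simulates linked survival outcomes, stratifies patients into the
#' three TMTV-by-Dmax risk categories, and computes Kaplan-Meier curves,
#' Cox hazard ratios (high-vs-low burden) and the time-dependent AUC.
#' Patients with fewer than two lesions are excluded from the survival
#' analysis and listed in the exclusion log.
#'
#' @param config A [run_config()].
#' @param cases Optional pre-generated cohort (list of `phantom_case`);
#'   by default a cohort is generated from the config seed.
#' @return A list with `biomarkers` (per-patient table), `survival`
#'   (records + category + analysis results), `exclusions`, `manifest`,
#'   and, when `out_dir` is set, the paths written.
#' @export
run_pipeline <- function(config, cases = NULL) {
  stopifnot(inherits(config, "run_config"))
  cases <- cases %||% generate_cohort(config$n_patients,
                                      seed = child_seed(config$seed, 1))
  pids <- vapply(cases, function(cs) cs$patient_id, character(1))

  ref_tab <- biomarker_table(cases)
  ref_tab$patient_id <- pids
  mode_pairs <- pipeline_masks(cases, config)
  mode_rows <- lapply(seq_along(cases), function(i) {
    st <- compute_stmtv(mode_pairs[[i]])
    sd <- compute_sdmax(mode_pairs[[i]])
    data.frame(patient_id = pids[i], stmtv_cm2 = st$stmtv_cm2,
               sdmax_cm = sd$sdmax_cm, stringsAsFactors = FALSE)
  })
  mode_tab <- do.call(rbind, mode_rows)
  tab <- ref_tab
  tab$stmtv_mode_cm2 <- mode_tab$stmtv_cm2
  tab$sdmax_mode_cm <- mode_tab$sdmax_cm

  excl <- tab[tab$flag_single_lesion, "patient_id", drop = FALSE]
  excl$reason <- if (nrow(excl)) "fewer than 2 lesions" else character(0)
  keep <- !tab$flag_single_lesion
  surv_tab <- tab[keep, , drop = FALSE]

  results <- list()
  degenerate <- sum(keep) >= 1L &&
    (stats::sd(surv_tab$stmtv_mode_cm2) == 0 ||
       stats::sd(surv_tab$sdmax_mode_cm) == 0 ||
       stats::sd(surv_tab$tmtv_cm3) == 0 || stats::sd(surv_tab$dmax_cm) == 0)
  if (degenerate) {
    warning("degenerate biomarker distribution: survival statistics skipped",
            call. = FALSE)
  }
  if (sum(keep) >= 5L && !degenerate) {
    surv_tab$log_tmtv <- log1p(surv_tab$tmtv_cm3)
    sspec <- config$survival_spec %||% default_survival_spec(config$seed)
    rec <- simulate_survival(surv_tab, sspec)
    rec$tmtv_cm3 <- surv_tab$tmtv_cm3
    rec$dmax_cm <- surv_tab$dmax_cm
    rec$stmtv_cm2 <- surv_tab$stmtv_mode_cm2
    rec$sdmax_cm <- surv_tab$sdmax_mode_cm
    rule3d <- list(tmtv_cutoff = select_cutoff(rec$tmtv_cm3, rec, config$cutoff_method),
                   dmax_cutoff = select_cutoff(rec$dmax_cm, rec, config$cutoff_method))
    rule2d <- list(tmtv_cutoff = select_cutoff(rec$stmtv_cm2, rec, config$cutoff_method),
                   dmax_cutoff = select_cutoff(rec$sdmax_cm, rec, config$cutoff_method))
    rec$category_3d <- stratify_risk(rec$tmtv_cm3, rec$dmax_cm, rule3d)
    rec$category_2d <- stratify_risk(rec$stmtv_cm2, rec$sdmax_cm, rule2d)
    hi <- rec$tmtv_cm3 > rule3d$tmtv_cutoff
    results <- list(
      rules = list(ref = rule3d, mode = rule2d),
      km_overall = km_estimate(rec),
      cox_high_burden = if (length(unique(hi)) == 2L)
        cox_hr(rec, hi, n_boot = config$n_boot,
               seed = child_seed(config$seed, 13)) else NULL,
      td_auc_tmtv = td_auc(rec, rec$tmtv_cm3, config$horizon_months),
      td_auc_stmtv = td_auc(rec, rec$stmtv_cm2, config$horizon_months),
      category_counts = table(rec$category_3d),
      risk_agreement = risk_agreement(rec$category_3d, rec$category_2d)
    )
  } else {
    rec <- NULL
  }

  manifest <- list(
    package_version = tryCatch(as.character(utils::packageVersion("petmip")),
                               error = function(e) "dev"),
    n_patients = config$n_patients,
    mode = config$mode,
    seed = config$seed,
    stage_seeds = list(cohort = child_seed(config$seed, 1),
                       survival = child_seed(config$seed, 7),
                       split = child_seed(config$seed, 11),
                       bootstrap = child_seed(config$seed, 13)),
    cutoff_method = config$cutoff_method,
    horizon_months = config$horizon_months,
    config_hash = config_hash(config)
  )

  out <- list(biomarkers = tab, survival = list(records = rec, results = results),
              exclusions = excl, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    p_bio <- file.path(config$out_dir, "biomarkers.csv")
    utils::write.csv(format_biomarker_csv(tab), p_bio, row.names = FALSE)
    p_exc <- file.path(config$out_dir, "exclusions.csv")
    utils::write.csv(excl, p_exc, row.names = FALSE)
    p_man <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, digits = NA)
    paths <- c(biomarkers = p_bio, exclusions = p_exc, manifest = p_man)
    if (!is.null(rec)) {
      p_sur <- file.path(config$out_dir, "survival.csv")
      utils::write.csv(rec, p_sur, row.names = FALSE)
      p_res <- file.path(config$out_dir, "results.json")
      jsonlite::write_json(serialize_results(results), p_res,
                           auto_unbox = TRUE, digits = NA)
      paths <- c(paths, survival = p_sur, results = p_res)
    }
    if (config$qc_png) {
      for (i in seq_along(cases)) {
        pr <- mode_pairs[[i]]
        export_mip_png(pr$coronal$image,
                       file.path(config$out_dir,
                                 paste0(pids[i], "_coronal_qc.png")),
                       mask = pr$coronal$mask)
      }
    }
    out$paths <- paths
  }
  out
}

# units in CSV headers to prevent silent unit drift
format_biomarker_csv <- function(tab) {
  names(tab) <- sub("^tmtv_cm3$", "TMTV_cm3", names(tab))
  names(tab) <- sub("^dmax_cm$", "Dmax_cm", names(tab))
  names(tab) <- sub("^stmtv_cm2$", "sTMTV_cm2", names(tab))
  names(tab) <- sub("^sdmax_cm$", "sDmax_cm", names(tab))
  tab
}

serialize_results <- function(results) {
  res <- results
  res$km_overall <- NULL
  res$category_counts <- as.list(results$category_counts)
  res$risk_agreement <- list(
    accuracy = results$risk_agreement$accuracy,
    confusion = results$risk_agreement$confusion)
  res
}

config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "out_dir")]
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE, digits = NA)
  # small stable polynomial hash over the JSON string (exact in doubles)
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 1000000007
  sprintf("%08x", as.integer(h))
}

#' Compare reference-mask and segmenter-derived surrogate biomarkers
#'
#' Runs the pipeline's mask stage in `"reference"` mode and in the
#' configured segmentation mode on the same cohort, and reports the paired
#' per-patient sTMTV/sDmax values with agreement statistics (Spearman
#' correlations, median-split concordance, and three-category risk
#' agreement under median cutoffs).
#'
#' @param config A [run_config()]; its `mode` selects the segmenter arm.
#' @param cases Optional pre-generated cohort.
#' @return List with `table` (paired values), `spearman_stmtv`,
#'   `spearman_sdmax`, `concordance_stmtv`, `concordance_sdmax`,
#'   `risk_agreement`.
#' @export
compare_modes <- function(config, cases = NULL) {
  stopifnot(inherits(config, "run_config"))
  assert_that(config$mode != "reference",
              "compare_modes needs a segmenter mode ('baseline' or 'cnn')")
  cases <- cases %||% generate_cohort(config$n_patients,
                                      seed = child_seed(config$seed, 1))
  assert_that(length(cases) >= 3L, "cohort too small to compare modes")
  ref_cfg <- config; ref_cfg$mode <- "reference"
  ref_pairs <- pipeline_masks(cases, ref_cfg)
  mode_pairs <- pipeline_masks(cases, config)
  one <- function(pairs) {
    do.call(rbind, lapply(pairs, function(pr) {
      data.frame(stmtv_cm2 = compute_stmtv(pr)$stmtv_cm2,
                 sdmax_cm = compute_sdmax(pr)$sdmax_cm)
    }))
  }
  a <- one(ref_pairs); b <- one(mode_pairs)
  tab <- data.frame(
    patient_id = vapply(cases, function(cs) cs$patient_id %||% NA_character_,
                        character(1)),
    stmtv_ref_cm2 = a$stmtv_cm2, stmtv_mode_cm2 = b$stmtv_cm2,
    sdmax_ref_cm = a$sdmax_cm, sdmax_mode_cm = b$sdmax_cm,
    stringsAsFactors = FALSE)
  rule_ref <- list(tmtv_cutoff = stats::median(a$stmtv_cm2),
                   dmax_cutoff = stats::median(a$sdmax_cm))
  rule_mode <- list(tmtv_cutoff = stats::median(b$stmtv_cm2),
                    dmax_cutoff = stats::median(b$sdmax_cm))
  ra <- if (all(unlist(rule_ref) > 0) && all(unlist(rule_mode) > 0)) {
    risk_agreement(stratify_risk(a$stmtv_cm2, a$sdmax_cm, rule_ref),
                   stratify_risk(b$stmtv_cm2, b$sdmax_cm, rule_mode))
  } else NULL
  list(table = tab,
       spearman_stmtv = spearman_cor(a$stmtv_cm2, b$stmtv_cm2),
       spearman_sdmax = spearman_cor(a$sdmax_cm, b$sdmax_cm),
       concordance_stmtv = median_concordance(a$stmtv_cm2, b$stmtv_cm2),
       concordance_sdmax = median_concordance(a$sdmax_cm, b$sdmax_cm),
       risk_agreement = ra)
}
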