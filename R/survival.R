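# Prognostic analysis: cutoff-based risk stratification, Kaplan-Meier,
# Cox hazard ratios with bootstrap CIs, and IPCW time-dependent AUC.
#
# `records` throughout is a data.frame with columns `time_months` (> 0) and
# `event` (0/1), plus whatever marker columns the caller carries along.

check_records <- function(records) {
  assert_that(all(c("time_months", "event") %in% names(records)),
              "records need columns time_months and event")
  assert_that(all(is.finite(records$time_months)) && all(records$time_months > 0),
              "time_months must be finite and positive")
  assert_that(all(records$event %in% c(0, 1)), "event must be 0/1")
  invisible(records)
}

#' Three-category risk stratification from burden and dissemination
#'
#' Category low: both values at or below their cutoffs; high: both strictly
#' above; intermediate: exactly one above. Values exactly at a cutoff are
#' low-side (the cutoffs are "<=" boundaries). Works identically for the 3D
#' biomarkers (TMTV cm^3, Dmax cm) and the surrogates (sTMTV cm^2, sDmax cm).
#'
#' @param tmtv_like Numeric vector of burden values.
#' @param dmax_like Numeric vector of dissemination values.
#' @param rule List with `tmtv_cutoff` and `dmax_cutoff` (both > 0), e.g.
#'   from [select_cutoff()].
#' @return Factor with levels low / intermediate / high.
#' @export
stratify_risk <- function(tmtv_like, dmax_like, rule) {
  assert_that(all(is.finite(tmtv_like)) && all(is.finite(dmax_like)),
              "biomarker values must be finite")
  assert_that(rule$tmtv_cutoff > 0 && rule$dmax_cutoff > 0,
              "cutoffs must be > 0")
  hi_t <- tmtv_like > rule$tmtv_cutoff
  hi_d <- dmax_like > rule$dmax_cutoff
  cat <- ifelse(hi_t & hi_d, "high", ifelse(hi_t | hi_d, "intermediate", "low"))
  factor(cat, levels = c("low", "intermediate", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' At each distinct event time `t` with `d` events among `n` subjects still
#' at risk, the survival estimate is multiplied by `1 - d/n`; censored
#' subjects leave the risk set without contributing a factor.
#'
#' @param records Data frame with `time_months` and `event`.
#' @return A `data.frame` (the at-risk table): one row per distinct observed
#'   time, with `time`, `n_risk`, `n_event`, `n_censor` and `surv`.
#' @export
km_estimate <- function(records) {
  check_records(records)
  n <- nrow(records)
  assert_that(n >= 1L, "need at least one record")
  tt <- sort(unique(records$time_months))
  out <- data.frame(time = tt, n_risk = NA_real_, n_event = NA_real_,
                    n_censor = NA_real_, surv = NA_real_)
  s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(records$time_months >= tt[i])
    d <- sum(records$time_months == tt[i] & records$event == 1)
    cns <- sum(records$time_months == tt[i] & records$event == 0)
    if (d > 0) s <- s * (1 - d / at_risk)
    out$n_risk[i] <- at_risk; out$n_event[i] <- d
    out$n_censor[i] <- cns; out$surv[i] <- s
  }
  out
}

# evaluate a KM step function at t (left limit optional)
km_eval <- function(km, t, left = FALSE) {
  idx <- if (left) which(km$time < t) else which(km$time <= t)
  if (!length(idx)) 1 else km$surv[max(idx)]
}

#' Cox proportional-hazards HR for a binary group with bootstrap CI
#'
#' Single-covariate Cox partial-likelihood fit (Breslow tie handling, via
#' the survival package); HR = exp(beta). The confidence interval is a
#' seeded patient-level percentile bootstrap (2.5/97.5 percentiles of the
#' resampled HR).
#'
#' @param records Data frame with `time_months` and `event`.
#' @param group Binary (0/1 or logical) indicator, one per record.
#' @param n_boot Bootstrap resamples, default 1000.
#' @param seed Integer seed for the bootstrap.
#' @return List with `hr`, `beta`, `ci_low`, `ci_high`, `n_boot`, `seed`,
#'   and `estimable` (FALSE, with `hr = NA`, when either group has no
#'   events).
#' @export
cox_hr <- function(records, group, n_boot = 1000L, seed = 1L) {
  check_records(records)
  g <- as.integer(as.logical(group))
  assert_that(length(g) == nrow(records), "group length must match records")
  assert_that(all(table(factor(g, levels = 0:1)) > 0), "both groups must be non-empty")
  ev <- tapply(records$event, g, sum)
  if (any(ev == 0)) {
    warning("no events in one group: HR non-estimable", call. = FALSE)
    return(list(hr = NA_real_, beta = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, n_boot = n_boot, seed = seed,
                estimable = FALSE))
  }
  fit_beta <- function(rec, gg) {
    fit <- survival::coxph(survival::Surv(rec$time_months, rec$event) ~ gg,
                           ties = "breslow")
    unname(stats::coef(fit))
  }
  beta <- fit_beta(records, g)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample(nrow(records), replace = TRUE)
      gg <- g[idx]
      if (length(unique(gg)) < 2L) return(NA_real_)
      rec <- records[idx, , drop = FALSE]
      if (any(tapply(rec$event, gg, sum) == 0)) return(NA_real_)
      tryCatch(fit_beta(rec, gg), error = function(e) NA_real_)
    }, numeric(1))
    ok <- bs[is.finite(bs)]
    if (length(ok) < 0.8 * n_boot) {
      warning("more than 20% of bootstrap resamples failed", call. = FALSE)
    }
    ci <- exp(stats::quantile(ok, c(0.025, 0.975), names = FALSE))
  }
  list(hr = exp(beta), beta = beta, ci_low = ci[1], ci_high = ci[2],
       n_boot = n_boot, seed = seed, estimable = TRUE)
}

#' Time-dependent AUC at a fixed horizon (IPCW cumulative/dynamic)
#'
#' Discrimination of a marker for events occurring on or before the horizon
#' (cases) versus subjects known event-free beyond it (controls). Pairs are
#' weighted by inverse probabilities of censoring estimated with a
#' Kaplan-Meier estimator of the censoring distribution: case `i` carries
#' weight `1/G(T_i-)`, control `j` weight `1/G(tau)`. Ties in the marker
#' count 1/2. With no censoring the estimator reduces exactly to the plain
#' rank AUC of cases versus controls.
#'
#' @param records Data frame with `time_months` and `event`.
#' @param marker Numeric risk marker, one per record (higher = worse).
#' @param horizon_months Evaluation horizon, default 48 (4 years).
#' @return List with `auc`, `horizon_months`, `n_cases`, `n_controls`,
#'   and `estimable`.
#' @export
td_auc <- function(records, marker, horizon_months = 48) {
  check_records(records)
  assert_that(length(marker) == nrow(records), "marker length must match records")
  tau <- horizon_months
  is_case <- records$time_months <= tau & records$event == 1
  is_ctrl <- records$time_months > tau
  if (!any(is_case) || !any(is_ctrl)) {
    warning("no cases before or no controls beyond the horizon", call. = FALSE)
    return(list(auc = NA_real_, horizon_months = tau, n_cases = sum(is_case),
                n_controls = sum(is_ctrl), estimable = FALSE))
  }
  cens_km <- km_estimate(data.frame(time_months = records$time_months,
                                    event = 1 - records$event))
  g_tau <- km_eval(cens_km, tau)
  if (g_tau <= 0) {
    warning("censoring survival reaches 0 before the horizon", call. = FALSE)
    return(list(auc = NA_real_, horizon_months = tau, n_cases = sum(is_case),
                n_controls = sum(is_ctrl), estimable = FALSE))
  }
  w_case <- 1 / vapply(records$time_months[is_case],
                       function(t) km_eval(cens_km, t, left = TRUE), numeric(1))
  w_ctrl <- rep(1 / g_tau, sum(is_ctrl))
  mc <- marker[is_case]; mk <- marker[is_ctrl]
  # pairwise comparison, vectorized over the case x control grid
  cmp <- outer(mc, mk, function(a, b) (a > b) + 0.5 * (a == b))
  num <- sum(cmp * outer(w_case, w_ctrl))
  den <- sum(w_case) * sum(w_ctrl)
  list(auc = num / den, horizon_months = tau, n_cases = sum(is_case),
       n_controls = sum(is_ctrl), estimable = TRUE)
}

#' Seeded patient-level percentile bootstrap CI for any statistic
#'
#' @param statistic Function taking a resampled `records` data.frame and
#'   returning a scalar.
#' @param records Data frame of patient rows to resample with replacement.
#' @param n_boot Number of resamples, default 1000.
#' @param seed Integer seed.
#' @return List with `ci_low`, `ci_high` (2.5/97.5 percentiles), `n_ok`,
#'   and `flagged` (TRUE if more than 20% of resamples failed).
#' @export
bootstrap_ci <- function(statistic, records, n_boot = 1000L, seed = 1L) {
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(b) {
    idx <- sample(nrow(records), replace = TRUE)
    tryCatch(as.numeric(statistic(records[idx, , drop = FALSE])),
             error = function(e) NA_real_)
  }, numeric(1))
  ok <- vals[is.finite(vals)]
  flagged <- length(ok) < 0.8 * n_boot
  if (flagged) warning("more than 20% of bootstrap resamples failed", call. = FALSE)
  q <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
  list(ci_low = q[1], ci_high = q[2], n_ok = length(ok), flagged = flagged)
}

#' Choose a dichotomization cutoff for a biomarker
#'
#' `supplied` echoes `value`; `median` uses the sample median;
#' `max_logrank` scans candidate cutoffs at the inner deciles (10%..90%) of
#' the marker and returns the one maximizing the two-group log-rank
#' chi-square statistic.
#'
#' @param values Numeric biomarker values, one per record.
#' @param records Survival records (needed for `max_logrank`).
#' @param method One of `"supplied"`, `"median"`, `"max_logrank"`.
#' @param value Cutoff for `method = "supplied"`.
#' @return The selected cutoff (numeric scalar).
#' @export
select_cutoff <- function(values, records = NULL,
                          method = c("median", "supplied", "max_logrank"),
                          value = NULL) {
  method <- match.arg(method)
  assert_that(stats::sd(values) > 0, "degenerate biomarker: all values equal")
  if (method == "supplied") {
    assert_that(!is.null(value), "method 'supplied' needs a value")
    return(value)
  }
  if (method == "median") return(stats::median(values))
  check_records(records)
  assert_that(nrow(records) == length(values), "values/records length mismatch")
  cand <- unique(stats::quantile(values, seq(0.1, 0.9, by = 0.1), names = FALSE))
  best <- cand[1]; best_chisq <- -Inf
  for (ct in cand) {
    g <- values > ct
    if (length(unique(g)) < 2L) next
    sd_fit <- tryCatch(
      survival::survdiff(survival::Surv(records$time_months, records$event) ~ g),
      error = function(e) NULL)
    if (is.null(sd_fit)) next
    if (sd_fit$chisq > best_chisq) { best_chisq <- sd_fit$chisq; best <- ct }
  }
  best
}
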