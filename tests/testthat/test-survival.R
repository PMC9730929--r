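sim_records <- function(n, beta, seed, censor = 0) {
  set.seed(seed)
  g <- rep(0:1, length.out = n)
  t_ev <- stats::rexp(n, rate = 0.05 * exp(beta * g))
  cens <- if (censor > 0) ifelse(stats::runif(n) < censor,
                                 stats::runif(n, 0, 40), Inf) else rep(Inf, n)
  data.frame(time_months = pmin(t_ev, cens),
             event = as.integer(t_ev <= cens), group = g)
}

test_that("risk stratification reproduces the published category logic", {
  rule <- list(tmtv_cutoff = 222, dmax_cutoff = 59)
  expect_equal(as.character(stratify_risk(100, 30, rule)), "low")
  expect_equal(as.character(stratify_risk(300, 30, rule)), "intermediate")
  expect_equal(as.character(stratify_risk(100, 80, rule)), "intermediate")
  expect_equal(as.character(stratify_risk(300, 80, rule)), "high")
  # values exactly at the cutoffs are low ("<=" boundary)
  expect_equal(as.character(stratify_risk(222, 59, rule)), "low")
  # exhaustive and exclusive over random inputs
  set.seed(31)
  cats <- stratify_risk(stats::runif(200, 0, 500), stats::runif(200, 0, 120), rule)
  expect_false(anyNA(cats))
  expect_equal(levels(cats), c("low", "intermediate", "high"))
})

test_that("Kaplan-Meier matches hand product-limit and survfit", {
  # events at 1, 2, 3 among n = 3: S = 2/3, 1/3, 0
  rec <- data.frame(time_months = 1:3, event = 1)
  km <- km_estimate(rec)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: S = 1 throughout
  rec2 <- data.frame(time_months = c(2, 5, 9), event = 0)
  expect_true(all(km_estimate(rec2)$surv == 1))
  # mixed case against survival::survfit
  set.seed(33)
  rec3 <- data.frame(time_months = round(stats::rexp(10, 0.1), 1) + 0.1,
                     event = stats::rbinom(10, 1, 0.7))
  km3 <- km_estimate(rec3)
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = rec3)
  expect_equal(petmip:::km_eval(km3, max(rec3$time_months)),
               min(sf$surv), tolerance = 1e-12)
  for (t in c(3, 8, 15)) {
    expect_equal(petmip:::km_eval(km3, t),
                 summary(sf, times = t)$surv, tolerance = 1e-12)
  }
  # non-increasing with S(0) = 1
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_equal(petmip:::km_eval(km3, 0), 1)
})

test_that("Cox beta matches the partial-likelihood grid-search oracle", {
  set.seed(34)
  for (rep in 1:20) {
    rec <- sim_records(sample(20:50, 1), beta = stats::runif(1, -1.5, 1.5),
                       seed = 600 + rep, censor = 0.2)
    if (min(tapply(rec$event, rec$group, sum)) == 0) next
    fit <- cox_hr(rec, rec$group, n_boot = 0)
    oracle <- oracle_cox_grid(rec$time_months, rec$event, rec$group)
    expect_lt(abs(fit$beta - oracle), 1e-3)
  }
})

test_that("Cox HR is 1 on symmetric data and flags non-estimable groups", {
  rec <- data.frame(time_months = rep(c(1, 2, 3, 4), 2),
                    event = 1, group = rep(0:1, each = 4))
  expect_equal(cox_hr(rec, rec$group, n_boot = 0)$hr, 1, tolerance = 1e-8)
  rec$event[rec$group == 1] <- 0
  expect_warning(fit <- cox_hr(rec, rec$group, n_boot = 0), "non-estimable")
  expect_false(fit$estimable)
  expect_true(is.na(fit$hr))
})

test_that("Cox HR recovery with bootstrap CI on a simulated two-group cohort", {
  rec <- sim_records(400, beta = log(4), seed = 35)
  fit <- cox_hr(rec, rec$group, n_boot = 200, seed = 9)
  expect_gt(fit$hr, 2.5)
  expect_lt(fit$hr, 6.5)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  # seeded bootstrap is reproducible
  fit2 <- cox_hr(rec, rec$group, n_boot = 200, seed = 9)
  expect_identical(fit[c("ci_low", "ci_high")], fit2[c("ci_low", "ci_high")])
})

test_that("time-dependent AUC reduces to the rank AUC without censoring", {
  set.seed(36)
  for (rep in 1:5) {
    rec <- sim_records(60, beta = 1, seed = 700 + rep, censor = 0)
    marker <- rec$group + stats::rnorm(60, 0, 0.5)
    tau <- stats::median(rec$time_months)
    got <- td_auc(rec, marker, tau)
    cases <- rec$time_months <= tau & rec$event == 1
    ctrls <- rec$time_months > tau
    expect_equal(got$auc, oracle_rank_auc(marker[cases], marker[ctrls]))
  }
  # a marker perfectly separating early events has AUC 1
  rec <- data.frame(time_months = c(1, 2, 3, 20, 30, 40), event = 1)
  expect_equal(td_auc(rec, c(10, 9, 8, 1, 2, 3), 10)$auc, 1)
  # degenerate horizons are flagged
  expect_warning(out <- td_auc(rec, 1:6, 100), "horizon")
  expect_false(out$estimable)
})

test_that("IPCW AUC stays close to the uncensored AUC under censoring", {
  rec <- sim_records(500, beta = 1.2, seed = 37, censor = 0)
  marker <- rec$group + stats::rnorm(500, 0, 0.3)
  auc_full <- td_auc(rec, marker, 15)$auc
  recc <- rec
  set.seed(38)
  cens <- stats::runif(500, 0, 60)
  keep_event <- rec$time_months <= cens
  recc$event[!keep_event] <- 0
  recc$time_months <- pmin(rec$time_months, cens)
  auc_cens <- td_auc(recc, marker, 15)$auc
  expect_equal(auc_cens, auc_full, tolerance = 0.05)
})

test_that("bootstrap_ci is seeded, honest about failures, and calibrated", {
  rec <- data.frame(time_months = rep(5, 40), event = 1, x = stats::rnorm(40))
  cst <- bootstrap_ci(function(d) 7, rec, n_boot = 50, seed = 1)
  expect_equal(cst$ci_low, 7)
  expect_equal(cst$ci_high, 7)
  b1 <- bootstrap_ci(function(d) mean(d$x), rec, n_boot = 200, seed = 4)
  b2 <- bootstrap_ci(function(d) mean(d$x), rec, n_boot = 200, seed = 4)
  expect_identical(b1, b2)
  # CI width for the mean of 100 standard normals ~ 2 * 1.96 / 10
  set.seed(39)
  recn <- data.frame(time_months = rep(1, 100), event = 1, x = stats::rnorm(100))
  bn <- bootstrap_ci(function(d) mean(d$x), recn, n_boot = 1000, seed = 5)
  expect_lt(abs((bn$ci_high - bn$ci_low) - 2 * 1.96 / 10), 0.2 * 2 * 1.96 / 10)
  # failing statistic is flagged
  expect_warning(
    bootstrap_ci(function(d) stop("boom"), rec, n_boot = 20, seed = 6),
    "20%")
})

test_that("select_cutoff offers median, supplied and max-logrank rules", {
  expect_equal(select_cutoff(1:9, method = "median"), 5)
  expect_equal(select_cutoff(1:9, method = "supplied", value = 3.3), 3.3)
  expect_error(select_cutoff(rep(2, 5), method = "median"), "degenerate")
  # two well-separated survival clusters: cutoff falls between them
  set.seed(41)
  values <- c(stats::runif(30, 0, 10), stats::runif(30, 90, 100))
  rec <- data.frame(
    time_months = c(stats::rexp(30, 0.02), stats::rexp(30, 0.4)) + 0.01,
    event = 1)
  ct <- select_cutoff(values, rec, method = "max_logrank")
  expect_gt(ct, 10)
  expect_lt(ct, 90)
})
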