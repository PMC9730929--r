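mkpair <- function(cor_pred, sag_pred) {
  list(coronal = list(mask = petmip:::new_mip(cor_pred, c(4, 4), "coronal", "mip_mask")),
       sagittal = list(mask = petmip:::new_mip(sag_pred, c(4, 4), "sagittal", "mip_mask")))
}

test_that("seg_metrics computes pooled Dice/sensitivity/specificity", {
  a <- matrix(0L, 10, 10); a[2:3, 2:3] <- 1L
  empty <- matrix(0L, 10, 10)

  same <- seg_metrics(mkpair(a, a), mkpair(a, a))
  expect_equal(same$dice, 1)
  expect_equal(same$sensitivity, 1)

  b <- matrix(0L, 10, 10); b[6:7, 6:7] <- 1L     # disjoint, equal size
  expect_equal(seg_metrics(mkpair(b, empty), mkpair(a, empty))$dice, 0)

  ov <- matrix(0L, 10, 10); ov[2:3, 2] <- 1L; ov[8, 8:9] <- 1L  # overlap 2 of 4
  half <- seg_metrics(mkpair(ov, empty), mkpair(a, empty))
  expect_equal(half$dice, 0.5)
  expect_equal(half$sensitivity, 0.5)

  # both empty: dice 1, flagged; empty ref with prediction: dice 0
  be <- seg_metrics(mkpair(empty, empty), mkpair(empty, empty))
  expect_equal(be$dice, 1)
  expect_true(be$flag_empty_reference)
  expect_equal(seg_metrics(mkpair(a, empty), mkpair(empty, empty))$dice, 0)

  # pooling over views, not averaging of per-view ratios
  pooled <- seg_metrics(mkpair(a, ov), mkpair(a, a))
  tp <- 4 + 2; fp <- 2; fn <- 2
  expect_equal(pooled$dice, 2 * tp / (2 * tp + fp + fn))
  expect_error(seg_metrics(mkpair(a, empty), mkpair(matrix(0L, 5, 5), empty)))

  # Dice is symmetric
  expect_equal(seg_metrics(mkpair(ov, empty), mkpair(a, empty))$dice,
               seg_metrics(mkpair(a, empty), mkpair(ov, empty))$dice)
})

test_that("specificity is dominated by background for sparse masks", {
  set.seed(8)
  for (rep in 1:5) {
    ref <- matrix(0L, 50, 80); ref[sample(4000, 60)] <- 1L
    pred <- matrix(0L, 50, 80); pred[sample(4000, 20)] <- 1L
    sm <- seg_metrics(mkpair(pred, pred), mkpair(ref, ref))
    fp_frac <- sm$fp / (sm$fp + sm$tn)
    expect_lt(fp_frac, 0.01)
    expect_gte(sm$specificity, 0.99)
  }
})

test_that("Wilcoxon signed-rank: worked example, symmetry, enumeration oracle", {
  # all differences positive, d = 1..6: V = 21, exact p = 2/64
  a <- c(11, 12, 13, 14, 15, 16); b <- c(10, 10, 10, 10, 10, 10)
  w <- wilcoxon_paired(a, b)
  expect_equal(w$statistic, 21)
  expect_equal(w$p_value, 2 / 64)
  # swapping the arguments leaves p unchanged
  expect_equal(wilcoxon_paired(b, a)$p_value, w$p_value)
  # identical vectors: p = 1 with warning
  expect_warning(w0 <- wilcoxon_paired(1:6, 1:6), "zero")
  expect_equal(w0$p_value, 1)

  # random datasets (with and without ties) vs full enumeration
  set.seed(15)
  for (n in 5:10) {
    for (rep in 1:3) {
      d <- sample(c(-4:-1, 1:5), n, replace = TRUE)  # ties in |d| included
      expect_equal(wilcoxon_paired(d, numeric(n))$p_value, oracle_wilcoxon_p(d),
                   label = sprintf("n=%d rep=%d", n, rep))
    }
  }

  # tie-less exact p also agrees with stats::wilcox.test
  set.seed(16)
  x <- stats::rnorm(9); y <- x + stats::rnorm(9)
  expect_equal(wilcoxon_paired(x, y)$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)

  # large-n normal approximation agrees with the reference implementation
  set.seed(17)
  x <- stats::rnorm(40); y <- x + stats::rnorm(40, 0.3)
  expect_equal(wilcoxon_paired(x, y)$p_value,
               stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                  correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("Spearman correlation is tie-aware and matches cor.test", {
  x <- c(1, 3, 5, 9, 11)
  expect_equal(spearman_cor(x, x^3)$r, 1)
  expect_equal(spearman_cor(x, -x)$r, -1)
  set.seed(21)
  for (rep in 1:5) {
    x <- sample(1:8, 20, replace = TRUE)   # ties present
    y <- x + stats::rnorm(20, 0, 2)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    got <- spearman_cor(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-10)
  }
  expect_warning(cc <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(cc$r))
})

test_that("median concordance counts strict exceedances of both medians", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(median_concordance(x, x)$fraction, 1)
  expect_equal(median_concordance(x, -x)$fraction, 0)
  set.seed(22)
  for (rep in 1:5) {
    x <- stats::rnorm(30); y <- stats::rnorm(30)
    got <- median_concordance(x, y)
    above <- which(x > stats::median(x))
    expect_equal(got$n_above_x, length(above))
    expect_equal(got$n_both_above, sum(y[above] > stats::median(y)))
    expect_equal(got$fraction, mean(y[above] > stats::median(y)))
  }
})

test_that("risk agreement builds the 3x3 confusion matrix and accuracy", {
  lev <- c("low", "intermediate", "high")
  a <- factor(rep(lev, times = c(4, 3, 2)), levels = lev)
  expect_equal(risk_agreement(a, a)$accuracy, 1)
  shifted <- factor(lev[(as.integer(a) %% 3) + 1], levels = lev)
  expect_equal(risk_agreement(a, shifted)$accuracy, 0)
  set.seed(23)
  x <- sample(lev, 30, replace = TRUE)
  y <- sample(lev, 30, replace = TRUE)
  ra <- risk_agreement(x, y)
  expect_equal(ra$accuracy, mean(x == y))
  expect_equal(rowSums(ra$confusion),
               c(low = sum(x == "low"), intermediate = sum(x == "intermediate"),
                 high = sum(x == "high")))
  expect_equal(sum(ra$confusion), 30)
  expect_error(risk_agreement(c("low", "none"), c("low", "high")), "low")
})
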