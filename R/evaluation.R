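# Agreement statistics between predicted and reference MIP masks, and
# between 3D and surrogate biomarkers.

#' Patientwise segmentation metrics (Dice, sensitivity, specificity)
#'
#' TP/FP/TN/FN are pooled over both views of a patient before ratio
#' formation (one patientwise value, not an average of per-view ratios);
#' per-view metrics are reported alongside. When both reference and
#' prediction are empty, Dice is defined as 1 (perfect agreement on absence)
#' and the row is flagged; an empty reference with a non-empty prediction
#' gives Dice 0.
#'
#' @param pred A `mip_pair` (or list with `coronal`/`sagittal` holding
#'   `mask`) of predicted masks.
#' @param ref The reference `mip_pair` masks, same shapes.
#' @param patient_id Identifier carried into the output.
#' @return One-row `data.frame`: `dice`, `sensitivity`, `specificity`,
#'   per-view Dice, pooled counts, `flag_empty_reference`.
#' @export
seg_metrics <- function(pred, ref, patient_id = NA_character_) {
  counts <- function(p, r) {
    stopifnot(all(dim(p$data) == dim(r$data)))
    pv <- p$data > 0; rv <- r$data > 0
    c(tp = sum(pv & rv), fp = sum(pv & !rv),
      fn = sum(!pv & rv), tn = sum(!pv & !rv))
  }
  dice_of <- function(ct) {
    if (ct["tp"] + ct["fp"] + ct["fn"] == 0) 1 else
      unname(2 * ct["tp"] / (2 * ct["tp"] + ct["fp"] + ct["fn"]))
  }
  cc <- counts(pred$coronal$mask, ref$coronal$mask)
  cs <- counts(pred$sagittal$mask, ref$sagittal$mask)
  ct <- cc + cs
  data.frame(
    patient_id = as.character(patient_id),
    dice = dice_of(ct),
    sensitivity = if (ct["tp"] + ct["fn"] == 0) NA_real_ else
      unname(ct["tp"] / (ct["tp"] + ct["fn"])),
    specificity = if (ct["tn"] + ct["fp"] == 0) NA_real_ else
      unname(ct["tn"] / (ct["tn"] + ct["fp"])),
    dice_coronal = dice_of(cc),
    dice_sagittal = dice_of(cs),
    tp = unname(ct["tp"]), fp = unname(ct["fp"]),
    fn = unname(ct["fn"]), tn = unname(ct["tn"]),
    flag_empty_reference = unname(ct["tp"] + ct["fn"] == 0),
    stringsAsFactors = FALSE
  )
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; ranks of `|d|` use midranks for ties. For
#' `n <= 12` retained pairs the p-value is computed by exact enumeration of
#' all `2^n` sign patterns (valid with ties, conditional on the observed
#' ranks); above that, a normal approximation with tie correction (no
#' continuity correction) is used.
#'
#' @param a,b Equal-length numeric vectors of paired observations.
#' @return A list with `statistic` (V = sum of positive ranks), `p_value`,
#'   `n` (retained pairs) and `method`.
#' @export
wilcoxon_paired <- function(a, b) {
  assert_that(length(a) == length(b), "a and b must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero", call. = FALSE)
    return(list(statistic = 0, p_value = 1, n = 0L, method = "degenerate"))
  }
  assert_that(n >= 5L, "need >= 5 non-zero paired differences")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= 12L) {
    # exact: distribution of V over all sign assignments of the ranks
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vdist <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(vdist <= v), mean(vdist >= v)))
    method <- "exact enumeration"
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4   # midranks make this the tie-corrected variance
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks (tie-aware); the p-value uses the
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`.
#' @return List with `r`, `p_value`, `n`; `r` is `NA` (flagged) when either
#'   input is constant.
#' @export
spearman_cor <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  assert_that(n >= 3L, "need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p_value = NA_real_, n = n))
  }
  r <- stats::cor(rank(x), rank(y))
  tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
  list(r = r, p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Median-split concordance between two biomarkers
#'
#' The fraction of observations strictly above the median of `x` that are
#' also strictly above the median of `y` (medians use the midpoint
#' convention for even n; "greater than median" is strict).
#'
#' @param x,y Equal-length numeric vectors.
#' @return List with `fraction`, `n_above_x`, `n_both_above`, and the two
#'   medians.
#' @export
median_concordance <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  mx <- stats::median(x); my <- stats::median(y)
  above_x <- x > mx
  both <- above_x & (y > my)
  list(fraction = if (sum(above_x) == 0) NA_real_ else sum(both) / sum(above_x),
       n_above_x = sum(above_x), n_both_above = sum(both),
       median_x = mx, median_y = my)
}

#' Agreement between 3D-based and surrogate-based risk categories
#'
#' @param cat3d Reference categories (factor or character in
#'   low/intermediate/high), one per patient.
#' @param cat2d Surrogate-based categories, same length.
#' @return List with `confusion` (3x3 matrix, rows = 3D reference),
#'   `accuracy` (diagonal fraction) and `n`.
#' @export
risk_agreement <- function(cat3d, cat2d) {
  lev <- c("low", "intermediate", "high")
  assert_that(length(cat3d) == length(cat2d), "category vectors differ in length")
  c3 <- as.character(cat3d); c2 <- as.character(cat2d)
  assert_that(all(c(c3, c2) %in% lev),
              "categories must be low / intermediate / high")
  conf <- table(factor(c3, levels = lev), factor(c2, levels = lev))
  conf <- unclass(conf)
  names(dimnames(conf)) <- c("reference_3d", "surrogate_2d")
  list(confusion = conf, accuracy = sum(diag(conf)) / sum(conf),
       n = length(c3))
}
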