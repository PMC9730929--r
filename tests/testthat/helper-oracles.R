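# Independent brute-force oracles used across tests. These deliberately do
# not share code with the package implementation.

# per-ray maximum by explicit triple loop
oracle_mip <- function(arr, axis) {
  dims <- dim(arr)
  keep <- setdiff(1:3, axis)
  out <- matrix(-Inf, dims[keep[1]], dims[keep[2]])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    co <- c(i, j, k)
    a <- co[keep[1]]; b <- co[keep[2]]
    if (arr[i, j, k] > out[a, b]) out[a, b] <- arr[i, j, k]
  }
  out
}

# cumulative-scan percentile span (independent of the package's cumsum form)
oracle_span <- function(profile, spacing, lo = 0.02, hi = 0.98) {
  total <- sum(profile)
  if (total == 0) return(0)
  find_q <- function(p) {
    acc <- 0
    for (k in seq_along(profile)) {
      acc <- acc + profile[k]
      if (acc / total >= p) return(k)
    }
    length(profile)
  }
  (find_q(hi) - find_q(lo)) * spacing
}

# connected components by union-find over all voxel pairs (O(V^2), tiny grids)
oracle_n_components <- function(a) {
  idx <- which(a > 0)
  if (!length(idx)) return(0L)
  co <- arrayInd(idx, dim(a))
  n <- length(idx)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (max(abs(co[i, ] - co[j, ])) <= 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Breslow log partial likelihood for a single binary covariate, written in
# terms of per-event-time risk-set counts (an independent derivation from
# the definition; the package route goes through survival::coxph).
oracle_cox_loglik <- function(beta, time, event, g) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    dead <- which(time == t & event == 1)
    risk <- time >= t
    n1 <- sum(g[risk] == 1); n0 <- sum(g[risk] == 0)
    ll <- ll + beta * sum(g[dead]) -
      length(dead) * log(n0 + n1 * exp(beta))
  }
  ll
}

# coarse-to-fine grid search, final resolution 1e-4
oracle_cox_grid <- function(time, event, g, lo = -5, hi = 5) {
  for (step in c(0.01, 1e-4)) {
    grid <- seq(lo, hi, by = step)
    ll <- vapply(grid, oracle_cox_loglik, numeric(1), time = time,
                 event = event, g = g)
    best <- grid[which.max(ll)]
    lo <- best - 2 * step; hi <- best + 2 * step
  }
  best
}

# plain rank AUC over all case-control pairs
oracle_rank_auc <- function(marker_case, marker_ctrl) {
  s <- 0
  for (a in marker_case) for (b in marker_ctrl) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(marker_case) * length(marker_ctrl))
}

# exact Wilcoxon signed-rank two-sided p by direct bit-pattern enumeration
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(m))[1:n]
    vs[m + 1] <- sum(r[bits == 1])
  }
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

dice_of <- function(p, t) {
  p <- p > 0; t <- t > 0
  if (!any(p) && !any(t)) return(1)
  2 * sum(p & t) / (sum(p) + sum(t))
}

# small high-contrast phantom helpers -------------------------------------

# clear_of_organs places lesions in the abdominal band between the bladder
# and heart planes, so no lesion is occluded by a physiologic organ in
# either projection (occluded pixels are unrecoverable for a pure
# intensity-threshold segmenter).
easy_phantom <- function(seed, n_lesions = NULL, noise = 0.05, uptake = 5,
                         clear_of_organs = FALSE) {
  sp <- petmip:::default_spec_sampler(1, seed, noise_sigma = noise,
                                      n_lesions = n_lesions)
  for (i in seq_along(sp$lesion_specs)) sp$lesion_specs[[i]]$uptake <- uptake
  if (clear_of_organs) {
    extent <- sp$extent
    set.seed(seed)
    for (i in seq_along(sp$lesion_specs)) {
      r <- stats::runif(1, 6, 16)
      sp$lesion_specs[[i]]$radii <- rep(r, 3)
      sp$lesion_specs[[i]]$center <-
        c(stats::runif(1, 0.3, 0.7) * extent[1],
          stats::runif(1, 0.32, 0.68) * extent[2],
          stats::runif(1, 0.27, 0.51) * extent[3])
    }
  }
  suppressMessages(generate_phantom(sp))
}

small_cohort <- function(n, seed) {
  suppressMessages(generate_cohort(n, seed = seed))
}

random_lesion_mask <- function(dims, density, seed, spacing = c(2, 3, 4)) {
  set.seed(seed)
  lesion_mask(array(as.integer(stats::runif(prod(dims)) < density), dims),
              spacing)
}
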