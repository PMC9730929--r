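# Compact U-Net-style encoder-decoder for 2D MIP lesion segmentation,
# implemented in plain vectorized R (no deep-learning backend is available
# in this stack). Three resolution levels, 3x3 convolutions via im2col,
# nearest-neighbour upsampling with skip concatenation, sigmoid output,
# Dice + binary cross-entropy loss, Adam. Designed for small fixed grids
# (default 48 x 96), where R's BLAS matmuls carry the cost.
#
# Convolution layout: kernels are stored as (9 * Cin) x Cout matrices whose
# row order matches the im2col column order (offset-major within channel).
# The gradient w.r.t. the input of a zero-padded same 3x3 convolution is the
# same convolution with offset-flipped, channel-transposed kernels.

make_im2col_idx <- function(H, W) {
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  offs <- as.matrix(expand.grid(di = -1L:1L, dj = -1L:1L))
  idx <- matrix(0L, H * W, 9L)
  for (o in 1:9) {
    idx[, o] <- (i + offs[o, 1] + 1L) + (j + offs[o, 2]) * (H + 2L)
  }
  idx
}

im2col <- function(x, idx) {
  dm <- dim(x)
  H <- dm[1]; W <- dm[2]; C <- if (length(dm) == 3L) dm[3] else 1L
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  M <- matrix(0, H * W, 9L * C)
  for (cc in seq_len(C)) {
    xpc <- xp[, , cc]
    M[, ((cc - 1L) * 9L + 1L):(cc * 9L)] <- xpc[idx]
  }
  M
}

conv_forward <- function(x, K, b, idx) {
  dm <- dim(x)
  M <- im2col(x, idx)
  Y <- M %*% K
  Y <- sweep(Y, 2, b, `+`)
  list(y = array(Y, c(dm[1], dm[2], ncol(K))), M = M)
}

# flip offsets and transpose channels: (9*Cin x Cout) -> (9*Cout x Cin)
flip_kernel <- function(K, cin, cout) {
  Ka <- array(K, c(9L, cin, cout))
  Kt <- array(0, c(9L, cout, cin))
  for (o in 1:9) Kt[o, , ] <- t(Ka[10L - o, , ])
  matrix(Kt, 9L * cout, cin)
}

conv_backward <- function(dy, M, K, cin, idx) {
  dm <- dim(dy)
  dY <- matrix(dy, dm[1] * dm[2], dm[3])
  dK <- crossprod(M, dY)
  db <- colSums(dY)
  Kt <- flip_kernel(K, cin, dm[3])
  Md <- im2col(dy, idx)
  dx <- array(Md %*% Kt, c(dm[1], dm[2], cin))
  list(dx = dx, dK = dK, db = db)
}

pool2_forward <- function(x) {
  dm <- dim(x)
  ro <- seq(1L, dm[1], 2L); re <- ro + 1L
  co <- seq(1L, dm[2], 2L); ce <- co + 1L
  parts <- list(x[ro, co, , drop = FALSE], x[re, co, , drop = FALSE],
                x[ro, ce, , drop = FALSE], x[re, ce, , drop = FALSE])
  y <- pmax(parts[[1]], parts[[2]], parts[[3]], parts[[4]])
  taken <- array(FALSE, dim(y))
  masks <- vector("list", 4L)
  for (k in 1:4) {
    mk <- (parts[[k]] == y) & !taken   # first max wins
    taken <- taken | mk
    masks[[k]] <- mk
  }
  list(y = y, masks = masks)
}

pool2_backward <- function(dy, masks, dims_in) {
  dx <- array(0, dims_in)
  ro <- seq(1L, dims_in[1], 2L); re <- ro + 1L
  co <- seq(1L, dims_in[2], 2L); ce <- co + 1L
  dx[ro, co, ] <- dy * masks[[1]]
  dx[re, co, ] <- dy * masks[[2]]
  dx[ro, ce, ] <- dy * masks[[3]]
  dx[re, ce, ] <- dy * masks[[4]]
  dx
}

upsample2 <- function(x) {
  dm <- dim(x)
  y <- array(0, c(2L * dm[1], 2L * dm[2], dm[3]))
  ro <- seq(1L, 2L * dm[1], 2L); re <- ro + 1L
  co <- seq(1L, 2L * dm[2], 2L); ce <- co + 1L
  y[ro, co, ] <- x; y[re, co, ] <- x; y[ro, ce, ] <- x; y[re, ce, ] <- x
  y
}

upsample2_backward <- function(dy) {
  dm <- dim(dy)
  ro <- seq(1L, dm[1], 2L); re <- ro + 1L
  co <- seq(1L, dm[2], 2L); ce <- co + 1L
  dy[ro, co, , drop = FALSE] + dy[re, co, , drop = FALSE] +
    dy[ro, ce, , drop = FALSE] + dy[re, ce, , drop = FALSE]
}

relu <- function(x) pmax(x, 0)

cnn_init_params <- function(config) {
  ch <- config$channels            # e.g. c(8, 16, 32)
  cin <- config$in_channels        # 3: intensity + 2 coordinate channels
  he <- function(fan_in, nrow, ncol) {
    matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
  }
  set.seed(config$seed)
  list(
    K1 = he(9 * cin, 9 * cin, ch[1]),            b1 = numeric(ch[1]),
    K2 = he(9 * ch[1], 9 * ch[1], ch[2]),        b2 = numeric(ch[2]),
    K3 = he(9 * ch[2], 9 * ch[2], ch[3]),        b3 = numeric(ch[3]),
    K4 = he(9 * (ch[3] + ch[2]), 9 * (ch[3] + ch[2]), ch[2]), b4 = numeric(ch[2]),
    K5 = he(9 * (ch[2] + ch[1]), 9 * (ch[2] + ch[1]), ch[1]), b5 = numeric(ch[1]),
    K6 = he(ch[1], ch[1], 1L),                   b6 = 0
  )
}

# forward pass; returns sigmoid probabilities and (optionally) the cache
cnn_forward <- function(x, params, caches, keep = TRUE) {
  ch <- caches$channels
  c1 <- conv_forward(x, params$K1, params$b1, caches$idx1); a1 <- relu(c1$y)
  p1 <- pool2_forward(a1)
  c2 <- conv_forward(p1$y, params$K2, params$b2, caches$idx2); a2 <- relu(c2$y)
  p2 <- pool2_forward(a2)
  c3 <- conv_forward(p2$y, params$K3, params$b3, caches$idx3); a3 <- relu(c3$y)
  u3 <- upsample2(a3)
  cat4 <- array(c(u3, a2), c(dim(u3)[1], dim(u3)[2], ch[3] + ch[2]))
  c4 <- conv_forward(cat4, params$K4, params$b4, caches$idx2); a4 <- relu(c4$y)
  u4 <- upsample2(a4)
  cat5 <- array(c(u4, a1), c(dim(u4)[1], dim(u4)[2], ch[2] + ch[1]))
  c5 <- conv_forward(cat5, params$K5, params$b5, caches$idx1); a5 <- relu(c5$y)
  A5 <- matrix(a5, ncol = ch[1])
  z <- A5 %*% params$K6 + params$b6
  p <- 1 / (1 + exp(-z))
  out <- list(p = matrix(p, dim(x)[1], dim(x)[2]))
  if (keep) {
    out$cache <- list(x = x, c1 = c1, a1 = a1, p1 = p1, c2 = c2, a2 = a2,
                      p2 = p2, c3 = c3, a3 = a3, cat4 = cat4, c4 = c4,
                      a4 = a4, cat5 = cat5, c5 = c5, a5 = a5, A5 = A5, z = z)
  }
  out
}

# gradient of (BCE + soft Dice) w.r.t. the logits, averaged per pixel
seg_loss_grad <- function(p, t, eps = 1) {
  n <- length(p)
  pv <- as.vector(p); tv <- as.vector(t)
  bce <- -mean(tv * log(pmax(pv, 1e-12)) + (1 - tv) * log(pmax(1 - pv, 1e-12)))
  inter <- sum(pv * tv); sp <- sum(pv); st <- sum(tv)
  dice <- (2 * inter + eps) / (sp + st + eps)
  # d(1-dice)/dp then chain through sigmoid; dBCE/dz = (p-t)/n
  ddice_dp <- (2 * tv * (sp + st + eps) - (2 * inter + eps)) / (sp + st + eps)^2
  dz <- (pv - tv) / n + (-ddice_dp) * pv * (1 - pv)
  list(loss = bce + (1 - dice), dz = dz)
}

cnn_backward <- function(dz, params, caches, cache) {
  ch <- caches$channels
  dA5 <- matrix(dz, ncol = 1) %*% t(params$K6)
  gK6 <- crossprod(cache$A5, matrix(dz, ncol = 1))
  gb6 <- sum(dz)
  da5 <- array(dA5, dim(cache$a5)) * (cache$c5$y > 0)
  g5 <- conv_backward(da5, cache$c5$M, params$K5, ch[2] + ch[1], caches$idx1)
  du4 <- g5$dx[, , seq_len(ch[2]), drop = FALSE]
  da1_skip <- g5$dx[, , ch[2] + seq_len(ch[1]), drop = FALSE]
  da4 <- upsample2_backward(du4) * (cache$c4$y > 0)
  g4 <- conv_backward(da4, cache$c4$M, params$K4, ch[3] + ch[2], caches$idx2)
  du3 <- g4$dx[, , seq_len(ch[3]), drop = FALSE]
  da2_skip <- g4$dx[, , ch[3] + seq_len(ch[2]), drop = FALSE]
  da3 <- upsample2_backward(du3) * (cache$c3$y > 0)
  g3 <- conv_backward(da3, cache$c3$M, params$K3, ch[2], caches$idx3)
  dp2 <- pool2_backward(g3$dx, cache$p2$masks, dim(cache$a2))
  da2 <- (dp2 + da2_skip) * (cache$c2$y > 0)
  g2 <- conv_backward(da2, cache$c2$M, params$K2, ch[1], caches$idx2)
  dp1 <- pool2_backward(g2$dx, cache$p1$masks, dim(cache$a1))
  da1 <- (dp1 + da1_skip) * (cache$c1$y > 0)
  g1 <- conv_backward(da1, cache$c1$M, params$K1, caches$in_channels, caches$idx1)
  list(K1 = g1$dK, b1 = g1$db, K2 = g2$dK, b2 = g2$db, K3 = g3$dK, b3 = g3$db,
       K4 = g4$dK, b4 = g4$db, K5 = g5$dK, b5 = g5$db, K6 = gK6, b6 = gb6)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

cnn_caches <- function(config) {
  g <- config$grid
  list(idx1 = make_im2col_idx(g[1], g[2]),
       idx2 = make_im2col_idx(g[1] %/% 2L, g[2] %/% 2L),
       idx3 = make_im2col_idx(g[1] %/% 4L, g[2] %/% 4L),
       channels = config$channels,
       in_channels = config$in_channels)
}

# --- geometric transforms between native MIP grids and the model grid ------

bilinear_resize <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  src_r <- pmin(pmax((seq_len(H2) - 0.5) * H / H2 + 0.5, 1), H)
  src_c <- pmin(pmax((seq_len(W2) - 0.5) * W / W2 + 0.5, 1), W)
  r0 <- pmin(floor(src_r), H - 1L); fr <- src_r - r0
  c0 <- pmin(floor(src_c), W - 1L); fc <- src_c - c0
  a <- m[r0, c0, drop = FALSE]; b <- m[r0 + 1L, c0, drop = FALSE]
  cc <- m[r0, c0 + 1L, drop = FALSE]; d <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  top <- a * (1 - fr) + b * fr
  bot <- cc * (1 - fr) + d * fr
  sweep(top, 2, 1 - fc, `*`) + sweep(bot, 2, fc, `*`)
}

nearest_resize <- function(m, H2, W2) {
  ri <- pmin(pmax(round((seq_len(H2) - 0.5) * nrow(m) / H2 + 0.5), 1L), nrow(m))
  ci <- pmin(pmax(round((seq_len(W2) - 0.5) * ncol(m) / W2 + 0.5), 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# aspect-preserving fit of a native-grid image into the model grid
to_model_grid <- function(m, grid, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  s <- min(grid[1] / H, grid[2] / W)
  H2 <- max(2L, round(H * s)); W2 <- max(2L, round(W * s))
  rs <- if (method == "bilinear") bilinear_resize(m, H2, W2) else nearest_resize(m, H2, W2)
  out <- matrix(0, grid[1], grid[2])
  off_r <- (grid[1] - H2) %/% 2L
  off_c <- (grid[2] - W2) %/% 2L
  out[off_r + seq_len(H2), off_c + seq_len(W2)] <- rs
  list(m = out, meta = list(H = H, W = W, H2 = H2, W2 = W2,
                            off_r = off_r, off_c = off_c))
}

from_model_grid <- function(m, meta) {
  inner <- m[meta$off_r + seq_len(meta$H2), meta$off_c + seq_len(meta$W2),
             drop = FALSE]
  bilinear_resize(inner, meta$H, meta$W)
}

# normalization: clip at the 99.9th intensity percentile, scale to [0, 1]
normalize_mip <- function(m, clip_pct = 0.999) {
  hi <- stats::quantile(m, clip_pct, names = FALSE)
  if (hi <= 0) return(m * 0)
  pmin(m, hi) / hi
}

# model input tensor: normalized intensity plus 2 coordinate channels
cnn_input <- function(m_grid, grid) {
  xc <- matrix(rep(seq_len(grid[1]) / grid[1], grid[2]), grid[1], grid[2])
  yc <- matrix(rep(seq_len(grid[2]) / grid[2], each = grid[1]), grid[1], grid[2])
  array(c(m_grid, xc, yc), c(grid[1], grid[2], 3L))
}
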