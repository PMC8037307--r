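# Analytic gradients of the loss terms.  These are internal: the public API
# exposes values only, the trainer consumes the gradients, and the test suite
# verifies every one of them against central finite differences.

mse_grad <- function(a, b) {
  g <- 2 * (a - b) / length(a)
  list(value = mean((a - b)^2), g1 = g, g2 = -g)
}

# Gradients of the windowed correlation metrics.  For a window centred at c,
# writing mu, v, cross for the local moments, the derivative of the local
# (squared) correlation w.r.t. a voxel p inside the window is an affine
# function of a(p) and b(p) with center-dependent coefficients; summing over
# all windows containing p is a box filter of those coefficient fields
# (the truncated cubic window is symmetric, so the filter is self-adjoint).
local_cc_grad <- function(a, b, window, squared) {
  m <- local_moments(a, b, window)
  n <- m$n; r <- m$r
  mu1 <- m$s1 / n; mu2 <- m$s2 / n
  v1 <- pmax(m$v1, .Machine$double.xmin)
  v2 <- pmax(m$v2, .Machine$double.xmin)
  cross <- m$cross
  if (squared) {
    value <- mean(ifelse(m$ok, cross^2 / (v1 * v2), 0))
    a1 <- ifelse(m$ok, 2 * cross / (v1 * v2), 0)       # coeff of (b - mu2)
    b1 <- ifelse(m$ok, -2 * cross^2 / (v1^2 * v2), 0)  # coeff of (a - mu1)
    a2 <- a1                                           # symmetric in cross
    b2 <- ifelse(m$ok, -2 * cross^2 / (v2^2 * v1), 0)
  } else {
    s12 <- sqrt(v1 * v2)
    value <- mean(ifelse(m$ok, cross / s12, 0))
    a1 <- ifelse(m$ok, 1 / s12, 0)
    b1 <- ifelse(m$ok, -cross / (v1 * s12), 0)
    a2 <- a1
    b2 <- ifelse(m$ok, -cross / (v2 * s12), 0)
  }
  N <- length(a)
  g1 <- (b * boxsum3(a1, r) + a * boxsum3(b1, r) -
           boxsum3(a1 * mu2 + b1 * mu1, r)) / N
  g2 <- (a * boxsum3(a2, r) + b * boxsum3(b2, r) -
           boxsum3(a2 * mu1 + b2 * mu2, r)) / N
  list(value = value, g1 = g1, g2 = g2)
}

# Value and gradients of the configured dissimilarity (MSE or 1 - correlation).
sim_loss_grad <- function(a, b, weights) {
  switch(weights$sim_metric,
         MSE = mse_grad(a, b),
         LCC = {
           g <- local_cc_grad(a, b, weights$lncc_window, squared = FALSE)
           list(value = 1 - g$value, g1 = -g$g1, g2 = -g$g2)
         },
         LNCC = {
           g <- local_cc_grad(a, b, weights$lncc_window, squared = TRUE)
           list(value = 1 - g$value, g1 = -g$g1, g2 = -g$g2)
         })
}

# Gradient of the diffusion regularizer: adjoint of the forward difference
# (zeroed at the trailing face) applied to each axis of each component.
smooth_grad <- function(u) {
  d <- dim(u)[1:3]
  N <- prod(d)
  g <- array(0, dim(u))
  value <- 0
  for (comp in 1:3) {
    uc <- u[, , , comp]
    gc <- array(0, d)
    dx <- uc[c(2:d[1], d[1]), , ] - uc; dx[d[1], , ] <- 0
    dy <- uc[, c(2:d[2], d[2]), ] - uc; dy[, d[2], ] <- 0
    dz <- uc[, , c(2:d[3], d[3])] - uc; dz[, , d[3]] <- 0
    value <- value + sum(dx^2) + sum(dy^2) + sum(dz^2)
    sx <- array(0, d); sx[2:d[1], , ] <- dx[1:(d[1] - 1), , ]
    sy <- array(0, d); sy[, 2:d[2], ] <- dy[, 1:(d[2] - 1), ]
    sz <- array(0, d); sz[, , 2:d[3]] <- dz[, , 1:(d[3] - 1)]
    gc <- (sx - dx) + (sy - dy) + (sz - dz)
    g[, , , comp] <- 2 * gc / N
  }
  list(value = value / N, g = g)
}

# Parzen-mode NMI with an explicit (frozen) intensity range for the first
# argument, plus the gradient w.r.t. that argument.  The range is treated as
# a constant of differentiation; the trainer refreshes it every iteration.
nmi_parzen_grad <- function(e, a, bins, lo = NULL, hi = NULL) {
  ev <- as.vector(e); av <- as.vector(a)
  if (is.null(lo)) lo <- min(ev)
  if (is.null(hi)) hi <- max(ev)
  ra <- range(av)
  if (lo == hi || ra[1] == ra[2])
    stop("degenerate input: constant image has no intensity range", call. = FALSE)
  N <- length(ev)
  se <- soft_bins(ev, bins, lo, hi)
  sa <- soft_bins(av, bins, ra[1], ra[2])
  joint <- (accumulate_joint(se$il + bins * (sa$il - 1), se$wlo * sa$wlo, bins) +
    accumulate_joint(se$ih + bins * (sa$il - 1), se$whi * sa$wlo, bins) +
    accumulate_joint(se$il + bins * (sa$ih - 1), se$wlo * sa$whi, bins) +
    accumulate_joint(se$ih + bins * (sa$ih - 1), se$whi * sa$whi, bins)) / N
  pe <- rowSums(joint); pa <- colSums(joint)
  He <- entropy(pe); Ha <- entropy(pa); Hab <- entropy(joint)
  value <- (He + Ha) / Hab
  # dNMI/dp[i,j]; empty cells get a floored log so untouched cells stay finite
  lp <- log(pmax(joint, 1e-300))
  lpe <- log(pmax(pe, 1e-300))
  dHe <- -(lpe + 1)            # per row i
  dHab <- -(lp + 1)            # per cell
  D <- (matrix(dHe, bins, bins) * Hab - (He + Ha) * dHab) / Hab^2
  live <- se$ih != se$il       # clamped values have zero derivative
  gv <- numeric(N)
  idx_l_l <- cbind(se$il, sa$il); idx_h_l <- cbind(se$ih, sa$il)
  idx_l_h <- cbind(se$il, sa$ih); idx_h_h <- cbind(se$ih, sa$ih)
  gv <- (sa$wlo * (D[idx_h_l] - D[idx_l_l]) +
           sa$whi * (D[idx_h_h] - D[idx_l_h])) / (se$width * N)
  gv[!live] <- 0
  g <- array(gv, dim(e))
  list(value = value, g = g)
}

# Value + gradient of the anatomical regularizer (Parzen mode) w.r.t. both
# corrected images.
anat_loss_grad <- function(e1, e2, a, bins) {
  n1 <- nmi_parzen_grad(e1, a, bins)
  n2 <- nmi_parzen_grad(e2, a, bins)
  list(value = 1 - (n1$value + n2$value) / 2,
       g1 = -0.5 * n1$g, g2 = -0.5 * n2$g)
}

# Full per-pair objective: corrected images, loss breakdown, and the gradient
# of the total loss w.r.t. the displacement field.
pair_loss_grad <- function(i1, i2, u, weights, anatomy = NULL) {
  e1 <- warp3(i1, u, +1)
  e2 <- warp3(i2, u, -1)
  s <- sim_loss_grad(e1, e2, weights)
  sm <- smooth_grad(u)
  ge1 <- s$g1; ge2 <- s$g2
  an_val <- NA_real_
  if (!is.null(anatomy) && weights$gamma_anat > 0) {
    an <- anat_loss_grad(e1, e2, anatomy, weights$nmi_bins)
    an_val <- an$value
    ge1 <- ge1 + weights$gamma_anat * an$g1
    ge2 <- ge2 + weights$gamma_anat * an$g2
  }
  gu <- warp3_grad_field(i1, u, +1, ge1) +
    warp3_grad_field(i2, u, -1, ge2) +
    weights$lambda_smooth * sm$g
  total <- s$value + weights$lambda_smooth * sm$value +
    if (is.na(an_val)) 0 else weights$gamma_anat * an_val
  list(total = total, sim = s$value, smooth = sm$value, anat = an_val,
       gu = gu, e1 = e1, e2 = e2)
}
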