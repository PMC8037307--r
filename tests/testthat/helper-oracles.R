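# Independent brute-force oracles and small fixture builders shared across
# the suite.  Every oracle is a direct transcription of the defining formula
# (triple loops, no shared code with the implementation).

seeded_array <- function(dims, seed, mean = 0, sd = 1) {
  set.seed(seed)
  array(rnorm(prod(dims), mean, sd), dims)
}

seeded_field <- function(extents, seed, max_abs = 1.5) {
  set.seed(seed)
  array(runif(prod(extents) * 3, -max_abs, max_abs), c(extents, 3))
}

# Per-voxel trilinear interpolation at grid + sign*u with border clamping.
trilinear_oracle <- function(img, u, sign) {
  d <- dim(img)
  out <- array(0, d)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    cx <- min(max((i - 1) + sign * u[i, j, k, 1], 0), d[1] - 1)
    cy <- min(max((j - 1) + sign * u[i, j, k, 2], 0), d[2] - 1)
    cz <- min(max((k - 1) + sign * u[i, j, k, 3], 0), d[3] - 1)
    x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
    x1 <- min(x0 + 1, d[1] - 1); y1 <- min(y0 + 1, d[2] - 1)
    z1 <- min(z0 + 1, d[3] - 1)
    fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      xi <- if (a == 0) x0 else x1
      yi <- if (b == 0) y0 else y1
      zi <- if (cc == 0) z0 else z1
      wt <- (if (a == 0) 1 - fx else fx) * (if (b == 0) 1 - fy else fy) *
        (if (cc == 0) 1 - fz else fz)
      acc <- acc + wt * img[xi + 1, yi + 1, zi + 1]
    }
    out[i, j, k] <- acc
  }
  out
}

# Mean local (squared) Pearson correlation over truncated cubic windows with
# the same degeneracy guard as the implementation contract.
windowed_cc_oracle <- function(a, b, window, squared) {
  r <- (window - 1) / 2
  d <- dim(a)
  ga <- var(as.vector(a)); gb <- var(as.vector(b))
  tot <- 0
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    xs <- max(1, i - r):min(d[1], i + r)
    ys <- max(1, j - r):min(d[2], j + r)
    zs <- max(1, k - r):min(d[3], k + r)
    av <- as.vector(a[xs, ys, zs]); bv <- as.vector(b[xs, ys, zs])
    v1 <- mean(av^2) - mean(av)^2
    v2 <- mean(bv^2) - mean(bv)^2
    if (v1 > 1e-5 * ga && v2 > 1e-5 * gb) {
      cc <- (mean(av * bv) - mean(av) * mean(bv)) / sqrt(v1 * v2)
      tot <- tot + (if (squared) cc^2 else cc)
    }
  }
  tot / prod(d)
}

# Diffusion regularizer by explicit loops over voxels, axes, components.
smooth_oracle <- function(u) {
  d <- dim(u)[1:3]
  tot <- 0
  for (comp in 1:3) for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    if (i < d[1]) tot <- tot + (u[i + 1, j, k, comp] - u[i, j, k, comp])^2
    if (j < d[2]) tot <- tot + (u[i, j + 1, k, comp] - u[i, j, k, comp])^2
    if (k < d[3]) tot <- tot + (u[i, j, k + 1, comp] - u[i, j, k, comp])^2
  }
  tot / prod(d)
}

# Hard-binned NMI straight from the definition.
nmi_oracle <- function(a, b, bins) {
  av <- as.vector(a); bv <- as.vector(b)
  bin <- function(x) {
    r <- range(x)
    pmin(pmax(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1, 1), bins)
  }
  ia <- bin(av); ib <- bin(bv)
  joint <- table(factor(ia, 1:bins), factor(ib, 1:bins)) / length(av)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (H(rowSums(joint)) + H(colSums(joint))) / H(joint)
}

# Central finite difference against an analytic gradient at sampled entries;
# returns the max relative deviation (scaled by the largest FD magnitude).
fd_rel_err <- function(f, x, g, n = 30, eps = 1e-5, seed = 1) {
  set.seed(seed)
  idx <- sample(length(x), min(n, length(x)))
  fd <- vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
  max(abs(fd - g[idx])) / max(max(abs(fd)), 1e-12)
}

# Small reversed-PE dataset used by several training tests.
tiny_dataset <- function(n, seed, extents = c(16, 16, 16), amplitude_pe = 2,
                         amplitude_offpe = 0.5, levels = c(60, 100, 140, 180)) {
  make_dataset(n,
               phantom_spec(extents = extents, noise_sigma = 1.5,
                            intensity_levels = levels),
               field_spec(pe_axis = "y", amplitude_pe = amplitude_pe,
                          amplitude_offpe = amplitude_offpe,
                          smoothness_sigma = 4),
               seed = seed)
}

# Read any NIfTI written by the CLI as a plain numeric array (for checksum
# comparisons between runs).
read_volume_or_field <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.vector(img), dim(img))
}
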