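# Loss terms: similarity metrics (MSE, LCC, LNCC), the diffusion smoothness
# regularizer on the displacement field, the NMI-based anatomical regularizer,
# and their weighted combination.

#' Loss weights and metric configuration
#'
#' @param lambda_smooth non-negative weight of the diffusion (smoothness)
#'   regularizer.
#' @param gamma_anat non-negative weight of the anatomical (NMI) regularizer.
#' @param sim_metric similarity metric: `"LNCC"`, `"LCC"` or `"MSE"`.
#' @param lncc_window odd window edge length in voxels (>= 3) for the local
#'   correlation metrics.
#' @param nmi_bins number of intensity bins (>= 8) for NMI.
#' @return object of class `sac_weights`.
#' @export
loss_weights <- function(lambda_smooth = 0.025, gamma_anat = 0.01,
                         sim_metric = c("LNCC", "LCC", "MSE"),
                         lncc_window = 9L, nmi_bins = 32L) {
  sim_metric <- match.arg(sim_metric)
  lncc_window <- as.integer(lncc_window)
  nmi_bins <- as.integer(nmi_bins)
  if (lambda_smooth < 0 || gamma_anat < 0)
    stop("regularization weights must be non-negative", call. = FALSE)
  if (lncc_window < 3L || lncc_window %% 2L == 0L)
    stop("lncc_window must be odd and >= 3", call. = FALSE)
  if (nmi_bins < 8L) stop("nmi_bins must be >= 8", call. = FALSE)
  structure(list(lambda_smooth = lambda_smooth, gamma_anat = gamma_anat,
                 sim_metric = sim_metric, lncc_window = lncc_window,
                 nmi_bins = nmi_bins),
            class = "sac_weights")
}

#' Per-dataset training weights
#'
#' Named presets for the four evaluation protocols the method ships with
#' (fMRI at 3T/7T, DWI at 3T/7T): the smoothness weight, anatomy weight and
#' batch size used when training on each.
#'
#' @param dataset one of `"fmri3t"`, `"dwi3t"`, `"fmri7t"`, `"dwi7t"`.
#' @return list with `weights` (a [loss_weights()] object) and `batch_size`.
#' @export
preset_weights <- function(dataset = c("fmri3t", "dwi3t", "fmri7t", "dwi7t")) {
  dataset <- match.arg(dataset)
  lam <- c(fmri3t = 0.1771, dwi3t = 0.002, fmri7t = 0.9323, dwi7t = 0.025)
  bs <- c(fmri3t = 4L, dwi3t = 1L, fmri7t = 1L, dwi7t = 1L)
  list(weights = loss_weights(lambda_smooth = lam[[dataset]], gamma_anat = 0.01),
       batch_size = bs[[dataset]])
}

check_same_extents <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("volumes must have identical extents", call. = FALSE)
}

#' Mean squared error between two volumes
#' @param e1,e2 volumes of identical extents.
#' @return non-negative scalar.
#' @export
mse <- function(e1, e2) {
  a <- as_vol_array(e1); b <- as_vol_array(e2)
  check_same_extents(a, b)
  mean((a - b)^2)
}

# Local first/second moments over truncated cubic windows; shared by LNCC and
# LCC values and their gradients.  Windows whose variance falls below
# 1e-5 * global variance of that image are flagged degenerate.
local_moments <- function(a, b, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 3L)
    stop("window must be odd and >= 3", call. = FALSE)
  if (window > min(dim(a)))
    stop("window exceeds the smallest volume extent", call. = FALSE)
  r <- (window - 1L) %/% 2L
  d <- dim(a)
  cnt_axis <- function(n) pmin(seq_len(n) - 1L, r) + pmin(n - seq_len(n), r) + 1
  n <- outer(outer(cnt_axis(d[1]), cnt_axis(d[2])), cnt_axis(d[3]))
  dim(n) <- d
  s1 <- boxsum3(a, r); s2 <- boxsum3(b, r)
  s11 <- boxsum3(a * a, r); s22 <- boxsum3(b * b, r); s12 <- boxsum3(a * b, r)
  cross <- s12 - s1 * s2 / n
  v1 <- s11 - s1 * s1 / n
  v2 <- s22 - s2 * s2 / n
  ok <- (v1 / n > 1e-5 * var(as.vector(a))) & (v2 / n > 1e-5 * var(as.vector(b)))
  list(n = n, r = r, s1 = s1, s2 = s2, cross = cross, v1 = v1, v2 = v2, ok = ok)
}

#' Local normalized cross-correlation
#'
#' Mean over voxels of the squared Pearson correlation of the two images over
#' the cubic window centred at each voxel (truncated at the border).  Windows
#' where either local variance is degenerate contribute 0.  Squaring makes
#' the metric invariant to any affine intensity map of either argument and
#' bounds it in \[0, 1\].
#'
#' @param e1,e2 volumes of identical extents.
#' @param window odd window edge length (voxels).
#' @return scalar in \[0, 1\].
#' @export
lncc <- function(e1, e2, window = 9L) {
  a <- as_vol_array(e1); b <- as_vol_array(e2)
  check_same_extents(a, b)
  m <- local_moments(a, b, window)
  cc <- ifelse(m$ok, m$cross^2 / pmax(m$v1 * m$v2, .Machine$double.xmin), 0)
  mean(cc)
}

#' Local (unsquared) cross-correlation
#'
#' Mean local Pearson correlation over cubic windows; sign-sensitive,
#' range \[-1, 1\].  Same border truncation and degeneracy guard as [lncc()].
#'
#' @inheritParams lncc
#' @return scalar in \[-1, 1\].
#' @export
lcc <- function(e1, e2, window = 9L) {
  a <- as_vol_array(e1); b <- as_vol_array(e2)
  check_same_extents(a, b)
  m <- local_moments(a, b, window)
  cc <- ifelse(m$ok, m$cross / pmax(sqrt(m$v1 * m$v2), .Machine$double.xmin), 0)
  mean(cc)
}

#' Similarity (dissimilarity) loss between two corrected volumes
#'
#' Returns the configured dissimilarity: MSE as-is, or `1 - LCC` /
#' `1 - LNCC` so that lower is better and a perfect match scores 0.
#'
#' @param e1,e2 volumes of identical extents.
#' @param weights a [loss_weights()] object.
#' @return scalar dissimilarity.
#' @export
sim_loss <- function(e1, e2, weights = loss_weights()) {
  switch(weights$sim_metric,
         MSE = mse(e1, e2),
         LCC = 1 - lcc(e1, e2, weights$lncc_window),
         LNCC = 1 - lncc(e1, e2, weights$lncc_window),
         stop("unknown similarity metric", call. = FALSE))
}

#' Diffusion regularizer of a displacement field
#'
#' `(1/N) * sum over voxels and components of |forward-difference gradient|^2`,
#' with the difference defined as 0 at the trailing face of each axis.
#' Penalizes non-smooth fields; translation-invariant.
#'
#' @param field `sac_field` or `(X, Y, Z, 3)` array.
#' @return non-negative scalar.
#' @export
smooth_loss <- function(field) {
  u <- as_field_array(field)
  d <- dim(u)[1:3]
  total <- 0
  for (comp in 1:3) {
    uc <- u[, , , comp]
    dx <- uc[c(2:d[1], d[1]), , ] - uc; dx[d[1], , ] <- 0
    dy <- uc[, c(2:d[2], d[2]), ] - uc; dy[, d[2], ] <- 0
    dz <- uc[, , c(2:d[3], d[3])] - uc; dz[, , d[3]] <- 0
    total <- total + sum(dx^2) + sum(dy^2) + sum(dz^2)
  }
  total / prod(d)
}

# Soft (linear-interpolation) bin assignment: each value contributes to the
# two nearest of `bins` equal-width bins spanning [lo, hi] with triangular
# weights.  Returns indices, weights, and the derivative bookkeeping needed
# for the Parzen-mode NMI gradient.
soft_bins <- function(x, bins, lo, hi) {
  w <- (hi - lo) / bins
  p <- (x - lo) / w + 0.5
  blo <- floor(p)
  frac <- p - blo
  il <- pmin(pmax(blo, 1), bins)
  ih <- pmin(pmax(blo + 1, 1), bins)
  list(il = il, ih = ih, wlo = 1 - frac, whi = frac, width = w)
}

hard_bins <- function(x, bins, lo, hi) {
  b <- floor((x - lo) / (hi - lo) * bins) + 1
  pmin(pmax(b, 1), bins)
}

accumulate_joint <- function(idx, w, bins) {
  s <- rowsum(w, idx)
  joint <- numeric(bins * bins)
  joint[as.integer(rownames(s))] <- s
  matrix(joint, bins, bins)
}

entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

joint_hist <- function(a, b, bins, mode) {
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2])
    stop("degenerate input: constant image has no intensity range", call. = FALSE)
  if (mode == "hard") {
    ia <- hard_bins(a, bins, ra[1], ra[2])
    ib <- hard_bins(b, bins, rb[1], rb[2])
    joint <- accumulate_joint(ia + bins * (ib - 1), rep(1, length(ia)), bins)
  } else {
    sa <- soft_bins(a, bins, ra[1], ra[2])
    sb <- soft_bins(b, bins, rb[1], rb[2])
    joint <- accumulate_joint(sa$il + bins * (sb$il - 1), sa$wlo * sb$wlo, bins) +
      accumulate_joint(sa$ih + bins * (sb$il - 1), sa$whi * sb$wlo, bins) +
      accumulate_joint(sa$il + bins * (sb$ih - 1), sa$wlo * sb$whi, bins) +
      accumulate_joint(sa$ih + bins * (sb$ih - 1), sa$whi * sb$whi, bins)
  }
  joint / length(a)
}

#' Normalized mutual information of two volumes
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` with Shannon entropies of the joint
#' intensity histogram over `bins` equal-width bins spanning each image's own
#' range; values lie in \[1, 2\] (the Studholme convention).  `hard` mode uses
#' discrete binning (evaluation); `parzen` mode uses differentiable soft
#' binning with a triangular kernel of one-bin width (training) and converges
#' to `hard` as the histogram is refined.
#'
#' @param a,b volumes of identical extents, neither constant.
#' @param bins number of histogram bins.
#' @param mode `"hard"` or `"parzen"`.
#' @return scalar in \[1, 2\].
#' @export
nmi <- function(a, b, bins = 32L, mode = c("hard", "parzen")) {
  mode <- match.arg(mode)
  av <- as_vol_array(a); bv <- as_vol_array(b)
  check_same_extents(av, bv)
  joint <- joint_hist(as.vector(av), as.vector(bv), as.integer(bins), mode)
  (entropy(rowSums(joint)) + entropy(colSums(joint))) / entropy(joint)
}

#' Anatomical regularizer against a structural volume
#'
#' `1 - (NMI(E1, A) + NMI(E2, A)) / 2`: drives both corrected images toward
#' the anatomy depicted by the T1-weighted volume `a`.  With NMI in \[1, 2\]
#' the value lies in \[-1, 0\]; only its ordering matters to the optimizer.
#'
#' @param e1,e2 corrected volumes.
#' @param a anatomical (T1w) volume, same extents, non-constant.
#' @param bins histogram bins for NMI.
#' @param mode NMI mode, `"hard"` (default) or `"parzen"`.
#' @return scalar in \[-1, 0\].
#' @export
anat_loss <- function(e1, e2, a, bins = 32L, mode = c("hard", "parzen")) {
  mode <- match.arg(mode)
  1 - (nmi(e1, a, bins, mode) + nmi(e2, a, bins, mode)) / 2
}

#' Total training loss for a reversed-PE pair
#'
#' Computes the corrected pair from `field`, then
#' `L = Lsim(E1, E2) + lambda * Lsmooth(U) + gamma * Lanat(E1, E2, A)`.
#' When `anatomy` is absent the gamma term is skipped entirely.
#'
#' @param i1,i2 distorted input volumes.
#' @param field displacement field.
#' @param weights a [loss_weights()] object.
#' @param anatomy optional anatomical volume.
#' @return list of class `sac_loss` with `total`, `sim`, `smooth`, `anat`
#'   (NA when `anatomy` is absent).
#' @export
total_loss <- function(i1, i2, field, weights = loss_weights(), anatomy = NULL) {
  e <- correct_pair(i1, i2, field)
  s <- sim_loss(e$e1, e$e2, weights)
  sm <- smooth_loss(field)
  an <- if (is.null(anatomy)) NA_real_
        else anat_loss(e$e1, e$e2, anatomy, weights$nmi_bins)
  tot <- s + weights$lambda_smooth * sm +
    if (is.null(anatomy)) 0 else weights$gamma_anat * an
  structure(list(total = tot, sim = s, smooth = sm, anat = an),
            class = "sac_loss")
}
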