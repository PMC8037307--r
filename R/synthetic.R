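# Desk-scale synthetic data with the statistical structure the method
# assumes: piecewise-smooth head-like phantoms, smooth ground-truth
# displacement fields dominated by the phase-encoding axis, anti-symmetric
# distortion of the two images, and an aligned anatomical companion with a
# different intensity mapping.

#' Phantom generator specification
#'
#' @param extents three integers (each >= 16): volume size in voxels.
#' @param n_tissue_shapes number of random smooth sub-regions inside the head.
#' @param intensity_levels intensities of background tissue and of each
#'   sub-region class (recycled over shapes).
#' @param noise_sigma additive Gaussian noise standard deviation, in
#'   intensity units (default 2% of the tissue contrast range).
#' @param texture_amp relative amplitude of the smooth intra-tissue
#'   intensity modulation (correlation length ~2.5 voxels) that emulates the
#'   voxel-scale texture of real EPI; 0 disables it.
#' @param seed integer seed.
#' @return object of class `sac_phantom_spec`.
#' @export
phantom_spec <- function(extents = c(48L, 48L, 32L), n_tissue_shapes = 6L,
                         intensity_levels = c(60, 100, 140, 180),
                         noise_sigma = 0.02 * 120, texture_amp = 0.15,
                         seed = 1L) {
  extents <- as.integer(extents)
  if (length(extents) != 3L || any(extents < 16L))
    stop("extents must be three integers >= 16", call. = FALSE)
  if (length(intensity_levels) == 0)
    stop("intensity_levels must be non-empty", call. = FALSE)
  stopifnot(noise_sigma >= 0, texture_amp >= 0)
  structure(list(extents = extents, n_tissue_shapes = as.integer(n_tissue_shapes),
                 intensity_levels = as.numeric(intensity_levels),
                 noise_sigma = noise_sigma, texture_amp = texture_amp,
                 seed = as.integer(seed)),
            class = "sac_phantom_spec")
}

#' Ground-truth field generator specification
#'
#' The phase-encoding amplitude must strictly dominate the off-PE amplitude,
#' mirroring the anisotropy of susceptibility distortion.
#'
#' @param pe_axis phase-encoding axis: `"x"`, `"y"` or `"z"`.
#' @param amplitude_pe maximum absolute displacement (voxels) on the PE axis.
#' @param amplitude_offpe maximum absolute displacement on the other axes.
#' @param smoothness_sigma Gaussian smoothing width (voxels) of the field.
#' @param seed integer seed.
#' @return object of class `sac_field_spec`.
#' @export
field_spec <- function(pe_axis = c("y", "x", "z"), amplitude_pe = 3,
                       amplitude_offpe = 0.5, smoothness_sigma = 6, seed = 1L) {
  pe_axis <- match.arg(pe_axis)
  if (!(amplitude_pe > amplitude_offpe && amplitude_offpe >= 0))
    stop("need amplitude_pe > amplitude_offpe >= 0 (PE dominance)", call. = FALSE)
  stopifnot(smoothness_sigma > 0)
  structure(list(pe_axis = pe_axis, amplitude_pe = amplitude_pe,
                 amplitude_offpe = amplitude_offpe,
                 smoothness_sigma = smoothness_sigma, seed = as.integer(seed)),
            class = "sac_field_spec")
}

#' Generate a head-like phantom with an anatomical companion
#'
#' Places a smooth head-shaped ellipsoid containing `n_tissue_shapes` random
#' smooth sub-regions at the given intensity levels, plus Gaussian noise.
#' The anatomical companion shares identical geometry but maps the tissue
#' classes through a different monotone intensity curve (emulating T1w vs EPI
#' contrast) and carries its own noise.  Seed-deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return list with `epi_like`, `anat_like` (both `sac_volume`) and `mask`
#'   (`sac_volume`, 1 inside the head).
#' @export
gen_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "sac_phantom_spec"))
  set.seed(spec$seed)
  d <- spec$extents
  cx <- (d - 1) / 2
  ax <- 0.42 * d                        # head semi-axes: 84% of each extent
  g <- make_grid(d)
  r2 <- ((g[, , , 1] - cx[1]) / ax[1])^2 + ((g[, , , 2] - cx[2]) / ax[2])^2 +
    ((g[, , , 3] - cx[3]) / ax[3])^2
  mask <- (r2 <= 1) * 1
  levels <- spec$intensity_levels
  label <- array(1L, d)                 # 1 = base tissue
  for (s in seq_len(spec$n_tissue_shapes)) {
    ctr <- cx + (runif(3) - 0.5) * 1.2 * ax
    rad <- pmax(2, (0.12 + 0.18 * runif(3)) * d)
    rr <- ((g[, , , 1] - ctr[1]) / rad[1])^2 + ((g[, , , 2] - ctr[2]) / rad[2])^2 +
      ((g[, , , 3] - ctr[3]) / rad[3])^2
    cls <- if (length(levels) > 1L) 2L + (s - 1L) %% (length(levels) - 1L) else 1L
    label[rr <= 1 & mask > 0] <- cls
  }
  epi_levels <- levels
  lmax <- max(levels)
  anat_levels <- 20 + 160 * sqrt(levels / lmax)   # different monotone contrast
  epi <- array(epi_levels[label], d) * mask
  anat <- array(anat_levels[label], d) * mask
  # band-limit the edges so trilinear resampling is well behaved
  epi <- gauss3(epi, 1.0)
  anat <- gauss3(anat, 1.0)
  if (spec$texture_amp > 0) {
    # smooth intra-tissue intensity modulation: real EPI/T1w are not
    # piecewise constant, and local texture is what windowed correlation
    # losses lock onto; the two modalities get independent draws
    tex <- gauss3(array(rnorm(prod(d)), d), 2.5)
    epi <- epi * (1 + spec$texture_amp * (tex / max(abs(tex))) * mask)
    tex <- gauss3(array(rnorm(prod(d)), d), 2.5)
    anat <- anat * (1 + spec$texture_amp * (tex / max(abs(tex))) * mask)
  }
  if (spec$noise_sigma > 0) {
    epi <- epi + array(rnorm(prod(d), 0, spec$noise_sigma), d)
    anat <- anat + array(rnorm(prod(d), 0, spec$noise_sigma), d)
  }
  list(epi_like = volume3d(epi), anat_like = volume3d(anat),
       mask = volume3d(mask))
}

#' Generate a smooth ground-truth displacement field
#'
#' Each component is Gaussian white noise smoothed with
#' `smoothness_sigma`, then rescaled so its maximum absolute value equals
#' `amplitude_pe` on the PE axis and `amplitude_offpe` on the other axes
#' (identically zero when the amplitude is zero).  Seed-deterministic.
#'
#' @param extents three integers.
#' @param spec a [field_spec()].
#' @return a `sac_field`.
#' @export
gen_field <- function(extents, spec = field_spec()) {
  stopifnot(inherits(spec, "sac_field_spec"))
  d <- as.integer(extents)
  set.seed(spec$seed)
  pe <- match(spec$pe_axis, c("x", "y", "z"))
  u <- array(0, c(d, 3L))
  for (comp in 1:3) {
    amp <- if (comp == pe) spec$amplitude_pe else spec$amplitude_offpe
    w <- array(rnorm(prod(d)), d)       # always draw: keeps components seeded
    if (amp == 0) next
    s <- gauss3(w, spec$smoothness_sigma)
    u[, , , comp] <- s * (amp / max(abs(s)))
  }
  displacement_field(u)
}

# Effective displacement that resamples the truth into a distorted image such
# that correcting with the true field recovers the truth: solves
# x + s*U(x) = w by fixed-point iteration, returning W(w) = x - w.  One
# iteration reproduces the plain single-warp construction.
effective_distortion <- function(u, s, iters = 8L) {
  d <- dim(u)[1:3]
  w <- array(0, dim(u))
  for (it in seq_len(iters)) {
    wn <- array(0, dim(u))
    for (comp in 1:3)
      wn[, , , comp] <- -s * warp3(u[, , , comp], w, +1)
    w <- wn
  }
  w
}

# Central-difference derivative of the PE component along the PE axis
# (one-sided at the faces).
pe_derivative <- function(u, pe) {
  uc <- u[, , , pe]
  d <- dim(uc)
  n <- d[pe]
  idx_hi <- pmin(seq_len(n) + 1L, n)
  idx_lo <- pmax(seq_len(n) - 1L, 1L)
  denom <- (idx_hi - idx_lo)
  pick <- function(i) switch(pe, uc[i, , , drop = FALSE],
                             uc[, i, , drop = FALSE], uc[, , i, drop = FALSE])
  diff <- pick(idx_hi) - pick(idx_lo)
  sweep(diff, pe, denom, "/")
}

#' Distort a truth volume into an anti-symmetric reversed-PE pair
#'
#' Produces `i1` and `i2` so that [correct_pair()] with the *true* field
#' recovers the truth (up to interpolation error): the distortion operator is
#' the exact inverse of the correction operator, computed by fixed-point
#' inversion of `G + U` and `G - U`.  Optional Jacobian intensity modulation
#' `1 + sign * dU_pe/d pe` multiplies each image (realism testing only; the
#' correction model itself is purely geometric).  If the modulation factor is
#' non-positive anywhere (folding), attribute `folding` is set on the result.
#'
#' @param truth undistorted `sac_volume` (or array).
#' @param field true displacement field.
#' @param noise_sigma independent additive Gaussian noise per image.
#' @param with_jacobian apply the intensity modulation (default `FALSE`).
#' @param exact use fixed-point inversion (default); `FALSE` gives the
#'   one-step approximation `i1 = warp(truth, U, -1)`, `i2 = warp(truth, U, +1)`.
#' @param seed seed for the noise draw.
#' @return list with volumes `i1`, `i2`; attribute `folding` is `TRUE` if
#'   the Jacobian modulation factor was clipped.
#' @export
distort_pair <- function(truth, field, noise_sigma = 0, with_jacobian = FALSE,
                         exact = TRUE, seed = 1L) {
  tr <- as_vol_array(truth)
  u <- as_field_array(field)
  if (!all(dim(tr) == dim(u)[1:3]))
    stop("truth extents and field extents must agree", call. = FALSE)
  iters <- if (exact) 8L else 1L
  w1 <- effective_distortion(u, +1, iters)   # i1 carries the -U distortion
  w2 <- effective_distortion(u, -1, iters)
  i1 <- warp3(tr, w1, +1)
  i2 <- warp3(tr, w2, +1)
  folding <- FALSE
  if (with_jacobian) {
    pe <- which.max(apply(abs(u), 4, max))
    dpe <- array(pe_derivative(u, pe), dim(tr))
    f1 <- 1 - dpe
    f2 <- 1 + dpe
    if (any(f1 <= 0) || any(f2 <= 0)) folding <- TRUE
    i1 <- i1 * pmax(f1, 0)
    i2 <- i2 * pmax(f2, 0)
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    i1 <- i1 + array(rnorm(length(i1), 0, noise_sigma), dim(i1))
    i2 <- i2 + array(rnorm(length(i2), 0, noise_sigma), dim(i2))
  }
  out <- list(i1 = volume3d(i1), i2 = volume3d(i2))
  attr(out, "folding") <- folding
  out
}

#' Generate a dataset of distorted reversed-PE pairs
#'
#' Independent seeded draws: per-item seeds are derived from the master seed,
#' so any item can be regenerated in isolation.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param phantom_spec a [phantom_spec()] (its seed field is overridden
#'   per item).
#' @param field_spec a [field_spec()] (likewise).
#' @param seed master seed.
#' @return list of `n_pairs` items, each with `i1`, `i2`, `anat`,
#'   `true_field`, `mask`.
#' @export
make_dataset <- function(n_pairs, phantom_spec = sacnet::phantom_spec(),
                         field_spec = sacnet::field_spec(), seed = 1L) {
  stopifnot(n_pairs >= 1)
  lapply(seq_len(n_pairs), function(i) {
    ps <- phantom_spec; ps$seed <- derive_seed(seed, 2L * i)
    fs <- field_spec; fs$seed <- derive_seed(seed, 2L * i + 1L)
    ph <- gen_phantom(ps)
    fld <- gen_field(ps$extents, fs)
    pair <- distort_pair(ph$epi_like, fld, noise_sigma = ps$noise_sigma,
                         seed = derive_seed(seed, 7919L + i))
    list(i1 = pair$i1, i2 = pair$i2, anat = ph$anat_like,
         true_field = fld, mask = ph$mask)
  })
}
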