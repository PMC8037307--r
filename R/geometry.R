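# Spatial transform unit and size-normalization helpers.

#' Warp a volume along a displacement field
#'
#' Differentiable trilinear resampling: output voxel `v` takes the trilinear
#' interpolation of `image` at `G(v) + sign * U(v)`, where `G` is the
#' identity grid.  Sample locations outside the volume are clamped to the
#' boundary (border replication).  With `sign = +1` this computes the
#' corrected image `E1 = I1 (x) (G + U)`; with `sign = -1`,
#' `E2 = I2 (x) (G - U)`.
#'
#' @param image `sac_volume` or 3D array.
#' @param field `sac_field` or `(X, Y, Z, 3)` array, same spatial extents.
#' @param sign `+1` or `-1`.
#' @return warped object of the same type as `image`.
#' @export
warp <- function(image, field, sign = 1) {
  arr <- as_vol_array(image)
  u <- as_field_array(field)
  if (!all(dim(arr) == dim(u)[1:3]))
    stop("image extents and field extents must agree", call. = FALSE)
  if (!(sign %in% c(-1, 1))) stop("sign must be +1 or -1", call. = FALSE)
  out <- warp3(arr, u, as.double(sign))
  if (inherits(image, "sac_volume"))
    volume3d(out, spacing = image$spacing, affine = image$affine)
  else out
}

#' Correct a reversed phase-encoding pair with one shared field
#'
#' Applies the inverse-distortion model of a reversed-PE pair: the two images
#' are resampled along the same displacement field with opposite signs,
#' `E1 = warp(i1, U, +1)` and `E2 = warp(i2, U, -1)`.
#'
#' @param i1,i2 the two distorted volumes (same extents).
#' @param field shared displacement field in voxel units.
#' @return list with elements `e1` and `e2`.
#' @export
correct_pair <- function(i1, i2, field) {
  a1 <- as_vol_array(i1); a2 <- as_vol_array(i2)
  if (!all(dim(a1) == dim(a2)))
    stop("the two volumes must have identical extents", call. = FALSE)
  list(e1 = warp(i1, field, +1), e2 = warp(i2, field, -1))
}

#' Pad a volume or field to a multiple of a given extent
#'
#' Size normalization before the encoder: each spatial extent is padded up
#' with trailing zeros to the next multiple of `multiple` (extents already
#' divisible are unchanged), so four stride-2 stages divide evenly.  Trailing
#' padding keeps voxel (0,0,0) fixed, making recovery a leading-block crop.
#'
#' @param x 3D array / `sac_volume` (or 4D `(X,Y,Z,C)` array / `sac_field`).
#' @param multiple positive integer, default 16.
#' @return list with `data` (padded array of the same kind) and `extents`
#'   (the original spatial extents, for [crop_to_size()]).
#' @export
pad_to_multiple <- function(x, multiple = 16L) {
  multiple <- as.integer(multiple)
  stopifnot(multiple >= 1L)
  arr <- if (inherits(x, "sac_volume")) x$data else if (inherits(x, "sac_field")) x$u else x
  nd <- length(dim(arr))
  stopifnot(nd %in% c(3L, 4L))
  d <- dim(arr)[1:3]
  target <- as.integer(ceiling(d / multiple) * multiple)
  if (all(target == d)) {
    out <- arr
  } else {
    full <- c(target, if (nd == 4L) dim(arr)[4])
    out <- array(0, full)
    if (nd == 3L) out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
    else out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- arr
  }
  list(data = out, extents = d)
}

#' Crop a padded volume or field back to recorded extents
#'
#' Inverse of [pad_to_multiple()]: returns the leading sub-block of the
#' recorded extents (consistent with trailing padding).
#'
#' @param x padded 3D or 4D array.
#' @param extents the spatial extents recorded at padding time.
#' @return array cropped to `extents`.
#' @export
crop_to_size <- function(x, extents) {
  arr <- if (inherits(x, "sac_volume")) x$data else if (inherits(x, "sac_field")) x$u else x
  extents <- as.integer(extents)
  d <- dim(arr)[1:3]
  if (any(extents > d))
    stop("recorded extents exceed current extents", call. = FALSE)
  if (length(dim(arr)) == 3L)
    arr[seq_len(extents[1]), seq_len(extents[2]), seq_len(extents[3]), drop = FALSE]
  else
    arr[seq_len(extents[1]), seq_len(extents[2]), seq_len(extents[3]), , drop = FALSE]
}
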