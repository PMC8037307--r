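# Core containers: scalar 3D volumes with voxel geometry, per-voxel 3-vector
# displacement fields, and the identity sampling grid.  All math is done in
# 0-based voxel coordinates; mm spacing and the affine are metadata carried
# through I/O only.

#' Construct a 3D scalar volume
#'
#' A `sac_volume` holds a 3D intensity array together with voxel spacing (mm)
#' and a voxel-to-world affine.  Spacing and affine are metadata: all warping
#' and loss computations work in 0-based voxel units.
#'
#' @param data numeric 3D array; every extent must be at least 2 and all
#'   values finite.
#' @param spacing numeric length-3 voxel size in mm (metadata only).
#' @param affine optional 4x4 voxel-to-world matrix (metadata only).
#' @return an object of class `sac_volume` with fields `data`, `spacing`,
#'   `affine`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  data <- as_vol_array(data)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (!is.null(affine)) {
    affine <- as.matrix(affine)
    stopifnot(all(dim(affine) == c(4, 4)))
  }
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "sac_volume")
}

#' @export
print.sac_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sac_volume %d x %d x %d, spacing %s mm, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

# Accept a sac_volume or a bare 3D array and return the validated array.
as_vol_array <- function(x) {
  if (inherits(x, "sac_volume")) x <- x$data
  if (!(is.array(x) && length(dim(x)) == 3L))
    stop("expected a 3D array or sac_volume", call. = FALSE)
  if (any(dim(x) < 2L)) stop("all three extents must be >= 2", call. = FALSE)
  if (!all(is.finite(x))) stop("volume contains non-finite values", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Construct a displacement field
#'
#' A `sac_field` stores per-voxel displacements in voxel units as an
#' `(X, Y, Z, 3)` array; the fourth margin is the component order (x, y, z).
#'
#' @param u numeric 4D array `(X, Y, Z, 3)`, finite everywhere.
#' @return an object of class `sac_field`.
#' @export
displacement_field <- function(u) {
  u <- as_field_array(u)
  structure(list(u = u), class = "sac_field")
}

#' @export
print.sac_field <- function(x, ...) {
  d <- dim(x$u)
  cat(sprintf("<sac_field %d x %d x %d, max |u| = %.4g voxels>\n",
              d[1], d[2], d[3], max(abs(x$u))))
  invisible(x)
}

as_field_array <- function(x) {
  if (inherits(x, "sac_field")) x <- x$u
  if (!(is.array(x) && length(dim(x)) == 4L && dim(x)[4] == 3L))
    stop("expected an (X, Y, Z, 3) array or sac_field", call. = FALSE)
  if (any(dim(x)[1:3] < 2L)) stop("field extents must be >= 2", call. = FALSE)
  if (!all(is.finite(x))) stop("field contains non-finite values", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Identity sampling grid
#'
#' Returns the regular grid `G`: an `(X, Y, Z, 3)` array whose component `d`
#' at voxel `(i, j, k)` equals that voxel's 0-based index along axis `d`.
#'
#' @param extents three positive integers, each at least 2.
#' @return `(X, Y, Z, 3)` array of class `sac_grid`.
#' @export
make_grid <- function(extents) {
  extents <- as.integer(extents)
  if (length(extents) != 3L || any(extents < 2L))
    stop("extents must be three integers >= 2", call. = FALSE)
  X <- extents[1]; Y <- extents[2]; Z <- extents[3]
  g <- array(0, c(X, Y, Z, 3))
  g[, , , 1] <- array(rep(seq_len(X) - 1, times = Y * Z), c(X, Y, Z))
  g[, , , 2] <- array(rep(rep(seq_len(Y) - 1, each = X), times = Z), c(X, Y, Z))
  g[, , , 3] <- array(rep(seq_len(Z) - 1, each = X * Y), c(X, Y, Z))
  structure(g, class = c("sac_grid", class(g)))
}

# Derive a 31-bit child seed from a master seed and an index; keeps every
# seed handed to set.seed() inside the integer range.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 1103515) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}
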