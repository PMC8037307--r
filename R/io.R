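# NIfTI-1 input/output for volumes and 4D displacement fields, plus run
# manifests.  All format handling is delegated to RNifti.

#' Read a 3D volume from a NIfTI-1 file
#'
#' Accepts 3D images (or 4D with a singleton trailing dimension).  Non-finite
#' voxels and higher-dimensional images are rejected with a clear error.
#'
#' @param path NIfTI file path.
#' @return a `sac_volume` carrying the header spacing and affine.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.vector(img), d[1:3])
  } else if (length(d) == 3L) {
    img2 <- array(as.vector(img), d)
  } else {
    stop("format error: ", path, " is not a 3D volume (dims: ",
         paste(d, collapse = "x"), ")", call. = FALSE)
  }
  if (!all(is.finite(img2)))
    stop("format error: ", path, " contains non-finite voxels", call. = FALSE)
  volume3d(img2, spacing = RNifti::pixdim(img)[1:3],
           affine = structure(RNifti::xform(img), code = NULL))
}

#' Write a volume to a NIfTI-1 file
#'
#' @param vol a `sac_volume` (or bare 3D array).
#' @param path destination path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- as_vol_array(vol)
  spacing <- if (inherits(vol, "sac_volume")) vol$spacing else c(1, 1, 1)
  affine <- if (inherits(vol, "sac_volume")) vol$affine else NULL
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  if (!is.null(affine))
    RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a displacement field as a 4D NIfTI
#'
#' Component order (x, y, z) along the 4th dimension; the header description
#' records that units are voxels.
#'
#' @param field a `sac_field`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  u <- as_field_array(field)
  img <- RNifti::asNifti(u)
  img$descrip <- "displacement field, voxel units, components (x,y,z)"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field from a 4D NIfTI
#'
#' @param path file written by [write_field()] (4D, 3 components).
#' @return a `sac_field`.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("format error: ", path, " is not a 3-component 4D field (dims: ",
         paste(d, collapse = "x"), ")", call. = FALSE)
  displacement_field(array(as.vector(img), d))
}

# Write the run manifest every CLI invocation produces: command, config
# snapshot, paths, seeds, package version, timestamp.
write_manifest <- function(dir, command, config, inputs, outputs, seed) {
  manifest <- list(
    command = command,
    config = config,
    inputs = inputs,
    outputs = outputs,
    seed = seed,
    package_version = as.character(utils::packageVersion("sacnet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
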