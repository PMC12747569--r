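#' Scalar volume container
#'
#' A 3D scalar grid (Hounsfield units, normalized intensity, or probability)
#' together with its voxel spacing and world origin. World coordinates follow
#' `world = index * spacing + origin` with 0-based indices, axes ordered
#' (x, y, z) and z the through-plane direction.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  if (any(dim(values) < 8L))
    stop("volume shape must be at least 8 voxels along every axis")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$values), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, range [", signif(min(x$values), 4), ", ",
      signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' Voxel volume in cm^3
#' @param vol a `scalar_volume` (or anything with a `spacing` field in mm).
#' @return volume of one voxel in cm^3.
#' @export
voxel_volume_cm3 <- function(vol) prod(vol$spacing) / 1000

as_volume_like <- function(values, vol) {
  scalar_volume(array(values, dim(vol$values)), vol$spacing, vol$origin)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti preserving the mm spacing in `pixdim`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `scalar_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- attr(img, "pixdim")[1:3]
  scalar_volume(array(as.numeric(img), dim(img)[1:3]), sp, c(0, 0, 0))
}

#' @rdname read_volume
#' @param vol a `scalar_volume` to write.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values, reference = NULL)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
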