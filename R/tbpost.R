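#' Reassemble probability patches into a full volume
#'
#' Voxels covered by a single patch are copied; voxels in overlap regions
#' are weighted by multiplying the contributing patch probabilities
#' together, so that a voxel is only confidently foreground when every
#' patch that saw it agrees.
#'
#' @param patches list of probability arrays from [make_probability_patches()]
#'   (or patch-wise inference).
#' @param layout the tiling layout produced alongside the patches.
#' @param spacing,origin grid geometry of the reassembled volume.
#' @return a [scalar_volume()] of probabilities.
#' @export
tb_reassemble <- function(patches, layout, spacing = c(1, 1, 1),
                          origin = c(0, 0, 0)) {
  shp <- layout$vol_shape
  ps <- layout$patch_shape
  out <- array(1, shp)
  covered <- array(FALSE, shp)
  for (i in seq_along(patches)) {
    s <- layout$starts[i, ]
    ix <- s[1]:(s[1] + ps[1] - 1L)
    iy <- s[2]:(s[2] + ps[2] - 1L)
    iz <- s[3]:(s[3] + ps[3] - 1L)
    out[ix, iy, iz] <- out[ix, iy, iz] * patches[[i]]
    covered[ix, iy, iz] <- TRUE
  }
  if (!all(covered)) stop("patch layout leaves a gap in coverage")
  scalar_volume(out, spacing, origin)
}

#' Constrain an airway probability map to the lungs
#'
#' Zeroes the probability outside the lung mask obtained by thresholding
#' the co-registered CT between -1000 and -600 HU.
#' @param prob probability [scalar_volume()].
#' @param ct HU [scalar_volume()] on the same grid.
#' @param hu_range lung HU window.
#' @export
tb_constrain_to_lungs <- function(prob, ct, hu_range = c(-1000, -600)) {
  if (!identical(dim(prob$values), dim(ct$values)))
    stop("probability and CT grids do not match")
  lung <- ct$values >= hu_range[1] & ct$values <= hu_range[2]
  out <- prob$values
  out[!lung] <- 0
  as_volume_like(out, prob)
}

#' Binarize a probability map and keep the largest component
#'
#' Thresholds at probability 0.5 (inclusive) and keeps the single largest
#' 26-connected component.
#' @param prob probability [scalar_volume()] with values in \[0, 1\].
#' @param threshold probability threshold (inclusive).
#' @return logical mask array.
#' @export
tb_binarize_largest <- function(prob, threshold = 0.5) {
  m <- prob$values >= threshold
  if (!any(m)) {
    warning("no voxels at or above threshold; returning empty mask")
    return(array(FALSE, dim(prob$values)))
  }
  lab <- cpp_label26(m, dim(m))
  counts <- tabulate(lab[lab > 0L])
  array(lab == which.max(counts), dim(m))
}
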