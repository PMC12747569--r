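#' Crop a mask into overlapping probability patches
#'
#' Emulates patch-wise network inference on large volumes: the mask is cut
#' into sub-volumes of `patch_shape` voxels (default 128 x 128 x 64) with a
#' stated overlap, each returned as a probability map (the mask as 0/1, with
#' optional multiplicative confidence), together with the tiling layout that
#' [tb_reassemble()] consumes.
#'
#' @param mask logical 3D array (or `scalar_volume` of 0/1).
#' @param patch_shape integer length-3 patch extent in voxels.
#' @param overlap voxel overlap between neighboring patches (scalar or
#'   length-3); must be smaller than `patch_shape`.
#' @param prob probability assigned inside the mask (outside gets 0);
#'   the default of 1 gives noiseless patches.
#' @return list with `patches` (list of numeric arrays) and `layout`
#'   (starts, patch shape, volume shape).
#' @export
make_probability_patches <- function(mask, patch_shape = c(128L, 128L, 64L),
                                     overlap = 0L, prob = 1) {
  if (inherits(mask, "scalar_volume")) mask <- mask$values >= 0.5
  shp <- dim(mask)
  patch_shape <- rep(as.integer(patch_shape), length.out = 3)
  overlap <- rep(as.integer(overlap), length.out = 3)
  if (any(patch_shape > shp)) stop("patch shape exceeds volume shape")
  if (any(overlap >= patch_shape)) stop("overlap must be smaller than the patch size")
  starts <- lapply(1:3, function(ax) {
    stride <- patch_shape[ax] - overlap[ax]
    s <- seq(1L, max(shp[ax] - patch_shape[ax] + 1L, 1L), by = stride)
    sort(unique(c(s, shp[ax] - patch_shape[ax] + 1L)))
  })
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  patches <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- as.integer(grid[i, ])
    sub <- mask[s[1]:(s[1] + patch_shape[1] - 1L),
                s[2]:(s[2] + patch_shape[2] - 1L),
                s[3]:(s[3] + patch_shape[3] - 1L), drop = FALSE]
    patches[[i]] <- array(ifelse(sub, prob, 0), patch_shape)
  }
  list(patches = patches,
       layout = list(starts = as.matrix(grid), patch_shape = patch_shape,
                     vol_shape = as.integer(shp)))
}
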