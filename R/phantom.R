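#' Specify a CT-like phantom
#'
#' Describes a synthetic Hounsfield-unit volume: soft-tissue background with
#' embedded air cavities (tube segments, bifurcating tube trees, ellipsoidal
#' pockets), optional additive Gaussian noise and metal inserts. The phantoms
#' emulate the inputs of the extrathoracic segmentation stage: air around
#' -1000 HU inside tissue at 0-60 HU, metal above 2000 HU.
#'
#' @param shape integer length-3 grid shape in voxels.
#' @param spacing voxel spacing in mm.
#' @param cavities list of cavity primitives, each a list with `type` one of
#'   `"tube"` (fields `p0`, `p1` world mm, and `volume_cm3` or `radius_mm`),
#'   `"pocket"` (fields `center`, `volume_cm3`), or `"tree"` (field `spec`,
#'   a [tree_spec()], and optional `offset` mm); all may set `hu`.
#' @param background_hu soft-tissue intensity (HU).
#' @param noise_sd additive Gaussian noise standard deviation (HU).
#' @param metal optional list of metal inserts, each
#'   `list(center =, radius_mm =, hu = 3000)`.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing = c(1, 1, 1), cavities = list(),
                         background_hu = 40, noise_sd = 0, metal = list()) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) stop("shape must be >= 8 voxels per axis")
  for (cav in cavities) {
    hu <- if (is.null(cav$hu)) -1000 else cav$hu
    if (hu >= -900) stop("cavity air intensity must be below -900 HU")
  }
  for (m in metal) {
    hu <- if (is.null(m$hu)) 3000 else m$hu
    if (hu <= 2000) stop("metal intensity must exceed 2000 HU")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 cavities = cavities, background_hu = background_hu,
                 noise_sd = noise_sd, metal = metal),
            class = "phantom_spec")
}

# World coordinates of all voxel centers, as three arrays.
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  list(x = array(rep(xs, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(ys, each = shape[1]), times = shape[3]), shape),
       z = array(rep(zs, each = shape[1] * shape[2]), shape))
}

cavity_mask <- function(cav, shape, spacing) {
  g <- voxel_grid(shape, spacing)
  world_max <- (shape - 1) * spacing
  if (cav$type == "tube") {
    p0 <- cav$p0; p1 <- cav$p1
    L <- sqrt(sum((p1 - p0)^2))
    r <- if (!is.null(cav$radius_mm)) cav$radius_mm else
      sqrt(cav$volume_cm3 * 1000 / (pi * L))
    lo <- pmin(p0, p1) - r; hi <- pmax(p0, p1) + r
    # the tube may legitimately exit the grid along its axis; only the
    # radial extent must fit
    d <- (p1 - p0) / L
    radial_pad <- r * sqrt(pmax(0, 1 - d^2))
    if (any(pmin(p0, p1) - radial_pad < -1e-9 & abs(d) < 0.99) ||
        any(pmax(p0, p1) + radial_pad > world_max + 1e-9 & abs(d) < 0.99))
      stop("cavity does not fit in grid: tube radial extent exceeds volume")
    ax <- g$x - p0[1]; ay <- g$y - p0[2]; az <- g$z - p0[3]
    t <- (ax * d[1] + ay * d[2] + az * d[3])
    t <- pmin(pmax(t, 0), L)
    dist2 <- (ax - t * d[1])^2 + (ay - t * d[2])^2 + (az - t * d[3])^2
    dist2 <= r^2
  } else if (cav$type == "pocket") {
    r <- (3 * cav$volume_cm3 * 1000 / (4 * pi))^(1 / 3)
    if (any(cav$center - r < -1e-9) || any(cav$center + r > world_max + 1e-9))
      stop("cavity does not fit in grid: pocket exceeds volume bounds")
    (g$x - cav$center[1])^2 + (g$y - cav$center[2])^2 +
      (g$z - cav$center[3])^2 <= r^2
  } else if (cav$type == "tree") {
    off <- if (is.null(cav$offset)) c(0, 0, 0) else cav$offset
    tr <- make_tube_tree(cav$spec)
    mesh <- tr$mesh
    mesh$vertices <- sweep(mesh$vertices, 2, off, "+")
    if (any(apply(mesh$vertices, 2, min) < -1e-9) ||
        any(apply(mesh$vertices, 2, max) > world_max + 1e-9))
      stop("cavity does not fit in grid: tree exceeds volume bounds")
    m <- cpp_voxelize(mesh$vertices, mesh$faces, as.integer(shape),
                      spacing, c(0, 0, 0))
    array(m, shape)
  } else stop("unknown cavity type: ", cav$type)
}

#' Generate a CT phantom volume with ground-truth cavity masks
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed controlling the additive noise; identical
#'   spec + seed give bit-identical volumes.
#' @return list with `volume` (a [scalar_volume()] in HU), `mask`
#'   (combined logical cavity mask) and `cavity_masks` (one logical array
#'   per cavity).
#' @export
make_ct_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; spacing <- spec$spacing
  vals <- array(spec$background_hu, shape)
  masks <- vector("list", length(spec$cavities))
  for (i in seq_along(spec$cavities)) {
    cav <- spec$cavities[[i]]
    m <- cavity_mask(cav, shape, spacing)
    hu <- if (is.null(cav$hu)) -1000 else cav$hu
    vals[m] <- hu
    masks[[i]] <- m
  }
  combined <- if (length(masks)) Reduce(`|`, masks) else array(FALSE, shape)
  for (m in spec$metal) {
    g <- voxel_grid(shape, spacing)
    hu <- if (is.null(m$hu)) 3000 else m$hu
    sel <- (g$x - m$center[1])^2 + (g$y - m$center[2])^2 +
      (g$z - m$center[3])^2 <= m$radius_mm^2
    vals[sel] <- hu
  }
  if (spec$noise_sd > 0) {
    set.seed(as.integer(seed))
    vals <- vals + array(rnorm(length(vals), 0, spec$noise_sd), shape)
  }
  list(volume = scalar_volume(vals, spacing),
       mask = combined, cavity_masks = masks)
}
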