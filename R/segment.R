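#' Intensity windowing parameters
#'
#' Lower and upper Hounsfield thresholds of the linear normalization window.
#' Defaults: air below -900 HU maps to 0, everything above the fat
#' threshold of -115 HU maps to 1.
#' @param I0 lower HU threshold.
#' @param I1 upper HU threshold (must exceed `I0`).
#' @export
window_params <- function(I0 = -900, I1 = -115) {
  if (!(I0 < I1)) stop("window requires I0 < I1")
  structure(list(I0 = I0, I1 = I1), class = "window_params")
}

#' Linearly normalize a HU volume into the unit interval
#'
#' Values at or below `I0` clamp to 0, at or above `I1` clamp to 1, linear
#' in between; monotone in the input.
#' @param vol a [scalar_volume()] in HU.
#' @param w a [window_params()].
#' @return a [scalar_volume()] with values in \[0, 1\].
#' @export
normalize_window <- function(vol, w = window_params()) {
  x <- (vol$values - w$I0) / (w$I1 - w$I0)
  as_volume_like(pmin(pmax(x, 0), 1), vol)
}

#' Median denoising with a cubic kernel
#'
#' Rank-order filtering with a 3 x 3 x 3 voxel kernel by default; removes
#' impulse noise while preserving air-tissue edges. Borders use replicate
#' padding.
#' @param vol a [scalar_volume()].
#' @param kernel odd kernel extent in voxels (>= 3).
#' @export
median_denoise <- function(vol, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) stop("kernel must be odd and >= 3")
  if (any(kernel > dim(vol$values))) stop("kernel larger than volume")
  out <- cpp_median3(as.numeric(vol$values), dim(vol$values), kernel)
  as_volume_like(out, vol)
}

# 2D Canny on one slice: Gaussian smoothing, Sobel gradients, quantized
# non-maximum suppression, hysteresis via connected components.
canny_slice <- function(img, sigma = 1.4, low = 0.1, high = 0.2) {
  sm <- EBImage::gblur(img, sigma = sigma)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(sm, kx)
  gy <- EBImage::filter2(sm, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  ang <- atan2(gy, gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4 # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  sh <- function(m, di, dj) {
    n <- matrix(0, nrow(m), ncol(m))
    si <- max(1, 1 + di):min(nrow(m), nrow(m) + di)
    sj <- max(1, 1 + dj):min(ncol(m), ncol(m) + dj)
    n[si, sj] <- m[si - di, sj - dj]
    n
  }
  offs <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  nms <- matrix(FALSE, nrow(img), ncol(img))
  for (sct in 0:3) {
    o <- offs[[sct + 1]]
    keep <- (sector == sct) & (mag >= sh(mag, o[1], o[2])) &
      (mag >= sh(mag, -o[1], -o[2]))
    nms <- nms | keep
  }
  mrel <- mag / max(mag)
  strong <- nms & (mrel >= high)
  weak <- nms & (mrel >= low)
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  lab <- EBImage::bwlabel(weak)
  keep_labels <- unique(lab[strong])
  weak & (lab %in% keep_labels)
}

#' Edge-guided contrast amplification
#'
#' Slice-wise Canny edge detection, morphological refinement (binary
#' dilation, hole filling, erosion) of the edge mask, then amplification of
#' the masked voxels by raising their normalized values to the third power
#' (darkening the air side of edges).
#' @param vol_norm normalized [scalar_volume()] in \[0, 1\].
#' @param sigma,low,high Canny parameters (Gaussian sigma; hysteresis
#'   thresholds as fractions of the peak gradient).
#' @export
edge_refine <- function(vol_norm, sigma = 1.4, low = 0.1, high = 0.2) {
  vals <- vol_norm$values
  out <- vals
  brush <- EBImage::makeBrush(3, shape = "box")
  for (k in seq_len(dim(vals)[3])) {
    sl <- vals[, , k]
    if (max(sl) == min(sl)) next
    edges <- canny_slice(sl, sigma, low, high)
    if (!any(edges)) next
    m <- EBImage::dilate(edges * 1, brush)
    m <- EBImage::fillHull(m)
    m <- EBImage::erode(m, brush) > 0.5
    sl[m] <- sl[m]^3
    out[, , k] <- sl
  }
  as_volume_like(out, vol_norm)
}

#' Laplacian enhancement
#'
#' Subtracts the 6-neighbor finite-difference Laplacian (scaled by the voxel
#' spacing) from the volume, which deepens large dark cavities relative to
#' their brighter walls.
#' @param vol a [scalar_volume()].
#' @return a [scalar_volume()] holding `I - laplacian(I)`.
#' @export
laplacian_enhance <- function(vol) {
  v <- vol$values
  lap <- array(0, dim(v))
  d <- dim(v)
  for (ax in 1:3) {
    idx_p <- pmin(seq_len(d[ax]) + 1L, d[ax]) # replicate border
    idx_m <- pmax(seq_len(d[ax]) - 1L, 1L)
    h2 <- vol$spacing[ax]^2
    if (ax == 1) lap <- lap + (v[idx_p, , , drop = FALSE] - 2 * v +
                                 v[idx_m, , , drop = FALSE]) / h2
    if (ax == 2) lap <- lap + (v[, idx_p, , drop = FALSE] - 2 * v +
                                 v[, idx_m, , drop = FALSE]) / h2
    if (ax == 3) lap <- lap + (v[, , idx_p, drop = FALSE] - 2 * v +
                                 v[, , idx_m, drop = FALSE]) / h2
  }
  as_volume_like(v - lap, vol)
}

#' Body-selection parameters for air-cavity segmentation
#'
#' The oral-cavity volume window and the minimum isolated-body volume. An
#' isolated air body is retained if it is the largest interior body or if
#' its volume falls inside the oral window of (3, 9.66) cm^3.
#' @param oral_low,oral_high oral-cavity volume window bounds in cm^3.
#' @param min_volume minimum isolated-body volume in cm^3.
#' @export
body_filter_params <- function(oral_low = 3, oral_high = 9.66,
                               min_volume = 3) {
  if (!(oral_low < oral_high) || oral_low <= 0)
    stop("oral window must satisfy 0 < low < high")
  structure(list(oral_low = oral_low, oral_high = oral_high,
                 min_volume = min_volume), class = "body_filter_params")
}

#' Segment air cavities from an enhanced volume
#'
#' Marker-based 3D watershed over the enhanced intensity: seeds grow from
#' strongly air-like minima, ambient background air is seeded from the
#' in-plane (x/y) volume borders and discarded, the surviving air voxels
#' are split into 26-connected bodies, and the final mask keeps the largest
#' interior body plus every isolated body whose volume falls inside the
#' oral-cavity window.
#'
#' @param enhanced [scalar_volume()] output of the enhancement chain
#'   (normalized, edge-amplified, Laplacian-enhanced).
#' @param filt a [body_filter_params()].
#' @param air_level voxels below this enhanced value are candidate air.
#' @param seed_level voxels below this value seed the watershed.
#' @return logical mask array with attribute `report` (a data.frame of body
#'   volumes and keep/drop decisions).
#' @export
segment_air_cavities <- function(enhanced, filt = body_filter_params(),
                                 air_level = 0.5, seed_level = 0.2) {
  v <- enhanced$values
  d <- dim(v)
  domain <- v < air_level
  if (!any(domain)) {
    warning("no air voxels found; returning empty mask")
    out <- array(FALSE, d)
    attr(out, "report") <- data.frame(body = integer(), volume_cm3 = numeric(),
                                      kept = logical(), reason = character())
    return(out)
  }
  seeds <- cpp_label26(domain & (v < seed_level), d)
  nlab <- max(seeds)
  bg_label <- nlab + 1L
  border <- array(FALSE, d)
  border[1, , ] <- TRUE; border[d[1], , ] <- TRUE
  border[, 1, ] <- TRUE; border[, d[2], ] <- TRUE
  markers <- seeds
  markers[border & domain] <- bg_label
  ws <- cpp_watershed(as.numeric(v), markers, domain, d)
  air <- domain & (ws != bg_label) & (ws > 0L)
  bodies <- cpp_label26(air, d)
  nb <- max(bodies)
  if (nb == 0L) {
    warning("no interior air bodies found; returning empty mask")
    out <- array(FALSE, d)
    attr(out, "report") <- data.frame(body = integer(), volume_cm3 = numeric(),
                                      kept = logical(), reason = character())
    return(out)
  }
  vox_cm3 <- prod(enhanced$spacing) / 1000
  counts <- tabulate(bodies[bodies > 0L], nbins = nb)
  vols <- counts * vox_cm3
  largest <- which.max(vols)
  kept <- logical(nb); reason <- character(nb)
  for (b in seq_len(nb)) {
    if (b == largest) { kept[b] <- TRUE; reason[b] <- "largest interior body" }
    else if (vols[b] > filt$oral_low && vols[b] < filt$oral_high) {
      kept[b] <- TRUE; reason[b] <- "within oral-cavity volume window"
    } else reason[b] <- "isolated body outside volume window"
  }
  out <- array(bodies %in% which(kept), d)
  attr(out, "report") <- data.frame(body = seq_len(nb), volume_cm3 = vols,
                                    kept = kept, reason = reason)
  out
}

#' Extract a triangulated surface from a binary mask
#'
#' Isosurface of the mask boundary in world millimetres with consistent
#' outward orientation. By default the binary mask is first converted to a
#' signed distance field (interior positive) and the zero level set is
#' extracted, which recovers smooth sub-voxel geometry; `method = "binary"`
#' interpolates the raw 0/1 field at level 0.5 instead.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing in mm.
#' @param origin world position of voxel (0,0,0).
#' @param method `"sdf"` (default) or `"binary"`.
#' @return a [surface_mesh()].
#' @export
extract_surface <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            method = c("sdf", "binary")) {
  method <- match.arg(method)
  if (!any(mask)) stop("cannot extract a surface from an empty mask")
  d <- dim(mask)
  if (method == "sdf") {
    din <- cpp_edt(mask, d, spacing)
    dout <- cpp_edt(!mask, d, spacing)
    field <- array(din - dout, d)
    # a couple of diffusion passes iron out the voxel-grid kinks of the
    # two-sided distance field (they otherwise inflate surface area)
    for (pass in 1:2) {
      nb <- array(0, d)
      for (ax in 1:3) {
        ip <- pmin(seq_len(d[ax]) + 1L, d[ax])
        im <- pmax(seq_len(d[ax]) - 1L, 1L)
        if (ax == 1) nb <- nb + field[ip, , , drop = FALSE] + field[im, , , drop = FALSE]
        if (ax == 2) nb <- nb + field[, ip, , drop = FALSE] + field[, im, , drop = FALSE]
        if (ax == 3) nb <- nb + field[, , ip, drop = FALSE] + field[, , im, drop = FALSE]
      }
      field <- 0.5 * field + 0.5 * nb / 6
    }
    # sign-preserve voxel-scale features the diffusion would erase
    raw <- din - dout
    flipped <- (raw > 0) != (field > 0)
    field[flipped] <- 0.25 * raw[flipped]
    level <- 0
  } else {
    field <- array(as.numeric(mask), d)
    level <- 0.5
  }
  iso <- cpp_march_tets(field, d, as.numeric(spacing), as.numeric(origin), level)
  if (nrow(iso$vertices) == 0) stop("isosurface is empty")
  surface_mesh(iso$vertices, iso$faces)
}
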