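# Sinogram-space metal-artifact reduction: per axial slice, metal is found
# by intensity thresholding, the slice is forward projected (Radon),
# detector bins whose rays cross metal are replaced by 1D linear
# interpolation along the detector axis, the slice is reconstructed by
# filtered backprojection, and the original metal voxels are restored.

rotate_bilinear <- function(m, angle, fill = 0) {
  n1 <- nrow(m); n2 <- ncol(m)
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2
  co <- cos(angle); si <- sin(angle)
  i <- matrix(seq_len(n1) - c1, n1, n2)
  j <- matrix(rep(seq_len(n2) - c2, each = n1), n1, n2)
  # source = R(-angle) %*% target
  si1 <- co * i + si * j + c1
  sj1 <- -si * i + co * j + c2
  i0 <- floor(si1); j0 <- floor(sj1)
  fi <- si1 - i0; fj <- sj1 - j0
  get <- function(ii, jj) {
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
    out <- matrix(fill, n1, n2)
    out[ok] <- m[cbind(ii[ok], jj[ok])]
    out
  }
  get(i0, j0) * (1 - fi) * (1 - fj) + get(i0 + 1, j0) * fi * (1 - fj) +
    get(i0, j0 + 1) * (1 - fi) * fj + get(i0 + 1, j0 + 1) * fi * fj
}

radon_2d <- function(img, angles) {
  sapply(angles, function(a) colSums(rotate_bilinear(img, a)))
}

iradon_2d <- function(sino, angles, out_n) {
  nd <- nrow(sino)
  npad <- 2^ceiling(log2(2 * nd))
  freqs <- c(seq(0, npad / 2), seq(-npad / 2 + 1, -1)) / npad
  ramp <- 2 * abs(freqs)
  rec <- matrix(0, nd, nd)
  for (t in seq_along(angles)) {
    p <- c(sino[, t], rep(0, npad - nd))
    filt <- Re(fft(fft(p) * ramp, inverse = TRUE)) / npad
    smear <- matrix(rep(filt[seq_len(nd)], each = nd), nd, nd)
    rec <- rec + rotate_bilinear(smear, -angles[t])
  }
  rec <- rec * pi / (2 * length(angles))
  ofs <- (nd - out_n) %/% 2
  rec[ofs + seq_len(out_n), ofs + seq_len(out_n)]
}

#' Reduce metal artifacts in sinogram space
#'
#' Each axial slice containing voxels at or above `metal_threshold` is
#' forward projected; projection bins crossing the metal are replaced by
#' linear interpolation along the detector axis; the slice is reconstructed
#' by filtered backprojection and the metal voxels themselves are restored
#' from the input. Slices without metal are returned unchanged.
#'
#' @param vol a [scalar_volume()] in HU.
#' @param metal_threshold HU threshold identifying metal (default 2500).
#' @param n_angles number of projection angles over 180 degrees.
#' @return a [scalar_volume()].
#' @export
reduce_metal_artifacts <- function(vol, metal_threshold = 2500,
                                   n_angles = 180L) {
  v <- vol$values
  d <- dim(v)
  if (d[1] < 8 || d[2] < 8) stop("slice size too small for projection")
  if (!any(v >= metal_threshold)) return(vol)
  angles <- seq(0, pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  out <- v
  # pad each slice into a square with room for rotation
  nd <- 2L * as.integer(ceiling(sqrt(d[1]^2 + d[2]^2) / 2)) + 8L
  o1 <- (nd - d[1]) %/% 2; o2 <- (nd - d[2]) %/% 2
  for (k in seq_len(d[3])) {
    sl <- v[, , k]
    metal <- sl >= metal_threshold
    if (!any(metal)) next
    base <- min(sl)
    pad <- matrix(base, nd, nd)
    pad[o1 + seq_len(d[1]), o2 + seq_len(d[2])] <- sl
    padm <- matrix(0, nd, nd)
    padm[o1 + seq_len(d[1]), o2 + seq_len(d[2])] <- metal * 1
    sino <- radon_2d(pad - base, angles)
    msino <- radon_2d(padm, angles) > 0.5
    for (t in seq_len(ncol(sino))) {
      bad <- msino[, t]
      if (!any(bad) || all(bad)) next
      good <- which(!bad)
      sino[bad, t] <- approx(good, sino[good, t], xout = which(bad),
                             rule = 2)$y
    }
    rec <- iradon_2d(sino, angles, nd) + base
    core <- rec[o1 + seq_len(d[1]), o2 + seq_len(d[2])]
    core[metal] <- sl[metal]
    out[, , k] <- core
  }
  as_volume_like(out, vol)
}
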