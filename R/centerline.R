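#' Maximal-inscribed-sphere radius field of a mesh interior
#'
#' Voxelizes the watertight mesh on a regular grid and computes, for every
#' interior voxel, the Euclidean distance to the surface — the radius of the
#' maximal inscribed sphere centered there (the distance-transform
#' realization of the medial-axis radius).
#'
#' @param mesh a watertight `surface_mesh` (mm).
#' @param pitch voxel pitch in mm; `NULL` picks `min lumen radius / 3`
#'   estimated from the interior, capped so the grid stays tractable.
#' @return list with `radius` (array, `NA` outside), `mask`, `spacing`,
#'   `origin`, `pitch`.
#' @export
interior_radius_field <- function(mesh, pitch = NULL) {
  # open meshes (uncapped airway ends) are closed transparently so the
  # parity voxelization sees a well-defined interior
  if (!is_watertight(mesh))
    mesh <- repair_to_watertight(mesh)$mesh
  bb_lo <- apply(mesh$vertices, 2, min)
  bb_hi <- apply(mesh$vertices, 2, max)
  if (is.null(pitch)) {
    # rough lumen estimate from a coarse pass
    coarse <- max((bb_hi - bb_lo)) / 64
    f0 <- interior_radius_field(mesh, pitch = coarse)
    rmax <- max(f0$radius, na.rm = TRUE)
    pitch <- max(rmax / 6, max(bb_hi - bb_lo) / 512)
  }
  origin <- bb_lo - 2 * pitch
  shape <- pmax(as.integer(ceiling((bb_hi - bb_lo + 4 * pitch) / pitch)) + 1L, 8L)
  mask <- cpp_voxelize(mesh$vertices, mesh$faces, shape,
                       rep(pitch, 3), origin)
  mask <- array(mask, shape)
  if (!any(mask)) stop("voxelization produced an empty interior; refine pitch")
  r <- cpp_edt(mask, shape, rep(pitch, 3))
  if (max(r[mask]) < 2 * pitch)
    stop("voxel pitch too coarse for the lumen: use a pitch below half the ",
         "minimal radius")
  r[!mask] <- NA_real_
  list(radius = array(r, shape), mask = mask, spacing = rep(pitch, 3),
       origin = origin, pitch = pitch)
}

world_to_index <- function(p, field) (p - field$origin) / field$spacing
index_to_world <- function(idx, field) field$origin + idx * field$spacing

#' Solve the radius-weighted Eikonal equation by fast marching
#'
#' Propagates a front from the source with `|grad T| = 1 / r(x)` (speed
#' equal to the local inscribed radius), so arrival time accumulates the
#' path cost `ds / r(s)`: wide lumens are fast, narrow ones slow.
#'
#' @param field output of [interior_radius_field()].
#' @param source world point (mm) or voxel index (length-3 integer, 1-based
#'   with `index = TRUE`) inside the interior.
#' @param index interpret `source` as a voxel index.
#' @param unit_speed propagate with unit speed instead (geodesic distance).
#' @return list with `T` (array of arrival times, `Inf` where unreached),
#'   plus the grid geometry.
#' @export
solve_eikonal <- function(field, source, index = FALSE, unit_speed = FALSE) {
  shape <- dim(field$mask)
  if (!index) {
    idx <- round(world_to_index(source, field)) + 1
  } else idx <- source
  idx <- pmin(pmax(as.integer(idx), 1L), shape)
  if (!field$mask[idx[1], idx[2], idx[3]])
    stop("source point is not inside the interior mask")
  speed <- field$radius
  if (unit_speed) speed[!is.na(speed)] <- 1
  speed[is.na(speed)] <- 0
  # exact initialization in a small ball around the source suppresses the
  # first-order point-source error of the fast-marching scheme
  w <- 4L
  lo <- pmax(idx - w, 1L); hi <- pmin(idx + w, shape)
  gi <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3])
  dist <- sqrt(((gi$i - idx[1]) * field$spacing[1])^2 +
                 ((gi$j - idx[2]) * field$spacing[2])^2 +
                 ((gi$k - idx[3]) * field$spacing[3])^2)
  spd0 <- speed[idx[1], idx[2], idx[3]]
  lins <- (gi$i - 1L) + shape[1] * ((gi$j - 1L) + shape[2] * (gi$k - 1L))
  inside <- speed[cbind(gi$i, gi$j, gi$k)] > 0 & dist <= w * max(field$spacing)
  Tarr <- cpp_fmm(as.numeric(speed), shape, field$spacing,
                  as.integer(lins[inside]), dist[inside] / spd0)
  list(T = array(Tarr, shape), source_index = idx, spacing = field$spacing,
       origin = field$origin, mask = field$mask)
}

trilinear <- function(arr, idx) {
  # idx: 0-based fractional voxel coordinates
  d <- dim(arr)
  i0 <- pmin(pmax(floor(idx), 0), d - 2)
  fr <- pmin(pmax(idx - i0, 0), 1)
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[1] else 1 - fr[1]) * (if (dy) fr[2] else 1 - fr[2]) *
      (if (dz) fr[3] else 1 - fr[3])
    if (w == 0) next
    val <- arr[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    if (!is.finite(val)) return(NA_real_)
    acc <- acc + w * val
  }
  acc
}

#' Trace a centerline by gradient backtracking
#'
#' Steepest-descent integration of `dx/ds = -grad T` from the target back to
#' the source, with central-difference gradients on trilinearly interpolated
#' arrival times and a step of half the voxel pitch. Plateaus are escaped by
#' stepping to the lowest-arrival-time neighbor voxel.
#'
#' @param sol output of [solve_eikonal()].
#' @param target world point (mm) with finite arrival time.
#' @param field the radius field (for per-point radii).
#' @param step integration step in mm (default half the pitch).
#' @return matrix of path points (target first, source last) with a
#'   `radius` attribute.
#' @export
backtrack_path <- function(sol, target, field, step = NULL) {
  Tarr <- sol$T
  sp <- sol$spacing
  if (is.null(step)) step <- 0.5 * sp[1]
  d <- dim(Tarr)
  Tuse <- Tarr
  Tuse[!is.finite(Tuse)] <- NA_real_
  src_w <- index_to_world(sol$source_index - 1, sol)
  p <- as.numeric(target)
  t_here <- trilinear(Tuse, world_to_index(p, sol))
  if (!is.finite(t_here)) stop("target has no finite arrival time")
  path <- list(p)
  maxsteps <- 20 * sum(d)
  h <- 0.5 * sp
  for (k in seq_len(maxsteps)) {
    if (sqrt(sum((p - src_w)^2)) <= max(sp)) break
    idx <- world_to_index(p, sol)
    g <- numeric(3)
    for (ax in 1:3) {
      e <- c(0, 0, 0); e[ax] <- h[ax] / sp[ax]
      tp <- trilinear(Tuse, idx + e); tm <- trilinear(Tuse, idx - e)
      if (is.na(tp) && is.na(tm)) { g[ax] <- 0 }
      else if (is.na(tp)) g[ax] <- (trilinear(Tuse, idx) - tm) / h[ax]
      else if (is.na(tm)) g[ax] <- (tp - trilinear(Tuse, idx)) / h[ax]
      else g[ax] <- (tp - tm) / (2 * h[ax])
    }
    gn <- sqrt(sum(g^2))
    moved <- FALSE
    if (is.finite(gn) && gn > 1e-12) {
      cand <- p - step * g / gn
      t_cand <- trilinear(Tuse, world_to_index(cand, sol))
      if (is.finite(t_cand) && t_cand < t_here) {
        p <- cand; t_here <- t_cand; moved <- TRUE
      }
    }
    if (!moved) {
      # plateau: hop to the lowest-T neighbor voxel
      vi <- round(idx) + 1
      best <- NULL; bestT <- t_here
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        ii <- vi + c(dx, dy, dz)
        if (any(ii < 1) || any(ii > d)) next
        tv <- Tarr[ii[1], ii[2], ii[3]]
        if (is.finite(tv) && tv < bestT - 1e-12) { best <- ii; bestT <- tv }
      }
      if (is.null(best)) stop("backtracking stalled: no lower arrival time nearby")
      p <- index_to_world(best - 1, sol)
      t_here <- bestT
    }
    path[[length(path) + 1L]] <- p
  }
  path[[length(path) + 1L]] <- src_w
  pts <- do.call(rbind, path)
  rad <- apply(pts, 1, function(q) {
    r <- trilinear(ifelse(is.na(field$radius), NA, field$radius),
                   world_to_index(q, field))
    if (is.na(r) || r <= 0) min(field$pitch, na.rm = TRUE) else r
  })
  attr(pts, "radius") <- rad
  pts
}

# Endpoint candidates are 26-neighborhood local maxima of the geodesic
# arrival field. Each candidate is re-centred onto the medial axis (moved
# to the largest-radius voxel in its neighborhood, iterated), which pulls
# wall-adjacent maxima at flat airway ends back to the lumen center; the
# re-centred candidates are then deduplicated by a radius-scaled
# suppression distance.
detect_endpoints <- function(field, geo) {
  Tg <- geo$T
  d <- dim(Tg)
  Tuse <- Tg
  Tuse[!is.finite(Tuse)] <- NA_real_
  lm <- array(cpp_local_maxima26(Tuse, d), d)
  lm[!is.finite(Tg)] <- FALSE
  cand <- which(lm, arr.ind = TRUE)
  if (nrow(cand) == 0) return(NULL)
  tv <- Tg[lm]
  rfield <- field$radius
  pitch <- field$pitch
  recentre <- function(ctr, tcand) {
    # estimate the local lumen radius, then move to the widest voxel whose
    # arrival time stays within about one lumen radius of the candidate's:
    # this pulls rim-adjacent maxima onto the medial axis without drifting
    # down the branch, and is stable under pitch refinement
    lo <- pmax(ctr - 3L, 1L); hi <- pmin(ctr + 3L, d)
    sub <- rfield[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    if (all(is.na(sub))) return(ctr)
    r1 <- max(sub, na.rm = TRUE)
    w <- as.integer(ceiling(1.3 * r1 / pitch)) + 2L
    lo <- pmax(ctr - w, 1L); hi <- pmin(ctr + w, d)
    sub <- rfield[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    tsub <- Tg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    lumen <- max(sub, na.rm = TRUE) # full local lumen radius
    sub[!is.finite(tsub) | tsub < tcand - 1.3 * r1] <- NA
    if (all(is.na(sub))) return(list(ctr = ctr, lumen = r1))
    best <- arrayInd(which.max(sub), dim(sub))[1, ]
    list(ctr = lo + best - 1L, lumen = lumen)
  }
  ridge_walk <- function(ctr, lumen) {
    # walk tipward along the medial ridge: climb the arrival field while
    # the inscribed radius stays above 70% of the local lumen, so the
    # endpoint lands a fixed fraction of a radius short of the tip
    # irrespective of the grid pitch
    max_steps <- as.integer(ceiling(2.5 * lumen / pitch)) + 2L
    for (step in seq_len(max_steps)) {
      tcur <- Tg[ctr[1], ctr[2], ctr[3]]
      lo <- pmax(ctr - 1L, 1L); hi <- pmin(ctr + 1L, d)
      sub_t <- Tg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      sub_r <- rfield[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      sub_t[is.na(sub_r) | sub_r < 0.7 * lumen | !is.finite(sub_t)] <- -Inf
      if (!is.finite(max(sub_t)) || max(sub_t) <= tcur) break
      best <- arrayInd(which.max(sub_t), dim(sub_t))[1, ]
      ctr <- lo + best - 1L
    }
    ctr
  }
  cand <- t(vapply(seq_len(nrow(cand)), function(i) {
    rc <- recentre(cand[i, ], tv[i])
    ridge_walk(rc$ctr, rc$lumen)
  }, integer(3)))
  tv <- Tg[cand]
  rv <- rfield[cand]
  ord <- order(tv, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; tv <- tv[ord]; rv <- rv[ord]
  pts <- sweep((cand - 1) * pitch, 2, field$origin, "+")
  # sub-voxel refinement: the medial axis runs between voxel centers at
  # coarse pitch, so snap each endpoint to the radius^3-weighted centroid
  # of its neighborhood
  for (i in seq_len(nrow(cand))) {
    lo <- pmax(cand[i, ] - 2L, 1L); hi <- pmin(cand[i, ] + 2L, d)
    gi <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    w <- rfield[gi]^3
    ok <- !is.na(w)
    if (sum(ok) < 2) next
    ctd <- colSums(gi[ok, , drop = FALSE] * w[ok]) / sum(w[ok])
    pts[i, ] <- field$origin + (ctd - 1) * pitch
  }
  keep <- integer()
  for (i in seq_len(nrow(cand))) {
    supp <- max(2 * rv[i], 4 * pitch)
    if (!length(keep)) { keep <- i; next }
    dmin <- min(sqrt(rowSums((pts[keep, , drop = FALSE] -
                                matrix(pts[i, ], length(keep), 3,
                                       byrow = TRUE))^2)))
    if (dmin > supp) keep <- c(keep, i)
  }
  list(index = cand[keep, , drop = FALSE], world = pts[keep, , drop = FALSE],
       radius = rv[keep], arrival = tv[keep])
}

#' Build a centerline network from a watertight mesh
#'
#' Pipeline: interior voxelization and inscribed-radius field; geodesic
#' arrival from the widest interior voxel to seed endpoint candidates
#' (suppressed local maxima of the arrival field); inlet chosen as the
#' endpoint with the largest local radius; radius-weighted fast marching
#' from the inlet; gradient backtracking from every other endpoint; shared
#' path prefixes merged into a branch graph; branches resampled at a
#' uniform arc-length interval.
#'
#' @param mesh a watertight `surface_mesh`.
#' @param pitch voxel pitch (mm) or `NULL` for automatic.
#' @param resample_mm branch resampling interval (mm).
#' @return a [centerline_network()]; the radius field is attached as
#'   attribute `field`.
#' @export
build_network <- function(mesh, pitch = NULL, resample_mm = 0.5) {
  field <- interior_radius_field(mesh, pitch)
  d <- dim(field$mask)
  # seed at a widest-lumen voxel; among near-maximal radii take the one
  # closest to the interior centroid (the radius field often plateaus
  # along a whole airway segment)
  rmax <- max(field$radius, na.rm = TRUE)
  cand_src <- which(!is.na(field$radius) & field$radius >= 0.95 * rmax)
  ci <- arrayInd(cand_src, d)
  ctd <- colMeans(arrayInd(which(field$mask), d))
  src_idx <- ci[which.min(rowSums(sweep(ci, 2, ctd)^2)), ]
  geo <- solve_eikonal(field, src_idx, index = TRUE, unit_speed = TRUE)
  ep <- detect_endpoints(field, geo)
  if (is.null(ep) || nrow(ep$world) < 2)
    stop("fewer than 2 endpoints detected")
  inlet_i <- pick_inlet(ep, field)
  wt <- solve_eikonal(field, ep$index[inlet_i, ], index = TRUE)
  paths <- list()
  for (i in seq_len(nrow(ep$world))) {
    if (i == inlet_i) next
    pth <- backtrack_path(wt, ep$world[i, ], field)
    # orient inlet -> endpoint
    paths[[length(paths) + 1L]] <- list(
      pts = pth[rev(seq_len(nrow(pth))), , drop = FALSE],
      rad = rev(attr(pth, "radius")))
  }
  net <- merge_paths(paths, tol = 1.5 * field$pitch)
  net <- resample_network(net, resample_mm)
  deg <- tabulate(as.vector(net$edges), nbins = nrow(net$points))
  eps <- which(deg == 1L)
  inlet <- eps[which.max(net$radius[eps])]
  out <- centerline_network(net$points, net$radius, net$edges,
                            branch_id = net$branch_id, endpoints = eps,
                            inlet = inlet)
  attr(out, "field") <- field
  out
}

pick_inlet <- function(ep, field) {
  r <- ep$radius
  best <- which.max(r)
  ties <- which(r >= 0.98 * r[best])
  if (length(ties) == 1L) return(best)
  # tie-break: largest mean radius in a 2-pitch ball, then lowest index
  score <- vapply(ties, function(i) {
    ctr <- ep$index[i, ]
    lo <- pmax(ctr - 2L, 1L); hi <- pmin(ctr + 2L, dim(field$mask))
    mean(field$radius[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]], na.rm = TRUE)
  }, 0)
  ties[order(-score, ties)][1]
}

# Merge traced paths (all starting at the inlet) by attaching each new path
# at the last point of its prefix that lies within `tol` of the existing
# network.
merge_paths <- function(paths, tol) {
  pts <- paths[[1]]$pts
  rad <- paths[[1]]$rad
  edges <- if (nrow(pts) > 1) cbind(seq_len(nrow(pts) - 1), 2:nrow(pts)) else
    matrix(integer(), 0, 2)
  for (k in seq_along(paths)[-1]) {
    pp <- paths[[k]]$pts; rr <- paths[[k]]$rad
    n_exist <- nrow(pts)
    # distance of each path point to the existing network
    attach_at <- 0L
    for (i in seq_len(nrow(pp))) {
      dmin <- min(sqrt(rowSums((pts - matrix(pp[i, ], n_exist, 3,
                                             byrow = TRUE))^2)))
      if (dmin <= tol) attach_at <- i else break
    }
    if (attach_at == 0L) attach_at <- 1L
    anchor_pt <- pp[attach_at, ]
    anchor <- which.min(sqrt(rowSums((pts - matrix(anchor_pt, n_exist, 3,
                                                   byrow = TRUE))^2)))
    if (attach_at < nrow(pp)) {
      new_pts <- pp[(attach_at + 1):nrow(pp), , drop = FALSE]
      new_rad <- rr[(attach_at + 1):nrow(pp)]
      ids <- n_exist + seq_len(nrow(new_pts))
      pts <- rbind(pts, new_pts)
      rad <- c(rad, new_rad)
      chain <- c(anchor, ids)
      edges <- rbind(edges, cbind(chain[-length(chain)], chain[-1]))
    }
  }
  list(points = pts, radius = rad, edges = edges)
}

# Decompose the merged graph into branches (chains between nodes of degree
# != 2) and resample each at a uniform arc-length interval.
resample_network <- function(net, interval) {
  g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(net$points) - igraph::vcount(g)))
  deg <- igraph::degree(g)
  nodes <- which(deg != 2L)
  visited_edge <- new.env()
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  pts_out <- NULL; rad_out <- NULL; bid_out <- integer()
  edges_out <- NULL
  node_map <- new.env()
  branch <- 0L
  add_pt <- function(p, r, b) {
    pts_out <<- rbind(pts_out, p); rad_out <<- c(rad_out, r)
    bid_out <<- c(bid_out, b)
    nrow(pts_out)
  }
  node_id <- function(v, b) {
    k <- as.character(v)
    if (!is.null(node_map[[k]])) return(node_map[[k]])
    id <- add_pt(net$points[v, ], net$radius[v], b)
    node_map[[k]] <- id
    id
  }
  for (v0 in nodes) {
    for (nb in as.integer(igraph::neighbors(g, v0))) {
      if (!is.null(visited_edge[[ekey(v0, nb)]])) next
      # walk the chain from v0 through nb to the next junction/terminal
      chain <- c(v0, nb)
      visited_edge[[ekey(v0, nb)]] <- TRUE
      cur <- nb; prev <- v0
      while (deg[cur] == 2L) {
        nxt <- setdiff(as.integer(igraph::neighbors(g, cur)), prev)[1]
        visited_edge[[ekey(cur, nxt)]] <- TRUE
        chain <- c(chain, nxt)
        prev <- cur; cur <- nxt
      }
      branch <- branch + 1L
      cpts <- net$points[chain, , drop = FALSE]
      crad <- net$radius[chain]
      # light moving-average smoothing of interior points removes traced-
      # path jitter (and steadies endpoint tangents); end nodes stay fixed
      if (nrow(cpts) >= 5) {
        sm <- cpts
        for (j in 3:(nrow(cpts) - 2))
          sm[j, ] <- colMeans(cpts[(j - 2):(j + 2), , drop = FALSE])
        for (j in c(2, nrow(cpts) - 1))
          sm[j, ] <- colMeans(cpts[(j - 1):(j + 1), , drop = FALSE])
        cpts <- sm
      }
      seglen <- sqrt(rowSums((cpts[-1, , drop = FALSE] -
                                cpts[-nrow(cpts), , drop = FALSE])^2))
      arc <- c(0, cumsum(seglen))
      L <- arc[length(arc)]
      nsamp <- max(2L, ceiling(L / interval) + 1L)
      si <- seq(0, L, length.out = nsamp)
      interp <- function(vals) approx(arc, vals, xout = si,
                                      ties = "ordered")$y
      rs_pts <- cbind(interp(cpts[, 1]), interp(cpts[, 2]), interp(cpts[, 3]))
      rs_rad <- interp(crad)
      # at terminal nodes, place the adjacent sample on the direction
      # fitted over the branch's last stretch, so the nearest-neighbor
      # endpoint tangent reflects the branch axis rather than one noisy
      # half-millimetre step
      step_len <- si[2] - si[1]
      if (nsamp >= 5) {
        if (deg[cur] == 1L) {
          dirv <- rs_pts[nsamp, ] - rs_pts[max(1L, nsamp - 4L), ]
          dirv <- dirv / sqrt(sum(dirv^2))
          rs_pts[nsamp - 1L, ] <- rs_pts[nsamp, ] - step_len * dirv
        }
        if (deg[v0] == 1L) {
          dirv <- rs_pts[min(nsamp, 5L), ] - rs_pts[1L, ]
          dirv <- dirv / sqrt(sum(dirv^2))
          rs_pts[2L, ] <- rs_pts[1L, ] + step_len * dirv
        }
      }
      a <- node_id(v0, branch)
      idx <- a
      if (nsamp > 2L) for (j in 2:(nsamp - 1L))
        idx <- c(idx, add_pt(rs_pts[j, ], rs_rad[j], branch))
      idx <- c(idx, node_id(cur, branch))
      edges_out <- rbind(edges_out, cbind(idx[-length(idx)], idx[-1]))
    }
  }
  list(points = pts_out, radius = pmax(rad_out, 1e-9), edges = edges_out,
       branch_id = bid_out)
}
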