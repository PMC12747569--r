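#' Specify a synthetic bifurcating tube tree
#'
#' A symmetric binary airway-like tree: a root segment (the trachea
#' analogue) followed by `generations` dihotomous branchings. Child radii
#' shrink by `radius_decay` per generation and branch planes alternate by
#' 90 degrees between generations so branches spread in 3D and do not
#' collide. An open tree exposes `2^n + 1` openings: the terminals of the
#' n-th generation plus the root.
#'
#' @param generations integer >= 0, number of bifurcation generations n.
#' @param root_radius root tube radius in mm.
#' @param radius_decay per-generation radius ratio (child = decay * parent).
#' @param segment_length root segment length in mm; later generations scale
#'   by `radius_decay` as well (or pass a vector of length n + 1).
#' @param half_angle bifurcation half-angle in degrees.
#' @param resolution effective circumferential facet count (>= 6); sets the
#'   isosurface sampling pitch.
#' @param open_ends if `TRUE` the root and every terminal are cut open.
#' @return a `tree_spec`.
#' @export
tree_spec <- function(generations = 2, root_radius = 4, radius_decay = 0.8,
                      segment_length = 16, half_angle = 35, resolution = 24,
                      open_ends = FALSE) {
  generations <- as.integer(generations)
  if (generations < 0) stop("generations must be >= 0")
  if (root_radius <= 0 || radius_decay <= 0) stop("radii must be strictly positive")
  if (resolution < 6) stop("resolution must be >= 6")
  lens <- if (length(segment_length) == 1L)
    segment_length * radius_decay^(0:generations) else as.numeric(segment_length)
  if (length(lens) != generations + 1L)
    stop("segment_length must be scalar or length generations + 1")
  structure(list(generations = generations, root_radius = root_radius,
                 radius_decay = radius_decay, lengths = lens,
                 half_angle = half_angle, resolution = as.integer(resolution),
                 open_ends = isTRUE(open_ends)),
            class = "tree_spec")
}

rot_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Skeleton of the tree: one row per segment (p0 -> p1, radius, generation).
tree_skeleton <- function(spec) {
  segs <- list()
  recurse <- function(p0, dir, normal, gen) {
    L <- spec$lengths[gen + 1]
    r <- spec$root_radius * spec$radius_decay^gen
    p1 <- p0 + L * dir
    segs[[length(segs) + 1L]] <<- list(p0 = p0, p1 = p1, r = r, gen = gen)
    if (gen < spec$generations) {
      th <- spec$half_angle * pi / 180
      for (sgn in c(-1, 1)) {
        dchild <- as.vector(rot_axis(normal, sgn * th) %*% dir)
        nchild <- as.vector(rot_axis(dchild, pi / 2) %*% normal)
        recurse(p1, dchild, nchild, gen + 1L)
      }
    }
  }
  recurse(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0), 0L)
  segs
}

seg_dist <- function(a0, a1, b0, b1) {
  # minimal distance between two 3D segments
  u <- a1 - a0; v <- b1 - b0; w <- a0 - b0
  A <- sum(u * u); B <- sum(u * v); C <- sum(v * v)
  D <- sum(u * w); E <- sum(v * w)
  den <- A * C - B * B
  sc <- if (den < 1e-12) 0 else (B * E - C * D) / den
  tc <- if (C < 1e-12) 0 else (A * E - B * D) / max(den, 1e-12)
  sc <- min(max(sc, 0), 1); tc <- min(max(tc, 0), 1)
  # refine clamped solution once
  tc <- if (C < 1e-12) 0 else min(max((E + sc * B) / C, 0), 1)
  sc <- if (A < 1e-12) 0 else min(max((sc * 0 + (B * tc - D)) / A, 0), 1)
  p <- a0 + sc * u; q <- b0 + tc * v
  sqrt(sum((p - q)^2))
}

#' Generate a watertight tube-tree mesh with its ground-truth centerline
#'
#' The tree is realized as the implicit union of capsules (one per skeleton
#' segment) isosurfaced on a regular grid, which yields a closed 2-manifold
#' by construction. With `open_ends` the root and terminal end caps are cut
#' off by local planes, leaving `2^n + 1` boundary loops.
#'
#' @param spec a [tree_spec()].
#' @return list with `mesh` (a [surface_mesh()]), `network` (ground-truth
#'   [centerline_network()]) and `skeleton` (raw segment list).
#' @export
make_tube_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  segs <- tree_skeleton(spec)
  # collision check between non-adjacent segments
  if (length(segs) > 1) {
    for (i in seq_along(segs)) for (j in seq_along(segs)) {
      if (j <= i) next
      si <- segs[[i]]; sj <- segs[[j]]
      touching <- any(apply(rbind(si$p0, si$p1), 1, function(p)
        min(sum((p - sj$p0)^2), sum((p - sj$p1)^2)) < 1e-12))
      if (touching) next
      if (seg_dist(si$p0, si$p1, sj$p0, sj$p1) < si$r + sj$r + 0.25)
        stop("self-intersecting parameterization: branches collide")
    }
  }
  rmin <- min(vapply(segs, function(s) s$r, 0))
  pitch <- min(2 * pi * rmin / spec$resolution, rmin / 2.5)
  pts <- do.call(rbind, lapply(segs, function(s) rbind(s$p0, s$p1)))
  rmax <- max(vapply(segs, function(s) s$r, 0))
  lo <- apply(pts, 2, min) - rmax - 3 * pitch
  hi <- apply(pts, 2, max) + rmax + 3 * pitch
  shape <- pmax(as.integer(ceiling((hi - lo) / pitch)) + 1L, 8L)
  g <- voxel_grid(shape, rep(pitch, 3), lo)
  phi <- array(-Inf, shape)
  for (s in segs) {
    d <- s$p1 - s$p0; L <- sqrt(sum(d * d)); d <- d / L
    ax <- g$x - s$p0[1]; ay <- g$y - s$p0[2]; az <- g$z - s$p0[3]
    t <- pmin(pmax(ax * d[1] + ay * d[2] + az * d[3], 0), L)
    dist <- sqrt((ax - t * d[1])^2 + (ay - t * d[2])^2 + (az - t * d[3])^2)
    phi <- pmax(phi, s$r - dist)
  }
  iso <- cpp_march_tets(phi, as.integer(shape), rep(pitch, 3), lo, 0)
  mesh <- surface_mesh(iso$vertices, iso$faces)

  if (spec$open_ends) {
    # cut the rounded caps: root (at p0, outward -z) and every terminal tip
    root <- segs[[1]]
    droot <- (root$p1 - root$p0) / sqrt(sum((root$p1 - root$p0)^2))
    cut <- plane_cut_mesh(mesh, root$p0 + 0.05 * root$r * droot, -droot,
                          lateral_bound = 1.6 * root$r, cap = FALSE)
    mesh <- cut$mesh
    for (s in segs) {
      if (s$gen == spec$generations) {
        d <- (s$p1 - s$p0) / sqrt(sum((s$p1 - s$p0)^2))
        cut <- plane_cut_mesh(mesh, s$p1 - 0.05 * s$r * d, d,
                              lateral_bound = 1.6 * s$r, cap = FALSE)
        mesh <- cut$mesh
      }
    }
  }
  net <- skeleton_to_network(segs, step = max(pitch, 0.5))
  list(mesh = mesh, network = net, skeleton = segs)
}

# Sample the analytic skeleton into a centerline_network (points every
# `step` mm along each segment; branch id = segment index).
skeleton_to_network <- function(segs, step = 0.5) {
  pts <- NULL; rad <- NULL; bid <- NULL; edges <- NULL
  node_key <- new.env()
  add_point <- function(p, r, b) {
    pts <<- rbind(pts, p); rad <<- c(rad, r); bid <<- c(bid, b)
    nrow(pts)
  }
  shared_node <- function(p, r, b) {
    k <- paste(round(p, 6), collapse = "|")
    if (!is.null(node_key[[k]])) return(node_key[[k]])
    id <- add_point(p, r, b)
    node_key[[k]] <- id
    id
  }
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    L <- sqrt(sum((s$p1 - s$p0)^2))
    nseg <- max(2L, ceiling(L / step) + 1L)
    t <- seq(0, 1, length.out = nseg)
    first <- shared_node(s$p0, s$r, i)
    prev <- first
    for (j in 2:(nseg - 1L)) {
      id <- add_point(s$p0 + t[j] * (s$p1 - s$p0), s$r, i)
      edges <- rbind(edges, c(prev, id)); prev <- id
    }
    last <- shared_node(s$p1, s$r, i)
    edges <- rbind(edges, c(prev, last))
  }
  deg <- tabulate(as.vector(edges), nbins = nrow(pts))
  ep <- which(deg == 1L)
  inlet <- ep[which.max(rad[ep])]
  centerline_network(pts, rad, edges, branch_id = bid,
                     endpoints = ep, inlet = inlet)
}
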