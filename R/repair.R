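#' Find non-manifold edges
#'
#' An edge is non-manifold when it is shared by more than two faces.
#' @param mesh a `surface_mesh`.
#' @return data.frame of offending edges (`v1`, `v2`, `count`).
#' @export
find_nonmanifold_edges <- function(mesh) {
  inc <- edge_incidence(mesh)
  inc[inc$count > 2L, , drop = FALSE]
}

#' Remove non-manifold structure
#'
#' Deletes every face containing at least one non-manifold edge, then drops
#' orphaned vertices. The result has edge incidence of at most two
#' everywhere (possibly with new boundary edges routed to hole filling).
#' @param mesh a `surface_mesh`.
#' @export
remove_nonmanifold <- function(mesh) {
  nm <- find_nonmanifold_edges(mesh)
  if (nrow(nm) == 0L) return(mesh)
  nv <- nrow(mesh$vertices)
  bad_keys <- edge_key(as.matrix(nm[, c("v1", "v2")]), nv)
  e <- mesh_edge_table(mesh$faces)
  keys <- matrix(edge_key(e, nv), ncol = 3)
  bad_face <- (keys[, 1] %in% bad_keys) | (keys[, 2] %in% bad_keys) |
    (keys[, 3] %in% bad_keys)
  if (all(bad_face)) stop("removing non-manifold faces empties the mesh")
  subset_faces(mesh, !bad_face)
}

#' Extract boundary loops
#'
#' Builds the graph of incidence-1 (boundary) edges and walks it into
#' closed vertex cycles. Boundary edges are traversed in the direction
#' induced by their single incident face, so each returned loop is wound
#' consistently with the surrounding surface. Open chains (non-cyclic
#' boundaries) are reported with a warning and skipped.
#' @param mesh a `surface_mesh` with edge incidence <= 2.
#' @return list of integer vertex cycles.
#' @export
boundary_loops <- function(mesh) {
  inc <- edge_incidence(mesh)
  b <- inc[inc$count == 1L, , drop = FALSE]
  if (nrow(b) == 0L) return(list())
  nv <- nrow(mesh$vertices)
  bkeys <- edge_key(as.matrix(b[, c("v1", "v2")]), nv)
  # directed boundary edges as traversed by their single face
  f <- mesh$faces
  de <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
              f[, c(3, 1), drop = FALSE])
  dkeys <- edge_key(cbind(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2])), nv)
  dirb <- de[dkeys %in% bkeys, , drop = FALSE]
  loops <- chain_loops(dirb)
  n_used <- sum(lengths(loops))
  if (n_used < nrow(dirb))
    warning("open boundary chains detected; ",
            nrow(dirb) - n_used, " boundary edges not part of any cycle")
  loops
}

# Triangulate a simple polygon given 3D loop coordinates: project onto the
# best-fit (principal-component) plane, then ear-clip; falls back to a fan
# with a warning if clipping stalls (e.g. self-intersecting projection).
triangulate_loop <- function(coords) {
  k <- nrow(coords)
  if (k == 3L) return(matrix(c(1L, 2L, 3L), ncol = 3))
  if (k == 4L) return(rbind(c(1L, 2L, 3L), c(3L, 4L, 1L)))
  ctr <- colMeans(coords)
  sv <- svd(sweep(coords, 2, ctr))
  uv <- sweep(coords, 2, ctr) %*% sv$v[, 1:2]
  # enforce counter-clockwise order in the projection
  area2 <- sum(uv[, 1] * uv[c(2:k, 1), 2] - uv[c(2:k, 1), 1] * uv[, 2])
  idx <- seq_len(k)
  if (area2 < 0) { uv <- uv[k:1, , drop = FALSE]; idx <- rev(idx) }
  tris <- matrix(0L, 0, 3)
  active <- seq_len(k)
  guard <- 0L
  cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) -
    (a[2] - o[2]) * (b[1] - o[1])
  while (length(active) > 3L && guard < k * k) {
    clipped <- FALSE
    for (ii in seq_along(active)) {
      n <- length(active)
      p <- active[(ii - 2L) %% n + 1L]
      q <- active[(ii - 1L) %% n + 1L]
      r <- active[ii %% n + 1L]
      if (cross2(uv[p, ], uv[q, ], uv[r, ]) <= 1e-12) next # reflex or flat
      others <- setdiff(active, c(p, q, r))
      inside <- FALSE
      for (o in others) {
        w1 <- cross2(uv[p, ], uv[q, ], uv[o, ])
        w2 <- cross2(uv[q, ], uv[r, ], uv[o, ])
        w3 <- cross2(uv[r, ], uv[p, ], uv[o, ])
        if (w1 >= 0 && w2 >= 0 && w3 >= 0) { inside <- TRUE; break }
      }
      if (inside) next
      tris <- rbind(tris, c(p, q, r))
      active <- setdiff(active, q)
      clipped <- TRUE
      break
    }
    guard <- guard + 1L
    if (!clipped) {
      warning("ear clipping stalled on a non-planar hole; using fan triangulation")
      n <- length(active)
      tris <- rbind(tris, cbind(active[1], active[2:(n - 1)], active[3:n]))
      active <- integer(0)
      break
    }
  }
  if (length(active) == 3L) tris <- rbind(tris, active)
  # map back to the original loop order; re-reverse orientation if the
  # projection had to be flipped to counter-clockwise
  out <- matrix(idx[tris], ncol = 3)
  if (area2 < 0) out <- out[, c(1, 3, 2), drop = FALSE]
  out
}

#' Fill boundary holes
#'
#' Each simple boundary cycle is triangulated: a 3-cycle becomes the single
#' missing triangle, a 4-cycle is split into two triangles along one
#' diagonal, and larger holes are triangulated on their best-fit plane. New
#' faces are wound so every edge they share with the existing surface is
#' traversed in the opposite direction, keeping winding consistent. Vertex
#' duplicates within `eps` are merged afterwards.
#' @param mesh a `surface_mesh` with edge incidence <= 2.
#' @param eps vertex-merge tolerance in mm (printed value 1e-6 cm = 1e-5 mm).
#' @export
fill_holes <- function(mesh, eps = 1e-5) {
  loops <- boundary_loops(mesh)
  if (!length(loops)) return(mesh)
  f <- mesh$faces
  labs <- mesh$labels
  for (lp in loops) {
    # loops arrive wound as the surrounding faces traverse them; new faces
    # must traverse shared edges in reverse
    lp <- rev(lp)
    tris <- triangulate_loop(mesh$vertices[lp, , drop = FALSE])
    newf <- matrix(lp[tris], ncol = 3)
    f <- rbind(f, newf)
    if (!is.null(labs)) labs <- c(labs, rep("wall", nrow(newf)))
  }
  out <- surface_mesh(mesh$vertices, f, labels = labs)
  merge_close_vertices(out, eps)
}

#' Merge near-duplicate vertices
#'
#' Vertices within `eps` of each other collapse to one; degenerate and
#' duplicate faces produced by the merge are dropped.
#' @param mesh a `surface_mesh`.
#' @param eps merge tolerance in mm.
#' @export
merge_close_vertices <- function(mesh, eps = 1e-5) {
  v <- mesh$vertices
  key <- paste(round(v[, 1] / eps), round(v[, 2] / eps), round(v[, 3] / eps))
  uid <- match(key, key) # first vertex of each eps-cell wins
  f <- matrix(uid[mesh$faces], ncol = 3)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 3] == f[, 1]
  fkey <- apply(f, 1, function(r) paste(sort(r), collapse = "|"))
  dup <- duplicated(fkey)
  keep <- !degen & !dup
  out <- surface_mesh(v, f[keep, , drop = FALSE],
                      labels = if (!is.null(mesh$labels)) mesh$labels[keep])
  drop_unused_vertices(out)
}

#' Enforce consistent outward winding
#'
#' Walks the face-adjacency graph from a seed face, flipping faces so that
#' every shared edge is traversed in opposite directions by its two faces,
#' then orients each closed shell so its signed volume is positive.
#' @param mesh a watertight-or-near `surface_mesh`.
#' @return list with `mesh` and `n_flipped`.
#' @export
fix_winding <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  nv <- nrow(mesh$vertices)
  e <- mesh_edge_table(f)
  keys <- edge_key(e, nv)
  fid <- rep(seq_len(m), 3L)
  ord <- order(keys)
  keys_s <- keys[ord]; fid_s <- fid[ord]
  runs <- rle(keys_s)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  adj <- vector("list", m)
  for (r in which(runs$lengths == 2L)) {
    a <- fid_s[starts[r]]; b <- fid_s[ends[r]]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  has_dir_edge <- function(face, a, b) {
    (face[1] == a && face[2] == b) || (face[2] == a && face[3] == b) ||
      (face[3] == a && face[1] == b)
  }
  shared_vertices <- function(fa, fb) intersect(fa, fb)
  visited <- logical(m)
  flipped <- logical(m)
  n_flipped <- 0L
  for (seed in seq_len(m)) {
    if (visited[seed]) next
    comp <- integer()
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      comp <- c(comp, cur)
      for (nb in adj[[cur]]) {
        if (visited[nb]) next
        sv <- shared_vertices(f[cur, ], f[nb, ])
        if (length(sv) >= 2) {
          a <- sv[1]; b <- sv[2]
          cur_dir <- has_dir_edge(f[cur, ], a, b)
          nb_dir <- has_dir_edge(f[nb, ], a, b)
          # consistent when one traverses a->b and the other b->a
          if (cur_dir == nb_dir) {
            f[nb, ] <- f[nb, c(1, 3, 2)]
            flipped[nb] <- TRUE
            n_flipped <- n_flipped + 1L
          }
        }
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    shell <- surface_mesh(mesh$vertices, f[comp, , drop = FALSE])
    if (is_watertight(shell) && mesh_volume(shell) < 0) {
      f[comp, ] <- f[comp, c(1, 3, 2)]
      n_flipped <- n_flipped + length(comp)
    }
  }
  list(mesh = surface_mesh(mesh$vertices, f, labels = mesh$labels),
       n_flipped = n_flipped)
}

#' Iteratively repair a mesh to watertightness
#'
#' Repeats \{merge duplicate vertices; remove non-manifold faces; fill
#' boundary holes\} until every edge is shared by exactly two faces, then
#' enforces consistent outward winding. Airway meshes converge in a small
#' number of iterations (the reference behavior is at most three).
#'
#' @param mesh a `surface_mesh`.
#' @param max_iter maximum repair iterations (default 10).
#' @param eps vertex-merge tolerance in mm.
#' @return list with `mesh` and `report` (class `repair_report`).
#' @export
repair_to_watertight <- function(mesh, max_iter = 10L, eps = 1e-5) {
  if (max_iter < 1L) stop("max_iter must be >= 1")
  removed_faces <- 0L; filled_holes <- 0L; merged <- 0L
  it <- 0L
  repeat {
    it <- it + 1L
    nv0 <- nrow(mesh$vertices)
    mesh2 <- merge_close_vertices(mesh, eps)
    merged <- merged + (nv0 - nrow(mesh2$vertices))
    nf0 <- nrow(mesh2$faces)
    mesh2 <- remove_nonmanifold(mesh2)
    removed_faces <- removed_faces + (nf0 - nrow(mesh2$faces))
    nloops <- length(boundary_loops(mesh2))
    if (nloops > 0) {
      mesh2 <- fill_holes(mesh2, eps)
      filled_holes <- filled_holes + nloops
    }
    mesh <- mesh2
    inc <- edge_incidence(mesh)
    done <- nrow(inc) > 0 && all(inc$count == 2L)
    if (done || it >= max_iter) break
  }
  if (!is_watertight(mesh))
    stop("repair did not converge within ", max_iter, " iterations (",
         sum(edge_incidence(mesh)$count != 2L), " irregular edges remain)")
  w <- fix_winding(mesh)
  mesh <- w$mesh
  report <- structure(list(iterations = it,
                           removed_nonmanifold_faces = removed_faces,
                           filled_holes = filled_holes,
                           merged_vertices = merged,
                           flipped_faces = w$n_flipped,
                           watertight = is_watertight(mesh),
                           manifold = is_manifold_edges(mesh),
                           volume_mm3 = mesh_volume(mesh)),
                      class = "repair_report")
  list(mesh = mesh, report = report)
}

#' @export
print.repair_report <- function(x, ...) {
  cat("<repair_report> iterations:", x$iterations,
      "| removed faces:", x$removed_nonmanifold_faces,
      "| holes filled:", x$filled_holes,
      "| merged vertices:", x$merged_vertices,
      "| flipped faces:", x$flipped_faces,
      "| watertight:", x$watertight, "\n")
  invisible(x)
}
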