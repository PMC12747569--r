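# Localized plane cut of a triangle mesh. The cut region is the connected
# patch of faces on the positive side of the plane (seeded at the face
# reaching farthest along the normal) restricted to a lateral bound around
# the plane point, so a cut near one airway opening never touches sibling
# branches. Positive-side geometry is discarded; faces straddling the plane
# are split on it; the resulting planar loop(s) can be left open or fan-
# triangulated into cap patches.
plane_cut_mesh <- function(mesh, point, normal, lateral_bound = Inf,
                           cap = TRUE, label = "cap") {
  normal <- normal / sqrt(sum(normal^2))
  v <- mesh$vertices
  rel <- sweep(v, 2, point)
  s <- as.vector(rel %*% normal)
  scale <- max(abs(s), 1)
  s[abs(s) < 1e-9 * scale] <- -1e-9 * scale
  lat <- sqrt(pmax(0, rowSums(rel^2) - s^2))
  f <- mesh$faces
  labels <- if (is.null(mesh$labels)) rep("wall", nrow(f)) else mesh$labels
  fs <- matrix(s[f], ncol = 3)
  flat <- matrix(lat[f], ncol = 3)
  cand <- (apply(fs, 1, max) > 0) & (apply(flat, 1, min) < lateral_bound)
  if (!any(cand)) stop("cut plane does not intersect the mesh within the lateral bound")

  # flood fill over edge-adjacency restricted to candidate faces
  cand_idx <- which(cand)
  sub <- subset_faces_keepmap(f, cand_idx)
  comp <- components_of_faces(sub$faces, nrow(mesh$vertices))
  seed_local <- which.max(apply(matrix(s[f[cand_idx, ]], ncol = 3), 1, max))
  region <- cand_idx[comp == comp[seed_local]]

  pos_face <- apply(fs, 1, min) > 0
  remove_idx <- intersect(region, which(pos_face))
  cross_idx <- setdiff(region, remove_idx)
  cross_idx <- cross_idx[apply(fs[cross_idx, , drop = FALSE], 1, max) > 0]

  keep_idx <- setdiff(seq_len(nrow(f)), union(remove_idx, cross_idx))
  new_v <- list()
  cut_edge_vertex <- new.env()
  nv0 <- nrow(v)
  get_cut_vertex <- function(a, b) {
    k <- paste(min(a, b), max(a, b))
    if (!is.null(cut_edge_vertex[[k]])) return(cut_edge_vertex[[k]])
    t <- s[a] / (s[a] - s[b])
    p <- v[a, ] + t * (v[b, ] - v[a, ])
    new_v[[length(new_v) + 1L]] <<- p
    id <- nv0 + length(new_v)
    cut_edge_vertex[[k]] <- id
    id
  }
  new_f <- list(); new_lab <- character(); loop_edges <- list()
  for (fi in cross_idx) {
    tri <- f[fi, ]
    pos <- s[tri] > 0
    if (sum(pos) == 1L) {
      # keep a quad on the negative side
      p <- tri[pos]; n1 <- tri[!pos][1]; n2 <- tri[!pos][2]
      # preserve original orientation: rotate so positive vertex first
      ord <- tri[order(match(tri, c(tri[pos], tri[!pos])))]
      rot <- which(tri == p)
      t2 <- c(tri, tri)[rot:(rot + 2)] # (p, a, b) in original winding
      a <- t2[2]; b <- t2[3]
      cpa <- get_cut_vertex(p, a); cbp <- get_cut_vertex(b, p)
      new_f[[length(new_f) + 1L]] <- c(cpa, a, b)
      new_f[[length(new_f) + 1L]] <- c(cpa, b, cbp)
      new_lab <- c(new_lab, labels[fi], labels[fi])
      loop_edges[[length(loop_edges) + 1L]] <- c(cbp, cpa)
    } else {
      # two positive vertices: keep the small negative-corner triangle
      nneg <- tri[s[tri] <= 0]
      rot <- which(tri == nneg)
      t2 <- c(tri, tri)[rot:(rot + 2)] # (n, a, b) original winding, a,b positive
      nvx <- t2[1]; a <- t2[2]; b <- t2[3]
      cna <- get_cut_vertex(nvx, a); cbn <- get_cut_vertex(b, nvx)
      new_f[[length(new_f) + 1L]] <- c(nvx, cna, cbn)
      new_lab <- c(new_lab, labels[fi])
      loop_edges[[length(loop_edges) + 1L]] <- c(cna, cbn)
    }
  }
  verts <- rbind(v, do.call(rbind, new_v))
  faces <- rbind(f[keep_idx, , drop = FALSE],
                 if (length(new_f)) do.call(rbind, new_f))
  labs <- c(labels[keep_idx], new_lab)
  cap_faces <- integer()
  loops <- chain_loops(do.call(rbind, loop_edges))
  if (cap && length(loops)) {
    for (lp in loops) {
      centroid <- colMeans(verts[lp, , drop = FALSE])
      verts <- rbind(verts, centroid)
      cid <- nrow(verts)
      k <- length(lp)
      fan <- cbind(cid, lp, lp[c(2:k, 1)])
      # orient cap outward (along +normal)
      e1 <- verts[fan[1, 2], ] - verts[fan[1, 1], ]
      e2 <- verts[fan[1, 3], ] - verts[fan[1, 1], ]
      if (sum(cross3(e1, e2) * normal) < 0) fan <- fan[, c(1, 3, 2)]
      cap_faces <- c(cap_faces, nrow(faces) + seq_len(nrow(fan)))
      faces <- rbind(faces, fan)
      labs <- c(labs, rep(label, nrow(fan)))
    }
  }
  out <- surface_mesh(verts, faces, labels = labs)
  out <- drop_unused_vertices(out)
  list(mesh = out, n_loops = length(loops),
       cap_label = if (cap) label else NULL)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[mesh$faces], ncol = 3), labels = mesh$labels)
}

# Face subset keeping a map back to original indices.
subset_faces_keepmap <- function(faces, idx) {
  list(faces = faces[idx, , drop = FALSE], idx = idx)
}

# Connected components of a face set via shared undirected edges.
components_of_faces <- function(faces, nv) {
  m <- nrow(faces)
  if (m <= 1) return(rep(1L, m))
  e <- rbind(faces[, c(1, 2), drop = FALSE], faces[, c(2, 3), drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  key <- (pmin(e[, 1], e[, 2]) - 1) * as.numeric(nv) + pmax(e[, 1], e[, 2])
  fid <- rep(seq_len(m), 3L)
  ord <- order(key)
  key <- key[ord]; fid <- fid[ord]
  runs <- rle(key)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  pairs <- list()
  for (r in which(runs$lengths > 1)) {
    ids <- fid[starts[r]:ends[r]]
    pairs[[length(pairs) + 1L]] <- cbind(ids[1], ids[-1])
  }
  if (!length(pairs)) return(seq_len(m))
  g <- igraph::graph_from_edgelist(do.call(rbind, pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, m - igraph::vcount(g)))
  as.integer(igraph::components(g)$membership[seq_len(m)])
}

# Chain directed boundary edges into simple closed vertex loops. The walk
# treats edges as traversable in either direction (defect regions may have
# locally inconsistent winding) and extracts a simple cycle whenever the
# walk revisits a vertex, which handles figure-eights and higher-degree
# boundary vertices; each extracted loop is then oriented by majority vote
# of the directed edges it contains.
chain_loops <- function(edges) {
  if (is.null(edges) || nrow(edges) == 0) return(list())
  ne <- nrow(edges)
  emap <- new.env()
  addinc <- function(v, ei) {
    k <- as.character(v)
    emap[[k]] <- c(emap[[k]], ei)
  }
  for (ei in seq_len(ne)) { addinc(edges[ei, 1], ei); addinc(edges[ei, 2], ei) }
  dirkey <- new.env()
  for (ei in seq_len(ne))
    dirkey[[paste(edges[ei, 1], edges[ei, 2])]] <- TRUE
  used <- rep(FALSE, ne)
  loops <- list()
  orient <- function(loop) {
    k <- length(loop)
    fwd <- sum(vapply(seq_len(k), function(i)
      isTRUE(dirkey[[paste(loop[i], loop[i %% k + 1])]]), TRUE))
    if (fwd * 2 < k) rev(loop) else loop
  }
  for (start_e in seq_len(ne)) {
    if (used[start_e]) next
    path <- c(edges[start_e, 1], edges[start_e, 2])
    used[start_e] <- TRUE
    repeat {
      cur <- path[length(path)]
      inc <- emap[[as.character(cur)]]
      inc <- inc[!used[inc]]
      if (!length(inc)) break
      ei <- inc[1]
      used[ei] <- TRUE
      nxt <- if (edges[ei, 1] == cur) edges[ei, 2] else edges[ei, 1]
      hit <- which(path == nxt)
      if (length(hit)) {
        cyc <- path[hit[length(hit)]:length(path)]
        if (length(cyc) >= 3) loops[[length(loops) + 1L]] <- orient(cyc)
        path <- path[1:hit[length(hit)]]
        if (length(path) == 1 && path[1] == nxt) {
          # walk closed fully; restart from any remaining edge
          rem <- which(!used)
          if (!length(rem)) break
          path <- c(edges[rem[1], 1], edges[rem[1], 2])
          used[rem[1]] <- TRUE
        }
      } else {
        path <- c(path, nxt)
      }
    }
  }
  loops
}
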