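#' Triangular surface mesh container
#'
#' Vertices in world millimetres and 1-based triangular face indices, with an
#' optional per-face patch label (used by the capping stage to mark
#' `wall` / `inlet` / `outlet_k` patches).
#'
#' @param vertices numeric n x 3 matrix (mm).
#' @param faces integer m x 3 matrix of vertex indices (1-based).
#' @param labels optional character/integer vector of length m.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("`vertices` must be n x 3")
  if (ncol(faces) != 3L) stop("`faces` must be m x 3")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite")
  if (!is.null(labels) && length(labels) != nrow(faces))
    stop("`labels` must have one entry per face")
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", if (!is.null(x$labels)) paste0(", ",
      length(unique(x$labels)), " patches"), "\n", sep = "")
  invisible(x)
}

# Undirected edge keys (v1 < v2) for all 3m face edges, one row per slot.
mesh_edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2), drop = FALSE],
             faces[, c(2, 3), drop = FALSE],
             faces[, c(3, 1), drop = FALSE])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

edge_key <- function(e, nv) (as.numeric(e[, 1]) - 1) * nv + as.numeric(e[, 2])

#' Edge-to-face incidence counts
#'
#' Counts, for every undirected edge of the mesh, the number of faces that
#' contain it. A closed 2-manifold has count 2 everywhere; boundary edges
#' count 1; non-manifold edges count 3 or more.
#'
#' @param mesh a `surface_mesh`.
#' @return data.frame with columns `v1`, `v2`, `count`.
#' @export
edge_incidence <- function(mesh) {
  if (nrow(mesh$faces) == 0)
    return(data.frame(v1 = integer(), v2 = integer(), count = integer()))
  e <- mesh_edge_table(mesh$faces)
  nv <- nrow(mesh$vertices)
  key <- edge_key(e, nv)
  tab <- table(key)
  k <- as.numeric(names(tab))
  data.frame(v1 = as.integer((k - 1) %/% nv + 1),
             v2 = as.integer((k - 1) %% nv + 1),
             count = as.integer(tab))
}

#' Per-face areas, normals, and enclosed volume
#'
#' `mesh_volume` uses the divergence theorem on the signed tetrahedra spanned
#' by the faces; it is positive for a consistently outward-wound closed mesh.
#' @param mesh a `surface_mesh`.
#' @return `face_areas`: numeric vector; `face_normals`: m x 3 matrix of unit
#'   normals; `mesh_volume`: scalar mm^3.
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- sqrt(rowSums(cr^2))
  nrm[nrm == 0] <- 1
  cr / nrm
}

#' @rdname face_areas
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Topological checks
#'
#' `is_watertight`: every edge shared by exactly two faces.
#' `is_manifold_edges`: no edge shared by more than two faces.
#' `euler_characteristic`: V - E + F.
#' @param mesh a `surface_mesh`.
#' @export
is_watertight <- function(mesh) {
  inc <- edge_incidence(mesh)
  nrow(inc) > 0 && all(inc$count == 2L)
}

#' @rdname is_watertight
#' @export
is_manifold_edges <- function(mesh) {
  inc <- edge_incidence(mesh)
  all(inc$count <= 2L)
}

#' @rdname is_watertight
#' @export
euler_characteristic <- function(mesh) {
  inc <- edge_incidence(mesh)
  nrow(mesh$vertices) - nrow(inc) + nrow(mesh$faces)
}

# Face connected components via shared edges; returns integer component id
# per face.
face_components <- function(mesh) {
  m <- nrow(mesh$faces)
  if (m == 0) return(integer())
  e <- mesh_edge_table(mesh$faces)
  nv <- nrow(mesh$vertices)
  key <- edge_key(e, nv)
  fid <- rep(seq_len(m), 3L)
  ord <- order(key)
  key <- key[ord]; fid <- fid[ord]
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  pairs <- list(); np <- 0L
  for (r in which(runs$lengths > 1)) {
    ids <- fid[starts[r]:ends[r]]
    np <- np + 1L
    pairs[[np]] <- cbind(ids[1], ids[-1])
  }
  if (np == 0L) return(seq_len(m))
  g <- igraph::graph_from_edgelist(do.call(rbind, pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, m - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(m)]
}

# Keep a subset of faces, dropping unreferenced vertices.
subset_faces <- function(mesh, keep) {
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[f], ncol = 3),
               labels = if (!is.null(mesh$labels)) mesh$labels[keep])
}

#' Read and write STL surface meshes
#'
#' Binary STL is the default; ASCII files are detected on read by the
#' leading `solid` keyword followed by facet records. Units are preserved
#' (mm throughout the package). STL stores no connectivity, so vertices are
#' welded on exact coordinate match at read time.
#'
#' @param path file path.
#' @param mesh a `surface_mesh`.
#' @param ascii write ASCII STL instead of binary.
#' @return `read_stl` returns a `surface_mesh`.
#' @export
write_stl <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  n <- face_normals(mesh)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid airforge", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("  outer loop", con)
      for (j in 1:3) {
        p <- v[f[i, j], ]
        writeLines(sprintf("    vertex %.9g %.9g %.9g", p[1], p[2], p[3]), con)
      }
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid airforge", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "airforge binary STL"))[1:80]
    writeBin(hdr, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    tri <- matrix(0, nrow = 12, ncol = nrow(f))
    tri[1:3, ] <- t(n)
    tri[4:6, ] <- t(v[f[, 1], , drop = FALSE])
    tri[7:9, ] <- t(v[f[, 2], , drop = FALSE])
    tri[10:12, ] <- t(v[f[, 3], , drop = FALSE])
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(tri[, i]), con, size = 4, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  }
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 512)
  is_ascii <- length(head_raw) > 10 &&
    identical(rawToChar(head_raw[1:5]), "solid") &&
    length(grepRaw("facet", head_raw)) > 0
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4])))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    xyz <- matrix(0, nrow = 3 * nf, ncol = 3)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "raw", n = 2)
      xyz[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], ncol = 3, byrow = TRUE)
    }
  }
  key <- apply(xyz, 1, function(p) paste(format(p, digits = 12), collapse = "|"))
  uid <- match(key, unique(key))
  verts <- xyz[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

# Icosphere used widely in tests and examples: subdivided icosahedron,
# radius r, centered at origin.
#' Unit icosphere
#' @param subdiv number of 4-to-1 subdivisions of the icosahedron.
#' @param r radius in mm.
#' @return a watertight `surface_mesh`.
#' @export
icosphere <- function(subdiv = 2, r = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[k]])) return(mid_cache[[k]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(4 * i - 3):(4 * i), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  surface_mesh(v, f)
}
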