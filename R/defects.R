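#' Inject controlled defects into a watertight mesh
#'
#' Produces the artifact classes that raw isosurface extraction can leave in
#' a surface mesh, so that the repair stage can be exercised with known
#' ground truth: holes (removed faces), non-manifold fins (an extra face on
#' an existing edge, making it shared by three faces), inconsistent winding
#' (reversed faces) and duplicate vertices (a shared vertex split into
#' near-coincident copies).
#'
#' @param mesh a watertight, manifold `surface_mesh`.
#' @param holes,fins,flips,duplicates number of defects of each kind.
#' @param seed integer seed; sampling is deterministic given the seed.
#' @param eps separation of duplicate-vertex copies (mm); kept below the
#'   repair stage's merge tolerance.
#' @return list with `mesh` (defective) and `manifest` (data.frame of kind,
#'   location, size).
#' @export
inject_defects <- function(mesh, holes = 0, fins = 0, flips = 0,
                           duplicates = 0, seed = 1L, eps = 5e-6) {
  if (!is_watertight(mesh) || !is_manifold_edges(mesh))
    stop("input mesh must be watertight and manifold")
  set.seed(as.integer(seed))
  nf <- nrow(mesh$faces)
  total_faces_needed <- holes + flips + fins
  if (total_faces_needed > nf)
    stop("requested defect count exceeds available faces")
  v <- mesh$vertices; f <- mesh$faces
  manifest <- list()

  pool <- sample.int(nf)
  hole_faces <- if (holes > 0) pool[seq_len(holes)] else integer()
  pool <- setdiff(pool, hole_faces)
  flip_faces <- if (flips > 0) pool[seq_len(flips)] else integer()
  pool <- setdiff(pool, flip_faces)
  fin_hosts <- if (fins > 0) pool[seq_len(fins)] else integer()

  for (fi in flip_faces) {
    f[fi, ] <- f[fi, c(1, 3, 2)]
    manifest[[length(manifest) + 1L]] <-
      data.frame(kind = "flipped_face", location = fi, size = 1)
  }
  nrm <- face_normals(surface_mesh(v, mesh$faces))
  for (fi in fin_hosts) {
    a <- f[fi, 1]; b <- f[fi, 2]
    apex <- (v[a, ] + v[b, ]) / 2 + nrm[fi, ] * 0.2 * sqrt(sum((v[a, ] - v[b, ])^2))
    v <- rbind(v, apex)
    f <- rbind(f, c(a, b, nrow(v)))
    manifest[[length(manifest) + 1L]] <-
      data.frame(kind = "nonmanifold_fin", location = fi, size = 1)
  }
  if (duplicates > 0) {
    cand <- sample(unique(as.vector(f)))
    done <- 0L
    for (vi in cand) {
      if (done >= duplicates) break
      inc <- which(apply(f == vi, 1, any))
      if (length(inc) < 2L) next
      split_set <- inc[seq_len(floor(length(inc) / 2))]
      v <- rbind(v, v[vi, ] + runif(3, -eps / 4, eps / 4))
      f[split_set, ][f[split_set, , drop = FALSE] == vi] <- nrow(v)
      manifest[[length(manifest) + 1L]] <-
        data.frame(kind = "duplicate_vertices", location = vi, size = 2)
      done <- done + 1L
    }
  }
  if (holes > 0) {
    keep <- setdiff(seq_len(nrow(f)), hole_faces)
    for (fi in hole_faces)
      manifest[[length(manifest) + 1L]] <-
        data.frame(kind = "hole", location = fi, size = 3)
    f <- f[keep, , drop = FALSE]
  }
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v)); remap[used] <- seq_along(used)
  out <- surface_mesh(v[used, , drop = FALSE], matrix(remap[f], ncol = 3))
  list(mesh = out,
       manifest = if (length(manifest)) do.call(rbind, manifest)
       else data.frame(kind = character(), location = integer(), size = numeric()))
}
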