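#' Cap specification for one airway opening
#'
#' Endpoint position, outward centerline tangent, cap radius (must cover
#' the cross-section) and prism thickness.
#' @param p_b endpoint position (mm).
#' @param n_b outward unit tangent.
#' @param r_b cap circumradius (mm).
#' @param t prism thickness (mm); the workable band is 0.1-0.5 mm.
#' @export
cap_spec <- function(p_b, n_b, r_b, t = 0.3) {
  n_b <- as.numeric(n_b)
  nn <- sqrt(sum(n_b^2))
  if (abs(nn - 1) > 1e-8) n_b <- n_b / nn
  if (r_b <= 0) stop("cap radius must be positive")
  if (t <= 0) stop("cap thickness must be positive")
  if (t < 0.1 || t > 0.5)
    warning("cap thickness outside the recommended 0.1-0.5 mm band")
  structure(list(p_b = as.numeric(p_b), n_b = n_b, r_b = r_b, t = t),
            class = "cap_spec")
}

#' Outward tangent at a centerline endpoint
#'
#' `n_b = (p_b - p_next) / ||p_b - p_next||` with `p_next` the nearest
#' neighboring centerline point; coincident neighbors are skipped.
#' @param net a [centerline_network()].
#' @param endpoint endpoint index into the network points.
#' @export
endpoint_tangent <- function(net, endpoint) {
  nbrs <- unique(c(net$edges[net$edges[, 1] == endpoint, 2],
                   net$edges[net$edges[, 2] == endpoint, 1]))
  if (!length(nbrs)) stop("endpoint has no neighbor")
  p_b <- net$points[endpoint, ]
  for (nb in nbrs) {
    d <- p_b - net$points[nb, ]
    L <- sqrt(sum(d^2))
    if (L > 1e-12) return(d / L)
  }
  # all immediate neighbors coincide; walk further along the graph
  deg2 <- unique(as.vector(net$edges))
  for (nb in setdiff(deg2, endpoint)) {
    d <- p_b - net$points[nb, ]
    L <- sqrt(sum(d^2))
    if (L > 1e-12) return(d / L)
  }
  stop("no distinct neighboring point found")
}

#' Rotation aligning the z-axis with a direction
#'
#' Rodrigues rotation `R = I + sin(theta) K + (1 - cos(theta)) K^2` with
#' `theta = acos(n_b . z)` and axis `a = z x n_b`. The antiparallel case
#' (`n_b` close to `-z`, where the axis degenerates) falls back to a
#' rotation by pi about x; near-zero angles return the identity.
#' @param n_b unit direction.
#' @return 3 x 3 rotation matrix with `R %*% z = n_b`.
#' @export
rodrigues_rotation <- function(n_b) {
  n_b <- n_b / sqrt(sum(n_b^2))
  z <- c(0, 0, 1)
  cth <- sum(n_b * z)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) return(diag(c(1, -1, -1))) # pi about x
  a <- cross3(z, n_b)
  a <- a / sqrt(sum(a^2))
  th <- acos(pmin(pmax(cth, -1), 1))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Build the hexagonal capping prism
#'
#' A closed hexagonal prism (12 vertices, 20 faces) of circumradius `r_b`
#' and thickness `t`, centered on `p_b` with its axis along `n_b` — the
#' thin quasi-cylinder subtracted from the airway at each opening.
#' @param spec a [cap_spec()].
#' @return a watertight `surface_mesh`.
#' @export
make_cap <- function(spec) {
  stopifnot(inherits(spec, "cap_spec"))
  ang <- (0:5) * pi / 3
  ring <- cbind(spec$r_b * cos(ang), spec$r_b * sin(ang), 0)
  v <- rbind(sweep(ring, 2, c(0, 0, -spec$t / 2), "+"),
             sweep(ring, 2, c(0, 0, spec$t / 2), "+"))
  f <- NULL
  for (i in 1:4) { # bottom fan (normal -z) and top fan (+z)
    f <- rbind(f, c(1, i + 2, i + 1))
    f <- rbind(f, c(7, 7 + i, 8 + i))
  }
  for (i in 0:5) { # sides
    a <- i + 1; b <- (i + 1) %% 6 + 1
    f <- rbind(f, c(a, b, 6 + b), c(a, 6 + b, 6 + a))
  }
  R <- rodrigues_rotation(spec$n_b)
  v <- sweep(v %*% t(R), 2, spec$p_b, "+")
  surface_mesh(v, f)
}

#' Cap one airway opening with a planar surface
#'
#' Subtracts the oriented capping prism from the mesh: the tip region
#' beyond the cap plane (offset half a thickness inward along the tangent,
#' so at most `t` of length is lost) and within the prism's lateral extent
#' is removed, faces straddling the plane are split on it, and the planar
#' cut loop is triangulated and labeled. Fails with diagnostics when the
#' prism does not transect the lumen.
#'
#' @param mesh a watertight (or open-ended) `surface_mesh`.
#' @param spec a [cap_spec()].
#' @param label patch label for the new cap faces.
#' @return a `surface_mesh` with labeled cap faces.
#' @export
cap_endpoint <- function(mesh, spec, label = "cap") {
  stopifnot(inherits(spec, "cap_spec"))
  # place the cut plane relative to the geometry actually present: just
  # inside an open rim (the centerline endpoint may sit a lumen radius
  # short of it), or half a thickness inside the endpoint for a closed
  # rounded tip
  rel <- sweep(mesh$vertices, 2, spec$p_b)
  s <- as.vector(rel %*% spec$n_b)
  lat2 <- pmax(rowSums(rel^2) - s^2, 0)
  if (!any(lat2 < spec$r_b^2 & abs(s) < 6 * spec$r_b))
    stop("no geometry near the endpoint within the cap radius")
  # if the endpoint owns an open rim (detected endpoints can sit up to a
  # lumen radius short of their opening), cut a thickness inside the whole
  # rim loop; for a closed rounded tip cut half a thickness inside p_b
  lateral <- spec$r_b
  r_loc <- spec$r_b / 1.5
  near_mask <- lat2 < spec$r_b^2
  smax <- max(s[near_mask & abs(s) < 6 * spec$r_b])
  # closed tip: if the end was already filled flat (face normals aligned
  # with the tangent over a substantial area) cut just inside it; for a
  # rounded dome cut deep enough that the cross-section is nearly full
  s_off <- -spec$t / 2 # default: cut at the endpoint (mid-lumen transection)
  if (smax < 2.5 * r_loc) {
    # the endpoint owns a closed tip just ahead
    fs <- matrix(s[mesh$faces], ncol = 3)
    fctr_s <- rowMeans(fs)
    flat2 <- matrix(lat2[mesh$faces], ncol = 3)
    tipf <- fctr_s > smax - 1.2 * r_loc & apply(flat2, 1, max) < spec$r_b^2
    s_off <- smax - max(0.6 * r_loc, 2 * spec$t)
    if (any(tipf)) {
      nrm <- face_normals(mesh)
      aligned <- tipf & (nrm %*% spec$n_b > 0.9)
      if (sum(face_areas(mesh)[aligned]) > 0.4 * pi * r_loc^2)
        s_off <- min(fs[aligned, ]) - spec$t
    }
  }
  loops <- boundary_loops(mesh)
  if (length(loops)) {
    score <- vapply(loops, function(lp) {
      ctd <- colMeans(mesh$vertices[lp, , drop = FALSE])
      drel <- ctd - spec$p_b
      ds <- sum(drel * spec$n_b)
      dl <- sqrt(max(sum(drel^2) - ds^2, 0))
      if (ds > -0.5 * spec$r_b && ds < 6 * spec$r_b && dl < spec$r_b)
        ds else Inf
    }, 0)
    if (any(is.finite(score))) {
      lp <- loops[[which.min(score)]]
      s_off <- min(s[lp]) - spec$t
      lateral <- max(spec$r_b, 1.1 * sqrt(max(lat2[lp])) + spec$t)
    }
  }
  ctr <- spec$p_b + s_off * spec$n_b
  cut <- plane_cut_mesh(mesh, ctr, spec$n_b, lateral_bound = lateral,
                        cap = TRUE, label = label)
  if (cut$n_loops == 0)
    stop("capping failed at endpoint (", paste(signif(spec$p_b, 4),
         collapse = ", "), "): prism does not transect the lumen")
  cut$mesh
}

#' Capped geometry with labeled patches
#'
#' @param mesh watertight labeled `surface_mesh`.
#' @param patches data.frame with per-patch label, area (mm^2), centroid
#'   and inlet flag.
#' @export
capped_geometry <- function(mesh, patches) {
  if (sum(patches$inlet) != 1L) stop("exactly one inlet patch required")
  structure(list(mesh = mesh, patches = patches), class = "capped_geometry")
}

#' @export
print.capped_geometry <- function(x, ...) {
  cat("<capped_geometry>", nrow(x$mesh$faces), "faces,",
      nrow(x$patches), "patches (",
      sum(grepl("outlet", x$patches$label)), "outlets )\n")
  invisible(x)
}

#' Cap every centerline endpoint and label patches
#'
#' Runs [cap_endpoint()] at all endpoints of the network (cap radius
#' `scale` times the local inscribed radius), retains the largest
#' connected body by enclosed volume, computes per-patch areas and
#' centroids, and assigns the inlet to the cap of largest area; remaining
#' caps become `outlet_000`, `outlet_001`, ... in decreasing area order.
#'
#' @param mesh a `surface_mesh`.
#' @param net a [centerline_network()].
#' @param scale cap radius scale over the local inscribed radius.
#' @param t cap thickness (mm).
#' @return a [capped_geometry()].
#' @export
cap_all <- function(mesh, net, scale = 1.5, t = 0.3) {
  out <- mesh
  if (is.null(out$labels)) out$labels <- rep("wall", nrow(out$faces))
  for (i in seq_along(net$endpoints)) {
    ep <- net$endpoints[i]
    # the cap must cover the local lumen; endpoints sit where the
    # inscribed radius has already started tapering toward the tip, so
    # scale the largest radius seen nearby on the endpoint's branch
    p_b <- net$points[ep, ]
    dists <- sqrt(rowSums(sweep(net$points, 2, p_b)^2))
    nearby <- dists < 5 * net$radius[ep]
    if (!is.null(net$branch_id))
      nearby <- nearby & net$branch_id == net$branch_id[ep]
    r_lumen <- max(net$radius[nearby], net$radius[ep])
    spec <- cap_spec(p_b, endpoint_tangent(net, ep),
                     r_b = scale * r_lumen, t = t)
    out <- tryCatch(cap_endpoint(out, spec, label = sprintf("cap_%03d", i)),
                    error = function(e)
                      stop("capping aborted at endpoint ", ep, ": ",
                           conditionMessage(e)))
  }
  # retain the largest body by enclosed volume
  comp <- face_components(out)
  if (max(comp) > 1L) {
    vols <- vapply(seq_len(max(comp)), function(cc)
      abs(mesh_volume(subset_faces(out, comp == cc))), 0)
    out <- subset_faces(out, comp == which.max(vols))
  }
  labs <- out$labels
  cap_names <- setdiff(unique(labs), "wall")
  if (!length(cap_names)) stop("no cap patches survived body retention")
  areas <- face_areas(out)
  fctr <- (out$vertices[out$faces[, 1], , drop = FALSE] +
             out$vertices[out$faces[, 2], , drop = FALSE] +
             out$vertices[out$faces[, 3], , drop = FALSE]) / 3
  pt <- do.call(rbind, lapply(cap_names, function(nm) {
    sel <- labs == nm
    A <- sum(areas[sel])
    ctd <- colSums(fctr[sel, , drop = FALSE] * areas[sel]) / A
    data.frame(label = nm, area_mm2 = A, cx = ctd[1], cy = ctd[2],
               cz = ctd[3], inlet = FALSE)
  }))
  ord <- order(-pt$area_mm2)
  pt <- pt[ord, ]
  pt$inlet[1] <- TRUE
  new_names <- c("inlet", sprintf("outlet_%03d", seq_len(nrow(pt) - 1) - 1))
  relabel <- setNames(new_names, pt$label)
  labs[labs != "wall"] <- relabel[labs[labs != "wall"]]
  pt$label <- new_names
  rownames(pt) <- NULL
  out$labels <- labs
  capped_geometry(out, pt)
}

#' Write capped-geometry patches as JSON (+ optional per-patch STL)
#' @param geom a [capped_geometry()].
#' @param path output JSON path.
#' @param stl_dir optional directory for one STL per patch.
#' @export
write_patches_json <- function(geom, path, stl_dir = NULL) {
  jsonlite::write_json(list(patches = geom$patches,
                            n_faces = nrow(geom$mesh$faces),
                            labels = geom$mesh$labels),
                       path, digits = NA, auto_unbox = TRUE)
  if (!is.null(stl_dir)) {
    dir.create(stl_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in unique(geom$mesh$labels)) {
      sub <- subset_faces(geom$mesh, geom$mesh$labels == nm)
      write_stl(sub, file.path(stl_dir, paste0(nm, ".stl")))
    }
  }
  invisible(path)
}
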