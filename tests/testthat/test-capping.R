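test_that("endpoint tangents follow the centerline direction", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  net <- centerline_network(pts, rep(1, 3), rbind(c(1, 2), c(2, 3)))
  expect_equal(endpoint_tangent(net, 3), c(0, 0, 1))
  expect_equal(endpoint_tangent(net, 1), c(0, 0, -1))
  # 45-degree branch on the analytic ground-truth network: within 5 degrees
  tr <- make_tube_tree(tree_spec(1, root_radius = 3, segment_length = 14,
                                 half_angle = 45, resolution = 10,
                                 open_ends = TRUE))
  gt <- tr$network
  gt_dirs <- lapply(tr$skeleton[-1], function(s)
    (s$p1 - s$p0) / sqrt(sum((s$p1 - s$p0)^2)))
  for (ep in setdiff(gt$endpoints, gt$inlet)) {
    tan <- endpoint_tangent(gt, ep)
    best <- max(vapply(gt_dirs, function(d) sum(d * tan), 0))
    expect_gt(best, cos(5 * pi / 180))
  }
  # and on the voxel-extracted network: a looser sanity bound
  net1 <- build_network(tr$mesh)
  for (ep in setdiff(net1$endpoints, net1$inlet)) {
    tan <- endpoint_tangent(net1, ep)
    best <- max(vapply(gt_dirs, function(d) sum(d * tan), 0))
    expect_gt(best, cos(30 * pi / 180))
  }
})

test_that("Rodrigues rotation maps z onto the target direction", {
  expect_equal(rodrigues_rotation(c(0, 0, 1)), diag(3))
  Rx <- rodrigues_rotation(c(1, 0, 0))
  expect_equal(as.vector(Rx %*% c(0, 0, 1)), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(t(Rx) %*% Rx, diag(3), tolerance = 1e-10)
  expect_equal(det(Rx), 1, tolerance = 1e-10)
  Rm <- rodrigues_rotation(c(0, 0, -1))
  expect_equal(as.vector(Rm %*% c(0, 0, 1)), c(0, 0, -1), tolerance = 1e-10)
  expect_equal(det(Rm), 1, tolerance = 1e-10)
  set.seed(5)
  for (i in 1:20) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    R <- rodrigues_rotation(n)
    expect_equal(as.vector(R %*% c(0, 0, 1)), n, tolerance = 1e-10)
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10)
  }
})

test_that("the capping prism is a watertight hexagonal solid", {
  sp <- cap_spec(c(1, 2, 3), c(0, 0, 1), r_b = 5, t = 0.3)
  prism <- make_cap(sp)
  expect_equal(nrow(prism$vertices), 12)
  expect_true(is_watertight(prism))
  expect_equal(euler_characteristic(prism), 2)
  vol <- abs(mesh_volume(fix_winding(prism)$mesh))
  expect_equal(vol, 3 * sqrt(3) / 2 * 25 * 0.3, tolerance = 1e-9)
  # axis along n_b: cap face normals align with the tangent
  spx <- cap_spec(c(0, 0, 0), c(1, 0, 0), 2, 0.2)
  px <- make_cap(spx)
  expect_equal(diff(range(px$vertices[, 1])), 0.2, tolerance = 1e-12)
  expect_warning(cap_spec(c(0, 0, 0), c(0, 0, 1), 1, t = 0.7), "0.1-0.5")
  expect_error(cap_spec(c(0, 0, 0), c(0, 0, 1), -1), "positive")
})

test_that("capping an open tube end yields a planar full-section cap", {
  cyl <- make_tube_tree(tree_spec(0, root_radius = 4, segment_length = 30,
                                  resolution = 14, open_ends = TRUE))
  sp <- cap_spec(c(0, 0, 27), c(0, 0, 1), r_b = 6, t = 0.3)
  capped <- cap_endpoint(cyl$mesh, sp, label = "top")
  sel <- capped$labels == "top"
  expect_true(any(sel))
  A <- sum(face_areas(capped)[sel])
  expect_lt(abs(A / (pi * 16) - 1), 0.05)
  # planarity
  vv <- unique(as.vector(capped$faces[sel, ]))
  pts <- capped$vertices[vv, , drop = FALSE]
  expect_lt(diff(range(pts[, 3])), 1e-6)
})

test_that("a mid-tube cut keeps the larger body and stays watertight", {
  tc <- make_tube_tree(tree_spec(0, root_radius = 4, segment_length = 40,
                                 resolution = 14))
  sp <- cap_spec(c(0, 0, 15), c(0, 0, -1), 6, 0.3)
  kept <- cap_endpoint(tc$mesh, sp)
  expect_true(is_watertight(kept))
  frac <- abs(mesh_volume(kept)) / abs(mesh_volume(tc$mesh))
  expect_gt(frac, 0.55) # the longer (upper) side survives
  expect_lt(frac, 0.72)
  # repeating on an already-capped endpoint trims less than t of length
  again <- cap_endpoint(kept, sp)
  expect_true(is_watertight(again))
  trimmed <- abs(mesh_volume(kept)) - abs(mesh_volume(again))
  expect_lt(trimmed, 0.3 * pi * 6^2)
})

test_that("cap_all caps every endpoint, labels one inlet, passes checks", {
  tr <- make_tube_tree(small_tree(2, open = TRUE, res = 12))
  net <- build_network(tr$mesh)
  geom <- cap_all(tr$mesh, net)
  expect_equal(nrow(geom$patches), 2^2 + 1)
  expect_equal(sum(geom$patches$inlet), 1)
  # inlet has the largest area and sits at the root
  expect_equal(which.max(geom$patches$area_mm2),
               which(geom$patches$inlet))
  expect_lt(geom$patches$cz[geom$patches$inlet], 3)
  # full meshrepair checks
  expect_true(is_watertight(geom$mesh))
  expect_true(is_manifold_edges(geom$mesh))
  expect_equal(euler_characteristic(geom$mesh), 2)
  expect_gt(mesh_volume(geom$mesh), 0)
  # cap planarity and tangent alignment
  for (nm in setdiff(unique(geom$mesh$labels), "wall")) {
    sel <- geom$mesh$labels == nm
    vv <- unique(as.vector(geom$mesh$faces[sel, ]))
    pts <- geom$mesh$vertices[vv, , drop = FALSE]
    sv <- svd(sweep(pts, 2, colMeans(pts)))
    expect_lt(max(abs(sweep(pts, 2, colMeans(pts)) %*% sv$v[, 3])), 1e-6)
  }
  # patches JSON export round-trips
  f <- tempfile(fileext = ".json")
  write_patches_json(geom, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(back$patches), nrow(geom$patches))
  unlink(f)
})
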