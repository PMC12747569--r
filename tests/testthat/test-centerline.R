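open_cyl <- function(r = 4, L = 30, res = 14)
  make_tube_tree(tree_spec(0, root_radius = r, segment_length = L,
                           resolution = res, open_ends = TRUE))

test_that("interior radius field recovers analytic inscribed radii", {
  cyl <- open_cyl()
  f <- interior_radius_field(cyl$mesh, pitch = 0.8)
  # voxels on the axis carry radius ~ 4 within one pitch
  idx <- round(sweep(matrix(c(0, 0, 15), 1), 2, f$origin) / f$pitch) + 1
  expect_lt(abs(f$radius[idx[1], idx[2], idx[3]] - 4), f$pitch + 0.1)
  # sphere: center radius ~ R
  sp <- extract_surface(ball_mask(28, 9), c(1, 1, 1))
  fs <- interior_radius_field(sp, pitch = 1)
  expect_lt(abs(max(fs$radius, na.rm = TRUE) - 9), 1.2)
  expect_error(interior_radius_field(cyl$mesh, pitch = 3), "pitch")
})

test_that("fast marching agrees with the Dijkstra oracle within 5%", {
  n <- 32
  worst <- 0
  for (seed in c(1, 7)) {
    r <- smooth_field(n, nc = 4, lo = 0.75, hi = 1.35, seed = seed)
    field <- list(radius = r, mask = array(TRUE, dim(r)),
                  spacing = c(1, 1, 1), origin = c(0, 0, 0), pitch = 1)
    ctr <- as.integer(rep(n / 2, 3))
    sol <- solve_eikonal(field, ctr, index = TRUE)
    dd <- dijkstra_arrival(r, ctr)
    far <- dd > stats::quantile(dd, 0.5)
    rel <- abs(sol$T - dd) / dd
    worst <- max(worst, max(rel[far]))
  }
  expect_lt(worst, 0.05)
})

test_that("arrival times follow unit-cost and line-integral limits", {
  # uniform speed: T is the geodesic (Euclidean in a convex box) distance
  n <- 20
  field <- list(radius = array(1, c(n, n, n)), mask = array(TRUE, c(n, n, n)),
                spacing = c(1, 1, 1), origin = c(0, 0, 0), pitch = 1)
  sol <- solve_eikonal(field, c(10L, 10L, 10L), index = TRUE, unit_speed = TRUE)
  xs <- 1:n
  ex <- sqrt(outer(outer((xs - 10)^2, (xs - 10)^2, "+"), (xs - 10)^2, "+"))
  expect_lt(max(abs(sol$T - ex)[ex > 4] / ex[ex > 4]), 0.05)
  # straight cylinder: T at the far end ~ L / r0
  cyl <- open_cyl()
  f <- interior_radius_field(cyl$mesh, pitch = 0.8)
  sol <- solve_eikonal(f, c(0, 0, 3))
  idx <- (c(0, 0, 27) - f$origin) / f$pitch
  Tend <- airforge:::trilinear(sol$T, idx)
  expect_lt(abs(Tend / (24 / 4) - 1), 0.1)
  expect_error(solve_eikonal(f, c(20, 20, 15)), "not inside")
})

test_that("gradient backtracking stays axial and reproduces the path cost", {
  cyl <- open_cyl()
  f <- interior_radius_field(cyl$mesh, pitch = 0.8)
  sol <- solve_eikonal(f, c(0, 0, 3))
  p <- backtrack_path(sol, c(0, 0, 27), f)
  expect_lt(max(sqrt(p[, 1]^2 + p[, 2]^2)), 0.8) # within one voxel of axis
  r <- attr(p, "radius")
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  cost <- sum(seg / ((r[-1] + r[-length(r)]) / 2))
  Tt <- airforge:::trilinear(sol$T, (c(0, 0, 27) - f$origin) / f$pitch)
  expect_lt(abs(cost / Tt - 1), 0.1)
  # target == source degenerates to a near-single-point path
  p0 <- backtrack_path(sol, c(0, 0, 3), f)
  expect_lte(nrow(p0), 2)
})

test_that("network construction recovers tree combinatorics and radii", {
  cyl <- open_cyl()
  net <- build_network(cyl$mesh, pitch = 1)
  expect_equal(length(net$endpoints), 2)
  expect_equal(length(unique(net$branch_id)), 1)
  expect_true(all(net$radius > 0))

  tr <- make_tube_tree(small_tree(3, open = TRUE, res = 12))
  net3 <- build_network(tr$mesh)
  expect_equal(length(net3$endpoints), 2^3 + 1) # matches boundary loops
  expect_equal(length(unique(net3$branch_id)), 2^(3 + 1) - 1)
  # the inlet is the largest-radius endpoint, at the root
  expect_equal(net3$inlet %in% net3$endpoints, TRUE)
  expect_lt(net3$points[net3$inlet, 3], 4)
  # decay 0.8: branch mean radii decrease from root branch to terminals
  root_branch <- net3$branch_id[net3$inlet]
  root_r <- mean(net3$radius[net3$branch_id == root_branch])
  term <- setdiff(net3$endpoints, net3$inlet)
  term_r <- mean(net3$radius[term])
  expect_gt(root_r, term_r)
  # every network point lies strictly inside the closed source mesh
  field <- attr(net3, "field")
  idx <- sweep(net3$points, 2, field$origin) / field$pitch
  rr <- apply(idx, 1, function(q) airforge:::trilinear(field$radius, q))
  expect_true(all(rr > 0, na.rm = TRUE))
})

test_that("endpoint positions are stable under pitch refinement", {
  cyl <- open_cyl(r = 3, L = 20, res = 12)
  n1 <- build_network(cyl$mesh, pitch = 1)
  n2 <- build_network(cyl$mesh, pitch = 0.5)
  e1 <- n1$points[n1$endpoints, , drop = FALSE]
  e2 <- n2$points[n2$endpoints, , drop = FALSE]
  for (i in seq_len(nrow(e1))) {
    dmin <- min(sqrt(rowSums(sweep(e2, 2, e1[i, ])^2)))
    expect_lt(dmin, 2 * 1) # within the coarser grid scale
  }
})

test_that("network serialization round-trips JSON and emits valid VTP XML", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), c(1, 0, 2))
  net <- centerline_network(pts, c(1, 1.1, 0.9, 0.8),
                            rbind(c(1, 2), c(2, 3), c(3, 4)),
                            branch_id = c(1L, 1L, 1L, 2L))
  fj <- tempfile(fileext = ".json")
  write_network_json(net, fj)
  back <- read_network_json(fj)
  expect_equal(back$points, net$points, ignore_attr = TRUE)
  expect_equal(back$radius, net$radius)
  expect_equal(back$edges, net$edges, ignore_attr = TRUE)
  fv <- tempfile(fileext = ".vtp")
  write_network_vtp(net, fv)
  doc <- xml2::read_xml(fv)
  expect_equal(xml2::xml_name(doc), "VTKFile")
  piece <- xml2::xml_find_first(doc, ".//Piece")
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfPoints")), 4L)
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfLines")), 3L)
  unlink(c(fj, fv))
})
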