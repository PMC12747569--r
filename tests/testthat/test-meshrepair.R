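tetra <- function() surface_mesh(
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
  rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))

test_that("edge incidence counts are exact", {
  inc <- edge_incidence(tetra())
  expect_equal(nrow(inc), 6)
  expect_true(all(inc$count == 2))
  tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                      matrix(1:3, 1))
  expect_true(all(edge_incidence(tri)$count == 1))
  d <- inject_defects(icosphere(1, 5), fins = 1, seed = 2)
  expect_equal(sum(edge_incidence(d$mesh)$count == 3), 1)
})

test_that("non-manifold edges are found and their faces removed", {
  tr <- make_tube_tree(small_tree(1, open = FALSE, res = 10))
  expect_equal(nrow(find_nonmanifold_edges(tr$mesh)), 0)
  # three triangles sharing edge AB
  m3 <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                           c(0, -1, 0)),
                     rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  nm <- find_nonmanifold_edges(m3)
  expect_equal(nrow(nm), 1)
  expect_equal(c(nm$v1, nm$v2), c(1, 2))
  # an open strip has only boundary edges, none non-manifold
  strip <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
                        rbind(c(1, 2, 3), c(2, 4, 3)))
  expect_equal(nrow(find_nonmanifold_edges(strip)), 0)
  # removal drops every face touching the shared edge; a mesh that is
  # nothing but the fan empties, which is an error
  expect_error(remove_nonmanifold(m3), "empties")
  m3b <- surface_mesh(rbind(m3$vertices, c(5, 5, 0), c(6, 5, 0), c(5, 6, 0)),
                      rbind(m3$faces, c(6, 7, 8)))
  expect_equal(nrow(remove_nonmanifold(m3b)$faces), 1)
  clean <- remove_nonmanifold(tr$mesh)
  expect_equal(clean$faces, tr$mesh$faces)
  fin <- inject_defects(icosphere(1, 5), fins = 1, seed = 3)
  rem <- remove_nonmanifold(fin$mesh)
  expect_true(all(edge_incidence(rem)$count <= 2))
})

test_that("boundary loops are closed cycles with face-consistent winding", {
  t3 <- tetra()
  open3 <- subset_faces(t3, c(TRUE, TRUE, TRUE, FALSE))
  loops <- boundary_loops(open3)
  expect_equal(length(loops), 1)
  expect_equal(length(loops[[1]]), 3)
  expect_equal(length(boundary_loops(t3)), 0)
  tr <- make_tube_tree(small_tree(3, open = TRUE, res = 10))
  expect_equal(length(boundary_loops(tr$mesh)), 9)
})

test_that("hole filling adds |h| - 2 triangles and restores watertightness", {
  t3 <- tetra()
  open3 <- subset_faces(t3, c(TRUE, TRUE, TRUE, FALSE))
  filled <- fill_holes(open3)
  expect_equal(nrow(filled$faces), 4)
  expect_true(is_watertight(filled))
  # cube with one square (4-vertex) hole: exactly two new triangles
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  cube <- surface_mesh(v, rbind(
    c(1, 3, 4), c(1, 4, 2),       # z = 0
    c(5, 6, 8), c(5, 8, 7),       # z = 1
    c(1, 2, 6), c(1, 6, 5),       # y = 0
    c(3, 7, 8), c(3, 8, 4),       # y = 1
    c(1, 5, 7), c(1, 7, 3)))      # x = 0; x = 1 face missing
  expect_equal(length(boundary_loops(cube)[[1]]), 4)
  filled <- fill_holes(cube)
  expect_equal(nrow(filled$faces), 12)
  expect_true(is_watertight(filled))
  expect_equal(abs(mesh_volume(fix_winding(filled)$mesh)), 1)
  # planar hexagonal hole: 4 new triangles
  ico <- icosphere(1, 5)
  vdeg6 <- which(tabulate(as.vector(ico$faces)) == 6)[1]
  holed <- subset_faces(ico, !apply(ico$faces == vdeg6, 1, any))
  lp <- boundary_loops(holed)
  expect_equal(length(lp[[1]]), 6)
  filled <- fill_holes(holed)
  expect_equal(nrow(filled$faces), nrow(holed$faces) + 4)
  expect_true(is_watertight(filled))
})

test_that("iterative repair converges on defect suites and is idempotent", {
  ic <- icosphere(2, 10)
  d <- inject_defects(ic, holes = 3, fins = 1, flips = 5, duplicates = 2,
                      seed = 9)
  r <- repair_to_watertight(d$mesh)
  expect_true(r$report$watertight)
  expect_true(r$report$manifold)
  expect_lte(r$report$iterations, 3)
  expect_true(all(edge_incidence(r$mesh)$count == 2))
  expect_lt(abs(mesh_volume(r$mesh) / mesh_volume(ic) - 1), 0.01)
  # a clean mesh passes through with no modifications
  r0 <- repair_to_watertight(ic)
  expect_equal(r0$report$iterations, 1)
  expect_equal(r0$report$removed_nonmanifold_faces, 0)
  expect_equal(r0$report$filled_holes, 0)
  # idempotence
  r2 <- repair_to_watertight(r$mesh)
  expect_equal(r2$report$filled_holes + r2$report$removed_nonmanifold_faces +
                 r2$report$merged_vertices, 0)
  expect_error(repair_to_watertight(ic, max_iter = 0), "max_iter")
})

test_that("repaired tube trees satisfy the closed-surface invariants", {
  tr <- make_tube_tree(small_tree(2, open = FALSE, res = 10))
  d <- inject_defects(tr$mesh, holes = 2, flips = 3, seed = 5)
  r <- repair_to_watertight(d$mesh)
  expect_true(all(edge_incidence(r$mesh)$count == 2))
  expect_equal(euler_characteristic(r$mesh), 2)
  expect_gt(mesh_volume(r$mesh), 0)
})

test_that("Taubin parameters enforce the printed stability bound", {
  p <- taubin_params(0.60, 0.635, 20)
  expect_equal(1 / p$lambda - 1 / p$nu, 0.0919, tolerance = 1e-3)
  expect_error(taubin_params(0.5, 0.9), "unstable")   # margin 0.889
  expect_error(taubin_params(0.6, 0.6), "unstable")   # margin 0
  expect_error(taubin_params(1.2, 0.9), "lambda")
})

test_that("Taubin smoothing preserves volume where Laplacian shrinks", {
  ic <- icosphere(4, 1)
  expect_equal(taubin_smooth(ic, taubin_params(n = 0))$vertices, ic$vertices)
  ts <- taubin_smooth(ic, taubin_params(0.60, 0.635, 20))
  ls <- laplacian_smooth(ic, 0.60, 20)
  v0 <- mesh_volume(ic)
  expect_lt(abs(mesh_volume(ts) / v0 - 1), 0.02)
  expect_gt(1 - mesh_volume(ls) / v0, 0.05)
  expect_true(is_watertight(ts))
  expect_equal(ts$faces, ic$faces) # connectivity unchanged
})

test_that("shape factor matches analytic values and a Heron oracle", {
  eq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
                     matrix(1:3, 1))
  expect_equal(quality_report(eq)$sq, 1, tolerance = 1e-12)
  degen <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                        matrix(1:3, 1))
  expect_equal(quality_report(degen)$sq, 0)
  expect_equal(quality_report(degen)$min_angle_deg, 0)
  ri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     matrix(1:3, 1))
  expect_equal(quality_report(ri)$sq, sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(quality_report(ri)$min_angle_deg, 45, tolerance = 1e-9)
  set.seed(31)
  for (i in 1:25) {
    pts <- matrix(rnorm(9), 3, 3)
    m <- surface_mesh(pts, matrix(1:3, 1))
    expect_equal(quality_report(m)$sq, heron_sq(pts[1, ], pts[2, ], pts[3, ]),
                 tolerance = 1e-12)
  }
})

test_that("STL round trip preserves geometry and topology", {
  ic <- icosphere(1, 7)
  for (ascii in c(FALSE, TRUE)) {
    f <- tempfile(fileext = ".stl")
    write_stl(ic, f, ascii = ascii)
    back <- read_stl(f)
    expect_equal(nrow(back$faces), nrow(ic$faces))
    expect_true(is_watertight(back))
    expect_equal(abs(mesh_volume(back)), abs(mesh_volume(ic)),
                 tolerance = 1e-5)
    unlink(f)
  }
})
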