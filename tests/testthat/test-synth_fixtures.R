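test_that("CT phantom cavities hit requested volumes and are deterministic", {
  spec <- phantom_spec(c(40, 40, 48), cavities = list(
    list(type = "tube", p0 = c(20, 20, 0), p1 = c(20, 20, 47),
         volume_cm3 = 5)), noise_sd = 10)
  ph <- make_ct_phantom(spec, seed = 11)
  # 5 cm^3 at 1 mm isotropic spacing ~ 5000 voxels within 5%
  expect_lt(abs(sum(ph$cavity_masks[[1]]) - 5000), 250)
  expect_true(all(ph$volume$values[ph$mask] < -900 + 10 * 6))
  ph2 <- make_ct_phantom(spec, seed = 11)
  expect_identical(ph$volume$values, ph2$volume$values)
  ph3 <- make_ct_phantom(spec, seed = 12)
  expect_false(identical(ph$volume$values, ph3$volume$values))
})

test_that("phantom with no cavities yields an all-false mask", {
  ph <- make_ct_phantom(phantom_spec(c(16, 16, 16)), seed = 1)
  expect_false(any(ph$mask))
  expect_equal(unique(as.vector(ph$volume$values)), 40)
})

test_that("cavities that do not fit the grid are rejected", {
  expect_error(make_ct_phantom(phantom_spec(c(16, 16, 16), cavities = list(
    list(type = "pocket", center = c(8, 8, 8), volume_cm3 = 10)))),
    "does not fit")
  expect_error(phantom_spec(c(16, 16, 16), cavities = list(
    list(type = "pocket", center = c(8, 8, 8), volume_cm3 = 1, hu = -500))),
    "below -900")
  expect_error(phantom_spec(c(16, 16, 16),
                            metal = list(list(center = c(8, 8, 8),
                                              radius_mm = 2, hu = 1500))),
    "exceed 2000")
})

test_that("closed tube trees are watertight with Euler characteristic 2", {
  for (n in 0:2) {
    tr <- make_tube_tree(small_tree(n, open = FALSE, res = 10))
    expect_true(is_watertight(tr$mesh), info = paste("n =", n))
    expect_true(is_manifold_edges(tr$mesh))
    expect_equal(euler_characteristic(tr$mesh), 2)
    expect_gt(mesh_volume(tr$mesh), 0)
  }
})

test_that("open trees expose 2^n + 1 boundary loops and scaled child radii", {
  for (n in 0:3) {
    tr <- make_tube_tree(small_tree(n, open = TRUE, res = 10))
    expect_equal(length(boundary_loops(tr$mesh)), 2^n + 1,
                 info = paste("n =", n))
  }
  tr <- make_tube_tree(tree_spec(1, root_radius = 4, radius_decay = 0.8,
                                 segment_length = 16, resolution = 10))
  child_r <- unique(vapply(tr$skeleton[-1], function(s) s$r, 0))
  expect_equal(child_r, 3.2)
})

test_that("colliding tree parameterizations are rejected", {
  expect_error(make_tube_tree(tree_spec(2, root_radius = 5, half_angle = 5,
                                        segment_length = 6, resolution = 8)),
               "collide")
})

test_that("defect injection produces exactly the manifested defects", {
  ic <- icosphere(2, 10)
  d <- inject_defects(ic, holes = 3, fins = 1, flips = 2, duplicates = 1,
                      seed = 4)
  expect_setequal(unique(d$manifest$kind),
                  c("hole", "nonmanifold_fin", "flipped_face",
                    "duplicate_vertices"))
  inc <- edge_incidence(d$mesh)
  expect_equal(sum(inc$count == 3L), 1) # exactly one fin edge
  expect_gte(length(boundary_loops(remove_nonmanifold(d$mesh))), 3)
  # zero defects leave the mesh unchanged
  d0 <- inject_defects(ic, seed = 4)
  expect_equal(d0$mesh$faces, ic$faces)
  expect_equal(nrow(d0$manifest), 0)
  expect_error(inject_defects(icosphere(0, 1), holes = 100), "exceeds")
})

test_that("probability patches tile the volume and round-trip the mask", {
  mask <- array(FALSE, c(20, 20, 12))
  mask[6:15, 6:15, 3:9] <- TRUE
  pp <- make_probability_patches(mask, patch_shape = c(12, 12, 8),
                                 overlap = 6)
  vol <- tb_reassemble(pp$patches, pp$layout)
  expect_identical(vol$values >= 0.5, mask)
  # single patch covering the volume is the identity layout
  pp1 <- make_probability_patches(mask, patch_shape = dim(mask))
  expect_equal(nrow(pp1$layout$starts), 1)
  expect_identical(array(pp1$patches[[1]] >= 0.5, dim(mask)), mask)
  expect_error(make_probability_patches(mask, patch_shape = c(12, 12, 8),
                                        overlap = 8), "smaller")
  expect_error(make_probability_patches(mask, patch_shape = c(64, 64, 64)),
               "exceeds")
  # the reference patch shape is accepted against a large enough volume
  big <- array(FALSE, c(128, 128, 64))
  expect_silent(make_probability_patches(big))
})
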