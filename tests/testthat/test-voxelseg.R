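mini_vol <- function(vals, spacing = c(1, 1, 1))
  scalar_volume(array(vals, c(8, 8, 8)), spacing)

test_that("window normalization clamps, interpolates, and is idempotent", {
  v <- mini_vol(0); w <- window_params()
  v$values[1, 1, 1] <- -1000   # below I0 -> 0
  v$values[2, 1, 1] <- -115    # at I1 -> 1
  v$values[3, 1, 1] <- -507.5  # midpoint of (-900, -115) -> 0.5
  out <- normalize_window(v, w)
  expect_equal(out$values[1, 1, 1], 0)
  expect_equal(out$values[2, 1, 1], 1)
  expect_equal(out$values[3, 1, 1], 0.5)
  expect_true(all(out$values >= 0 & out$values <= 1))
  # already-normalized input with the unit window is a fixed point
  again <- normalize_window(out, window_params(0, 1))
  expect_equal(again$values, out$values)
  # monotone in the input
  x <- seq(-1200, 200, by = 50)
  v2 <- scalar_volume(array(rep(x, length.out = 512), c(8, 8, 8)))
  y <- normalize_window(v2)$values
  expect_true(all(diff(y[order(v2$values)]) >= 0))
  expect_error(window_params(-100, -200), "I0 < I1")
})

test_that("median filter removes impulses and preserves structure", {
  v <- mini_vol(7)
  expect_equal(median_denoise(v)$values, v$values)
  v$values[4, 4, 4] <- 500 # single impulse
  expect_equal(median_denoise(v)$values[4, 4, 4], 7)
  # planar step positions preserved (rank filter oracle on a step field)
  st <- mini_vol(0)
  st$values[5:8, , ] <- 10
  ms <- median_denoise(st)$values
  expect_equal(ms, st$values)
  expect_error(median_denoise(v, 4), "odd")
  expect_error(median_denoise(v, 9), "larger than")
})

test_that("metal artifact reduction inpaints streaks and restores metal", {
  spec <- phantom_spec(c(40, 40, 16),
                       metal = list(list(center = c(28, 20, 8),
                                         radius_mm = 2.5, hu = 3000)))
  ph <- make_ct_phantom(spec, seed = 1)
  v <- ph$volume$values
  sl <- v[, , 9]
  ang <- atan2(row(sl) - 29, col(sl) - 21)
  v[, , 9] <- sl + 120 * sin(8 * ang) * (sl < 2000)
  vol <- scalar_volume(v, c(1, 1, 1))
  out <- reduce_metal_artifacts(vol, 2500, n_angles = 120)
  metal <- ph$volume$values >= 2500
  expect_identical(v >= 2500, metal) # thresholding oracle
  expect_true(all(out$values[metal] == vol$values[metal]))
  nm <- !metal[, , 9]
  expect_lt(var(out$values[, , 9][nm]), var(v[, , 9][nm]))
  expect_identical(out$values[, , 2], v[, , 2]) # streak-free slice untouched
  clean <- scalar_volume(ph$volume$values * (ph$volume$values < 2500))
  expect_identical(reduce_metal_artifacts(clean, 2500)$values, clean$values)
})

test_that("edge refinement amplifies only masked voxels by cubing", {
  z <- mini_vol(0)
  expect_equal(edge_refine(z)$values, z$values) # all-zero in, all-zero out
  # a crisp disk in one slice: voxels inside the refined edge mask get ^3
  v <- scalar_volume(array(1, c(24, 24, 8)))
  sl <- v$values[, , 4]
  disk <- (row(sl) - 12)^2 + (col(sl) - 12)^2 <= 36
  v$values[, , 4][disk] <- 0.5
  out <- edge_refine(v)
  changed <- out$values != v$values
  expect_true(any(changed))
  expect_true(all(out$values[changed] == v$values[changed]^3))
  expect_true(all(out$values[, , 4][!disk] == 1)) # untouched outside
})

test_that("Laplacian enhancement matches finite-difference oracles", {
  v <- mini_vol(3)
  expect_equal(laplacian_enhance(v)$values, v$values) # constant unchanged
  # f(x) = x^2 on unit spacing: interior enhanced value is f - 2
  q <- scalar_volume(array(rep((0:7)^2, times = 64), c(8, 8, 8)))
  out <- laplacian_enhance(q)
  expect_equal(out$values[4, 4, 4], q$values[4, 4, 4] - 2)
  # impulse of height h: center becomes h + 6h
  im <- mini_vol(0); im$values[4, 4, 4] <- 5
  expect_equal(laplacian_enhance(im)$values[4, 4, 4], 5 + 30)
})

test_that("air-cavity segmentation keeps the main body and the oral window", {
  spec <- phantom_spec(c(72, 72, 48), cavities = list(
    list(type = "tube", p0 = c(36, 36, 0), p1 = c(36, 36, 47),
         radius_mm = 9),
    list(type = "pocket", center = c(14, 14, 24), volume_cm3 = 1),
    list(type = "pocket", center = c(58, 14, 24), volume_cm3 = 5)),
    noise_sd = 15)
  ph <- make_ct_phantom(spec, seed = 2)
  ve <- laplacian_enhance(edge_refine(median_denoise(
    normalize_window(ph$volume))))
  m <- segment_air_cavities(ve)
  rep <- attr(m, "report")
  expect_equal(sum(rep$kept), 2)
  tube <- ph$cavity_masks[[1]]; p1 <- ph$cavity_masks[[2]]
  p5 <- ph$cavity_masks[[3]]
  expect_gt(mean(m[tube]), 0.95)
  expect_gt(mean(m[p5]), 0.95)
  expect_equal(sum(m & p1), 0) # 1 cm^3 isolated pocket dropped
  truth <- tube | p5
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gt(dice, 0.95)
})

test_that("all-tissue volumes give an empty mask with a warning", {
  ph <- make_ct_phantom(phantom_spec(c(16, 16, 16)), seed = 1)
  ve <- laplacian_enhance(normalize_window(ph$volume))
  expect_warning(m <- segment_air_cavities(ve), "empty mask")
  expect_false(any(m))
})

test_that("surface extraction recovers analytic geometry", {
  mask <- ball_mask(32, 10)
  s <- extract_surface(mask)
  expect_true(is_watertight(s))
  expect_lt(abs(sum(face_areas(s)) / (4 * pi * 100) - 1), 0.05)
  s1 <- extract_surface(array(c(rep(FALSE, 219), TRUE, rep(FALSE, 292)),
                              c(8, 8, 8)))
  expect_equal(euler_characteristic(s1), 2)
  # tube exiting the grid: two open boundary loops
  tm <- array(FALSE, c(24, 24, 24))
  dd <- outer((0:23 - 11.5)^2, (0:23 - 11.5)^2, "+")
  for (k in 1:24) tm[, , k] <- dd <= 36
  expect_equal(length(boundary_loops(extract_surface(tm))), 2)
  expect_error(extract_surface(array(FALSE, c(8, 8, 8))), "empty")
})

test_that("probability post-processing follows the product/threshold rules", {
  mask <- array(FALSE, c(16, 16, 16)); mask[5:12, 5:12, 5:12] <- TRUE
  pp <- make_probability_patches(mask, patch_shape = c(16, 16, 10),
                                 overlap = 4)
  vol <- tb_reassemble(pp$patches, pp$layout)
  expect_identical(vol$values >= 0.5, mask) # 1*1 = 1 in overlaps
  # overlap multiplication: 0.8 * 0.8 = 0.64
  p2 <- lapply(pp$patches, function(p) p * 0.8)
  v2 <- tb_reassemble(p2, pp$layout)
  overlap_z <- 7 # covered by both z-patches
  expect_equal(max(v2$values[, , overlap_z]), 0.64)
  expect_equal(max(v2$values[, , 2][mask[, , 2]], 0), 0)
  # lung-mask constraint zeroes exactly where HU is outside [-1000, -600]
  ct <- scalar_volume(array(0, c(16, 16, 16)))
  pr <- scalar_volume(array(0.9, c(16, 16, 16)))
  expect_true(all(tb_constrain_to_lungs(pr, ct)$values == 0))
  ct$values[] <- -800
  expect_equal(tb_constrain_to_lungs(pr, ct)$values, pr$values)
  ct$values[1:4, , ] <- -200
  out <- tb_constrain_to_lungs(pr, ct)
  expect_true(all(out$values[1:4, , ] == 0))
  expect_true(all(out$values[5:16, , ] == 0.9))
  expect_error(tb_constrain_to_lungs(pr, scalar_volume(array(0, c(8, 8, 8)))),
               "match")
})

test_that("binarization keeps the largest 26-connected component", {
  pr <- scalar_volume(array(0, c(16, 16, 16)))
  pr$values[2:6, 2:6, 2:5] <- 0.9     # 100 voxels
  pr$values[10:14, 10:14, 10:11] <- 0.9 # 50 voxels
  m <- tb_binarize_largest(pr)
  expect_equal(sum(m), 100)
  expect_true(all(m[2:6, 2:6, 2:5]))
  # exactly 0.5 is included
  pr2 <- scalar_volume(array(0, c(8, 8, 8))); pr2$values[4, 4, 4] <- 0.5
  expect_true(tb_binarize_largest(pr2)[4, 4, 4])
  # diagonal-touching voxels are one component under 26-connectivity
  pr3 <- scalar_volume(array(0, c(8, 8, 8)))
  pr3$values[3, 3, 3] <- 1; pr3$values[4, 4, 4] <- 1; pr3$values[5, 5, 5] <- 1
  expect_equal(sum(tb_binarize_largest(pr3)), 3)
  expect_warning(m0 <- tb_binarize_largest(scalar_volume(array(0, c(8, 8, 8)))),
                 "empty")
  expect_false(any(m0))
})
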