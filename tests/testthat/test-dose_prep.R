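test_that("deposition fraction follows the corrected-count formula", {
  expect_equal(deposition_fraction(50, 50, 100, 0), 0.5)
  expect_equal(deposition_fraction(50, 50, 100, 1), 1.0)
  expect_equal(deposition_fraction(30, 60, 100, 0.25), 0.45)
  expect_error(deposition_fraction(60, 60, 100, 0.5), "exceeds")
  expect_error(deposition_fraction(10, 10, 0, 0.5), "positive")
  expect_error(deposition_fraction(10, 10, 100, 1.5), "0, 1")
  # monotone in the correction and in the stuck count
  cs <- seq(0, 1, by = 0.1)
  expect_true(all(diff(vapply(cs, function(c)
    deposition_fraction(30, 60, 100, c), 0)) >= 0))
  expect_true(all(diff(vapply(0:40, function(s)
    deposition_fraction(s, 40, 100, 0.3), 0)) >= 0))
})

test_that("activity assignment is proportional to volume and conserved", {
  rec <- deposition_records(matrix(0, 3, 3), volume = c(1e-15, 0, 2e-15))
  out <- assign_activity(rec, specific_activity = 1e12, density = 1000)
  expect_equal(out$activity_bq, c(1, 0, 2))
  expect_equal(attr(out, "total_bq"), sum(out$activity_bq))
  expect_error(assign_activity(rec, specific_activity = -1), "positive")
  # diameter-volume consistency check
  expect_error(deposition_records(matrix(0, 1, 3), diameter = 1e-6,
                                  volume = 1), "inconsistent")
})

test_that("source batching honors the per-batch limit and grouping", {
  mk <- function(n) assign_activity(deposition_records(
    matrix(seq_len(3 * n), n, 3), volume = rep(1e-15, n)))
  expect_equal(n_source_batches(1154, 500, dual_decay = TRUE), 5)
  expect_equal(n_source_batches(500, 500, dual_decay = FALSE), 1)
  expect_equal(n_source_batches(501, 500, dual_decay = FALSE), 2)
  b <- batch_sources(mk(1154), dual_decay = TRUE)
  expect_equal(length(b), 5)
  expect_true(all(vapply(b, nrow, 0) <= 500))
  # both sources of each particle share a batch; union = input; disjoint
  all_rows <- do.call(rbind, b)
  expect_equal(nrow(all_rows), 2 * 1154)
  key <- paste(all_rows$x, all_rows$y, all_rows$z)
  tab <- table(key)
  expect_true(all(tab == 2))
  per_particle_batches <- tapply(all_rows$batch, key, function(x)
    length(unique(x)))
  expect_true(all(per_particle_batches == 1))
  # activity conserved across batching
  expect_equal(sum(all_rows$activity_bq), 2 * 1154 * 1e-15 * 1e12 * 1000)
  # minimal batch count for the grouping constraint
  expect_equal(length(batch_sources(mk(500))), 1)
  expect_equal(length(batch_sources(mk(501))), 2)
})

test_that("carina-referenced alignment is a rigid isometry", {
  set.seed(8)
  pts <- matrix(rnorm(60, sd = 20), 20, 3)
  # identical frames: identity
  a0 <- align_to_reference(pts, c(0, 0, 0), c(0, 0, 0),
                           c(0, 0, 1), c(0, 0, 1))
  expect_equal(a0$points, pts, tolerance = 1e-12)
  # pure translation
  a1 <- align_to_reference(pts, c(0, 0, 0), c(10, 0, 0),
                           c(0, 0, 1), c(0, 0, 1))
  expect_equal(a1$points, sweep(pts, 2, c(10, 0, 0), "+"), tolerance = 1e-12)
  # 90-degree axis mismatch: axis aligned, distances preserved
  a2 <- align_to_reference(pts, c(1, 2, 3), c(-5, 0, 7),
                           c(0, 0, 1), c(1, 0, 0))
  expect_equal(as.vector(a2$transform$rotation %*% c(0, 0, 1)), c(1, 0, 0),
               tolerance = 1e-10)
  d_in <- as.matrix(dist(pts)); d_out <- as.matrix(dist(a2$points))
  expect_lt(max(abs(d_out - d_in) / pmax(d_in, 1e-12)), 1e-9)
  R <- a2$transform$rotation
  expect_equal(t(R) %*% R, diag(3), tolerance = 1e-10)
  expect_error(align_to_reference(pts, c(0, 0, 0), c(0, 0, 0),
                                  c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("correction tables interpolate over aerodynamic diameter", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(diameter_um = c(0.1, 1, 10),
                       correction = c(0.5, 0.2, 0.4)), f, row.names = FALSE)
  corr <- load_correction_table(f)
  expect_equal(corr(1), 0.2)
  expect_equal(corr(5.5), 0.3)
  expect_equal(corr(100), 0.4) # constant extrapolation
  unlink(f)
})

test_that("source batches export as plain text with a manifest", {
  rec <- assign_activity(deposition_records(matrix(rnorm(30), 10, 3),
                                            volume = rep(1e-15, 10)))
  b <- batch_sources(rec, max_sources = 8, dual_decay = TRUE)
  f <- tempfile(fileext = ".txt")
  write_source_batches(b, f)
  tab <- read.table(f, header = TRUE)
  expect_equal(nrow(tab), 20)
  man <- jsonlite::read_json(paste0(f, ".manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(sum(man$n_sources), 20)
  unlink(c(f, paste0(f, ".manifest.json")))
})
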