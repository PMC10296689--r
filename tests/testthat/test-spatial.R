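test_that("nearest-neighbour distances match hand geometry", {
  expect_equal(nearest_neighbour_distances(cbind(0, 0), cbind(3, 4)), 5)
  d <- nearest_neighbour_distances(rbind(c(0, 0), c(10, 0)),
                                   rbind(c(0, 1), c(14, 3)))
  expect_equal(d, c(1, 5))
  expect_equal(mean(d), 3)
})

test_that("radius counts use an inclusive boundary and handle empty sets", {
  res <- count_within_radius(cbind(0, 0), cbind(c(29.9, 30, 30.1), c(0, 0, 0)))
  expect_identical(res$counts, 2L)
  empty <- count_within_radius(rbind(c(0, 0), c(1, 1)), cbind(numeric(0), numeric(0)))
  expect_identical(empty$counts, c(0L, 0L))
  expect_identical(empty$mean, 0)
  expect_warning(nnd <- nearest_neighbour_distances(cbind(0, 0),
                                                    cbind(numeric(0), numeric(0))),
                 "not computable")
  expect_null(nnd)
  expect_warning(out <- nearest_neighbour_distances(cbind(numeric(0), numeric(0)),
                                                    cbind(0, 0)),
                 "empty reference")
  expect_identical(out, numeric(0))
})

test_that("grid-accelerated search equals the exhaustive oracle exactly on random instances", {
  set.seed(101)
  for (i in 1:50) {
    nr <- sample(5:250, 1); nt <- sample(1:250, 1)
    ref <- cbind(runif(nr, 0, 800), runif(nr, 0, 800))
    tgt <- cbind(runif(nt, 0, 800), runif(nt, 0, 800))
    radius <- runif(1, 10, 60)
    cfg <- spatial_config(radius = radius)
    expect_equal(nearest_neighbour_distances(ref, tgt, method = "grid"),
                 oracle_nnd(ref, tgt), tolerance = 0)
    expect_equal(count_within_radius(ref, tgt, cfg, method = "grid")$counts,
                 oracle_count(ref, tgt, radius), tolerance = 0)
    expect_equal(nearest_neighbour_distances(ref, tgt, method = "exhaustive"),
                 oracle_nnd(ref, tgt), tolerance = 0)
  }
})

test_that("metrics are translation-invariant, monotone in radius, and NND/count are consistent", {
  set.seed(55)
  ref <- cbind(runif(120, 0, 500), runif(120, 0, 500))
  tgt <- cbind(runif(80, 0, 500), runif(80, 0, 500))
  shift <- c(1234.5, -987.6)
  ref2 <- sweep(ref, 2, -shift)
  tgt2 <- sweep(tgt, 2, -shift)
  nnd <- nearest_neighbour_distances(ref, tgt)
  expect_equal(nearest_neighbour_distances(ref2, tgt2), nnd, tolerance = 1e-9)
  radii <- c(10, 30, 60, 120)
  means <- vapply(radii, function(r) {
    count_within_radius(ref, tgt, spatial_config(radius = r))$mean
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  for (r in radii) {
    counts <- count_within_radius(ref, tgt, spatial_config(radius = r))$counts
    expect_identical(counts >= 1L, nnd <= r)
  }
})

test_that("patient summary pools ROIs, never matches cells across ROIs, and flags non-computable patients", {
  a <- make_cells(roi_id = "R1", x = c(0, 10, 0, 14), y = c(0, 0, 1, 3),
                  profile = c("TUMOUR_CELL", "TUMOUR_CELL", "TREG", "TREG"))
  s <- patient_spatial_summary(a, "TREG")
  expect_equal(s$mean_nnd_um, 3)       # the 1.0 / 5.0 hand example
  expect_true(s$computable)

  # a second ROI with a far-away Treg: pooling = concatenation of per-ROI results
  b <- make_cells(roi_id = "R2", x = c(0, 3), y = c(0, 4),
                  profile = c("TUMOUR_CELL", "TREG"))
  both <- rbind(a, b)
  s2 <- patient_spatial_summary(both, "TREG")
  expect_equal(s2$mean_nnd_um, mean(c(1, 5, 5)))
  expect_equal(s2$n_tumour_cells, 3L)
  # cross-ROI distances are not used: R2's tumour cell sits at the same
  # coordinates as an R1 Treg yet its NND is 5, not 0 (checked above)

  none <- make_cells(x = c(0, 5), y = c(0, 5),
                     profile = c("TUMOUR_CELL", "CD8_T"))
  s3 <- patient_spatial_summary(none, "TREG")
  expect_false(s3$computable)
  expect_true(is.na(s3$mean_nnd_um))
  expect_equal(s3$mean_count_within_radius, 0)
})
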