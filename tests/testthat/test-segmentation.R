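test_that("threshold of an isolated hot voxel returns exactly that voxel", {
  g <- voxel_grid(c(8, 8, 8), 4)
  v <- array(0, c(8, 8, 8)); v[4, 5, 6] <- 100
  voi <- threshold_voi(v, 0.5, g)
  expect_equal(sum(voi$mask), 1L)
  expect_true(voi$mask[4, 5, 6])
  expect_equal(voi$threshold_fraction, 0.5)
})

test_that("threshold VOI equals the flood-fill oracle on a blurred blob", {
  ph <- mini_phantom()
  v <- ph$series$volumes[[2]]
  search <- lesion_search_region(ph$anatomy, "lesion_1")
  voi <- threshold_voi(v, 0.42, ph$series$grid, search_region = search)
  vals <- ifelse(search$mask, v, -Inf)
  expected <- flood26_oracle(array(vals >= 0.42 * max(vals), dim(v)),
                             which.max(vals))
  expect_identical(voi$mask, expected)
})

test_that("superlevel sets nest: volume is non-increasing in the fraction", {
  ph <- mini_phantom()
  v <- ph$series$volumes[[1]]
  search <- lesion_search_region(ph$anatomy, "lesion_1")
  vols <- vapply(c(0.10, 0.25, 0.42, 0.60, 0.75), function(f)
    voi_volume_ml(threshold_voi(v, f, ph$series$grid, search_region = search)),
    numeric(1))
  expect_true(all(diff(vols) <= 1e-12))
})

test_that("threshold rejects bad fractions and zero signal", {
  g <- voxel_grid(c(4, 4, 4), 4)
  z <- array(0, c(4, 4, 4))
  expect_error(threshold_voi(z + 1, 0, g), "fraction")
  expect_error(threshold_voi(z + 1, 1, g), "fraction")
  expect_error(threshold_voi(z, 0.5, g), "no signal")
})

test_that("propagation of an identical volume is the identity", {
  ph <- mini_phantom()
  v <- ph$series$volumes[[2]]
  search <- lesion_search_region(ph$anatomy, "lesion_1")
  src <- threshold_voi(v, 0.4, ph$series$grid, search_region = search)
  prop <- propagate_voi(src, v, v)
  expect_identical(prop$mask, src$mask)
  expect_equal(prop$method, "threshold_propagated")
})

test_that("propagation recovers a constructed integer translation", {
  ph <- mini_phantom()
  v <- ph$series$volumes[[2]]
  d <- dim(v)
  tgt <- array(0, d)
  tgt[3:d[1], , ] <- v[1:(d[1] - 2), , ]  # shift +2 along axis 1
  search <- lesion_search_region(ph$anatomy, "lesion_1")
  src <- threshold_voi(v, 0.4, ph$series$grid, search_region = search)
  prop <- propagate_voi(src, v, tgt)
  shifted <- array(FALSE, d)
  shifted[3:d[1], , ] <- src$mask[1:(d[1] - 2), , ]
  expect_identical(prop$mask, shifted)
  # no reshaping: voxel count preserved
  expect_equal(sum(prop$mask), sum(src$mask))
})

test_that("propagation near the grid edge never reshapes the mask", {
  g <- voxel_grid(c(10, 10, 10), 4)
  v <- array(0, c(10, 10, 10)); v[2, 5, 5] <- 10
  src <- threshold_voi(v, 0.5, g)
  tgt <- array(0, c(10, 10, 10)); tgt[1, 5, 5] <- 1e6
  prop <- propagate_voi(src, v, tgt)
  expect_equal(sum(prop$mask), 1L)
  expect_true(prop$mask[1, 5, 5])
})

test_that("sphere VOI voxel counts behave analytically", {
  g <- voxel_grid(c(32, 32, 32), 4)
  ctr <- c(62, 62, 62)  # a voxel centre (odd multiples of 2 are centres)
  expect_equal(sum(sphere_voi(c(60, 60, 60), 1.5, g)$mask), 1L)
  for (r in c(20, 24, 30)) {
    v <- voi_volume_ml(sphere_voi(ctr, r, g))
    expect_lt(abs(v - 4 / 3 * pi * r^3 / 1000) / (4 / 3 * pi * r^3 / 1000),
              0.15)
  }
  expect_gt(sum(sphere_voi(ctr, 20, g)$mask), sum(sphere_voi(ctr, 10, g)$mask))
  expect_error(sphere_voi(c(500, 500, 500), 5, g), "no voxel centres")
  expect_error(sphere_voi(ctr, -1, g), "radius")
})

test_that("combine_voi implements set algebra with inclusion-exclusion", {
  g <- voxel_grid(c(16, 16, 16), 4)
  a <- sphere_voi(c(28, 30, 30), 12, g)
  b <- sphere_voi(c(40, 30, 30), 12, g)
  empty <- new_voi(g, array(FALSE, c(16, 16, 16)))
  expect_identical(combine_voi(a, empty, "union")$mask, a$mask)
  expect_equal(sum(combine_voi(a, a, "difference")$mask), 0L)
  inter <- sum(a$mask & b$mask)
  expect_equal(sum(combine_voi(a, b, "union")$mask),
               sum(a$mask) + sum(b$mask) - inter)
  g2 <- voxel_grid(c(16, 16, 16), 2)
  expect_error(combine_voi(a, sphere_voi(c(14, 15, 15), 6, g2), "union"),
               "grid")
})

test_that("mass estimation follows volume, density and strategy contracts", {
  g <- voxel_grid(c(10, 10, 10), 4)
  v <- array(0, c(10, 10, 10)); v[1:4, 1:5, 1:5] <- 1  # 100 voxels
  voi <- new_voi(g, v > 0)
  m <- estimate_mass(voi, "spect_variable")
  expect_equal(m$mass_g, 6.4)
  expect_equal(estimate_mass(voi, "spect_variable",
                             density_g_per_ml = 1.05)$mass_g, 6.4 * 1.05)
  # ct_constant ignores the per-time VOIs entirely
  small <- new_voi(g, array(c(TRUE, rep(FALSE, 999)), c(10, 10, 10)))
  m1 <- estimate_mass(list(voi, voi), "ct_constant", reference_voi = voi)
  m2 <- estimate_mass(list(small, small), "ct_constant", reference_voi = voi)
  expect_equal(m1$mass_g, m2$mass_g)
  expect_length(m1$mass_g, 1L)
  # averaging mode collapses per-time masses
  m3 <- estimate_mass(list(voi, small), "spect_variable", average = TRUE)
  expect_equal(m3$mass_g, mean(c(6.4, 0.064)))
  expect_error(estimate_mass(list(voi), "ct_constant"), "reference_voi")
  emptyv <- new_voi(g, array(FALSE, c(10, 10, 10)))
  expect_error(estimate_mass(list(emptyv), "spect_variable"), "zero mass")
})
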