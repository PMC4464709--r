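test_that("all five canonical phantoms are calibrated to their target volumes", {
  ph <- canonical_phantoms()
  targets <- c(oval_big = 54, oval_small = 51, oval_oblique = 61,
               spherical = 55, curved = 70)
  for (nm in names(ph)) {
    expect_equal(reference_volume(ph[[nm]]), unname(targets[nm]), tolerance = 2e-3)
    # independent voxel-integration oracle
    expect_equal(phantom_voxel_volume(ph[[nm]], step = 0.5),
                 unname(targets[nm]), tolerance = 2e-3)
  }
  # sphere radius closed form
  expect_equal(make_phantom("sphere", 55)$semi_axes[1],
               (3 * 55000 / (4 * pi))^(1 / 3), tolerance = 1e-9)
  expect_error(make_phantom("sphere", -5), class = "atriarecon_phantom_error")
  expect_error(make_phantom("curved", 70, bend_radius = 10),
               class = "atriarecon_phantom_error")
})

test_that("plane sections match analytic cross-sections and converge quadratically", {
  sp <- make_phantom("sphere", 55)
  r <- sp$semi_axes[1]
  pl <- flat_plane(0)
  uv <- contour_to_plane_mm(slice_phantom(sp, pl), pl)
  expect_equal(polygon_area(uv), pi * r^2, tolerance = 0.005)
  pl10 <- flat_plane(10)
  uv10 <- contour_to_plane_mm(slice_phantom(sp, pl10), pl10)
  expect_equal(sqrt(polygon_area(uv10) / pi), sqrt(r^2 - 100), tolerance = 0.005)
  expect_null(slice_phantom(sp, flat_plane(30)))
  # O(step^2) area convergence
  errs <- sapply(c(2, 1, 0.5), function(h) {
    pts <- slice_phantom(sp, pl, sample_step = h)
    abs(polygon_area(contour_to_plane_mm(pts, pl)) - pi * r^2)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], errs[1] / 8) # at least ~quadratic
})

test_that("strategy datasets carry ground truth and are seed-deterministic", {
  ph <- make_phantom("oval", 54)
  d1 <- generate_strategy(ph, 1, noise_mm = 0.5, seed = 7)
  d2 <- generate_strategy(ph, 1, noise_mm = 0.5, seed = 7)
  expect_identical(d1$points, d2$points)
  d3 <- generate_strategy(ph, 1, noise_mm = 0.5, seed = 8)
  expect_false(identical(d1$points, d3$points))
  gt <- dataset_ground_truth(d1)
  expect_equal(gt$reference_volume_ml, 54)
  expect_equal(gt$strategy, "A1")
  expect_equal(gt$noise_mm, 0.5)
  expect_equal(nrow(d1), 5)
  expect_setequal(d1$plane_id, c("LAX1", "LAX2", "SAX1", "SAX2", "SAX3"))
})

test_that("strategy rows map to the alignment/perpendicularity flags", {
  s1 <- slice_strategy(1); s2 <- slice_strategy(2); s3 <- slice_strategy(3)
  expect_true(s1$long_axis_aligned && s1$short_axis_perpendicular)
  expect_true(s2$long_axis_aligned && !s2$short_axis_perpendicular)
  expect_true(!s3$long_axis_aligned && s3$short_axis_perpendicular)
  expect_equal(s3$misalign_deg, 25)
  expect_equal(s2$tilt_deg, 20)
  expect_error(slice_strategy(4), class = "atriarecon_phantom_error")
})

test_that("cine phantoms track the prescribed curve and its analytic indices", {
  sp <- make_phantom("sphere", 55)
  cds <- generate_cine_phantom(sp, 82.6, 43.6, 64.4, n_frames = 16, seed = 5)
  gt <- dataset_ground_truth(cds)
  expect_equal(max(gt$curve$volumes), 82.6)
  expect_equal(min(gt$curve$volumes), 43.6)
  expect_equal(gt$curve$volumes[gt$curve$i_pre_a + 1], 64.4)
  expect_equal(gt$indices$total_emptying, 39)
  expect_equal(gt$indices$total_ef, 100 * 39 / 82.6)
  expect_equal(length(unique(cds$frame)), 16)
  # same plane set on every frame
  expect_equal(length(dataset_planes(cds)), 5)
  expect_error(generate_cine_phantom(sp, 80, -1, 50), class = "atriarecon_phantom_error")
  expect_error(generate_cine_phantom(sp, 80, 40, 60, n_frames = 4),
               class = "atriarecon_phantom_error")
})
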