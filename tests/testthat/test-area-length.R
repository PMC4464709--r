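test_that("chamber length is the maximal distance from the mitral landmark", {
  circ <- circle_contour(10, 256)
  expect_equal(la_length(circ, c(-10, 0)), 20, tolerance = 0.05)
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  ell <- cbind(30 * cos(th), 20 * sin(th))
  expect_equal(la_length(ell, c(-30, 0)), 60, tolerance = 0.05)
  expect_error(la_length(circ, c(0, 0)), class = "atriarecon_landmark_error")
})

test_that("bi-plane area-length volume follows the 0.848 formula", {
  # ellipsoid (30, 25, 20) mm sliced through its axes
  expect_equal(biplane_volume(pi * 30 * 25, pi * 30 * 20, 60, 60),
               62.77, tolerance = 1e-3)
  # sphere r = 20 mm
  expect_equal(biplane_volume(pi * 400, pi * 400, 40, 40), 33.48, tolerance = 1e-2)
  expect_error(biplane_volume(0, 100, 10, 10), class = "atriarecon_geometry_error")
  expect_error(biplane_volume(10, 10, 0, 0), class = "atriarecon_geometry_error")
})

test_that("for axis-sliced ellipsoids the formula is exactly 0.848/(8/3pi) of truth", {
  for (ax in list(c(30, 25, 20), c(40, 22, 18), c(25, 25, 25))) {
    v <- biplane_volume(pi * ax[1] * ax[2], pi * ax[1] * ax[3], 2 * ax[1], 2 * ax[1])
    truth <- 4 / 3 * pi * prod(ax) / 1000
    expect_equal(v / truth, 0.848 / (8 / (3 * pi)), tolerance = 1e-12)
  }
})

test_that("misaligned long-axis planes break the model but not the reconstruction", {
  ph <- make_phantom("oblique_oval", 61)
  ref <- reference_volume(ph)
  d1 <- generate_strategy(ph, 1)
  d3 <- generate_strategy(ph, 3)
  al1 <- area_length_volume(d1)$volume_ml
  al3 <- area_length_volume(d3)$volume_ml
  expect_gt(abs(al3 - ref) / ref, 0.05)          # model collapses off-axis
  expect_lt(abs(al1 - ref) / ref, 0.05)          # but is fine on-axis
  cfg <- recon_config(grid_mm = 1.5)
  r1 <- reconstruct_frame(d1, config = cfg)$volume_ml
  r3 <- reconstruct_frame(d3, config = cfg)$volume_ml
  expect_lt(abs(r3 - r1) / ref, 0.02)            # reconstruction does not care
})

test_that("dataset-level area-length uses the stored mitral landmark", {
  ds <- generate_strategy(make_phantom("sphere", 55), 1)
  out <- area_length_volume(ds)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$volume_ml, 55 * 0.848 / (8 / (3 * pi)), tolerance = 0.01)
  expect_equal(out$length_a, 2 * 23.59, tolerance = 0.3)
})
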