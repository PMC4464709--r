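test_that("mask tracing recovers a disk area at subpixel accuracy", {
  xy <- mask_to_contour(disk_mask(101, 51, 20))
  expect_equal(polygon_area(xy), pi * 400, tolerance = 0.01)
  expect_gt(nrow(xy), 20)
})

test_that("mask tracing enforces the component policy", {
  expect_error(mask_to_contour(matrix(0, 10, 10)), class = "atriarecon_contour_error")
  m <- matrix(0, 61, 61)
  m[(row(m) - 20)^2 + (col(m) - 20)^2 <= 100] <- 1
  m[(row(m) - 48)^2 + (col(m) - 48)^2 <= 25] <- 1
  expect_error(mask_to_contour(m, "error_if_multiple"), "2")
  xy <- mask_to_contour(m, "largest")
  expect_equal(polygon_area(xy), pi * 100, tolerance = 0.05)
})

test_that("smoothing is periodic, shape-preserving and reduces noise", {
  pts <- circle_contour(50, 128, c(50, 50))
  # a smooth closed curve is essentially a fixed point under auto smoothing
  sm <- smooth_contour(pts)
  expect_equal(dim(sm), dim(pts))
  expect_lt(max(sqrt(rowSums((sm - pts)^2))), 0.05)
  # zero smoothing is the identity
  expect_identical(smooth_contour(pts, smoothing = 0), pts)
  # seeded vertex noise: radial RMS against the true circle must shrink
  set.seed(7)
  noisy <- pts + matrix(rnorm(256, 0, 1), ncol = 2)
  rms <- function(p) sqrt(mean((sqrt(rowSums(sweep(p, 2, c(50, 50))^2)) - 50)^2))
  expect_lt(rms(smooth_contour(noisy)), rms(noisy))
  expect_error(smooth_contour(pts, closed = FALSE), class = "atriarecon_contour_error")
  expect_error(smooth_contour(pts[1:5, ]), class = "atriarecon_contour_error")
})

test_that("shoelace area matches closed forms and ignores orientation", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1)
  ngon <- circle_contour(10, 360)
  expect_equal(polygon_area(ngon), 0.5 * 360 * 100 * sin(2 * pi / 360))
  expect_equal(polygon_area(ngon), pi * 100, tolerance = 1e-3)
  # anisotropic pixel spacing scales the area
  expect_equal(polygon_area(sq, spacing = c(2, 3)), 6)
  expect_error(polygon_area(sq[1:2, ]), class = "atriarecon_contour_error")
})

test_that("signed distance is positive inside, negative outside, zero on vertices", {
  cc <- circle_contour(10, 256)
  expect_equal(signed_distance_2d(cc, c(0, 0)), 10, tolerance = 0.01)
  expect_equal(signed_distance_2d(cc, c(15, 0)), -5, tolerance = 0.01)
  expect_equal(signed_distance_2d(cc, cc[17, ]), 0)
  expect_error(signed_distance_2d(cc[1:2, ], c(0, 0)), class = "atriarecon_contour_error")
})

test_that("signed distance is 1-Lipschitz and changes sign once along a ray", {
  cc <- circle_contour(10, 128)
  tt <- seq(0, 25, by = 0.1)
  for (ang in c(0.3, 1.2, 2.8)) {
    q <- cbind(tt * cos(ang), tt * sin(ang))
    sd <- signed_distance_2d(cc, q)
    expect_lte(max(abs(diff(sd))), 0.1 + 1e-9)
    expect_equal(sum(diff(sign(sd)) != 0), 1)
  }
})

test_that("arc-length resampling preserves the polygon", {
  cc <- circle_contour(10, 37)
  rs <- resample_contour(cc, 256)
  expect_equal(nrow(rs), 256)
  expect_equal(polygon_area(rs), polygon_area(cc), tolerance = 1e-3)
})
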