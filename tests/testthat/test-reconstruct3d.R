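# contour in fractional pixels of flat_plane(z): circle radius r mm at centre
px_circle <- function(plane, r = 10, n = 64) {
  cc <- circle_contour(r, n)
  u <- cc[, 1] - plane$origin[1]
  v <- cc[, 2] - plane$origin[2]
  cbind(v / plane$spacing[1], u / plane$spacing[2])
}

test_that("plane fields carry the inside/outside indicator with the contour as zero set", {
  pl <- flat_plane(0)
  ctr <- px_circle(pl, 10)
  fb <- build_plane_field(pl, ctr, mode = "binary")
  # centre inside -> +1; 15 mm out -> -1 (queried through the interpolant on-plane)
  expect_equal(interpolate_indicator(list(fb), c(0, 0, 0)), 1)
  expect_equal(interpolate_indicator(list(fb), c(15, 0, 0)), -1)
  fs <- build_plane_field(pl, ctr, tau = 3)
  # clamped signed distance: 1.5 mm inside the wall -> +0.5
  expect_equal(interpolate_indicator(list(fs), c(8.5, 0, 0)), 0.5, tolerance = 0.05)
  # on the contour the field vanishes within a sampling step
  expect_lt(abs(interpolate_indicator(list(fs), c(10, 0, 0))), 1 / 3 + 0.05)
  expect_error(build_plane_field(pl, ctr, sample_step = 5),
               class = "atriarecon_geometry_error")
  expect_error(build_plane_field(pl, ctr[1:2, ]), class = "atriarecon_geometry_error")
})

test_that("projection interpolation reproduces plane fields on-slice and blends symmetrically", {
  p0 <- flat_plane(0, "A"); p1 <- flat_plane(10, "B")
  f0 <- build_plane_field(p0, px_circle(p0, 20))
  f1 <- build_plane_field(p1, px_circle(p1, 20))
  # exactly on plane A the blend equals plane A's field
  expect_equal(interpolate_indicator(list(f0, f1), c(0, 0, 0)), 1)
  expect_equal(interpolate_indicator(list(f0, f1), c(0, 0, 1e-8)), 1)
  # equal constant fields blend to themselves anywhere between
  expect_equal(interpolate_indicator(list(f0, f1), c(0, 0, 5)), 1)
  # antisymmetric fields cancel at the midpoint
  f1n <- f1; f1n$values <- -f1$values
  expect_equal(interpolate_indicator(list(f0, f1n), c(0, 0, 5)), 0)
  expect_error(interpolate_indicator(list(), c(0, 0, 0)),
               class = "atriarecon_geometry_error")
})

test_that("indicator grids are positive at the centroid and forced negative at the boundary", {
  ds <- generate_strategy(make_phantom("sphere", 55), 1)
  planes <- dataset_planes(ds)
  fields <- lapply(seq_len(nrow(ds)), function(i)
    build_plane_field(planes[[ds$plane_id[i]]], ds$points[[i]]))
  g <- evaluate_grid(fields, spacing = 2)
  A <- g$values
  ctr <- dim(A) %/% 2
  expect_gt(A[ctr[1], ctr[2], ctr[3]], 0)
  expect_true(all(A[c(1, dim(A)[1]), , ] == -1))
  expect_true(all(A[, c(1, dim(A)[2]), ] == -1))
  expect_true(all(A[, , c(1, dim(A)[3])] == -1))
  expect_error(evaluate_grid(fields, spacing = 500), class = "atriarecon_geometry_error")

  # projection engine reproduces each plane's sign at grid nodes on the slice
  gp <- evaluate_grid(fields, spacing = 2, engine = "projection")
  nodes <- as.matrix(expand.grid(x = gp$x, y = gp$y, z = gp$z))
  fl <- fields[[1]]
  pp <- patient_to_plane(fl$plane, nodes)
  on_plane <- abs(pp$d) < 0.4 # nodes essentially on the slice
  uv <- cbind(pp$u[on_plane], pp$v[on_plane])
  sd <- signed_distance_2d(fl$contour_uv, uv)
  clear <- abs(sd) > gp$spacing # away from the contour
  agree <- sign(as.numeric(gp$values)[on_plane][clear]) == sign(sd[clear])
  expect_gt(mean(agree), 0.99)
})

test_that("marching tetrahedra recover analytic volumes and converge under grid refinement", {
  err <- sapply(c(4, 2, 1), function(h) {
    g <- indicator_grid_from_function(function(x, y, z) 20 - sqrt(x^2 + y^2 + z^2),
                                      c(-26, -26, -26), c(26, 26, 26), h)
    m <- extract_zero_surface(g)
    expect_true(is_watertight(m))
    abs(m$volume_ml - 4 / 3 * pi * 8000 / 1000) / (4 / 3 * pi * 8)
  })
  expect_lt(err[3], 0.01)                      # 1 mm grid within 1%
  expect_true(all(diff(err) < 0.002))          # monotone within 0.2% jitter
  g_neg <- indicator_grid_from_function(function(x, y, z) -1 - 0 * x,
                                        c(0, 0, 0), c(5, 5, 5), 1)
  expect_error(extract_zero_surface(g_neg), "no enclosed region")
})

test_that("mesh volume matches closed forms and is rigid-invariant", {
  expect_equal(mesh_volume(cube_mesh(10)), 1)
  tet <- structure(list(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    faces = rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  ), class = "triangle_mesh")
  expect_equal(mesh_volume(tet), 1 / 6 / 1000)
  R <- atriarecon:::rotate_about(c(2, 1, 0.3), 0.9)
  m2 <- cube_mesh(10)
  m2$vertices <- t(R %*% t(m2$vertices)) + 5
  expect_equal(mesh_volume(m2), 1, tolerance = 1e-12)
  bad <- cube_mesh(10); bad$faces <- bad$faces[-1, ]
  expect_error(mesh_volume(bad), "watertight")
})

test_that("single-frame reconstruction is accurate and orientation-invariant", {
  ph <- make_phantom("sphere", 55)
  cfg <- recon_config(grid_mm = 1.5)
  v1 <- reconstruct_frame(generate_strategy(ph, 1), config = cfg)$volume_ml
  v3 <- reconstruct_frame(generate_strategy(ph, 3), config = cfg)$volume_ml
  expect_lt(abs(v1 - 55) / 55, 0.02)
  expect_lt(abs(v1 - v3) / 55, 0.01)
  # rigid motion of the whole scene leaves the volume almost unchanged
  R <- atriarecon:::rotate_about(c(1, 2, 3), 0.7)
  php <- make_phantom("sphere", 55, pose_R = R, pose_t = c(30, -20, 10))
  vp <- reconstruct_frame(generate_strategy(php, 1), config = cfg)$volume_ml
  expect_lt(abs(vp - v1) / 55, 0.005)
})

test_that("degenerate plane sets are rejected or flagged", {
  ph <- make_phantom("sphere", 55)
  ds <- generate_strategy(ph, 1)
  one <- ds[ds$plane_id == "LAX1", ]
  expect_error(reconstruct_frame(contour_set(dataset_planes(ds)["LAX1"], one)),
               class = "atriarecon_geometry_error")
  # two parallel planes: insufficient
  two <- lapply(c(0, 10), function(z) flat_plane(z, paste0("P", z)))
  ctr <- tibble::tibble(plane_id = c("P0", "P10"), frame = 0L,
                        points = list(px_circle(two[[1]], 15), px_circle(two[[2]], 15)))
  expect_error(reconstruct_frame(contour_set(two, ctr)),
               class = "atriarecon_geometry_error")
  # three parallel planes: degenerate stack, warn and proceed
  three <- lapply(c(-10, 0, 10), function(z) flat_plane(z, paste0("P", z)))
  ctr3 <- tibble::tibble(plane_id = c("P-10", "P0", "P10"), frame = 0L,
                         points = lapply(three, function(p) px_circle(p, 15)))
  expect_warning(reconstruct_frame(contour_set(three, ctr3),
                                   config = recon_config(grid_mm = 2)),
                 "parallel")
})

test_that("dense parallel stacks agree with Simpson slice summation", {
  sp <- make_phantom("sphere", 55)
  zs <- seq(-23.5, 23.5, by = 1)
  planes <- lapply(seq_along(zs), function(i) flat_plane(zs[i], paste0("P", i)))
  rows <- lapply(planes, function(pl) slice_phantom(sp, pl))
  keep <- vapply(rows, function(x) !is.null(x) && nrow(x) >= 8, logical(1))
  ds <- contour_set(planes[keep],
                    tibble::tibble(plane_id = paste0("P", seq_along(zs))[keep],
                                   frame = 0L, points = rows[keep]))
  suppressWarnings(
    rec <- reconstruct_frame(ds, config = recon_config(grid_mm = 1, smoothing = 0)))
  simpson <- sum(vapply(which(keep), function(i)
    polygon_area(contour_to_plane_mm(rows[[i]], planes[[i]])), numeric(1))) * 1 / 1000
  expect_lt(abs(rec$volume_ml - simpson) / simpson, 0.01)
})

test_that("cine reconstruction recovers a prescribed volume curve and flags gaps", {
  sp <- make_phantom("sphere", 55)
  cds <- generate_cine_phantom(sp, 70, 50, 60, n_frames = 10)
  gt <- dataset_ground_truth(cds)$curve
  cv <- reconstruct_cine(cds, config = recon_config(grid_mm = 1.5))
  expect_equal(nrow(cv), 10)
  expect_lt(max(abs(cv$volume_ml - gt$volumes) / gt$volumes), 0.02)
  expect_equal(attr(cv, "rr_ms"), 300)
  # constant phantom: flat curve
  ccds <- generate_cine_phantom(sp, 55, 55, 55, n_frames = 8)
  ccv <- reconstruct_cine(ccds, config = recon_config(grid_mm = 2))
  expect_lt(max(ccv$volume_ml) - min(ccv$volume_ml), 0.01 * mean(ccv$volume_ml))
  # a frame with a missing contour is flagged, not interpolated
  gap <- cds[-which(cds$frame == 3 & cds$plane_id == "SAX2")[1], ]
  gap <- contour_set(dataset_planes(cds), gap)
  cvg <- reconstruct_cine(gap, config = recon_config(grid_mm = 2))
  expect_false(cvg$complete[cvg$frame == 3])
  expect_true(all(cvg$complete[cvg$frame != 3]))
})
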