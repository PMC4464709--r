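#' Create a synthetic left-atrial phantom
#'
#' Builds an implicit solid emulating a typical LA morphology, calibrated so
#' its enclosed volume equals `target_volume_ml`. Four families are
#' available:
#' \describe{
#'   \item{`oval`}{an ellipsoid with semi-axis ratio `axis_ratio` (long axis
#'     third); the large/small end-systolic and end-diastolic ovals are this
#'     family at different target volumes.}
#'   \item{`oblique_oval`}{the ellipsoid sheared along its long axis
#'     (`x <- x + shear * z`), emulating an LA with oblique connection to
#'     the LV. Shear is volume-preserving.}
#'   \item{`sphere`}{a sphere.}
#'   \item{`curved`}{the ellipsoid bent along a circular arc of radius
#'     `bend_radius` (aortic-root impression). The toroidal bend Jacobian is
#'     linear in the bend coordinate, so bending about the centroid
#'     preserves the ellipsoid volume exactly.}
#' }
#' All families therefore have analytic reference volumes
#' (`(4/3) pi a b c`); [phantom_voxel_volume()] provides an independent
#' voxel-integration cross-check. The phantom is a closed solid; the mitral
#' plane is a labelled landmark at the long-axis end, not an open boundary.
#'
#' @param family one of `"oval"`, `"oblique_oval"`, `"sphere"`, `"curved"`.
#' @param target_volume_ml enclosed volume, ml (> 0).
#' @param axis_ratio length-3 semi-axis ratio, long axis last.
#' @param shear shear of the long axis (oblique family), dimensionless.
#' @param bend_radius bend arc radius, mm (curved family).
#' @param pose_R,pose_t rigid pose applied to the shape (rotation matrix and
#'   translation, mm).
#' @return an object of class `la_phantom`: the implicit inside/outside
#'   function (`$f`, positive inside), calibrated semi-axes, the posed long
#'   axis, centre and mitral landmark, and the reference volume.
#' @examples
#' ph <- make_phantom("sphere", 55)
#' ph$semi_axes[1] # radius 23.59 mm
#' @export
make_phantom <- function(family = c("oval", "oblique_oval", "sphere", "curved"),
                         target_volume_ml, axis_ratio = c(1, 1.2, 1.5),
                         shear = 0.45, bend_radius = 40,
                         pose_R = diag(3), pose_t = c(0, 0, 0)) {
  family <- match.arg(family)
  if (target_volume_ml <= 0)
    abort("target volume must be positive", class = "atriarecon_phantom_error")
  if (family == "sphere") axis_ratio <- c(1, 1, 1)
  if (any(axis_ratio <= 0))
    abort("infeasible shape parameters: axis ratio must be positive",
          class = "atriarecon_phantom_error")
  scale <- (target_volume_ml * .ML * 3 / (4 * pi * prod(axis_ratio)))^(1 / 3)
  ax <- axis_ratio * scale # (a, b, c); long axis c along shape z
  a <- ax[1]; b <- ax[2]; cl <- ax[3]
  Rb <- bend_radius
  if (family == "curved" && cl / Rb >= pi / 2 - 0.05)
    abort("infeasible shape parameters: bend too strong for the long axis",
          class = "atriarecon_phantom_error")

  # inverse family transform: posed patient point -> straight ellipsoid frame
  to_ellipsoid <- function(q) {
    switch(family,
      oval = , sphere = q,
      oblique_oval = cbind(q[, 1] - shear * q[, 3], q[, 2], q[, 3]),
      curved = {
        rr <- sqrt(q[, 1]^2 + (q[, 3] + Rb)^2)
        cbind(rr - Rb, q[, 2], Rb * atan2(q[, 1], q[, 3] + Rb))
      })
  }
  from_ellipsoid <- function(e) {
    switch(family,
      oval = , sphere = e,
      oblique_oval = cbind(e[, 1] + shear * e[, 3], e[, 2], e[, 3]),
      curved = {
        th <- e[, 3] / Rb
        cbind((Rb + e[, 1]) * sin(th), e[, 2], (Rb + e[, 1]) * cos(th) - Rb)
      })
  }

  Rt <- t(pose_R)
  f <- function(x, y, z) {
    q <- cbind(x, y, z)
    q <- sweep(q, 2, pose_t) %*% pose_R # rows: R^T (p - t)
    e <- to_ellipsoid(q)
    1 - sqrt((e[, 1] / a)^2 + (e[, 2] / b)^2 + (e[, 3] / cl)^2)
  }

  ends_e <- rbind(c(0, 0, -cl), c(0, 0, cl))
  ends <- from_ellipsoid(ends_e) %*% Rt + matrix(pose_t, 2, 3, byrow = TRUE)
  axis <- ends[2, ] - ends[1, ]
  axis <- axis / sqrt(sum(axis^2))
  center <- (ends[1, ] + ends[2, ]) / 2
  # mitral-disc normal: the mitral plane stays perpendicular to the body
  # axis for the ovals (the oblique family's defining feature is precisely
  # the tilt of the chamber axis against it); for the curved family it
  # follows the arc tangent at the mitral end
  mitral_n_e <- switch(family,
    oval = , sphere = , oblique_oval = c(0, 0, 1),
    curved = c(cos(cl / Rb), 0, sin(cl / Rb)))
  mitral_normal <- as.numeric(pose_R %*% mitral_n_e)

  structure(list(
    family = family, target_volume_ml = target_volume_ml,
    semi_axes = ax, shear = if (family == "oblique_oval") shear else 0,
    bend_radius = if (family == "curved") Rb else NA_real_,
    pose_R = pose_R, pose_t = pose_t,
    f = f, axis = axis, center = center,
    mitral_point = as.numeric(ends[1, ]),
    mitral_normal = mitral_normal,
    reference_volume_ml = 4 / 3 * pi * prod(ax) / .ML
  ), class = "la_phantom")
}

#' @export
print.la_phantom <- function(x, ...) {
  cat(sprintf("<la_phantom %s> %.1f ml, semi-axes %s mm\n", x$family,
              x$reference_volume_ml,
              paste(sprintf("%.2f", x$semi_axes), collapse = " x ")))
  invisible(x)
}

#' Reference volume of a phantom
#'
#' @param phantom an [make_phantom()] object.
#' @return the calibrated enclosed volume, ml (analytic).
#' @export
reference_volume <- function(phantom) phantom$reference_volume_ml

#' Voxel-integration volume of a phantom
#'
#' Independent numerical cross-check of [reference_volume()]: counts voxels
#' with positive implicit value on a dense grid over the phantom bounding
#' box. Converges as `O(step)` on the surface shell; 0.5 mm is accurate to
#' well under 0.2% for LA-sized shapes.
#'
#' @param phantom an [make_phantom()] object.
#' @param step voxel edge, mm.
#' @return volume in ml.
#' @export
phantom_voxel_volume <- function(phantom, step = 0.5) {
  ext <- max(phantom$semi_axes) + abs(phantom$shear) * phantom$semi_axes[3] +
    (if (is.na(phantom$bend_radius)) 0 else phantom$semi_axes[3]) + 2
  lo <- phantom$center - ext; hi <- phantom$center + ext
  xs <- seq(lo[1], hi[1], by = step)
  ys <- seq(lo[2], hi[2], by = step)
  zs <- seq(lo[3], hi[3], by = step)
  count <- 0
  for (z in zs) { # slab-wise to bound memory
    g <- expand.grid(x = xs, y = ys)
    count <- count + sum(phantom$f(g$x, g$y, z) > 0)
  }
  count * step^3 / .ML
}

#' Intersect a phantom with an image plane
#'
#' Samples the implicit function on the plane's (optionally refined) pixel
#' lattice and traces its zero level with subpixel marching squares. The
#' section area converges as `O(sample_step^2)` to the analytic section.
#'
#' @param phantom an [make_phantom()] object.
#' @param plane an [image_plane()].
#' @param sample_step lattice step in mm (default: the pixel spacing).
#' @return `n x 2` matrix of `(row, col)` fractional pixel vertices, or
#'   `NULL` when the plane misses the shape (flagged, not an error).
#' @export
slice_phantom <- function(phantom, plane, sample_step = NULL) {
  sp <- plane$spacing
  if (is.null(sample_step)) sample_step <- min(sp)
  rstep <- sample_step / sp[1]; cstep <- sample_step / sp[2]
  rows <- seq(0, plane$n_rows - 1, by = rstep)
  cols <- seq(0, plane$n_cols - 1, by = cstep)
  g <- expand.grid(row = rows, col = cols)
  p <- pixel_to_patient(plane, g$row, g$col)
  vals <- matrix(phantom$f(p[, 1], p[, 2], p[, 3]), nrow = length(rows))
  if (!any(vals > 0)) return(NULL)
  cl <- contourLines(x = rows, y = cols, z = vals, levels = 0)
  if (length(cl) == 0) return(NULL)
  areas <- vapply(cl, function(g) abs(.shoelace(g$x, g$y)), numeric(1))
  g <- cl[[which.max(areas)]]
  pts <- cbind(row = g$x, col = g$y)
  if (nrow(pts) > 3 && sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9)
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 3) return(NULL)
  .dedupe_contour(pts)
}

#' Slice-orientation strategy descriptor
#'
#' The three acquisition strategies applied to every phantom shape: two
#' long-axis planes plus three short-axis planes, with
#' \describe{
#'   \item{row 1}{long axis aligned with the phantom long axis, short axis
#'     perpendicular to it;}
#'   \item{row 2}{long axis aligned, short axis tilted (non-perpendicular);}
#'   \item{row 3}{long axis rotated off the phantom axis, short axis
#'     perpendicular to the acquired (not the true) long axis.}
#' }
#'
#' @param row strategy row, 1, 2 or 3.
#' @param misalign_deg long-axis misalignment used by row 3 (default 25).
#' @param tilt_deg short-axis tilt used by row 2 (default 20).
#' @return a list with the strategy flags and angles.
#' @export
slice_strategy <- function(row, misalign_deg = 25, tilt_deg = 20) {
  row <- as.integer(row)
  if (!row %in% 1:3) abort("strategy row must be 1, 2 or 3",
                           class = "atriarecon_phantom_error")
  list(row = row,
       long_axis_aligned = row != 3L,
       short_axis_perpendicular = row != 2L,
       misalign_deg = if (row == 3L) misalign_deg else 0,
       tilt_deg = if (row == 2L) tilt_deg else 0)
}

# letter codes matching the five canonical shapes
.strategy_code <- function(family, target, row) {
  letter <- switch(family,
    oval = if (target >= 52.5) "A" else "B",
    oblique_oval = "C", sphere = "D", curved = "E")
  paste0(letter, row)
}

#' Generate a sliced phantom acquisition
#'
#' Poses two long-axis and three short-axis planes around the phantom
#' according to a slice-orientation strategy, intersects each with the
#' implicit shape, optionally perturbs the contour vertices with seeded
#' Gaussian noise, and returns the standard contour dataset carrying the
#' ground truth (reference volume, mitral landmark, strategy metadata).
#'
#' @param phantom an [make_phantom()] object.
#' @param strategy a [slice_strategy()] or a row number 1-3.
#' @param noise_mm standard deviation of i.i.d. Gaussian vertex noise, mm.
#' @param seed RNG seed for the noise (recorded in metadata).
#' @param spacing pixel spacing, mm (default 1.5, isotropic).
#' @param fov_mm in-plane field of view, mm.
#' @param frame frame index stamped on the contours (default 0).
#' @return a [contour_set()] with a `ground_truth` attribute.
#' @export
generate_strategy <- function(phantom, strategy = 1, noise_mm = 0, seed = NULL,
                              spacing = 1.5, fov_mm = 180, frame = 0L) {
  if (!is.list(strategy)) strategy <- slice_strategy(strategy)
  planes <- pose_strategy_planes(phantom, strategy, spacing = spacing,
                                 fov_mm = fov_mm)
  .slice_with_planes(phantom, planes, strategy, noise_mm = noise_mm,
                     seed = seed, spacing = spacing, fov_mm = fov_mm,
                     frame = frame)
}

#' Pose the five acquisition planes of a slice strategy
#'
#' Places the two long-axis planes (crossing the mitral mid-point along the
#' acquired axis) and the three short-axis planes (at quartiles of the
#' shape's projected extent along that axis) for a phantom and strategy.
#' The cine generator poses planes once and keeps them fixed over the
#' cycle, as a real acquisition does.
#'
#' @param phantom an [make_phantom()] object.
#' @param strategy a [slice_strategy()] or row number.
#' @param spacing,fov_mm pixel spacing and field of view, mm.
#' @return named list of five [image_plane()] objects.
#' @export
pose_strategy_planes <- function(phantom, strategy = 1, spacing = 1.5,
                                 fov_mm = 180) {
  if (!is.list(strategy)) strategy <- slice_strategy(strategy)
  anchor <- phantom$mitral_point # long-axis planes cross the mitral mid-point
  za <- phantom$axis
  if (strategy$misalign_deg != 0) {
    # acquisition axis planned off the standard ventricular view: tilt the
    # true axis away from the mitral-disc normal, in the plane the two span
    mn <- phantom$mitral_normal
    piv <- c(za[2] * mn[3] - za[3] * mn[2],
             za[3] * mn[1] - za[1] * mn[3],
             za[1] * mn[2] - za[2] * mn[1])
    if (sqrt(sum(piv^2)) < 1e-6) { # axis along the normal: fixed transverse pivot
      e <- diag(3)[, which.min(abs(za))]
      piv <- e - sum(e * za) * za
    }
    piv <- piv / sqrt(sum(piv^2))
    za <- as.numeric(rotate_about(piv, -strategy$misalign_deg * pi / 180) %*% za)
  }
  ref <- diag(3)[, which.min(abs(za))]
  xa <- ref - sum(ref * za) * za; xa <- xa / sqrt(sum(xa^2))
  ya <- c(za[2] * xa[3] - za[3] * xa[2],
          za[3] * xa[1] - za[1] * xa[3],
          za[1] * xa[2] - za[2] * xa[1])

  n_px <- ceiling(fov_mm / spacing)
  mk_plane <- function(center, u, v, id)
    image_plane(center - (n_px / 2) * spacing * u - (n_px / 2) * spacing * v,
                u, v, spacing = spacing, n_rows = n_px, n_cols = n_px,
                plane_id = id)

  # short-axis slices cover the proximal / mid / distal thirds of the
  # chamber as actually seen along the acquired axis: project the shape's
  # support onto za (coarse implicit sampling) and place them at quartiles
  ext <- max(phantom$semi_axes) * 2 + 10
  cs <- seq(-ext, ext, by = 4)
  gg <- expand.grid(x = phantom$center[1] + cs, y = phantom$center[2] + cs,
                    z = phantom$center[3] + cs)
  ins <- phantom$f(gg$x, gg$y, gg$z) > 0
  tproj <- (as.matrix(gg[ins, ]) %*% za) - sum(anchor * za)
  t0 <- min(tproj); t1 <- max(tproj)
  lax_c <- anchor + 0.5 * (t0 + t1) * za

  sa_n <- za
  if (strategy$tilt_deg != 0)
    sa_n <- as.numeric(rotate_about(xa, strategy$tilt_deg * pi / 180) %*% sa_n)
  sa_u <- xa - sum(xa * sa_n) * sa_n; sa_u <- sa_u / sqrt(sum(sa_u^2))
  sa_v <- c(sa_n[2] * sa_u[3] - sa_n[3] * sa_u[2],
            sa_n[3] * sa_u[1] - sa_n[1] * sa_u[3],
            sa_n[1] * sa_u[2] - sa_n[2] * sa_u[1])

  list(
    LAX1 = mk_plane(lax_c, xa, za, "LAX1"),
    LAX2 = mk_plane(lax_c, ya, za, "LAX2"),
    SAX1 = mk_plane(anchor + (t0 + 0.25 * (t1 - t0)) * za, sa_u, sa_v, "SAX1"),
    SAX2 = mk_plane(anchor + (t0 + 0.50 * (t1 - t0)) * za, sa_u, sa_v, "SAX2"),
    SAX3 = mk_plane(anchor + (t0 + 0.75 * (t1 - t0)) * za, sa_u, sa_v, "SAX3")
  )
}

.slice_with_planes <- function(phantom, planes, strategy, noise_mm = 0,
                               seed = NULL, spacing = 1.5, fov_mm = 180,
                               frame = 0L) {
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map(planes, function(pl) {
    pts <- slice_phantom(phantom, pl)
    if (is.null(pts)) return(NULL)
    if (noise_mm > 0)
      pts <- pts + cbind(rnorm(nrow(pts), 0, noise_mm / pl$spacing[1]),
                         rnorm(nrow(pts), 0, noise_mm / pl$spacing[2]))
    pts
  })
  keep <- !vapply(rows, is.null, logical(1))
  contours <- tibble(
    plane_id = vapply(planes[keep], function(p) p$plane_id, character(1)),
    frame = as.integer(frame), points = rows[keep])
  code <- .strategy_code(phantom$family, phantom$target_volume_ml, strategy$row)
  contour_set(
    planes[keep], contours,
    ground_truth = list(
      reference_volume_ml = phantom$reference_volume_ml,
      mitral_point = phantom$mitral_point,
      axis = phantom$axis, family = phantom$family,
      strategy = code, strategy_row = strategy$row,
      misalign_deg = strategy$misalign_deg, tilt_deg = strategy$tilt_deg,
      noise_mm = noise_mm, seed = seed),
    meta = list(spacing_mm = spacing, fov_mm = fov_mm))
}

# prescribed periodic LA volume curve: filling to v_max, passive emptying to
# the v_pre_a shoulder, active emptying back to v_min; cosine segments give
# zero slope at every landmark, so the shoulder is a genuine flat point
.prescribed_curve <- function(v_max, v_min, v_pre_a, n_frames) {
  i_max <- round(0.40 * n_frames)
  i_pre <- round(0.75 * n_frames)
  i <- seq_len(n_frames) - 1
  v <- numeric(n_frames)
  seg1 <- i <= i_max
  v[seg1] <- v_min + (v_max - v_min) * (1 - cos(pi * i[seg1] / i_max)) / 2
  seg2 <- i > i_max & i <= i_pre
  v[seg2] <- v_pre_a + (v_max - v_pre_a) *
    (1 + cos(pi * (i[seg2] - i_max) / (i_pre - i_max))) / 2
  seg3 <- i > i_pre
  v[seg3] <- v_min + (v_pre_a - v_min) *
    (1 + cos(pi * (i[seg3] - i_pre) / (n_frames - i_pre))) / 2
  list(volumes = v, i_max = i_max, i_pre = i_pre)
}

#' Generate a cine phantom acquisition with a prescribed volume curve
#'
#' Animates a phantom by pure self-similar scaling about its centre so that
#' the enclosed volume tracks a prescribed left-atrial cycle: filling from
#' `v_min` to `v_max`, passive emptying to the `v_pre_a` shoulder, then
#' active emptying back to `v_min` (smooth cosine segments; the shoulder is
#' a flat point of the curve). Each frame is sliced with the same plane set.
#'
#' @param phantom an [make_phantom()] object (its calibrated volume is the
#'   scaling reference).
#' @param v_max,v_min,v_pre_a prescribed landmark volumes, ml; `v_pre_a = NA`
#'   generates a cycle without atrial contraction.
#' @param n_frames cardiac frames per cycle (>= 8, default 34).
#' @param dt_ms frame duration, ms (default 30).
#' @param strategy,noise_mm,seed,spacing,fov_mm as in [generate_strategy()].
#' @return a [contour_set()] over all frames; its ground truth carries the
#'   prescribed [tv_curve()] and the analytic [la_indices_from_volumes()].
#' @export
generate_cine_phantom <- function(phantom, v_max, v_min, v_pre_a,
                                  n_frames = 34L, dt_ms = 30, strategy = 1,
                                  noise_mm = 0, seed = NULL, spacing = 1.5,
                                  fov_mm = 180) {
  if (n_frames < 8) abort("need at least 8 frames", class = "atriarecon_phantom_error")
  if (v_min <= 0 || v_min > v_max)
    abort("need 0 < v_min <= v_max", class = "atriarecon_phantom_error")
  no_con <- is.na(v_pre_a)
  pre <- if (no_con) v_min else v_pre_a
  curve <- .prescribed_curve(v_max, v_min, pre, n_frames)
  if (!is.null(seed)) set.seed(seed)

  base <- phantom
  if (!is.list(strategy)) strategy <- slice_strategy(strategy)
  # one fixed plane set for the whole cycle, as in a real acquisition
  planes <- pose_strategy_planes(base, strategy, spacing = spacing,
                                 fov_mm = fov_mm)
  sets <- purrr::map(seq_len(n_frames), function(k) {
    s <- (curve$volumes[k] / base$reference_volume_ml)^(1 / 3)
    ph_k <- base
    c0 <- base$center
    ph_k$f <- function(x, y, z)
      base$f(c0[1] + (x - c0[1]) / s, c0[2] + (y - c0[2]) / s,
             c0[3] + (z - c0[3]) / s)
    ph_k$semi_axes <- base$semi_axes * s
    ph_k$reference_volume_ml <- curve$volumes[k]
    .slice_with_planes(ph_k, planes, strategy, noise_mm = noise_mm,
                       seed = NULL, spacing = spacing, fov_mm = fov_mm,
                       frame = k - 1L)
  })
  contours <- dplyr::bind_rows(lapply(sets, function(s) as_tibble(s)))
  gt_curve <- tv_curve(frames = seq_len(n_frames) - 1L,
                       times = (seq_len(n_frames) - 1) * dt_ms,
                       volumes = curve$volumes, rr_ms = n_frames * dt_ms)
  gt_idx <- la_indices_from_volumes(v_max, v_min,
                                    if (no_con) NA else v_pre_a)
  contour_set(planes, contours, ground_truth = list(
    reference_volume_ml = base$reference_volume_ml,
    mitral_point = base$mitral_point, axis = base$axis,
    family = base$family,
    curve = list(frames = gt_curve$frame, times = gt_curve$time_ms,
                 volumes = gt_curve$volume_ml, rr_ms = n_frames * dt_ms,
                 i_max = curve$i_max, i_pre_a = curve$i_pre,
                 v_max = v_max, v_min = v_min, v_pre_a = v_pre_a),
    indices = unclass(gt_idx)[c("total_emptying", "passive_emptying",
                                "active_emptying", "total_ef",
                                "passive_fraction", "active_fraction")],
    noise_mm = noise_mm, seed = seed),
    meta = list(dt_ms = dt_ms, spacing_mm = spacing))
}

#' The five canonical phantom shapes
#'
#' Convenience constructor for the validation set: oval large (54 ml,
#' end-systolic), oval small (51 ml, end-diastolic), oblique oval (61 ml),
#' sphere (55 ml) and curved (70 ml).
#'
#' @param pose_R,pose_t optional common rigid pose.
#' @return named list of [make_phantom()] objects.
#' @export
canonical_phantoms <- function(pose_R = diag(3), pose_t = c(0, 0, 0)) {
  list(
    oval_big = make_phantom("oval", 54, pose_R = pose_R, pose_t = pose_t),
    oval_small = make_phantom("oval", 51, pose_R = pose_R, pose_t = pose_t),
    oval_oblique = make_phantom("oblique_oval", 61, pose_R = pose_R, pose_t = pose_t),
    spherical = make_phantom("sphere", 55, pose_R = pose_R, pose_t = pose_t),
    curved = make_phantom("curved", 70, pose_R = pose_R, pose_t = pose_t)
  )
}
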