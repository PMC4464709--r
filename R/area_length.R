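#' Atrial length from the mitral mid-position
#'
#' The chamber length on a long-axis view is the maximum distance from the
#' mitral valve mid-position to the opposite wall, i.e. the farthest contour
#' vertex. The contour is resampled to at least 256 vertices first so the
#' discretization error stays below 0.1 mm. The landmark must lie on (or
#' within 2 mm of) the contour.
#'
#' @param points `n x 2` matrix of contour vertices in mm `(u, v)`.
#' @param mitral_mid length-2 mitral mid-position, mm, on the contour.
#' @return the length in mm.
#' @export
la_length <- function(points, mitral_mid) {
  pts <- resample_contour(as.matrix(points), max(256L, nrow(points)))
  d_land <- min(sqrt(rowSums(sweep(pts, 2, mitral_mid)^2)))
  if (d_land > 2)
    abort(sprintf("mitral mid-position is %.2f mm from the contour (landmark must lie on the wall)",
                  d_land), class = "atriarecon_landmark_error")
  max(sqrt(rowSums(sweep(pts, 2, mitral_mid)^2)))
}

#' Model-based bi-plane area-length volume
#'
#' The modified bi-plane area-length formula
#' `V = 0.848 * A_4ch * A_2ch / ((L_4ch + L_2ch) / 2)`, with the two areas
#' in mm^2 from orthogonal long-axis views and the two lengths in mm
#' measured from the mitral mid-position to the opposite wall. The constant
#' is kept at the conventional printed value 0.848 (not `8 / (3 * pi)`).
#' Returns ml.
#'
#' @param area_a,area_b long-axis areas, mm^2.
#' @param length_a,length_b chamber lengths, mm.
#' @return volume in ml.
#' @examples
#' # sphere of radius 20 mm
#' biplane_volume(pi * 400, pi * 400, 40, 40)
#' @export
biplane_volume <- function(area_a, area_b, length_a, length_b) {
  if (any(c(area_a, area_b) <= 0))
    abort("areas must be positive", class = "atriarecon_geometry_error")
  Lbar <- (length_a + length_b) / 2
  if (Lbar <= 0)
    abort("mean length must be positive", class = "atriarecon_geometry_error")
  0.848 * area_a * area_b / Lbar / .ML
}

#' Bi-plane area-length volume from a contour dataset
#'
#' Applies [biplane_volume()] to two long-axis planes of a dataset: contours
#' are smoothed, converted to mm, areas taken by the shoelace formula and
#' lengths measured from the per-plane mitral mid-position. For phantom
#' datasets the mitral landmark stored in the ground-truth block is used
#' when `mitral_a` / `mitral_b` are not given (projected into each plane and
#' snapped to the nearest contour vertex).
#'
#' @param contours a [contour_set()].
#' @param frame cardiac frame (default: the only one).
#' @param plane_a,plane_b plane ids of the two long-axis views; default the
#'   first two planes whose id starts with `"LAX"`.
#' @param mitral_a,mitral_b optional length-2 in-plane mm landmarks.
#' @param smoothing contour smoothing passed to [smooth_contour()].
#' @return a tibble with `area_a`, `area_b` (mm^2), `length_a`, `length_b`
#'   (mm) and `volume_ml`.
#' @export
area_length_volume <- function(contours, frame = NULL, plane_a = NULL,
                               plane_b = NULL, mitral_a = NULL, mitral_b = NULL,
                               smoothing = "auto") {
  stopifnot(inherits(contours, "contour_set"))
  if (is.null(frame)) {
    fr <- unique(contours$frame)
    if (length(fr) != 1) abort("dataset has multiple frames; pass `frame`")
    frame <- fr
  }
  planes <- dataset_planes(contours)
  if (is.null(plane_a) || is.null(plane_b)) {
    lax <- grep("^LAX", names(planes), value = TRUE)
    if (length(lax) < 2)
      abort("cannot identify two long-axis planes; pass plane_a/plane_b",
            class = "atriarecon_geometry_error")
    plane_a <- lax[1]; plane_b <- lax[2]
  }

  gt <- dataset_ground_truth(contours)
  one <- function(id, mitral) {
    row <- which(contours$plane_id == id & contours$frame == frame)
    if (length(row) != 1)
      abort(sprintf("no contour for plane %s frame %s", id, frame),
            class = "atriarecon_geometry_error")
    pts <- contours$points[[row]]
    if (!identical(smoothing, 0) && nrow(pts) >= 8)
      pts <- smooth_contour(pts, smoothing = smoothing)
    uv <- contour_to_plane_mm(pts, planes[[id]])
    if (is.null(mitral)) {
      if (is.null(gt$mitral_point))
        abort("no mitral landmark: pass mitral_a/mitral_b",
              class = "atriarecon_landmark_error")
      proj <- patient_to_plane(planes[[id]], unlist(gt$mitral_point))
      mitral <- unlist(uv[which.min((uv[, 1] - proj$u)^2 + (uv[, 2] - proj$v)^2), ])
    }
    list(area = polygon_area(uv), length = la_length(uv, mitral))
  }
  a <- one(plane_a, mitral_a)
  b <- one(plane_b, mitral_b)
  tibble(frame = frame, plane_a = plane_a, plane_b = plane_b,
         area_a = a$area, area_b = b$area,
         length_a = a$length, length_b = b$length,
         volume_ml = biplane_volume(a$area, b$area, a$length, b$length))
}
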