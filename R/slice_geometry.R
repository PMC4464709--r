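#' Define an image plane in DICOM patient coordinates
#'
#' An `image_plane` carries the geometry of one acquired 2D slice in the
#' DICOM LPS patient coordinate convention: the position of the centre of the
#' pixel at row 0, column 0 (`origin`), the unit direction of increasing
#' column index (`u_dir`), the unit direction of increasing row index
#' (`v_dir`), and the in-plane pixel spacing in mm. The plane normal is
#' always recomputed as `u_dir x v_dir` and never stored independently.
#'
#' Pixel indices are 0-based and refer to pixel centres, matching DICOM
#' `ImagePositionPatient` / `ImageOrientationPatient` semantics. Direction
#' cosines deviating from orthonormality by less than `1e-3` (as rounded
#' DICOM headers routinely do) are re-orthonormalised; larger deviations are
#' a geometry error.
#'
#' @param origin numeric length-3, mm.
#' @param u_dir,v_dir numeric length-3 direction cosines.
#' @param spacing numeric length-2 `(row spacing, column spacing)` in
#'   mm/pixel; a scalar is recycled. Default 1.5 mm isotropic.
#' @param n_rows,n_cols image matrix size in pixels.
#' @param thickness slice thickness in mm (metadata only).
#' @param plane_id label used to match contours to planes.
#' @return an object of class `image_plane`.
#' @examples
#' pl <- image_plane(c(-100, -80, 40), c(1, 0, 0), c(0, 1, 0))
#' pixel_to_patient(pl, row = 10, col = 20)
#' @export
image_plane <- function(origin, u_dir, v_dir, spacing = c(1.5, 1.5),
                        n_rows = 128L, n_cols = 128L, thickness = 6,
                        plane_id = "plane") {
  origin <- as.numeric(origin)
  u_dir <- as.numeric(u_dir)
  v_dir <- as.numeric(v_dir)
  if (length(origin) != 3L || length(u_dir) != 3L || length(v_dir) != 3L)
    abort("origin, u_dir and v_dir must be length-3 numeric vectors",
          class = "atriarecon_geometry_error")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    abort("pixel spacing must be positive", class = "atriarecon_geometry_error")

  nu <- sqrt(sum(u_dir^2)); nv <- sqrt(sum(v_dir^2))
  dot <- abs(sum(u_dir * v_dir))
  dev <- max(abs(nu - 1), abs(nv - 1), dot)
  if (!is.finite(dev) || dev >= 1e-3)
    abort(sprintf(
      "direction cosines are not orthonormal (deviation %.2e): degenerate or corrupt plane basis",
      dev), class = "atriarecon_geometry_error")
  if (dev > 1e-6) { # re-orthonormalise rounded header cosines (Gram-Schmidt)
    u_dir <- u_dir / nu
    v_dir <- v_dir - sum(v_dir * u_dir) * u_dir
    v_dir <- v_dir / sqrt(sum(v_dir^2))
  } else {
    u_dir <- u_dir / nu
    v_dir <- v_dir / nv
  }

  structure(list(
    origin = origin, u_dir = u_dir, v_dir = v_dir,
    spacing = as.numeric(spacing),
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    thickness = as.numeric(thickness), plane_id = as.character(plane_id)
  ), class = "image_plane")
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane '%s'>  %d x %d px @ %.3g x %.3g mm\n",
              x$plane_id, x$n_rows, x$n_cols, x$spacing[1], x$spacing[2]))
  cat("  origin:", paste(sprintf("%.2f", x$origin), collapse = " "), "mm\n")
  cat("  normal:", paste(sprintf("%.4f", plane_normal(x)), collapse = " "), "\n")
  invisible(x)
}

#' Plane normal (derived, never stored)
#'
#' @param plane an [image_plane()].
#' @return unit length-3 vector `u_dir x v_dir`.
#' @export
plane_normal <- function(plane) {
  u <- plane$u_dir; v <- plane$v_dir
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  n / sqrt(sum(n^2))
}

#' Map fractional pixel indices to patient coordinates
#'
#' Applies the affine DICOM transform
#' `origin + col * spacing_col * u_dir + row * spacing_row * v_dir`.
#' Row/column indices may be fractional (subpixel contour vertices).
#'
#' @param plane an [image_plane()].
#' @param row,col numeric vectors of equal length, 0-based pixel indices.
#' @return an `n x 3` matrix of patient coordinates in mm.
#' @export
pixel_to_patient <- function(plane, row, col) {
  stopifnot(inherits(plane, "image_plane"))
  if (length(row) != length(col))
    abort("row and col must have equal length", class = "atriarecon_geometry_error")
  outer(col * plane$spacing[2], plane$u_dir) +
    outer(row * plane$spacing[1], plane$v_dir) +
    matrix(plane$origin, length(row), 3, byrow = TRUE)
}

#' Project patient coordinates onto a plane
#'
#' Returns in-plane coordinates `(u, v)` in mm relative to the plane origin
#' and the signed out-of-plane distance `d` (positive along the plane
#' normal). For points on the plane (`d = 0`), composing with
#' [pixel_to_patient()] restores the point to within 1e-9 mm.
#'
#' @param plane an [image_plane()].
#' @param p numeric length-3 vector or `n x 3` matrix, mm.
#' @return a tibble with columns `u`, `v`, `d` (mm).
#' @export
patient_to_plane <- function(plane, p) {
  stopifnot(inherits(plane, "image_plane"))
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  rel <- sweep(p, 2, plane$origin)
  tibble(
    u = as.numeric(rel %*% plane$u_dir),
    v = as.numeric(rel %*% plane$v_dir),
    d = as.numeric(rel %*% plane_normal(plane))
  )
}

#' In-plane mm coordinates of pixel-index contour points
#'
#' @param points `n x 2` matrix of `(row, col)` fractional pixel indices.
#' @param plane an [image_plane()] (its spacing is applied).
#' @return `n x 2` matrix of `(u, v)` mm in-plane coordinates.
#' @export
contour_to_plane_mm <- function(points, plane) {
  cbind(u = points[, 2] * plane$spacing[2],
        v = points[, 1] * plane$spacing[1])
}

# rigid transform helper used by phantom posing and invariance tests
rotate_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ca + sa * K + (1 - ca) * (a %o% a)
}

#' Apply a rigid transform to an image plane
#'
#' Rotates and translates the plane geometry (origin and direction cosines)
#' by `p -> R p + t`. Used to pose phantom acquisitions and to check rigid
#' equivariance of the coordinate transforms.
#'
#' @param plane an [image_plane()].
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation, mm.
#' @return the transformed [image_plane()].
#' @export
transform_plane <- function(plane, R = diag(3), t = c(0, 0, 0)) {
  image_plane(as.numeric(R %*% plane$origin + t),
              as.numeric(R %*% plane$u_dir),
              as.numeric(R %*% plane$v_dir),
              spacing = plane$spacing, n_rows = plane$n_rows,
              n_cols = plane$n_cols, thickness = plane$thickness,
              plane_id = plane$plane_id)
}
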