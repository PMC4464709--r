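#' Build a contour dataset
#'
#' A `contour_set` is the package's exchange container: a tibble with one row
#' per (plane, cardiac frame) holding the closed subpixel contour, plus the
#' slice-plane geometry as an attribute. It is what the reconstruction, the
#' area-length comparator and the phantom generator all produce or consume.
#'
#' @param planes list of [image_plane()] objects (names are taken from their
#'   `plane_id`).
#' @param contours a data frame with columns `plane_id`, `frame` and a list
#'   column `points` of `n x 2` `(row, col)` matrices.
#' @param ground_truth optional list of ground-truth metadata (phantom
#'   reference volume, mitral landmark, prescribed time-volume curve...).
#' @param meta optional named list recorded in outputs (seeds, smoothing...).
#' @return a tibble of class `contour_set`.
#' @export
contour_set <- function(planes, contours, ground_truth = NULL, meta = list()) {
  planes <- setNames(planes, vapply(planes, function(p) p$plane_id, character(1)))
  x <- as_tibble(contours[c("plane_id", "frame", "points")])
  missing <- setdiff(unique(x$plane_id), names(planes))
  if (length(missing) > 0)
    abort(paste("contours reference unknown plane(s):", paste(missing, collapse = ", ")),
          class = "atriarecon_io_error")
  structure(x, planes = planes, ground_truth = ground_truth, meta = meta,
            class = c("contour_set", class(x)))
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set> %d contours, %d planes, frames %s\n",
              nrow(x), length(attr(x, "planes")),
              paste(range(x$frame), collapse = "..")))
  NextMethod()
}

#' Slice planes of a contour dataset
#' @param x a [contour_set()].
#' @return named list of [image_plane()] objects.
#' @export
dataset_planes <- function(x) attr(x, "planes")

#' Ground-truth metadata of a (synthetic) contour dataset
#' @param x a [contour_set()].
#' @return list, or `NULL` for real data.
#' @export
dataset_ground_truth <- function(x) attr(x, "ground_truth")

#' Write a contour dataset to the contour-exchange JSON format
#'
#' The format stores plane geometry in DICOM patient-coordinate convention
#' (origin of pixel (0, 0), row/column direction cosines, pixel spacing) and
#' per-plane, per-frame closed contours as `(row, col)` fractional pixel
#' vertices.
#'
#' @param x a [contour_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(x, path) {
  planes <- lapply(unname(dataset_planes(x)), function(p) list(
    plane_id = p$plane_id, origin = p$origin, u_dir = p$u_dir, v_dir = p$v_dir,
    spacing = p$spacing, n_rows = p$n_rows, n_cols = p$n_cols,
    thickness = p$thickness))
  contours <- lapply(seq_len(nrow(x)), function(i) list(
    plane_id = x$plane_id[i], frame = x$frame[i],
    points_rowcol = unname(as.matrix(x$points[[i]])), closed = TRUE))
  payload <- list(planes = planes, contours = contours)
  gt <- dataset_ground_truth(x)
  if (!is.null(gt)) payload$ground_truth <- gt
  if (length(attr(x, "meta")) > 0) payload$meta <- attr(x, "meta")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a contour-exchange JSON file
#'
#' @param path file written by [write_contours()] (or by any tool emitting
#'   the same schema).
#' @return a [contour_set()].
#' @export
read_contours <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  planes <- lapply(j$planes, function(p)
    image_plane(p$origin, p$u_dir, p$v_dir, spacing = p$spacing,
                n_rows = p$n_rows, n_cols = p$n_cols,
                thickness = if (is.null(p$thickness)) 6 else p$thickness,
                plane_id = p$plane_id))
  contours <- tibble(
    plane_id = vapply(j$contours, function(c) c$plane_id, character(1)),
    frame = vapply(j$contours, function(c) as.integer(c$frame), integer(1)),
    points = lapply(j$contours, function(c) {
      m <- c$points_rowcol
      if (is.list(m)) m <- do.call(rbind, m)
      colnames(m) <- c("row", "col")
      m
    })
  )
  contour_set(planes, contours, ground_truth = j$ground_truth,
              meta = if (is.null(j$meta)) list() else j$meta)
}

#' Read per-plane binary masks from a NIfTI file
#'
#' Accepts the segmentation layout where one file holds a single 2D slab and
#' cardiac frames are stacked on the third or fourth axis (the "time as z"
#' segmentation convention). The NIfTI affine (RAS) is converted to DICOM
#' LPS and the plane geometry is derived from its direction cosines; masks
#' are traced to subpixel contours with [mask_to_contour()].
#'
#' @param path `.nii` / `.nii.gz` file with binary mask values.
#' @param plane_id label for the plane.
#' @param component_policy forwarded to [mask_to_contour()].
#' @return a [contour_set()] with one contour per non-empty frame.
#' @export
read_mask_nifti <- function(path, plane_id = "plane",
                            component_policy = "largest") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 2) arr <- array(arr, c(d, 1))
  if (length(dim(arr)) == 4) { # one 2D slab, frames on axis 4
    if (dim(arr)[3] != 1)
      abort("expected a single 2D slab (third axis of length 1)",
            class = "atriarecon_io_error")
    arr <- array(arr[, , 1, ], c(dim(arr)[1:2], dim(arr)[4]))
  }
  aff <- RNifti::xform(img)
  ras_to_lps <- diag(c(-1, -1, 1, 1))
  A <- ras_to_lps %*% aff
  # first voxel axis (array rows) -> v_dir, second (array cols) -> u_dir
  vcol <- A[1:3, 1]; ucol <- A[1:3, 2]
  sp_row <- sqrt(sum(vcol^2)); sp_col <- sqrt(sum(ucol^2))
  plane <- image_plane(A[1:3, 4], ucol / sp_col, vcol / sp_row,
                       spacing = c(sp_row, sp_col), n_rows = dim(arr)[1],
                       n_cols = dim(arr)[2], plane_id = plane_id)
  frames <- seq_len(dim(arr)[3])
  rows <- purrr::keep(frames, function(f) any(arr[, , f] > 0.5))
  contours <- tibble(
    plane_id = plane_id,
    frame = as.integer(rows - 1L),
    points = lapply(rows, function(f)
      mask_to_contour(arr[, , f], component_policy = component_policy))
  )
  contour_set(list(plane), contours)
}
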