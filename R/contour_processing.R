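#' Extract a closed subpixel contour from a binary mask
#'
#' Traces the 0.5 iso-level of a binary segmentation mask with
#' marching-squares-style subpixel interpolation ([grDevices::contourLines()])
#' after zero-padding, so the result is always a closed polygon in fractional
#' `(row, col)` pixel indices. Segmentations exported by balloon/snake tools
#' are ingested this way; the contour itself — not the mask — is what the
#' reconstruction consumes.
#'
#' @param mask numeric/logical matrix; values `> 0.5` are foreground.
#' @param component_policy `"largest"` keeps the largest connected foreground
#'   component; `"error_if_multiple"` fails when more than one is present.
#' @return an `n x 2` matrix of `(row, col)` subpixel contour vertices,
#'   implicitly closed.
#' @examples
#' m <- outer(1:61, 1:61, function(r, c) (r - 31)^2 + (c - 31)^2 <= 15^2)
#' xy <- mask_to_contour(m)
#' polygon_area(xy) / (pi * 15^2)
#' @export
mask_to_contour <- function(mask, component_policy = c("largest", "error_if_multiple")) {
  component_policy <- match.arg(component_policy)
  m <- (mask > 0.5) * 1
  if (!any(m > 0))
    abort("mask contains no foreground pixels", class = "atriarecon_contour_error")

  lab <- EBImage::bwlabel(m)
  ncomp <- max(lab)
  if (ncomp > 1L) {
    if (component_policy == "error_if_multiple")
      abort(sprintf("mask has %d connected components (expected 1)", ncomp),
            class = "atriarecon_contour_error")
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    m <- (lab == which.max(sizes)) * 1
  }

  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  cl <- contourLines(x = seq(0, nr + 1) - 1, y = seq(0, nc + 1) - 1,
                     z = pad, levels = 0.5)
  if (length(cl) == 0)
    abort("no iso-contour found in mask", class = "atriarecon_contour_error")
  areas <- vapply(cl, function(g) abs(.shoelace(g$x, g$y)), numeric(1))
  g <- cl[[which.max(areas)]]
  pts <- cbind(row = g$x, col = g$y)
  if (nrow(pts) > 1 && sqrt(sum((pts[1, ] - pts[nrow(pts), ])^2)) < 1e-9)
    pts <- pts[-nrow(pts), , drop = FALSE]
  .dedupe_contour(pts)
}

.shoelace <- function(x, y) {
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

.dedupe_contour <- function(pts) {
  if (nrow(pts) < 2) return(pts)
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2) > 1e-18)
  pts[keep, , drop = FALSE]
}

#' Smooth a closed contour by robust periodic penalized least squares
#'
#' Both coordinates of the closed polygon are smoothed jointly as a periodic
#' sequence by penalized least squares in the Fourier basis (a discrete
#' second-difference roughness penalty), with the smoothing parameter chosen
#' by generalized cross-validation when `smoothing = "auto"`. Up to
#' `robust_iter` bisquare reweighting passes downweight outlier vertices.
#' Periodic treatment means there are no endpoint artifacts and closure and
#' point count are preserved; `smoothing = 0` is the identity.
#'
#' @param points `n x 2` matrix of contour vertices (any planar coordinates;
#'   pixels or mm), implicitly closed, `n >= 8`.
#' @param smoothing `"auto"` (GCV) or a non-negative smoothing parameter.
#' @param robust_iter number of bisquare reweighting iterations (0 disables
#'   robustness).
#' @param closed sanity flag; open contours are rejected.
#' @return the smoothed `n x 2` matrix (same point count and column names).
#' @export
smooth_contour <- function(points, smoothing = "auto", robust_iter = 3L,
                           closed = TRUE) {
  if (!isTRUE(closed))
    abort("smooth_contour requires a closed contour", class = "atriarecon_contour_error")
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 8) abort("need at least 8 contour points", class = "atriarecon_contour_error")
  if (identical(smoothing, 0) || identical(smoothing, 0L)) return(pts)

  lam2 <- (2 - 2 * cos(2 * pi * (seq_len(n) - 1) / n))^2
  y <- complex(real = pts[, 1], imaginary = pts[, 2])

  filt <- function(v, s) fft(fft(v) / (1 + s * lam2), inverse = TRUE) / n
  smooth_w <- function(s, W) {
    # fixed-point iteration for weighted penalized least squares
    z <- y
    for (it in 1:60) {
      z_new <- filt(W * (y - z) + z, s)
      if (max(Mod(z_new - z)) < 1e-10) { z <- z_new; break }
      z <- z_new
    }
    z
  }
  gcv <- function(log10s, W) {
    s <- 10^log10s
    z <- smooth_w(s, W)
    trH <- sum(1 / (1 + s * lam2))
    n * sum(W * Mod(y - z)^2) / (n - trH)^2
  }

  W <- rep(1, n)
  pick_s <- function(W) {
    if (is.numeric(smoothing)) return(smoothing)
    opt <- optimize(gcv, c(-8, 8), W = W)
    10^opt$minimum
  }
  s <- pick_s(W)
  z <- smooth_w(s, W)
  if (robust_iter > 0) {
    for (k in seq_len(robust_iter)) {
      r <- Mod(y - z)
      sig <- 1.4826 * stats::median(r)
      if (sig < 1e-12) break
      u <- r / (4.685 * sig)
      W <- ifelse(u < 1, (1 - u^2)^2, 0)
      if (all(W > 0.999)) break
      s <- pick_s(W)
      z <- smooth_w(s, W)
    }
  }
  out <- cbind(Re(z), Im(z))
  dimnames(out) <- dimnames(pts)
  out
}

#' Planar polygon area by the shoelace formula
#'
#' @param points `n x 2` matrix of `(row, col)` (or any planar) vertices of a
#'   simple closed polygon.
#' @param spacing length-2 `(row, col)` scale in mm/pixel; default `c(1, 1)`
#'   for points already in mm.
#' @return the enclosed area (mm^2), independent of vertex orientation.
#' @export
polygon_area <- function(points, spacing = c(1, 1)) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3)
    abort("polygon needs at least 3 points", class = "atriarecon_contour_error")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  abs(.shoelace(pts[, 2] * spacing[2], pts[, 1] * spacing[1]))
}

#' Signed distance from points to a closed contour
#'
#' Positive inside, negative outside (even-odd rule; boundary counts as
#' inside with value 0). This field is the numerical carrier of the
#' inside/outside indicator whose zero set is the contour.
#'
#' @param points `n x 2` matrix of contour vertices in mm `(u, v)`.
#' @param q query points: length-2 vector or `m x 2` matrix, mm.
#' @return numeric vector of signed distances, mm.
#' @export
signed_distance_2d <- function(points, q) {
  pts <- as.matrix(points)
  if (nrow(pts) < 3)
    abort("degenerate polygon", class = "atriarecon_contour_error")
  if (is.null(dim(q))) q <- matrix(q, ncol = 2, byrow = TRUE)
  cpp_polygon_sdf(q[, 1], q[, 2], pts[, 1], pts[, 2])
}

#' Resample a closed contour uniformly by arc length
#'
#' @param points `n x 2` matrix, implicitly closed.
#' @param n_out number of output vertices (default 256).
#' @return `n_out x 2` matrix.
#' @export
resample_contour <- function(points, n_out = 256L) {
  pts <- as.matrix(points)
  m <- nrow(pts)
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums((closed[-1, , drop = FALSE] - closed[-(m + 1), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[m + 1]
  if (total <= 0) abort("zero-length contour", class = "atriarecon_contour_error")
  tt <- seq(0, total, length.out = n_out + 1)[-(n_out + 1)]
  cbind(approx(cum, closed[, 1], xout = tt)$y,
        approx(cum, closed[, 2], xout = tt)$y)
}
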