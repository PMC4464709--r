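# shared geometric fixtures, all built in code

# closed circle contour, mm coordinates, n vertices
circle_contour <- function(r = 10, n = 256, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# axis-aligned plane at z = z0 with 1 mm pixels, origin in the corner
flat_plane <- function(z0 = 0, id = "P", n = 121, spacing = 1) {
  half <- (n - 1) / 2 * spacing
  image_plane(c(-half, -half, z0), c(1, 0, 0), c(0, 1, 0),
              spacing = c(spacing, spacing), n_rows = n, n_cols = n,
              plane_id = id)
}

# filled-disk binary mask
disk_mask <- function(n = 101, center = (n + 1) / 2, r = 20) {
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - center)^2 + (j - center)^2 <= r^2) + 0
}

# unit cube surface mesh scaled to `edge` mm, 12 triangles
cube_mesh <- function(edge = 10) {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * edge
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  structure(list(vertices = v, faces = f), class = "triangle_mesh")
}
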