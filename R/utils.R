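# Shared geometry helpers. Convention (stated once, used everywhere):
# volumes are [x, y, z] arrays, 1-based; physical coordinates are
# (x, y, z) in micrometres with the origin at the centre of voxel [1,1,1].

#' Convert Cartesian points to spherical coordinates about a centre
#' @param p n x 3 matrix of points (um)
#' @param center length-3 centre (um)
#' @return list with r (um), theta (polar angle from +z), phi (azimuth)
#' @keywords internal
sph_coords <- function(p, center) {
  dx <- p[, 1] - center[1]
  dy <- p[, 2] - center[2]
  dz <- p[, 3] - center[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  ct <- dz / pmax(r, 1e-300)
  theta <- acos(pmin(1, pmax(-1, ct)))
  phi <- atan2(dy, dx)
  list(r = r, theta = theta, phi = phi)
}

#' Radius of an ellipsoid surface along a direction
#' @keywords internal
ellipsoid_radius <- function(theta, phi, axes) {
  if (axes[1] == axes[2] && axes[2] == axes[3]) {
    return(rep.int(axes[1], length(theta)))
  }
  st <- sin(theta)
  1 / sqrt((st * cos(phi) / axes[1])^2 + (st * sin(phi) / axes[2])^2 +
             (cos(theta) / axes[3])^2)
}

#' Smallest signed angular difference a - b, wrapped to (-pi, pi]
#' @keywords internal
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d - 2 * pi * (d > pi)
}

#' Cubic smoothstep ramp: 0 below 0, 1 above 1
#' @keywords internal
smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

#' Per-triangle areas by the cross-product formula
#' @param vertices n x 3 matrix (um)
#' @param triangles m x 3 integer matrix of 1-based vertex indices
#' @return numeric vector of areas (um^2)
#' @export
triangle_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c3 <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a
  v <- c3 - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Triangle centroids
#' @keywords internal
triangle_centroids <- function(vertices, triangles) {
  (vertices[triangles[, 1], , drop = FALSE] +
     vertices[triangles[, 2], , drop = FALSE] +
     vertices[triangles[, 3], , drop = FALSE]) / 3
}

#' Unit-sphere triangulation by icosahedron subdivision
#'
#' @param subdiv number of 4-to-1 subdivision passes (0 gives 20 faces)
#' @return list with vertices (unit directions) and triangles (1-based)
#' @export
icosphere <- function(subdiv = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      edge_mid[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c3 <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf[4 * k - 3, ] <- c(a, ab, ca)
      nf[4 * k - 2, ] <- c(b, bc, ab)
      nf[4 * k - 1, ] <- c(c3, ca, bc)
      nf[4 * k, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- nf
  }
  list(vertices = v, triangles = f)
}

#' Arc-length resampling of a 3-D polyline
#'
#' Linear interpolation at a fixed spacing along the cumulative arc length;
#' endpoints are always retained.
#' @param p n x 3 matrix of ordered points
#' @param step target spacing (um)
#' @return matrix of resampled points
#' @export
densify_polyline <- function(p, step = 0.5) {
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate polyline")
  n_out <- max(2L, ceiling(total / step) + 1L)
  si <- seq(0, total, length.out = n_out)
  out <- cbind(approx(s, p[, 1], xout = si)$y,
               approx(s, p[, 2], xout = si)$y,
               approx(s, p[, 3], xout = si)$y)
  out
}

#' Total length of a polyline
#' @keywords internal
polyline_length <- function(p) {
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' @importFrom stats approx
NULL
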