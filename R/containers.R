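# Core data containers (S3). Pixel arrays are [x, y, (frame)] with
# physical (x, y, z) um coordinates at voxel centres.

#' A single-z 2-D time series
#'
#' @param pixels nx x ny x nframes array of camera counts
#' @param frame_interval time between frames (s)
#' @param z_um z position (um)
#' @param pixel_size in-plane pixel size (um)
#' @param id slice identifier
#' @return `slice_movie` object
#' @export
slice_movie <- function(pixels, frame_interval, z_um, pixel_size,
                        id = "slice") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] >= 2,
            frame_interval > 0, pixel_size > 0)
  structure(list(pixels = pixels, frame_interval = frame_interval,
                 z_um = z_um, pixel_size = pixel_size, id = id),
            class = "slice_movie")
}

#' A set of per-z slice movies forming one acquisition
#'
#' @param slices list of [slice_movie()] (any order; z positions are stored
#'   per slice and sorted on use)
#' @param frame_rate frames per second
#' @param seed seed recorded for provenance
#' @return `volume_movie` object
#' @export
volume_movie <- function(slices, frame_rate, seed = NA_integer_) {
  stopifnot(length(slices) >= 1)
  px <- vapply(slices, function(s) s$pixel_size, numeric(1))
  if (max(px) - min(px) > 1e-9) stop("slices must share pixel size")
  structure(list(slices = slices, frame_rate = frame_rate, seed = seed),
            class = "volume_movie")
}

#' @export
print.volume_movie <- function(x, ...) {
  zs <- vapply(x$slices, function(s) s$z_um, numeric(1))
  cat(sprintf("volume_movie: %d slices, z %.1f..%.1f um, %g Hz\n",
              length(x$slices), min(zs), max(zs), x$frame_rate))
  invisible(x)
}

#' Binary myocardium label volume
#'
#' @param labels [x, y, z] integer array, 0 background / 1 myocardium
#' @param spacing voxel spacing (um per axis)
#' @return `label_volume` object
#' @export
label_volume <- function(labels, spacing) {
  stopifnot(length(dim(labels)) == 3, length(spacing) == 3,
            all(spacing > 0))
  vals <- unique(as.vector(labels))
  if (!all(vals %in% c(0L, 1L))) stop("labels must be binary 0/1")
  structure(list(labels = labels, spacing = spacing),
            class = "label_volume")
}

#' Triangulated myocardial surface mesh
#'
#' @param vertices n x 3 matrix (um)
#' @param triangles m x 3 integer matrix, 1-based
#' @param surface per-triangle label: "epi", "endo" or "unassigned"
#' @param region per-triangle logical sampling-region mask
#' @return `myo_mesh` with per-triangle reference areas
#' @export
myo_mesh <- function(vertices, triangles,
                     surface = rep("unassigned", nrow(triangles)),
                     region = rep(TRUE, nrow(triangles))) {
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3,
            length(surface) == nrow(triangles),
            length(region) == nrow(triangles))
  areas <- triangle_areas(vertices, triangles)
  if (any(areas <= 0)) stop("mesh contains degenerate triangles")
  structure(list(vertices = vertices, triangles = triangles,
                 surface = surface, region = region, ref_areas = areas),
            class = "myo_mesh")
}

#' @export
print.myo_mesh <- function(x, ...) {
  cat(sprintf("myo_mesh: %d vertices, %d triangles (epi %d, endo %d), area %.1f um^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$surface == "epi"),
              sum(x$surface == "endo"), sum(x$ref_areas)))
  invisible(x)
}

#' Ordered ridge centreline annotation
#'
#' @param points n x 3 matrix of ordered points on the endocardial surface
#' @param class "radial" or "circumferential"
#' @param id identifier
#' @return `ridge_trace` object
#' @export
ridge_trace <- function(points, class = c("radial", "circumferential"),
                        id = "ridge") {
  class <- match.arg(class)
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 3, ncol(points) == 3)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive trace points must be distinct")
  structure(list(points = points, class = class, id = id),
            class = "ridge_trace")
}
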