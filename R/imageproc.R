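# Preprocessing, myocardial segmentation at the reference phase, and
# surface meshing. 2-D grayscale morphology is delegated to EBImage; 3-D
# morphology, connected components and iso-surfacing are package kernels.

#' Resample a volume to a coarser voxel spacing
#'
#' Trilinear interpolation; the physical extent is preserved to within one
#' voxel. Used to reduce the computational burden before registration.
#'
#' @param vol [x,y,z] array
#' @param spacing native voxel spacing (um per axis)
#' @param target_spacing requested spacing (um per axis, each >= native)
#' @return list with `vol` (resampled array) and `spacing`
#' @export
resample_volume <- function(vol, spacing, target_spacing) {
  stopifnot(length(dim(vol)) == 3)
  target_spacing <- rep(target_spacing, length.out = 3)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  if (any(target_spacing < spacing - 1e-9)) {
    stop("target spacing must be >= native spacing")
  }
  d <- dim(vol)
  out_dims <- pmax(2L, as.integer(floor((d - 1) * spacing /
                                          target_spacing)) + 1L)
  scale <- target_spacing / spacing
  out <- .cpp_resample3d(as.double(vol), as.integer(d), as.double(scale),
                         out_dims)
  list(vol = array(out, dim = out_dims), spacing = target_spacing)
}

#' Rolling-ball background removal
#'
#' Subtracts the morphological grayscale opening with a disc structuring
#' element of the given radius (the classic rolling-ball background), then
#' clips at zero. 2-D input is processed directly; 3-D input slice by
#' slice in z.
#'
#' @param image matrix or [x,y,z] array of intensities
#' @param radius_px structuring-element radius in pixels (>= 1)
#' @return background-subtracted image, same shape
#' @export
rolling_ball <- function(image, radius_px) {
  if (radius_px < 1) stop("radius must be >= 1")
  d <- dim(image)
  if (radius_px * 2 + 1 > min(d[1], d[2])) {
    stop("structuring element larger than image")
  }
  brush <- EBImage::makeBrush(2 * as.integer(radius_px) + 1, "disc")
  one <- function(m) {
    scale <- max(m, 1)
    img <- EBImage::Image(m / scale)
    bg <- EBImage::dilate(EBImage::erode(img, brush), brush)
    pmax(m - EBImage::imageData(bg) * scale, 0)
  }
  if (length(d) == 2) return(one(image))
  out <- image
  for (k in seq_len(d[3])) out[, , k] <- one(image[, , k])
  out
}

# single global Otsu threshold for a volume of any dimension (EBImage's
# otsu thresholds 3-D images frame-wise, so flatten to one 2-D image)
otsu_threshold <- function(vol) {
  v <- as.vector(vol)
  vmax <- max(v)
  flat <- EBImage::Image(matrix(v / vmax, nrow = length(v)))
  EBImage::otsu(flat, range = c(0, 1)) * vmax
}

# ellipsoidal structuring-element offsets for anisotropic voxels
ball_offsets <- function(radius_um, spacing) {
  rv <- pmax(0L, as.integer(floor(radius_um / spacing)))
  g <- expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3])
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dz * spacing[3])^2 <= radius_um^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Segment the myocardium in a reference-phase volume
#'
#' Otsu threshold, 3-D morphological closing, largest connected component,
#' then filling of internal cavities smaller than a fraction of the
#' foreground — the ventricular lumen (a large cavity) is deliberately NOT
#' filled, so the wall remains a shell.
#'
#' @param vol background-subtracted [x,y,z] intensity array
#' @param spacing voxel spacing (um)
#' @param closing_radius_um radius of the closing ball (um)
#' @param max_fill_frac cavities smaller than this fraction of the
#'   foreground volume are treated as holes and filled
#' @return a [label_volume()]
#' @export
segment_myocardium <- function(vol, spacing, closing_radius_um = 1.0,
                               max_fill_frac = 0.02) {
  d <- dim(vol)
  vmax <- max(vol)
  if (vmax <= 0) stop("implausible segmentation: empty volume")
  thr <- otsu_threshold(vol)
  mask <- vol > thr
  frac <- mean(mask)
  if (frac < 0.001 || frac > 0.5) {
    stop(sprintf(
      "implausible segmentation: foreground fraction %.4f outside [0.001, 0.5]",
      frac))
  }
  # Otsu separability: fraction of variance explained by the two-class
  # split; unimodal noise has no foreground/background structure
  m0 <- mean(vol[!mask]); m1 <- mean(vol[mask])
  eta <- frac * (1 - frac) * (m1 - m0)^2 / stats::var(as.vector(vol))
  if (eta < 0.75) {
    stop(sprintf(
      "implausible segmentation: threshold separability %.2f below 0.75",
      eta))
  }
  if (closing_radius_um > 0) {
    off <- ball_offsets(closing_radius_um, spacing)
    x <- .cpp_minmax3d(as.double(mask), as.integer(d), off, TRUE)
    x <- .cpp_minmax3d(x, as.integer(d), off, FALSE)
    mask <- array(x > 0.5, dim = d)
  }
  cc <- .cpp_label3d(as.logical(mask), as.integer(d), 26L)
  big <- which.max(cc$sizes)
  if (cc$sizes[big] < 0.95 * sum(mask)) {
    warning("largest component covers < 95% of foreground")
  }
  mask <- array(cc$labels == big, dim = d)
  # cavities: background components not touching the border
  bg <- .cpp_label3d(as.logical(!mask), as.integer(d), 6L)
  fg_n <- sum(mask)
  for (comp in seq_along(bg$sizes)) {
    if (bg$touches_border[comp] == 0 &&
        bg$sizes[comp] < max_fill_frac * fg_n) {
      mask[bg$labels == comp] <- TRUE
    }
  }
  label_volume(array(as.integer(mask), dim = d), spacing)
}

#' Extract a triangulated surface mesh from a label volume
#'
#' Iso-surface at 0.5 on the Gaussian-smoothed label field, with vertices
#' in physical um. Optional Taubin smoothing (area change is verified to
#' stay below 2%).
#'
#' @param labels a [label_volume()]
#' @param smooth_sigma_um Gaussian smoothing of the label field (um)
#' @param taubin_iters Taubin smoothing passes (0 to disable)
#' @return a [myo_mesh()] with per-triangle reference areas
#' @export
mesh_surface <- function(labels, smooth_sigma_um = 0.6, taubin_iters = 0) {
  d <- dim(labels$labels)
  field <- as.double(labels$labels)
  if (smooth_sigma_um > 0) {
    field <- .cpp_gauss3d(field, as.integer(d),
                          smooth_sigma_um / labels$spacing)
  }
  res <- .cpp_march_tetra(field, as.integer(d), 0.5,
                          as.double(labels$spacing), c(0, 0, 0))
  v <- res$vertices
  f <- res$triangles
  areas <- triangle_areas(v, f)
  keep <- areas > 1e-9
  f <- f[keep, , drop = FALSE]
  if (nrow(f) == 0) stop("empty iso-surface")
  # watertightness: every edge should be shared by exactly two triangles
  ek <- c(paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
          paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
          paste(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1])))
  etab <- table(table(ek))
  nbad <- sum(as.integer(etab[names(etab) != "2"]))
  if (nbad > 0.005 * length(ek)) {
    stop(sprintf("non-manifold iso-surface: %d boundary/overshared edges of %d",
                 nbad, length(ek)))
  }
  if (taubin_iters > 0) {
    a0 <- sum(triangle_areas(v, f))
    v <- taubin_smooth(v, f, taubin_iters)
    a1 <- sum(triangle_areas(v, f))
    if (abs(a1 - a0) / a0 > 0.02) {
      stop("Taubin smoothing changed total area by more than 2%")
    }
  }
  myo_mesh(v, f)
}

# Taubin lambda/mu smoothing (volume-preserving pair of Laplacian steps)
taubin_smooth <- function(v, f, iters, lambda = 0.5, mu = -0.53) {
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  step <- function(v, w) {
    sums <- rowsum(v[edges[, 2], , drop = FALSE], edges[, 1],
                   reorder = FALSE)
    cnt <- as.vector(table(factor(edges[, 1], levels = seq_len(nrow(v)))))
    idx <- as.integer(rownames(sums))
    lap <- v
    lap[idx, ] <- sums / pmax(cnt[idx], 1)
    v + w * (lap - v)
  }
  for (i in seq_len(iters)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  v
}

#' Separate epicardial and endocardial surfaces by connectivity
#'
#' The mesh of a closed myocardial shell has two connected components; the
#' one with the larger bounding-box diagonal is the epicardium, the second
#' the endocardium. Further small components are left unassigned.
#'
#' @param mesh a [myo_mesh()]
#' @return the mesh with per-triangle `surface` labels
#' @export
split_epi_endo <- function(mesh) {
  g <- igraph::graph_from_edgelist(
    rbind(mesh$triangles[, 1:2], mesh$triangles[, 2:3],
          mesh$triangles[, c(3, 1)]), directed = FALSE)
  comp <- igraph::components(g)$membership
  tri_comp <- comp[mesh$triangles[, 1]]
  ids <- sort(unique(tri_comp))
  if (length(ids) < 2) stop("no endocardial surface: mesh has a single component")
  diag_of <- vapply(ids, function(cid) {
    vv <- mesh$vertices[unique(as.vector(
      mesh$triangles[tri_comp == cid, , drop = FALSE])), , drop = FALSE]
    sqrt(sum((apply(vv, 2, max) - apply(vv, 2, min))^2))
  }, numeric(1))
  ord <- ids[order(diag_of, decreasing = TRUE)]
  surface <- rep("unassigned", nrow(mesh$triangles))
  surface[tri_comp == ord[1]] <- "epi"
  surface[tri_comp == ord[2]] <- "endo"
  if (length(ord) > 2) {
    message(sprintf("%d small components left unassigned",
                    length(ord) - 2))
  }
  mesh$surface <- surface
  mesh
}

#' Select a sampling region on the mesh
#'
#' Epicardial triangles are selected by the region specification (a
#' half-space); endocardial triangles are then selected within a distance
#' band of the selected epicardial elements so that the two surfaces'
#' sampling regions overlap spatially.
#'
#' @param mesh a labelled [myo_mesh()] (after [split_epi_endo()])
#' @param region list with `point` and `normal`: keep the half-space
#'   `normal . (x - point) >= 0`
#' @param band_um endocardial inclusion distance from selected epicardial
#'   elements (um); must exceed the wall thickness plus ridge height
#' @return the mesh with its per-triangle `region` mask set
#' @export
select_region <- function(mesh, region, band_um = 12) {
  cen <- triangle_centroids(mesh$vertices, mesh$triangles)
  side <- as.vector((cen - matrix(region$point, nrow(cen), 3,
                                  byrow = TRUE)) %*% region$normal) >= 0
  epi_sel <- side & mesh$surface == "epi"
  if (!any(epi_sel)) stop("empty selection")
  endo_idx <- which(mesh$surface == "endo")
  sel_cen <- cen[epi_sel, , drop = FALSE]
  endo_sel <- rep(FALSE, nrow(cen))
  if (length(endo_idx)) {
    block <- 512L
    for (s in seq(1, length(endo_idx), by = block)) {
      idx <- endo_idx[s:min(s + block - 1L, length(endo_idx))]
      dmin <- apply(cen[idx, , drop = FALSE], 1, function(p) {
        min(sqrt((sel_cen[, 1] - p[1])^2 + (sel_cen[, 2] - p[2])^2 +
                   (sel_cen[, 3] - p[3])^2))
      })
      endo_sel[idx] <- dmin <= band_um
    }
  }
  mesh$region <- epi_sel | endo_sel
  mesh
}
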