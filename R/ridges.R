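# Trabecular ridge strain metrics: shortening of radial and
# circumferential ridge centrelines, transmural thickening of ridges, and
# circumferential strain of the surrounding compact layer, measured on 2-D
# cross-sections of the morphed surfaces.

# apply either a fitted motion model or an arbitrary deformation function
apply_deform <- function(deform, points, phase) {
  if (inherits(deform, "motion_model")) {
    points + evaluate_displacement(deform, points, phase)
  } else {
    deform(points, phase)
  }
}

#' Pick the measurement (peak-deformation) phase
#'
#' The phase with maximal mean displacement magnitude of the endocardial
#' surface — the antipode of the reference phase of the fitted motion.
#'
#' @param model a `motion_model`
#' @param mesh labelled [myo_mesh()]
#' @return phase index (0-based)
#' @export
pick_systole_phase <- function(model, mesh) {
  endo_v <- unique(as.vector(
    mesh$triangles[mesh$surface == "endo", , drop = FALSE]))
  pts <- mesh$vertices[endo_v, , drop = FALSE]
  mags <- vapply(seq_len(model$K) - 1L, function(ph) {
    mean(sqrt(rowSums(evaluate_displacement(model, pts, ph)^2)))
  }, numeric(1))
  which.max(mags) - 1L
}

#' Ridge centreline shortening between reference and a measurement phase
#'
#' The trace is densified by arc-length resampling (<= `step` um), each
#' point is displaced to the measurement phase, and the shortening
#' fraction is `(L(0) - L(t)) / L(0)`.
#'
#' @param trace a [ridge_trace()]
#' @param deform a `motion_model` or a function `(points, phase) ->
#'   positions`
#' @param systole_phase measurement phase (bin index)
#' @param step resampling step (um)
#' @return list with reference length, deformed length and shortening
#'   fraction
#' @export
measure_ridge_shortening <- function(trace, deform, systole_phase,
                                     step = 0.5) {
  dense <- densify_polyline(trace$points, step)
  l0 <- polyline_length(dense)
  l1 <- polyline_length(apply_deform(deform, dense, systole_phase))
  list(id = trace$id, class = trace$class, length_ref = l0,
       length_sys = l1, shortening = (l0 - l1) / l0)
}

# intersect the triangles of one surface with a plane, returning closed
# contour loops (ordered point matrices)
mesh_plane_contours <- function(vertices, triangles, plane) {
  n <- plane$normal / sqrt(sum(plane$normal^2))
  s <- as.vector((vertices - matrix(plane$point, nrow(vertices), 3,
                                    byrow = TRUE)) %*% n)
  s[s == 0] <- 1e-12
  pts <- new.env(hash = TRUE)      # edge key -> interpolated point
  links <- new.env(hash = TRUE)    # edge key -> neighbouring edge keys
  ekey <- function(i, j) paste(min(i, j), max(i, j))
  cut_point <- function(i, j) {
    key <- ekey(i, j)
    if (is.null(pts[[key]])) {
      t <- s[i] / (s[i] - s[j])
      pts[[key]] <- vertices[i, ] + t * (vertices[j, ] - vertices[i, ])
    }
    key
  }
  for (r in seq_len(nrow(triangles))) {
    v3 <- triangles[r, ]
    sg <- s[v3] > 0
    if (all(sg) || all(!sg)) next
    alone <- if (sum(sg) == 1) which(sg) else which(!sg)
    others <- setdiff(1:3, alone)
    k1 <- cut_point(v3[alone], v3[others[1]])
    k2 <- cut_point(v3[alone], v3[others[2]])
    links[[k1]] <- c(links[[k1]], k2)
    links[[k2]] <- c(links[[k2]], k1)
  }
  keys <- ls(pts)
  if (length(keys) == 0) return(list())
  visited <- new.env(hash = TRUE)
  loops <- list()
  for (k0 in keys) {
    if (!is.null(visited[[k0]])) next
    loop <- character(0)
    k <- k0
    prev <- ""
    open <- FALSE
    repeat {
      visited[[k]] <- TRUE
      loop <- c(loop, k)
      nbrs <- setdiff(links[[k]], prev)
      if (length(nbrs) == 0) { open <- TRUE; break }
      prev <- k
      k <- nbrs[1]
      if (k == k0) break
    }
    pmat <- do.call(rbind, lapply(loop, function(kk) pts[[kk]]))
    attr(pmat, "open") <- open
    loops[[length(loops) + 1]] <- pmat
  }
  loops
}

loop_perimeter <- function(p, closed = TRUE) {
  per <- polyline_length(p)
  if (closed) per <- per + sqrt(sum((p[1, ] - p[nrow(p), ])^2))
  per
}

# polar coordinates of points in the cutting plane about a centre
plane_polar <- function(points, plane, center) {
  n <- plane$normal / sqrt(sum(plane$normal^2))
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  c_in <- center - sum((center - plane$point) * n) * n
  d <- sweep(points, 2, c_in)
  x <- as.vector(d %*% e1)
  y <- as.vector(d %*% e2)
  list(rho = sqrt(x^2 + y^2), alpha = atan2(y, x))
}

#' Transmural (thickening) strain at a trabecular ridge
#'
#' On a 2-D cross-section through the ridge, the transmural extent of the
#' wall at the ridge is measured as the distance from the ridge crest (the
#' deepest point of the endocardial contour in an angular window around
#' the ridge) to the epicardial contour in the same window — a caliper
#' measurement of the crest-to-epicardium wall span, which elongates as
#' the ridge thickens transmurally. Strain is `(h(t) - h(0)) / h(0)`
#' (positive = thickening).
#'
#' @param trace the ridge's [ridge_trace()] (locates the crest)
#' @param plane list with `point` and `normal` defining the cross-section
#' @param surfaces `morphed_surfaces` with epi/endo labels
#' @param phase measurement phase (bin index)
#' @param crest_window half-width (rad) of the angular window for the
#'   crest and epicardial searches
#' @return list with h at reference and phase, and transmural strain
#' @export
measure_transmural_strain <- function(trace, plane, surfaces, phase,
                                      crest_window = 0.12) {
  mesh <- surfaces$mesh
  endo_tri <- mesh$triangles[mesh$surface == "endo", , drop = FALSE]
  epi_tri <- mesh$triangles[mesh$surface == "epi", , drop = FALSE]
  if (nrow(endo_tri) == 0) stop("no endocardial surface in mesh")
  center <- colMeans(mesh$vertices[unique(as.vector(epi_tri)), ,
                                   drop = FALSE])
  # crest seed: trace point nearest the plane
  n <- plane$normal / sqrt(sum(plane$normal^2))
  sd_tr <- abs(as.vector((trace$points -
                            matrix(plane$point, nrow(trace$points), 3,
                                   byrow = TRUE)) %*% n))
  if (min(sd_tr) > 2) stop("plane misses the ridge trace")
  seed <- trace$points[which.min(sd_tr), , drop = FALSE]
  alpha0 <- plane_polar(seed, plane, center)$alpha

  h_of <- function(verts) {
    endo <- mesh_plane_contours(verts, endo_tri, plane)
    epi <- mesh_plane_contours(verts, epi_tri, plane)
    if (length(endo) == 0 || length(epi) == 0) {
      stop("plane misses the myocardial surfaces")
    }
    pe <- plane_polar(do.call(rbind, endo), plane, center)
    pp <- plane_polar(do.call(rbind, epi), plane, center)
    crest <- pe$rho[abs(ang_diff(pe$alpha, alpha0)) < crest_window]
    outer <- pp$rho[abs(ang_diff(pp$alpha, alpha0)) < crest_window]
    if (length(crest) == 0 || length(outer) == 0) {
      stop("plane misses the ridge: no contour points in measurement window")
    }
    median(outer) - min(crest)
  }
  ref_i <- surfaces$ref_col
  ph_i <- match(phase, surfaces$phases)
  h0 <- h_of(surfaces$vertices[[ref_i]])
  h1 <- h_of(surfaces$vertices[[ph_i]])
  if (h0 <= 0) stop("non-positive reference ridge thickness")
  list(id = trace$id, h_ref = h0, h_sys = h1,
       transmural_strain = (h1 - h0) / h0)
}

#' Circumferential strain of the compact layer on a cross-section
#'
#' Perimeter of the epicardial-side contour in the cutting plane at the
#' reference and measurement phases; strain is `(C(t) - C(0)) / C(0)`
#' (negative = contraction).
#'
#' @param plane list with `point` and `normal`
#' @param surfaces `morphed_surfaces` with epi/endo labels
#' @param phase measurement phase (bin index)
#' @return list with both circumferences and the circumferential strain
#' @export
measure_compact_circumferential <- function(plane, surfaces, phase) {
  mesh <- surfaces$mesh
  epi_tri <- mesh$triangles[mesh$surface == "epi", , drop = FALSE]
  c_of <- function(verts) {
    loops <- mesh_plane_contours(verts, epi_tri, plane)
    loops <- Filter(function(l) !isTRUE(attr(l, "open")), loops)
    if (length(loops) == 0) stop("open contour: no closed compact-layer loop")
    max(vapply(loops, loop_perimeter, numeric(1)))
  }
  c0 <- c_of(surfaces$vertices[[surfaces$ref_col]])
  c1 <- c_of(surfaces$vertices[[match(phase, surfaces$phases)]])
  list(c_ref = c0, c_sys = c1, circumferential_strain = (c1 - c0) / c0)
}

#' Read ridge annotations from a JSON file
#'
#' Expected schema: an array of objects with `id`, `class`
#' ("radial"/"circumferential") and `points` (array of [x, y, z] um).
#'
#' @param path JSON file path
#' @return list of [ridge_trace()]
#' @export
read_ridge_annotations <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(ann, function(a) {
    pts <- do.call(rbind, lapply(a$points, unlist))
    ridge_trace(pts, class = a$class, id = a$id)
  })
}

#' Write ridge annotations to JSON
#' @param traces list of [ridge_trace()]
#' @param path output path
#' @export
write_ridge_annotations <- function(traces, path) {
  ann <- lapply(traces, function(tr) {
    list(id = tr$id, class = tr$class,
         points = lapply(seq_len(nrow(tr$points)),
                         function(i) unname(tr$points[i, ])))
  })
  jsonlite::write_json(ann, path, auto_unbox = TRUE, digits = NA)
}
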