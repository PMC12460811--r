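# Cyclic deformable registration across the cardiac cycle. The motion
# model is a tensor-product cubic B-spline control lattice in space,
# multiplied by a truncated Fourier basis in cardiac phase whose functions
# all vanish at the reference phase — so the displacement is identically
# zero at the reference and exactly periodic over the cycle, by
# construction. Fitting minimises an image-dissimilarity metric (normalized
# cross-correlation by default, or sum of squared differences) between the
# reference volume warped to each phase and the observed phase volumes,
# plus a bending-energy penalty on the control lattice, coarse-to-fine
# over control-grid resolutions with an L-BFGS quasi-Newton optimiser and
# analytic gradients.

#' Registration settings
#'
#' @param grid_spacing control-point spacing at the finest level (voxels)
#' @param harmonics number of temporal Fourier harmonics H (H <= K/2 - 1
#'   below the phase-sampling Nyquist limit)
#' @param lambda bending-energy weight (metric-relative)
#' @param metric "ncc" (negative normalized cross-correlation) or "ssd"
#' @param levels number of coarse-to-fine grid levels (spacing halves each
#'   level down to `grid_spacing`)
#' @param maxit optimiser iteration cap per level (fixed, for determinism)
#' @param ref_phase reference phase index (0-based); NULL selects the
#'   minimum-foreground (systolic) phase automatically
#' @return settings list for [fit_motion()]
#' @export
motion_spec <- function(grid_spacing = 8, harmonics = 2, lambda = 0.01,
                        metric = c("ncc", "ssd"), levels = 2, maxit = 40,
                        ref_phase = NULL) {
  list(grid_spacing = grid_spacing, harmonics = harmonics, lambda = lambda,
       metric = match.arg(metric), levels = levels, maxit = maxit,
       ref_phase = ref_phase)
}

# temporal basis row(s): 2H columns [cos(h a) - 1, sin(h a)] with
# a = 2 pi (phase - ref) / K; vanishes identically at phase = ref
temporal_basis <- function(phase, H, K, ref) {
  ang <- outer(2 * pi * (phase - ref) / K, seq_len(H))
  cbind(cos(ang) - 1, sin(ang))
}

grid_dims_for <- function(dims, sp) {
  ncells <- pmax(1L, as.integer(ceiling((dims - 1) / sp)))
  ncells + 3L
}

#' Fit the cyclic motion model to a phase-binned cycle
#'
#' @param cycle a `cardiac_cycle_set` from [reconstruct_4d()] (or any list
#'   with `volumes`, `K`, `spacing`)
#' @param spec a [motion_spec()]
#' @return a `motion_model`: per-level B-spline coefficient arrays, the
#'   temporal basis definition, the reference phase, and a fitting report
#'   (final metric per phase, bending energy)
#' @export
fit_motion <- function(cycle, spec = motion_spec()) {
  K <- cycle$K
  if (K < 3) stop("need at least 3 phase volumes")
  if (spec$harmonics > floor(K / 2)) {
    stop("harmonics exceed the phase-sampling Nyquist limit")
  }
  vmax <- max(vapply(cycle$volumes, max, numeric(1)))
  vols <- lapply(cycle$volumes, function(v) as.double(v) / vmax)
  dims <- dim(cycle$volumes[[1]])

  ref <- spec$ref_phase
  if (is.null(ref)) {
    meanvol <- Reduce(`+`, vols) / K
    thr <- otsu_threshold(meanvol)
    counts <- vapply(vols, function(v) sum(v > thr), numeric(1))
    ref <- which.min(counts) - 1L
  }
  Tmat <- temporal_basis(seq_len(K) - 1L, spec$harmonics, K, ref)
  phases_use <- setdiff(seq_len(K) - 1L, ref)
  refvol <- vols[[ref + 1L]]
  # fold-over is only meaningful where there is tissue: the model is free
  # (pure extrapolation) in background and lumen regions
  fg <- as.double(array(refvol, dims) > otsu_threshold(refvol))
  fg <- .cpp_minmax3d(fg, as.integer(dims),
                      ball_offsets(2, c(1, 1, 1)), TRUE)
  fg_mask <- array(fg > 0.5, dims)

  spacings <- spec$grid_spacing * 2^((spec$levels - 1):0)
  levels <- list()
  base <- NULL
  report <- list()
  for (li in seq_along(spacings)) {
    sp <- rep(spacings[li], 3)
    gdims <- grid_dims_for(dims, sp)
    nb <- 2 * spec$harmonics
    npar <- prod(gdims) * 3 * nb
    # image pyramid: smooth proportionally to the control spacing so coarse
    # levels see coarse structure (final level: sigma = spacing/8 voxels)
    sig <- spacings[li] / 8
    if (sig >= 0.4) {
      vols_l <- lapply(vols, function(v) {
        .cpp_gauss3d(v, as.integer(dims), rep(sig, 3))
      })
    } else {
      vols_l <- vols
    }
    refvol_l <- vols_l[[ref + 1L]]
    lambda <- spec$lambda
    for (attempt in 1:3) {
      # memoise: L-BFGS-B asks for the cost and gradient at the same point
      last <- new.env()
      eval_at <- function(par) {
        if (!is.null(last$par) && identical(par, last$par)) {
          return(last$res)
        }
        res <- .cpp_ffd_cost_grad(refvol_l, vols_l, as.integer(dims), par,
                                  as.integer(gdims), as.double(sp), Tmat,
                                  as.integer(phases_use), lambda,
                                  spec$metric, base)
        last$par <- par
        last$res <- res
        res
      }
      fit <- optim(rep(0, npar), function(p) eval_at(p)$cost,
                   function(p) eval_at(p)$grad, method = "L-BFGS-B",
                   control = list(maxit = spec$maxit))
      coef <- array(fit$par, dim = c(prod(gdims), 3, nb))
      lev <- list(coef = coef, gdims = gdims, sp = sp)
      # fold-over check on the composed field at each phase
      folded <- FALSE
      for (k in phases_use) {
        fld <- level_field(c(levels, list(lev)), Tmat[k + 1L, ], dims)
        if (min_jacobian(fld, dims, mask = fg_mask) <= 0) {
          folded <- TRUE
          break
        }
      }
      if (!folded) break
      warning(sprintf(
        "fold-over detected at level %d; retrying with lambda x10", li))
      lambda <- lambda * 10
    }
    levels <- c(levels, list(lev))
    base <- lapply(seq_len(K) - 1L, function(k) {
      level_field(levels, Tmat[k + 1L, ], dims)
    })
    final <- .cpp_ffd_cost_grad(refvol, vols, as.integer(dims),
                                rep(0, npar), as.integer(gdims),
                                as.double(sp), Tmat,
                                as.integer(phases_use), 0, spec$metric,
                                base)
    report[[li]] <- list(spacing = spacings[li],
                         phase_metric = final$phase_metric,
                         value = fit$value, convergence = fit$convergence,
                         lambda = lambda)
  }
  structure(list(levels = levels, H = spec$harmonics, K = K,
                 ref_phase = ref, spacing_um = cycle$spacing, dims = dims,
                 metric = spec$metric, report = report),
            class = "motion_model")
}

# composed full-grid displacement field (voxel units) over given levels
level_field <- function(levels, tb, dims) {
  total <- NULL
  for (lev in levels) {
    f <- .cpp_ffd_field(as.double(lev$coef), as.integer(lev$gdims),
                        as.double(lev$sp), as.double(tb), as.integer(dims))
    total <- if (is.null(total)) f else total + f
  }
  if (is.null(total)) matrix(0, prod(dims), 3) else total
}

# minimum determinant of I + grad(u) over interior voxels (fold-over test);
# an optional mask restricts the test to tissue
min_jacobian <- function(field, dims, stride = 2L, mask = NULL) {
  ux <- array(field[, 1], dims)
  uy <- array(field[, 2], dims)
  uz <- array(field[, 3], dims)
  ix <- seq(2L, dims[1] - 1L, by = stride)
  iy <- seq(2L, dims[2] - 1L, by = stride)
  iz <- seq(2L, dims[3] - 1L, by = stride)
  d <- function(a, ax) {
    (a[ix + (ax == 1), iy + (ax == 2), iz + (ax == 3)] -
       a[ix - (ax == 1), iy - (ax == 2), iz - (ax == 3)]) / 2
  }
  j11 <- 1 + d(ux, 1); j12 <- d(ux, 2); j13 <- d(ux, 3)
  j21 <- d(uy, 1); j22 <- 1 + d(uy, 2); j23 <- d(uy, 3)
  j31 <- d(uz, 1); j32 <- d(uz, 2); j33 <- 1 + d(uz, 3)
  det <- j11 * (j22 * j33 - j23 * j32) - j12 * (j21 * j33 - j23 * j31) +
    j13 * (j21 * j32 - j22 * j31)
  if (!is.null(mask)) {
    m <- mask[ix, iy, iz]
    if (!any(m)) return(1)
    det <- det[m]
  }
  min(det)
}

#' Evaluate the fitted displacement at physical points
#'
#' @param model a `motion_model`
#' @param points n x 3 matrix of physical positions (um)
#' @param phase cardiac phase in bin units (0..K; fractional values allowed;
#'   `phase = ref_phase` returns exactly zero, and phase K equals phase 0)
#' @return n x 3 matrix of displacements (um)
#' @export
evaluate_displacement <- function(model, points, phase) {
  pts_vox <- sweep(points, 2, model$spacing_um, "/")
  tb <- temporal_basis(phase, model$H, model$K, model$ref_phase)[1, ]
  u <- matrix(0, nrow(points), 3)
  for (lev in model$levels) {
    u <- u + .cpp_ffd_eval_points(as.double(lev$coef),
                                  as.integer(lev$gdims),
                                  as.double(lev$sp), as.double(tb),
                                  pts_vox)
  }
  sweep(u, 2, model$spacing_um, "*")
}

#' Morph the reference mesh through all phases
#'
#' Vertex positions are displaced by the motion model at each phase; the
#' triangulation is shared. Elements that degenerate (nonpositive area) at
#' any phase are flagged for exclusion from strain.
#'
#' @param mesh a [myo_mesh()] at the reference phase
#' @param model a `motion_model`
#' @param phases phase indices (default 0..K-1)
#' @return `morphed_surfaces`: per-phase vertices, per-phase triangle
#'   areas, and flagged element indices
#' @export
morph_mesh <- function(mesh, model, phases = NULL) {
  if (is.null(phases)) phases <- seq_len(model$K) - 1L
  verts <- lapply(phases, function(ph) {
    mesh$vertices + evaluate_displacement(model, mesh$vertices, ph)
  })
  areas <- vapply(verts, function(v) triangle_areas(v, mesh$triangles),
                  numeric(nrow(mesh$triangles)))
  flagged <- which(apply(areas <= 1e-9, 1, any))
  if (length(flagged)) {
    message(sprintf("%d degenerate elements flagged for exclusion",
                    length(flagged)))
  }
  structure(list(mesh = mesh, vertices = verts, areas = areas,
                 phases = phases, ref_col = match(model$ref_phase, phases),
                 flagged = flagged), class = "morphed_surfaces")
}

#' Morph a mesh with an arbitrary deformation function
#'
#' Drop-in alternative to [morph_mesh()] taking a function
#' `f(points, phase)` returning deformed positions — e.g. the analytic
#' phantom map — so downstream strain code can run on ground truth.
#'
#' @param mesh a [myo_mesh()]
#' @param deform function of (points, phase_index) returning positions
#' @param phases phase indices
#' @param ref_phase which phase is the reference
#' @return `morphed_surfaces`
#' @export
morph_mesh_fun <- function(mesh, deform, phases, ref_phase = phases[1]) {
  verts <- lapply(phases, function(ph) deform(mesh$vertices, ph))
  areas <- vapply(verts, function(v) triangle_areas(v, mesh$triangles),
                  numeric(nrow(mesh$triangles)))
  flagged <- which(apply(areas <= 1e-9, 1, any))
  structure(list(mesh = mesh, vertices = verts, areas = areas,
                 phases = phases, ref_col = match(ref_phase, phases),
                 flagged = flagged), class = "morphed_surfaces")
}

#' Warp morphed surfaces along their displacement vectors
#'
#' Each phase mesh is displaced by `scale` times its own displacement from
#' the reference; `scale = -1` removes the contractile motion, collapsing
#' every phase onto the reference configuration while carrying per-phase
#' attributes.
#'
#' @param surfaces `morphed_surfaces`
#' @param scale warp factor
#' @return `morphed_surfaces` with warped vertices and updated areas
#' @export
warp_for_visualization <- function(surfaces, scale) {
  ref_v <- surfaces$mesh$vertices
  surfaces$vertices <- lapply(surfaces$vertices, function(v) {
    v + scale * (v - ref_v)
  })
  surfaces$areas <- vapply(surfaces$vertices, function(v) {
    triangle_areas(v, surfaces$mesh$triangles)
  }, numeric(nrow(surfaces$mesh$triangles)))
  surfaces
}
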