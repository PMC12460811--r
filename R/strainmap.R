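# Per-element area strain over the cardiac cycle, regional summaries
# (mean and strain-variation curves), and scalar functional metrics.

#' Per-element area strain
#'
#' For each kept triangular element j and phase t,
#' `epsilon_area,j(t) = sqrt(A_j(t) / A_j(0))`, where A_j(0) is the element
#' area at the reference (minimum-volume) phase. Elements flagged as
#' degenerate at any phase, or with nonpositive reference area, are
#' excluded at all phases so summary counts stay phase-constant.
#'
#' @param surfaces a `morphed_surfaces` from [morph_mesh()]
#' @return `strain_field`: matrix of strains (kept elements x phases),
#'   kept element indices, and the exclusion list
#' @export
area_strain <- function(surfaces) {
  a0 <- surfaces$areas[, surfaces$ref_col]
  bad <- union(surfaces$flagged, which(a0 <= 0))
  keep <- setdiff(seq_len(nrow(surfaces$areas)), bad)
  strain <- sqrt(surfaces$areas[keep, , drop = FALSE] / a0[keep])
  structure(list(strain = strain, kept = keep, excluded = sort(bad),
                 phases = surfaces$phases, ref_col = surfaces$ref_col),
            class = "strain_field")
}

#' Regional strain summary: mean and strain variation per phase
#'
#' For each phase and each surface (epi, endo) within the sampling region,
#' the mean area strain and the strain variation — the standard deviation
#' of element strains at that phase, with denominator n (the elements
#' tessellate the region exhaustively; they are not a sample).
#'
#' @param field a `strain_field`
#' @param mesh the labelled [myo_mesh()] the field was computed on
#' @param use_region restrict to the mesh's sampling-region mask
#' @return data frame with phase, surface, n, mean_strain, sd_strain
#' @export
summarize_strain <- function(field, mesh, use_region = TRUE) {
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- list()
  for (surf in c("epi", "endo")) {
    sel <- mesh$surface[field$kept] == surf
    if (use_region) sel <- sel & mesh$region[field$kept]
    n <- sum(sel)
    if (n == 0) next
    if (n < 10) warning(sprintf("region '%s' has only %d elements", surf, n))
    for (j in seq_along(field$phases)) {
      x <- field$strain[sel, j]
      out[[length(out) + 1]] <- data.frame(
        phase = field$phases[j], surface = surf, n = n,
        mean_strain = mean(x), sd_strain = pop_sd(x))
    }
  }
  do.call(rbind, out)
}

#' Ejection fraction from diastolic and systolic ventricular areas
#'
#' `(Diastolic area - Systolic area) / Diastolic area x 100%`, the 2-D
#' projection-based contractility estimate.
#'
#' @param diastolic_area,systolic_area ventricular areas (same units)
#' @return ejection fraction in percent; negative values (systolic larger
#'   than diastolic) raise a warning as they signal mis-identified phases
#' @export
ejection_fraction <- function(diastolic_area, systolic_area) {
  stopifnot(diastolic_area > 0, systolic_area >= 0)
  ef <- (diastolic_area - systolic_area) / diastolic_area * 100
  if (ef < 0) warning("negative ejection fraction: phases may be swapped")
  ef
}

# shoelace area of a simple polygon (n x 2 matrix)
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

# segment-intersection test for polygon simplicity
is_simple_polygon <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE]))
  inter <- function(a, b, c3, d) {
    o <- function(p1, p2, p3) {
      v <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
        (p2[2] - p1[2]) * (p3[1] - p1[1])
      sign(v)
    }
    o(a, b, c3) != o(a, b, d) && o(c3, d, a) != o(c3, d, b)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (inter(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Cell cross-sectional area change as a strain estimate
#'
#' The ratio of cross-sectional areas of a cell outline between two time
#' points; with cardiomyocytes treated as incompressible (conserved volume
#' during contraction), area change estimates deformation.
#'
#' @param outline_t0,outline_t simple polygons (n x 2 matrices, um)
#' @return area ratio (t over t0); percent change in attribute
#'   `"percent_change"`
#' @export
cell_area_strain <- function(outline_t0, outline_t) {
  outline_t0 <- as.matrix(outline_t0)
  outline_t <- as.matrix(outline_t)
  if (!is_simple_polygon(outline_t0) || !is_simple_polygon(outline_t)) {
    stop("self-intersecting polygon")
  }
  ratio <- polygon_area(outline_t) / polygon_area(outline_t0)
  structure(ratio, percent_change = 100 * (ratio - 1))
}
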