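# Area strain, regional summaries and scalar functional metrics.

# fabricate morphed surfaces from a mesh and a deformation function
fab_surfaces <- function(mesh, deform, K = 4) {
  morph_mesh_fun(mesh, deform, phases = 0:(K - 1), ref_phase = 0)
}

unit_mesh <- function() {
  ico <- icosphere(2)
  myo_mesh(ico$vertices * 10, ico$triangles)
}

test_that("area strain follows the square root of the area ratio", {
  mesh <- unit_mesh()
  id <- fab_surfaces(mesh, function(p, ph) p)
  f <- area_strain(id)
  expect_true(all(f$strain == 1))
  # linear scaling by 1.1 about the centroid: strain 1.1 everywhere
  sc <- fab_surfaces(mesh, function(p, ph) if (ph == 0) p else p * 1.1)
  f2 <- area_strain(sc)
  expect_lt(max(abs(f2$strain[, 2:4] - 1.1)), 1e-12)
  # random affine map: strain agrees with a direct cross-product oracle
  set.seed(21)
  A <- diag(3) + matrix(rnorm(9, 0, 0.1), 3)
  af <- fab_surfaces(mesh, function(p, ph) if (ph == 0) p else p %*% t(A))
  f3 <- area_strain(af)
  a0 <- triangle_areas(mesh$vertices, mesh$triangles)
  a1 <- triangle_areas(mesh$vertices %*% t(A), mesh$triangles)
  expect_equal(f3$strain[, 2], sqrt(a1 / a0), tolerance = 1e-12)
})

test_that("strain summaries use the population SD and behave at phase 0", {
  mesh <- unit_mesh()
  mesh$surface <- rep(c("epi", "endo"), length.out = nrow(mesh$triangles))
  sc <- fab_surfaces(mesh, function(p, ph) if (ph == 0) p else p * 1.05)
  f <- area_strain(sc)
  sm <- summarize_strain(f, mesh)
  # homogeneous scaling: zero strain variation at every phase
  expect_true(all(sm$sd_strain < 1e-12))
  expect_true(all(sm$mean_strain[sm$phase == 0] == 1))
  # two-subpopulation field: mean 1.1, SD 0.1 by the population formula
  half <- nrow(f$strain) / 2
  f$strain[, 2] <- rep(c(1.0, 1.2), each = half)
  sm2 <- summarize_strain(f, myo_mesh(mesh$vertices, mesh$triangles,
                                      surface = rep("endo",
                                                    nrow(mesh$triangles))))
  row <- sm2[sm2$phase == 1, ]
  expect_equal(row$mean_strain, 1.1, tolerance = 1e-12)
  expect_equal(row$sd_strain, 0.1, tolerance = 1e-12)
  # SD agrees with the one-line brute-force computation on random fields
  set.seed(22)
  f$strain[, 3] <- runif(nrow(f$strain), 0.9, 1.3)
  sm3 <- summarize_strain(f, mesh)
  x <- f$strain[mesh$surface[f$kept] == "epi" & mesh$region[f$kept], 3]
  expect_equal(sm3$sd_strain[sm3$phase == 2 & sm3$surface == "epi"],
               sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
})

test_that("total deformed area is conserved through the strain field", {
  mesh <- unit_mesh()
  set.seed(23)
  A <- diag(3) + matrix(rnorm(9, 0, 0.05), 3)
  surf <- fab_surfaces(mesh, function(p, ph) if (ph == 0) p else p %*% t(A))
  f <- area_strain(surf)
  a0 <- mesh$ref_areas[f$kept]
  expect_equal(sum(a0 * f$strain[, 2]^2), sum(surf$areas[f$kept, 2]),
               tolerance = 1e-12)
})

test_that("ejection fraction follows the printed formula", {
  expect_equal(ejection_fraction(100, 50), 50)
  expect_equal(ejection_fraction(100, 100), 0)
  expect_warning(ef <- ejection_fraction(80, 100), "negative")
  expect_equal(ef, -25)
})

test_that("phantom ejection fraction matches the prescribed area change", {
  # endocardial amplitude chosen for a 15% systolic/diastolic area ratio
  # reduction of the mid-slice lumen
  A <- 1 / sqrt(0.85) - 1
  spec <- phantom_spec(ridges = list(), radial_ampl_epi = A,
                       radial_ampl_endo = A, ridge_shortening = NA,
                       ridge_thickening = 0, poisson = FALSE,
                       read_noise_sd = 0, seed = 24)
  lumen_area <- function(pf) {
    vol <- strain4d:::render_volume(spec, pf)
    seg <- segment_myocardium(rolling_ball(vol, 40),
                              c(spec$pixel_size, spec$pixel_size,
                                spec$z_step))
    mid <- seg$labels[, , 20]
    # lumen: background not connected to the image border
    cc <- strain4d:::.cpp_label3d(as.logical(array(mid == 0L,
                                                   c(dim(mid), 1))),
                                  c(dim(mid), 1L), 6L)
    inner <- which(cc$touches_border == 0)
    sum(cc$labels %in% inner) * spec$pixel_size^2
  }
  ef <- ejection_fraction(lumen_area(0.5), lumen_area(0))
  expect_lt(abs(ef - 15), 1)
})

test_that("cell cross-sectional area change matches polygon areas", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(as.numeric(cell_area_strain(sq, sq)), 1)
  expect_equal(as.numeric(cell_area_strain(sq, sq * 2)), 4)
  # random convex polygon under an affine map: ratio is |det|
  set.seed(25)
  ang <- sort(runif(8, 0, 2 * pi))
  poly <- cbind(cos(ang), sin(ang)) * runif(1, 1, 3)
  M <- matrix(rnorm(4, 0, 1), 2)
  while (abs(det(M)) < 0.1) M <- matrix(rnorm(4, 0, 1), 2)
  r <- cell_area_strain(poly, poly %*% t(M))
  expect_equal(as.numeric(r), abs(det(M)), tolerance = 1e-12)
  expect_equal(attr(r, "percent_change"), 100 * (abs(det(M)) - 1),
               tolerance = 1e-9)
  bow <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(cell_area_strain(bow, bow), "self-intersecting")
})
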