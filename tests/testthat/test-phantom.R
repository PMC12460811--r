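# Synthetic beating-heart generator: spec validation, analytic-truth
# identities, determinism, and export round-trips.

test_that("phantom spec invariants are enforced", {
  expect_error(phantom_spec(inner_axes = c(15, 15, 15)), "inner")
  expect_error(phantom_spec(period = -1))
  expect_error(phantom_spec(radial_ampl_epi = 1.2), "amplitude")
  expect_error(phantom_spec(ridge_shortening = 1.5), "ridge_shortening")
  expect_error(phantom_spec(n_frames = 10), "two cardiac cycles")
  # shell thinner than two voxels at the requested resolution
  expect_error(phantom_spec(inner_axes = c(13.5, 13.5, 13.5)),
               "thinner than 2 voxels")
})

test_that("zero-amplitude phantom is static and has unit area strain", {
  spec <- small_spec(seed = 5, radial_ampl_epi = 0, radial_ampl_endo = 0,
                     ridge_shortening = NA, ridge_thickening = 0,
                     n_frames = 44, poisson = FALSE, read_noise_sd = 0)
  ph <- build_phantom(spec)
  px <- ph$movie$slices[[12]]$pixels
  for (f in c(7, 23, 40)) {
    expect_identical(px[, , f], px[, , 1])
  }
  eps <- ph$truth$area_strain(c(0.25, 0.5, 0.8))
  expect_lt(max(abs(eps - 1)), 1e-12)
})

test_that("isotropic contraction gives area strain equal to the scale", {
  A <- 0.1
  spec <- small_spec(seed = 6, radial_ampl_epi = A, radial_ampl_endo = A,
                     ridge_shortening = NA, ridge_thickening = 0)
  tru <- phantom_truth(spec)
  for (pf in c(0.2, 0.5)) {
    s <- 1 + A * phantom_waveform(pf, spec$waveform)
    expect_lt(max(abs(tru$area_strain(pf) - s)), 1e-10)
  }
})

test_that("prescribed radial-ridge shortening is realised at peak", {
  spec <- phantom_spec(ridge_shortening = 0.20, ridge_thickening = 0,
                       radial_ampl_epi = 0.08, radial_ampl_endo = 0.12,
                       seed = 7)
  tru <- phantom_truth(spec)
  rad <- which(vapply(tru$ridge_traces, function(t) t$class, "") ==
                 "radial")
  for (i in rad[1:2]) {
    s <- tru$ridge_shortening(tru$ridge_traces[[i]], 0.5)
    expect_lt(abs(s - 0.20), 0.005)
  }
})

test_that("deformation is exactly periodic and identity at phase 0", {
  spec <- phantom_spec(seed = 8)
  set.seed(1)
  p <- cbind(runif(40, 15, 36), runif(40, 15, 36), runif(40, 10, 30))
  expect_lt(max(abs(phantom_deform(p, 0, spec) - p)), 1e-12)
  u0 <- phantom_deform(p, 0.3, spec)
  u1 <- phantom_deform(p, 1.3, spec)
  expect_lt(max(abs(u0 - u1)), 1e-9)
})

test_that("identical spec and seed give bit-identical movies", {
  spec <- small_spec(seed = 9, n_frames = 40)
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(a$movie$slices[[10]]$pixels, b$movie$slices[[10]]$pixels)
  spec2 <- small_spec(seed = 10, n_frames = 40)
  c3 <- build_phantom(spec2)
  expect_false(identical(a$movie$slices[[10]]$pixels,
                         c3$movie$slices[[10]]$pixels))
})

test_that("Jacobian-route truth agrees with subdivided-mesh area ratios", {
  # ridge-free phantom: agreement to numerical precision of the routes
  spec0 <- phantom_spec(ridges = list(), ridge_thickening = 0, seed = 11,
                        radial_ampl_epi = 0.06, radial_ampl_endo = 0.12,
                        ridge_shortening = NA)
  tru0 <- phantom_truth(spec0, mesh_subdiv = 4)
  cen <- strain4d:::triangle_centroids(tru0$mesh$vertices,
                                       tru0$mesh$triangles)
  jac <- tru0$strain_jacobian(cen, 0.5)
  msh <- tru0$area_strain(0.5)
  expect_lt(max(abs(jac - msh) / msh), 5e-3)
  # default ridged phantom: agreement within 1% on average at 4x
  # subdivision (per-element differences near ridges are O(h^2))
  spec <- phantom_spec(seed = 11)
  tru <- phantom_truth(spec, mesh_subdiv = 5)
  cen <- strain4d:::triangle_centroids(tru$mesh$vertices,
                                       tru$mesh$triangles)
  jac <- tru$strain_jacobian(cen, 0.5)
  msh <- tru$area_strain(0.5)
  expect_lt(mean(abs(jac - msh) / msh), 0.01)
})

test_that("export round-trips bit-exactly with correct bookkeeping", {
  spec <- small_spec(seed = 12, nz = 5, n_frames = 60)
  ph <- build_phantom(spec)
  dir <- withr::local_tempdir()
  export_phantom(ph$movie, dir)
  expect_length(list.files(dir, pattern = "\\.tif$"), 5)
  pages <- tiff::readTIFF(file.path(dir, "z003.tif"), all = TRUE)
  expect_length(pages, 60)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$frame_rate_hz, 30)
  back <- read_movies(dir)
  for (k in c(1, 3, 5)) {
    expect_identical(back$slices[[k]]$pixels, ph$movie$slices[[k]]$pixels)
    expect_equal(back$slices[[k]]$z_um, ph$movie$slices[[k]]$z_um)
  }
  expect_error(export_phantom(ph$movie, dir), "force")
  expect_silent(export_phantom(ph$movie, dir, force = TRUE))
})
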