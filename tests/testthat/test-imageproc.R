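# Preprocessing, segmentation and meshing.

test_that("resampling preserves identity, constants and linear ramps", {
  set.seed(3)
  vol <- array(runif(20 * 18 * 12), c(20, 18, 12))
  same <- resample_volume(vol, c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$vol, vol)
  const <- resample_volume(array(3.5, c(16, 16, 8)), c(1, 1, 1), c(2, 2, 2))
  expect_true(all(abs(const$vol - 3.5) < 1e-12))
  # linear ramp: downsampled values equal the ramp at new voxel centres
  ramp <- array(rep(seq(0, 19), times = 16 * 8), c(20, 16, 8))
  down <- resample_volume(ramp, c(1, 1, 1), c(2, 1, 1))
  expected <- array(rep(seq(0, 18, by = 2), times = 16 * 8),
                    dim = dim(down$vol))
  expect_equal(down$vol, expected, tolerance = 1e-12)
  expect_error(resample_volume(vol, c(1, 1, 1), c(0.5, 1, 1)), ">=")
  expect_error(resample_volume(vol, c(1, 1, 1), c(-1, 1, 1)))
})

test_that("rolling-ball background removal matches brute-force opening", {
  expect_equal(rolling_ball(matrix(0, 30, 30), 5), matrix(0, 30, 30))
  expect_true(all(rolling_ball(matrix(7, 30, 30), 5) < 1e-9))
  # constant background + bright spot: spot preserved, background removed
  img <- matrix(10, 48, 48)
  img[23:25, 23:25] <- 110
  out <- rolling_ball(img, 10)
  expect_gt(min(out[23:25, 23:25]), 0.95 * 100)
  expect_lt(max(out[-(15:33), ]), 0.01 * 100)
  # oracle: explicit min/max-filter opening (interior, away from the
  # differing border-padding conventions)
  set.seed(4)
  rnd <- matrix(runif(30 * 30, 0, 50), 30, 30)
  rnd[12:14, 18:20] <- 200
  inner <- 6:25
  expect_equal(rolling_ball(rnd, 5)[inner, inner],
               bf_rolling_ball(rnd, 5)[inner, inner], tolerance = 1e-8)
  # idempotent on its own output
  once <- rolling_ball(rnd, 5)
  expect_equal(rolling_ball(once, 5), once, tolerance = 1e-8)
  expect_error(rolling_ball(matrix(0, 10, 10), 20), "larger")
})

test_that("segmentation of the phantom overlaps the true labels", {
  fx <- fx_segmented()
  ph <- fx_noisy_phantom()
  truth <- ph$truth$label_volume(0.05)  # centre of the reference bin
  dice <- 2 * sum(fx$seg$labels & truth$labels) /
    (sum(fx$seg$labels) + sum(truth$labels))
  expect_gte(dice, 0.90)
})

test_that("noiseless segmentation is near-perfect", {
  spec <- phantom_spec(seed = 301, poisson = FALSE, read_noise_sd = 0)
  vol <- strain4d:::render_volume(spec, 0.05)
  seg <- segment_myocardium(rolling_ball(vol, 40),
                            c(spec$pixel_size, spec$pixel_size,
                              spec$z_step))
  truth <- phantom_truth(spec)$label_volume(0.05)
  dice <- 2 * sum(seg$labels & truth$labels) /
    (sum(seg$labels) + sum(truth$labels))
  expect_gte(dice, 0.97)
})

test_that("implausible volumes are rejected", {
  set.seed(5)
  noise <- array(abs(rnorm(32^3, 10, 3)), c(32, 32, 32))
  expect_error(segment_myocardium(noise, c(1, 1, 1)), "implausible")
})

test_that("meshed sphere area matches the closed form and converges", {
  sphere_labels <- function(spacing, r = 20) {
    n <- ceiling(2 * (r + 4) / spacing)
    ax <- (seq_len(n) - 1) * spacing
    c0 <- mean(range(ax))
    g <- expand.grid(x = ax, y = ax, z = ax)
    lab <- array(as.integer((g$x - c0)^2 + (g$y - c0)^2 +
                              (g$z - c0)^2 <= r^2), rep(n, 3))
    label_volume(lab, rep(spacing, 3))
  }
  area_err <- function(spacing) {
    mesh <- mesh_surface(sphere_labels(spacing))
    abs(sum(mesh$ref_areas) - 4 * pi * 400) / (4 * pi * 400)
  }
  e2 <- area_err(2)
  e1 <- area_err(1)
  expect_lt(e1, 0.05)
  expect_lt(e1, 0.7 * e2)
})

test_that("a shell meshes into epicardial and endocardial components", {
  fx <- fx_segmented()
  mesh <- fx$mesh
  expect_true(all(mesh$ref_areas > 0))
  expect_setequal(unique(mesh$surface), c("epi", "endo"))
  a_epi <- sum(mesh$ref_areas[mesh$surface == "epi"])
  a_endo <- sum(mesh$ref_areas[mesh$surface == "endo"])
  expect_gt(a_epi, a_endo)
  # epi/endo assignment matches the truth transmural side for every element
  ph <- fx_noisy_phantom()
  spec <- ph$truth$spec
  cen <- strain4d:::triangle_centroids(mesh$vertices, mesh$triangles)
  sc <- strain4d:::sph_coords(cen, spec$center)
  r_mid <- strain4d:::ellipsoid_radius(sc$theta, sc$phi,
                                       (spec$outer_axes +
                                          spec$inner_axes) / 2)
  truth_side <- ifelse(sc$r > r_mid, "epi", "endo")
  expect_equal(mean(mesh$surface == truth_side), 1)
})

test_that("a solid sphere has no endocardial surface", {
  n <- 24
  ax <- seq_len(n) - 1
  g <- expand.grid(x = ax, y = ax, z = ax)
  lab <- array(as.integer((g$x - 11.5)^2 + (g$y - 11.5)^2 +
                            (g$z - 11.5)^2 <= 64), rep(n, 3))
  mesh <- mesh_surface(label_volume(lab, c(1, 1, 1)))
  expect_error(split_epi_endo(mesh), "no endocardial surface")
})

test_that("region selection behaves like a clipping plane", {
  fx <- fx_segmented()
  mesh <- fx$mesh
  spec <- fx_noisy_phantom()$truth$spec
  all_sel <- select_region(mesh, list(point = c(-100, 0, 0),
                                      normal = c(1, 0, 0)))
  expect_true(all(all_sel$region))
  half <- select_region(mesh, list(point = spec$center,
                                   normal = c(1, 0, 0)))
  frac <- sum(mesh$ref_areas[half$region & mesh$surface == "epi"]) /
    sum(mesh$ref_areas[mesh$surface == "epi"])
  expect_lt(abs(frac - 0.5), 0.05)
  # selected endocardial elements overlap the selected epicardial region
  endo_sel <- which(half$region & half$surface == "endo")
  expect_gt(length(endo_sel), 100)
  expect_error(select_region(mesh, list(point = c(1e4, 0, 0),
                                        normal = c(1, 0, 0))), "empty")
})
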