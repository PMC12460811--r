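# Cyclic B-spline/Fourier registration: basis evaluation, invariants and
# motion recovery on small phantoms.

# hand-built single-level motion model
toy_model <- function(coef, gdims, sp, H, K, ref = 0L,
                      spacing_um = c(1, 1, 1), dims = c(16, 16, 16)) {
  structure(list(levels = list(list(coef = coef, gdims = gdims,
                                    sp = rep(sp, 3))),
                 H = H, K = K, ref_phase = ref, spacing_um = spacing_um,
                 dims = dims, metric = "ssd", report = list()),
            class = "motion_model")
}

test_that("displacement evaluation matches brute-force B-spline sums", {
  set.seed(11)
  gdims <- c(6, 5, 5)
  H <- 2; K <- 8
  coef <- array(rnorm(prod(gdims) * 3 * 2 * H, 0, 0.5),
                c(prod(gdims), 3, 2 * H))
  mod <- toy_model(coef, gdims, 4, H, K)
  pts <- cbind(runif(25, 0, 8), runif(25, 0, 8), runif(25, 0, 8))
  for (ph in c(1, 3.5, 6)) {
    tb <- strain4d:::temporal_basis(ph, H, K, 0)[1, ]
    expect_equal(evaluate_displacement(mod, pts, ph),
                 bf_bspline_eval(coef, gdims, rep(4, 3), tb, pts),
                 tolerance = 1e-10)
  }
})

test_that("displacement vanishes at the reference phase and is periodic", {
  set.seed(12)
  gdims <- c(5, 5, 5)
  coef <- array(rnorm(prod(gdims) * 3 * 4), c(prod(gdims), 3, 4))
  mod <- toy_model(coef, gdims, 4, 2, 10, ref = 3L)
  pts <- cbind(runif(10, 2, 10), runif(10, 2, 10), runif(10, 2, 10))
  expect_true(all(evaluate_displacement(mod, pts, 3) == 0))
  expect_equal(evaluate_displacement(mod, pts, 0),
               evaluate_displacement(mod, pts, 10), tolerance = 1e-12)
})

test_that("a single cosine harmonic traces a cosine over phase", {
  gdims <- c(5, 5, 5)
  K <- 12
  coef <- array(0, c(prod(gdims), 3, 2))
  coef[, 1, 1] <- 1  # cos-1 basis, x component, all control points equal
  mod <- toy_model(coef, gdims, 4, 1, K)
  p <- matrix(c(6, 6, 6), 1)
  u <- vapply(0:(K - 1), function(ph) {
    evaluate_displacement(mod, p, ph)[1, 1]
  }, numeric(1))
  expect_equal(u, cos(2 * pi * (0:(K - 1)) / K) - 1, tolerance = 1e-12)
})

test_that("identical volumes fit to a negligible displacement", {
  set.seed(13)
  vol <- array(runif(32 * 32 * 20), c(32, 32, 20))
  vol <- array(strain4d:::.cpp_gauss3d(as.double(vol), as.integer(dim(vol)),
                                       c(2, 2, 2)), dim(vol))
  cyc <- list(volumes = rep(list(vol), 5), K = 5, spacing = c(1, 1, 1))
  mod <- fit_motion(cyc, motion_spec(grid_spacing = 8, levels = 1,
                                     maxit = 20, ref_phase = 0L))
  pts <- as.matrix(expand.grid(seq(4, 28, 4), seq(4, 28, 4), seq(4, 16, 4)))
  umax <- max(abs(vapply(0:4, function(ph) {
    max(abs(evaluate_displacement(mod, pts, ph)))
  }, numeric(1))))
  expect_lt(umax, 0.1)
})

test_that("morphing respects rigid motions and the zero model", {
  fx <- fx_small_fit()
  mesh0 <- phantom_truth(fx$spec)$mesh
  dims <- dim(fx$cycle$volumes[[1]])
  gdims <- strain4d:::grid_dims_for(dims, rep(6, 3))
  zero <- toy_model(array(0, c(prod(gdims), 3, 2)), gdims, 6, 1, 6,
                    spacing_um = fx$cycle$spacing, dims = dims)
  surf0 <- morph_mesh(mesh0, zero)
  expect_equal(surf0$vertices[[4]], mesh0$vertices)
  expect_true(all(abs(surf0$areas - mesh0$ref_areas) < 1e-12))
  # uniform translation: partition of unity makes all-equal coefficients a
  # constant displacement; areas are unchanged at every phase
  trans <- zero
  trans$levels[[1]]$coef[, 1, 1] <- 2
  trans$levels[[1]]$coef[, 3, 2] <- 1
  surft <- morph_mesh(mesh0, trans)
  expect_lt(max(abs(surft$areas - mesh0$ref_areas)), 1e-9)
})

test_that("fitted motion recovers the phantom deformation", {
  fx <- fx_small_fit()
  spec <- fx$spec
  tru <- fx$truth
  labv <- tru$label_volume(0.5 / 6)
  idx <- which(labv$labels == 1)
  d <- dim(labv$labels)
  co <- cbind((idx - 1) %% d[1], ((idx - 1) %/% d[1]) %% d[2],
              (idx - 1) %/% (d[1] * d[2]))
  set.seed(14)
  pts <- sweep(co[sample(nrow(co), 1500), ], 2,
               c(spec$pixel_size, spec$pixel_size, spec$z_step), "*")
  epe <- vapply(1:5, function(b) {
    u_est <- evaluate_displacement(fx$model, pts, b)
    u_true <- tru$u_fun(pts, (b + 0.5) / 6) - tru$u_fun(pts, 0.5 / 6)
    mean(sqrt(rowSums((u_est - u_true)^2)))
  }, numeric(1))
  expect_lt(mean(epe), max(spec$pixel_size, spec$z_step))
})

test_that("reversing the phase order mirrors the fitted motion", {
  fx <- fx_small_fit()
  cyc <- fx$cycle
  K <- cyc$K
  rev_cyc <- cyc
  rev_cyc$volumes <- cyc$volumes[c(1, K:2)]
  mod_r <- fit_motion(rev_cyc, motion_spec(grid_spacing = 8, levels = 1,
                                           maxit = 25, ref_phase = 0L))
  pts <- fx$truth$mesh$vertices[seq(1, 600, by = 7), ]
  for (k in c(1, 2)) {
    u_f <- evaluate_displacement(fx$model, pts, k)
    u_r <- evaluate_displacement(mod_r, pts, K - k)
    expect_lt(mean(sqrt(rowSums((u_f - u_r)^2))), 0.25)
  }
})

test_that("stronger regularisation never increases bending energy", {
  fx <- fx_small_fit()
  cyc <- fx$cycle
  bends <- vapply(c(1e-3, 1e-1, 10), function(lam) {
    mod <- fit_motion(cyc, motion_spec(grid_spacing = 8, levels = 1,
                                       maxit = 15, lambda = lam,
                                       ref_phase = 0L))
    lev <- mod$levels[[1]]
    res <- strain4d:::.cpp_ffd_cost_grad(
      as.double(cyc$volumes[[1]]), lapply(cyc$volumes, as.double),
      as.integer(dim(cyc$volumes[[1]])), as.double(lev$coef),
      as.integer(lev$gdims), as.double(lev$sp),
      strain4d:::temporal_basis(0:5, 2, 6, 0), integer(0), 1, "ssd", NULL)
    res$bending
  }, numeric(1))
  expect_true(all(diff(bends) <= 1e-12))
})

test_that("finer control grids reduce registration error", {
  fx <- fx_small_fit()
  cyc <- fx$cycle
  tru <- fx$truth
  pts <- tru$mesh$vertices[seq(1, nrow(tru$mesh$vertices), by = 5), ]
  err_at <- function(sp) {
    mod <- fit_motion(cyc, motion_spec(grid_spacing = sp, levels = 1,
                                       maxit = 25, ref_phase = 0L))
    u_est <- evaluate_displacement(mod, pts, 3)
    u_true <- tru$u_fun(pts, 3.5 / 6) - tru$u_fun(pts, 0.5 / 6)
    mean(sqrt(rowSums((u_est - u_true)^2)))
  }
  expect_lt(err_at(8), err_at(24))
})

test_that("visualization warp removes or doubles the motion", {
  fx <- fx_small_fit()
  mesh0 <- fx$truth$mesh
  surf <- morph_mesh(mesh0, fx$model)
  w0 <- warp_for_visualization(surf, 0)
  expect_equal(w0$vertices, surf$vertices)
  wm1 <- warp_for_visualization(surf, -1)
  for (j in seq_along(surf$phases)) {
    expect_equal(wm1$vertices[[j]], mesh0$vertices, tolerance = 1e-12)
  }
  wp1 <- warp_for_visualization(surf, 1)
  d1 <- wp1$vertices[[3]] - mesh0$vertices
  d0 <- surf$vertices[[3]] - mesh0$vertices
  expect_equal(d1, 2 * d0, tolerance = 1e-12)
})
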