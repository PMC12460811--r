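# Trabecular ridge metrics: lengths, transmural thickening, compact-layer
# circumference, and their invariances.

test_that("trace length is invariant to resampling density", {
  set.seed(31)
  t <- seq(0, 1, length.out = 40)
  pts <- cbind(10 * cos(t), 10 * sin(t), 5 * t)
  tr <- ridge_trace(pts, "radial")
  l1 <- measure_ridge_shortening(tr, function(p, ph) p, 1,
                                 step = 0.5)$length_ref
  l2 <- measure_ridge_shortening(tr, function(p, ph) p, 1,
                                 step = 0.05)$length_ref
  expect_lt(abs(l1 - l2) / l2, 0.001)
})

test_that("ridge shortening follows prescribed 1-D compressions", {
  straight <- ridge_trace(cbind(seq(0, 10, length.out = 21), 0, 0),
                          "radial")
  none <- measure_ridge_shortening(straight, function(p, ph) p, 1)
  expect_equal(none$shortening, 0)
  squeeze <- function(p, ph) cbind(p[, 1] * 0.8, p[, 2], p[, 3])
  m <- measure_ridge_shortening(straight, squeeze, 1)
  expect_equal(m$shortening, 0.2, tolerance = 1e-12)
})

test_that("all ridge metrics vanish under rigid motion", {
  spec <- small_spec(seed = 32)
  tru <- phantom_truth(spec)
  # any translation leaves material lengths unchanged
  shift <- function(p, ph) {
    if (ph == 0) p else sweep(p, 2, c(1.5, -2, 0.5), "+")
  }
  tr <- tru$ridge_traces[[1]]
  expect_equal(measure_ridge_shortening(tr, shift, 2)$shortening, 0,
               tolerance = 1e-12)
  # cross-section metrics use planes fixed in space, so rigid invariance
  # holds for translations within the cutting plane
  th <- 55 * pi / 180
  crest_r <- strain4d:::ellipsoid_radius(th, 0, spec$inner_axes) -
    strain4d:::ridge_bump(th, 0, spec, "all")
  dirv <- c(sin(th), 0, cos(th))
  shift_r <- function(p, ph) {
    if (ph == 0) p else sweep(p, 2, 1.5 * dirv, "+")
  }
  surf_r <- morph_mesh_fun(tru$mesh, shift_r, 0:3, 0)
  pl <- list(point = spec$center + crest_r * dirv,
             normal = c(cos(th), 0, -sin(th)))
  tm <- measure_transmural_strain(tr, pl, surf_r, 2)
  expect_lt(abs(tm$transmural_strain), 0.02)
  shift_xy <- function(p, ph) {
    if (ph == 0) p else sweep(p, 2, c(1.5, -2, 0), "+")
  }
  surf_xy <- morph_mesh_fun(tru$mesh, shift_xy, 0:3, 0)
  cc <- measure_compact_circumferential(
    list(point = spec$center, normal = c(0, 0, 1)), surf_xy, 2)
  expect_lt(abs(cc$circumferential_strain), 1e-9)
})

test_that("transmural caliper reproduces a prescribed thickening", {
  spec <- trabecular_spec(seed = 33)
  tru <- phantom_truth(spec, mesh_subdiv = 4)
  deform <- function(p, b) phantom_deform(p, (b + 0.5) / 10, spec)
  surf <- morph_mesh_fun(tru$mesh, deform, 0:9, 0)
  th <- 55 * pi / 180
  crest_r <- 12 - strain4d:::ridge_bump(th, 0, spec, "all")
  pl <- list(point = spec$center + crest_r * c(sin(th), 0, cos(th)),
             normal = c(cos(th), 0, -sin(th)))
  tm <- measure_transmural_strain(tru$ridge_traces[[1]], pl, surf, 5)
  # analytic caliper truth: deformed crest and epicardial points
  dirv <- c(sin(th), 0, cos(th))
  h_at <- function(pf) {
    c1 <- phantom_deform(rbind(spec$center + crest_r * dirv), pf, spec)
    e1 <- phantom_deform(rbind(spec$center + 18 * dirv), pf, spec)
    sqrt(sum((e1 - spec$center)^2)) - sqrt(sum((c1 - spec$center)^2))
  }
  truth <- (h_at(0.55) - h_at(0.05)) / h_at(0.05)
  expect_lt(abs(tm$transmural_strain - truth), 0.03)
})

test_that("compact circumferential strain tracks the contour scale", {
  ico <- icosphere(3)
  mesh <- myo_mesh(rbind(ico$vertices * 20, ico$vertices * 12),
                   rbind(ico$triangles, ico$triangles + nrow(ico$vertices)),
                   surface = rep(c("epi", "endo"),
                                 each = nrow(ico$triangles)))
  shrink <- function(p, ph) {
    if (ph == 0) p else cbind(p[, 1] * 0.9, p[, 2] * 0.9, p[, 3])
  }
  surf <- morph_mesh_fun(mesh, shrink, 0:2, 0)
  cc <- measure_compact_circumferential(
    list(point = c(0, 0, 0), normal = c(0, 0, 1)), surf, 1)
  expect_equal(cc$circumferential_strain, -0.10, tolerance = 1e-6)
})

test_that("ridge annotations round-trip through JSON", {
  tr <- list(ridge_trace(cbind(1:5, 2, 3), "radial", id = "r1"),
             ridge_trace(cbind(0, 1:4, 2), "circumferential", id = "c1"))
  path <- withr::local_tempfile(fileext = ".json")
  write_ridge_annotations(tr, path)
  back <- read_ridge_annotations(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$points, unname(tr[[1]]$points))
  expect_equal(back[[2]]$class, "circumferential")
  expect_equal(back[[1]]$id, "r1")
})

test_that("degenerate traces are rejected", {
  expect_error(ridge_trace(cbind(1:2, 0, 0), "radial"), "3")
  expect_error(ridge_trace(rbind(c(1, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                           "radial"), "distinct")
})
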