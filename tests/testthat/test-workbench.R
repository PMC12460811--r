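# Acquisition I/O, VTK export and the end-to-end pipeline contract.

test_that("reader demands the sidecar and validates pages", {
  dir <- withr::local_tempdir()
  expect_error(read_movies(dir), "metadata.json")
  spec <- small_spec(seed = 41, nz = 3, n_frames = 40)
  ph <- build_phantom(spec)
  export_phantom(ph$movie, dir)
  # truncate one TIFF to fewer pages than declared
  pages <- tiff::readTIFF(file.path(dir, "z002.tif"), all = TRUE)
  tiff::writeTIFF(pages[1:10], file.path(dir, "z002.tif"),
                  bits.per.sample = 16, compression = "none")
  expect_error(read_movies(dir), "z002")
})

test_that("mixed frame counts across slices are accepted", {
  spec <- small_spec(seed = 42, nz = 3, n_frames = 40)
  ph <- build_phantom(spec)
  s <- ph$movie$slices
  s[[2]] <- slice_movie(s[[2]]$pixels[, , 1:30], s[[2]]$frame_interval,
                        s[[2]]$z_um, s[[2]]$pixel_size, s[[2]]$id)
  mv <- volume_movie(s, 30)
  dir <- withr::local_tempdir()
  export_phantom(mv, dir)
  back <- read_movies(dir)
  counts <- vapply(back$slices, function(x) dim(x$pixels)[3], integer(1))
  expect_equal(counts, c(40L, 30L, 40L))
})

test_that("strain surfaces round-trip through legacy VTK", {
  ico <- icosphere(2)
  mesh <- myo_mesh(rbind(ico$vertices * 15, ico$vertices * 9),
                   rbind(ico$triangles, ico$triangles + nrow(ico$vertices)),
                   surface = rep(c("epi", "endo"),
                                 each = nrow(ico$triangles)))
  surf <- morph_mesh_fun(mesh, function(p, ph) p * (1 + 0.01 * ph), 0:9, 0)
  field <- area_strain(surf)
  dir <- withr::local_tempdir()
  paths <- write_strain_vtk(surf, field, dir)
  expect_length(paths, 10)
  back <- read_strain_vtk(paths[[4]])
  expect_equal(back$triangles, unname(mesh$triangles))
  expect_equal(back$area_strain, unname(field$strain[, 4]),
               tolerance = 1e-6)
  expect_equal(back$surface,
               as.integer(mesh$surface == "endo"))
  # attribute/element mismatch is rejected before writing
  bad <- field
  bad$strain <- bad$strain[-1, , drop = FALSE]
  expect_error(write_strain_vtk(surf, bad, dir), "counts")
})

test_that("the pipeline runs end to end and is deterministic", {
  spec <- small_spec(seed = 43)
  ph <- build_phantom(spec)
  cfg <- pipeline_config(
    movie = ph$movie, K = 6, target_spacing = c(0.8, 0.8, 1),
    rolling_ball_radius = 30,
    registration = motion_spec(grid_spacing = 6, levels = 1, maxit = 15),
    ridge_annotations = ph$truth$ridge_traces[1:2],
    seed = 43)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg$out_dir <- dir1
  rep1 <- run_pipeline(cfg)
  cfg$out_dir <- dir2
  rep2 <- run_pipeline(cfg)
  # reference-phase mean strain is exactly 1
  sm <- rep1$summary
  expect_true(all(sm$mean_strain[sm$phase == rep1$model$ref_phase] == 1))
  expect_true(all(sm$sd_strain[sm$phase == rep1$model$ref_phase] == 0))
  expect_s3_class(rep1$ridge_metrics, "data.frame")
  # identical seed and config: byte-identical outputs
  f1 <- file.path(dir1, "strain_summary.csv")
  f2 <- file.path(dir2, "strain_summary.csv")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # provenance sidecars exist
  expect_true(file.exists(file.path(dir1, "run_log.json")))
  expect_true(file.exists(file.path(dir1, "resolved_config.json")))
})

test_that("pipeline configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(K = 8, rolling_ball_radius = 25,
                        registration = list(grid_spacing = 6, maxit = 10),
                        seed = 7), path)
  cfg <- read_pipeline_config(path)
  expect_equal(cfg$K, 8)
  expect_equal(cfg$rolling_ball_radius, 25)
  expect_equal(cfg$registration$grid_spacing, 6)
  expect_equal(cfg$registration$maxit, 10)
  expect_equal(cfg$seed, 7L)
})
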