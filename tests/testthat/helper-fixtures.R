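# Shared fixtures, built once per test run and cached. Heavy objects
# (phantom movies, reconstructions, segmentations) are reused across test
# files; every fixture is fully deterministic for its seed.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# compact phantom for fast unit tests: 64 x 64 x 24 grid, wall 2.5 um
small_spec <- function(n_frames = 60, nz = 24, ...) {
  phantom_spec(outer_axes = c(9, 9, 7.5), inner_axes = c(6.5, 6.5, 5),
               ridges = default_ridges(height = 2, width_sigma = 0.9),
               nx = 64, ny = 64, nz = nz, n_frames = n_frames, ...)
}

fx_noisy_phantom <- function() {
  fixture("noisy_phantom", function() build_phantom(phantom_spec(seed = 101)))
}

fx_noisy_cycle <- function() {
  fixture("noisy_cycle", function() {
    reconstruct_4d(fx_noisy_phantom()$movie$slices, K = 10)
  })
}

# compact phantom acquired like the study protocol: 300 frames per slice
fx_sync_phantom <- function() {
  fixture("sync_phantom", function() {
    build_phantom(small_spec(seed = 201, n_frames = 300))
  })
}

# noise-free default-scale phantom (shared by synchronization-error and
# registration-recovery checks)
fx_noiseless_phantom <- function() {
  fixture("noiseless_phantom", function() {
    build_phantom(phantom_spec(seed = 203, poisson = FALSE,
                               read_noise_sd = 0))
  })
}

fx_segmented <- function() {
  fixture("segmented", function() {
    cyc <- fx_noisy_cycle()
    bg <- rolling_ball(cyc$volumes[[1]], 40)
    seg <- segment_myocardium(bg, cyc$spacing)
    mesh <- split_epi_endo(mesh_surface(seg))
    list(seg = seg, mesh = mesh, cycle = cyc)
  })
}

# small noiseless phantom rendered synchronously at K bin centres, plus a
# quick single-level registration fit
fx_small_fit <- function() {
  fixture("small_fit", function() {
    spec <- small_spec(seed = 102, poisson = FALSE, read_noise_sd = 0,
                       radial_ampl_epi = 0.08, radial_ampl_endo = 0.12,
                       ridge_shortening = 0.08, ridge_thickening = 0.15)
    K <- 6
    vols <- lapply(seq_len(K), function(b) {
      strain4d:::render_volume(spec, (b - 0.5) / K)
    })
    cyc <- list(volumes = vols, K = K,
                spacing = c(spec$pixel_size, spec$pixel_size, spec$z_step))
    mod <- fit_motion(cyc, motion_spec(grid_spacing = 8, levels = 1,
                                       maxit = 25, ref_phase = 0L))
    list(spec = spec, cycle = cyc, model = mod,
         truth = phantom_truth(spec))
  })
}

# brute-force tensor-product B-spline evaluation (independent oracle for
# evaluate_displacement)
bf_bspline_eval <- function(coef, gdims, sp, tb, pts) {
  b3 <- function(t, i) {
    # cubic B-spline basis value for control offset i at local t
    switch(i + 1,
           (1 - t)^3 / 6,
           (3 * t^3 - 6 * t^2 + 4) / 6,
           (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
           t^3 / 6)
  }
  ncp <- prod(gdims)
  nb <- length(tb)
  ck <- matrix(0, ncp, 3)
  for (b in seq_len(nb)) ck <- ck + tb[b] * coef[, , b]
  out <- matrix(0, nrow(pts), 3)
  for (p in seq_len(nrow(pts))) {
    u <- pts[p, ] / sp
    i0 <- pmin(pmax(floor(u), 0), gdims - 4)
    t <- u - i0
    for (a in 0:3) for (b2 in 0:3) for (c3 in 0:3) {
      w <- b3(t[1], a) * b3(t[2], b2) * b3(t[3], c3)
      g <- (i0[1] + a) + gdims[1] * ((i0[2] + b2) + gdims[2] * (i0[3] + c3))
      out[p, ] <- out[p, ] + w * ck[g + 1, ]
    }
  }
  out
}

# brute-force grayscale opening (independent oracle for the rolling-ball
# background); uses the same disc structuring element as the
# implementation but an explicit min/max double loop
bf_rolling_ball <- function(img, radius) {
  d <- dim(img)
  brush <- EBImage::makeBrush(2 * radius + 1, "disc")
  idx <- which(brush == 1, arr.ind = TRUE)
  off <- data.frame(dx = idx[, 1] - radius - 1, dy = idx[, 2] - radius - 1)
  filt <- function(m, fun) {
    out <- matrix(0, d[1], d[2])
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      ii <- pmin(pmax(i + off$dx, 1), d[1])
      jj <- pmin(pmax(j + off$dy, 1), d[2])
      out[i, j] <- fun(m[cbind(ii, jj)])
    }
    out
  }
  opened <- filt(filt(img, min), max)
  pmax(img - opened, 0)
}

# exhaustive integer-period scan maximising the folded-signal variance
# ratio (independent oracle for estimate_period); multiples of the true
# period score equally well, so take the smallest near-optimal period
bf_period_scan <- function(s, min_p = 5, max_p = 60) {
  ps <- min_p:max_p
  score <- vapply(ps, function(p) {
    ph <- (seq_along(s) - 1) %% p
    means <- tapply(s, ph, mean)
    stats::var(means[ph + 1]) / stats::var(s)
  }, numeric(1))
  ps[which(score >= 0.95 * max(score))[1]]
}
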