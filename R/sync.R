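# Retrospective cardiac-phase synchronization of asynchronously acquired
# per-slice movies, and kymograph-style heart-rate estimation from the
# spatially integrated intensity trace.

#' Estimate the cardiac period of a slice movie
#'
#' The dominant period of the spatially integrated intensity (or of a
#' user-supplied trace) from the first autocorrelation peak above a
#' significance floor, refined to sub-frame precision by parabolic
#' interpolation around the peak.
#'
#' @param movie a [slice_movie()]
#' @param trace optional intensity trace to use instead of the mean image
#'   intensity per frame
#' @param significance autocorrelation floor below which a slice is
#'   declared aperiodic
#' @param min_lag smallest admissible period (frames)
#' @return period in seconds; the period in frames is in attribute
#'   `"frames"`
#' @export
estimate_period <- function(movie, trace = NULL, significance = 0.3,
                            min_lag = 4) {
  s <- if (is.null(trace)) apply(movie$pixels, 3, mean) else trace
  n <- length(s)
  if (sd(s) < 1e-12) stop("aperiodic slice: constant intensity trace")
  ac <- stats::acf(s, lag.max = floor(n / 2), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  # undo the finite-length taper so the peak is not biased to shorter lags
  ac <- ac * n / (n - lags)
  # local maxima of the autocorrelation beyond min_lag
  cand <- which(lags >= min_lag & lags < max(lags) &
                  ac > c(-Inf, head(ac, -1)) & ac >= c(tail(ac, -1), -Inf))
  cand <- cand[ac[cand] > significance]
  if (length(cand) == 0) {
    stop("aperiodic slice: no autocorrelation peak above significance floor")
  }
  pk <- lags[cand[1]]
  # sub-frame refinement: maximise the correlation of the
  # spline-interpolated trace with itself at a continuously varying lag
  # (the intensity trace of a beating heart is smooth in time)
  step <- 0.02
  xs <- seq(1, n, by = step)
  ss <- stats::spline(seq_len(n), s - mean(s), xout = xs)$y
  lag_grid <- seq(max(min_lag, pk - 1.2), pk + 1.2, by = step)
  corr_at <- vapply(lag_grid, function(p) {
    L <- round((p - 0) / step)
    m <- length(ss) - L
    a <- ss[seq_len(m)]
    b <- ss[seq_len(m) + L]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  frames <- lag_grid[which.max(corr_at)]
  structure(frames * movie$frame_interval, frames = frames)
}

# sub-frame systolic anchor: phase fraction minimising the kernel-smoothed
# folded intensity profile (systole = minimum integrated intensity)
fold_anchor <- function(s, period_frames, n_grid = 256) {
  n <- length(s)
  ph <- ((seq_len(n) - 1) / period_frames) %% 1
  grid <- (seq_len(n_grid) - 1) / n_grid
  bw <- max(0.02, 0.75 / period_frames)
  prof <- vapply(grid, function(g) {
    d <- abs(ph - g)
    d <- pmin(d, 1 - d)
    w <- exp(-0.5 * (d / bw)^2)
    sum(w * s) / sum(w)
  }, numeric(1))
  i <- which.min(prof)
  im <- if (i == 1) n_grid else i - 1
  ip <- if (i == n_grid) 1L else i + 1
  y1 <- prof[im]; y2 <- prof[i]; y3 <- prof[ip]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  ((grid[i] + max(-0.5, min(0.5, delta)) / n_grid) %% 1)
}

#' Assign each frame to one of K cardiac phase bins
#'
#' Frame i (time t_i) receives label `floor(K * (((t_i - t0) mod T) / T))`.
#' The anchor t0 marks phase 0 at the minimum of the folded integrated
#' intensity (a systole proxy, where the ventricular cross-section is
#' smallest), unless given explicitly.
#'
#' @param movie a [slice_movie()]
#' @param period_s cardiac period (s)
#' @param K number of phase bins (default 10)
#' @param t0 optional explicit anchor time (s) of phase 0
#' @param merge_empty merge an empty bin into its neighbour instead of
#'   erroring
#' @return integer vector of phase labels in 0..K-1; attributes `t0`
#'   (anchor, s) and `phase` (continuous phase fraction per frame)
#' @export
assign_phases <- function(movie, period_s, K = 10, t0 = NULL,
                          merge_empty = FALSE) {
  stopifnot(K >= 1)
  n <- dim(movie$pixels)[3]
  tfr <- (seq_len(n) - 1) * movie$frame_interval
  period_frames <- period_s / movie$frame_interval
  if (is.null(t0)) {
    s <- apply(movie$pixels, 3, mean)
    t0 <- fold_anchor(s, period_frames) * period_s
  }
  phase <- ((tfr - t0) %% period_s) / period_s
  # guard against representation error exactly at bin boundaries
  labels <- pmin(K - 1L, floor(K * phase + 1e-9))
  counts <- tabulate(labels + 1L, nbins = K)
  if (any(counts == 0) && K > 1) {
    if (!merge_empty) {
      stop(sprintf("empty phase bin(s): %s; rerun with merge_empty = TRUE",
                   paste(which(counts == 0) - 1L, collapse = ", ")))
    }
    warning("empty phase bin(s) merged with neighbours")
    for (b in which(counts == 0)) {
      nb <- if (b > 1) b - 1L else b + 1L
      labels[labels == b - 1L] <- nb - 1L
    }
  }
  structure(as.integer(labels), t0 = t0, phase = phase)
}

#' Reconstruct K phase-binned 3-D volumes from per-slice movies
#'
#' Per slice, frames falling into each of K phase bins are averaged; the
#' per-slice images are then stacked along z. Slices whose period deviates
#' more than `period_tol` from the median, or which are aperiodic, are
#' excluded from gating (their time-average fills their z plane) and
#' logged. After per-slice anchoring, each slice's binning is refined by
#' maximising the cyclic correlation of its per-bin image sequence with the
#' already-aligned adjacent slice, chaining outward from the
#' highest-signal slice.
#'
#' @param movies list of [slice_movie()] (any order; sorted by z)
#' @param K number of cardiac phases (default 10, systole to diastole)
#' @param period_tol relative period deviation beyond which a slice is
#'   excluded
#' @param align_slices refine anchors by adjacent-slice cyclic correlation
#' @return a `cardiac_cycle_set`: K volumes ([x,y,z] arrays), per-slice
#'   period and phase-offset estimates, bin counts, and exclusions
#' @export
reconstruct_4d <- function(movies, K = 10, period_tol = 0.1,
                           align_slices = TRUE) {
  zs <- vapply(movies, function(m) m$z_um, numeric(1))
  ord <- order(zs)
  movies <- movies[ord]
  zs <- zs[ord]
  if (any(diff(zs) <= 0)) stop("z positions must be strictly increasing")
  px <- movies[[1]]$pixel_size
  nslice <- length(movies)
  nx <- dim(movies[[1]]$pixels)[1]
  ny <- dim(movies[[1]]$pixels)[2]

  periods <- rep(NA_real_, nslice)
  excluded <- character(0)
  for (i in seq_len(nslice)) {
    periods[i] <- tryCatch(as.numeric(estimate_period(movies[[i]])),
                           error = function(e) NA_real_)
  }
  med <- median(periods, na.rm = TRUE)
  if (!is.finite(med)) stop("no slice yielded a period estimate")
  ok <- !is.na(periods) & abs(periods - med) <= period_tol * med
  for (i in which(!ok)) {
    excluded <- c(excluded, sprintf(
      "%s: %s", movies[[i]]$id,
      if (is.na(periods[i])) "aperiodic" else
        sprintf("period %.3fs deviates >%.0f%% from median %.3fs",
                periods[i], 100 * period_tol, med)))
  }

  # per-slice binned phase stacks
  bins <- vector("list", nslice)
  offsets <- rep(NA_real_, nslice)
  counts <- matrix(0L, nslice, K)
  for (i in seq_len(nslice)) {
    m <- movies[[i]]
    if (!ok[i]) {
      avg <- rowMeans(m$pixels, dims = 2)
      bins[[i]] <- array(avg, dim = c(nx, ny, K))
      next
    }
    lab <- assign_phases(m, periods[i], K)
    offsets[i] <- attr(lab, "t0") / periods[i]
    st <- array(0, dim = c(nx, ny, K))
    for (b in seq_len(K) - 1L) {
      idx <- which(lab == b)
      counts[i, b + 1L] <- length(idx)
      st[, , b + 1L] <- rowMeans(m$pixels[, , idx, drop = FALSE], dims = 2)
    }
    bins[[i]] <- st
  }

  # chain cyclic alignment outward from the strongest modulated slice
  if (align_slices && K > 1 && sum(ok) > 1) {
    amp <- vapply(seq_len(nslice), function(i) {
      if (!ok[i]) return(-Inf)
      mm <- apply(bins[[i]], 3, mean)
      max(mm) - min(mm)
    }, numeric(1))
    anchor <- which.max(amp)
    orddist <- order(abs(seq_len(nslice) - anchor))
    aligned <- rep(FALSE, nslice)
    aligned[anchor] <- TRUE
    for (i in orddist) {
      if (aligned[i] || !ok[i]) next
      nb <- NA_integer_
      for (d in seq_len(nslice)) {
        lo <- i - d; hi <- i + d
        if (lo >= 1 && aligned[lo] && ok[lo]) { nb <- lo; break }
        if (hi <= nslice && aligned[hi] && ok[hi]) { nb <- hi; break }
      }
      if (is.na(nb)) { aligned[i] <- TRUE; next }
      a <- bins[[nb]]; b <- bins[[i]]
      sc <- vapply(seq_len(K) - 1L, function(s) {
        shifted <- b[, , ((seq_len(K) - 1L + s) %% K) + 1L, drop = FALSE]
        stats::cor(as.vector(a), as.vector(shifted))
      }, numeric(1))
      s_best <- which.max(sc) - 1L
      if (s_best != 0) {
        bins[[i]] <- bins[[i]][, , ((seq_len(K) - 1L + s_best) %% K) + 1L,
                               drop = FALSE]
        counts[i, ] <- counts[i, ((seq_len(K) - 1L + s_best) %% K) + 1L]
        offsets[i] <- (offsets[i] + s_best / K) %% 1
      }
      aligned[i] <- TRUE
    }
  }

  volumes <- lapply(seq_len(K), function(b) {
    arr <- array(0, dim = c(nx, ny, nslice))
    for (i in seq_len(nslice)) arr[, , i] <- bins[[i]][, , b]
    arr
  })
  structure(list(volumes = volumes, K = K,
                 spacing = c(px, px, if (nslice > 1) diff(zs)[1] else 1),
                 z_um = zs, periods = periods, offsets = offsets,
                 bin_counts = counts, excluded = excluded,
                 included = ok), class = "cardiac_cycle_set")
}

#' @export
print.cardiac_cycle_set <- function(x, ...) {
  cat(sprintf(
    "cardiac_cycle_set: K = %d phases, %d slices (%d gated), period %.3f s\n",
    x$K, length(x$z_um), sum(x$included), median(x$periods, na.rm = TRUE)))
  if (length(x$excluded)) {
    cat("excluded from gating:\n")
    cat(paste0("  ", x$excluded, collapse = "\n"), "\n")
  }
  invisible(x)
}
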