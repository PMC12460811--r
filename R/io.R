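# Acquisition I/O: multi-page TIFF per z position with a JSON metadata
# sidecar, and legacy-VTK polydata export of strain-carrying surfaces.

#' Export a volume movie as multi-page TIFFs plus a JSON sidecar
#'
#' One 16-bit multi-page TIFF per z position (counts stored as
#' value / 65535) and a `metadata.json` sidecar with spacings, frame rate,
#' z order and seed. The round trip through [read_movies()] is bit-exact.
#'
#' @param movie a [volume_movie()]
#' @param dir_path output directory
#' @param force overwrite an existing export
#' @return invisibly, the written file names
#' @export
export_phantom <- function(movie, dir_path, force = FALSE) {
  meta_path <- file.path(dir_path, "metadata.json")
  if (file.exists(meta_path) && !force) {
    stop("export target already exists; use force = TRUE to overwrite")
  }
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(movie$slices))
  for (i in seq_along(movie$slices)) {
    s <- movie$slices[[i]]
    files[i] <- sprintf("%s.tif", s$id)
    pages <- lapply(seq_len(dim(s$pixels)[3]), function(f) {
      t(s$pixels[, , f]) / 65535
    })
    tiff::writeTIFF(pages, file.path(dir_path, files[i]),
                    bits.per.sample = 16, compression = "none")
  }
  meta <- list(
    format = "strain4d-acquisition",
    pixel_size_um = movie$slices[[1]]$pixel_size,
    frame_rate_hz = movie$frame_rate,
    seed = movie$seed,
    slices = lapply(seq_along(movie$slices), function(i) {
      s <- movie$slices[[i]]
      list(file = files[i], z_um = s$z_um, n_frames = dim(s$pixels)[3],
           frame_interval_s = s$frame_interval, id = s$id)
    }))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, "metadata.json"))
}

#' Read an exported acquisition back into a volume movie
#'
#' z order comes from the sidecar, never from file-name order.
#'
#' @param dir_path directory containing TIFFs and `metadata.json`
#' @return a [volume_movie()]
#' @export
read_movies <- function(dir_path) {
  meta_path <- file.path(dir_path, "metadata.json")
  if (!file.exists(meta_path)) {
    stop(paste("missing metadata.json sidecar; required fields:",
               "pixel_size_um, frame_rate_hz, slices[{file, z_um,",
               "n_frames, frame_interval_s}]"))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
  slices <- lapply(meta$slices, function(si) {
    path <- file.path(dir_path, si$file)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                      error = function(e) {
                        stop(sprintf("corrupt TIFF %s: %s", si$file,
                                     conditionMessage(e)))
                      })
    if (length(pages) != si$n_frames) {
      stop(sprintf("corrupt TIFF %s: expected %d pages, found %d",
                   si$file, si$n_frames, length(pages)))
    }
    arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]),
                            length(pages)))
    for (f in seq_along(pages)) arr[, , f] <- round(t(pages[[f]]) * 65535)
    slice_movie(arr, frame_interval = si$frame_interval_s, z_um = si$z_um,
                pixel_size = meta$pixel_size_um, id = si$id)
  })
  volume_movie(slices, frame_rate = meta$frame_rate_hz,
               seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Write one legacy-VTK polydata file per phase with strain attributes
#'
#' Each file carries the shared triangulation with that phase's vertex
#' positions, plus per-triangle cell data: `area_strain`, `surface`
#' (0 epi, 1 endo, 2 unassigned) and `region` (0/1).
#'
#' @param surfaces a `morphed_surfaces` object from [morph_mesh()]
#' @param field a `strain_field` from [area_strain()]
#' @param dir_path output directory
#' @param basename file name stem
#' @return invisibly, written file paths
#' @export
write_strain_vtk <- function(surfaces, field, dir_path,
                             basename = "strain") {
  mesh <- surfaces$mesh
  ntri <- nrow(mesh$triangles)
  if (nrow(field$strain) + length(field$excluded) != ntri) {
    stop("strain field and mesh element counts do not match")
  }
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  surf_code <- match(mesh$surface, c("epi", "endo")) - 1L
  surf_code[is.na(surf_code)] <- 2L
  full <- rep(NA_real_, ntri)
  keep <- setdiff(seq_len(ntri), field$excluded)
  paths <- character(length(surfaces$phases))
  for (j in seq_along(surfaces$phases)) {
    full[keep] <- field$strain[, j]
    full[field$excluded] <- -1
    path <- file.path(dir_path, sprintf("%s_phase%02d.vtk", basename,
                                        surfaces$phases[j]))
    v <- surfaces$vertices[[j]]
    con <- file(path, "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 "strain4d myocardial surface", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(v))), con)
    write(t(format(v, digits = 9, scientific = FALSE, trim = TRUE)),
          con, ncolumns = 3)
    writeLines(sprintf("POLYGONS %d %d", ntri, 4 * ntri), con)
    write(t(cbind(3L, mesh$triangles - 1L)), con, ncolumns = 4)
    writeLines(c(sprintf("CELL_DATA %d", ntri),
                 "SCALARS area_strain float 1",
                 "LOOKUP_TABLE default"), con)
    write(format(full, digits = 9, trim = TRUE), con, ncolumns = 9)
    writeLines(c("SCALARS surface int 1", "LOOKUP_TABLE default"), con)
    write(surf_code, con, ncolumns = 9)
    writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
    write(as.integer(mesh$region), con, ncolumns = 9)
    close(con)
    paths[j] <- path
  }
  invisible(paths)
}

#' Read back a legacy-VTK polydata file written by [write_strain_vtk()]
#' @param path file path
#' @return list with vertices, triangles and cell data vectors
#' @export
read_strain_vtk <- function(path) {
  lines <- readLines(path)
  npts <- as.integer(sub("POINTS (\\d+).*", "\\1",
                         grep("^POINTS", lines, value = TRUE)[1]))
  i0 <- grep("^POINTS", lines)[1]
  nums <- scan(text = lines[(i0 + 1):length(lines)], what = numeric(),
               n = 3 * npts, quiet = TRUE)
  vertices <- matrix(nums, ncol = 3, byrow = TRUE)
  ip <- grep("^POLYGONS", lines)[1]
  ntri <- as.integer(sub("POLYGONS (\\d+).*", "\\1", lines[ip]))
  pol <- scan(text = lines[(ip + 1):length(lines)], what = integer(),
              n = 4 * ntri, quiet = TRUE)
  pol <- matrix(pol, ncol = 4, byrow = TRUE)
  triangles <- pol[, 2:4, drop = FALSE] + 1L
  read_scalar <- function(name, what) {
    is <- grep(sprintf("^SCALARS %s", name), lines)[1]
    if (is.na(is)) return(NULL)
    scan(text = lines[(is + 2):length(lines)], what = what, n = ntri,
         quiet = TRUE)
  }
  list(vertices = vertices, triangles = triangles,
       area_strain = read_scalar("area_strain", numeric()),
       surface = read_scalar("surface", integer()),
       region = read_scalar("region", integer()))
}
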