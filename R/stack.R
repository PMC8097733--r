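#' Lazy plane-addressable stacks
#'
#' A `lazy_stack` addresses a multi-dimensional grayscale stack by
#' `(t, c, z)` -- timepoint, channel, slice, all 0-based -- and loads one
#' plane at a time through its `get_plane(t, c, z)` accessor, so a stack far
#' larger than memory can be traversed plane by plane. Reading the same plane
#' twice yields identical values.
#'
#' @param get_plane Function `(t, c, z) -> numeric matrix`, 0-based indices.
#' @param n_t,n_c,n_z Extents of the time, channel and z axes (>= 1).
#' @param height,width Plane dimensions in pixels.
#' @param pixel_depth Source bit depth: 8, 16 or 32.
#' @param voxel_size Optional numeric `c(x, y, z)` voxel size in micrometers.
#' @param source Description of where planes come from (path or label).
#' @return An object of class `lazy_stack`.
#' @name lazy_stack
NULL

new_lazy_stack <- function(get_plane, n_t, n_c, n_z, height, width,
                           pixel_depth = 16L, voxel_size = NULL,
                           source = "memory") {
  stopifnot(is.function(get_plane),
            n_t >= 1, n_c >= 1, n_z >= 1, height >= 1, width >= 1,
            pixel_depth %in% c(8, 16, 32))
  if (!is.null(voxel_size)) stopifnot(is.numeric(voxel_size), length(voxel_size) == 3)
  raw_get <- get_plane
  checked_get <- function(t, c, z) {
    check_index(t, n_t, "t")
    check_index(c, n_c, "c")
    check_index(z, n_z, "z")
    pl <- raw_get(t, c, z)
    if (!is.matrix(pl) || nrow(pl) != height || ncol(pl) != width) {
      stop(sprintf("plane (t=%d, c=%d, z=%d) has wrong dimensions", t, c, z),
           call. = FALSE)
    }
    pl
  }
  structure(
    list(get_plane = checked_get,
         n_t = as.integer(n_t), n_c = as.integer(n_c), n_z = as.integer(n_z),
         height = as.integer(height), width = as.integer(width),
         pixel_depth = as.integer(pixel_depth),
         voxel_size = voxel_size, source = source),
    class = "lazy_stack"
  )
}

check_index <- function(i, n, axis) {
  if (!is.numeric(i) || length(i) != 1L || i != round(i) || i < 0 || i >= n) {
    stop(sprintf("index %s=%s out of range [0, %d)", axis, format(i), n),
         call. = FALSE)
  }
}

#' @export
print.lazy_stack <- function(x, ...) {
  cat(sprintf("lazy_stack: %d x %d px, t=%d c=%d z=%d, %d-bit, source: %s\n",
              x$height, x$width, x$n_t, x$n_c, x$n_z, x$pixel_depth,
              if (is.character(x$source)) x$source else "memory"))
  invisible(x)
}

#' In-memory stack from planes
#'
#' Wraps a list of numeric matrices (or a 3D array sliced along its third
#' dimension) as a [lazy_stack]. Planes are ordered channel-fastest, then z,
#' then time (the multi-page convention used by hyperstack TIFFs).
#'
#' @param x List of equally-sized numeric matrices, or a 3D array.
#' @param n_c,n_t Channel and timepoint counts; `n_z` is inferred as
#'   `length(planes) / (n_c * n_t)`.
#' @param pixel_depth,voxel_size,source See [lazy_stack].
#' @return A [lazy_stack].
#' @export
as_lazy_stack <- function(x, n_c = 1L, n_t = 1L, pixel_depth = 16L,
                          voxel_size = NULL, source = "memory") {
  if (is.array(x) && length(dim(x)) == 3L) {
    x <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  }
  if (!is.list(x) || length(x) == 0) {
    stop("`x` must be a nonempty list of matrices or a 3D array", call. = FALSE)
  }
  lapply(x, assert_plane)
  dims <- vapply(x, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all planes must share the same dimensions", call. = FALSE)
  }
  n_planes <- length(x)
  if (n_planes %% (n_c * n_t) != 0) {
    stop(sprintf("%d planes cannot be split into %d channel(s) x %d timepoint(s)",
                 n_planes, n_c, n_t), call. = FALSE)
  }
  n_z <- n_planes %/% (n_c * n_t)
  force(x)
  new_lazy_stack(
    get_plane = function(t, c, z) x[[t * n_c * n_z + z * n_c + c + 1L]],
    n_t = n_t, n_c = n_c, n_z = n_z,
    height = dims[1, 1], width = dims[2, 1],
    pixel_depth = pixel_depth, voxel_size = voxel_size, source = source
  )
}

#' Open a multi-page TIFF as a lazy stack
#'
#' Reads only the TIFF directory up front; pixel data are decoded page by
#' page on demand through the stack's accessor. Pages are interpreted in
#' channel-fastest order (c, then z, then t), the hyperstack convention.
#' Axis extents are taken from ImageJ-style metadata in the image description
#' (`channels=`, `slices=`, `frames=`) when present; the `channels` /
#' `slices` / `frames` arguments override them.
#'
#' @param path Path to a grayscale multi-page TIFF (8-, 16- or 32-bit).
#' @param channels,slices,frames Optional axis extents overriding (or
#'   supplying missing) metadata.
#' @param voxel_size Optional numeric `c(x, y, z)` in micrometers.
#' @return A [lazy_stack].
#' @examples
#' \dontrun{
#' st <- open_stack("stack.tif", channels = 2)
#' pl <- st$get_plane(0, 0, 3)
#' }
#' @export
open_stack <- function(path, channels = NULL, slices = NULL, frames = NULL,
                       voxel_size = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("cannot read TIFF: '%s' does not exist", path), call. = FALSE)
  }
  info <- tryCatch(
    tiff::readTIFF(path, payload = FALSE, all = TRUE),
    error = function(e) {
      stop(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (is.null(dim(info))) info <- as.data.frame(as.list(info))
  n_pages <- nrow(info)
  if (n_pages < 1) stop(sprintf("'%s' contains no images", path), call. = FALSE)
  if (any(info$samples.per.pixel != 1L)) {
    bad <- which(info$samples.per.pixel != 1L)[1]
    stop(sprintf("'%s' plane %d is not grayscale (RGB input is unsupported)",
                 path, bad), call. = FALSE)
  }
  if (any(info$width != info$width[1]) || any(info$length != info$length[1])) {
    bad <- which(info$width != info$width[1] | info$length != info$length[1])[1]
    stop(sprintf("'%s' plane %d has inconsistent dimensions", path, bad),
         call. = FALSE)
  }
  depth <- info$bits.per.sample[1]
  if (!depth %in% c(8, 16, 32)) {
    stop(sprintf("'%s': unsupported bit depth %d", path, depth), call. = FALSE)
  }
  meta <- parse_imagej_description(info$description[1])
  n_c <- as.integer(channels %||% meta$channels %||% 1L)
  n_t <- as.integer(frames %||% meta$frames %||% 1L)
  n_z <- as.integer(slices %||% meta$slices %||% (n_pages %/% (n_c * n_t)))
  if (n_c * n_t * n_z != n_pages) {
    stop(sprintf("'%s': %d page(s) do not match c=%d x z=%d x t=%d",
                 path, n_pages, n_c, n_z, n_t), call. = FALSE)
  }
  new_lazy_stack(
    get_plane = function(t, c, z) {
      page <- t * n_c * n_z + z * n_c + c + 1L
      read_tiff_page(path, page, depth)
    },
    n_t = n_t, n_c = n_c, n_z = n_z,
    height = info$length[1], width = info$width[1],
    pixel_depth = depth, voxel_size = voxel_size, source = path
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_imagej_description <- function(desc) {
  out <- list(channels = NULL, slices = NULL, frames = NULL)
  if (is.null(desc) || is.na(desc) || !nzchar(desc)) return(out)
  for (key in names(out)) {
    m <- regmatches(desc, regexec(paste0(key, "=(\\d+)"), desc))[[1]]
    if (length(m) == 2) out[[key]] <- as.integer(m[2])
  }
  out
}

# Decode one TIFF page as a numeric matrix of raw intensities. Integer pages
# are read as stored values; 32-bit float pages are returned as read (the
# tone-mapped folder convention rescales them in read_plane_file()).
read_tiff_page <- function(path, page, depth) {
  pl <- tryCatch(
    tiff::readTIFF(path, all = page, as.is = depth != 32),
    error = function(e) {
      stop(sprintf("cannot decode plane %d of '%s': %s", page, path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (is.list(pl)) pl <- pl[[1]]
  if (length(dim(pl)) == 3L) {
    stop(sprintf("'%s' plane %d is not grayscale (RGB input is unsupported)",
                 path, page), call. = FALSE)
  }
  storage.mode(pl) <- "double"
  pl
}

# --- the tone-mapped folder convention ---------------------------------------
#
# process_stack() writes one file per plane, named
#   <stem>_t{TTT}_c{CC}_z{ZZZZ}.tif     (0-based, zero-padded)
# 8/16-bit planes hold converted integers. 32-bit planes hold float samples
# scaled by 2^-16 -- an exact exponent shift, because the TIFF writer only
# stores floats in [0, 1] -- and readers multiply back by 2^16.

plane_file_name <- function(stem, t, c, z) {
  sprintf("%s_t%03d_c%02d_z%04d.tif", stem, t, c, z)
}

FLOAT_SCALE <- 2^16

write_plane_file <- function(plane, path, depth) {
  if (depth == 32) {
    tiff::writeTIFF(pmax(plane, 0) / FLOAT_SCALE, path,
                    bits.per.sample = 32L, compression = "none")
  } else {
    tiff::writeTIFF(plane / (2^depth - 1), path,
                    bits.per.sample = as.integer(depth), compression = "none")
  }
  invisible(path)
}

read_plane_file <- function(path, depth) {
  pl <- read_tiff_page(path, 1L, depth)
  if (depth == 32) pl * FLOAT_SCALE else pl
}

#' Reopen a processed-plane folder as a lazy stack
#'
#' Reconstitutes a [lazy_stack] from a folder of per-plane TIFF files written
#' by [process_stack()] (names `<stem>_t{TTT}_c{CC}_z{ZZZZ}.tif`, 0-based).
#' The `(t, c, z)` grid is recovered from the file names and must be
#' complete; any missing combination is reported by name.
#'
#' @param path Folder containing the per-plane files.
#' @param voxel_size Optional numeric `c(x, y, z)` in micrometers.
#' @return A [lazy_stack] whose planes equal the processed planes exactly
#'   (at 32-bit, to float32 precision).
#' @export
open_devils_folder <- function(path, voxel_size = NULL) {
  if (!dir.exists(path)) {
    stop(sprintf("'%s' is not a directory", path), call. = FALSE)
  }
  rx <- "^(.*)_t(\\d{3})_c(\\d{2})_z(\\d{4})\\.tif$"
  files <- list.files(path, pattern = rx)
  if (length(files) == 0) {
    stop(sprintf("'%s' contains no plane files (expected *_tTTT_cCC_zZZZZ.tif)",
                 path), call. = FALSE)
  }
  m <- regmatches(files, regexec(rx, files))
  stem <- unique(vapply(m, `[`, character(1), 2))
  if (length(stem) > 1) {
    stop(sprintf("'%s' mixes several stacks: stems %s", path,
                 paste(stem, collapse = ", ")), call. = FALSE)
  }
  t_i <- as.integer(vapply(m, `[`, character(1), 3))
  c_i <- as.integer(vapply(m, `[`, character(1), 4))
  z_i <- as.integer(vapply(m, `[`, character(1), 5))
  n_t <- max(t_i) + 1L; n_c <- max(c_i) + 1L; n_z <- max(z_i) + 1L
  grid <- expand.grid(t = 0:(n_t - 1L), c = 0:(n_c - 1L), z = 0:(n_z - 1L))
  have <- paste(t_i, c_i, z_i)
  want <- paste(grid$t, grid$c, grid$z)
  missing <- grid[!(want %in% have), , drop = FALSE]
  if (nrow(missing) > 0) {
    miss_names <- plane_file_name(stem, missing$t, missing$c, missing$z)
    stop(sprintf("'%s' has gaps in the plane grid; missing: %s", path,
                 paste(utils::head(miss_names, 10), collapse = ", ")),
         call. = FALSE)
  }
  first <- file.path(path, plane_file_name(stem, 0L, 0L, 0L))
  info <- tiff::readTIFF(first, payload = FALSE, all = TRUE)
  if (is.null(dim(info))) info <- as.data.frame(as.list(info))
  depth <- info$bits.per.sample[1]
  new_lazy_stack(
    get_plane = function(t, c, z) {
      read_plane_file(file.path(path, plane_file_name(stem, t, c, z)), depth)
    },
    n_t = n_t, n_c = n_c, n_z = n_z,
    height = info$length[1], width = info$width[1],
    pixel_depth = depth, voxel_size = voxel_size, source = path
  )
}
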