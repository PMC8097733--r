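#' Process a stack plane by plane
#'
#' Applies the tone-mapping operator to every plane of a stack and writes one
#' TIFF file per plane into `output_dir`, named
#' `<stem>_t{TTT}_c{CC}_z{ZZZZ}.tif` (0-based, zero-padded). Each plane is
#' processed with its channel's parameters ([devils_transform()]), converted
#' with [convert_bit_depth()], and written independently; an `"auto"` division
#' scale is resolved once per channel before any plane is touched, so the
#' output is bitwise identical for any number of workers. Per-plane statistics
#' of the converted output are returned and written alongside the planes as
#' `plane_stats.tsv`.
#'
#' Planes are loaded on demand and released after writing: peak plane data in
#' memory is bounded by the number of workers, never by the stack size.
#'
#' @param stack A [lazy_stack].
#' @param params A single [devils_params()] (broadcast to all channels) or a
#'   list with one entry per channel.
#' @param output_dir Output folder, created if needed.
#' @param workers Number of parallel workers (forked; >= 1).
#' @param export_hdf5 If `TRUE`, additionally write a BigDataViewer HDF5/XML
#'   pair of the converted stack into `output_dir` (see [export_hdf5()]).
#' @param stem File-name stem; defaults to the input file name, or `"stack"`
#'   for in-memory stacks.
#' @param progress If `TRUE`, log each written plane to the console.
#' @return Invisibly, a list with `output_dir`, `stats` (data frame with
#'   columns t, c, z, mean, max), `files` (relative file names in write
#'   order), `scales` (resolved division scale per channel) and `hdf5`
#'   (path or `NULL`).
#' @examples
#' st <- as_lazy_stack(replicate(4, matrix(runif(256, 0, 200), 16, 16),
#'                               simplify = FALSE))
#' run <- process_stack(st, devils_params(p = 4, division_scale = 100),
#'                      output_dir = tempfile())
#' head(run$stats)
#' @export
process_stack <- function(stack, params, output_dir, workers = 1L,
                          export_hdf5 = FALSE, stem = NULL, progress = FALSE) {
  if (!inherits(stack, "lazy_stack")) {
    stop("`stack` must be a lazy_stack", call. = FALSE)
  }
  if (inherits(params, "devils_params")) params <- list(params)
  if (!is.list(params) || !all(vapply(params, inherits, logical(1), "devils_params"))) {
    stop("`params` must be a devils_params object or a list of them", call. = FALSE)
  }
  if (length(params) == 1L) params <- rep(params, stack$n_c)
  if (length(params) != stack$n_c) {
    stop(sprintf("`params` has %d entries for %d channel(s); give 1 or n_c",
                 length(params), stack$n_c), call. = FALSE)
  }
  assert_scalar(workers, "workers", positive = TRUE)
  workers <- as.integer(workers)
  if (is.null(stem)) {
    stem <- if (is.character(stack$source) && file.exists(stack$source)) {
      tools::file_path_sans_ext(basename(stack$source))
    } else "stack"
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) {
    stop(sprintf("cannot create output directory '%s'", output_dir), call. = FALSE)
  }

  # Resolve "auto" scales once, outside the parallel region (determinism).
  scales <- vapply(params, resolve_scale, numeric(1))

  grid <- expand.grid(z = 0:(stack$n_z - 1L), c = 0:(stack$n_c - 1L),
                      t = 0:(stack$n_t - 1L))
  do_plane <- function(i) {
    t <- grid$t[i]; c <- grid$c[i]; z <- grid$z[i]
    pp <- params[[c + 1L]]
    pl <- stack$get_plane(t, c, z)
    out <- devils_transform(pl, with_scale(pp, scales[c + 1L]))
    conv <- convert_bit_depth(out, pp$conv_min, pp$conv_max, pp$out_depth)
    fn <- plane_file_name(stem, t, c, z)
    write_plane_file(conv, file.path(output_dir, fn), pp$out_depth)
    if (progress) {
      message(sprintf("plane t=%d c=%d z=%d -> %s", t, c, z, fn))
    }
    list(t = t, c = c, z = z, mean = mean(conv), max = max(conv), file = fn)
  }
  idx <- seq_len(nrow(grid))
  res <- if (workers > 1L) {
    parallel::mclapply(idx, do_plane, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(idx, do_plane)
  }
  errs <- vapply(res, inherits, logical(1), "try-error")
  bad <- vapply(res, function(r) !is.list(r) || is.null(r$file), logical(1))
  if (any(errs | bad)) {
    i <- which(errs | bad)[1]
    detail <- if (errs[i]) conditionMessage(attr(res[[i]], "condition")) else "worker failed"
    stop(sprintf("processing failed at plane t=%d c=%d z=%d: %s",
                 grid$t[i], grid$c[i], grid$z[i], detail), call. = FALSE)
  }
  stats <- data.frame(
    t = vapply(res, `[[`, numeric(1), "t"),
    c = vapply(res, `[[`, numeric(1), "c"),
    z = vapply(res, `[[`, numeric(1), "z"),
    mean = vapply(res, `[[`, numeric(1), "mean"),
    max = vapply(res, `[[`, numeric(1), "max")
  )
  write_plane_stats(stats, file.path(output_dir, "plane_stats.tsv"))
  h5 <- NULL
  if (isTRUE(export_hdf5)) {
    h5 <- file.path(output_dir, paste0(stem, ".h5"))
    export_hdf5(open_devils_folder(output_dir, voxel_size = stack$voxel_size), h5)
  }
  invisible(list(output_dir = output_dir, stats = stats,
                 files = vapply(res, `[[`, character(1), "file"),
                 scales = scales, hdf5 = h5))
}

with_scale <- function(params, s) {
  params$division_scale <- s
  params
}

write_plane_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Preview one plane
#'
#' Processes a single plane without writing anything -- the quick way to tune
#' `p` and the conversion bounds before launching a full run. Indices are
#' 0-based; `"middle"` picks the central index of an axis.
#'
#' @param stack A [lazy_stack].
#' @param t,c,z Plane indices (0-based) or `"middle"`.
#' @param params A [devils_params()].
#' @return A list with `original`, `processed` (both unconverted), and
#'   `indices` (the resolved `c(t, c, z)`).
#' @export
preview_plane <- function(stack, t = "middle", c = "middle", z = "middle",
                          params = devils_params(p = 25)) {
  if (!inherits(stack, "lazy_stack")) {
    stop("`stack` must be a lazy_stack", call. = FALSE)
  }
  assert_params(params)
  t <- resolve_middle(t, stack$n_t, "t")
  c <- resolve_middle(c, stack$n_c, "c")
  z <- resolve_middle(z, stack$n_z, "z")
  original <- stack$get_plane(t, c, z)
  list(original = original,
       processed = devils_transform(original, params),
       indices = c(t = t, c = c, z = z))
}

resolve_middle <- function(i, n, axis) {
  if (identical(i, "middle")) return(n %/% 2L)
  check_index(i, n, axis)
  as.integer(i)
}

#' Per-plane intensity statistics
#'
#' Mean and maximum intensity of every plane of a stack, one row per
#' `(t, c, z)`. Plotted against z this is the per-plane intensity profile
#' used to judge depth-dependent falloff -- and how much plane-wise tone
#' mapping flattens it.
#'
#' @param stack A [lazy_stack].
#' @return A data frame with columns `t`, `c`, `z`, `mean`, `max`.
#' @export
plane_stats <- function(stack) {
  if (!inherits(stack, "lazy_stack")) {
    stop("`stack` must be a lazy_stack", call. = FALSE)
  }
  grid <- expand.grid(z = 0:(stack$n_z - 1L), c = 0:(stack$n_c - 1L),
                      t = 0:(stack$n_t - 1L))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pl <- stack$get_plane(grid$t[i], grid$c[i], grid$z[i])
    data.frame(t = grid$t[i], c = grid$c[i], z = grid$z[i],
               mean = mean(pl), max = max(pl))
  })
  do.call(rbind, rows)
}
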