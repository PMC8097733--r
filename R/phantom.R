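#' Disk-grid phantom description
#'
#' Describes the synthetic benchmark image: a grid of uniform disks whose
#' intensity increases left to right and whose diameter increases top to
#' bottom, on a faint constant background with additive Gaussian noise. The
#' defaults give a 512 x 512, 8-bit-range image with 49 disks (intensities
#' 5, 10, 20, 50, 100, 150, 250 by column; diameters 7, 9, 11, 15, 20, 25, 50
#' px by row; background 2; noise SD 0.5), the configuration used throughout
#' the package's quantitative validation.
#'
#' @param intensities Strictly increasing positive disk intensities, one per
#'   column (left to right).
#' @param diameters Strictly increasing positive disk diameters in pixels,
#'   one per row (top to bottom).
#' @param background Constant added to the whole image.
#' @param noise_sd Standard deviation of the additive Gaussian noise (>= 0).
#' @param cell_size Grid pitch in pixels; every disk must fit its cell.
#' @param margin Blank border around the grid, in pixels.
#' @param seed Default seed used by [generate_disk_image()] when none is given.
#' @param clip_max Intensities are clipped to `[0, clip_max]` after noise;
#'   default 255 (an 8-bit phantom).
#' @return An object of class `disk_grid_spec`.
#' @export
disk_grid_spec <- function(intensities = c(5, 10, 20, 50, 100, 150, 250),
                           diameters = c(7, 9, 11, 15, 20, 25, 50),
                           background = 2,
                           noise_sd = 0.5,
                           cell_size = 70,
                           margin = 11,
                           seed = 1,
                           clip_max = 255) {
  if (length(intensities) < 1 || any(intensities <= 0) ||
      is.unsorted(intensities, strictly = TRUE)) {
    stop("`intensities` must be positive and strictly increasing", call. = FALSE)
  }
  if (length(diameters) < 1 || any(diameters <= 0) ||
      is.unsorted(diameters, strictly = TRUE)) {
    stop("`diameters` must be positive and strictly increasing", call. = FALSE)
  }
  assert_scalar(background, "background")
  assert_scalar(noise_sd, "noise_sd")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  assert_scalar(cell_size, "cell_size", positive = TRUE)
  assert_scalar(margin, "margin")
  if (margin < 0) stop("`margin` must be >= 0", call. = FALSE)
  assert_scalar(clip_max, "clip_max", positive = TRUE)
  if (max(diameters) > cell_size) {
    stop("largest disk does not fit the grid cell", call. = FALSE)
  }
  structure(
    list(intensities = as.numeric(intensities),
         diameters = as.numeric(diameters),
         background = as.numeric(background),
         noise_sd = as.numeric(noise_sd),
         cell_size = as.integer(cell_size),
         margin = as.integer(margin),
         seed = seed,
         clip_max = as.numeric(clip_max)),
    class = "disk_grid_spec"
  )
}

#' Generate the disk-grid phantom
#'
#' Rasterizes the phantom described by a [disk_grid_spec()]: each disk is the
#' set of pixels whose center lies strictly within `diameter / 2` of the disk
#' center (a 7 px disk covers exactly 37 pixels), disks are centered on the
#' integer pixel nearest their cell center, the background constant is added
#' everywhere, Gaussian noise is added, and the image is clipped to
#' `[0, clip_max]`. The noise is the only random component, so masks are
#' seed-independent and the image is reproducible for a fixed seed.
#'
#' @param spec A [disk_grid_spec()].
#' @param seed Integer seed for the noise; defaults to `spec$seed`.
#' @return A list with `image` (numeric matrix), and `masks`: one entry per
#'   disk (row-major over the grid) holding `diameter`, `intensity`, `row`,
#'   `col` (grid position), `center` (pixel coordinates) and `mask` (logical
#'   footprint matrix).
#' @examples
#' ph <- generate_disk_image(disk_grid_spec(), seed = 1)
#' dim(ph$image)
#' length(ph$masks)
#' @export
generate_disk_image <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "disk_grid_spec")) {
    stop("`spec` must be created with disk_grid_spec()", call. = FALSE)
  }
  n_rows <- length(spec$diameters)
  n_cols <- length(spec$intensities)
  h <- 2L * spec$margin + spec$cell_size * n_rows
  w <- 2L * spec$margin + spec$cell_size * n_cols
  img <- matrix(spec$background, h, w)
  rowc <- row(img)
  colc <- col(img)
  masks <- vector("list", n_rows * n_cols)
  k <- 0L
  for (i in seq_len(n_rows)) {
    for (j in seq_len(n_cols)) {
      k <- k + 1L
      cr <- spec$margin + (i - 1L) * spec$cell_size + ceiling(spec$cell_size / 2)
      cc <- spec$margin + (j - 1L) * spec$cell_size + ceiling(spec$cell_size / 2)
      d <- spec$diameters[i]
      m <- (rowc - cr)^2 + (colc - cc)^2 < (d / 2)^2
      img[m] <- img[m] + spec$intensities[j]
      masks[[k]] <- list(diameter = d, intensity = spec$intensities[j],
                         row = i, col = j, center = c(cr, cc), mask = m)
    }
  }
  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(seed, {
      matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    })
    img <- img + noise
  }
  img <- pmin(pmax(img, 0), spec$clip_max)
  list(image = img, masks = masks)
}

# Binary erosion with the 4-neighbour cross (shrink a footprint by one pixel).
erode_mask_cross <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  ctr <- pad[2:(h + 1L), 2:(w + 1L)]
  ctr & pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
}

#' Per-disk intensity amplification
#'
#' Quantifies how processing changed each disk of the phantom: for every disk,
#' the mean intensity over its footprint in the original and in the processed
#' plane, and their ratio (the amplification factor). Means are taken over the
#' one-pixel-eroded footprint so partially covered rim pixels do not bias
#' them; if erosion empties a footprint the full footprint is used and the row
#' is flagged (`eroded = FALSE`). No background correction is applied: the
#' ratio compares plain mean intensities.
#'
#' The summary `max_amplification_ratio` is the amplification of the smallest,
#' dimmest disk divided by that of the largest, brightest disk -- the dynamic
#' range compression achieved across the grid. Both share the same dependence
#' on the division scale, so the summary is essentially scale-free.
#'
#' @param original,processed Planes of identical dimensions.
#' @param masks Disk mask list, as produced by [generate_disk_image()].
#' @return An object of class `amplification_report`: a list with `table`
#'   (data frame with columns diameter, intensity, input_mean, output_mean,
#'   amplification, eroded), `max_amplification_ratio`, and
#'   `calibrated_scale` (`NA` unless filled in by the caller).
#' @export
measure_amplification <- function(original, processed, masks) {
  assert_plane(original, "original")
  assert_plane(processed, "processed")
  if (!all(dim(original) == dim(processed))) {
    stop("`original` and `processed` must have identical dimensions", call. = FALSE)
  }
  if (!is.list(masks) || length(masks) == 0) {
    stop("`masks` must be a nonempty list", call. = FALSE)
  }
  rows <- lapply(masks, function(mk) {
    m <- erode_mask_cross(mk$mask)
    eroded <- TRUE
    if (!any(m)) {
      m <- mk$mask
      eroded <- FALSE
    }
    inm <- mean(original[m])
    outm <- mean(processed[m])
    data.frame(diameter = mk$diameter, intensity = mk$intensity,
               input_mean = inm, output_mean = outm,
               amplification = outm / inm, eroded = eroded)
  })
  tab <- do.call(rbind, rows)
  if (any(tab$input_mean <= 0)) {
    stop("every disk must have positive input mean", call. = FALSE)
  }
  sm <- tab$diameter == min(tab$diameter) & tab$intensity == min(tab$intensity)
  lg <- tab$diameter == max(tab$diameter) & tab$intensity == max(tab$intensity)
  structure(
    list(table = tab,
         max_amplification_ratio =
           tab$amplification[sm][1] / tab$amplification[lg][1],
         calibrated_scale = NA_real_),
    class = "amplification_report"
  )
}

#' @export
print.amplification_report <- function(x, ...) {
  cat("amplification_report:", nrow(x$table), "disks\n")
  print(utils::head(x$table, 10))
  if (nrow(x$table) > 10) cat("  ...\n")
  cat(sprintf("max_amplification_ratio (smallest/dimmest over largest/brightest): %.3g\n",
              x$max_amplification_ratio))
  if (!is.na(x$calibrated_scale)) {
    cat(sprintf("calibrated_scale: %.6g\n", x$calibrated_scale))
  }
  invisible(x)
}

#' Calibrate the division scale on the phantom
#'
#' Resolves the `"auto"` division scale: finds the scale `s` for which the
#' tone-mapping operator leaves the mean amplification of the intensity-20
#' column of the noise-free phantom at 1 (disks of intensity 20 keep their
#' mean intensity). Before background subtraction the operator output is
#' exactly proportional to `sqrt(s)`, so a probe run at one scale predicts the
#' answer as `s <- s * (1 / amplification)^2`; the subtraction perturbs that
#' slightly, so the update is iterated until the column amplification is
#' within `tol` of 1.
#'
#' @param spec A [disk_grid_spec()]; its noise is ignored (calibration runs on
#'   the noise-free phantom). If no intensity-20 column exists the nearest
#'   column is used, with a warning.
#' @param params A [devils_params()]; its `division_scale` entry is ignored.
#' @param tol Convergence tolerance on the column amplification (default 0.01).
#' @return The calibrated scale (positive number), with the number of probe
#'   runs in attribute `"iterations"`.
#' @export
calibrate_scale <- function(spec, params, tol = 0.01) {
  if (!inherits(spec, "disk_grid_spec")) {
    stop("`spec` must be created with disk_grid_spec()", call. = FALSE)
  }
  assert_params(params)
  spec0 <- spec
  spec0$noise_sd <- 0
  ph <- generate_disk_image(spec0, seed = 0L)
  if (all(ph$image == 0)) stop("degenerate (all-zero) phantom", call. = FALSE)
  jcol <- which(spec$intensities == 20)
  if (length(jcol) == 0) {
    jcol <- which.min(abs(spec$intensities - 20))
    warning(sprintf("no intensity-20 column; calibrating on nearest (I = %g)",
                    spec$intensities[jcol]))
  }
  jcol <- jcol[1]
  in_col <- vapply(ph$masks, function(mk) mk$col == jcol, logical(1))
  col_amp <- function(processed) {
    rep <- measure_amplification(ph$image, processed, ph$masks[in_col])
    mean(rep$table$amplification)
  }
  # The blur and the ratio image do not depend on s; only the opening does.
  q <- sqrt_transform(divide_by_blur(ph$image, params$sigma, scale = 1,
                                     epsilon = params$epsilon))
  bg_src <- if (isTRUE(params$presmooth)) mean3x3(q) else q
  s <- 1
  for (it in seq_len(10L)) {
    out <- sqrt(s) * q -
      rolling_ball_background(sqrt(s) * bg_src, params$ball_radius)
    a <- col_amp(out)
    if (abs(a - 1) <= tol) {
      return(structure(s, iterations = it))
    }
    s <- s * (1 / a)^2
  }
  stop("scale calibration did not converge", call. = FALSE)
}

#' Extract a line profile
#'
#' Returns the 1D intensity sequence along one full row or column of a plane,
#' as plotted over the phantom disks.
#'
#' @inheritParams gaussian_blur
#' @param axis `"row"` (values along a given row) or `"column"`.
#' @param index 1-based row or column index.
#' @return Numeric vector of intensities.
#' @export
line_profile <- function(plane, axis = c("row", "column"), index) {
  assert_plane(plane)
  axis <- match.arg(axis)
  n <- if (axis == "row") nrow(plane) else ncol(plane)
  if (!is.numeric(index) || length(index) != 1L || index < 1 || index > n ||
      index != round(index)) {
    stop(sprintf("`index` must be an integer in [1, %d]", n), call. = FALSE)
  }
  if (axis == "row") plane[index, ] else plane[, index]
}

#' Edge-artefact index of a processed disk
#'
#' When the object-size parameter `p` is smaller than a disk, the rolling ball
#' enters the disk and carves out its interior, leaving a bright rim. This
#' index quantifies the dip: the mean intensity over the outer band of the
#' footprint (pixels within `band_px` of the nearest outside pixel, by
#' Euclidean distance) divided by the mean over the remaining interior.
#' A uniform disk gives 1; a value above 1 indicates the rim artefact.
#'
#' @param processed Processed plane.
#' @param mask Logical footprint matrix (or a mask entry from
#'   [generate_disk_image()]).
#' @param band_px Width of the edge band in pixels (>= 1).
#' @return The band/interior mean ratio.
#' @export
edge_artifact_index <- function(processed, mask, band_px = 5) {
  assert_plane(processed, "processed")
  if (is.list(mask)) mask <- mask$mask
  if (!is.matrix(mask) || !is.logical(mask) || !any(mask)) {
    stop("`mask` must be a logical matrix with at least one TRUE pixel", call. = FALSE)
  }
  assert_scalar(band_px, "band_px")
  if (band_px < 1) stop("`band_px` must be >= 1", call. = FALSE)
  d <- distance_to_outside(mask)
  band <- mask & d <= band_px
  interior <- mask & d > band_px
  if (!any(interior) || !any(band)) {
    stop("degenerate mask: footprint not larger than the edge band", call. = FALSE)
  }
  mean(processed[band]) / mean(processed[interior])
}

# Euclidean distance from each footprint pixel to the nearest pixel outside
# the footprint, computed against the outside pixels 4-adjacent to the mask.
distance_to_outside <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  nb <- pad[1:h, 2:(w + 1L)] | pad[3:(h + 2L), 2:(w + 1L)] |
    pad[2:(h + 1L), 1:w] | pad[2:(h + 1L), 3:(w + 2L)]
  boundary_out <- !mask & nb
  if (!any(boundary_out)) {
    # mask touches every border: fall back against all outside pixels
    boundary_out <- !mask
  }
  idx_in <- which(mask, arr.ind = TRUE)
  idx_out <- which(boundary_out, arr.ind = TRUE)
  d2 <- outer(idx_in[, 1], idx_out[, 1], "-")^2 +
    outer(idx_in[, 2], idx_out[, 2], "-")^2
  d <- matrix(Inf, h, w)
  d[mask] <- sqrt(apply(d2, 1, min))
  d
}

#' Synthetic z-bell stack
#'
#' Generates a small multi-plane stack whose per-plane mean intensity follows
#' a bell (Gaussian) profile along z, emulating the depth-dependent intensity
#' falloff of a volumetric acquisition: every plane contains the same pattern
#' of disks on a faint background, scaled by
#' `exp(-(z - (n_z - 1) / 2)^2 / (2 * sd_z^2))`, plus noise. Used to
#' demonstrate that plane-wise tone mapping flattens the per-plane mean curve.
#'
#' @param n_z Number of planes.
#' @param side Plane side length in pixels (square planes).
#' @param peak Disk intensity at the bell's peak plane.
#' @param background Constant background added before scaling.
#' @param sd_z Standard deviation of the bell along z, in planes.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @return A [lazy_stack] with `n_z` planes (one channel, one timepoint).
#' @export
generate_bell_stack <- function(n_z = 12, side = 64, peak = 200,
                                background = 5, sd_z = 2.5, noise_sd = 1,
                                seed = 1) {
  assert_scalar(side, "side", positive = TRUE)
  if (n_z < 2) stop("`n_z` must be >= 2", call. = FALSE)
  base <- matrix(background, side, side)
  centers <- round(side * c(0.3, 0.7))
  rowc <- row(base); colc <- col(base)
  for (cr in centers) {
    for (cc in centers) {
      base[(rowc - cr)^2 + (colc - cc)^2 < (side / 10)^2] <- peak
    }
  }
  zmid <- (n_z - 1) / 2
  planes <- withr::with_seed(seed, {
    lapply(seq_len(n_z) - 1L, function(z) {
      bell <- exp(-(z - zmid)^2 / (2 * sd_z^2))
      pmax(base * bell +
             matrix(stats::rnorm(side * side, 0, noise_sd), side, side), 0)
    })
  })
  as_lazy_stack(planes, n_c = 1L, n_t = 1L, source = "bell-phantom")
}
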