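#' Export a stack as a BigDataViewer HDF5 dataset
#'
#' Writes the stack in the chunked HDF5 layout that BigDataViewer reads, plus
#' the companion XML: one setup per channel (`s00`, `s01`, ...) with
#' single-level `resolutions` / `subdivisions` arrays at the file root, and
#' one 3D `cells` dataset per timepoint and setup at
#' `t{TTTTT}/s{SS}/0/cells`, chunked at most 64 px per axis and stored as
#' 16-bit integers (values are rounded, clipped to `[0, 65535]` and stored
#' with unsigned semantics). The XML describes the setups, image size, voxel
#' size and the HDF5 loader, with identity view registrations.
#'
#' @param stack A [lazy_stack]; its values should already be converted
#'   (integer-valued in `[0, 65535]`), as produced by [process_stack()].
#' @param path Output `.h5` path; the XML sidecar is written next to it with
#'   the same stem.
#' @return Invisibly, `c(h5 = path, xml = xml_path)`.
#' @examples
#' st <- as_lazy_stack(replicate(4, matrix(round(runif(64, 0, 1000)), 8, 8),
#'                               simplify = FALSE))
#' \dontrun{export_hdf5(st, "stack.h5")}
#' @export
export_hdf5 <- function(stack, path) {
  if (!inherits(stack, "lazy_stack")) {
    stop("`stack` must be a lazy_stack", call. = FALSE)
  }
  if (!grepl("\\.h5$", path)) path <- paste0(path, ".h5")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (file.exists(path)) file.remove(path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stop(sprintf("cannot create HDF5 file '%s'", path), call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  w <- stack$width; h <- stack$height; d <- stack$n_z
  chunk <- c(min(64L, w), min(64L, h), min(64L, d))
  for (ci in 0:(stack$n_c - 1L)) {
    grp <- sprintf("s%02d", ci)
    rhdf5::h5createGroup(path, grp)
    rhdf5::h5write(matrix(c(1, 1, 1), 1, 3), path,
                   paste0(grp, "/resolutions"))
    rhdf5::h5write(matrix(as.integer(chunk), 1, 3), path,
                   paste0(grp, "/subdivisions"))
  }
  for (ti in 0:(stack$n_t - 1L)) {
    tgrp <- sprintf("t%05d", ti)
    rhdf5::h5createGroup(path, tgrp)
    for (ci in 0:(stack$n_c - 1L)) {
      sgrp <- sprintf("%s/s%02d", tgrp, ci)
      rhdf5::h5createGroup(path, sgrp)
      rhdf5::h5createGroup(path, paste0(sgrp, "/0"))
      ds <- paste0(sgrp, "/0/cells")
      # R dims (x, y, z) appear reversed, (z, y, x), at the file level --
      # the C-order layout BigDataViewer expects.
      rhdf5::h5createDataset(path, ds, dims = c(w, h, d), chunk = chunk,
                             H5type = "H5T_STD_I16LE")
      a <- array(0L, dim = c(w, h, d))
      for (zi in 0:(d - 1L)) {
        pl <- round(pmin(pmax(stack$get_plane(ti, ci, zi), 0), 65535))
        a[, , zi + 1L] <- as.integer(t(pl))
      }
      a[a > 32767L] <- a[a > 32767L] - 65536L
      rhdf5::h5write(a, path, ds)
    }
  }
  xml_path <- sub("\\.h5$", ".xml", path)
  write_bdv_xml(stack, path, xml_path)
  invisible(c(h5 = path, xml = xml_path))
}

write_bdv_xml <- function(stack, h5_path, xml_path) {
  vs <- stack$voxel_size %||% c(1, 1, 1)
  doc <- xml2::xml_new_root("SpimData", version = "0.2")
  xml2::xml_add_child(doc, "BasePath", ".", type = "relative")
  seq <- xml2::xml_add_child(doc, "SequenceDescription")
  loader <- xml2::xml_add_child(seq, "ImageLoader", format = "bdv.hdf5")
  xml2::xml_add_child(loader, "hdf5", basename(h5_path), type = "relative")
  setups <- xml2::xml_add_child(seq, "ViewSetups")
  for (ci in 0:(stack$n_c - 1L)) {
    vs_node <- xml2::xml_add_child(setups, "ViewSetup")
    xml2::xml_add_child(vs_node, "id", as.character(ci))
    xml2::xml_add_child(vs_node, "name", sprintf("channel %d", ci))
    xml2::xml_add_child(vs_node, "size",
                        paste(stack$width, stack$height, stack$n_z))
    vox <- xml2::xml_add_child(vs_node, "voxelSize")
    xml2::xml_add_child(vox, "unit", "micrometer")
    xml2::xml_add_child(vox, "size", paste(vs[1], vs[2], vs[3]))
    attrs <- xml2::xml_add_child(vs_node, "attributes")
    xml2::xml_add_child(attrs, "channel", as.character(ci))
  }
  chan_attrs <- xml2::xml_add_child(setups, "Attributes", name = "channel")
  for (ci in 0:(stack$n_c - 1L)) {
    ch <- xml2::xml_add_child(chan_attrs, "Channel")
    xml2::xml_add_child(ch, "id", as.character(ci))
    xml2::xml_add_child(ch, "name", as.character(ci))
  }
  tp <- xml2::xml_add_child(seq, "Timepoints", type = "range")
  xml2::xml_add_child(tp, "first", "0")
  xml2::xml_add_child(tp, "last", as.character(stack$n_t - 1L))
  regs <- xml2::xml_add_child(doc, "ViewRegistrations")
  for (ti in 0:(stack$n_t - 1L)) {
    for (ci in 0:(stack$n_c - 1L)) {
      reg <- xml2::xml_add_child(regs, "ViewRegistration",
                                 timepoint = as.character(ti),
                                 setup = as.character(ci))
      tr <- xml2::xml_add_child(reg, "ViewTransform", type = "affine")
      xml2::xml_add_child(tr, "affine",
                          paste(vs[1], 0, 0, 0, 0, vs[2], 0, 0, 0, 0, vs[3], 0))
    }
  }
  xml2::write_xml(doc, xml_path)
  invisible(xml_path)
}

#' Read back a BigDataViewer HDF5 dataset
#'
#' Reads one `cells` dataset written by [export_hdf5()] and restores unsigned
#' 16-bit semantics. Mainly used to verify round trips.
#'
#' @param path `.h5` file.
#' @param t,c Timepoint and setup (channel), 0-based.
#' @return A 3D array indexed `[x, y, z]`.
#' @export
read_hdf5_cells <- function(path, t = 0L, c = 0L) {
  ds <- sprintf("t%05d/s%02d/0/cells", t, c)
  a <- rhdf5::h5read(path, ds)
  rhdf5::h5closeAll()
  dims <- dim(a)
  v <- as.integer(a)
  v <- v + ifelse(v < 0L, 65536L, 0L)
  # h5read returns the R-dims (x, y, z) layout written by export_hdf5()
  array(v, dim = dims)
}
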